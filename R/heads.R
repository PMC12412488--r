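#' Prediction heads on the final atom states
#'
#' All self-supervised targets are predicted from the final atom states:
#' pair targets (bond length, binned distance, bond order) from the sum of
#' the two endpoint states (symmetric by construction); angles from the
#' apex state concatenated with the sum of the end states; dihedrals from
#' the two symmetric end/center sums. Each head is a two-layer perceptron.
#' @name heads
#' @keywords internal
NULL

mlp2_fwd <- function(par, X) {
  u1 <- sweep(X %*% par$W1, 2, par$b1, `+`)
  r1 <- pmax(u1, 0)
  y <- sweep(r1 %*% par$W2, 2, par$b2, `+`)
  list(y = y, cache = list(X = X, u1 = u1, r1 = r1))
}

mlp2_bwd <- function(par, cache, dy) {
  dW2 <- t(cache$r1) %*% dy
  db2 <- colSums(dy)
  dr1 <- dy %*% t(par$W2)
  du1 <- dr1 * (cache$u1 > 0)
  dW1 <- t(cache$X) %*% du1
  db1 <- colSums(du1)
  dX <- du1 %*% t(par$W1)
  list(dX = dX, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Initialize the six self-supervised heads
#'
#' Output biases of the scalar regression heads start at the typical
#' scale of their target family (1.45 A for bond lengths, 1.95 rad for
#' bond angles, 1 for bond orders), so early optimization refines
#' deviations instead of first climbing to the target scale.
#'
#' @param hidden encoder hidden width.
#' @param n_bins number of distance classes (default 30).
#' @param dihedral_out 2 for the (sin, cos) target, 1 for raw angle.
#' @param seed seed for the weight draw.
#' @return named list of head parameter sets.
#' @export
init_heads <- function(hidden, n_bins = 30, dihedral_out = 2, seed = 1) {
  set.seed(seed)
  heads <- list(length = mlp2_init(hidden, hidden, 1),
                angle = mlp2_init(2 * hidden, hidden, 1),
                dihedral = mlp2_init(2 * hidden, hidden, dihedral_out),
                distance = mlp2_init(hidden, hidden, n_bins),
                charge = mlp2_init(hidden, hidden, 1),
                wiberg = mlp2_init(hidden, hidden, 1))
  heads$length$b2 <- 1.45
  heads$angle$b2 <- 1.95
  heads$wiberg$b2 <- 1
  heads
}

#' Evaluate the self-supervised heads for one masked molecule
#'
#' @param heads from [init_heads()].
#' @param h_atom final atom states (n x hidden).
#' @param graph the molecule's `t3d_trigraph`.
#' @param plan a `t3d_mask_plan`.
#' @return list of predictions aligned with the plan's masked index sets:
#'   `length`, `angle`, `dihedral` (matrix), `distance` (logits over the
#'   plan's `dist_pairs`), `charge`, `wiberg`, plus forward caches.
#' @export
predict_ssl_heads <- function(heads, h_atom, graph, plan) {
  HK <- h_atom
  inputs <- ssl_head_inputs(HK, graph, plan)
  out <- list(inputs = inputs, caches = list())
  for (nm in names(inputs)) {
    f <- mlp2_fwd(heads[[nm]], inputs[[nm]]$X)
    out[[nm]] <- if (ncol(f$y) == 1) drop(f$y) else f$y
    if (length(out[[nm]]) == 0 && ncol(f$y) > 1) {
      out[[nm]] <- f$y  # keep 0-row matrix shape
    }
    out$caches[[nm]] <- f$cache
  }
  out
}

ssl_head_inputs <- function(HK, graph, plan) {
  h <- ncol(HK)
  pick <- function(idx) HK[idx, , drop = FALSE]
  mb <- plan$masked_bonds
  ma <- plan$masked_angles
  md <- plan$masked_dihedrals
  bonds <- graph$bonds[mb, , drop = FALSE]
  angles <- graph$angles[ma, , drop = FALSE]
  dihedrals <- graph$dihedrals[md, , drop = FALSE]
  pairs <- plan$dist_pairs
  list(
    length = list(X = pick(bonds$i) + pick(bonds$j),
                  atoms = cbind(bonds$i, bonds$j)),
    angle = list(X = cbind(pick(angles$u) + pick(angles$w), pick(angles$v)),
                 atoms = cbind(angles$u, angles$w, angles$v)),
    dihedral = list(X = cbind(pick(dihedrals$u) + pick(dihedrals$x),
                              pick(dihedrals$v) + pick(dihedrals$w)),
                    atoms = cbind(dihedrals$u, dihedrals$x,
                                  dihedrals$v, dihedrals$w)),
    distance = list(X = pick(pairs[, 1]) + pick(pairs[, 2]),
                    atoms = pairs),
    charge = list(X = pick(plan$masked_atoms),
                  atoms = cbind(plan$masked_atoms)),
    wiberg = list(X = pick(bonds$i) + pick(bonds$j),
                  atoms = cbind(bonds$i, bonds$j)))
}

# Scatter a head-input gradient back onto the atom states. `atoms` columns
# are grouped per hidden-width block of the input: pair-sum heads have one
# block shared by several atom columns; concatenated heads have one block
# per column group.
head_input_to_atoms <- function(dX, atoms, blocks, n_atoms) {
  h <- ncol(dX) / length(blocks)
  dH <- matrix(0, n_atoms, h)
  for (b in seq_along(blocks)) {
    cols <- ((b - 1) * h + 1):(b * h)
    for (ac in blocks[[b]]) {
      dH <- dH + scatter_sum(dX[, cols, drop = FALSE], atoms[, ac], n_atoms)
    }
  }
  dH
}

head_blocks <- list(
  length = list(1:2),
  angle = list(1:2, 3),
  dihedral = list(1:2, 3:4),
  distance = list(1:2),
  charge = list(1),
  wiberg = list(1:2))
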