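#' Multiscale self-supervised learning
#'
#' Pretraining masks 15% of the atoms (at least one) together with their
#' first-order neighborhood -- the features of the selected atoms, their
#' adjacent atoms, the connecting bonds, and every angle and dihedral that
#' contains a selected atom -- and predicts, from the final hidden states:
#' masked bond lengths, bond angles, and dihedral angles (mean squared
#' error, dihedrals via their sine/cosine pair), the binned interatomic
#' distance over atom pairs (30-class cross-entropy), and, in the
#' electronic stage, the partial charge of masked atoms and the
#' Wiberg-style order of masked bonds (mean squared error).
#' @name ssl
NULL

hash_id <- function(id) {
  v <- utf8ToInt(id)
  s <- 0
  for (k in seq_along(v)) s <- (s * 31 + v[k]) %% 2147483647
  as.integer(s)
}

#' Build a mask plan for one molecule
#'
#' Selects `max(1, ceiling(rate * n_atoms))` atoms uniformly without
#' replacement. Targets are the selected atoms, the bonds/angles/dihedrals
#' containing a selected atom; the features of the adjacent atoms are
#' hidden as well (`context_atoms`). Also draws the (sub)sampled ordered
#' atom-pair set used by the distance task. Deterministic for fixed seed.
#'
#' @param mol a `t3d_molecule`.
#' @param graph its `t3d_trigraph`.
#' @param rate masking fraction in (0, 1] (default 0.15).
#' @param seed integer seed.
#' @param max_dist_pairs cap on the ordered atom pairs used by the
#'   distance task (default 500).
#' @return a `t3d_mask_plan`.
#' @export
make_mask <- function(mol, graph, rate = 0.15, seed = 1,
                      max_dist_pairs = 500) {
  if (!(rate > 0 && rate <= 1)) {
    stop(t3d_error("t3d_value_error", "mask rate must be in (0, 1]"))
  }
  n <- graph$n_atoms
  k <- max(1L, as.integer(ceiling(rate * n)))
  set.seed(seed)
  sel <- sort(sample.int(n, k))
  in_sel <- logical(n); in_sel[sel] <- TRUE
  b <- graph$bonds
  masked_bonds <- which(in_sel[b$i] | in_sel[b$j])
  context_atoms <- setdiff(sort(unique(unlist(graph$nbrs[sel]))), sel)
  a <- graph$angles
  masked_angles <- which(in_sel[a$u] | in_sel[a$v] | in_sel[a$w])
  d <- graph$dihedrals
  masked_dihedrals <- which(in_sel[d$u] | in_sel[d$v] | in_sel[d$w] |
                              in_sel[d$x])
  if (n > 1) {
    all_pairs <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), n))
    all_pairs <- all_pairs[all_pairs[, 1] != all_pairs[, 2], , drop = FALSE]
    if (nrow(all_pairs) > max_dist_pairs) {
      all_pairs <- all_pairs[sample.int(nrow(all_pairs), max_dist_pairs), ,
                             drop = FALSE]
    }
  } else {
    all_pairs <- matrix(integer(), 0, 2)
  }
  structure(list(masked_atoms = sel, context_atoms = context_atoms,
                 masked_bonds = masked_bonds,
                 masked_angles = masked_angles,
                 masked_dihedrals = masked_dihedrals,
                 dist_pairs = all_pairs, rate = rate, seed = seed),
            class = "t3d_mask_plan")
}

#' Equal-width distance binner
#'
#' @param n_bins number of classes (default 30).
#' @param lower,upper range in Angstrom (default [0, 15]); distances
#'   outside are clamped into the edge bins.
#' @return a `t3d_distance_binner`.
#' @export
distance_binner <- function(n_bins = 30, lower = 0, upper = 15) {
  stopifnot(n_bins >= 2, upper > lower)
  structure(list(n_bins = n_bins, lower = lower, upper = upper,
                 width = (upper - lower) / n_bins),
            class = "t3d_distance_binner")
}

#' Map a distance to its class index
#'
#' `floor((d - lower) / width)` clamped to `[0, n_bins - 1]`.
#'
#' @param d nonnegative distance(s) in Angstrom.
#' @param binner a `t3d_distance_binner`.
#' @return integer class index in `[0, n_bins - 1]` (0-based).
#' @export
bin_distance <- function(d, binner = distance_binner()) {
  stopifnot(all(d >= 0))
  idx <- floor((d - binner$lower) / binner$width)
  as.integer(pmax(0, pmin(binner$n_bins - 1, idx)))
}

#' Assemble a loss breakdown
#'
#' @param terms named numeric vector over the six loss families.
#' @param counts contributing item counts per term.
#' @param weights per-term weights (default 1); the total is the weighted
#'   sum over terms with at least one contributing item.
#' @return a `t3d_loss_breakdown`.
#' @export
loss_breakdown <- function(terms, counts, weights = NULL) {
  fam <- c("length", "angle", "dihedral", "distance", "charge", "wiberg")
  full <- stats::setNames(rep(0, 6), fam)
  full[names(terms)] <- terms
  cnt <- stats::setNames(rep(0L, 6), fam)
  cnt[names(counts)] <- counts
  if (is.null(weights)) weights <- stats::setNames(rep(1, 6), fam)
  w <- stats::setNames(rep(0, 6), fam)
  w[names(weights)] <- weights
  structure(list(terms = full, counts = cnt, weights = w,
                 total = sum(w * full)),
            class = "t3d_loss_breakdown")
}

#' @export
print.t3d_loss_breakdown <- function(x, ...) {
  active <- x$counts > 0
  cat("<loss breakdown> total =", format(x$total, digits = 6), "\n")
  for (nm in names(x$terms)[active]) {
    cat(sprintf("  %-9s %10.6f  (n = %d, w = %g)\n", nm, x$terms[[nm]],
                x$counts[[nm]], x$weights[[nm]]))
  }
  invisible(x)
}

softmax_rows <- function(L) {
  mx <- apply(L, 1, max)
  e <- exp(L - mx)
  e / rowSums(e)
}

#' Geometric self-supervised losses
#'
#' Mean squared error over the masked bonds/angles/dihedrals (degenerate
#' collinear frames excluded) and mean 30-class cross-entropy of the
#' binned distance over the plan's atom-pair set. Dihedral targets are
#' compared through their (sin, cos) pair by default, which respects the
#' 2-pi periodicity; pass a one-column prediction for the raw-angle mode.
#'
#' @param predictions list with `length`, `angle` (numeric, aligned with
#'   the plan's masked sets), `dihedral` (matrix, 2 columns for sin/cos or
#'   1 for raw theta), `distance` (logit matrix over `plan$dist_pairs`).
#' @param geo the molecule's `t3d_geometry` (the targets).
#' @param plan the `t3d_mask_plan`.
#' @param binner the `t3d_distance_binner`.
#' @param weights optional per-term weights.
#' @return a `t3d_loss_breakdown` over the four geometric terms.
#' @export
geometric_losses <- function(predictions, geo, plan,
                             binner = distance_binner(), weights = NULL) {
  terms <- c(length = 0, angle = 0, dihedral = 0, distance = 0)
  counts <- c(length = 0L, angle = 0L, dihedral = 0L, distance = 0L)

  mb <- plan$masked_bonds
  if (length(mb) > 0) {
    terms[["length"]] <- mean((predictions$length - geo$lengths[mb])^2)
    counts[["length"]] <- length(mb)
  }
  ma <- plan$masked_angles
  va <- ma[!geo$angle_degenerate[ma]]
  if (length(va) > 0) {
    keep <- !geo$angle_degenerate[ma]
    terms[["angle"]] <- mean((predictions$angle[keep] - geo$angles[va])^2)
    counts[["angle"]] <- length(va)
  }
  md <- plan$masked_dihedrals
  keep <- !geo$dihedral_degenerate[md]
  vd <- md[keep]
  if (length(vd) > 0) {
    pred <- predictions$dihedral
    if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1)
    pred <- pred[keep, , drop = FALSE]
    th <- geo$dihedrals[vd]
    if (ncol(pred) == 2) {
      terms[["dihedral"]] <- mean((pred[, 1] - sin(th))^2 +
                                    (pred[, 2] - cos(th))^2)
    } else {
      terms[["dihedral"]] <- mean((pred[, 1] - th)^2)
    }
    counts[["dihedral"]] <- length(vd)
  }
  pairs <- plan$dist_pairs
  if (nrow(pairs) > 0) {
    tb <- bin_distance(geo$dist_matrix[pairs], binner) + 1L
    P <- softmax_rows(predictions$distance)
    terms[["distance"]] <- -mean(log(pmax(P[cbind(seq_len(nrow(pairs)), tb)],
                                          1e-12)))
    counts[["distance"]] <- nrow(pairs)
  }
  loss_breakdown(terms, counts, weights)
}

#' Electronic-structure self-supervised losses
#'
#' Mean squared error of predicted partial charges over masked atoms and
#' of predicted bond orders over masked bonds.
#'
#' @param predictions list with `charge` (over `plan$masked_atoms`) and
#'   `wiberg` (over `plan$masked_bonds`).
#' @param mol molecule carrying `atom_labels` and `bond_labels`.
#' @param plan the `t3d_mask_plan`.
#' @param weights optional per-term weights.
#' @return a `t3d_loss_breakdown` over the two electronic terms.
#' @export
electronic_losses <- function(predictions, mol, plan, weights = NULL) {
  if (is.null(mol$atom_labels) || is.null(mol$bond_labels)) {
    stop(t3d_error("t3d_label_error",
                   sprintf("molecule '%s' lacks electronic labels", mol$id)))
  }
  terms <- c(charge = 0, wiberg = 0)
  counts <- c(charge = 0L, wiberg = 0L)
  sel <- plan$masked_atoms
  if (length(sel) > 0) {
    terms[["charge"]] <- mean((predictions$charge - mol$atom_labels[sel])^2)
    counts[["charge"]] <- length(sel)
  }
  mb <- plan$masked_bonds
  if (length(mb) > 0) {
    terms[["wiberg"]] <- mean((predictions$wiberg - mol$bond_labels[mb])^2)
    counts[["wiberg"]] <- length(mb)
  }
  loss_breakdown(terms, counts, weights)
}
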