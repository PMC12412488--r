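#' Three linked molecular graphs
#'
#' `build_trigraph()` derives the three graphs that drive the geometric
#' message passing:
#' \itemize{
#'   \item G (atom-bond): atoms are nodes, bonds are edges;
#'   \item H (bond-angle): bonds are nodes, bond angles (u, v, w) -- two
#'     bonds sharing apex atom v -- are edges;
#'   \item I (angle-dihedral): bond angles are nodes, dihedral angles
#'     (u, v, w, x) -- two angles sharing the central bond (v, w) -- are
#'     edges.
#' }
#' Every bond, angle, and dihedral is stored once in canonical undirected
#' form; the directed edge tables (`g_edges`, `h_edges`, `i_edges`) carry
#' both orientations so that message passing is symmetric.
#' @name trigraph
NULL

angle_key <- function(u, v, w) {
  paste(pmin(u, w), v, pmax(u, w), sep = ".")
}

#' Build the atom-bond / bond-angle / angle-dihedral graphs
#'
#' Angles are all (u, v, w) with u, w neighbors of apex v, u != w.
#' Dihedrals are all (u, v, w, x) around each bond (v, w) with
#' u in N(v)\\{w}, x in N(w)\\{v}, u != x. Empty levels are valid: a
#' diatomic has no angles and no dihedrals.
#'
#' @param mol a `t3d_molecule`.
#' @return a `t3d_trigraph` with undirected element tables (`bonds`,
#'   `angles`, `dihedrals`), directed message tables (`g_edges`, `h_edges`,
#'   `i_edges`), and the bond/angle id lookups.
#' @export
build_trigraph <- function(mol) {
  n <- nrow(mol$atoms)
  bonds <- mol$bonds[, c("i", "j")]
  m <- nrow(bonds)
  bond_id <- matrix(0L, n, n)
  nbrs <- vector("list", n)
  if (m > 0) {
    for (b in seq_len(m)) {
      i <- bonds$i[b]; j <- bonds$j[b]
      bond_id[i, j] <- b; bond_id[j, i] <- b
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  nbrs <- lapply(nbrs, sort)

  # directed atom-level edges: message u -> v through bond (u, v)
  if (m > 0) {
    g_edges <- data.frame(src = c(bonds$i, bonds$j),
                          dst = c(bonds$j, bonds$i),
                          bond = rep(seq_len(m), 2L))
  } else {
    g_edges <- data.frame(src = integer(), dst = integer(), bond = integer())
  }

  # undirected angles: apex v, ends u < w
  au <- integer(); av <- integer(); aw <- integer()
  for (v in seq_len(n)) {
    nb <- nbrs[[v]]
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      au <- c(au, pr[1, ]); av <- c(av, rep(v, ncol(pr))); aw <- c(aw, pr[2, ])
    }
  }
  angles <- data.frame(u = au, v = av, w = aw)
  a <- nrow(angles)
  aid <- stats::setNames(seq_len(a), angle_key(au, av, aw))

  # directed bond-level edges: orientation (u, v, w) sends the state of
  # bond (v, w) to bond (u, v) through angle (u, v, w)
  if (a > 0) {
    h_edges <- data.frame(
      src_bond = c(bond_id[cbind(av, aw)], bond_id[cbind(av, au)]),
      dst_bond = c(bond_id[cbind(au, av)], bond_id[cbind(aw, av)]),
      angle = rep(seq_len(a), 2L))
  } else {
    h_edges <- data.frame(src_bond = integer(), dst_bond = integer(),
                          angle = integer())
  }

  # undirected dihedrals around each bond (v, w); (u,v,w,x) == (x,w,v,u)
  du <- integer(); dv <- integer(); dw <- integer(); dx <- integer()
  if (m > 0) {
    for (b in seq_len(m)) {
      v <- bonds$i[b]; w <- bonds$j[b]
      for (u in setdiff(nbrs[[v]], w)) {
        for (x in setdiff(nbrs[[w]], v)) {
          if (u == x) next
          quad <- c(u, v, w, x)
          if (quad[1] > quad[4] || (quad[1] == quad[4] && quad[2] > quad[3])) {
            quad <- rev(quad)
          }
          du <- c(du, quad[1]); dv <- c(dv, quad[2])
          dw <- c(dw, quad[3]); dx <- c(dx, quad[4])
        }
      }
    }
  }
  dihedrals <- unique(data.frame(u = du, v = dv, w = dw, x = dx))
  rownames(dihedrals) <- NULL
  d <- nrow(dihedrals)

  # directed angle-level edges: orientation (u,v,w,x) sends the state of
  # angle (v,w,x) to angle (u,v,w) through the dihedral
  if (d > 0) {
    left <- unname(aid[angle_key(dihedrals$u, dihedrals$v, dihedrals$w)])
    right <- unname(aid[angle_key(dihedrals$v, dihedrals$w, dihedrals$x)])
    i_edges <- data.frame(src_angle = c(right, left),
                          dst_angle = c(left, right),
                          dihedral = rep(seq_len(d), 2L))
  } else {
    i_edges <- data.frame(src_angle = integer(), dst_angle = integer(),
                          dihedral = integer())
  }

  structure(list(n_atoms = n, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, g_edges = g_edges,
                 h_edges = h_edges, i_edges = i_edges,
                 bond_id = bond_id, angle_id = aid, nbrs = nbrs),
            class = "t3d_trigraph")
}

#' @export
print.t3d_trigraph <- function(x, ...) {
  cat(sprintf(
    "<t3d_trigraph: %d atoms, %d bonds, %d angles, %d dihedrals>\n",
    x$n_atoms, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}
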