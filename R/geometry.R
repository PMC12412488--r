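#' Geometric features of a conformer
#'
#' Internal coordinates derived from the 3D structure: bond lengths l_uv
#' (Angstrom), bond angles phi_uvw (radians, [0, pi]), signed dihedral
#' torsions theta_uvwx (radians, [-pi, pi)), and the all-pairs atomic
#' distance matrix. All are invariant under proper rigid motions; under a
#' mirror reflection only the torsion signs change, which is what makes the
#' downstream representation sensitive to absolute configuration.
#' @name geometry
NULL

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle of four points
#'
#' Standard atan2-of-cross-products formula; returns a value in
#' [-pi, pi). Invariant under reversing the atom order; negated by
#' reflection. Returns 0 with `degenerate = TRUE` attribute handling left
#' to [compute_geometry()] when either plane is undefined.
#' @param p1,p2,p3,p4 3-vectors.
#' @return list(theta, degenerate).
#' @keywords internal
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  s1 <- sqrt(sum(n1^2)) / (sqrt(sum(b1^2)) * sqrt(sum(b2^2)))
  s2 <- sqrt(sum(n2^2)) / (sqrt(sum(b2^2)) * sqrt(sum(b3^2)))
  if (s1 < 1e-2 || s2 < 1e-2) {  # a frame within ~0.6 deg of collinear
    return(list(theta = 0, degenerate = TRUE))
  }
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- vcross(n1, b2n)
  theta <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (theta >= pi) theta <- theta - 2 * pi
  list(theta = theta, degenerate = FALSE)
}

#' Compute bond lengths, angles, torsions, and the distance matrix
#'
#' @param coords n x 3 coordinate matrix (Angstrom), finite.
#' @param graph a `t3d_trigraph`.
#' @return a `t3d_geometry` list: `lengths` (per undirected bond), `angles`
#'   (per undirected angle, [0, pi]), `dihedrals` (per undirected dihedral,
#'   signed, [-pi, pi)), `angle_degenerate` / `dihedral_degenerate` flags
#'   (collinear frames; flagged values are excluded from self-supervised
#'   losses downstream), and `dist_matrix`.
#' @export
compute_geometry <- function(coords, graph) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, all(is.finite(coords)),
            nrow(coords) == graph$n_atoms)
  m <- nrow(graph$bonds); a <- nrow(graph$angles); d <- nrow(graph$dihedrals)

  lengths <- numeric(m)
  if (m > 0) {
    dvec <- coords[graph$bonds$i, , drop = FALSE] -
      coords[graph$bonds$j, , drop = FALSE]
    lengths <- sqrt(rowSums(dvec^2))
    if (any(lengths < 1e-6)) {
      stop(t3d_error("t3d_geometry_error",
                     "degenerate geometry: coincident bonded atoms"))
    }
  }

  angles <- numeric(a); angle_degenerate <- logical(a)
  for (k in seq_len(a)) {
    u <- graph$angles$u[k]; v <- graph$angles$v[k]; w <- graph$angles$w[k]
    e1 <- coords[u, ] - coords[v, ]; e2 <- coords[w, ] - coords[v, ]
    cosphi <- sum(e1 * e2) / (sqrt(sum(e1^2)) * sqrt(sum(e2^2)))
    cosphi <- max(-1, min(1, cosphi))
    angles[k] <- acos(cosphi)
    angle_degenerate[k] <- sqrt(sum(vcross(e1, e2)^2)) <
      1e-2 * sqrt(sum(e1^2)) * sqrt(sum(e2^2))
  }

  dihedrals <- numeric(d); dihedral_degenerate <- logical(d)
  for (k in seq_len(d)) {
    tor <- torsion4(coords[graph$dihedrals$u[k], ],
                    coords[graph$dihedrals$v[k], ],
                    coords[graph$dihedrals$w[k], ],
                    coords[graph$dihedrals$x[k], ])
    dihedrals[k] <- tor$theta
    dihedral_degenerate[k] <- tor$degenerate
  }

  dist_matrix <- as.matrix(stats::dist(coords))
  dimnames(dist_matrix) <- NULL

  structure(list(lengths = lengths, angles = angles, dihedrals = dihedrals,
                 angle_degenerate = angle_degenerate,
                 dihedral_degenerate = dihedral_degenerate,
                 dist_matrix = dist_matrix),
            class = "t3d_geometry")
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) rotation via QR decomposition of a Gaussian matrix with
#' the determinant sign corrected; used in invariance checks.
#' @param seed integer seed.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation_matrix <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Apply a rigid motion to coordinates
#'
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(coords, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}
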