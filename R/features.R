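#' Initial feature construction
#'
#' Categorical atom/bond attributes are one-hot encoded (with a reserved
#' "other" bucket for unseen levels); continuous geometry (bond lengths,
#' bond angles, signed torsions) is expanded on a Gaussian radial basis.
#' Each feature family carries one trailing mask-token bit, set only when a
#' self-supervised mask plan hides the element.
#' @name features
NULL

#' Default feature configuration
#'
#' Vocabularies for the categorical features and centers/widths of the
#' radial bases: 20 Gaussian centers per family, bond lengths on [0, 5]
#' Angstrom, bond angles on [0, pi], dihedrals on [-pi, pi), width equal to
#' the center spacing.
#'
#' @return a `t3d_feature_config` list.
#' @export
feature_config <- function() {
  structure(list(
    elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
                 "Si", "Se"),
    degrees = as.character(0:5),
    formal_charges = as.character(-2:2),
    num_hs = as.character(0:4),
    hybridizations = c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2"),
    chiralities = c("none", "cw", "ccw"),
    bond_orders = c("1", "1.5", "2", "3"),
    bond_stereo = c("none", "z", "e", "cis", "trans"),
    rbf = list(
      length = list(centers = seq(0, 5, length.out = 20), width = 5 / 19),
      angle = list(centers = seq(0, pi, length.out = 20), width = pi / 19),
      dihedral = list(centers = -pi + (0:19) * (2 * pi / 20),
                      width = 2 * pi / 20))
  ), class = "t3d_feature_config")
}

onehot <- function(values, levels) {
  idx <- match(as.character(values), levels, nomatch = length(levels) + 1L)
  out <- matrix(0, length(values), length(levels) + 1L)
  out[cbind(seq_along(values), idx)] <- 1
  out
}

#' Gaussian radial-basis expansion
#'
#' `exp(-0.5 ((x - c) / w)^2)` per center c; equals 1 exactly at a center
#' and lies in [0, 1] elementwise.
#'
#' @param x numeric vector of values.
#' @param basis list with `centers` and `width`.
#' @return length(x) x length(centers) matrix.
#' @export
rbf_expand <- function(x, basis) {
  out <- outer(x, basis$centers, function(v, cc) {
    exp(-0.5 * ((v - cc) / basis$width)^2)
  })
  dim(out) <- c(length(x), length(basis$centers))
  out
}

#' Build the initial features of all four element families
#'
#' @param mol a `t3d_molecule`.
#' @param graph its `t3d_trigraph`.
#' @param geo its `t3d_geometry`.
#' @param config a `t3d_feature_config`.
#' @param ablate_dihedrals if TRUE, torsion inputs are zeroed before the
#'   radial-basis expansion; the resulting features are mirror-invariant
#'   (used for the chirality ablation experiments).
#' @return a `t3d_features` list with matrices `x_atom`, `x_bond`,
#'   `x_angle`, `x_dihedral` (mask bit last column, zero here) and a `dims`
#'   field.
#' @export
featurize <- function(mol, graph, geo, config = feature_config(),
                      ablate_dihedrals = FALSE) {
  at <- mol$atoms
  x_atom <- cbind(onehot(at$element, config$elements),
                  onehot(pmin(at$degree, 5L), config$degrees),
                  onehot(at$formal_charge, config$formal_charges),
                  onehot(pmin(at$num_h, 4L), config$num_hs),
                  onehot(at$hybridization, config$hybridizations),
                  as.numeric(at$aromatic),
                  as.numeric(at$in_ring),
                  onehot(at$chirality, config$chiralities),
                  0)  # mask bit

  bd <- mol$bonds
  if (nrow(bd) > 0) {
    x_bond <- cbind(onehot(bd$order, config$bond_orders),
                    as.numeric(bd$aromatic),
                    as.numeric(bd$in_ring),
                    onehot(bd$stereo, config$bond_stereo),
                    rbf_expand(geo$lengths, config$rbf$length),
                    0)
  } else {
    x_bond <- matrix(0, 0, length(config$bond_orders) + 1L + 2L +
                       length(config$bond_stereo) + 1L +
                       length(config$rbf$length$centers) + 1L)
  }

  x_angle <- cbind(rbf_expand(geo$angles, config$rbf$angle),
                   rep(0, length(geo$angles)))
  theta <- if (ablate_dihedrals) rep(0, length(geo$dihedrals)) else
    geo$dihedrals
  x_dihedral <- cbind(rbf_expand(theta, config$rbf$dihedral),
                      rep(0, length(theta)))

  structure(list(x_atom = x_atom, x_bond = x_bond, x_angle = x_angle,
                 x_dihedral = x_dihedral,
                 dims = c(atom = ncol(x_atom), bond = ncol(x_bond),
                          angle = ncol(x_angle), dihedral = ncol(x_dihedral))),
            class = "t3d_features")
}

#' Replace the features of masked elements by the mask token
#'
#' Masked rows are zeroed except for the trailing mask bit, which is set to
#' one; graph structure is untouched.
#'
#' @param feats a `t3d_features`.
#' @param plan a `t3d_mask_plan` from [make_mask()].
#' @return masked `t3d_features`.
#' @export
apply_mask <- function(feats, plan) {
  mask_rows <- function(x, idx) {
    if (length(idx) > 0) {
      x[idx, ] <- 0
      x[idx, ncol(x)] <- 1
    }
    x
  }
  feats$x_atom <- mask_rows(feats$x_atom,
                            union(plan$masked_atoms, plan$context_atoms))
  feats$x_bond <- mask_rows(feats$x_bond, plan$masked_bonds)
  feats$x_angle <- mask_rows(feats$x_angle, plan$masked_angles)
  feats$x_dihedral <- mask_rows(feats$x_dihedral, plan$masked_dihedrals)
  feats
}
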