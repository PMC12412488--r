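#' Stereoisomer and conformer discrimination experiments
#'
#' Utilities to probe whether an embedding separates stereoisomers and
#' distinguishable conformers: full stereoisomer enumeration with MMFF94
#' conformers, uniform coordinate perturbation, Kabsch-aligned RMSD, and
#' the Davies-Bouldin cluster-separation index.
#' @name stereo
NULL

#' Enumerate all stereoisomers of a molecule
#'
#' All stereocenter assignments are enumerated as isomeric SMILES; each
#' isomer is embedded and MMFF94-optimized deterministically. A molecule
#' with k independent stereocenters yields 2^k isomers (fewer under meso
#' symmetry).
#'
#' @param smiles input SMILES.
#' @param id parent identifier.
#' @param embed generate conformers for the isomers (default TRUE).
#' @param n_candidates,seed conformer settings (see
#'   [generate_conformer()]).
#' @return a `t3d_isomer_set`: `parent_id`, `smiles` (isomer strings),
#'   `n_stereocenters`, and `molecules` (with coordinates when
#'   `embed = TRUE`); empty with a warning when there are no
#'   stereocenters.
#' @export
enumerate_stereoisomers <- function(smiles, id = "mol", embed = TRUE,
                                    n_candidates = 1, seed = 0) {
  res <- chem_backend("stereo", list(list(id = id, smiles = smiles)))[[1]]
  if (!is.null(res$error)) {
    stop(t3d_error("t3d_parse_error",
                   sprintf("molecule '%s': %s", id, res$error)))
  }
  iso <- unlist(res$isomers)
  nsc <- res$n_stereocenters
  if (is.null(nsc) || nsc == 0) {
    warning(sprintf("molecule '%s' has no stereocenters", id))
    return(structure(list(parent_id = id, smiles = character(),
                          n_stereocenters = 0L, molecules = list()),
                     class = "t3d_isomer_set"))
  }
  ids <- paste0(id, "_iso", seq_along(iso))
  mols <- parse_molecules(stats::setNames(iso, ids))
  if (embed) {
    mols <- generate_conformers(mols, n_candidates = n_candidates,
                                seed = seed)
  }
  structure(list(parent_id = id, smiles = iso,
                 n_stereocenters = as.integer(nsc), molecules = mols),
            class = "t3d_isomer_set")
}

#' Perturb a conformer with one-sided uniform coordinate noise
#'
#' Adds an independent uniform(0, `noise_max`) draw to every coordinate of
#' every atom (the induced net translation is removed by any subsequent
#' alignment). Deterministic per seed.
#'
#' @param coords n x 3 coordinate matrix.
#' @param noise_max upper bound of the noise in Angstrom (> 0).
#' @param seed integer seed.
#' @return perturbed n x 3 matrix.
#' @export
perturb_conformer <- function(coords, noise_max = 0.5, seed = 1) {
  stopifnot(noise_max > 0, is.matrix(coords), ncol(coords) == 3)
  set.seed(seed)
  coords + matrix(stats::runif(length(coords), 0, noise_max),
                  nrow(coords), 3)
}

#' Kabsch-aligned RMSD of two matched point sets
#'
#' Removes the centroids, finds the optimal proper rotation (SVD with the
#' reflection branch excluded), and returns the root-mean-square deviation
#' of the superposed sets. With fewer than 3 atoms only the translation is
#' removed and the result carries attribute `translation_only = TRUE`.
#'
#' @param coords_a,coords_b n x 3 matrices with matched atom order.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  stopifnot(nrow(coords_a) == nrow(coords_b))
  n <- nrow(coords_a)
  A <- sweep(coords_a, 2, colMeans(coords_a))
  B <- sweep(coords_b, 2, colMeans(coords_b))
  if (n < 3) {
    out <- sqrt(mean(rowSums((A - B)^2)))
    attr(out, "translation_only") <- TRUE
    return(out)
  }
  s <- svd(t(B) %*% A)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

#' Davies-Bouldin index of labelled embeddings
#'
#' Mean over clusters of the worst ratio (S_i + S_j) / M_ij, with S the
#' mean member-to-centroid distance and M the centroid separation; smaller
#' means better separated.
#'
#' @param embeddings numeric matrix, one row per point.
#' @param labels cluster labels (>= 2 distinct, each nonempty).
#' @return the index (>= 0).
#' @export
davies_bouldin <- function(embeddings, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(embeddings) == length(labels))
  lv <- unique(labels)
  if (length(lv) < 2) {
    stop(t3d_error("t3d_value_error", "need at least two clusters"))
  }
  cent <- t(vapply(lv, function(l) {
    colMeans(embeddings[labels == l, , drop = FALSE])
  }, numeric(ncol(embeddings))))
  S <- vapply(seq_along(lv), function(k) {
    rows <- embeddings[labels == lv[k], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cent[k, ])^2)))
  }, 0)
  K <- length(lv)
  ratios <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i == j) next
      M <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (M < 1e-12) {
        stop(t3d_error("t3d_value_error",
                       sprintf("coincident centroids for clusters '%s'/'%s'",
                               lv[i], lv[j])))
      }
      ratios[i, j] <- (S[i] + S[j]) / M
    }
  }
  mean(apply(ratios, 1, max, na.rm = TRUE))
}

#' Conformer/stereoisomer discrimination experiment
#'
#' For every molecule (with coordinates), builds a perturbed copy with
#' uniform coordinate noise, embeds original and perturbed conformers
#' under each encoder variant, and reports per-variant original-perturbed
#' embedding distances, the Davies-Bouldin index over the
#' original/perturbed labels, and the mean Kabsch-aligned RMSD of the
#' perturbation.
#'
#' @param mols list of molecules with coordinates.
#' @param encoders named list of encoder variants, each
#'   `list(net=, ablate_dihedrals=)`; typically a dihedral-enabled and a
#'   dihedral-ablated network.
#' @param noise_max noise bound in Angstrom (default 0.5).
#' @param seed base seed for the perturbations.
#' @param config the shared `t3d_network_config`.
#' @param fconfig feature configuration.
#' @return a `t3d_separation_report`: `mean_rmsd`, and per variant the
#'   per-molecule embedding distances, their mean, and the
#'   Davies-Bouldin index.
#' @export
run_discrimination_experiment <- function(mols, encoders, noise_max = 0.5,
                                          seed = 1,
                                          config = network_config(),
                                          fconfig = feature_config()) {
  stopifnot(length(encoders) >= 1, !is.null(names(encoders)))
  perturbed <- lapply(seq_along(mols), function(k) {
    m <- mols[[k]]
    m$coords <- perturb_conformer(m$coords, noise_max, seed = seed + k)
    m$id <- paste0(m$id, "_noise")
    m
  })
  rmsds <- vapply(seq_along(mols), function(k) {
    kabsch_rmsd(mols[[k]]$coords, perturbed[[k]]$coords)
  }, 0)
  variants <- lapply(encoders, function(enc) {
    ab <- isTRUE(enc$ablate_dihedrals)
    ds_o <- prepare_dataset(mols, fconfig, ablate_dihedrals = ab)
    ds_p <- prepare_dataset(perturbed, fconfig, ablate_dihedrals = ab)
    emb_o <- embed_molecules(enc$net, ds_o, config)
    emb_p <- embed_molecules(enc$net, ds_p, config)
    dists <- sqrt(rowSums((emb_o - emb_p)^2))
    db <- davies_bouldin(rbind(emb_o, emb_p),
                         rep(c("original", "perturbed"),
                             each = length(mols)))
    list(distances = dists, mean_distance = mean(dists), db_index = db)
  })
  structure(list(mean_rmsd = mean(rmsds), rmsds = rmsds,
                 variants = variants, noise_max = noise_max, seed = seed),
            class = "t3d_separation_report")
}

#' @export
print.t3d_separation_report <- function(x, ...) {
  cat(sprintf("<separation report: %d molecules, mean RMSD %.3f A>\n",
              length(x$rmsds), x$mean_rmsd))
  for (nm in names(x$variants)) {
    v <- x$variants[[nm]]
    cat(sprintf("  %-20s mean distance %.4f, DB index %.3f\n", nm,
                v$mean_distance, v$db_index))
  }
  invisible(x)
}
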