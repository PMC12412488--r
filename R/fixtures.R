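#' Deterministic built-in fixtures
#'
#' A curated, fully deterministic molecule set plus surrogate electronic
#' labels and toy property targets, so pretraining, fine-tuning, and the
#' discrimination experiments all run without any external download. The
#' set mixes named drugs and natural products, systematically enumerated
#' drug-like families (benzamides, sulfonamides, aryl esters, pyridine
#' amides), molecules with 1-4 stereocenters, and a handful of degenerate
#' edge cases (single heavy atom, diatomic, linear nitrile).
#' @name fixtures
NULL

#' The built-in molecule list
#'
#' @param include_degenerate include the degenerate edge cases (default
#'   TRUE).
#' @return data.frame with columns `id`, `smiles`, `family`; two calls
#'   return identical lists.
#' @export
builtin_molecules <- function(include_degenerate = TRUE) {
  drugs <- c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    ibuprofen = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    benzocaine = "CCOC(=O)c1ccc(N)cc1",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    naproxen = "COc1ccc2cc([C@@H](C)C(=O)O)ccc2c1",
    salbutamol = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    metoprolol = "COCCc1ccc(OCC(O)CNC(C)C)cc1",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    theophylline = "Cn1c(=O)c2[nH]cnc2n(C)c1=O",
    phenytoin = "O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1",
    diazepam = "CN1c2ccc(Cl)cc2C(c2ccccc2)=NCC1=O",
    sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
    trimethoprim = "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",
    chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    fluoxetine = "CNCCC(Oc1ccc(C(F)(F)F)cc1)c1ccccc1",
    ketamine = "CNC1(c2ccccc2Cl)CCCCC1=O",
    dopamine = "NCCc1ccc(O)c(O)c1",
    serotonin = "NCCc1c[nH]c2ccc(O)cc12",
    histamine = "NCCc1c[nH]cn1",
    melatonin = "COc1ccc2[nH]cc(CCNC(C)=O)c2c1",
    nicotine = "CN1CCC[C@H]1c1cccnc1",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    camphor = "CC1(C)C2CCC1(C)C(=O)C2",
    choline = "C[N+](C)(C)CCO",
    gaba = "NCCCC(=O)O",
    citrate = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
    urea = "NC(N)=O",
    glycerol = "OCC(O)CO",
    nicotinamide = "NC(=O)c1cccnc1",
    indomethacin_frag = "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1",
    piperine_frag = "O=C(C=Cc1ccc2OCOc2c1)N1CCCCC1",
    quinoline = "c1ccc2ncccc2c1",
    coumarin = "O=c1ccc2ccccc2o1",
    imidazole_et = "CCn1ccnc1",
    morpholine_ac = "CC(=O)N1CCOCC1",
    tolbutamide = "CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1",
    phenacetin = "CCOc1ccc(NC(C)=O)cc1",
    antipyrine = "Cc1cc(=O)n(-c2ccccc2)n1C",
    cinnamate = "COC(=O)C=Cc1ccccc1",
    vanillin = "COc1cc(C=O)ccc1O")

  stereo <- c(
    alanine = "C[C@H](N)C(=O)O",
    lactic_acid = "C[C@H](O)C(=O)O",
    phenylalanine = "N[C@@H](Cc1ccccc1)C(=O)O",
    valine = "CC(C)[C@H](N)C(=O)O",
    tryptophan = "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O",
    threonine = "C[C@@H](O)[C@H](N)C(=O)O",
    isoleucine = "CC[C@H](C)[C@H](N)C(=O)O",
    ephedrine = "CN[C@@H](C)[C@H](O)c1ccccc1",
    pseudoephedrine = "CN[C@@H](C)[C@@H](O)c1ccccc1",
    chloramphenicol = "O=[N+]([O-])c1ccc(cc1)[C@H](O)[C@@H](NC(=O)C(Cl)Cl)CO",
    tartaric_acid = "OC(=O)[C@H](O)[C@@H](O)C(=O)O",
    menthol = "C[C@@H]1CC[C@H](C(C)C)[C@@H](O)C1",
    limonene = "CC(=C)[C@@H]1CCC(C)=CC1",
    carvone = "CC(=C)[C@@H]1CC(C)=CC(=O)C1",
    sertraline = "CN[C@H]1CC[C@@H](c2ccc(Cl)c(Cl)c2)c2ccccc21",
    ribose = "OC[C@H](O)[C@H](O)[C@H](O)C=O",
    glucose_open = "OC[C@H](O)[C@@H](O)[C@H](O)[C@H](O)C=O",
    aminobutanol = "C[C@H](N)[C@@H](C)O",
    dihydroxyester = "CCOC(=O)[C@H](O)[C@@H](O)c1ccccc1")

  degenerate <- c(
    methane = "C",
    methanol = "CO",
    hydrogen_cyanide = "C#N",
    acetonitrile = "CC#N",
    carbon_dioxide = "O=C=O",
    ethane = "CC",
    propane = "CCC",
    butane = "CCCC",
    cyclopropane = "C1CC1",
    benzene = "c1ccccc1")

  subs <- c("F", "Cl", "Br", "C", "OC", "C#N", "[N+](=O)[O-]", "C(F)(F)F",
            "O", "N")
  amines_small <- c("C", "CC", "C(C)C", "C1CC1", "CCO", "C1CCCC1")
  amines_large <- c("Cc1ccccc1", "CCc1ccccc1", "CCN1CCOCC1", "CCCN1CCCC1",
                    "CCN(C)C", "C1CCN(C)CC1")

  fam <- function(fmt, a, s, tag) {
    grid <- expand.grid(a = a, s = s, stringsAsFactors = FALSE)
    smi <- sprintf(fmt, grid$a, grid$s)
    stats::setNames(smi, sprintf("%s_%03d", tag, seq_along(smi)))
  }
  benzamides <- fam("O=C(N%s)c1ccc(%s)cc1", amines_small, subs, "benzamide")
  biphenylamides <- fam("O=C(N%s)c1ccc(-c2ccc(%s)cc2)cc1", amines_large[1:5],
                        subs, "biphenylamide")
  sulfonamides <- fam("O=S(=O)(N%s)c1ccc(%s)cc1", amines_large,
                      subs[1:8], "sulfonamide")
  phenoxyacetamides <- fam("O=C(N%s)COc1ccc(%s)cc1", amines_large[1:4],
                           subs[1:8], "phenoxyacetamide")
  pyridinamides <- fam("O=C(N%s)c1ccc(%s)cn1", amines_small[1:4], subs[1:6],
                       "pyridinamide")
  esters <- fam("%sOC(=O)c1ccc(%s)cc1", c("C", "CC", "CCC"), subs[1:8],
                "arylester")

  tab <- function(x, family) {
    data.frame(id = names(x), smiles = unname(x), family = family,
               stringsAsFactors = FALSE)
  }
  out <- rbind(tab(drugs, "drug"), tab(stereo, "stereo"),
               tab(benzamides, "benzamide"),
               tab(biphenylamides, "biphenylamide"),
               tab(sulfonamides, "sulfonamide"),
               tab(phenoxyacetamides, "phenoxyacetamide"),
               tab(pyridinamides, "pyridinamide"), tab(esters, "arylester"))
  if (include_degenerate) out <- rbind(out, tab(degenerate, "degenerate"))
  rownames(out) <- NULL
  out
}

#' Fixture-generation settings
#'
#' @param seed master seed for conformers and label noise.
#' @param label_noise standard deviation of the Gaussian noise added to
#'   surrogate charges and bond orders (default 0.02).
#' @param kappa electronegativity-difference coefficient of the surrogate
#'   charge (default 0.2).
#' @param length_sensitivity bond-order change per Angstrom of deviation
#'   from the reference length (default 2).
#' @return a `t3d_fixture_spec`.
#' @export
fixture_spec <- function(seed = 0, label_noise = 0.02, kappa = 0.2,
                         length_sensitivity = 2) {
  structure(list(seed = seed, label_noise = label_noise, kappa = kappa,
                 length_sensitivity = length_sensitivity),
            class = "t3d_fixture_spec")
}

electronegativity <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, F = 3.98,
                       Cl = 3.16, Br = 2.96, I = 2.66, P = 2.19, B = 2.04,
                       Si = 1.90, Se = 2.55)

reference_bond_length <- c(`1` = 1.54, `1.5` = 1.40, `2` = 1.34, `3` = 1.20)

#' Surrogate electronic labels for a molecule
#'
#' Emulates quantum-chemical targets at desk scale: the charge of atom u
#' is `kappa * (EN(u) - mean EN of its neighbors)` plus Gaussian noise,
#' clipped to [-1, 1] and re-centered so the charges sum to the total
#' formal charge; the order of bond (u, v) is the nominal order minus
#' `length_sensitivity * (l_uv - reference length of that order)` plus
#' noise. The charge surrogate is intentionally topology-driven while the
#' bond-order surrogate depends on the conformer's bond lengths.
#'
#' @param mol molecule with coordinates.
#' @param spec a `t3d_fixture_spec`.
#' @return the molecule with `atom_labels` and `bond_labels` attached.
#' @export
surrogate_electronic_labels <- function(mol, spec = fixture_spec()) {
  stopifnot(!is.null(mol$coords))
  el <- mol$atoms$element
  unknown <- setdiff(el, names(electronegativity))
  if (length(unknown) > 0) {
    stop(t3d_error("t3d_value_error",
                   sprintf("element(s) missing from EN table: %s",
                           paste(unknown, collapse = ", "))))
  }
  en <- electronegativity[el]
  graph <- build_trigraph(mol)
  n <- nrow(mol$atoms)
  set.seed((spec$seed + hash_id(mol$id)) %% 2147483647)
  nb_mean <- vapply(seq_len(n), function(u) {
    nb <- graph$nbrs[[u]]
    if (length(nb) == 0) en[u] else mean(en[nb])
  }, 0)
  charges <- spec$kappa * (en - nb_mean) +
    stats::rnorm(n, 0, spec$label_noise)
  charges <- pmax(-1, pmin(1, charges))
  total <- sum(mol$atoms$formal_charge)
  charges <- charges - mean(charges) + total / n
  m <- nrow(mol$bonds)
  if (m > 0) {
    geo_len <- sqrt(rowSums((mol$coords[mol$bonds$i, , drop = FALSE] -
                               mol$coords[mol$bonds$j, , drop = FALSE])^2))
    ref <- reference_bond_length[as.character(mol$bonds$order)]
    orders <- mol$bonds$order -
      spec$length_sensitivity * (geo_len - ref) +
      stats::rnorm(m, 0, spec$label_noise)
  } else {
    orders <- numeric(0)
  }
  mol$atom_labels <- unname(charges)
  mol$bond_labels <- unname(orders)
  mol
}

# descriptor counts used by the toy targets
toy_descriptors <- function(mol) {
  n_hetero <- sum(mol$atoms$element != "C")
  n_ring_bonds <- sum(mol$bonds$in_ring)
  deg <- mol$atoms$degree
  n_rot <- sum(mol$bonds$order == 1 & !mol$bonds$in_ring &
                 deg[mol$bonds$i] > 1 & deg[mol$bonds$j] > 1)
  c(n_hetero = n_hetero, n_ring_bonds = n_ring_bonds, n_rot = n_rot)
}

# linear coefficients and classification threshold of the toy targets;
# the threshold is the median noiseless score of the built-in list
toy_coefficients <- c(intercept = 0, n_hetero = 0.5, n_ring_bonds = 0.2,
                      n_rot = 0.3)
toy_class_threshold <- 5.5
toy_noise_sd <- 0.3

#' Toy supervised targets with known generating process
#'
#' Regression label: `0.5 * heteroatoms + 0.2 * ring bonds +
#' 0.3 * rotatable bonds` plus Gaussian noise (sd 0.3). Classification
#' label: the same noisy score thresholded at 5.5 (the median noiseless
#' score of the built-in set).
#'
#' @param mol a molecule.
#' @param kind "regression" or "classification".
#' @param seed integer seed for the noise.
#' @param noise_sd noise standard deviation (0 gives the exact linear
#'   score).
#' @return numeric label (0/1 for classification).
#' @export
toy_property_targets <- function(mol, kind = c("regression",
                                               "classification"),
                                 seed = 0, noise_sd = toy_noise_sd) {
  kind <- match.arg(kind)
  d <- toy_descriptors(mol)
  score <- toy_coefficients[["intercept"]] +
    sum(toy_coefficients[names(d)] * d)
  set.seed((seed + hash_id(mol$id)) %% 2147483647)
  score <- score + stats::rnorm(1, 0, noise_sd)
  if (kind == "regression") score else as.numeric(score > toy_class_threshold)
}

#' Build the full fixture set: molecules, conformers, labels
#'
#' @param n number of molecules (default: the whole built-in list).
#' @param seed conformer/label seed.
#' @param spec a `t3d_fixture_spec`.
#' @param with_labels attach surrogate electronic labels (default TRUE).
#' @param include_degenerate include the degenerate edge cases.
#' @param n_candidates conformer candidates per molecule.
#' @return named list of molecules with coordinates (and labels).
#' @export
build_fixture_set <- function(n = NULL, seed = 0, spec = fixture_spec(),
                              with_labels = TRUE,
                              include_degenerate = TRUE, n_candidates = 1) {
  tab <- builtin_molecules(include_degenerate = include_degenerate)
  if (!is.null(n)) {
    stopifnot(n >= 1, n <= nrow(tab))
    tab <- tab[seq_len(n), ]
  }
  mols <- parse_molecules(stats::setNames(tab$smiles, tab$id))
  mols <- generate_conformers(mols, n_candidates = n_candidates,
                              seed = seed)
  if (with_labels) {
    spec$seed <- spec$seed + seed
    mols <- lapply(mols, surrogate_electronic_labels, spec = spec)
  }
  stats::setNames(mols, tab$id)
}

#' Stable digest of a fixture dataset
#'
#' Coordinates are rounded to 1e-4 Angstrom and labels to 1e-6 before
#' hashing, so the digest is stable across platforms.
#'
#' @param mols list of molecules.
#' @return md5 hex digest string.
#' @export
dataset_digest <- function(mols) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  for (mol in mols) {
    writeLines(c(mol$id, paste(mol$atoms$element, collapse = ","),
                 paste(mol$bonds$i, mol$bonds$j, mol$bonds$order,
                       collapse = ";")), con)
    if (!is.null(mol$coords)) {
      writeLines(paste(sprintf("%.4f", round(mol$coords, 4)),
                       collapse = ","), con)
    }
    if (!is.null(mol$atom_labels)) {
      writeLines(paste(sprintf("%.6f", mol$atom_labels), collapse = ","),
                 con)
    }
    if (!is.null(mol$bond_labels)) {
      writeLines(paste(sprintf("%.6f", mol$bond_labels), collapse = ","),
                 con)
    }
  }
  close(con)
  unname(tools::md5sum(tmp))
}
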