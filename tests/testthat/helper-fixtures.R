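# Shared fixtures, built once per test run. Conformer generation goes
# through one batched backend call; everything downstream is cached in
# this environment and reused across test files.
.fx <- new.env(parent = emptyenv())

fx_all <- function() {
  if (is.null(.fx$all)) {
    .fx$all <- build_fixture_set(seed = 0)
  }
  .fx$all
}

# first n molecules of the built-in list (same coordinates/labels as a
# direct build_fixture_set(n) call, because per-molecule seeds are stable)
fx_set <- function(n) fx_all()[seq_len(n)]

fx_druglike <- function() {
  all <- fx_all()
  fam <- builtin_molecules()
  all[fam$id[fam$family != "degenerate"]]
}

# small named molecules used by many unit tests (one backend call)
fx_small <- function() {
  if (is.null(.fx$small)) {
    smi <- c(ethanol = "CCO", propane = "CCC", butane = "CCCC",
             benzene = "c1ccccc1", ethane = "CC", methane = "C",
             cyclopropane = "C1CC1", acetonitrile = "CC#N",
             butanol = "CCCCO", chiral2 = "C[C@H](N)[C@@H](C)O",
             isopentanol = "CC(C)CCO", toluene = "Cc1ccccc1")
    mols <- parse_molecules(smi)
    .fx$small <- stats::setNames(
      generate_conformers(mols, n_candidates = 1, seed = 0), names(smi))
  }
  .fx$small
}

fx_record <- function(mol, fconfig = feature_config(),
                      ablate_dihedrals = FALSE) {
  graph <- build_trigraph(mol)
  geo <- compute_geometry(mol$coords, graph)
  list(mol = mol, graph = graph, geo = geo,
       feats = featurize(mol, graph, geo, fconfig,
                         ablate_dihedrals = ablate_dihedrals))
}

# an enantiomeric conformer pair: a chiral conformer and its exact mirror
fx_enantiomer_pair <- function(name = "chiral2") {
  mol <- fx_small()[[name]]
  list(R = mol, S = mirror_conformer(mol))
}
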