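test_that("SMILES parsing yields sanitized heavy-atom molecules", {
  sm <- fx_small()
  eth <- sm$ethanol
  expect_equal(nrow(eth$atoms), 3)
  expect_equal(nrow(eth$bonds), 2)
  expect_equal(sum(eth$atoms$num_h), 6)

  benz <- sm$benzene
  expect_equal(nrow(benz$atoms), 6)
  expect_equal(nrow(benz$bonds), 6)
  expect_true(all(benz$atoms$aromatic))
  expect_true(all(benz$bonds$aromatic))
  expect_equal(benz$bonds$order, rep(1.5, 6))

  expect_equal(sum(sm$cyclopropane$bonds$in_ring), 3)
  expect_equal(sum(sm$propane$bonds$in_ring), 0)
})

test_that("parse failures are structured errors naming the input", {
  expect_error(parse_molecule("not-a-smiles(", "badmol"),
               class = "t3d_parse_error")
  expect_error(parse_molecule("not-a-smiles(", "badmol"), "badmol")
  expect_error(parse_molecule("[H][H]", "h2"), class = "t3d_parse_error")
})

test_that("conformer generation is MMFF94-plausible and deterministic", {
  eth <- fx_small()$ethane
  len <- sqrt(sum((eth$coords[1, ] - eth$coords[2, ])^2))
  expect_gt(len, 1.45)
  expect_lt(len, 1.60)

  one <- fx_small()$methane
  expect_equal(dim(one$coords), c(1L, 3L))

  again <- generate_conformer(parse_molecule("CC", "ethane"),
                              n_candidates = 1, seed = 0)
  expect_equal(again$coords, eth$coords, tolerance = 1e-12)
})

test_that("tri-graph enumeration matches hand counts on chains and rings", {
  g <- build_trigraph(fx_small()$propane)
  expect_equal(nrow(g$angles), 1)
  expect_equal(nrow(g$dihedrals), 0)

  g <- build_trigraph(fx_small()$butane)
  expect_equal(nrow(g$angles), 2)
  expect_equal(nrow(g$dihedrals), 1)

  g <- build_trigraph(fx_small()$benzene)
  expect_equal(nrow(g$angles), 6)
  expect_equal(nrow(g$dihedrals), 6)

  # diatomic: empty higher levels are valid
  g <- build_trigraph(fx_small()$ethane)
  expect_equal(nrow(g$h_edges), 0)
  expect_equal(nrow(g$i_edges), 0)
})

test_that("angle/dihedral sets equal the brute-force double-loop oracle", {
  mols <- fx_set(60)
  small <- Filter(function(m) nrow(m$atoms) <= 12, mols)
  expect_gte(length(small), 10)
  for (mol in small) {
    g <- build_trigraph(mol)
    got_angles <- sort(paste(g$angles$u, g$angles$v, g$angles$w, sep = "-"))
    expect_equal(got_angles, oracle_angles(mol$bonds, nrow(mol$atoms)),
                 info = mol$id)
    got_dih <- sort(paste(g$dihedrals$u, g$dihedrals$v, g$dihedrals$w,
                          g$dihedrals$x, sep = "-"))
    expect_equal(got_dih, oracle_dihedrals(mol$bonds, nrow(mol$atoms)),
                 info = mol$id)
    # directed tables carry both orientations of every element
    expect_equal(nrow(g$h_edges), 2 * nrow(g$angles))
    expect_equal(nrow(g$i_edges), 2 * nrow(g$dihedrals))
  }
})

test_that("geometry matches hand-computed values on canonical points", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  mol <- fx_small()$butane
  g <- build_trigraph(mol)
  geo <- compute_geometry(pts, g)
  ang <- g$angles
  k <- which(ang$u == 1 & ang$v == 2 & ang$w == 3)
  expect_equal(geo$angles[k], pi / 2, tolerance = 1e-12)
  expect_equal(abs(geo$dihedrals[1]), pi / 2, tolerance = 1e-12)

  mirrored <- pts
  mirrored[, 3] <- -mirrored[, 3]
  geo_m <- compute_geometry(mirrored, g)
  expect_equal(geo_m$dihedrals[1], -geo$dihedrals[1], tolerance = 1e-12)
  expect_equal(geo_m$lengths, geo$lengths, tolerance = 1e-12)
  expect_equal(geo_m$angles, geo$angles, tolerance = 1e-12)
})

test_that("internal coordinates are invariant under proper rigid motions", {
  mols <- fx_set(20)
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    g <- build_trigraph(mol)
    geo <- compute_geometry(mol$coords, g)
    for (r in 1:10) {
      R <- random_rotation_matrix(100 * k + r)
      set.seed(200 * k + r)
      tr <- stats::rnorm(3, sd = 5)
      geo2 <- compute_geometry(apply_rigid(mol$coords, R, tr), g)
      expect_lt(max(abs(geo2$lengths - geo$lengths), 0), 1e-6)
      expect_lt(max(abs(geo2$angles - geo$angles), 0), 1e-6)
      expect_lt(max(abs(geo2$dihedrals - geo$dihedrals), 0), 1e-6)
      expect_lt(max(abs(geo2$dist_matrix - geo$dist_matrix)), 1e-6)
    }
  }
})

test_that("mirror reflection flips every non-degenerate torsion only", {
  mols <- fx_set(30)
  for (mol in mols) {
    g <- build_trigraph(mol)
    geo <- compute_geometry(mol$coords, g)
    geo_m <- compute_geometry(mirror_conformer(mol)$coords, g)
    expect_equal(geo_m$lengths, geo$lengths, tolerance = 1e-6)
    expect_equal(geo_m$angles, geo$angles, tolerance = 1e-6)
    ok <- !geo$dihedral_degenerate
    if (any(ok)) {
      expect_equal(geo_m$dihedrals[ok], -geo$dihedrals[ok],
                   tolerance = 1e-6)
    }
  }
})

test_that("distance matrices satisfy the triangle inequality", {
  mol <- fx_druglike()[["chlorpromazine"]]
  g <- build_trigraph(mol)
  D <- compute_geometry(mol$coords, g)$dist_matrix
  expect_equal(diag(D), rep(0, nrow(D)))
  expect_equal(D, t(D), tolerance = 1e-12)
  n <- nrow(D)
  set.seed(42)
  for (k in seq_len(1000)) {
    ijk <- sample.int(n, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-6)
  }
})

test_that("degenerate geometries are flagged, coincident atoms error", {
  nitrile <- fx_small()$acetonitrile  # C-C#N is nearly collinear
  g <- build_trigraph(nitrile)
  geo <- compute_geometry(nitrile$coords, g)
  expect_true(any(geo$angle_degenerate))

  mol <- fx_small()$ethane
  bad <- mol$coords
  bad[2, ] <- bad[1, ]
  expect_error(compute_geometry(bad, build_trigraph(mol)),
               class = "t3d_geometry_error")
})

test_that("radial basis features hit 1 at centers and stay in [0, 1]", {
  fc <- feature_config()
  x <- rbf_expand(fc$rbf$length$centers[7], fc$rbf$length)
  expect_equal(x[1, 7], 1)
  set.seed(3)
  vals <- rbf_expand(runif(50, -2, 8), fc$rbf$length)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("featurization encodes aromaticity and is chirality-stable under mirroring", {
  fc <- feature_config()
  rec <- fx_record(fx_small()$benzene)
  arom_col <- length(fc$elements) + 1 + length(fc$degrees) + 1 +
    length(fc$formal_charges) + 1 + length(fc$num_hs) + 1 +
    length(fc$hybridizations) + 1 + 1
  expect_equal(rec$feats$x_atom[, arom_col], rep(1, 6))

  pair <- fx_enantiomer_pair()
  ra <- fx_record(pair$R); rb <- fx_record(pair$S)
  expect_equal(ra$feats$x_atom, rb$feats$x_atom)
  expect_equal(ra$feats$x_bond, rb$feats$x_bond)
  expect_equal(ra$feats$x_angle, rb$feats$x_angle)
  # torsion-derived features differ wherever theta is not 0 or pi
  expect_gt(max(abs(ra$feats$x_dihedral - rb$feats$x_dihedral)), 1e-4)
})

test_that("SDF writer round-trips structures and coordinates", {
  mols <- fx_small()[c("ethanol", "benzene", "chiral2")]
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- parse_molecules(read_sdf_file(path))
  expect_equal(length(back), 3)
  for (k in seq_along(mols)) {
    expect_equal(back[[k]]$atoms$element, mols[[k]]$atoms$element)
    expect_equal(back[[k]]$bonds[, c("i", "j")],
                 mols[[k]]$bonds[, c("i", "j")])
    expect_equal(back[[k]]$coords, mols[[k]]$coords, tolerance = 1e-3)
  }
})

test_that("SMILES file reader handles ids and comments", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1\tbenzene", "# comment", "CC"), path)
  smi <- read_smiles_file(path)
  expect_equal(unname(smi[1:2]), c("CCO", "c1ccccc1"))
  expect_equal(names(smi)[1:2], c("ethanol", "benzene"))
  expect_equal(names(smi)[3], "mol3")
})
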