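small_cfg <- function(...) {
  network_config(hidden = 8, K = 2, dropout = 0, ...)
}

test_that("vectorized forward pass matches the plain-loop oracle", {
  mols <- c(fx_small()[c("butane", "benzene", "ethanol", "chiral2",
                         "methane", "ethane")], fx_set(6))
  for (flags in list(list(residual = TRUE, layernorm = TRUE,
                          graphnorm = TRUE),
                     list(residual = FALSE, layernorm = FALSE,
                          graphnorm = FALSE))) {
    cfg <- do.call(small_cfg, flags)
    for (mol in mols) {
      rec <- fx_record(mol)
      net <- init_network(rec$feats$dims, cfg, seed = 7)
      fast <- forward_network(net, rec$graph, rec$feats, cfg)
      slow <- oracle_forward(net, rec$graph, rec$feats, cfg)
      expect_equal(fast$h_atom, slow$h_atom, tolerance = 1e-10,
                   info = mol$id)
      expect_equal(fast$h_graph, slow$h_graph, tolerance = 1e-10)
    }
  }
})

test_that("embedding is invariant to rigid motion and atom permutation", {
  cfg <- small_cfg()
  mols <- fx_set(20)
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    rec <- fx_record(mol)
    net <- init_network(rec$feats$dims, cfg, seed = 11)
    ref <- forward_network(net, rec$graph, rec$feats, cfg)$h_graph
    for (r in 1:10) {
      m2 <- mol
      m2$coords <- apply_rigid(mol$coords, random_rotation_matrix(k * 31 + r),
                               c(r, -r, 2 * r))
      rec2 <- fx_record(m2)
      got <- forward_network(net, rec2$graph, rec2$feats, cfg)$h_graph
      expect_lt(max(abs(got - ref)), 1e-5)
    }
  }

  # atom permutation: relabel a molecule and compare pooled embeddings
  mol <- fx_small()$isopentanol
  rec <- fx_record(mol)
  net <- init_network(rec$feats$dims, cfg, seed = 11)
  ref <- forward_network(net, rec$graph, rec$feats, cfg)$h_graph
  set.seed(5)
  for (r in 1:5) {
    perm <- sample(nrow(mol$atoms))
    m2 <- mol
    m2$atoms <- mol$atoms[order(perm), ]
    m2$coords <- mol$coords[order(perm), , drop = FALSE]
    b <- mol$bonds
    b$i <- perm[b$i]; b$j <- perm[b$j]
    swap <- b$i > b$j
    tmp <- b$i[swap]; b$i[swap] <- b$j[swap]; b$j[swap] <- tmp
    m2$bonds <- b
    rec2 <- fx_record(m2)
    got <- forward_network(net, rec2$graph, rec2$feats, cfg)$h_graph
    expect_lt(max(abs(got - ref)), 1e-5)
  }
})

test_that("mirror reflection changes the embedding iff torsions carry sign", {
  cfg <- small_cfg()
  pair <- fx_enantiomer_pair()
  ra <- fx_record(pair$R); rb <- fx_record(pair$S)
  net <- init_network(ra$feats$dims, cfg, seed = 3)
  hR <- forward_network(net, ra$graph, ra$feats, cfg)$h_graph
  hS <- forward_network(net, rb$graph, rb$feats, cfg)$h_graph
  expect_gt(sqrt(sum((hR - hS)^2)), 1e-3)

  ra0 <- fx_record(pair$R, ablate_dihedrals = TRUE)
  rb0 <- fx_record(pair$S, ablate_dihedrals = TRUE)
  h0R <- forward_network(net, ra0$graph, ra0$feats, cfg)$h_graph
  h0S <- forward_network(net, rb0$graph, rb0$feats, cfg)$h_graph
  expect_lt(max(abs(h0R - h0S)), 1e-5)

  # a molecule with no non-trivial torsion is mirror-invariant outright
  benz <- fx_small()$benzene
  r1 <- fx_record(benz); r2 <- fx_record(mirror_conformer(benz))
  net2 <- init_network(r1$feats$dims, cfg, seed = 3)
  h1 <- forward_network(net2, r1$graph, r1$feats, cfg)$h_graph
  h2 <- forward_network(net2, r2$graph, r2$feats, cfg)$h_graph
  expect_lt(max(abs(h1 - h2)), 1e-5)
})

test_that("molecules without higher-level elements pass through cleanly", {
  cfg <- small_cfg()
  for (nm in c("methane", "ethane", "propane")) {
    rec <- fx_record(fx_small()[[nm]])
    net <- init_network(rec$feats$dims, cfg, seed = 2)
    emb <- forward_network(net, rec$graph, rec$feats, cfg)
    expect_true(all(is.finite(emb$h_graph)))
    expect_equal(length(emb$h_graph), cfg$hidden)
  }
})

test_that("ablated architectures nest: angle-only and atom-bond-only run", {
  rec <- fx_record(fx_small()$isopentanol)
  for (cfg in list(small_cfg(use_dihedral_level = FALSE),
                   small_cfg(use_angle_level = FALSE,
                             use_dihedral_level = FALSE))) {
    net <- init_network(rec$feats$dims, cfg, seed = 4)
    emb <- forward_network(net, rec$graph, rec$feats, cfg)
    expect_true(all(is.finite(emb$h_graph)))
  }
})

test_that("analytic gradients agree with numerical differentiation", {
  mol <- fx_small()$chiral2
  mol <- surrogate_electronic_labels(mol, fixture_spec())
  rec <- fx_record(mol)
  cfg <- network_config(hidden = 5, K = 2, dropout = 0)
  pc <- pretrain_config(network = cfg, seed = 3)
  net <- init_network(rec$feats$dims, cfg, seed = 3)
  heads <- init_heads(5, seed = 4)
  plan <- make_mask(mol, rec$graph, seed = 9)
  lossfn <- function(net, heads, stage) {
    tripod3d:::ssl_molecule_grad(net, heads, rec, plan, stage, pc,
                                 want_grads = FALSE)$breakdown$total
  }
  eps <- 1e-6
  for (stage in c("geometry", "electronic")) {
    out <- tripod3d:::ssl_molecule_grad(net, heads, rec, plan, stage, pc)
    check <- function(setter, analytic) {
      l1 <- do.call(lossfn, c(setter(eps), list(stage)))
      l2 <- do.call(lossfn, c(setter(-eps), list(stage)))
      expect_equal((l1 - l2) / (2 * eps), analytic, tolerance = 1e-4)
    }
    set.seed(17)
    for (rep in 1:3) {
      i <- sample(nrow(net$emb$atom$W), 1)
      j <- sample(ncol(net$emb$atom$W), 1)
      check(function(e) {
        n <- net; n$emb$atom$W[i, j] <- n$emb$atom$W[i, j] + e
        list(n, heads)
      }, out$net_grads$emb$atom$W[i, j])
      i2 <- sample(cfg$hidden, 1); j2 <- sample(cfg$hidden, 1)
      check(function(e) {
        n <- net
        n$layers[[1]]$I$W1[i2, j2] <- n$layers[[1]]$I$W1[i2, j2] + e
        list(n, heads)
      }, out$net_grads$layers[[1]]$I$W1[i2, j2])
      check(function(e) {
        n <- net
        n$layers[[2]]$G$W2[i2, j2] <- n$layers[[2]]$G$W2[i2, j2] + e
        list(n, heads)
      }, out$net_grads$layers[[2]]$G$W2[i2, j2])
      check(function(e) {
        n <- net; n$layers[[2]]$H$eps <- n$layers[[2]]$H$eps + e
        list(n, heads)
      }, out$net_grads$layers[[2]]$H$eps)
    }
  }
})

test_that("non-finite states fail loudly naming iteration and level", {
  rec <- fx_record(fx_small()$ethanol)
  cfg <- small_cfg()
  net <- init_network(rec$feats$dims, cfg, seed = 2)
  net$layers[[2]]$G$W2[1, 1] <- Inf
  expect_error(forward_network(net, rec$graph, rec$feats, cfg),
               "iteration 2, level G")
})

test_that("checkpoints round-trip and refuse mismatched dimensions", {
  rec <- fx_record(fx_small()$ethanol)
  cfg <- small_cfg()
  net <- init_network(rec$feats$dims, cfg, seed = 6)
  heads <- init_heads(cfg$hidden, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path, heads = heads,
                  extra = list(parents = list("a.json")))
  back <- load_checkpoint(path, feat_dims = rec$feats$dims)
  emb1 <- forward_network(net, rec$graph, rec$feats, cfg)$h_graph
  emb2 <- forward_network(back$net, rec$graph, rec$feats, cfg)$h_graph
  expect_equal(emb1, emb2, tolerance = 1e-12)
  expect_equal(back$extra$parents[[1]], "a.json")

  wrong <- rec$feats$dims
  wrong[["atom"]] <- wrong[["atom"]] + 1
  expect_error(load_checkpoint(path, feat_dims = wrong),
               class = "t3d_checkpoint_error")
})
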