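#' Two-stage self-supervised pretraining
#'
#' Stage "geometry" fits the four geometric tasks on MMFF94 conformers;
#' stage "electronic" fits the charge and bond-order tasks (optionally
#' warm-started from geometry-stage weights, which is the full two-stage
#' recipe). Optimization is mini-batch Adam with a fresh mask plan per
#' molecule per epoch; all randomness derives from the configured seed, so
#' repeated runs are bitwise identical.
#' @name pretrain-module
NULL

stage_terms <- list(geometry = c("length", "angle", "dihedral", "distance"),
                    electronic = c("charge", "wiberg"))

#' Pretraining configuration
#'
#' @param epochs number of passes over the dataset.
#' @param batch_size molecules per Adam step.
#' @param lr Adam learning rate.
#' @param seed master seed for shuffling, masking, dropout, and weights.
#' @param mask_rate atom masking fraction (default 0.15).
#' @param max_dist_pairs cap on distance-task atom pairs per molecule.
#' @param weights named per-term loss weights (default 1 for every term).
#' @param dihedral_target "sincos" (periodicity-safe, default) or "raw".
#' @param network a `t3d_network_config`; the default disables dropout,
#'   since the self-supervised stages are fitting problems where
#'   regularization only slows convergence (fine-tuning keeps its own
#'   dropout default).
#' @param binner a `t3d_distance_binner`.
#' @return a `t3d_pretrain_config`.
#' @export
pretrain_config <- function(epochs = 20, batch_size = 16, lr = 1e-3,
                            seed = 1, mask_rate = 0.15,
                            max_dist_pairs = 500,
                            weights = NULL, dihedral_target = "sincos",
                            network = network_config(dropout = 0),
                            binner = distance_binner()) {
  stopifnot(epochs >= 1, batch_size >= 1,
            dihedral_target %in% c("sincos", "raw"))
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 seed = seed, mask_rate = mask_rate,
                 max_dist_pairs = max_dist_pairs, weights = weights,
                 dihedral_target = dihedral_target, network = network,
                 binner = binner),
            class = "t3d_pretrain_config")
}

#' Precompute graphs, geometry, and features for a molecule list
#'
#' @param mols list of molecules with coordinates.
#' @param config a `t3d_feature_config`.
#' @param ablate_dihedrals zero torsion inputs (see [featurize()]).
#' @return list of records `list(mol, graph, geo, feats)`.
#' @export
prepare_dataset <- function(mols, config = feature_config(),
                            ablate_dihedrals = FALSE) {
  lapply(mols, function(mol) {
    graph <- build_trigraph(mol)
    geo <- compute_geometry(mol$coords, graph)
    feats <- featurize(mol, graph, geo, config,
                       ablate_dihedrals = ablate_dihedrals)
    list(mol = mol, graph = graph, geo = geo, feats = feats)
  })
}

# loss + full gradient for one masked molecule; terms limited to `stage`
ssl_molecule_grad <- function(net, heads, rec, plan, stage, config,
                              training = FALSE, want_grads = TRUE) {
  terms <- stage_terms[[stage]]
  netcfg <- config$network
  feats_m <- apply_mask(rec$feats, plan)
  emb <- forward_network(net, rec$graph, feats_m, netcfg,
                         training = training, keep_cache = want_grads)
  preds <- predict_ssl_heads(heads, emb$h_atom, rec$graph, plan)
  geo <- rec$geo

  if (stage == "geometry") {
    bd_geo <- geometric_losses(preds, geo, plan, config$binner,
                               config$weights)
    bd <- bd_geo
  } else {
    bd <- electronic_losses(preds, rec$mol, plan, config$weights)
  }
  if (!want_grads) return(list(breakdown = bd))

  n <- rec$graph$n_atoms
  h <- net$hidden
  dHK <- matrix(0, n, h)
  head_grads <- tree_zero(heads)
  w <- bd$weights

  backprop_head <- function(nm, dy) {
    bk <- mlp2_bwd(heads[[nm]], preds$caches[[nm]], dy)
    head_grads[[nm]] <<- bk$grads
    dHK <<- dHK + head_input_to_atoms(bk$dX, preds$inputs[[nm]]$atoms,
                                      head_blocks[[nm]], n)
  }

  if ("length" %in% terms && bd$counts[["length"]] > 0) {
    mb <- plan$masked_bonds
    dy <- matrix(2 * (preds$length - geo$lengths[mb]) *
                   w[["length"]] / length(mb), ncol = 1)
    backprop_head("length", dy)
  }
  if ("angle" %in% terms && bd$counts[["angle"]] > 0) {
    ma <- plan$masked_angles
    keep <- !geo$angle_degenerate[ma]
    dy <- numeric(length(ma))
    dy[keep] <- 2 * (preds$angle[keep] - geo$angles[ma[keep]]) *
      w[["angle"]] / sum(keep)
    backprop_head("angle", matrix(dy, ncol = 1))
  }
  if ("dihedral" %in% terms && bd$counts[["dihedral"]] > 0) {
    md <- plan$masked_dihedrals
    keep <- !geo$dihedral_degenerate[md]
    th <- geo$dihedrals[md]
    pred <- preds$dihedral
    if (is.null(dim(pred))) pred <- matrix(pred, ncol = 1)
    dy <- matrix(0, length(md), ncol(pred))
    if (ncol(pred) == 2) {
      dy[keep, 1] <- 2 * (pred[keep, 1] - sin(th[keep]))
      dy[keep, 2] <- 2 * (pred[keep, 2] - cos(th[keep]))
    } else {
      dy[keep, 1] <- 2 * (pred[keep, 1] - th[keep])
    }
    dy <- dy * w[["dihedral"]] / sum(keep)
    backprop_head("dihedral", dy)
  }
  if ("distance" %in% terms && bd$counts[["distance"]] > 0) {
    pairs <- plan$dist_pairs
    tb <- bin_distance(geo$dist_matrix[pairs], config$binner) + 1L
    P <- softmax_rows(preds$distance)
    dy <- P
    dy[cbind(seq_len(nrow(pairs)), tb)] <-
      dy[cbind(seq_len(nrow(pairs)), tb)] - 1
    dy <- dy * w[["distance"]] / nrow(pairs)
    backprop_head("distance", dy)
  }
  if ("charge" %in% terms && bd$counts[["charge"]] > 0) {
    sel <- plan$masked_atoms
    dy <- matrix(2 * (preds$charge - rec$mol$atom_labels[sel]) *
                   w[["charge"]] / length(sel), ncol = 1)
    backprop_head("charge", dy)
  }
  if ("wiberg" %in% terms && bd$counts[["wiberg"]] > 0) {
    mb <- plan$masked_bonds
    dy <- matrix(2 * (preds$wiberg - rec$mol$bond_labels[mb]) *
                   w[["wiberg"]] / length(mb), ncol = 1)
    backprop_head("wiberg", dy)
  }

  net_grads <- backward_network(net, rec$graph, emb, dHK, netcfg)
  list(breakdown = bd, net_grads = net_grads, head_grads = head_grads)
}

plan_seed <- function(master, epoch, id) {
  as.integer((as.numeric(master) * 7919 + epoch * 104729 + hash_id(id)) %%
               2147483647)
}

#' Pretrain the encoder with one self-supervised stage
#'
#' @param dataset records from [prepare_dataset()]; the electronic stage
#'   requires `atom_labels`/`bond_labels` on the molecules (unlabelled
#'   molecules are skipped with a warning).
#' @param stage "geometry" or "electronic".
#' @param config a `t3d_pretrain_config`.
#' @param init optional warm start: a previous fit's `$net` (stage
#'   chaining) or a full `list(net=, heads=)`.
#' @return a `t3d_pretrain_fit`: `net`, `heads`, per-epoch `history` (one
#'   row per epoch with each loss term and the weighted total), `stage`,
#'   and `status` ("ok" or "aborted", in which case the last finite-loss
#'   checkpoint is returned).
#' @export
pretrain <- function(dataset, stage = c("geometry", "electronic"),
                     config = pretrain_config(), init = NULL) {
  stage <- match.arg(stage)
  stopifnot(length(dataset) >= 1)
  if (stage == "electronic") {
    labelled <- vapply(dataset, function(r) {
      !is.null(r$mol$atom_labels) && !is.null(r$mol$bond_labels)
    }, TRUE)
    if (!all(labelled)) {
      warning(sprintf("skipping %d molecule(s) without electronic labels",
                      sum(!labelled)))
      dataset <- dataset[labelled]
    }
    if (length(dataset) == 0) {
      stop(t3d_error("t3d_label_error",
                     "no labelled molecules for the electronic stage"))
    }
  }
  feat_dims <- dataset[[1]]$feats$dims
  dihedral_out <- if (config$dihedral_target == "sincos") 2L else 1L
  net <- if (!is.null(init)) {
    if (!is.null(init$net)) init$net else init
  } else {
    init_network(feat_dims, config$network, seed = config$seed)
  }
  heads <- if (!is.null(init) && !is.null(init$heads)) init$heads else
    init_heads(net$hidden, n_bins = config$binner$n_bins,
               dihedral_out = dihedral_out, seed = config$seed + 1L)

  opt_params <- list(emb = net$emb, layers = net$layers, heads = heads)
  opt_state <- adam_init(opt_params)
  nmol <- length(dataset)
  hist <- vector("list", config$epochs)
  last_good <- opt_params
  status <- "ok"

  for (epoch in seq_len(config$epochs)) {
    set.seed(plan_seed(config$seed, epoch, "epoch-order"))
    order_ <- sample.int(nmol)
    batches <- split(order_, ceiling(seq_along(order_) / config$batch_size))
    sums <- NULL; cnts <- NULL; total <- 0; nseen <- 0
    aborted <- FALSE
    for (batch in batches) {
      acc <- NULL
      for (k in batch) {
        rec <- dataset[[k]]
        plan <- make_mask(rec$mol, rec$graph, rate = config$mask_rate,
                          seed = plan_seed(config$seed, epoch, rec$mol$id),
                          max_dist_pairs = config$max_dist_pairs)
        set.seed(plan_seed(config$seed, epoch, paste0("drop-", rec$mol$id)))
        out <- ssl_molecule_grad(net, heads, rec, plan, stage, config,
                                 training = TRUE)
        if (!is.finite(out$breakdown$total)) {
          aborted <- TRUE
          break
        }
        g <- list(emb = out$net_grads$emb, layers = out$net_grads$layers,
                  heads = out$head_grads)
        acc <- if (is.null(acc)) g else tree_axpy(acc, g)
        bd <- out$breakdown
        sums <- if (is.null(sums)) bd$terms else sums + bd$terms
        cnts <- if (is.null(cnts)) as.numeric(bd$counts > 0) else
          cnts + (bd$counts > 0)
        total <- total + bd$total
        nseen <- nseen + 1
      }
      if (aborted) break
      acc <- tree_map(function(x) x / length(batch), acc)
      st <- adam_step(opt_params, acc, opt_state, lr = config$lr)
      opt_params <- st$params; opt_state <- st$state
      net$emb <- opt_params$emb; net$layers <- opt_params$layers
      heads <- opt_params$heads
    }
    if (aborted) {
      status <- "aborted"
      warning(sprintf("non-finite loss in epoch %d; keeping last checkpoint",
                      epoch))
      opt_params <- last_good
      net$emb <- opt_params$emb; net$layers <- opt_params$layers
      heads <- opt_params$heads
      break
    }
    last_good <- opt_params
    mean_terms <- sums / pmax(cnts, 1)
    hist[[epoch]] <- c(epoch = epoch, mean_terms, total = total / nseen)
  }
  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  structure(list(net = net, heads = heads, history = history,
                 stage = stage, config = config, status = status),
            class = "t3d_pretrain_fit")
}

#' Evaluate self-supervised losses with fresh masks (no training)
#'
#' @param net,heads encoder and head parameters (e.g. a fit's `$net` and
#'   `$heads`).
#' @param dataset records from [prepare_dataset()].
#' @param stage "geometry" or "electronic".
#' @param config a `t3d_pretrain_config` (its seed drives the masks).
#' @return mean `t3d_loss_breakdown` over molecules, plus the list of
#'   plans used (for baseline comparisons on the same masked sets).
#' @export
ssl_eval <- function(net, heads, dataset, stage, config = pretrain_config()) {
  sums <- NULL; cnts <- NULL; plans <- vector("list", length(dataset))
  for (k in seq_along(dataset)) {
    rec <- dataset[[k]]
    plan <- make_mask(rec$mol, rec$graph, rate = config$mask_rate,
                      seed = plan_seed(config$seed, 0L, rec$mol$id),
                      max_dist_pairs = config$max_dist_pairs)
    plans[[k]] <- plan
    out <- ssl_molecule_grad(net, heads, rec, plan, stage, config,
                             training = FALSE, want_grads = FALSE)
    bd <- out$breakdown
    sums <- if (is.null(sums)) bd$terms else sums + bd$terms
    cnts <- if (is.null(cnts)) as.numeric(bd$counts > 0) else
      cnts + (bd$counts > 0)
  }
  list(terms = sums / pmax(cnts, 1), plans = plans)
}

#' Run one of the four pretraining strategies
#'
#' "none" returns freshly initialized weights; "geo" runs the geometry
#' stage only; "qcp" runs the electronic stage only; "qgem" chains
#' geometry then electronic.
#'
#' @param dataset records from [prepare_dataset()] (labelled molecules
#'   required for "qcp"/"qgem").
#' @param strategy one of "none", "geo", "qcp", "qgem".
#' @param config a `t3d_pretrain_config`.
#' @param electronic_config optional distinct config for the electronic
#'   stage (defaults to `config`).
#' @return a `t3d_pretrain_fit` (for "none", an untrained fit).
#' @export
pretrain_strategy <- function(dataset, strategy = c("qgem", "geo", "qcp",
                                                    "none"),
                              config = pretrain_config(),
                              electronic_config = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(electronic_config)) electronic_config <- config
  if (strategy == "none") {
    feat_dims <- dataset[[1]]$feats$dims
    net <- init_network(feat_dims, config$network, seed = config$seed)
    heads <- init_heads(net$hidden, n_bins = config$binner$n_bins,
                        seed = config$seed + 1L)
    return(structure(list(net = net, heads = heads,
                          history = data.frame(), stage = "none",
                          config = config, status = "ok"),
                     class = "t3d_pretrain_fit"))
  }
  if (strategy == "geo") return(pretrain(dataset, "geometry", config))
  if (strategy == "qcp") {
    return(pretrain(dataset, "electronic", electronic_config))
  }
  geo_fit <- pretrain(dataset, "geometry", config)
  pretrain(dataset, "electronic", electronic_config, init = geo_fit$net)
}
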