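#' Scaffold-split fine-tuning and evaluation
#'
#' Supervised heads are attached to the pretrained encoder and trained
#' end-to-end: molecule-level tasks read the mean-pooled embedding,
#' atom-level tasks read the final per-atom states. Datasets are
#' partitioned by Bemis-Murcko scaffold so test molecules come from
#' scaffolds never seen in training, and every reported score is the mean
#' and standard deviation over independent repeats with distinct seeds.
#' @name finetune
NULL

#' Murcko scaffolds of a molecule list
#'
#' @param mols list of `t3d_molecule`.
#' @param generic if TRUE, the generic (carbon-skeleton) scaffold variant.
#' @return character vector of scaffold SMILES ("" for acyclic molecules).
#' @export
murcko_scaffolds <- function(mols, generic = FALSE) {
  recs <- lapply(mols, function(m) {
    if (!is.null(m$smiles)) list(id = m$id, smiles = m$smiles)
    else list(id = m$id, sdf = m$sdf)
  })
  out <- chem_backend("scaffold", recs, generic = generic)
  vapply(out, function(r) {
    if (!is.null(r$error)) stop(t3d_error("t3d_parse_error", r$error))
    r$scaffold
  }, "")
}

#' Deterministic scaffold-based data split
#'
#' Scaffold groups are sorted by descending size, ties broken by the
#' scaffold string, and assigned greedily: groups go to train until the
#' train fraction is reached, then to validation, then to test. Molecules
#' sharing a scaffold are never separated.
#'
#' @param mols list of `t3d_molecule` (their `id`s name the split).
#' @param fractions train/valid/test fractions summing to 1.
#' @param generic use generic scaffolds (see [murcko_scaffolds()]).
#' @param scaffolds optional precomputed scaffold strings (skips the
#'   backend call).
#' @return a `t3d_scaffold_split`: `train`, `valid`, `test` id vectors,
#'   `fractions`, and the scaffold-to-ids map.
#' @export
scaffold_split <- function(mols, fractions = c(0.8, 0.1, 0.1),
                           generic = FALSE, scaffolds = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  ids <- vapply(mols, `[[`, "", "id")
  if (is.null(scaffolds)) scaffolds <- murcko_scaffolds(mols, generic)
  groups <- split(ids, scaffolds)
  if (length(groups) < 3) {
    stop(t3d_error("t3d_split_error",
                   paste("fewer distinct scaffolds than partitions;",
                         "use a random split instead")))
  }
  ord <- order(-vapply(groups, length, 1L), names(groups))
  groups <- groups[ord]
  n <- length(ids)
  target_train <- fractions[1] * n
  target_valid <- fractions[2] * n
  train <- character(); valid <- character(); test <- character()
  for (g in groups) {
    if (length(train) < target_train) train <- c(train, g)
    else if (length(valid) < target_valid) valid <- c(valid, g)
    else test <- c(test, g)
  }
  structure(list(train = train, valid = valid, test = test,
                 fractions = fractions, scaffold_map = groups),
            class = "t3d_scaffold_split")
}

#' Task specification
#'
#' @param kind "classification" (binary, ROC-AUC), "regression"
#'   (molecule-level, RMSE or MAE), or "atom_regression" (per-atom, MAE
#'   or RMSE).
#' @param metric "roc_auc", "rmse", or "mae"; defaults to the kind's
#'   conventional metric.
#' @param repeats independent fine-tuning repeats (default 4).
#' @return a `t3d_task_spec`.
#' @export
task_spec <- function(kind = c("regression", "classification",
                               "atom_regression"),
                      metric = NULL, repeats = 4) {
  kind <- match.arg(kind)
  if (is.null(metric)) {
    metric <- switch(kind, classification = "roc_auc", regression = "rmse",
                     atom_regression = "mae")
  }
  ok <- switch(kind, classification = "roc_auc",
               regression = c("rmse", "mae"),
               atom_regression = c("rmse", "mae"))
  stopifnot(metric %in% ok, repeats >= 1)
  structure(list(kind = kind, metric = metric, repeats = repeats),
            class = "t3d_task_spec")
}

#' Evaluate predictions under a named metric
#'
#' ROC-AUC is computed by the rank statistic (ties counted one half),
#' identical to exhaustive positive/negative pair counting. For matrix
#' inputs (multi-task classification) the mean AUC over tasks with at
#' least one positive and one negative label is returned, with the number
#' of excluded tasks in the `"excluded"` attribute.
#'
#' @param predictions numeric vector (or matrix for multi-task) of scores.
#' @param labels matching labels (0/1 for classification).
#' @param metric "roc_auc", "rmse", or "mae".
#' @return the score (named attributes for exclusions).
#' @export
evaluate_metric <- function(predictions, labels,
                            metric = c("roc_auc", "rmse", "mae")) {
  metric <- match.arg(metric)
  if (is.matrix(labels) && ncol(labels) > 1) {
    stopifnot(metric == "roc_auc")
    per <- vapply(seq_len(ncol(labels)), function(k) {
      keep <- !is.na(labels[, k])
      y <- labels[keep, k]
      if (length(unique(y)) < 2) return(NA_real_)
      evaluate_metric(predictions[keep, k], y, "roc_auc")
    }, 0)
    out <- mean(per, na.rm = TRUE)
    attr(out, "excluded") <- sum(is.na(per))
    return(out)
  }
  keep <- !is.na(labels)
  predictions <- predictions[keep]; labels <- labels[keep]
  switch(metric,
         roc_auc = {
           pos <- labels == 1
           n1 <- sum(pos); n0 <- sum(!pos)
           if (n1 == 0 || n0 == 0) {
             stop(t3d_error("t3d_metric_error",
                            "ROC-AUC needs both classes present"))
           }
           r <- rank(predictions)
           (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
         },
         rmse = sqrt(mean((predictions - labels)^2)),
         mae = mean(abs(predictions - labels)))
}

#' Fine-tuning configuration
#'
#' @param epochs maximum epochs (default 100).
#' @param patience early-stopping patience on the validation metric
#'   (default 10).
#' @param lr,batch_size Adam settings.
#' @param seed base seed; repeat r uses `seed + r - 1`.
#' @param network the `t3d_network_config` of the encoder.
#' @return a `t3d_finetune_config`.
#' @export
finetune_config <- function(epochs = 100, patience = 10, lr = 1e-3,
                            batch_size = 16, seed = 1,
                            network = network_config()) {
  structure(list(epochs = epochs, patience = patience, lr = lr,
                 batch_size = batch_size, seed = seed, network = network),
            class = "t3d_finetune_config")
}

metric_better <- function(metric) {
  if (metric == "roc_auc") function(a, b) a > b else function(a, b) a < b
}

finetune_predict <- function(net, head, recs, task, config) {
  lapply(recs, function(rec) {
    emb <- forward_network(net, rec$graph, rec$feats, config$network)
    if (task$kind == "atom_regression") {
      drop(mlp2_fwd(head, emb$h_atom)$y)
    } else {
      y <- mlp2_fwd(head, matrix(emb$h_graph, 1))$y[1, 1]
      if (task$kind == "classification") stats::plogis(y) else y
    }
  })
}

finetune_collect <- function(preds, labels, ids, task) {
  if (task$kind == "atom_regression") {
    list(p = unlist(preds[ids]), y = unlist(labels[ids]))
  } else {
    list(p = unlist(preds[ids]), y = unlist(labels[ids]))
  }
}

#' Fine-tune a supervised head on (pre)trained embeddings
#'
#' Attaches a two-layer perceptron to the pooled embedding (molecule
#' tasks) or the final atom states (atom tasks) and trains end-to-end
#' with Adam, selecting the epoch with the best validation metric
#' (early stopping) and scoring it on the test partition. The whole
#' procedure is repeated `task$repeats` times with distinct seeds.
#'
#' @param dataset named list of records from [prepare_dataset()] (names
#'   are molecule ids).
#' @param labels named numeric vector (molecule tasks; NA allowed,
#'   dropped with a warning) or named list of per-atom numeric vectors
#'   (atom tasks).
#' @param task a `t3d_task_spec`.
#' @param split a `t3d_scaffold_split`.
#' @param config a `t3d_finetune_config`.
#' @param init optional pretrained encoder (`t3d_pretrain_fit` or its
#'   `$net`); NULL trains from scratch.
#' @return a `t3d_finetune_fit`: `mean`, `sd`, per-repeat `scores`,
#'   `metric`, and the best model of the last repeat (`net`, `head`).
#' @export
fit_head <- function(dataset, labels, task, split,
                     config = finetune_config(), init = NULL) {
  stopifnot(inherits(task, "t3d_task_spec"),
            inherits(split, "t3d_scaffold_split"))
  ids <- names(dataset)
  stopifnot(!is.null(ids))
  mol_level <- task$kind != "atom_regression"
  if (mol_level) {
    labels <- labels[ids]
    if (anyNA(labels)) {
      bad <- ids[is.na(labels)]
      warning(sprintf("dropping %d molecule(s) with missing labels",
                      length(bad)))
      keep_tv <- function(v) setdiff(v, bad)
      split$train <- keep_tv(split$train); split$valid <- keep_tv(split$valid)
      split$test <- keep_tv(split$test)
    }
    if (task$kind == "classification" &&
        length(unique(labels[split$train])) < 2) {
      stop(t3d_error("t3d_label_error",
                     "training labels contain a single class"))
    }
  }
  if (length(split$train) == 0 || length(split$valid) == 0 ||
      length(split$test) == 0) {
    stop(t3d_error("t3d_split_error",
                   "empty train/valid/test partition; need more scaffold diversity"))
  }
  if (!is.null(init) && inherits(init, "t3d_pretrain_fit")) init <- init$net
  feat_dims <- dataset[[1]]$feats$dims
  h <- config$network$hidden
  better <- metric_better(task$metric)
  scores <- numeric(task$repeats)
  best_model <- NULL

  for (r in seq_len(task$repeats)) {
    seed_r <- config$seed + r - 1L
    net <- if (is.null(init)) {
      init_network(feat_dims, config$network, seed = seed_r)
    } else {
      init
    }
    set.seed(seed_r * 131 + 7)
    head <- mlp2_init(h, h, 1)
    opt <- list(emb = net$emb, layers = net$layers, head = head)
    state <- adam_init(opt)
    best <- NULL; best_score <- NULL; stall <- 0

    for (epoch in seq_len(config$epochs)) {
      set.seed(seed_r * 100003 + epoch)
      order_ <- sample(split$train)
      batches <- split(order_,
                       ceiling(seq_along(order_) / config$batch_size))
      for (batch in batches) {
        acc <- NULL
        for (id in batch) {
          rec <- dataset[[id]]
          emb <- forward_network(net, rec$graph, rec$feats, config$network,
                                 training = TRUE, keep_cache = TRUE)
          n <- rec$graph$n_atoms
          if (task$kind == "atom_regression") {
            f <- mlp2_fwd(head, emb$h_atom)
            y <- labels[[id]]
            dy <- matrix(2 * (drop(f$y) - y) / n, ncol = 1)
            bk <- mlp2_bwd(head, f$cache, dy)
            dHK <- bk$dX
          } else {
            f <- mlp2_fwd(head, matrix(emb$h_graph, 1))
            y <- labels[[id]]
            if (task$kind == "classification") {
              p <- stats::plogis(f$y[1, 1])
              dout <- p - y
            } else {
              dout <- 2 * (f$y[1, 1] - y)
            }
            bk <- mlp2_bwd(head, f$cache, matrix(dout, 1, 1))
            dHK <- matrix(bk$dX[1, ] / n, n, h, byrow = TRUE)
          }
          ng <- backward_network(net, rec$graph, emb, dHK, config$network)
          g <- list(emb = ng$emb, layers = ng$layers, head = bk$grads)
          acc <- if (is.null(acc)) g else tree_axpy(acc, g)
        }
        acc <- tree_map(function(x) x / length(batch), acc)
        st <- adam_step(opt, acc, state, lr = config$lr)
        opt <- st$params; state <- st$state
        net$emb <- opt$emb; net$layers <- opt$layers; head <- opt$head
      }
      vp <- finetune_predict(net, head, dataset[split$valid], task, config)
      vc <- finetune_collect(vp, labels, split$valid, task)
      vscore <- evaluate_metric(vc$p, vc$y, task$metric)
      if (is.null(best_score) || better(vscore, best_score)) {
        best_score <- vscore
        best <- list(net = net, head = head)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= config$patience) break
      }
    }
    tp <- finetune_predict(best$net, best$head, dataset[split$test], task,
                           config)
    tc <- finetune_collect(tp, labels, split$test, task)
    scores[r] <- evaluate_metric(tc$p, tc$y, task$metric)
    best_model <- best
  }
  structure(list(mean = mean(scores), sd = stats::sd(scores),
                 scores = scores, metric = task$metric, task = task,
                 net = best_model$net, head = best_model$head,
                 config = config),
            class = "t3d_finetune_fit")
}

#' @export
print.t3d_finetune_fit <- function(x, ...) {
  cat(sprintf("<finetune fit: %s = %.4f +/- %.4f over %d repeats>\n",
              x$metric, x$mean, if (is.na(x$sd)) 0 else x$sd,
              length(x$scores)))
  invisible(x)
}

#' Embed molecules with a (pre)trained encoder
#'
#' @param net encoder parameters.
#' @param dataset records from [prepare_dataset()].
#' @param config the matching `t3d_network_config`.
#' @return matrix (one row per molecule) of pooled embeddings; rownames
#'   are molecule ids.
#' @export
embed_molecules <- function(net, dataset, config = network_config()) {
  out <- t(vapply(dataset, function(rec) {
    forward_network(net, rec$graph, rec$feats, config)$h_graph
  }, numeric(net$hidden)))
  rownames(out) <- vapply(dataset, function(r) r$mol$id, "")
  out
}
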