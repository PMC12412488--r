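#' Three-level geometric message passing
#'
#' The encoder runs K iterations; within each iteration the three graphs
#' are updated top-down (angle-dihedral I, then bond-angle H, then
#' atom-bond G) so that each lower level consumes the current iteration's
#' higher-level states as edge embeddings:
#' \itemize{
#'   \item I: every bond angle aggregates its neighbor angles across the
#'     incident dihedrals, with the dihedral's torsion embedding as the
#'     edge feature;
#'   \item H: every bond aggregates its neighbor bonds through the shared
#'     angle, with that angle's current hidden state as the edge feature;
#'   \item G: every atom aggregates its neighbor atoms, with the
#'     connecting bond's current hidden state as the edge feature.
#' }
#' Aggregation and combination follow the Graph Isomorphism Network:
#' sum aggregation and a two-layer perceptron applied to
#' (1 + eps) h + a, with optional residual connection, layer
#' normalization (with learnable gain and bias), and graph normalization
#' (aggregates scaled by 1/sqrt(level size)). The readout is average pooling of the final
#' atom states. All inputs are internal coordinates, so the embedding is
#' invariant to proper rigid motions and atom permutations, while the
#' signed torsion features make it sensitive to mirror reflection.
#' @name network
NULL

#' Network configuration
#'
#' @param hidden hidden width of all states (default 32).
#' @param K number of message-passing iterations (default 8).
#' @param dropout dropout rate on the perceptron hidden layer during
#'   training (default 0.2).
#' @param residual,layernorm,graphnorm architecture flags (all TRUE).
#' @param readout readout kind; only "mean" is provided.
#' @param use_angle_level if FALSE, both the bond-angle and angle-dihedral
#'   updates are disabled (plain atom-bond GNN).
#' @param use_dihedral_level if FALSE, the angle-dihedral update is
#'   disabled (bond-angle model without torsion messages).
#' @return a `t3d_network_config`.
#' @export
network_config <- function(hidden = 32, K = 8, dropout = 0.2,
                           residual = TRUE, layernorm = TRUE,
                           graphnorm = TRUE, readout = "mean",
                           use_angle_level = TRUE,
                           use_dihedral_level = TRUE) {
  stopifnot(K >= 1, hidden >= 1, dropout >= 0, dropout < 1,
            readout == "mean")
  structure(list(hidden = hidden, K = K, dropout = dropout,
                 residual = residual, layernorm = layernorm,
                 graphnorm = graphnorm, readout = readout,
                 use_angle_level = use_angle_level,
                 use_dihedral_level = use_dihedral_level),
            class = "t3d_network_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

mlp2_init <- function(nin, nhidden, nout) {
  list(W1 = glorot(nin, nhidden), b1 = rep(0, nhidden),
       W2 = glorot(nhidden, nout), b2 = rep(0, nout))
}

gin_init <- function(h, layernorm = TRUE) {
  out <- c(mlp2_init(h, h, h), list(eps = 0))
  if (layernorm) {
    out$ln_g <- rep(1, h)  # layer-norm gain/bias (Ba-style affine)
    out$ln_b <- rep(0, h)
  }
  out
}

#' Initialize encoder parameters
#'
#' @param feat_dims named vector of input feature widths (from
#'   [featurize()]'s `dims`).
#' @param config a `t3d_network_config`.
#' @param seed integer seed for the weight draw.
#' @return parameter tree: linear input embeddings per feature family plus
#'   K per-iteration GIN blocks for the three levels.
#' @export
init_network <- function(feat_dims, config = network_config(), seed = 1) {
  set.seed(seed)
  h <- config$hidden
  layers <- lapply(seq_len(config$K), function(t) {
    list(I = gin_init(h, config$layernorm),
         H = gin_init(h, config$layernorm),
         G = gin_init(h, config$layernorm))
  })
  structure(list(
    emb = list(atom = list(W = glorot(feat_dims[["atom"]], h), b = rep(0, h)),
               bond = list(W = glorot(feat_dims[["bond"]], h), b = rep(0, h)),
               angle = list(W = glorot(feat_dims[["angle"]], h), b = rep(0, h)),
               dihedral = list(W = glorot(feat_dims[["dihedral"]], h),
                               b = rep(0, h))),
    layers = layers,
    feat_dims = feat_dims, hidden = h, K = config$K),
    class = "t3d_network_params")
}

# ---- primitive forward/backward pieces --------------------------------

scatter_sum <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  if (length(idx) > 0 && nrow(M) > 0) {
    tmp <- rowsum(M, idx)
    out[as.integer(rownames(tmp)), ] <- tmp
  }
  out
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  if (nrow(x) == 0) {
    return(list(y = x, xhat = x, sd = numeric()))
  }
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  sd <- sqrt(v + eps)
  xhat <- (x - mu) / sd
  list(y = sweep(sweep(xhat, 2, g, `*`), 2, b, `+`), xhat = xhat, sd = sd)
}

layernorm_bwd <- function(dy, ln, g) {
  if (nrow(dy) == 0) {
    return(list(dx = dy, dg = numeric(length(g)), db = numeric(length(g))))
  }
  dg <- colSums(dy * ln$xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- (dxhat - rowMeans(dxhat) - ln$xhat * rowMeans(dxhat * ln$xhat)) /
    ln$sd
  list(dx = dx, dg = dg, db = db)
}

gin_combine_fwd <- function(par, H_prev, A, config, dropmask = NULL) {
  z <- (1 + par$eps) * H_prev + A
  u1 <- z %*% par$W1
  u1 <- sweep(u1, 2, par$b1, `+`)
  r1 <- pmax(u1, 0)
  r1d <- if (is.null(dropmask)) r1 else r1 * dropmask
  u2 <- r1d %*% par$W2
  u2 <- sweep(u2, 2, par$b2, `+`)
  u3 <- if (config$residual) u2 + H_prev else u2
  ln <- NULL
  if (config$layernorm) {
    ln <- layernorm_fwd(u3, par$ln_g, par$ln_b)
    y <- ln$y
  } else {
    y <- u3
  }
  list(y = y, cache = list(H_prev = H_prev, z = z, u1 = u1, r1d = r1d,
                           ln = ln, dropmask = dropmask))
}

gin_combine_bwd <- function(par, cache, dy, config) {
  dln_g <- NULL; dln_b <- NULL
  if (config$layernorm) {
    lb <- layernorm_bwd(dy, cache$ln, par$ln_g)
    du3 <- lb$dx; dln_g <- lb$dg; dln_b <- lb$db
  } else {
    du3 <- dy
  }
  dH_prev <- if (config$residual) du3 else matrix(0, nrow(du3), ncol(du3))
  du2 <- du3
  dW2 <- t(cache$r1d) %*% du2
  db2 <- colSums(du2)
  dr1d <- du2 %*% t(par$W2)
  dr1 <- if (is.null(cache$dropmask)) dr1d else dr1d * cache$dropmask
  du1 <- dr1 * (cache$u1 > 0)
  dW1 <- t(cache$z) %*% du1
  db1 <- colSums(du1)
  dz <- du1 %*% t(par$W1)
  dH_prev <- dH_prev + (1 + par$eps) * dz
  deps <- sum(dz * cache$H_prev)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, eps = deps)
  if (config$layernorm) {
    grads$ln_g <- dln_g
    grads$ln_b <- dln_b
  }
  list(dH_prev = dH_prev, dA = dz, grads = grads)
}

lin_fwd <- function(par, x) sweep(x %*% par$W, 2, par$b, `+`)

# ---- full encoder ------------------------------------------------------

#' Run the encoder on one molecule
#'
#' @param params a `t3d_network_params`.
#' @param graph a `t3d_trigraph`.
#' @param feats a `t3d_features` (possibly masked).
#' @param config the `t3d_network_config` used at [init_network()] time.
#' @param training if TRUE, dropout is applied (uses the R RNG stream).
#' @param keep_cache if TRUE, intermediates for [backward_network()] are
#'   retained.
#' @return a `t3d_embedding`: `h_graph` (mean-pooled molecule vector),
#'   `h_atom` (final per-atom states), and optionally `cache`.
#' @export
forward_network <- function(params, graph, feats, config,
                            training = FALSE, keep_cache = FALSE) {
  n <- graph$n_atoms
  m <- nrow(graph$bonds)
  a <- nrow(graph$angles)
  H_atom <- lin_fwd(params$emb$atom, feats$x_atom)
  H_bond <- lin_fwd(params$emb$bond, feats$x_bond)
  H_angle <- lin_fwd(params$emb$angle, feats$x_angle)
  E_dih <- lin_fwd(params$emb$dihedral, feats$x_dihedral)
  h <- params$hidden
  p <- config$dropout
  caches <- if (keep_cache) vector("list", config$K)
  check <- function(x, t, level) {
    if (nrow(x) > 0 && any(!is.finite(x))) {
      stop(t3d_error("t3d_numeric_error",
                     sprintf("non-finite state at iteration %d, level %s",
                             t, level)))
    }
    x
  }
  dmask <- function(nr) {
    if (!training || p <= 0 || nr == 0) return(NULL)
    matrix(stats::rbinom(nr * h, 1, 1 - p) / (1 - p), nr, h)
  }
  for (t in seq_len(config$K)) {
    cc <- list()
    if (config$use_angle_level && config$use_dihedral_level) {
      M <- H_angle[graph$i_edges$src_angle, , drop = FALSE] +
        E_dih[graph$i_edges$dihedral, , drop = FALSE]
      A <- scatter_sum(M, graph$i_edges$dst_angle, a)
      if (config$graphnorm) A <- A / sqrt(max(a, 1))
      res <- gin_combine_fwd(params$layers[[t]]$I, H_angle, A, config,
                             dmask(a))
      H_angle <- check(res$y, t, "I")
      cc$I <- res$cache
    }
    if (config$use_angle_level) {
      M <- H_bond[graph$h_edges$src_bond, , drop = FALSE] +
        H_angle[graph$h_edges$angle, , drop = FALSE]
      A <- scatter_sum(M, graph$h_edges$dst_bond, m)
      if (config$graphnorm) A <- A / sqrt(max(m, 1))
      res <- gin_combine_fwd(params$layers[[t]]$H, H_bond, A, config,
                             dmask(m))
      cc$H_angle_in <- H_angle
      H_bond <- check(res$y, t, "H")
      cc$H <- res$cache
    }
    M <- H_atom[graph$g_edges$src, , drop = FALSE] +
      H_bond[graph$g_edges$bond, , drop = FALSE]
    A <- scatter_sum(M, graph$g_edges$dst, n)
    if (config$graphnorm) A <- A / sqrt(max(n, 1))
    res <- gin_combine_fwd(params$layers[[t]]$G, H_atom, A, config,
                           dmask(n))
    cc$G_bond_in <- H_bond
    H_atom <- check(res$y, t, "G")
    cc$G <- res$cache
    if (keep_cache) caches[[t]] <- cc
  }
  structure(list(h_graph = colMeans(H_atom), h_atom = H_atom,
                 cache = if (keep_cache) {
                   list(layers = caches, feats = feats)
                 }),
            class = "t3d_embedding")
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else rep(0, length(x))
}

#' Backpropagate through the encoder
#'
#' @param params encoder parameters used in the forward pass.
#' @param graph,config as in [forward_network()].
#' @param emb the `t3d_embedding` returned with `keep_cache = TRUE`.
#' @param d_h_atom gradient of the loss w.r.t. the final atom states
#'   (n x hidden); gradients w.r.t. the pooled vector should be spread as
#'   `matrix(d_h_graph / n, n, hidden, byrow = TRUE)` and added.
#' @return gradient tree matching `params`.
#' @export
backward_network <- function(params, graph, emb, d_h_atom, config) {
  stopifnot(!is.null(emb$cache))
  n <- graph$n_atoms; m <- nrow(graph$bonds); a <- nrow(graph$angles)
  h <- params$hidden
  grads <- zero_like(params[c("emb", "layers")])
  dH_atom <- d_h_atom
  dH_bond <- matrix(0, m, h)
  dH_angle <- matrix(0, a, h)
  dE_dih <- matrix(0, nrow(emb$cache$feats$x_dihedral), h)
  for (t in rev(seq_len(config$K))) {
    cc <- emb$cache$layers[[t]]
    # G level
    bk <- gin_combine_bwd(params$layers[[t]]$G, cc$G, dH_atom, config)
    grads$layers[[t]]$G <- bk$grads
    dA <- bk$dA
    if (config$graphnorm) dA <- dA / sqrt(max(n, 1))
    dM <- dA[graph$g_edges$dst, , drop = FALSE]
    dH_atom <- bk$dH_prev +
      scatter_sum(dM, graph$g_edges$src, n)
    dH_bond <- dH_bond + scatter_sum(dM, graph$g_edges$bond, m)
    # H level
    if (config$use_angle_level) {
      bk <- gin_combine_bwd(params$layers[[t]]$H, cc$H, dH_bond, config)
      grads$layers[[t]]$H <- bk$grads
      dA <- bk$dA
      if (config$graphnorm) dA <- dA / sqrt(max(m, 1))
      dM <- dA[graph$h_edges$dst_bond, , drop = FALSE]
      dH_bond <- bk$dH_prev +
        scatter_sum(dM, graph$h_edges$src_bond, m)
      dH_angle <- dH_angle + scatter_sum(dM, graph$h_edges$angle, a)
    }
    # I level
    if (config$use_angle_level && config$use_dihedral_level) {
      bk <- gin_combine_bwd(params$layers[[t]]$I, cc$I, dH_angle, config)
      grads$layers[[t]]$I <- bk$grads
      dA <- bk$dA
      if (config$graphnorm) dA <- dA / sqrt(max(a, 1))
      dM <- dA[graph$i_edges$dst_angle, , drop = FALSE]
      dH_angle <- bk$dH_prev +
        scatter_sum(dM, graph$i_edges$src_angle, a)
      dE_dih <- dE_dih +
        scatter_sum(dM, graph$i_edges$dihedral, nrow(dE_dih))
    }
  }
  feats <- emb$cache$feats
  grads$emb$atom <- list(W = t(feats$x_atom) %*% dH_atom,
                         b = colSums(dH_atom))
  grads$emb$bond <- list(W = t(feats$x_bond) %*% dH_bond,
                         b = colSums(dH_bond))
  grads$emb$angle <- list(W = t(feats$x_angle) %*% dH_angle,
                          b = colSums(dH_angle))
  grads$emb$dihedral <- list(W = t(feats$x_dihedral) %*% dE_dih,
                             b = colSums(dE_dih))
  grads
}
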