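#' Parameter-tree utilities and the Adam optimizer
#'
#' Parameters and gradients are nested lists of matrices/vectors; these
#' helpers map elementwise functions over aligned trees.
#' @name optim
#' @keywords internal
NULL

tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(k) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, k)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

tree_axpy <- function(acc, g, a = 1) tree_map(function(x, y) x + a * y, acc, g)

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

#' Initialize Adam state for a parameter tree
#' @param params parameter tree.
#' @return optimizer state.
#' @export
adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

#' One Adam update
#'
#' @param params parameter tree.
#' @param grads matching gradient tree.
#' @param state from [adam_init()].
#' @param lr learning rate (default 1e-3).
#' @param beta1,beta2,eps standard Adam constants.
#' @return list(params, state).
#' @export
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
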