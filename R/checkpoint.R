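#' Checkpoint I/O
#'
#' Weights are serialized to JSON with a versioned header carrying the
#' network configuration and input feature widths; loading refuses a
#' checkpoint whose dimensions do not match the requested ones.
#' @name checkpoint
NULL

#' Save encoder (and optional head) weights
#'
#' @param net a `t3d_network_params`.
#' @param path output file (JSON).
#' @param heads optional head parameter list.
#' @param extra optional named metadata list stored in the header (e.g.
#'   parent checkpoints of a chained run).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, heads = NULL, extra = NULL) {
  payload <- list(
    format = "tripod3d-checkpoint",
    version = 1L,
    hidden = net$hidden,
    K = net$K,
    feat_dims = as.list(net$feat_dims),
    emb = net$emb,
    layers = net$layers,
    heads = heads,
    extra = extra)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

relist_matrices <- function(x) {
  if (is.list(x) && length(x) > 0 && all(vapply(x, is.numeric, TRUE)) &&
      length(unique(vapply(x, length, 1L))) == 1 &&
      length(x[[1]]) > 0 && is.null(names(x))) {
    return(do.call(rbind, x))
  }
  if (is.list(x)) return(lapply(x, relist_matrices))
  x
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @param feat_dims optional named vector; when given, loading fails if
#'   the checkpoint was built for different input feature widths.
#' @return list with `net` (a `t3d_network_params`), `heads` (or NULL),
#'   and `extra` metadata.
#' @export
load_checkpoint <- function(path, feat_dims = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(raw$format, "tripod3d-checkpoint")) {
    stop(t3d_error("t3d_checkpoint_error", "not a tripod3d checkpoint"))
  }
  stored_dims <- unlist(raw$feat_dims)
  if (!is.null(feat_dims) &&
      !isTRUE(all.equal(as.numeric(stored_dims[names(feat_dims)]),
                        as.numeric(feat_dims),
                        check.attributes = FALSE))) {
    stop(t3d_error("t3d_checkpoint_error",
                   "checkpoint feature dimensions do not match"))
  }
  net <- structure(list(emb = relist_matrices(raw$emb),
                        layers = relist_matrices(raw$layers),
                        feat_dims = stored_dims,
                        hidden = raw$hidden, K = raw$K),
                   class = "t3d_network_params")
  heads <- if (!is.null(raw$heads)) relist_matrices(raw$heads)
  list(net = net, heads = heads, extra = raw$extra)
}
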