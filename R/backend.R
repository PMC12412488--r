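#' @title RDKit backend bridge
#' @description Internal helpers that delegate cheminformatics plumbing
#'   (SMILES/SDF perception, MMFF94 conformer embedding, stereoisomer
#'   enumeration, Murcko scaffolds) to the bundled RDKit helper script,
#'   batched so one Python process serves a whole molecule list.
#' @name backend
#' @keywords internal
NULL

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "tripod3d")
  if (!nzchar(path) || !file.exists(path)) {
    stop("tripod3d: bundled chem_backend.py not found", call. = FALSE)
  }
  path
}

backend_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("tripod3d: no 'python' on PATH", call. = FALSE)
  unname(py)
}

#' Run one batched request against the RDKit helper
#'
#' @param op one of "parse", "conformer", "stereo", "scaffold".
#' @param molecules list of records, each `list(id=, smiles=)` or
#'   `list(id=, sdf=)`.
#' @param ... extra request fields (`n_candidates`, `seed`, `generic`).
#' @return list of per-molecule result records, in input order.
#' @keywords internal
chem_backend <- function(op, molecules, ...) {
  req <- c(list(op = op, molecules = unname(molecules)), list(...))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(req, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(backend_python(), c(backend_script(), fin, fout),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("tripod3d: chemistry backend failed (exit ", status, ")",
         call. = FALSE)
  }
  out <- jsonlite::read_json(fout, simplifyVector = FALSE)
  out$results
}
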