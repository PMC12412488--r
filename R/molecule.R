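#' Molecule records
#'
#' A `t3d_molecule` is the universal input record: a heavy-atom graph with
#' optional 3D coordinates and optional electronic-structure labels.
#' Explicit hydrogens are removed at parse time; the implicit-hydrogen count
#' is kept as an atom attribute. Fields:
#' \describe{
#'   \item{id}{stable identifier string.}
#'   \item{atoms}{data.frame: element, formal_charge, degree, num_h,
#'     hybridization, aromatic, in_ring, chirality.}
#'   \item{bonds}{data.frame (1-based atom indices i < j): i, j, order
#'     (1, 1.5, 2, 3), aromatic, in_ring, stereo.}
#'   \item{coords}{n x 3 matrix of coordinates in Angstrom, or NULL.}
#'   \item{atom_labels}{optional per-atom partial charges.}
#'   \item{bond_labels}{optional per-bond Wiberg-style orders.}
#' }
#' @name molecule
NULL

t3d_error <- function(class, msg) {
  structure(class = c(class, "t3d_error", "error", "condition"),
            list(message = msg, call = NULL))
}

result_to_molecule <- function(res, smiles = NULL, sdf = NULL) {
  if (!is.null(res$error)) {
    stop(t3d_error("t3d_parse_error",
                   sprintf("molecule '%s': %s", res$id, res$error)))
  }
  atoms <- do.call(rbind, lapply(res$atoms, function(a) {
    data.frame(element = a$element, formal_charge = a$formal_charge,
               degree = a$degree, num_h = a$num_h,
               hybridization = a$hybridization, aromatic = a$aromatic,
               in_ring = a$in_ring, chirality = a$chirality,
               stringsAsFactors = FALSE)
  }))
  if (length(res$bonds) > 0) {
    bonds <- do.call(rbind, lapply(res$bonds, function(b) {
      i <- b$i + 1L; j <- b$j + 1L
      data.frame(i = min(i, j), j = max(i, j), order = b$order,
                 kek_order = b$kek_order, aromatic = b$aromatic,
                 in_ring = b$in_ring, stereo = b$stereo,
                 stringsAsFactors = FALSE)
    }))
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric(),
                        kek_order = integer(), aromatic = logical(),
                        in_ring = logical(), stereo = character(),
                        stringsAsFactors = FALSE)
  }
  coords <- NULL
  if (!is.null(res$coords)) {
    coords <- matrix(unlist(res$coords), ncol = 3, byrow = TRUE)
  }
  mol <- structure(list(id = as.character(res$id), atoms = atoms,
                        bonds = bonds, coords = coords,
                        atom_labels = NULL, bond_labels = NULL,
                        smiles = smiles, sdf = sdf),
                   class = "t3d_molecule")
  validate_molecule(mol)
  mol
}

#' Validate the structural invariants of a molecule record
#'
#' Checks bond endpoints, duplicate bonds, and coordinate shape/finiteness.
#' @param mol a `t3d_molecule`.
#' @return `mol`, invisibly; errors on violation.
#' @export
validate_molecule <- function(mol) {
  n <- nrow(mol$atoms)
  if (n < 1) stop(t3d_error("t3d_parse_error", "molecule has zero atoms"))
  b <- mol$bonds
  if (nrow(b) > 0) {
    stopifnot(all(b$i >= 1), all(b$j <= n), all(b$i != b$j))
    if (anyDuplicated(paste(b$i, b$j))) {
      stop(t3d_error("t3d_parse_error", "duplicate undirected bond"))
    }
  }
  if (!is.null(mol$coords)) {
    stopifnot(is.matrix(mol$coords), nrow(mol$coords) == n,
              ncol(mol$coords) == 3, all(is.finite(mol$coords)))
  }
  invisible(mol)
}

looks_like_sdf <- function(text) {
  grepl("V2000", text, fixed = TRUE) || grepl("M  END", text, fixed = TRUE)
}

#' Parse a molecule from SMILES or an SDF block
#'
#' Returns a sanitized heavy-atom molecule; explicit hydrogens are folded
#' into the per-atom implicit-H count. SDF coordinates, if present, are
#' attached. For many molecules prefer [parse_molecules()], which makes a
#' single batched backend call.
#'
#' @param text a SMILES string or a single-record SDF (molblock) string.
#' @param id identifier attached to the molecule (used in error messages).
#' @return a `t3d_molecule`.
#' @export
#' @examples \dontrun{
#' parse_molecule("CCO", "ethanol")
#' }
parse_molecule <- function(text, id = "mol") {
  parse_molecules(stats::setNames(text, id))[[1]]
}

#' Parse a batch of molecules in one backend call
#'
#' @param texts character vector of SMILES strings or SDF blocks; names are
#'   used as ids (defaulting to `mol1..molN`).
#' @return list of `t3d_molecule`.
#' @export
parse_molecules <- function(texts) {
  ids <- names(texts)
  if (is.null(ids)) ids <- paste0("mol", seq_along(texts))
  recs <- lapply(seq_along(texts), function(k) {
    if (looks_like_sdf(texts[[k]])) list(id = ids[[k]], sdf = texts[[k]])
    else list(id = ids[[k]], smiles = texts[[k]])
  })
  out <- chem_backend("parse", recs)
  lapply(seq_along(out), function(k) {
    result_to_molecule(out[[k]],
                       smiles = if (is.null(recs[[k]]$sdf)) texts[[k]],
                       sdf = recs[[k]]$sdf)
  })
}

#' Generate an MMFF94 conformer
#'
#' Embeds `n_candidates` 3D conformers, optimizes each with the MMFF94
#' force field, and attaches the lowest-energy one. Deterministic for a
#' fixed seed. For many molecules prefer [generate_conformers()].
#'
#' @param mol a `t3d_molecule`.
#' @param n_candidates number of embedded candidates (>= 1).
#' @param seed integer RNG seed for the embedding.
#' @return the molecule with `coords` set.
#' @export
generate_conformer <- function(mol, n_candidates = 1, seed = 0) {
  generate_conformers(list(mol), n_candidates = n_candidates,
                      seed = seed)[[1]]
}

#' Generate MMFF94 conformers for a list of molecules (one backend call)
#'
#' @inheritParams generate_conformer
#' @param mols list of `t3d_molecule`.
#' @return list of molecules with `coords` set.
#' @export
generate_conformers <- function(mols, n_candidates = 1, seed = 0) {
  stopifnot(n_candidates >= 1)
  recs <- lapply(mols, function(m) {
    if (!is.null(m$smiles)) list(id = m$id, smiles = m$smiles)
    else list(id = m$id, sdf = m$sdf)
  })
  out <- chem_backend("conformer", recs, n_candidates = n_candidates,
                      seed = seed)
  lapply(seq_along(mols), function(k) {
    res <- out[[k]]
    if (!is.null(res$error)) {
      stop(t3d_error("t3d_embed_error",
                     sprintf("conformer generation failed for '%s': %s",
                             mols[[k]]$id, res$error)))
    }
    mol <- mols[[k]]
    mol$coords <- matrix(unlist(res$coords), ncol = 3, byrow = TRUE)
    validate_molecule(mol)
    mol
  })
}

#' Reflect a conformer through the xy-plane
#'
#' Produces the mirror-image geometry (the enantiomeric conformer): every
#' bond length and bond angle is preserved while every non-degenerate
#' torsion changes sign.
#'
#' @param mol a molecule with coordinates.
#' @return the molecule with `coords[, 3]` negated.
#' @export
mirror_conformer <- function(mol) {
  stopifnot(!is.null(mol$coords))
  mol$coords[, 3] <- -mol$coords[, 3]
  mol$id <- paste0(mol$id, "_mirror")
  mol
}

#' @export
print.t3d_molecule <- function(x, ...) {
  cat(sprintf("<t3d_molecule '%s': %d atoms, %d bonds, coords: %s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (is.null(x$coords)) "none" else "3D"))
  invisible(x)
}

#' Read a SMILES file
#'
#' One molecule per line, `SMILES<TAB>id` with the id optional.
#'
#' @param path file path.
#' @return named character vector of SMILES (names = ids), ready for
#'   [parse_molecules()].
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  smi <- vapply(parts, `[[`, "", 1)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) >= 2) parts[[k]][[2]] else paste0("mol", k)
  }, "")
  stats::setNames(smi, ids)
}

#' Split a multi-record SDF file into molblock strings
#'
#' @param path SDF (V2000) file path.
#' @return named character vector of molblocks (names from the title line
#'   or record index), ready for [parse_molecules()].
#' @export
read_sdf_file <- function(path) {
  txt <- readLines(path, warn = FALSE)
  idx <- cumsum(c(0, head(txt, -1) == "$$$$"))
  blocks <- split(txt, idx)
  blocks <- lapply(blocks, function(b) b[b != "$$$$"])
  blocks <- Filter(function(b) any(grepl("V2000", b, fixed = TRUE)), blocks)
  out <- vapply(blocks, paste, "", collapse = "\n")
  ids <- vapply(seq_along(blocks), function(k) {
    ttl <- trimws(blocks[[k]][1])
    if (nzchar(ttl)) ttl else paste0("mol", k)
  }, "")
  stats::setNames(unname(out), ids)
}

#' Write molecules with coordinates to an SDF (V2000) file
#'
#' Used as the conformer cache so a pretraining run can resume without
#' re-embedding; records round-trip through [read_sdf_file()] /
#' [parse_molecules()].
#'
#' @param mols list of molecules with coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    stopifnot(!is.null(mol$coords))
    n <- nrow(mol$atoms); m <- nrow(mol$bonds)
    lines <- c(mol$id, "  tripod3d", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
    for (u in seq_len(n)) {
      lines <- c(lines, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        mol$coords[u, 1], mol$coords[u, 2], mol$coords[u, 3],
        mol$atoms$element[u]))
    }
    if (m > 0) {
      # kekulized orders: type-4 aromatic records do not survive a
      # round-trip through RDKit without explicit hydrogens
      btype <- mol$bonds$kek_order
      for (b in seq_len(m)) {
        lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$i[b],
                                  mol$bonds$j[b], btype[b]))
      }
    }
    chg <- which(mol$atoms$formal_charge != 0)
    if (length(chg) > 0) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        lines <- c(lines, paste0(sprintf("M  CHG%3d", length(grp)),
                                 paste(sprintf("%4d%4d", grp,
                                               mol$atoms$formal_charge[grp]),
                                       collapse = "")))
      }
    }
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
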