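#' Single-chain structure
#'
#' The input unit of all descriptor computation: the retained atoms of one
#' chain of a PDB entry. Constructed by [read_structure()]; users rarely need
#' to build one by hand.
#'
#' @param structure_id identifier of the parent structure (usually the file
#'   stem); database entries are keyed `"<structure_id>_<chain_id>"`.
#' @param chain_id single-character chain identifier.
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `chain_id`, `residue_seq`, `x`, `y`, `z`, `is_hetero`.
#' @return an object of class `chain_structure`.
#' @export
chain_structure <- function(structure_id, chain_id, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  need <- c("serial", "name", "element", "residue_name", "chain_id",
            "residue_seq", "x", "y", "z", "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (!all(atoms$chain_id == chain_id))
    stop("all atoms must share chain_id '", chain_id, "'")
  structure(
    list(structure_id = as.character(structure_id),
         chain_id = as.character(chain_id),
         atoms = atoms),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s chain %s: %d atoms\n",
              x$structure_id, x$chain_id, nrow(x$atoms)))
  invisible(x)
}

#' Coordinates of a chain as a matrix
#' @param chain a [chain_structure].
#' @return n x 3 numeric matrix (Angstrom).
#' @export
chain_coords <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  unname(as.matrix(chain$atoms[, c("x", "y", "z")]))
}

#' Read a PDB file and split it into single chains
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d) and returns one
#' [chain_structure] per distinct chain identifier, in order of first
#' appearance. Only the first MODEL of multi-model (NMR) files is used, so
#' each entry contributes one shape. Waters (HOH/WAT/DOD) and hydrogens are
#' always dropped; other HETATM records are dropped unless `keep_hetatm =
#' TRUE`. For alternate locations only the first altloc (blank or 'A') is
#' kept.
#'
#' @param path path to a `.pdb` file.
#' @param keep_hetatm retain non-water HETATM records?
#' @param structure_id id recorded on the returned chains; defaults to the
#'   file stem.
#' @return list of [chain_structure], one per chain.
#' @export
read_structure <- function(path, keep_hetatm = FALSE,
                           structure_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(structure_id))
    structure_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no ATOM records in '", path, "'")
  # first MODEL only: bio3d stores extra models in pdb$xyz; the atom table
  # already corresponds to model 1 for multi=FALSE.
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad))
    stop("malformed coordinate field in '", path, "' at atom serial(s) ",
         paste(utils::head(at$eleno[bad], 5L), collapse = ", "))

  elem <- at$elesy
  elem[is.na(elem)] <- ""
  elem <- trimws(elem)
  # fallback: derive the element from the atom-name columns
  fix <- elem == ""
  if (any(fix)) {
    nm <- gsub("[^A-Za-z]", "", at$elety[fix])
    elem[fix] <- toupper(substr(nm, 1L, 1L))
  }
  elem <- toupper(elem)

  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  keep <- (alt == "" | alt == "A") &
    elem != "H" & elem != "D" &
    !(toupper(trimws(at$resid)) %in% c("HOH", "WAT", "DOD"))
  if (!keep_hetatm) keep <- keep & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L)
    stop("no atoms retained from '", path, "' after filtering")

  chain <- trimws(ifelse(is.na(at$chain), "", at$chain))
  chain[chain == ""] <- " "
  out <- lapply(unique(chain), function(cid) {
    idx <- which(chain == cid)
    chain_structure(
      structure_id = structure_id,
      chain_id = cid,
      atoms = data.frame(
        serial = at$eleno[idx],
        name = trimws(at$elety[idx]),
        element = elem[idx],
        residue_name = trimws(at$resid[idx]),
        chain_id = cid,
        residue_seq = at$resno[idx],
        x = at$x[idx], y = at$y[idx], z = at$z[idx],
        is_hetero = at$type[idx] == "HETATM",
        stringsAsFactors = FALSE
      )
    )
  })
  out
}

#' Write a chain back to a PDB file
#'
#' Emits fixed-column ATOM (or HETATM) records that round-trip through
#' [read_structure()] with coordinates identical to 0.001 Angstrom, the PDB
#' column precision.
#'
#' @param chain a [chain_structure] with at least one atom.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "chain_structure"))
  at <- chain$atoms
  if (nrow(at) == 0L) stop("cannot write an empty chain")
  if (any(at$residue_seq > 9999L))
    stop("residue_seq exceeds 9999; PDB fixed columns cannot encode it")
  if (any(abs(c(at$x, at$y, at$z)) >= 10000))
    stop("coordinates exceed PDB fixed-column range")
  name4 <- vapply(at$name, function(n) {
    # standard PDB alignment: 1-letter elements start in column 14
    if (nchar(n) >= 4L) substr(n, 1L, 4L) else sprintf(" %-3s", n)
  }, character(1L))
  rec <- ifelse(at$is_hetero, "HETATM", "ATOM  ")
  lines <- sprintf(
    "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    rec, at$serial %% 100000L, name4, substr(at$residue_name, 1L, 3L),
    substr(chain$chain_id, 1L, 1L), at$residue_seq,
    at$x, at$y, at$z, substr(at$element, 1L, 2L)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}
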