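#' Descriptor database
#'
#' A set of Zernike descriptors of common mode and order, keyed by structure
#' id, held as a dense matrix for fast linear-scan retrieval.
#'
#' @param descriptors list of [zernike_descriptor] objects sharing mode and
#'   order, with unique structure ids.
#' @return object of class `descriptor_db` with `$mode`, `$order`,
#'   `$grid_n`, `$ids`, `$vectors` (one row per entry).
#' @export
descriptor_db <- function(descriptors) {
  stopifnot(length(descriptors) >= 1L)
  modes <- unique(vapply(descriptors, `[[`, character(1L), "mode"))
  orders <- unique(vapply(descriptors, `[[`, integer(1L), "order"))
  if (length(modes) > 1L || length(orders) > 1L)
    stop("all descriptors in a database must share mode and order")
  ids <- vapply(descriptors, `[[`, character(1L), "structure_id")
  if (anyDuplicated(ids))
    stop("duplicate structure ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vectors <- do.call(rbind, lapply(descriptors, `[[`, "values"))
  rownames(vectors) <- ids
  structure(
    list(mode = modes, order = orders,
         grid_n = descriptors[[1L]]$grid_n, ids = ids, vectors = vectors),
    class = "descriptor_db"
  )
}

#' @export
print.descriptor_db <- function(x, ...) {
  cat(sprintf("<descriptor_db> %d entries, mode %s, order %d\n",
              length(x$ids), x$mode, x$order))
  invisible(x)
}

#' Build a descriptor database from a folder of PDB files
#'
#' Computes one descriptor per chain of every parseable `.pdb` file in
#' `folder` (entries keyed `"<file-stem>_<chain>"`). Files that fail to
#' parse are skipped with a warning rather than aborting the build. The
#' result is deterministic across runs; with `out` set, the database is also
#' persisted in the plain-text descriptor format (see
#' [write_descriptor_db()]), byte-identically on rebuild.
#'
#' @param folder directory containing `.pdb` files.
#' @param mode representation mode (or vector of modes for a fused
#'   descriptor), as in [compute_descriptor()].
#' @param n_max,grid_n,config passed to [compute_descriptor()].
#' @param out optional output path for the descriptor file.
#' @param verbose log per-file progress to stderr?
#' @return a [descriptor_db].
#' @export
build_database <- function(folder, mode = "PM", n_max = 20L, grid_n = 200L,
                           config = list(), out = NULL, verbose = FALSE) {
  files <- sort(list.files(folder, pattern = "\\.pdb$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files)) stop("no .pdb files in '", folder, "'")
  descs <- list()
  for (f in files) {
    chains <- tryCatch(read_structure(f), error = function(e) {
      warning("skipping '", basename(f), "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    for (ch in chains) {
      if (verbose)
        message("describing ", ch$structure_id, " chain ", ch$chain_id)
      d <- tryCatch(
        compute_descriptor(ch, mode = mode, n_max = n_max, grid_n = grid_n,
                           config = config),
        error = function(e) {
          warning("skipping ", ch$structure_id, "_", ch$chain_id, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(d)) descs[[length(descs) + 1L]] <- d
    }
  }
  if (!length(descs))
    stop("no descriptors could be computed from '", folder, "'")
  db <- descriptor_db(descs)
  if (!is.null(out)) write_descriptor_db(db, out)
  db
}

#' Write / read a descriptor database as plain text
#'
#' One CSV record per structure: `structure_id`, `mode`, `n_max`, `N`, then
#' the descriptor components printed with 17 significant digits (lossless
#' for doubles) in lexicographic `(n, l)` order. Writing is deterministic,
#' so rebuilding the same database yields a byte-identical file.
#'
#' @param db a [descriptor_db].
#' @param path file path.
#' @return `write_descriptor_db`: `path` invisibly; `read_descriptor_db`:
#'   a [descriptor_db].
#' @export
write_descriptor_db <- function(db, path) {
  stopifnot(inherits(db, "descriptor_db"))
  p <- length(db$ids)
  ncomp <- ncol(db$vectors)
  header <- paste(c("structure_id", "mode", "n_max", "N",
                    paste0("F", seq_len(ncomp))), collapse = ",")
  rows <- vapply(seq_len(p), function(i) {
    paste(c(db$ids[i], db$mode, db$order,
            if (is.na(db$grid_n)) "NA" else db$grid_n,
            sprintf("%.17g", db$vectors[i, ])), collapse = ",")
  }, character(1L))
  con <- file(path, "wb")   # binary mode: fixed LF endings for determinism
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' @rdname write_descriptor_db
#' @export
read_descriptor_db <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) < 1L) stop("empty descriptor file: ", path)
  vec <- as.matrix(tab[, -(1:4), drop = FALSE])
  storage.mode(vec) <- "double"
  rownames(vec) <- tab$structure_id
  structure(
    list(mode = tab$mode[1L], order = as.integer(tab$n_max[1L]),
         grid_n = suppressWarnings(as.integer(tab$N[1L])),
         ids = tab$structure_id, vectors = vec),
    class = "descriptor_db"
  )
}

#' Nearest-neighbour query against a descriptor database
#'
#' Computes the Euclidean distance from the query descriptor to every entry
#' and returns the `k` nearest in ascending order. Ties are broken by
#' lexicographic structure id, so results are stable; a query identical to a
#' database entry comes back at rank 1 with distance 0. `k` larger than the
#' database returns all entries.
#'
#' @param db a [descriptor_db].
#' @param query_desc a [zernike_descriptor] (or bare numeric vector of
#'   matching length) of the same mode and order as `db`.
#' @param k number of hits.
#' @return data frame with columns `rank`, `structure_id`, `distance`.
#' @export
query <- function(db, query_desc, k = 10L) {
  stopifnot(inherits(db, "descriptor_db"), k >= 1L)
  if (inherits(query_desc, "zernike_descriptor")) {
    if (query_desc$order != db$order)
      stop("order mismatch: query ", query_desc$order, ", database ", db$order)
    if (query_desc$mode != db$mode)
      stop("mode mismatch: query ", query_desc$mode, ", database ", db$mode)
    v <- query_desc$values
  } else {
    v <- as.numeric(query_desc)
  }
  if (length(v) != ncol(db$vectors))
    stop("descriptor length ", length(v), " does not match database (",
         ncol(db$vectors), ")")
  d <- sqrt(rowSums(sweep(db$vectors, 2L, v)^2))
  ord <- order(d, db$ids, method = "radix")
  k <- min(k, length(d))
  sel <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), structure_id = db$ids[sel],
             distance = unname(d[sel]), stringsAsFactors = FALSE)
}

# Distance thresholds at tabulated P levels, estimated by the method's
# authors from ~1.99 million random structure-pairs over the PDB. The GMM
# descriptor is intentionally absent (too weak a shape characterization for
# a meaningful null).
.significance_table <- local({
  p <- c(5e-2, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6)
  tab <- rbind(
    ATOM = c(2.987906, 2.442935, 1.988947, 1.477029, 0.522746, 0.080739),
    PM   = c(4.653991, 3.932048, 3.169391, 1.259989, 0.252537, 0.000244),
    PS   = c(3.299481, 2.772549, 2.306926, 1.411444, 0.514943, 0.285697)
  )
  colnames(tab) <- format(p, scientific = TRUE)
  attr(tab, "p_levels") <- p
  tab
})

#' Significance thresholds for descriptor distances
#'
#' @return matrix of distance thresholds, rows ATOM/PM/PS, columns the
#'   tabulated P levels (0.05 down to 1e-6).
#' @export
significance_thresholds <- function() .significance_table

#' Significance level of a descriptor distance
#'
#' Annotates a Euclidean distance between two descriptors with the most
#' significant tabulated P level it passes: the smallest P whose distance
#' threshold is still >= the observed distance. Distances above the P = 0.05
#' threshold are reported as not significant (`"n.s."`). Thresholds exist
#' for the ATOM, PM and PS descriptors only.
#'
#' @param distance non-negative Euclidean distance (vectorized).
#' @param descriptor_type `"ATOM"`, `"PM"` or `"PS"` (the `"FP-"` prefixed
#'   spellings are also accepted).
#' @return character vector: `"5e-02"`, `"1e-02"`, `"1e-03"`, `"1e-04"`,
#'   `"1e-05"`, `"1e-06"` or `"n.s."`.
#' @examples
#' significance(3.932048, "PM")   # "1e-02"
#' significance(10, "ATOM")       # "n.s."
#' @export
significance <- function(distance, descriptor_type = c("ATOM", "PM", "PS")) {
  type <- toupper(sub("^FP-", "", descriptor_type[1L]))
  if (!type %in% rownames(.significance_table))
    stop("no significance table for descriptor type '", descriptor_type,
         "' (available: ", paste(rownames(.significance_table),
                                 collapse = ", "), ")")
  if (any(distance < 0)) stop("distances must be non-negative")
  thr <- .significance_table[type, ]
  p <- attr(.significance_table, "p_levels")
  vapply(distance, function(d) {
    passed <- which(thr >= d)
    if (!length(passed)) "n.s."
    else format(p[max(passed)], scientific = TRUE)
  }, character(1L))
}
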