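#' Feature points embedded in the unit ball
#'
#' The support set of the structure representation function: dimensionless
#' points with centroid at the origin and every norm strictly below 1, so
#' the occupancy grid over `[-1,1]^3` captures them all and the cube/ball
#' integral equivalence holds.
#'
#' @param points n x 3 matrix, all norms < 1.
#' @param source_mode `"ATOM"`, `"GMM"`, `"PM"`, `"PS"` or `"FUSED"`.
#' @param provenance structure id the points came from.
#' @param modes for fused sets, the constituent modes.
#' @return object of class `unit_point_set`.
#' @export
unit_point_set <- function(points, source_mode, provenance = "",
                           modes = source_mode) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("non-finite feature points")
  nrm2 <- rowSums(points^2)
  if (any(nrm2 >= 1))
    stop("feature point outside the open unit ball (|s| >= 1)")
  structure(
    list(points = unname(points), source_mode = source_mode,
         provenance = provenance, modes = modes),
    class = "unit_point_set"
  )
}

#' @export
print.unit_point_set <- function(x, ...) {
  cat(sprintf("<unit_point_set> %d points, mode %s%s\n",
              nrow(x$points), x$source_mode,
              if (x$source_mode == "FUSED")
                paste0(" (", paste(x$modes, collapse = "+"), ")") else ""))
  invisible(x)
}

#' Extract feature points from a structural representation
#'
#' Mode-specific rules: `ATOM` takes the atom coordinates verbatim; `GMM`
#' draws `n_samples` points from the mixture density (seeded, so
#' deterministic); `PM` takes the decimated-mesh vertices; `PS` takes all
#' isosurface vertices. Consequently the PS set is the largest and the ATOM
#' and GMM counts are comparable (GMM defaults to one sample per atom).
#'
#' @param representation a [point_cloud] (ATOM), [gmm_model] (GMM) or
#'   [surface_mesh] (PM/PS), matching `mode`.
#' @param mode one of `"ATOM"`, `"GMM"`, `"PM"`, `"PS"`.
#' @param n_samples number of GMM samples (GMM mode only).
#' @param seed seed for the GMM draw.
#' @return a [point_cloud] tagged with `mode`.
#' @export
extract_feature_points <- function(representation,
                                   mode = c("ATOM", "GMM", "PM", "PS"),
                                   n_samples = NULL, seed = 0L) {
  mode <- match.arg(mode)
  if (mode == "ATOM") {
    if (!inherits(representation, "point_cloud"))
      stop("ATOM mode expects a point_cloud")
    return(point_cloud(representation$points, mode = "ATOM"))
  }
  if (mode == "GMM") {
    if (!inherits(representation, "gmm_model"))
      stop("GMM mode expects a gmm_model")
    if (is.null(n_samples))
      stop("GMM mode needs n_samples (typically the atom count)")
    return(sample_gmm(representation, n_samples, seed = seed))
  }
  if (!inherits(representation, "surface_mesh"))
    stop(mode, " mode expects a surface_mesh")
  point_cloud(representation$vertices, mode = mode)
}

#' Embed feature points in the unit ball
#'
#' Subtracts the centroid and rescales so the farthest point sits at radius
#' `1 - margin`; every point then lies strictly inside the unit ball (and
#' inside the occupancy grid). The map is exactly invariant to translation
#' and uniform scaling of the input, which is what makes the final
#' descriptor translation- and scale-invariant, and it is idempotent.
#'
#' @param points a [point_cloud] or n x 3 matrix.
#' @param margin fraction of the radius kept free; the default, one grid
#'   cell (`1/grid_n`), guarantees strict interior support while giving up
#'   at most one voxel of resolution.
#' @param grid_n grid resolution used for the default margin.
#' @param provenance structure id to record.
#' @return a [unit_point_set].
#' @export
scale_to_unit_ball <- function(points, margin = NULL, grid_n = 200L,
                               provenance = "") {
  mode <- "ATOM"
  if (inherits(points, "point_cloud")) {
    mode <- points$mode
    points <- points$points
  }
  points <- rbind(points)
  if (nrow(points) < 1L) stop("need at least one point")
  if (is.null(margin)) margin <- 1 / grid_n
  if (margin <= 0 || margin >= 1) stop("margin must be in (0, 1)")
  ctr <- colMeans(points)
  centered <- sweep(points, 2L, ctr)
  rmax <- sqrt(max(rowSums(centered^2)))
  if (rmax == 0) {
    warning("all points coincide; returning a single point at the origin")
    return(unit_point_set(matrix(0, 1L, 3L), source_mode = mode,
                          provenance = provenance))
  }
  unit_point_set(centered * ((1 - margin) / rmax), source_mode = mode,
                 provenance = provenance)
}

#' Fuse unit-ball feature-point sets into a hybrid set
#'
#' Concatenates feature-point sets that were each already embedded in the
#' unit ball for the same structure (embedding happens per representation,
#' then the points are pooled; the fused set is deliberately not re-centred
#' or re-scaled). Four modes taken two or more at a time yield the 11
#' possible hybrid descriptors.
#'
#' @param ... two or more [unit_point_set] objects from the same structure,
#'   or a single list of them.
#' @return a [unit_point_set] with `source_mode = "FUSED"` and the
#'   constituent modes recorded in `$modes`.
#' @export
fuse <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "unit_point_set"))
    sets <- sets[[1L]]
  if (length(sets) < 2L) stop("fuse needs at least two point sets")
  ok <- vapply(sets, inherits, logical(1L), "unit_point_set")
  if (!all(ok)) stop("all inputs must be unit_point_set objects")
  prov <- unique(vapply(sets, `[[`, character(1L), "provenance"))
  if (length(prov) > 1L)
    stop("cannot fuse point sets from different structures: ",
         paste(prov, collapse = ", "))
  pts <- do.call(rbind, lapply(sets, `[[`, "points"))
  modes <- unlist(lapply(sets, `[[`, "modes"))
  unit_point_set(pts, source_mode = "FUSED", provenance = prov,
                 modes = modes)
}

#' Enumerate hybrid descriptor combinations
#'
#' All ways of combining the four representation modes taken two or more at
#' a time; there are `choose(4,2) + choose(4,3) + choose(4,4) = 11`.
#'
#' @param modes character vector of available modes.
#' @return list of character vectors, one per combination.
#' @export
fusion_combinations <- function(modes = c("ATOM", "GMM", "PM", "PS")) {
  out <- list()
  for (k in 2:length(modes))
    out <- c(out, utils::combn(modes, k, simplify = FALSE))
  out
}
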