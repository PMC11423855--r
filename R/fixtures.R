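#' Deterministic synthetic point clouds
#'
#' Generates parametric point clouds used throughout the package's tests and
#' examples: spherical shells, solid balls, helices, Gaussian blob mixtures
#' and regular cube lattices. Every generator is a pure function of its
#' arguments — the same `seed` always yields the bitwise-identical cloud — so
#' the full descriptor pipeline can be exercised without downloading any real
#' structure.
#'
#' Shapes and their parameters (all lengths in Angstrom):
#' \describe{
#'   \item{`sphere_shell`}{`n` points uniform on a sphere of radius `radius`.}
#'   \item{`solid_ball`}{`n` points uniform in a ball of radius `radius`.}
#'   \item{`helix`}{`n` points on `(r cos t, r sin t, c t)` for `n_turns`
#'     turns with radius `radius` and `pitch` (rise per turn, so
#'     `c = pitch / (2 * pi)`), plus Gaussian jitter of sd `jitter`.}
#'   \item{`blob_mixture`}{`n` points split evenly across isotropic Gaussian
#'     components centred at the rows of `centers` with sd `sigma`.}
#'   \item{`cube_lattice`}{regular `m x m x m` lattice (`m = round(n^(1/3))`)
#'     of side `side`; the actual point count is `m^3`.}
#' }
#'
#' @param kind one of `"sphere_shell"`, `"solid_ball"`, `"helix"`,
#'   `"blob_mixture"`, `"cube_lattice"`.
#' @param n target number of points (>= 1).
#' @param seed integer seed fixing the output.
#' @param radius,pitch,n_turns,jitter,centers,sigma,side shape parameters,
#'   see Details.
#' @return a [point_cloud] with `mode = "ATOM"` (raw coordinates).
#' @examples
#' shell <- make_points("sphere_shell", n = 100, radius = 10)
#' range(sqrt(rowSums(shell$points^2)))
#' @export
make_points <- function(kind = c("sphere_shell", "solid_ball", "helix",
                                 "blob_mixture", "cube_lattice"),
                        n = 100L, seed = 0L,
                        radius = 10, pitch = 5, n_turns = 3, jitter = 0,
                        centers = rbind(c(-10, 0, 0), c(10, 0, 0)),
                        sigma = 1, side = 10) {
  kind <- match.arg(kind)
  if (n < 1L) stop("'n' must be >= 1")
  pts <- with_seed(seed, {
    switch(kind,
      sphere_shell = {
        v <- matrix(stats::rnorm(3L * n), ncol = 3L)
        nrm <- sqrt(rowSums(v^2))
        nrm[nrm == 0] <- 1
        radius * v / nrm
      },
      solid_ball = {
        v <- matrix(stats::rnorm(3L * n), ncol = 3L)
        nrm <- sqrt(rowSums(v^2))
        nrm[nrm == 0] <- 1
        r <- radius * stats::runif(n)^(1 / 3)
        r * v / nrm
      },
      helix = {
        t <- seq(0, n_turns * 2 * pi, length.out = n)
        p <- cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
        if (jitter > 0) p <- p + matrix(stats::rnorm(3L * n, sd = jitter), ncol = 3L)
        p
      },
      blob_mixture = {
        centers <- rbind(centers)
        k <- nrow(centers)
        comp <- rep(seq_len(k), length.out = n)
        centers[comp, , drop = FALSE] +
          matrix(stats::rnorm(3L * n, sd = sigma), ncol = 3L)
      },
      cube_lattice = {
        m <- max(1L, round(n^(1 / 3)))
        g <- if (m == 1L) 0 else seq(-side / 2, side / 2, length.out = m)
        as.matrix(expand.grid(x = g, y = g, z = g))
      }
    )
  })
  pts <- unname(as.matrix(pts))
  point_cloud(pts, mode = "ATOM")
}

#' Write a toy PDB file from a synthetic point cloud
#'
#' Emits one C-alpha atom per point (residue ALA, chain A, sequential residue
#' numbers), producing a minimal but fully valid PDB file that exercises
#' parsing, chain splitting and the complete descriptor path.
#' [read_structure()] round-trips the coordinates to 0.001 Angstrom (PDB
#' fixed-column precision).
#'
#' @param points a [point_cloud] or an n x 3 coordinate matrix (max 99999
#'   points, the PDB serial-number limit).
#' @param path output file path.
#' @param chain_id chain identifier to write (single character).
#' @return `path`, invisibly.
#' @export
make_toy_pdb <- function(points, path, chain_id = "A") {
  if (inherits(points, "point_cloud")) points <- points$points
  points <- rbind(points)
  n <- nrow(points)
  if (n < 1L) stop("need at least one point")
  if (n > 99999L) stop("PDB format supports at most 99999 atoms")
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain_id, seq_len(n),
    points[, 1L], points[, 2L], points[, 3L]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}

#' Uniformly random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) via a normalized quaternion of
#' seeded Gaussian draws. Used by the rotation-invariance property tests.
#'
#' @param seed integer seed.
#' @return 3 x 3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function(seed = 0L) {
  q <- with_seed(seed, stats::rnorm(4L))
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2
  ), nrow = 3L, byrow = TRUE)
}

# Run code under a local RNG state so generators never disturb the caller's
# random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
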