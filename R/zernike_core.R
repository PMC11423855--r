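#' Occupancy grid on [-1,1]^3
#'
#' The discretized structure representation function f: an N x N x N grid of
#' cubic cells over `[-1,1]^3`, of which the cells listed in `one_set` carry
#' the value 1 and all others 0. Cell `(i,j,k)` (0-based) covers
#' `[-1 + i*2/N, -1 + (i+1)*2/N)` per axis.
#'
#' @param one_set m x 3 integer matrix of 0-based cell indices (duplicates
#'   are removed; the grid has set semantics).
#' @param N cells per axis (default 200).
#' @return object of class `occupancy_grid`.
#' @export
occupancy_grid <- function(one_set, N = 200L) {
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2")
  one_set <- rbind(one_set)
  storage.mode(one_set) <- "integer"
  if (nrow(one_set)) {
    if (min(one_set) < 0L || max(one_set) >= N)
      stop("cell index out of range [0, N)")
    one_set <- unique(one_set)
    ord <- order(one_set[, 1L], one_set[, 2L], one_set[, 3L])
    one_set <- one_set[ord, , drop = FALSE]
  }
  structure(list(N = N, one_set = unname(one_set)), class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> N = %d, %d occupied cells\n",
              x$N, nrow(x$one_set)))
  invisible(x)
}

#' Voxelize a unit-ball point set
#'
#' Builds the occupancy grid of the structure representation function: each
#' feature point turns on the cell it falls in, with per-axis index
#' `floor((coord + 1) / (2/N))` (clamped to `N-1` at the upper edge so the
#' map is total). Cost is linear in the number of points.
#'
#' @param S a [unit_point_set] (all norms strictly < 1).
#' @param N cells per axis.
#' @return an [occupancy_grid].
#' @export
voxelize <- function(S, N = 200L) {
  stopifnot(inherits(S, "unit_point_set"))
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2")
  nrm2 <- rowSums(S$points^2)
  if (any(nrm2 >= 1)) {
    bad <- which(nrm2 >= 1)[1L]
    stop(sprintf("point %d (%.4f, %.4f, %.4f) lies outside the unit ball",
                 bad, S$points[bad, 1L], S$points[bad, 2L], S$points[bad, 3L]))
  }
  idx <- floor((S$points + 1) * (N / 2))
  idx[idx > N - 1L] <- N - 1L
  idx[idx < 0L] <- 0L
  occupancy_grid(idx, N = N)
}

#' Geometric moments of an occupancy grid
#'
#' Computes `M_rst = integral of f(x,y,z) x^r y^s z^t` over `[-1,1]^3` for
#' all `r,s,t <= n_max`, by exact per-cell monomial integration: each
#' occupied cell contributes the product over axes of
#' `(upper^(p+1) - lower^(p+1)) / (p+1)`. Because the feature points lie
#' strictly inside the unit ball the integral over the cube equals the
#' integral over the ball. The per-axis factors are assembled with one BLAS
#' product (chunked over cells), which is algebraically identical to the
#' direct triple sum.
#'
#' @param grid an [occupancy_grid].
#' @param n_max maximum total order.
#' @return object of class `geometric_moments`: `values[r+1, s+1, t+1]`
#'   holds `M_rst` (all combinations with each exponent `<= n_max` are
#'   filled; entries with `r+s+t <= n_max` are the ones the Zernike
#'   reconstruction uses).
#' @export
geometric_moments <- function(grid, n_max = 20L) {
  stopifnot(inherits(grid, "occupancy_grid"))
  n_max <- as.integer(n_max)
  if (n_max < 0L) stop("n_max must be >= 0")
  N <- grid$N
  P <- n_max + 1L
  M <- array(0, dim = c(P, P, P))
  cells <- grid$one_set
  if (nrow(cells)) {
    edges <- -1 + (0:N) * (2 / N)
    # antider[i, p+1] = (edges[i+1]^(p+1) - edges[i]^(p+1)) / (p+1)
    pow <- outer(edges, seq_len(P), `^`)
    antider <- (pow[-1L, , drop = FALSE] - pow[-(N + 1L), , drop = FALSE]) /
      matrix(seq_len(P), N, P, byrow = TRUE)
    si <- rep(seq_len(P), times = P)
    ti <- rep(seq_len(P), each = P)
    chunk <- max(1L, floor(2e7 / (P * P)))
    flat <- matrix(0, P, P * P)
    for (start in seq(1L, nrow(cells), by = chunk)) {
      rows <- start:min(start + chunk - 1L, nrow(cells))
      Ax <- antider[cells[rows, 1L] + 1L, , drop = FALSE]
      Ay <- antider[cells[rows, 2L] + 1L, , drop = FALSE]
      Az <- antider[cells[rows, 3L] + 1L, , drop = FALSE]
      flat <- flat + crossprod(Ax, Ay[, si, drop = FALSE] *
                                   Az[, ti, drop = FALSE])
    }
    M <- array(flat, dim = c(P, P, P))
  }
  structure(list(order = n_max, N = N, values = M),
            class = "geometric_moments")
}

#' @export
print.geometric_moments <- function(x, ...) {
  cat(sprintf("<geometric_moments> order %d, M_000 = %.6g\n",
              x$order, x$values[1L, 1L, 1L]))
  invisible(x)
}

# ---- Zernike basis as polynomials in x, y, z ------------------------------
#
# Z_nlm(x) = R_nl(r) Y_lm(theta, phi), with orthonormal complex spherical
# harmonics (Condon-Shortley phase) and radial polynomials normalized so
# that (3/(4pi)) * integral over the unit ball of Z_nlm conj(Z_n'l'm') is
# the Kronecker delta; equivalently Z_000 == 1. Expanding Z_nlm in monomials
# x^r y^s z^t yields the chi coefficients: the Zernike moments are then
# linear in the geometric moments, Omega_nlm = (3/(4pi)) sum conj(chi) M_rst.

log_fact <- function(n) lgamma(n + 1)

# radial coefficients: R_nl(r) = 2*sqrt(pi) * sum_v q_klv r^(l + 2v), k=(n-l)/2
radial_coefs <- function(n, l) {
  k <- (n - l) %/% 2L
  v <- 0:k
  pref <- ((-1)^k / 4^k) * sqrt((2 * l + 4 * k + 3) / 3) * choose(2 * k, k)
  q <- pref * (-1)^v * choose(k, v) *
    choose(2 * (k + l + v) + 1, 2 * k) / choose(k + l + v, k)
  2 * sqrt(pi) * q
}

# monomial expansion of r^l Y_lm for m >= 0, as a data frame (r, s, t, coef)
solid_harmonic_poly <- function(l, m) {
  stopifnot(m >= 0L, m <= l)
  Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(log_fact(l - m) - log_fact(l + m)))
  out_r <- integer(0L); out_s <- integer(0L); out_t <- integer(0L)
  out_c <- complex(0L)
  jmax <- (l - m) %/% 2L
  for (j in 0:jmax) {
    aj <- 2^(-l) * (-1)^j * choose(l, j) * choose(2 * l - 2 * j, l) *
      exp(log_fact(l - 2 * j) - log_fact(l - 2 * j - m))
    # aj * z^(l - m - 2j) * (x^2+y^2+z^2)^j * (x+iy)^m
    for (alpha in 0:j) for (beta in 0:(j - alpha)) {
      gamma <- j - alpha - beta
      mult <- exp(log_fact(j) - log_fact(alpha) - log_fact(beta) -
                    log_fact(gamma))
      for (u in 0:m) {
        cf <- aj * mult * choose(m, u) * (1i)^(m - u)
        out_r <- c(out_r, 2L * alpha + u)
        out_s <- c(out_s, 2L * beta + (m - u))
        out_t <- c(out_t, 2L * gamma + (l - m - 2L * j))
        out_c <- c(out_c, cf)
      }
    }
  }
  list(r = out_r, s = out_s, t = out_t, coef = Nlm * out_c)
}

# full monomial expansion of Z_nlm for m >= 0 (sparse triplet form);
# P fixes the array dimension so indices are valid for the whole table
zernike_poly <- function(n, l, m, P = n + 1L) {
  q <- radial_coefs(n, l)
  harm <- solid_harmonic_poly(l, m)
  acc <- array(0 + 0i, dim = c(P, P, P))
  for (v in seq_along(q)) {          # (r^2)^(v-1) factor from the radial part
    e <- v - 1L
    for (alpha in 0:e) for (beta in 0:(e - alpha)) {
      gamma <- e - alpha - beta
      mult <- exp(log_fact(e) - log_fact(alpha) - log_fact(beta) -
                    log_fact(gamma))
      rr <- harm$r + 2L * alpha
      ss <- harm$s + 2L * beta
      tt <- harm$t + 2L * gamma
      idx <- cbind(rr + 1L, ss + 1L, tt + 1L)
      vals <- q[v] * mult * harm$coef
      for (w in seq_len(nrow(idx)))
        acc[idx[w, 1L], idx[w, 2L], idx[w, 3L]] <-
          acc[idx[w, 1L], idx[w, 2L], idx[w, 3L]] + vals[w]
    }
  }
  nz <- which(abs(acc) > 0)
  list(idx = nz, coef = acc[nz], P = P)
}

.chi_cache <- new.env(parent = emptyenv())

#' Table of chi coefficients for a given order
#'
#' The chi coefficients are the monomial-expansion coefficients of the
#' Zernike basis functions: `Z_nlm(x,y,z) = sum over (r,s,t) of
#' chi_nlm^rst x^r y^s z^t`. They depend only on the order, never on the
#' structure, so the table is computed once per `n_max` and memoized for the
#' session (optionally persisted under `cache_dir`). Entries with
#' `r+s+t` of different parity than `n` vanish, and
#' `chi_{n,l,-m} = (-1)^m conj(chi_{n,l,m})`.
#'
#' @param n_max maximum order.
#' @param cache_dir optional directory for an RDS cache keyed by order.
#' @return object of class `chi_table`: `$order`, `$index` (data frame of
#'   n, l, m), `$entries` (per row: list with flat monomial indices into an
#'   `(n_max+1)^3` array and complex coefficients).
#' @export
chi_table <- function(n_max = 20L, cache_dir = NULL) {
  n_max <- as.integer(n_max)
  if (n_max < 0L) stop("n_max must be >= 0")
  key <- as.character(n_max)
  if (!is.null(.chi_cache[[key]])) return(.chi_cache[[key]])
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, sprintf("chi_table_%d.rds", n_max))
    if (file.exists(f)) {
      tab <- readRDS(f)
      .chi_cache[[key]] <- tab
      return(tab)
    }
  }
  P <- n_max + 1L
  nn <- integer(0L); ll <- integer(0L); mm <- integer(0L)
  entries <- list()
  for (n in 0:n_max) for (l in seq(n %% 2L, n, by = 2L)) {
    pos <- lapply(0:l, function(m) zernike_poly(n, l, m, P = P))
    for (m in -l:l) {
      e <- pos[[abs(m) + 1L]]
      coef <- if (m >= 0L) e$coef else (-1)^m * Conj(e$coef)
      nn <- c(nn, n); ll <- c(ll, l); mm <- c(mm, m)
      entries[[length(entries) + 1L]] <- list(idx = e$idx, coef = coef)
    }
  }
  tab <- structure(
    list(order = n_max, P = P,
         index = data.frame(n = nn, l = ll, m = mm),
         entries = entries),
    class = "chi_table"
  )
  .chi_cache[[key]] <- tab
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(tab, file.path(cache_dir, sprintf("chi_table_%d.rds", n_max)))
  }
  tab
}

#' @export
print.chi_table <- function(x, ...) {
  cat(sprintf("<chi_table> order %d, %d (n,l,m) basis functions\n",
              x$order, nrow(x$index)))
  invisible(x)
}

#' 3D Zernike moments from geometric moments
#'
#' Assembles `Omega_nlm = (3/(4pi)) * sum over r+s+t <= n of
#' conj(chi_nlm^rst) M_rst` for every valid `(n, l, m)`. For a real-valued
#' occupancy function the moments obey
#' `Omega_{n,l,-m} = (-1)^m conj(Omega_{n,l,m})`.
#'
#' @param M a [geometric_moments] object.
#' @param chi a [chi_table] of the same order.
#' @return object of class `zernike_moments`: `$index` (n, l, m) and
#'   `$values` (complex vector).
#' @export
zernike_moments <- function(M, chi = chi_table(M$order)) {
  stopifnot(inherits(M, "geometric_moments"), inherits(chi, "chi_table"))
  if (M$order != chi$order)
    stop("order mismatch: moments have order ", M$order,
         ", chi table has order ", chi$order)
  flatM <- as.vector(M$values)
  vals <- vapply(chi$entries, function(e)
    sum(Conj(e$coef) * flatM[e$idx]), complex(1L))
  structure(
    list(order = M$order, index = chi$index,
         values = (3 / (4 * pi)) * vals),
    class = "zernike_moments"
  )
}

#' @export
print.zernike_moments <- function(x, ...) {
  cat(sprintf("<zernike_moments> order %d, %d moments\n",
              x$order, length(x$values)))
  invisible(x)
}

#' Rotation-invariant descriptor from Zernike moments
#'
#' Collapses each `(n, l)` block of moments to its Euclidean norm
#' `F_nl = |(Omega_{nl,-l}, ..., Omega_{nl,l})|`; the resulting real vector,
#' ordered lexicographically in `(n, l)`, is invariant under rotation of the
#' underlying shape. Its length is `sum over n of (floor(n/2) + 1)` (121 at
#' order 20).
#'
#' @param omega a [zernike_moments] object.
#' @param mode,structure_id tags carried on the descriptor.
#' @param grid_n grid resolution used (metadata).
#' @return object of class `zernike_descriptor` with `$n`, `$l`, `$values`.
#' @export
descriptor <- function(omega, mode = "ATOM", structure_id = "",
                       grid_n = NA_integer_) {
  stopifnot(inherits(omega, "zernike_moments"))
  agg <- rowsum(Mod(omega$values)^2, group = paste(omega$index$n,
                                                   omega$index$l))
  # rebuild lexicographic (n, l) order explicitly
  nl <- unique(omega$index[, c("n", "l")])
  nl <- nl[order(nl$n, nl$l), , drop = FALSE]
  vals <- sqrt(agg[match(paste(nl$n, nl$l), rownames(agg)), 1L])
  structure(
    list(order = omega$order, n = nl$n, l = nl$l,
         values = unname(vals), mode = mode,
         structure_id = structure_id, grid_n = grid_n),
    class = "zernike_descriptor"
  )
}

#' @export
print.zernike_descriptor <- function(x, ...) {
  cat(sprintf("<zernike_descriptor> %s%s order %d (%d invariants), mode %s\n",
              x$structure_id, if (nzchar(x$structure_id)) "," else "",
              x$order, length(x$values), x$mode))
  cat("  first components:",
      paste(signif(utils::head(x$values, 5L), 6L), collapse = ", "), "...\n")
  invisible(x)
}

#' Plot a Zernike descriptor
#'
#' Invariant magnitudes `F_nl` against component index, coloured by order
#' band; a quick visual fingerprint of a shape.
#'
#' @param x a [zernike_descriptor].
#' @param log plot magnitudes on a log scale?
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.zernike_descriptor <- function(x, log = FALSE, ...) {
  graphics::plot(seq_along(x$values), x$values,
                 type = "h", lwd = 2, col = x$n %/% 4 + 1L,
                 log = if (log) "y" else "",
                 xlab = "component (lexicographic n, l)",
                 ylab = expression(F[n * "," * l]),
                 main = sprintf("%s (%s, order %d)", x$structure_id,
                                x$mode, x$order), ...)
  invisible(x)
}

#' Number of descriptor components at a given order
#' @param n_max maximum order.
#' @return integer count of (n, l) pairs with n - l even.
#' @export
descriptor_length <- function(n_max) {
  sum(vapply(0:n_max, function(n) n %/% 2L + 1L, integer(1L)))
}

#' Compute a 3D Zernike descriptor for a chain
#'
#' The full pipeline: build the requested structural representation(s),
#' extract feature points, embed them in the unit ball, voxelize on the
#' `grid_n^3` occupancy grid, form geometric moments, assemble Zernike
#' moments and collapse to the rotation-invariant descriptor. Deterministic
#' given the configuration (all stochastic stages are seeded), and exactly
#' invariant to translation and uniform scaling of the input chain.
#'
#' `mode` may be a vector of two or more modes, in which case the per-mode
#' unit-ball point sets are pooled into the corresponding hybrid (fused)
#' descriptor.
#'
#' @param chain a [chain_structure].
#' @param mode one of `"ATOM"`, `"GMM"`, `"PM"`, `"PS"`, or a vector of
#'   several for a fused descriptor.
#' @param n_max descriptor order (default 20, giving 121 invariants).
#' @param grid_n occupancy-grid resolution (default 200).
#' @param config list of stage parameters; recognised keys (defaults):
#'   `gmm.K` (atom count / 50), `gmm.seed` (0), `featurepoints.gmm_samples`
#'   (atom count), `featurepoints.seed` (0), `surface.voxel_size` (1.0),
#'   `surface.isovalue` (0.3), `surface.sigma_scale` (0.5),
#'   `mesh.decimate_target` (500), `unitball.margin` (`1/grid_n`).
#' @return a [zernike_descriptor].
#' @export
compute_descriptor <- function(chain, mode = "PM", n_max = 20L,
                               grid_n = 200L, config = list()) {
  stopifnot(inherits(chain, "chain_structure"))
  modes <- toupper(mode)
  bad <- setdiff(modes, c("ATOM", "GMM", "PM", "PS"))
  if (length(bad)) stop("unknown mode(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(modes)) stop("duplicated modes in fusion request")
  cfg <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  n_atoms <- nrow(chain$atoms)
  margin <- cfg("unitball.margin", 1 / grid_n)
  sid <- paste0(chain$structure_id, "_", chain$chain_id)

  mesh_cache <- NULL
  get_mesh <- function(decimate) {
    if (is.null(mesh_cache))
      mesh_cache <<- gaussian_density_mesh(
        chain,
        voxel_size = cfg("surface.voxel_size", 1.0),
        isovalue = cfg("surface.isovalue", 0.3),
        sigma_scale = cfg("surface.sigma_scale", 0.5),
        decimate_target = NULL
      )
    if (is.null(decimate)) mesh_cache else decimate_mesh(mesh_cache, decimate)
  }

  sets <- lapply(modes, function(md) {
    fp <- switch(md,
      ATOM = extract_feature_points(atom_cloud(chain), "ATOM"),
      GMM = {
        gmm <- fit_gmm(atom_cloud(chain),
                       K = cfg("gmm.K", max(1L, round(n_atoms / 50))),
                       seed = cfg("gmm.seed", 0L))
        extract_feature_points(
          gmm, "GMM",
          n_samples = cfg("featurepoints.gmm_samples", n_atoms),
          seed = cfg("featurepoints.seed", 0L)
        )
      },
      PM = extract_feature_points(
        get_mesh(cfg("mesh.decimate_target", 500L)), "PM"),
      PS = extract_feature_points(get_mesh(NULL), "PS")
    )
    scale_to_unit_ball(fp, margin = margin, provenance = sid)
  })
  S <- if (length(sets) == 1L) sets[[1L]] else fuse(sets)
  grid <- voxelize(S, N = grid_n)
  M <- geometric_moments(grid, n_max = n_max)
  omega <- zernike_moments(M, chi_table(n_max))
  descriptor(omega,
             mode = if (length(modes) > 1L)
               paste(modes, collapse = "+") else modes,
             structure_id = sid, grid_n = grid_n)
}
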