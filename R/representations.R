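#' Point cloud
#'
#' A set of 3D points in Angstrom together with the representation mode it
#' came from (`ATOM`, `GMM`, `PM` or `PS`).
#'
#' @param points n x 3 numeric matrix.
#' @param mode representation tag.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, mode = c("ATOM", "GMM", "PM", "PS")) {
  mode <- match.arg(mode)
  points <- rbind(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1L) stop("point cloud must be non-empty")
  if (!all(is.finite(points))) stop("non-finite coordinates in point cloud")
  structure(list(points = unname(points), mode = mode), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points, mode %s\n", nrow(x$points), x$mode))
  invisible(x)
}

#' Atomic point cloud of a chain
#'
#' The ATOM representation: the retained atom coordinates themselves.
#'
#' @param chain a [chain_structure].
#' @return a [point_cloud] with `mode = "ATOM"`.
#' @export
atom_cloud <- function(chain) {
  point_cloud(chain_coords(chain), mode = "ATOM")
}

# van der Waals radii (Angstrom) used for the Gaussian atom widths.
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
           FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, "NA" = 2.27, K = 2.75)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Fit a Gaussian mixture model to a point cloud
#'
#' Maximum-likelihood full-covariance GMM fitted by expectation-maximization
#' with k-means++-style initialization from `seed`. The fit is deterministic
#' given `(cloud, K, seed)` and the log-likelihood is non-decreasing across
#' EM iterations (recorded in `$loglik_trace`). Covariances that lose
#' positive-definiteness during EM are regularized by adding `eps * I`
#' (default 1e-6 A^2) with a warning.
#'
#' @param cloud a [point_cloud] (or n x 3 matrix) with at least `K` points.
#' @param K number of mixture components; default `max(1, n_points / 50)`
#'   (descriptors are insensitive to the mixture resolution).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood improvement falls below `tol`.
#' @param eps covariance regularization floor (A^2).
#' @return object of class `gmm_model` with elements `weights` (simplex
#'   vector), `means` (K x 3), `covariances` (list of K 3 x 3 SPD matrices),
#'   `loglik` and `loglik_trace`.
#' @export
fit_gmm <- function(cloud, K = NULL, seed = 0L, max_iter = 200L,
                    tol = 1e-8, eps = 1e-6) {
  x <- if (inherits(cloud, "point_cloud")) cloud$points else rbind(cloud)
  n <- nrow(x)
  if (is.null(K)) K <- max(1L, round(n / 50))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop("point cloud has fewer points (", n, ") than components (", K, ")")

  centers <- with_seed(seed, kmeanspp_centers(x, K))
  d2 <- pairwise_sq_dist(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  means <- centers
  covs <- vector("list", K)
  w <- numeric(K)
  fallback_var <- mean(apply(x, 2L, stats::var)) + eps
  for (k in seq_len(K)) {
    idx <- which(assign == k)
    w[k] <- max(length(idx), 1L) / n
    means[k, ] <- if (length(idx)) colMeans(x[idx, , drop = FALSE]) else centers[k, ]
    ck <- if (length(idx) >= 2L)
      stats::cov(x[idx, , drop = FALSE]) * (length(idx) - 1L) / length(idx)
    else diag(fallback_var, 3L)
    covs[[k]] <- ensure_spd(ck, eps, warn = FALSE)
  }
  w <- w / sum(w)

  loglik_trace <- numeric(0L)
  prev <- -Inf
  warned <- FALSE
  for (it in seq_len(max_iter)) {
    # E step: log responsibilities via log-sum-exp
    logdens <- vapply(seq_len(K), function(k)
      log(w[k]) + dmvnorm_log(x, means[k, ], covs[[k]]), numeric(n))
    logdens <- rbind(logdens)   # n x K (n == 1 safe)
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    loglik <- sum(lse)
    loglik_trace <- c(loglik_trace, loglik)
    resp <- exp(logdens - lse)
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-300)
    w <- nk / n
    means <- crossprod(resp, x) / nk
    for (k in seq_len(K)) {
      xc <- sweep(x, 2L, means[k, ])
      ck <- crossprod(xc * resp[, k], xc) / nk[k]
      fixed <- ensure_spd(ck, eps, warn = FALSE)
      if (!isTRUE(all.equal(fixed, ck)) && !warned) {
        warning("degenerate covariance regularized by adding ", eps, " * I")
        warned <- TRUE
      }
      covs[[k]] <- fixed
    }
    if (is.finite(prev) && (loglik - prev) < tol * abs(loglik)) break
    prev <- loglik
  }

  structure(
    list(weights = as.numeric(w), means = unname(means), covariances = covs,
         K = K, loglik = loglik_trace[length(loglik_trace)],
         loglik_trace = loglik_trace, seed = as.integer(seed)),
    class = "gmm_model"
  )
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> %d components, log-likelihood %.3f\n",
              x$K, x$loglik))
  invisible(x)
}

#' Draw points from a fitted Gaussian mixture
#'
#' @param gmm a [gmm_model].
#' @param n number of samples.
#' @param seed integer seed; the draw is deterministic.
#' @return a [point_cloud] with `mode = "GMM"`.
#' @export
sample_gmm <- function(gmm, n, seed = 0L) {
  stopifnot(inherits(gmm, "gmm_model"), n >= 1L)
  pts <- with_seed(seed, {
    comp <- sample.int(gmm$K, n, replace = TRUE, prob = gmm$weights)
    z <- matrix(stats::rnorm(3L * n), ncol = 3L)
    out <- matrix(0, n, 3L)
    for (k in seq_len(gmm$K)) {
      idx <- which(comp == k)
      if (!length(idx)) next
      L <- chol(gmm$covariances[[k]])
      out[idx, ] <- z[idx, , drop = FALSE] %*% L +
        matrix(gmm$means[k, ], length(idx), 3L, byrow = TRUE)
    }
    out
  })
  point_cloud(pts, mode = "GMM")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center. Caller controls the RNG state.
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, 3L)
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (K > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (k in 2L:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- x[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[k, ])^2))
    }
  }
  centers
}

pairwise_sq_dist <- function(x, y) {
  outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * tcrossprod(x, y)
}

dmvnorm_log <- function(x, mean, cov) {
  L <- chol(cov)
  xc <- sweep(rbind(x), 2L, mean)
  q <- backsolve(L, t(xc), transpose = TRUE)
  -0.5 * colSums(q^2) - sum(log(diag(L))) - 1.5 * log(2 * pi)
}

ensure_spd <- function(m, eps, warn = TRUE) {
  m <- (m + t(m)) / 2
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  if (!ok || det(m) <= 0) {
    if (warn) warning("covariance regularized by adding ", eps, " * I")
    repeat {
      m <- m + diag(eps, 3L)
      ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
      if (ok && det(m) > 0) break
      eps <- eps * 10
    }
  }
  m
}

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix (Angstrom).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- rbind(vertices); storage.mode(vertices) <- "double"
  faces <- rbind(faces); storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range")
  structure(list(vertices = unname(vertices), faces = unname(faces)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Gaussian-density isosurface mesh of a chain
#'
#' Places an isotropic Gaussian on every atom (width `sigma = sigma_scale *
#' r_vdw`, unit peak height), samples the summed density on a padded cubic
#' lattice centred on the structure centroid, and extracts the `isovalue`
#' isosurface as a triangle mesh by marching tetrahedra (each lattice cube is
#' split into six tetrahedra sharing the main diagonal, with vertices
#' interpolated along crossing edges; the splitting pattern is uniform, so
#' the mesh is watertight by construction). With `decimate_target` the mesh
#' is simplified by vertex clustering to approximately that many vertices —
#' this is the PM (mesh) representation; the undecimated isosurface is the
#' PS (surface) representation.
#'
#' Because the lattice is anchored to the centroid, translating the chain
#' translates the mesh exactly.
#'
#' @param chain a [chain_structure].
#' @param voxel_size lattice spacing in Angstrom.
#' @param isovalue density threshold; default `0.3` (0.3 x the unit
#'   single-atom peak).
#' @param sigma_scale Gaussian width as a fraction of the vdW radius.
#' @param decimate_target approximate vertex count after decimation, or
#'   `NULL` for no decimation.
#' @return a [surface_mesh].
#' @export
gaussian_density_mesh <- function(chain, voxel_size = 1.0, isovalue = 0.3,
                                  sigma_scale = 0.5, decimate_target = NULL) {
  stopifnot(inherits(chain, "chain_structure"))
  if (voxel_size <= 0) stop("voxel_size must be positive")
  xyz <- chain_coords(chain)
  sigma <- sigma_scale * vdw_radius(chain$atoms$element)
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2L, ctr)
  pad <- 4 * max(sigma) + voxel_size
  half <- max(abs(rel)) + pad
  m <- ceiling(half / voxel_size)
  ax <- voxel_size * seq.int(-m, m)        # symmetric lattice about 0
  nax <- length(ax)

  dens <- array(0, dim = c(nax, nax, nax))
  cutoff <- 4
  for (a in seq_len(nrow(rel))) {
    s <- sigma[a]
    rng <- lapply(1:3, function(d) {
      which(abs(ax - rel[a, d]) <= cutoff * s)
    })
    if (any(lengths(rng) == 0L)) next
    gx <- exp(-(ax[rng[[1L]]] - rel[a, 1L])^2 / (2 * s^2))
    gy <- exp(-(ax[rng[[2L]]] - rel[a, 2L])^2 / (2 * s^2))
    gz <- exp(-(ax[rng[[3L]]] - rel[a, 3L])^2 / (2 * s^2))
    dens[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      dens[rng[[1L]], rng[[2L]], rng[[3L]]] + gx %o% gy %o% gz
  }

  if (isovalue <= min(dens) || isovalue >= max(dens))
    stop("isovalue ", isovalue, " outside the sampled density range [",
         signif(min(dens), 3L), ", ", signif(max(dens), 3L), "]")

  mesh <- marching_tetrahedra(dens, ax, ax, ax, isovalue)
  mesh$vertices <- sweep(mesh$vertices, 2L, ctr, `+`)
  if (!is.null(decimate_target))
    mesh <- decimate_mesh(mesh, decimate_target)
  mesh
}

# Marching tetrahedra over a scalar lattice. Six-tetrahedron cube split
# along the main diagonal; face diagonals agree between neighbouring cubes,
# so every interior surface edge is shared by exactly two triangles.
marching_tetrahedra <- function(values, xs, ys, zs, iso) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  inside <- values >= iso
  # cubes whose 8 corners are not all on one side
  cnt <- array(0L, dim = c(nx - 1L, ny - 1L, nz - 1L))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    cnt <- cnt + (inside[(1:(nx - 1L)) + dx, (1:(ny - 1L)) + dy,
                         (1:(nz - 1L)) + dz] * 1L)
  mixed <- which(cnt > 0L & cnt < 8L, arr.ind = TRUE)

  # cube corner offsets, indexed 0..7 (see tet list)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
                c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6)) + 1L

  tri_edges <- vector("list", 4096L)  # grows; rows of 3 edge keys
  ntri <- 0L
  np <- as.double(nx) * ny * nz
  lin <- function(i, j, k) (k - 1) * (nx * ny) + (j - 1) * nx + i  # double ok
  edge_key <- function(a, b) ifelse(a < b, a * np + b, b * np + a)

  if (nrow(mixed)) {
    for (r in seq_len(nrow(mixed))) {
      ci <- mixed[r, 1L]; cj <- mixed[r, 2L]; ck <- mixed[r, 3L]
      ii <- ci + corner[, 1L]; jj <- cj + corner[, 2L]; kk <- ck + corner[, 3L]
      ids <- lin(ii, jj, kk)
      vin <- inside[cbind(ii, jj, kk)]
      for (t in 1:6) {
        tv <- tets[t, ]
        m <- vin[tv]
        s <- sum(m)
        if (s == 0L || s == 4L) next
        a <- tv[m]; b <- tv[!m]
        if (s == 1L || s == 3L) {
          # apex on one side, base on the other: one triangle
          apex <- if (s == 1L) a[1L] else b[1L]
          base <- if (s == 1L) b else a
          tr <- rbind(c(edge_key(ids[apex], ids[base[1L]]),
                        edge_key(ids[apex], ids[base[2L]]),
                        edge_key(ids[apex], ids[base[3L]])))
        } else {
          # two inside (a1,a2) / two outside (b1,b2): quad -> two triangles
          e11 <- edge_key(ids[a[1L]], ids[b[1L]])
          e12 <- edge_key(ids[a[1L]], ids[b[2L]])
          e21 <- edge_key(ids[a[2L]], ids[b[1L]])
          e22 <- edge_key(ids[a[2L]], ids[b[2L]])
          tr <- rbind(c(e11, e12, e22), c(e11, e22, e21))
        }
        for (q in seq_len(nrow(tr))) {
          ntri <- ntri + 1L
          if (ntri > length(tri_edges))
            length(tri_edges) <- 2L * length(tri_edges)
          tri_edges[[ntri]] <- tr[q, ]
        }
      }
    }
  }
  if (ntri == 0L)
    return(surface_mesh(matrix(numeric(0), 0L, 3L),
                        matrix(integer(0), 0L, 3L)))
  tri <- do.call(rbind, tri_edges[seq_len(ntri)])
  keys <- unique(as.vector(tri))
  # decode each unique edge and interpolate the crossing point
  k1 <- keys %/% np; k2 <- keys %% np
  k2[k2 == 0] <- np; k1[keys %% np == 0] <- k1[keys %% np == 0] - 1  # guard (unused in practice)
  decode <- function(id) {
    id0 <- id - 1
    k <- id0 %/% (nx * ny)
    j <- (id0 - k * nx * ny) %/% nx
    i <- id0 - k * nx * ny - j * nx
    cbind(i + 1, j + 1, k + 1)
  }
  p1 <- decode(k1); p2 <- decode(k2)
  v1 <- values[p1]; v2 <- values[p2]
  tfrac <- (iso - v1) / (v2 - v1)
  verts <- cbind(xs[p1[, 1L]], ys[p1[, 2L]], zs[p1[, 3L]]) * (1 - tfrac) +
           cbind(xs[p2[, 1L]], ys[p2[, 2L]], zs[p2[, 3L]]) * tfrac
  faces <- matrix(match(as.vector(tri), keys), ncol = 3L)
  surface_mesh(verts, faces)
}

#' Decimate a mesh by vertex clustering
#'
#' Clusters vertices on a uniform grid whose cell size is chosen by
#' bisection so the simplified mesh has approximately `target` vertices
#' (within 10% where achievable). Faces collapsing inside one cluster are
#' dropped.
#'
#' @param mesh a [surface_mesh].
#' @param target desired vertex count.
#' @return a [surface_mesh].
#' @export
decimate_mesh <- function(mesh, target) {
  nv <- nrow(mesh$vertices)
  if (target >= nv) return(mesh)
  bb <- apply(mesh$vertices, 2L, range)
  diag_len <- sqrt(sum((bb[2L, ] - bb[1L, ])^2))
  lo <- 1e-6 * diag_len; hi <- diag_len
  best <- NULL
  for (it in 1:40) {
    h <- sqrt(lo * hi)
    cl <- cluster_vertices(mesh, h)
    if (is.null(best) ||
        abs(nrow(cl$vertices) - target) < abs(nrow(best$vertices) - target))
      best <- cl
    if (nrow(cl$vertices) > target) lo <- h else hi <- h
    if (abs(nrow(cl$vertices) - target) <= max(1, 0.05 * target)) break
  }
  best
}

cluster_vertices <- function(mesh, h) {
  idx <- floor(sweep(mesh$vertices, 2L, apply(mesh$vertices, 2L, min)) / h)
  key <- paste(idx[, 1L], idx[, 2L], idx[, 3L])
  grp <- match(key, unique(key))
  verts <- rowsum(mesh$vertices, grp) / as.vector(table(grp))
  f <- matrix(grp[mesh$faces], ncol = 3L)
  keep <- f[, 1L] != f[, 2L] & f[, 1L] != f[, 3L] & f[, 2L] != f[, 3L]
  surface_mesh(verts, f[keep, , drop = FALSE])
}
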