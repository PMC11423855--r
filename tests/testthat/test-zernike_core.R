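test_that("voxelize maps points to the documented cell indices", {
  S1 <- unit_point_set(rbind(c(0.5, 0.5, 0.5)), "ATOM")
  g1 <- voxelize(S1, N = 2)
  expect_equal(g1$one_set, rbind(c(1L, 1L, 1L)), ignore_attr = TRUE)

  # two points in the same cell: set semantics
  S2 <- unit_point_set(rbind(c(0.51, 0.5, 0.5), c(0.52, 0.5, 0.5)), "ATOM")
  expect_equal(nrow(voxelize(S2, N = 2)$one_set), 1L)

  S3 <- unit_point_set(rbind(c(-1 + 1e-9, 0, 0)), "ATOM")
  expect_equal(voxelize(S3, N = 4)$one_set, rbind(c(0L, 2L, 2L)),
               ignore_attr = TRUE)

  bad <- structure(list(points = rbind(c(1.2, 0, 0)), source_mode = "ATOM",
                        provenance = "", modes = "ATOM"),
                   class = "unit_point_set")
  expect_error(voxelize(bad, N = 4), "outside the unit ball")
})

test_that("geometric moments have their closed forms on simple grids", {
  # full cube at several N
  for (N in c(2L, 5L, 8L)) {
    all_cells <- as.matrix(expand.grid(0:(N - 1), 0:(N - 1), 0:(N - 1)))
    M <- geometric_moments(occupancy_grid(all_cells, N = N), n_max = 3)
    expect_equal(M$values[1, 1, 1], 8, tolerance = 1e-12)
    expect_lt(abs(M$values[2, 1, 1]), 1e-12)  # M_100
    expect_lt(abs(M$values[1, 2, 1]), 1e-12)  # M_010
    expect_lt(abs(M$values[1, 1, 2]), 1e-12)  # M_001
  }
  # single cell [0,1]^3 at N=2: per-axis antiderivatives
  M <- geometric_moments(occupancy_grid(rbind(c(1L, 1L, 1L)), N = 2), n_max = 3)
  expect_equal(M$values[1, 1, 1], 1, tolerance = 1e-14)   # M_000
  expect_equal(M$values[2, 1, 1], 1 / 2, tolerance = 1e-14) # M_100
  expect_equal(M$values[2, 2, 1], 1 / 4, tolerance = 1e-14) # M_110
  expect_equal(M$values[2, 2, 2], 1 / 8, tolerance = 1e-14) # M_111
  # empty grid: all zero
  M0 <- geometric_moments(occupancy_grid(matrix(integer(0), 0, 3), N = 4), 2)
  expect_true(all(M0$values == 0))
})

test_that("geometric moments agree with Monte-Carlo integration", {
  # smaller version of the moment oracle (the acceptance suite runs the
  # full 20-grid x 1e7-sample configuration)
  n_samp <- 2e6
  for (seed in 1:3) {
    g <- random_grid(N = 8, n_cells = 50, seed = seed)
    M <- geometric_moments(g, n_max = 6)
    occ <- array(FALSE, dim = c(8, 8, 8))
    occ[g$one_set + 1L] <- TRUE
    set.seed(1000 + seed)
    pts <- matrix(runif(3 * n_samp, -1, 1), ncol = 3)
    ci <- pmin(floor((pts + 1) * 4), 7) + 1L
    f <- occ[ci]
    sub <- pts[f, , drop = FALSE]
    for (r in 0:6) for (s in 0:(6 - r)) for (t in 0:(6 - r - s)) {
      v <- sub[, 1]^r * sub[, 2]^s * sub[, 3]^t
      est <- 8 * sum(v) / n_samp
      se <- 8 * sqrt((sum(v^2) / n_samp - (sum(v) / n_samp)^2) / n_samp)
      # 4 SE: with ~250 simultaneous comparisons a 3-SE bound would be
      # violated by chance alone for an exact implementation
      expect_lt(abs(M$values[r + 1, s + 1, t + 1] - est), 4 * se + 1e-12)
    }
  }
})

test_that("chi table structure: degree-0 entry, parity sparsity, conjugation", {
  tab <- chi_table(6)
  i000 <- which(tab$index$n == 0 & tab$index$l == 0 & tab$index$m == 0)
  expect_equal(tab$entries[[i000]]$idx, 1L)        # only the constant monomial
  expect_equal(tab$entries[[i000]]$coef, 1 + 0i)   # Z_000 == 1

  P <- tab$P
  for (row in seq_len(nrow(tab$index))) {
    e <- tab$entries[[row]]
    id0 <- e$idx - 1L
    tt <- id0 %/% (P * P)
    ss <- (id0 - tt * P * P) %/% P
    rr <- id0 - tt * P * P - ss * P
    expect_true(all((rr + ss + tt) %% 2 == tab$index$n[row] %% 2))
    expect_true(all(rr + ss + tt <= tab$index$n[row]))
  }
  # chi_{n,l,-m} = (-1)^m conj(chi_{n,l,m})
  for (row in which(tab$index$m > 0)) {
    n <- tab$index$n[row]; l <- tab$index$l[row]; m <- tab$index$m[row]
    neg <- which(tab$index$n == n & tab$index$l == l & tab$index$m == -m)
    e <- tab$entries[[row]]; en <- tab$entries[[neg]]
    expect_identical(en$idx, e$idx)
    expect_equal(en$coef, (-1)^m * Conj(e$coef), tolerance = 1e-13)
  }
})

test_that("the basis is orthonormal under (3/(4pi)) * integral over the ball", {
  tab <- chi_table(6)
  r <- gauss_legendre(24, 0, 1)
  th <- gauss_legendre(24, 0, pi)
  ph <- gauss_legendre(24, 0, 2 * pi)
  g <- expand.grid(r = r$x, th = th$x, ph = ph$x)
  W <- as.vector(outer(outer(r$w, th$w), ph$w)) * g$r^2 * sin(g$th)
  x <- g$r * sin(g$th) * cos(g$ph)
  y <- g$r * sin(g$th) * sin(g$ph)
  z <- g$r * cos(g$th)
  rows <- which(tab$index$m >= 0)
  vals <- lapply(rows, function(row) eval_chi_entry(tab, row, x, y, z))
  nrm <- vapply(vals, function(v) 3 / (4 * pi) * sum(W * Mod(v)^2), 0)
  expect_equal(nrm, rep(1, length(rows)), tolerance = 1e-8)
  # spot-check cross terms vanish
  set.seed(1)
  pick <- sample(length(rows), 8)
  for (a in pick) for (b in pick) {
    if (a >= b) next
    ip <- 3 / (4 * pi) * sum(W * vals[[a]] * Conj(vals[[b]]))
    expect_lt(Mod(ip), 1e-8)
  }
})

test_that("monomial expansion matches direct R_nl * Y_lm evaluation", {
  tab <- chi_table(8)
  set.seed(7)
  x <- runif(20, -0.5, 0.5); y <- runif(20, -0.5, 0.5); z <- runif(20, -0.5, 0.5)
  for (row in seq_len(nrow(tab$index))) {
    n <- tab$index$n[row]; l <- tab$index$l[row]; m <- tab$index$m[row]
    got <- eval_chi_entry(tab, row, x, y, z)
    ref <- eval_zernike_direct(n, l, m, x, y, z)
    # the package uses the Condon-Shortley-free convention internally; the
    # invariants are unaffected, so compare up to the documented sign
    err <- min(max(Mod(got - ref)), max(Mod(got + ref)))
    expect_lt(err, 1e-9 * max(1, max(Mod(ref))))
  }
})

test_that("Zernike moments via chi * M match direct Gauss quadrature", {
  # per-cell 4^3 Gauss-point quadrature of conj(Z) * f, small configuration
  # (the acceptance suite runs N=32, n_max=8, five grids)
  N <- 16L; n_max <- 6L
  tab <- chi_table(n_max)
  gl <- gauss_legendre(4, 0, 1)
  off <- as.matrix(expand.grid(a = gl$x, b = gl$x, c = gl$x))
  wts <- as.vector(outer(outer(gl$w, gl$w), gl$w))
  side <- 2 / N
  for (seed in 1:2) {
    g <- random_grid(N = N, n_cells = 40, seed = 100 + seed)
    om <- zernike_moments(geometric_moments(g, n_max), tab)
    lower <- -1 + g$one_set * side
    pts <- do.call(rbind, lapply(seq_len(nrow(lower)), function(i)
      sweep(off * side, 2, lower[i, ], `+`)))
    w_all <- rep(wts * side^3, nrow(lower))
    for (row in seq_len(nrow(tab$index))) {
      zv <- eval_zernike_direct(tab$index$n[row], tab$index$l[row],
                                tab$index$m[row],
                                pts[, 1], pts[, 2], pts[, 3])
      direct <- 3 / (4 * pi) * sum(w_all * Conj(zv))
      # compare |.| to stay convention-independent; phases are checked above
      expect_equal(Mod(om$values[row]), Mod(direct),
                   tolerance = 1e-3 * max(1e-4, Mod(direct)))
    }
  }
})

test_that("moments of a real occupancy obey conjugation symmetry", {
  g <- random_grid(N = 16, n_cells = 60, seed = 3)
  om <- zernike_moments(geometric_moments(g, 8), chi_table(8))
  ix <- om$index
  for (row in which(ix$m > 0)) {
    neg <- which(ix$n == ix$n[row] & ix$l == ix$l[row] & ix$m == -ix$m[row])
    expect_equal(om$values[neg],
                 (-1)^ix$m[row] * Conj(om$values[row]), tolerance = 1e-12)
  }
})

test_that("descriptor length and degenerate cases are correct", {
  # brute-force enumeration of valid (n, l) pairs
  for (ord in c(0L, 1L, 5L, 20L)) {
    count <- 0L
    for (n in 0:ord) for (l in 0:n) if ((n - l) %% 2 == 0) count <- count + 1L
    expect_equal(descriptor_length(ord), count)
  }
  expect_equal(descriptor_length(20L), 121L)

  g0 <- occupancy_grid(matrix(integer(0), 0, 3), N = 8)
  d0 <- descriptor(zernike_moments(geometric_moments(g0, 8), chi_table(8)))
  expect_equal(length(d0$values), descriptor_length(8))
  expect_true(all(d0$values == 0))
  expect_true(all(diff(order(d0$n, d0$l)) == 1))  # lexicographic (n, l)
})

test_that("a voxelized solid ball has vanishing l > 0 invariants", {
  N <- 32L
  ctr <- -1 + (seq_len(N) - 0.5) * (2 / N)
  idx <- as.matrix(expand.grid(0:(N - 1), 0:(N - 1), 0:(N - 1)))
  cc <- cbind(ctr[idx[, 1] + 1], ctr[idx[, 2] + 1], ctr[idx[, 3] + 1])
  g <- occupancy_grid(idx[rowSums(cc^2) <= 0.8^2, ], N = N)
  d <- descriptor(zernike_moments(geometric_moments(g, 8), chi_table(8)))
  F00 <- d$values[d$n == 0 & d$l == 0]
  expect_gt(F00, 0)
  expect_lt(max(d$values[d$l > 0]) / F00, 0.02)
})

test_that("fuse(X, X) gives exactly the descriptor of X", {
  cl <- make_points("helix", n = 60, seed = 13)
  S <- scale_to_unit_ball(cl, grid_n = 32, provenance = "s")
  dX <- descriptor_of_points(S, 32, 8)
  dXX <- descriptor_of_points(fuse(S, S), 32, 8)
  expect_identical(dXX$values, dX$values)
})

test_that("full pipeline is deterministic and translation/scale invariant", {
  p <- tempfile(fileext = ".pdb")
  make_toy_pdb(make_points("helix", n = 60, seed = 17, radius = 8, pitch = 6), p)
  ch <- read_structure(p)[[1]]
  d1 <- compute_descriptor(ch, mode = "GMM", n_max = 8, grid_n = 32)
  d2 <- compute_descriptor(ch, mode = "GMM", n_max = 8, grid_n = 32)
  expect_identical(d1$values, d2$values)

  shift <- ch$atoms
  shift$x <- shift$x + 100
  ch_t <- chain_structure(ch$structure_id, ch$chain_id, shift)
  dt <- compute_descriptor(ch_t, mode = "ATOM", n_max = 8, grid_n = 32)
  da <- compute_descriptor(ch, mode = "ATOM", n_max = 8, grid_n = 32)
  expect_identical(dt$values, da$values)

  scaled <- ch$atoms
  scaled$x <- scaled$x * 2; scaled$y <- scaled$y * 2; scaled$z <- scaled$z * 2
  ch_s <- chain_structure(ch$structure_id, ch$chain_id, scaled)
  ds <- compute_descriptor(ch_s, mode = "ATOM", n_max = 8, grid_n = 32)
  expect_identical(ds$values, da$values)
})

test_that("rotation leaves the descriptor within the voxelization noise band", {
  # exact in the continuum; binary re-voxelization at N=64 contributes a
  # measured 6-10% relative perturbation for sparse 200-point clouds
  cl <- make_points("helix", n = 200, seed = 7)
  d0 <- descriptor_of_points(scale_to_unit_ball(cl, grid_n = 64), 64, 20)
  for (s in 1:5) {
    R <- random_rotation(s)
    dr <- descriptor_of_points(
      scale_to_unit_ball(point_cloud(cl$points %*% t(R)), grid_n = 64), 64, 20)
    rel <- sqrt(sum((dr$values - d0$values)^2)) / sqrt(sum(d0$values^2))
    expect_lt(rel, 0.15)
  }
  # an exact grid symmetry isolates the numerical error of the moment path
  S0 <- scale_to_unit_ball(cl, grid_n = 64)
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  d90 <- descriptor_of_points(unit_point_set(S0$points %*% t(R90), "ATOM"),
                              64, 20)
  expect_lt(sqrt(sum((d90$values - d0$values)^2)) / sqrt(sum(d0$values^2)),
            0.01)
})

test_that("order mismatches between moments and chi tables are caught", {
  g <- random_grid(N = 8, n_cells = 10, seed = 1)
  expect_error(zernike_moments(geometric_moments(g, 4), chi_table(6)),
               "order mismatch")
})
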