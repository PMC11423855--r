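# Independent numerical oracles shared across test files. These deliberately
# avoid the package's chi-coefficient / geometric-moment code path: basis
# functions are evaluated from the Legendre-recurrence definition and
# integrals by Gauss-Legendre quadrature or Monte Carlo.

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch).
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1L)
  bv <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1L)] <- bv
  J[cbind(i + 1L, i)] <- bv
  ev <- eigen(J, symmetric = TRUE)
  list(x = (b - a) / 2 * ev$values + (a + b) / 2,
       w = (b - a) * ev$vectors[1L, ]^2)
}

# Associated Legendre P_l^m(t) for all l = 0..lmax at fixed m (no
# Condon-Shortley phase), standard recurrence.
assoc_legendre <- function(lmax, m, t) {
  out <- matrix(0, length(t), lmax + 1L)
  if (m > lmax) return(out)
  pmm <- rep(1, length(t))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - t^2))
    for (i in seq_len(m)) pmm <- pmm * (2 * i - 1) * somx2
  }
  out[, m + 1L] <- pmm
  if (lmax > m) {
    pmmp1 <- t * (2 * m + 1) * pmm
    out[, m + 2L] <- pmmp1
    if (lmax > m + 1L) {
      for (l in (m + 2L):lmax) {
        pll <- (t * (2 * l - 1) * pmmp1 - (l + m - 1) * pmm) / (l - m)
        pmm <- pmmp1
        pmmp1 <- pll
        out[, l + 1L] <- pll
      }
    }
  }
  out
}

# Direct evaluation of the Zernike basis Z_nlm at Cartesian points, from the
# definition R_nl(r) * Y_lm(theta, phi): radial part from the package's
# closed-form coefficients, angular part from the Legendre recurrence above.
# Independent of the monomial (chi) expansion and of geometric moments.
eval_zernike_direct <- function(n, l, m, x, y, z) {
  r <- sqrt(x^2 + y^2 + z^2)
  t <- ifelse(r > 0, z / r, 1)
  phi <- atan2(y, x)
  am <- abs(m)
  Plm <- assoc_legendre(l, am, t)[, l + 1L]
  Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  Y <- Nlm * Plm * exp(1i * am * phi)
  if (m < 0) Y <- (-1)^am * Conj(Y)
  q <- zernike3d:::radial_coefs(n, l)
  R <- rep(0, length(r))
  for (v in seq_along(q)) R <- R + q[v] * r^(l + 2 * (v - 1))
  R * Y
}

# Monomial evaluation of one chi-table entry at Cartesian points.
eval_chi_entry <- function(tab, row, x, y, z) {
  e <- tab$entries[[row]]
  P <- tab$P
  id0 <- e$idx - 1L
  tt <- id0 %/% (P * P)
  ss <- (id0 - tt * P * P) %/% P
  rr <- id0 - tt * P * P - ss * P
  v <- rep(0 + 0i, length(x))
  for (q in seq_along(e$coef)) v <- v + e$coef[q] * x^rr[q] * y^ss[q] * z^tt[q]
  v
}

# Random occupancy grid with a given number of occupied cells.
random_grid <- function(N, n_cells, seed) {
  set.seed(seed)
  # keep cells inside the inscribed ball so the cube/ball equivalence holds
  ctr <- -1 + (seq_len(N) - 0.5) * (2 / N)
  idx <- as.matrix(expand.grid(i = 0:(N - 1L), j = 0:(N - 1L), k = 0:(N - 1L)))
  cc <- cbind(ctr[idx[, 1L] + 1L], ctr[idx[, 2L] + 1L], ctr[idx[, 3L] + 1L])
  inside <- which(rowSums(cc^2) < (1 - 2 / N)^2)
  occupancy_grid(idx[sample(inside, min(n_cells, length(inside))), ], N = N)
}

# Descriptor straight from a unit point set (shared shorthand).
descriptor_of_points <- function(S, N, n_max) {
  descriptor(zernike_moments(geometric_moments(voxelize(S, N), n_max),
                             chi_table(n_max)))
}

# Connected components of a triangle mesh via union-find on shared vertices.
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (f in seq_len(nrow(mesh$faces))) {
    a <- find(mesh$faces[f, 1L])
    b <- find(mesh$faces[f, 2L])
    c <- find(mesh$faces[f, 3L])
    parent[b] <- a
    parent[find(c)] <- a
  }
  length(unique(vapply(seq_len(n), find, integer(1L))))
}

# Write a PDB text fixture from raw record lines.
write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          record = "ATOM", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resseq, x, y, z, element)
}
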