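# Independent oracles and cached fixtures shared across the test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

get_fixture <- function(target) {
  cached(paste0("fixture_", target), tune_to_target(target))
}

# Global Hamiltonian recomputed in plain vectorized R, independently of the
# compiled bookkeeping: interface energy over 6-adjacent pairs plus the
# quadratic volume/surface penalties.
r_hamiltonian <- function(ids, params) {
  d <- dim(ids)
  jpair <- function(a, b) ifelse(a == b, 0,
                                 ifelse(a == 0 | b == 0,
                                        params$j_cell_medium,
                                        params$j_cell_cell))
  e_int <- 0
  surf <- numeric(max(ids))
  # pairs along each axis (in-bounds only)
  for (axis in 1:3) {
    n <- d[axis]
    idx1 <- list(1:d[1], 1:d[2], 1:d[3]); idx1[[axis]] <- 1:(n - 1)
    idx2 <- idx1; idx2[[axis]] <- 2:n
    a <- ids[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE]
    b <- ids[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]
    e_int <- e_int + sum(jpair(a, b))
  }
  # per-cell exposed-face counts (out-of-bounds treated as medium)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ids
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2],
              2:(d[3] + 1) + sh[3], drop = FALSE]
    diff <- core > 0 & nb != core
    if (any(diff))
      surf <- surf + tabulate(core[diff], nbins = length(surf))
  }
  vols <- tabulate(ids[ids > 0], nbins = length(surf))
  h <- e_int
  for (c in seq_along(vols)) {
    h <- h + params$lambda_v * (vols[c] - params$target_volume[c])^2 +
      params$lambda_s * (surf[c] - params$target_surface[c])^2
  }
  list(H = h, volume = vols, surface = surf)
}

# small random lattice with a compact blob of cell 1 (plus optional cell 2)
random_blob_lattice <- function(n = 16, r = 4, two_cells = FALSE) {
  ids <- array(0L, c(n, n, n))
  ctr <- (n + 1) / 2
  ax <- seq_len(n) - ctr
  X <- array(ax, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  ids[X^2 + Y^2 + Z^2 <= r^2] <- 1L
  if (two_cells) ids[X^2 + (Y - r)^2 + Z^2 <= (r - 1)^2] <- 2L
  cpm_lattice(ids)
}

params_for <- function(lattice, ...) {
  p <- cpm_params(...)
  max_id <- max(lattice$ids)
  p$target_volume <- vapply(seq_len(max_id),
                            function(c) sum(lattice$ids == c), 0)
  p$target_surface <- rep(1500, max_id)
  p
}

# digitized solid ellipsoid mask (axis-aligned), for analytic axis checks
ellipsoid_mask <- function(semi, spacing = 1, n = 2 * ceiling(max(semi)) + 5) {
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr) * spacing
  X <- array(ax, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  binary_volume((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1,
                spacing)
}
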