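#' CPM lattice
#'
#' A cubic lattice of cell identifiers (0 = medium, >= 1 = cell) with a
#' physical site length. The outermost one-site frame is frozen medium, so
#' cells never touch the lattice edge.
#'
#' @param ids integer 3D array of cell identifiers.
#' @param side_um lattice site side length in micrometres (default 0.5).
#' @return An object of class `cpm_lattice`.
#' @export
cpm_lattice <- function(ids, side_um = 0.5) {
  ids <- as.array(ids)
  if (length(dim(ids)) != 3L) stop("`ids` must be a 3D array")
  storage.mode(ids) <- "integer"
  if (any(ids < 0L)) stop("cell ids must be >= 0")
  structure(list(ids = ids, side_um = side_um), class = "cpm_lattice")
}

#' @export
print.cpm_lattice <- function(x, ...) {
  cells <- sort(unique(x$ids[x$ids > 0L]))
  cat("<cpm_lattice>", paste(dim(x$ids), collapse = " x "),
      "sites,", x$side_um, "um/site, cells:",
      if (length(cells)) paste(cells, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Build a lattice around a voxelized cell
#'
#' Embeds the mask (as cell id 1) at the center of a cubic lattice of medium.
#' The lattice is sized so that the ball of radius equal to the largest
#' center-of-mass-to-boundary distance fits inside it with margin: the
#' shape-weighted particle initialization draws a comparison site uniformly
#' from the whole lattice, and its distance distribution must span the
#' farthest boundary site for the cubed-distance law to hold.
#'
#' Anisotropic masks are resampled (nearest neighbour) onto an isotropic
#' grid of `side_um` before embedding.
#'
#' @param mask a [binary_volume()].
#' @param side_um lattice site length in micrometres.
#' @param margin_factor lattice half-width as a multiple of the maximum
#'   boundary distance (>= 1).
#' @param min_dim minimum lattice side length in sites.
#' @return A [cpm_lattice()] containing cell 1.
#' @export
lattice_from_mask <- function(mask, side_um = 0.5, margin_factor = 1.05,
                              min_dim = 32L) {
  stopifnot(inherits(mask, "binary_volume"))
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  if (any(abs(mask$spacing - side_um) > 1e-9))
    m <- resample_mask(m, mask$spacing, side_um)
  idx <- which(m, arr.ind = TRUE)
  ctr <- colMeans(idx)
  rmax <- sqrt(max(rowSums(sweep(idx, 2L, ctr)^2)))
  half <- max(ceiling(margin_factor * rmax) + 2L, ceiling(min_dim / 2))
  n <- as.integer(2L * half)
  ids <- array(0L, c(n, n, n))
  shift <- round(n / 2 - ctr)
  dest <- sweep(idx, 2L, shift, `+`)
  if (any(dest < 2L) || any(dest > n - 1L))
    stop("mask does not fit in the lattice with a frozen frame")
  ids[dest] <- 1L
  cpm_lattice(ids, side_um)
}

resample_mask <- function(m, spacing, side_um) {
  d <- dim(m)
  out_d <- pmax(1L, as.integer(round(d * spacing / side_um)))
  src <- lapply(1:3, function(a)
    pmin(d[a], pmax(1L, as.integer(ceiling((seq_len(out_d[a]) - 0.5) *
                                           side_um / spacing[a])))))
  m[src[[1]], src[[2]], src[[3]], drop = FALSE]
}

#' CPM parameters
#'
#' Energy and dynamics parameters for the cellular Potts model. Interfacial
#' energies are per exposed face; the temperature sets the scale of accepted
#' uphill moves (membrane fluctuation). Target volume and surface are in
#' lattice units (sites and faces) and are usually filled in by
#' [set_rounding_targets()]. Defaults were calibrated so that the fixture
#' cells shed surface steadily during rounding and divide inside the
#' rounding transient (roughly 20-80 Monte Carlo steps depending on
#' eccentricity), within one mixing time of the membrane particle layer;
#' see the methods vignette for the timescale analysis behind this choice.
#'
#' @param j_cell_medium interfacial energy per cell-medium face.
#' @param j_cell_cell interfacial energy per cell-cell face.
#' @param lambda_v volume elasticity.
#' @param lambda_s surface elasticity (cortical tension).
#' @param temperature Boltzmann temperature, > 0.
#' @param target_volume,target_surface per-cell targets (sites / faces),
#'   indexed by cell id.
#' @param s_division_factor division triggers when the current surface falls
#'   to this multiple of the target surface.
#' @param surface_correction digital-surface factor: the face-counted area
#'   of a digitized sphere exceeds `4*pi*r^2` by about this factor, so the
#'   rounding target `S = surface_correction * 4*pi*r^2` makes the sphere
#'   the actual minimizer.
#' @param total_mcs simulation length cap in Monte Carlo steps.
#' @return A list of class `cpm_params`.
#' @export
cpm_params <- function(j_cell_medium = 2, j_cell_cell = 1,
                       lambda_v = 2, lambda_s = 0.2, temperature = 16,
                       target_volume = numeric(), target_surface = numeric(),
                       s_division_factor = 1.2, surface_correction = 1.5,
                       total_mcs = 500L) {
  stopifnot(temperature > 0, lambda_v >= 0, lambda_s >= 0)
  structure(list(
    j_cell_medium = j_cell_medium, j_cell_cell = j_cell_cell,
    lambda_v = lambda_v, lambda_s = lambda_s, temperature = temperature,
    target_volume = as.numeric(target_volume),
    target_surface = as.numeric(target_surface),
    s_division_factor = s_division_factor,
    surface_correction = surface_correction,
    total_mcs = as.integer(total_mcs)), class = "cpm_params")
}

ensure_targets <- function(lattice, params) {
  max_id <- max(lattice$ids, 0L)
  nv <- length(params$target_volume)
  if (nv < max_id) params$target_volume <- c(params$target_volume,
                                             rep(0, max_id - nv))
  ns <- length(params$target_surface)
  if (ns < max_id) params$target_surface <- c(params$target_surface,
                                              rep(0, max_id - ns))
  params
}

#' Global Hamiltonian
#'
#' Energy of the configuration: interfacial cost over all 6-adjacent pairs
#' of unequal identifiers, plus quadratic volume and surface penalties per
#' cell.
#'
#' @param lattice a [cpm_lattice()].
#' @param params [cpm_params()] with targets for every cell id.
#' @return List with `H`, per-cell `volume` (sites) and `surface` (faces).
#' @export
hamiltonian <- function(lattice, params) {
  params <- ensure_targets(lattice, params)
  cpp_hamiltonian(lattice$ids, params)
}

#' Energy change of a single copy attempt
#'
#' Incremental Hamiltonian change if the identifier at `source` were copied
#' into the adjacent `target` site; exactly equals the global energy
#' difference.
#'
#' @param lattice a [cpm_lattice()].
#' @param params [cpm_params()].
#' @param source,target 1-based (x, y, z) site coordinates carrying
#'   different cell ids.
#' @return Scalar energy change.
#' @export
delta_h <- function(lattice, params, source, target) {
  params <- ensure_targets(lattice, params)
  cpp_delta_h(lattice$ids, params, as.integer(source) - 1L,
              as.integer(target) - 1L)
}

#' Set mitotic-rounding targets
#'
#' Mitotic rounding is induced by setting the target volume to the cell's
#' current volume and the target surface to the (digitally corrected) area
#' of the volume-equivalent sphere, `surface_correction * 4*pi*r^2` with
#' radius `(3V/4pi)^(1/3)` in site units. Minimizing the surface at fixed
#' volume drives the cell toward a sphere. The division-trigger surface is
#' set to `s_division_factor` times the target surface.
#'
#' @param lattice a [cpm_lattice()].
#' @param params [cpm_params()].
#' @param cell cell id (default 1).
#' @return `params` with `target_volume`, `target_surface` and `s_division`
#'   filled in for `cell`.
#' @export
set_rounding_targets <- function(lattice, params, cell = 1L) {
  v <- sum(lattice$ids == cell)
  if (v == 0L) stop("cell ", cell, " not present")
  params <- ensure_targets(lattice, params)
  r <- (3 * v / (4 * pi))^(1 / 3)
  params$target_volume[cell] <- v
  params$target_surface[cell] <- params$surface_correction * 4 * pi * r^2
  params$s_division <- params$s_division_factor * params$target_surface[cell]
  params
}

#' Division trigger
#'
#' During rounding the surface area decreases toward the spherical target;
#' the cell divides at the first downward crossing of `s_division`.
#'
#' @param lattice a [cpm_lattice()].
#' @param cell cell id.
#' @param s_division trigger surface in faces; `<= 0` never triggers.
#' @return Logical.
#' @export
check_division_trigger <- function(lattice, cell, s_division) {
  if (s_division <= 0) return(FALSE)
  p <- ensure_targets(lattice, cpm_params())
  s <- cpp_hamiltonian(lattice$ids, p)$surface[cell]
  s <= s_division
}

#' Run Monte Carlo steps
#'
#' One Monte Carlo step performs as many copy attempts as there are lattice
#' sites: each attempt picks a random site and a random 26-neighbour and
#' copies the source identifier into the target with the Metropolis rule
#' (always when the energy drops, else with Boltzmann probability
#' `exp(-dH/T)`). The particle layer is repaired after every accepted copy
#' and diffused once at the end of each step. Seed the R RNG before calling
#' for reproducible runs.
#'
#' @param lattice a [cpm_lattice()].
#' @param params [cpm_params()] (targets must cover all cells).
#' @param particles optional [particle_set()] riding on the boundary.
#' @param n_mcs number of Monte Carlo steps.
#' @param s_division optional trigger surface; the run stops at the end of
#'   the first mcs whose surface is at or below it. `0` disables.
#' @param record_log keep a per-mcs log of volume, surface and energy.
#' @return List with updated `lattice`, `particles`, `mcs` performed,
#'   `triggered`, acceptance counters and (optionally) `log`.
#' @export
run_mcs <- function(lattice, params, particles = NULL, n_mcs = 1L,
                    s_division = 0, record_log = FALSE) {
  params <- ensure_targets(lattice, params)
  pm <- particles_to_matrix(particles, dim(lattice$ids))
  steps <- particle_steps(particles)
  res <- cpp_cpm_run(lattice$ids, params, pm, steps, as.integer(n_mcs),
                     s_division, record_log)
  out <- list(
    lattice = cpm_lattice(res$ids, lattice$side_um),
    particles = matrix_to_particles(res$particles, particles),
    mcs = res$mcs, triggered = res$triggered,
    attempts = res$attempts, accepted = res$accepted,
    hamiltonian = res$hamiltonian, volume = res$volume,
    surface = res$surface)
  if (record_log) {
    out$log <- as.data.frame(res$log)
    names(out$log) <- c("volume", "surface", "hamiltonian")
    out$log$mcs <- seq_len(nrow(out$log))
  }
  out
}

#' Divide a cell along the plane perpendicular to the cell vector
#'
#' Sites on the positive side of the plane through the cell centroid with
#' normal `cell_vector` keep the mother's identifier (the plus daughter);
#' sites on the negative side become a new cell. Sites exactly on the plane
#' are assigned alternately to balance the daughter volumes. Daughter target
#' volumes are set to their actual post-split volumes and target surfaces to
#' their actual surfaces (daughters keep their shapes while the fate
#' decision runs).
#'
#' @param lattice a [cpm_lattice()].
#' @param params [cpm_params()].
#' @param cell mother cell id.
#' @param cell_vector division-axis vector (plane normal). A zero vector is
#'   degenerate: a uniformly random direction is drawn and flagged.
#' @return List with `lattice`, updated `params`, `plus_id`, `minus_id`,
#'   `volumes` (named), `degenerate_axis` flag.
#' @export
divide_cell <- function(lattice, params, cell = 1L, cell_vector) {
  ids <- lattice$ids
  sites <- which(ids == cell, arr.ind = TRUE)
  if (nrow(sites) == 0L) stop("cell ", cell, " not present")
  cv <- as.numeric(cell_vector)
  degenerate <- sqrt(sum(cv^2)) < 1e-12
  if (degenerate) {
    v <- rnorm(3)
    cv <- v / sqrt(sum(v^2))
  }
  ctr <- colMeans(sites)
  proj <- as.numeric(sweep(sites, 2L, ctr) %*% cv)
  on_plane <- abs(proj) < 1e-9
  plus <- proj > 0 & !on_plane
  minus <- proj < 0 & !on_plane
  if (any(on_plane)) {
    # alternate plane sites between daughters, topping up the smaller side
    k <- which(on_plane)
    take_plus <- logical(length(k))
    n_plus <- sum(plus); n_minus <- sum(minus)
    for (i in seq_along(k)) {
      take_plus[i] <- n_plus <= n_minus
      if (take_plus[i]) n_plus <- n_plus + 1L else n_minus <- n_minus + 1L
    }
    plus[k[take_plus]] <- TRUE
    minus[k[!take_plus]] <- TRUE
  }
  minus_id <- max(ids) + 1L
  ids[sites[minus, , drop = FALSE]] <- minus_id
  lat <- cpm_lattice(ids, lattice$side_um)
  params <- ensure_targets(lat, params)
  h <- cpp_hamiltonian(lat$ids, params)
  params$target_volume[cell] <- h$volume[cell]
  params$target_volume[minus_id] <- h$volume[minus_id]
  params$target_surface[cell] <- h$surface[cell]
  params$target_surface[minus_id] <- h$surface[minus_id]
  list(lattice = lat, params = params, plus_id = cell, minus_id = minus_id,
       volumes = c(plus = unname(h$volume[cell]),
                   minus = unname(h$volume[minus_id])),
       degenerate_axis = degenerate)
}
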