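#' Membrane-bound particle set
#'
#' Particles live on boundary lattice sites of their cell: blue particles
#' are cortical force generators (they set the division axis), yellow
#' particles are Delta molecules (they seed the fate decision). Multiple
#' particles may share a site. Each colour diffuses with its own step size,
#' in lattice lengths per Monte Carlo step.
#'
#' @param x,y,z integer 1-based site coordinates.
#' @param color character, `"blue"` or `"yellow"`.
#' @param steps named numeric, diffusion step per colour (defaults: blue 1,
#'   yellow 2).
#' @return A data frame of class `particle_set` with attribute `steps`.
#' @export
particle_set <- function(x = integer(), y = integer(), z = integer(),
                         color = character(),
                         steps = c(blue = 1, yellow = 2)) {
  stopifnot(length(x) == length(y), length(y) == length(z),
            length(z) == length(color))
  if (!all(color %in% c("blue", "yellow")))
    stop("particle colours must be 'blue' or 'yellow'")
  out <- data.frame(x = as.integer(x), y = as.integer(y), z = as.integer(z),
                    color = as.character(color),
                    stringsAsFactors = FALSE)
  attr(out, "steps") <- steps
  class(out) <- c("particle_set", "data.frame")
  out
}

particles_to_matrix <- function(particles, dims) {
  if (is.null(particles) || nrow(particles) == 0L)
    return(matrix(0L, 0L, 4L))
  m <- cbind(particles$x - 1L, particles$y - 1L, particles$z - 1L,
             as.integer(particles$color == "yellow"))
  storage.mode(m) <- "integer"
  m
}

particle_steps <- function(particles) {
  s <- if (is.null(particles)) c(blue = 1, yellow = 2)
       else attr(particles, "steps")
  if (is.null(s)) s <- c(blue = 1, yellow = 2)
  as.numeric(c(s[["blue"]], s[["yellow"]]))
}

matrix_to_particles <- function(m, template = NULL) {
  steps <- if (!is.null(template)) attr(template, "steps")
           else c(blue = 1, yellow = 2)
  if (is.null(m) || nrow(m) == 0L)
    return(particle_set(steps = steps))
  ps <- particle_set(m[, 1] + 1L, m[, 2] + 1L, m[, 3] + 1L,
                     ifelse(m[, 4] == 1L, "yellow", "blue"), steps = steps)
  if (ncol(m) >= 5L) ps$cell <- m[, 5]
  ps
}

#' Boundary sites of a cell
#'
#' All sites of the cell with at least one 6-neighbour carrying a different
#' identifier (the membrane).
#'
#' @param lattice a [cpm_lattice()].
#' @param cell cell id.
#' @return Integer matrix of 1-based (x, y, z) coordinates.
#' @export
boundary_sites <- function(lattice, cell = 1L) {
  if (!any(lattice$ids == cell)) stop("cell ", cell, " not present")
  cpp_boundary_sites(lattice$ids, as.integer(cell)) + 1L
}

#' Shape-weighted particle initialization
#'
#' Rejection scheme that concentrates particles at membrane regions far from
#' the cell's center of mass: draw a random boundary site (distance `d1`
#' from the center of mass), draw a random site from the whole lattice
#' (distance `d2` from the same center), and place a particle at the
#' boundary site iff `d1 > d2`. Acceptance is proportional to the volume of
#' the radius-`d1` ball, so per-site placement frequency grows as `d1^3`,
#' concentrating particles at the spiky (+) end of an eccentric cell.
#'
#' @param lattice a [cpm_lattice()].
#' @param cell cell id.
#' @param n_particles number to place.
#' @param color `"blue"` or `"yellow"`.
#' @param steps diffusion steps per colour (see [particle_set()]).
#' @return A [particle_set()] of `n_particles` rows.
#' @export
init_particles_shape_weighted <- function(lattice, cell = 1L, n_particles,
                                          color = "yellow",
                                          steps = c(blue = 1, yellow = 2)) {
  b <- boundary_sites(lattice, cell)
  if (nrow(b) == 0L) stop("cell has no boundary sites")
  if (n_particles == 0L) return(particle_set(steps = steps))
  sites <- which(lattice$ids == cell, arr.ind = TRUE)
  ctr <- colMeans(sites)
  d1 <- sqrt(rowSums(sweep(b, 2L, ctr)^2))
  dims <- dim(lattice$ids)
  chosen <- integer(0)
  while (length(chosen) < n_particles) {
    m <- max(2L * n_particles, 256L)
    cand <- sample.int(nrow(b), m, replace = TRUE)
    probe <- cbind(sample.int(dims[1], m, replace = TRUE),
                   sample.int(dims[2], m, replace = TRUE),
                   sample.int(dims[3], m, replace = TRUE))
    d2 <- sqrt(rowSums(sweep(probe, 2L, ctr)^2))
    chosen <- c(chosen, cand[d1[cand] > d2])
  }
  chosen <- chosen[seq_len(n_particles)]
  particle_set(b[chosen, 1], b[chosen, 2], b[chosen, 3],
               rep(color, n_particles), steps = steps)
}

#' Uniform particle initialization
#'
#' Particles placed uniformly at random over the boundary sites, the control
#' condition that erases the shape memory carried by the initial
#' polarization.
#'
#' @inheritParams init_particles_shape_weighted
#' @return A [particle_set()].
#' @export
init_particles_uniform <- function(lattice, cell = 1L, n_particles,
                                   color = "yellow",
                                   steps = c(blue = 1, yellow = 2)) {
  b <- boundary_sites(lattice, cell)
  if (nrow(b) == 0L) stop("cell has no boundary sites")
  if (n_particles == 0L) return(particle_set(steps = steps))
  chosen <- sample.int(nrow(b), n_particles, replace = TRUE)
  particle_set(b[chosen, 1], b[chosen, 2], b[chosen, 3],
               rep(color, n_particles), steps = steps)
}

#' Reattach stranded particles to the membrane
#'
#' Any particle whose site is no longer a boundary site of its cell steps to
#' one of the nearest boundary sites (uniformly among ties). Inside the
#' Monte Carlo loop this repair runs after every accepted copy; this
#' standalone version repairs a whole set at once.
#'
#' @param particles a [particle_set()].
#' @param lattice a [cpm_lattice()].
#' @return The repaired [particle_set()].
#' @export
reattach_particles <- function(particles, lattice) {
  if (nrow(particles) == 0L) return(particles)
  params <- ensure_targets(lattice, cpm_params())
  m <- cpp_reattach_particles(lattice$ids, params,
                              particles_to_matrix(particles, dim(lattice$ids)))
  matrix_to_particles(m, particles)
}

#' Annulus diffusion sweep
#'
#' Each particle moves to a uniformly chosen boundary site of its cell whose
#' Euclidean distance from the current site lies in the open annulus
#' `(s - 0.5, s + 0.5)` lattice lengths, where `s` is the colour's step
#' size; with no candidate (or `s = 0`) the particle stays. One sweep is
#' applied at the end of every Monte Carlo step.
#'
#' @param particles a [particle_set()].
#' @param lattice a [cpm_lattice()].
#' @param steps optional override of the per-colour step sizes.
#' @return The moved [particle_set()].
#' @export
diffuse_particles <- function(particles, lattice, steps = NULL) {
  if (nrow(particles) == 0L) return(particles)
  if (!is.null(steps)) attr(particles, "steps") <- steps
  params <- ensure_targets(lattice, cpm_params())
  m <- cpp_diffuse_particles(lattice$ids, params,
                             particles_to_matrix(particles, dim(lattice$ids)),
                             particle_steps(particles))
  matrix_to_particles(m, particles)
}

#' Cell vector from the cortical force generators
#'
#' Sum of unit vectors from the cell's center of mass to each blue particle;
#' the division plane is perpendicular to it. Blue particles exactly at the
#' center of mass are excluded (and flagged).
#'
#' @param particles a [particle_set()].
#' @param c_mass center of mass in lattice coordinates (1-based site units).
#' @return List with `cv` (3-vector), `n_used`, `excluded`.
#' @export
cell_vector <- function(particles, c_mass) {
  blue <- particles[particles$color == "blue", , drop = FALSE]
  if (nrow(blue) == 0L) stop("no blue particles")
  d <- sweep(as.matrix(blue[, c("x", "y", "z")]), 2L, as.numeric(c_mass))
  len <- sqrt(rowSums(d^2))
  keep <- len > 1e-12
  cv <- colSums(d[keep, , drop = FALSE] / len[keep])
  list(cv = as.numeric(cv), n_used = sum(keep), excluded = sum(!keep))
}

#' Partition yellow particles between the daughters
#'
#' After division every particle sits on a site owned by one daughter; the
#' yellow (Delta) counts per daughter seed the fate decision.
#'
#' @param particles a [particle_set()].
#' @param lattice the post-division [cpm_lattice()].
#' @param plus_id,minus_id daughter identifiers.
#' @return List with `n_plus`, `n_minus`, `n_yellow` and the relabelled
#'   `particles` (column `cell` updated).
#' @export
partition_particles <- function(particles, lattice, plus_id, minus_id) {
  if (nrow(particles) > 0L) {
    owner <- lattice$ids[cbind(particles$x, particles$y, particles$z)]
    if (any(owner == 0L)) stop("particle on a medium site after division")
    particles$cell <- owner
  } else owner <- integer()
  yellow <- particles$color == "yellow"
  n_plus <- sum(yellow & owner == plus_id)
  n_minus <- sum(yellow & owner == minus_id)
  if (n_plus + n_minus != sum(yellow))
    stop("yellow particles on sites owned by neither daughter")
  list(n_plus = n_plus, n_minus = n_minus, n_yellow = sum(yellow),
       particles = particles)
}
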