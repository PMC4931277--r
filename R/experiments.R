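#' Ensemble configuration
#'
#' Bundles everything one in-silico division experiment needs: the shape
#' fixtures, replicate count, particle concentrations (particles per
#' boundary site), per-colour diffusion steps, yellow initialization mode
#' and the CPM / fate parameter sets. Per-replicate seeds are derived
#' deterministically from `base_seed`.
#'
#' Baseline particle parameters follow the fitted operating point:
#' concentration 5.0e-2 per site for both colours, diffusion step 1 lattice
#' length per mcs for the blue force generators and 2 for the yellow Delta
#' particles.
#'
#' @param fixtures list of `shape_fixture` objects (see [tune_to_target()]).
#' @param replicates divisions per fixture.
#' @param conc_blue,conc_yellow particles per boundary site.
#' @param step_blue,step_yellow diffusion steps (lattice lengths per mcs).
#' @param init_mode `"shape_weighted"` or `"uniform"` for the yellow
#'   particles (blue are always shape-weighted).
#' @param conc_basis what a concentration of 1 means: one particle per cell
#'   lattice site (`"cell_sites"`, default; at the fitted concentrations
#'   this yields the reported 100-200 particles per cell) or per boundary
#'   site (`"boundary_sites"`).
#' @param base_seed integer master seed.
#' @param cpm [cpm_params()].
#' @param fate [fate_params()].
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(fixtures, replicates = 48L,
                            conc_blue = 0.05, conc_yellow = 0.05,
                            step_blue = 1, step_yellow = 2,
                            init_mode = c("shape_weighted", "uniform"),
                            conc_basis = c("cell_sites", "boundary_sites"),
                            base_seed = 1L, cpm = cpm_params(),
                            fate = fate_params()) {
  init_mode <- match.arg(init_mode)
  conc_basis <- match.arg(conc_basis)
  stopifnot(replicates >= 1L, length(fixtures) >= 1L)
  if (inherits(fixtures, "shape_fixture")) fixtures <- list(fixtures)
  structure(list(fixtures = fixtures, replicates = as.integer(replicates),
                 conc_blue = conc_blue, conc_yellow = conc_yellow,
                 step_blue = step_blue, step_yellow = step_yellow,
                 init_mode = init_mode, conc_basis = conc_basis,
                 base_seed = as.integer(base_seed),
                 cpm = cpm, fate = fate), class = "ensemble_config")
}

combine_particles <- function(..., steps) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  particle_set(df$x, df$y, df$z, df$color, steps = steps)
}

#' Run one in-silico cell division
#'
#' Embeds the fixture in a lattice, places shape-weighted blue and (shape-
#' weighted or uniform) yellow particles on the membrane, runs mitotic
#' rounding under the Metropolis dynamics until the surface trigger fires,
#' divides perpendicular to the cell vector, partitions the yellow
#' particles, and resolves the Delta-Notch switch.
#'
#' @param fixture a `shape_fixture`.
#' @param config an [ensemble_config()] (its fixture list is ignored here).
#' @param seed integer seed for this replicate.
#' @return One-row data frame with geometry, particle and fate outcomes.
#' @export
run_replicate <- function(fixture, config, seed) {
  set.seed(seed)
  lattice <- lattice_from_mask(fixture$mask, side_um = 0.5)
  params <- set_rounding_targets(lattice, config$cpm, cell = 1L)
  nb <- nrow(boundary_sites(lattice, 1L))
  basis <- if (identical(config$conc_basis, "boundary_sites")) nb
           else sum(lattice$ids == 1L)
  n_blue <- max(1L, round(config$conc_blue * basis))
  n_yellow <- max(1L, round(config$conc_yellow * basis))
  steps <- c(blue = config$step_blue, yellow = config$step_yellow)
  blue <- init_particles_shape_weighted(lattice, 1L, n_blue, "blue", steps)
  yellow <- if (config$init_mode == "uniform")
    init_particles_uniform(lattice, 1L, n_yellow, "yellow", steps)
  else
    init_particles_shape_weighted(lattice, 1L, n_yellow, "yellow", steps)
  particles <- combine_particles(blue, yellow, steps = steps)
  a_long <- fixture$descriptor$a_long

  res <- run_mcs(lattice, params, particles, n_mcs = params$total_mcs,
                 s_division = params$s_division)
  base <- data.frame(
    a_long_target = fixture$a_long_index, seed = seed, n_boundary = nb,
    n_blue = n_blue, n_yellow = n_yellow, divided = res$triggered,
    mcs_division = if (res$triggered) res$mcs else NA_integer_,
    angle_cv_along = NA_real_, n_plus_side = NA_integer_,
    n_minus_side = NA_integer_, fate_plus_side = "no_division",
    tie = FALSE, degenerate_axis = FALSE, fate_mcs = NA_integer_)
  if (!res$triggered) return(base)

  sites <- which(res$lattice$ids == 1L, arr.ind = TRUE)
  c_mass <- colMeans(sites)
  cv <- cell_vector(res$particles, c_mass)
  cv_len <- sqrt(sum(cv$cv^2))
  base$degenerate_axis <- cv_len < 1e-12
  base$angle_cv_along <- if (cv_len > 1e-12)
    axis_change_angle(cv$cv, a_long)$angle else NA_real_
  div <- divide_cell(res$lattice, params, 1L, cv$cv)
  part <- partition_particles(res$particles, div$lattice,
                              div$plus_id, div$minus_id)
  # which daughter sits on the (+) side of the oriented long axis?
  cp <- colMeans(which(div$lattice$ids == div$plus_id, arr.ind = TRUE))
  cm <- colMeans(which(div$lattice$ids == div$minus_id, arr.ind = TRUE))
  plus_is_cv_plus <- sum((cp - cm) * a_long) > 0
  n_plus_side <- if (plus_is_cv_plus) part$n_plus else part$n_minus
  n_minus_side <- part$n_yellow - n_plus_side
  st <- initial_conditions(part$n_plus, part$n_minus)
  fp <- config$fate
  fp$max_mcs <- max(1L, fp$max_mcs - res$mcs)
  fate <- resolve_fate(st, fp)
  fate_cv_plus <- unname(fate$fate[["plus"]])
  base$n_plus_side <- n_plus_side
  base$n_minus_side <- n_minus_side
  base$fate_plus_side <- if (!fate$resolved) "unresolved"
    else if (plus_is_cv_plus) fate_cv_plus
    else unname(fate$fate[["minus"]])
  base$tie <- fate$tie
  base$fate_mcs <- fate$mcs
  base
}

#' Run a division ensemble over shape fixtures
#'
#' Repeats [run_replicate()] `replicates` times per fixture with seeds
#' derived from the base seed, and summarizes each fixture: counts of
#' plus-side V2a / plus-side V2b / unresolved outcomes, the plus-side V2a
#' bias fraction among resolved replicates, and a chi-squared test of the
#' resolved counts against the 50:50 null (1 degree of freedom).
#'
#' @param config an [ensemble_config()].
#' @return List of class `ensemble_result` with `results` (one row per
#'   replicate) and `summary` (one row per fixture).
#' @export
run_division_ensemble <- function(config) {
  set.seed(config$base_seed)
  n_total <- length(config$fixtures) * config$replicates
  seeds <- sample.int(.Machine$integer.max, n_total)
  rows <- vector("list", n_total)
  k <- 0L
  for (f in config$fixtures) {
    for (r in seq_len(config$replicates)) {
      k <- k + 1L
      rows[[k]] <- cbind(replicate = r, run_replicate(f, config, seeds[k]))
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$a_long_target),
                                   summarize_fixture))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 config = config), class = "ensemble_result")
}

summarize_fixture <- function(df) {
  n_v2a <- sum(df$fate_plus_side == "V2a")
  n_v2b <- sum(df$fate_plus_side == "V2b")
  n_res <- n_v2a + n_v2b
  test <- if (n_res > 0)
    chi_square_gof(c(n_v2a, n_v2b), rep(n_res / 2, 2), df = 1L)
  else list(chi_sq = NA_real_, p = NA_real_)
  data.frame(a_long_target = df$a_long_target[1], replicates = nrow(df),
             divided = sum(df$divided), resolved = n_res,
             plus_v2a = n_v2a, plus_v2b = n_v2b,
             unresolved = sum(df$fate_plus_side == "unresolved"),
             bias = if (n_res > 0) n_v2a / n_res else NA_real_,
             chi_sq = test$chi_sq, p = test$p,
             median_angle = median(df$angle_cv_along, na.rm = TRUE),
             mean_mcs_division = mean(df$mcs_division, na.rm = TRUE))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result>", nrow(x$results), "replicates over",
      nrow(x$summary), "fixture(s)\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Chi-squared goodness-of-fit test
#'
#' The statistic is `sum((O - E)^2 / E)`; the p-value is the upper tail of
#' the chi-squared distribution at the supplied degrees of freedom (1 for
#' the binary fate counts, 2 for the three-bin division-orientation
#' classes).
#'
#' @param observed,expected count vectors (equal sums, expected all > 0).
#' @param df degrees of freedom.
#' @return List with `chi_sq` and `p`.
#' @export
chi_square_gof <- function(observed, expected, df = length(observed) - 1L) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) stop("expected counts must all be positive")
  if (abs(sum(observed) - sum(expected)) > 1e-8)
    stop("observed and expected totals differ")
  chi_sq <- sum((observed - expected)^2 / expected)
  list(chi_sq = chi_sq, p = pchisq(chi_sq, df, lower.tail = FALSE))
}

#' Division-orientation statistics (long-axis rule)
#'
#' Distribution of the angle between the division axis (cell vector) and
#' the cell's oriented long axis across replicates; cells obeying the
#' long-axis rule divide with small angles.
#'
#' @param results replicate data frame from [run_division_ensemble()] (or
#'   its `results` element).
#' @return List with `angles`, `median_angle`, `frac_below_30`,
#'   `frac_below_45`, `n`.
#' @export
long_axis_rule_stats <- function(results) {
  if (inherits(results, "ensemble_result")) results <- results$results
  ang <- results$angle_cv_along
  ang <- ang[is.finite(ang)]
  if (length(ang) == 0L) stop("no resolved replicates with a division axis")
  list(angles = ang, median_angle = median(ang),
       frac_below_30 = mean(ang < 30), frac_below_45 = mean(ang < 45),
       n = length(ang))
}

#' Perturbation sweep of the Delta-particle parameters
#'
#' Runs the named model perturbations on the supplied fixtures:
#' `uniform_init` (no initial Delta polarization), `step0` / `step4`
#' (frozen and fast Delta diffusion), and `conc_low` / `conc_high` (yellow
#' concentration 5.0e-3 and 0.50 per site at step 2, i.e.
#' concentration-to-diffusion ratios 0.0025 and 0.25 against the baseline
#' 0.025).
#'
#' @param config baseline [ensemble_config()].
#' @param variants character subset of
#'   `c("baseline", "uniform_init", "step0", "step4", "conc_low",
#'   "conc_high")`.
#' @return List of class `sweep_result`: per-variant `ensemble_result`s and
#'   a combined summary table with a `variant` column.
#' @export
sweep_fig4 <- function(config,
                       variants = c("baseline", "uniform_init", "step0",
                                    "step4", "conc_low", "conc_high")) {
  variants <- match.arg(variants, several.ok = TRUE)
  alter <- list(
    baseline     = identity,
    uniform_init = function(cf) { cf$init_mode <- "uniform"; cf },
    step0        = function(cf) { cf$step_yellow <- 0; cf },
    step4        = function(cf) { cf$step_yellow <- 4; cf },
    conc_low     = function(cf) { cf$conc_yellow <- 5e-3; cf },
    conc_high    = function(cf) { cf$conc_yellow <- 0.5; cf })
  runs <- lapply(variants, function(v) run_division_ensemble(alter[[v]](config)))
  names(runs) <- variants
  summary <- do.call(rbind, lapply(variants, function(v)
    cbind(variant = v, runs[[v]]$summary)))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Physical-unit calibration
#'
#' Maps the Monte Carlo clock to seconds via the observed and simulated
#' division times, and converts a lattice diffusion step to a physical
#' diffusion coefficient through the two-dimensional surface-diffusion
#' relation `MSD = 4 D t` with `MSD = (step * L)^2` per Monte Carlo step.
#' Both outputs are reported at two significant figures.
#'
#' @param real_division_minutes observed division time (default 21 min).
#' @param sim_division_mcs simulated division time (default 215 mcs).
#' @param lattice_um lattice site length in micrometres.
#' @param step_lattice_lengths diffusion step in lattice lengths per mcs.
#' @return List with `seconds_per_mcs` and `diffusion_coefficient_cm2_s`.
#' @export
calibrate_units <- function(real_division_minutes = 21,
                            sim_division_mcs = 215,
                            lattice_um = 0.5, step_lattice_lengths = 2) {
  stopifnot(real_division_minutes > 0, sim_division_mcs > 0,
            lattice_um > 0, step_lattice_lengths > 0)
  sec_per_mcs <- real_division_minutes * 60 / sim_division_mcs
  step_cm <- step_lattice_lengths * lattice_um * 1e-4
  d_coef <- step_cm^2 / (4 * sec_per_mcs)
  list(seconds_per_mcs = signif(sec_per_mcs, 2),
       diffusion_coefficient_cm2_s = signif(d_coef, 2))
}

#' Fit particle parameters to a target bias profile
#'
#' Runs a small ensemble (12 replicates per fixture by default) for every
#' candidate (concentration, step) pair and ranks candidates by the summed
#' squared difference between the per-fixture plus-side V2a bias and a
#' user-supplied target profile.
#'
#' @param config baseline [ensemble_config()] carrying the fixtures.
#' @param grid data frame with columns `conc` and `step` (yellow particle
#'   concentration and diffusion step).
#' @param target_bias numeric target bias per fixture (recycled).
#' @param replicates replicates per fixture per candidate.
#' @return List with `table` (one row per candidate, with `score`) and
#'   `best` (the selected row).
#' @export
fit_mode <- function(config, grid, target_bias, replicates = 12L) {
  if (nrow(grid) == 0L) stop("empty candidate grid")
  target <- rep_len(target_bias, length(config$fixtures))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cf <- config
    cf$conc_yellow <- grid$conc[i]
    cf$step_yellow <- grid$step[i]
    cf$replicates <- as.integer(replicates)
    ens <- run_division_ensemble(cf)
    bias <- ens$summary$bias
    data.frame(conc = grid$conc[i], step = grid$step[i],
               ratio = grid$conc[i] / max(grid$step[i], 1e-12),
               score = sum((bias - target)^2),
               mean_bias = mean(bias),
               n_records = sum(ens$summary$replicates))
  })
  table <- do.call(rbind, rows)
  list(table = table, best = table[which.min(table$score), ])
}
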