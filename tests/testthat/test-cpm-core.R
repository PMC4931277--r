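test_that("hamiltonian matches the independent R recomputation", {
  set.seed(3)
  lat <- random_blob_lattice(12, 3, two_cells = TRUE)
  p <- params_for(lat, j_cell_medium = 2, j_cell_cell = 1,
                  lambda_v = 1.5, lambda_s = 0.02)
  got <- hamiltonian(lat, p)
  oracle <- r_hamiltonian(lat$ids, p)
  expect_equal(got$H, oracle$H)
  expect_equal(got$volume, oracle$volume)
  expect_equal(got$surface, oracle$surface)

  # single 1-site cell in medium with only interfacial energy: 6 faces x J
  ids <- array(0L, c(5, 5, 5)); ids[3, 3, 3] <- 1L
  lat1 <- cpm_lattice(ids)
  p1 <- cpm_params(j_cell_medium = 2, lambda_v = 0, lambda_s = 0,
                   target_volume = 0, target_surface = 0)
  expect_equal(hamiltonian(lat1, p1)$H, 12)

  # all terms vanish when the cell sits exactly at its targets with J = 0
  p0 <- cpm_params(j_cell_medium = 0, lambda_v = 1, lambda_s = 1,
                   target_volume = 1, target_surface = 6)
  expect_equal(hamiltonian(lat1, p0)$H, 0)
})

test_that("local energy change equals global recomputation exactly", {
  set.seed(17)
  for (rep in 1:3) {
    lat <- random_blob_lattice(10, 3, two_cells = rep > 1)
    p <- params_for(lat, lambda_v = 2, lambda_s = 0.1)
    checked <- 0
    while (checked < 60) {
      src <- sample(2:9, 3, replace = TRUE)
      o <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      tgt <- src + o
      if (all(o == 0) || any(tgt < 2) || any(tgt > 9)) next
      if (lat$ids[src[1], src[2], src[3]] == lat$ids[tgt[1], tgt[2], tgt[3]])
        next
      dh <- delta_h(lat, p, src, tgt)
      after <- lat$ids
      after[tgt[1], tgt[2], tgt[3]] <- lat$ids[src[1], src[2], src[3]]
      dh_global <- r_hamiltonian(after, p)$H - r_hamiltonian(lat$ids, p)$H
      expect_equal(dh, dh_global)
      checked <- checked + 1
    }
  }
  # a copy between two sites of the same cell is a rejected no-op
  lat <- random_blob_lattice(10, 3)
  p <- params_for(lat)
  expect_error(delta_h(lat, p, c(5, 5, 5), c(5, 5, 6)), "no-op")
})

test_that("cached energy does not drift over many accepted copies", {
  set.seed(21)
  lat <- random_blob_lattice(16, 4)
  p <- params_for(lat, lambda_s = 0.05, temperature = 12)
  p <- ensure_targets(lat, p)
  res <- shapemem:::cpp_cpm_attempts(lat$ids, p, 100000L)
  expect_gt(res$accepted, 100)  # the audit actually exercised copies
  fresh <- hamiltonian(cpm_lattice(res$ids), p)
  expect_lt(abs(res$hamiltonian_cached - fresh$H), 1e-6)
})

test_that("metropolis acceptance follows the Boltzmann rule", {
  # empirical acceptance at dH = T is exp(-1) within MC error; measured by
  # driving a volume-displaced cell where every growth copy costs ~constant
  # energy: instead we check the implemented probability directly via many
  # single attempts on a crafted two-level system
  set.seed(8)
  ids <- array(0L, c(6, 6, 6)); ids[3, 3, 3] <- 1L
  lat <- cpm_lattice(ids)
  # lambda_v = T/2 with v = V+... craft dH: growing the 1-site cell by one
  # site changes interfaces +4 faces x J... simpler: rely on run_mcs zero-
  # temperature limit and the dH<0 acceptance path
  # J = 0 and the cell exactly at target volume: every state change (grow
  # or shrink) costs lambda_v > 0, so at T -> 0 all moves are uphill
  p_cold <- cpm_params(j_cell_medium = 0, lambda_v = 5, lambda_s = 0,
                       temperature = 1e-6,
                       target_volume = 1, target_surface = 0)
  r <- run_mcs(lat, p_cold, NULL, n_mcs = 5)
  # at T -> 0 with all moves uphill (v at target, J > 0) nothing is accepted
  expect_equal(r$accepted, 0)
  expect_equal(r$lattice$ids, lat$ids)
  expect_equal(r$attempts, 5 * 6^3)  # one attempt per site per mcs

  # downhill moves are always accepted: an oversized target volume makes
  # growth strictly favourable until the cell fills the allowed region
  p_grow <- cpm_params(j_cell_medium = 0, lambda_v = 10, lambda_s = 0,
                       temperature = 1e-6,
                       target_volume = 30, target_surface = 0)
  r2 <- run_mcs(lat, p_grow, NULL, n_mcs = 30)
  expect_equal(r2$volume, 30)
})

test_that("empirical acceptance at dH = T matches exp(-1)", {
  # two-state construction: a 1-site cell with target volume 1 and J = 0,
  # so the only state-changing moves are grow (v 1 -> 2, dH = lambda_v) and
  # vanish (v 1 -> 0, dH = lambda_v). With lambda_v = T every change has
  # dH/T = 1 exactly; the chance that a 26-attempt batch changes the state
  # is 1 - (1 - q p_acc)^26 with q = 2/N the chance an attempt hits one of
  # the 52 active ordered pairs. Comparing against a near-infinite
  # temperature reference isolates p_acc = exp(-1).
  ids <- array(0L, c(6, 6, 6)); ids[3, 3, 3] <- 1L
  lat <- cpm_lattice(ids)
  tt <- 5
  p <- cpm_params(j_cell_medium = 0, j_cell_cell = 0, lambda_v = tt,
                  lambda_s = 0, temperature = tt,
                  target_volume = 1, target_surface = 0)
  p <- ensure_targets(lat, p)
  p_hot <- p; p_hot$temperature <- tt * 1e9
  trials <- 4000L
  set.seed(99)
  changed <- function(pp) {
    sum(vapply(seq_len(trials), function(i) {
      r <- shapemem:::cpp_cpm_attempts(lat$ids, pp, 26L)
      !identical(r$ids, lat$ids)
    }, logical(1)))
  }
  n_t <- changed(p)
  n_ref <- changed(p_hot)
  q <- 2 / length(lat$ids)
  expected <- (1 - (1 - q * exp(-1))^26) / (1 - (1 - q)^26)
  expect_equal(n_t / n_ref, expected, tolerance = 0.12)
})

test_that("rounding targets follow the equivalent-sphere formula", {
  f <- get_fixture(0.052)
  lat <- lattice_from_mask(f$mask)
  p <- set_rounding_targets(lat, cpm_params())
  v <- sum(lat$ids == 1L)
  r <- (3 * v / (4 * pi))^(1 / 3)
  expect_equal(p$target_volume[1], v)
  expect_equal(p$target_surface[1], 1.5 * 4 * pi * r^2)
  expect_equal(p$s_division, 1.2 * p$target_surface[1])

  # v = 4189 sites (r = 10): S = 4 pi 100 before the digital correction
  p2 <- cpm_params(surface_correction = 1)
  p2$target_volume <- 4189
  lat2 <- lattice_from_mask(ellipsoid_mask(c(10, 10, 10), n = 27,
                                           spacing = 1))
  p2 <- set_rounding_targets(lat2, p2)
  v2 <- sum(lat2$ids == 1L)
  expect_equal(p2$target_surface[1], 4 * pi * ((3 * v2 / (4 * pi))^(1/3))^2)
})

test_that("division trigger fires on the armed downward crossing", {
  f <- get_fixture(0.031)
  lat <- lattice_from_mask(f$mask)
  p <- set_rounding_targets(lat, cpm_params())
  set.seed(2)
  r <- run_mcs(lat, p, NULL, n_mcs = 500, s_division = p$s_division,
               record_log = TRUE)
  expect_true(r$triggered)
  expect_lt(r$mcs, 100)
  expect_lte(r$log$surface[r$mcs], p$s_division)
  # s_division = 0 never triggers; the run ends at the requested length
  set.seed(2)
  r0 <- run_mcs(lat, p, NULL, n_mcs = 30, s_division = 0)
  expect_false(r0$triggered)
  expect_equal(r0$mcs, 30)
  expect_false(check_division_trigger(lat, 1L, 0))
})

test_that("rounding shrinks the cell's geometric anisotropy", {
  # the face-counted surface is a weak shape readout on digitized smooth
  # cells, so sphericity progress is measured on the inertia eigenvalues
  f <- get_fixture(0.092)
  lat <- lattice_from_mask(f$mask)
  p <- set_rounding_targets(lat, cpm_params())
  aniso <- function(l) {
    sd <- shape_descriptor(binary_volume(l$ids == 1L, rep(l$side_um, 3)))
    sd$lambda_short / sd$lambda_long
  }
  a0 <- aniso(lat)
  set.seed(5)
  r <- run_mcs(lat, p, NULL, n_mcs = 200, s_division = 0)
  expect_lt(aniso(r$lattice), a0)
  # and the face-count surface has relaxed toward the spherical target
  s0 <- hamiltonian(lat, p)$surface[1]
  expect_lt(r$surface, s0)
})

test_that("division conserves volume and matches half-space classification", {
  f <- get_fixture(0.063)
  lat <- lattice_from_mask(f$mask)
  p <- set_rounding_targets(lat, cpm_params())
  cv <- c(1, 0.3, 0.2)
  div <- divide_cell(lat, p, 1L, cv)
  v_parent <- sum(lat$ids == 1L)
  expect_equal(sum(div$lattice$ids == div$plus_id) +
               sum(div$lattice$ids == div$minus_id), v_parent)
  expect_equal(sum(div$volumes), v_parent)

  # brute-force half-space classification of off-plane sites
  sites <- which(lat$ids == 1L, arr.ind = TRUE)
  ctr <- colMeans(sites)
  proj <- as.numeric(sweep(sites, 2, ctr) %*% cv)
  lab <- div$lattice$ids[sites]
  expect_true(all(lab[proj > 1e-9] == div$plus_id))
  expect_true(all(lab[proj < -1e-9] == div$minus_id))

  # a sphere split along +x gives near-equal halves
  sph <- lattice_from_mask(ellipsoid_mask(c(5, 5, 5), spacing = 0.5, n = 25))
  p2 <- set_rounding_targets(sph, cpm_params())
  d2 <- divide_cell(sph, p2, 1L, c(1, 0, 0))
  expect_lt(abs(d2$volumes[["plus"]] - d2$volumes[["minus"]]),
            0.02 * sum(d2$volumes))

  # zero division axis: random plane, flagged
  set.seed(1)
  d3 <- divide_cell(sph, p2, 1L, c(0, 0, 0))
  expect_true(d3$degenerate_axis)
  expect_equal(sum(d3$volumes), sum(sph$ids == 1L))
})
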