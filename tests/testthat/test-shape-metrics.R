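test_that("inertia tensor matches direct summation and equivariance", {
  # single voxel: zero tensor, centroid at the voxel center
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  it <- inertia_tensor(binary_volume(m, 1))
  expect_equal(it$tensor, matrix(0, 3, 3))
  expect_equal(unname(it$c_mass), c(1.5, 1.5, 1.5))

  # axis-aligned 1x1x9 rod at 1 um spacing: direct voxel sums
  rod <- array(FALSE, c(3, 3, 11)); rod[2, 2, 2:10] <- TRUE
  it <- inertia_tensor(binary_volume(rod, 1))
  z <- ((2:10) - 0.5) - mean((2:10) - 0.5)
  expect_equal(it$tensor, diag(c(sum(z^2), sum(z^2), 0)))
  ax <- principal_axes(it$tensor)
  expect_equal(abs(unname(ax$e_long)), c(0, 0, 1))

  # 90-degree rotation about z permutes the tensor accordingly
  ell <- ellipsoid_mask(c(8, 4, 3))
  rot <- binary_volume(aperm(ell$mask, c(2, 1, 3))[dim(ell$mask)[2]:1, , ],
                       ell$spacing)
  t1 <- inertia_tensor(ell)$tensor
  t2 <- inertia_tensor(rot)$tensor
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(t2, R %*% t1 %*% t(R), tolerance = 1e-6)
})

test_that("principal axes recover analytic ellipsoid directions", {
  # prolate ellipsoid semi-axes (10, 4, 4): long axis along x within 2 deg,
  # eigenvalues within 3% of the analytic uniform-ellipsoid moments
  ell <- ellipsoid_mask(c(10, 4, 4), spacing = 0.5,
                        n = 2 * ceiling(10 / 0.5) + 5)
  it <- inertia_tensor(ell)
  ax <- principal_axes(it$tensor)
  ang <- acos(abs(sum(ax$e_long * c(1, 0, 0)))) * 180 / pi
  expect_lt(ang, 2)
  n_vox <- sum(ell$mask)
  lam <- c(long = (4^2 + 4^2), mid = (10^2 + 4^2), short = (10^2 + 4^2)) / 5
  expect_equal(ax$lambda_long / n_vox, lam[["long"]], tolerance = 0.03)
  expect_equal(ax$lambda_short / n_vox, lam[["short"]], tolerance = 0.03)
  # rotationally symmetric rod: the long axis is sharp, only the
  # transverse pair is degenerate
  expect_false(ax$degenerate)
  expect_true(ax$transverse_degenerate)

  # sphere: all eigenvalues within tolerance, degeneracy flagged
  sph <- ellipsoid_mask(c(6, 6, 6))
  axs <- principal_axes(inertia_tensor(sph)$tensor)
  expect_true(axs$degenerate)
  expect_equal(axs$lambda_long, axs$lambda_short,
               tolerance = 0.01)
  expect_gte(axs$lambda_long, 0)

  expect_error(principal_axes(matrix(1:9, 3, 3)), "symmetric")
})

test_that("asymmetry vector vanishes for centrosymmetric shapes and points
           to the tapered end of a teardrop", {
  for (mask in list(ellipsoid_mask(c(5, 5, 5)), ellipsoid_mask(c(8, 5, 3)))) {
    sd <- shape_descriptor(mask)
    expect_lt(sqrt(sum(sd$d_asym^2)), 0.1)
  }

  f <- get_fixture(0.092)
  sd <- f$descriptor
  cosang <- sum(sd$d_asym * f$axis) / sqrt(sum(sd$d_asym^2))
  expect_gt(cosang, cos(10 * pi / 180))  # within 10 deg of the process axis

  # translation invariance of d_asym
  m <- f$mask$mask
  big <- array(FALSE, dim(m) + 10L)
  big[5 + seq_len(dim(m)[1]), 5 + seq_len(dim(m)[2]), 5 + seq_len(dim(m)[3])] <- m
  sd2 <- shape_descriptor(binary_volume(big, f$mask$spacing))
  expect_equal(sd2$d_asym, sd$d_asym, tolerance = 1e-8)
})

test_that("axis orientation follows the sign of the asymmetry vector", {
  axes <- list(e_long = c(1, 0, 0), e_mid = c(0, 1, 0), e_short = c(0, 0, 1),
               degenerate = FALSE)
  or <- orient_axes(axes, d_asym = c(-2, 0.5, 0))
  expect_equal(or$a_long, c(-1, 0, 0))   # flipped: dot was negative
  expect_equal(or$a_middle, c(0, 1, 0))  # kept: dot positive
  expect_equal(or$a_short, c(0, 0, 1))   # kept: dot exactly zero
  expect_false(or$degenerate)
  expect_true(orient_axes(axes, c(0, 0, 0))$degenerate)
})

test_that("eccentricity index is scale invariant and zero for spheres", {
  expect_lt(abs(shape_descriptor(ellipsoid_mask(c(6, 6, 6)))$a_long_index),
            0.003)
  f1 <- make_teardrop(5, 0.1, spacing = 0.5)
  f2 <- make_teardrop(10, 0.1, spacing = 1)  # same shape, x2 scale
  expect_equal(f1$a_long_index, f2$a_long_index, tolerance = 0.004)
  # after orientation the projection on the long axis is nonnegative
  expect_gte(f1$descriptor$d_long, 0)
})

test_that("fate-axis angle implements the sign rule with a tie flag", {
  a <- c(1, 0, 0)
  expect_equal(theta_fate(a, a)$theta_fate, 0)
  expect_equal(theta_fate(a, a)$plus_side_fate, "V2a")
  expect_equal(theta_fate(a, -a)$theta_fate, 180)
  expect_equal(theta_fate(a, -a)$plus_side_fate, "V2b")
  tie <- theta_fate(a, c(0, 1, 0))
  expect_equal(tie$theta_fate, 90)
  expect_equal(tie$plus_side_fate, "tie")
  expect_error(theta_fate(c(0, 0, 0), a), "zero-length")
})

test_that("axis change angle treats axes as undirected lines", {
  expect_equal(axis_change_angle(c(1, 0, 0), c(-1, 0, 0))$angle, 0)
  perp <- axis_change_angle(c(1, 0, 0), c(0, 0, 1))
  expect_equal(perp$angle, 90)
  expect_true(perp$changed)
  # known synthetic rotation by 60 degrees about z
  th <- 60 * pi / 180
  got <- axis_change_angle(c(1, 0, 0), c(cos(th), sin(th), 0))
  expect_equal(got$angle, 60, tolerance = 1e-8)
  expect_true(got$changed)
})

test_that("localization descriptor equals the weighted-centroid oracle", {
  f <- get_fixture(0.052)
  sd <- f$descriptor
  # uniform intensity over the mask: no offset
  unif <- intensity_volume(array(as.numeric(f$mask$mask), dim(f$mask$mask)),
                           f$mask$spacing)
  ld <- localization_descriptor(unif, f$mask, sd)
  expect_lt(ld$d_norm, 0.01)

  # all intensity in one voxel at a known distance: d_norm forced
  idx <- which(f$mask$mask, arr.ind = TRUE)
  far <- idx[which.max(idx[, 1]), ]
  a <- array(0, dim(f$mask$mask)); a[far[1], far[2], far[3]] <- 50
  ld1 <- localization_descriptor(intensity_volume(a, f$mask$spacing),
                                 f$mask, sd)
  ctr_um <- (far - 0.5) * f$mask$spacing
  expect_equal(ld1$d_norm,
               sqrt(sum((ctr_um - sd$c_mass)^2)) / sd$equiv_radius)

  # linear gradient along +a_long: plus side, exact agreement with a
  # direct voxel-sum oracle
  stack <- make_synthetic_stack(f, polarization_axis = sd$a_long,
                                gradient_strength = 1)
  ld2 <- localization_descriptor(stack, f$mask, sd)
  expect_true(ld2$plus_side)
  xyz <- sweep(which(f$mask$mask, arr.ind = TRUE) - 0.5, 2,
               f$mask$spacing, `*`)
  b <- stack$data[f$mask$mask]
  oracle <- colSums(xyz * b) / sum(b)
  expect_equal(unname(ld2$c_signal), unname(oracle), tolerance = 1e-9)

  expect_error(localization_descriptor(
    intensity_volume(array(0, dim(f$mask$mask)), f$mask$spacing),
    f$mask, sd), "zero total intensity")
})

test_that("surface-area-to-volume ratio matches face-count formulas", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(sav_ratio(binary_volume(one, 0.5)), 12)  # 6*0.25/0.125
  blk <- array(FALSE, c(4, 4, 4)); blk[2:3, 2:3, 2:3] <- TRUE
  expect_equal(sav_ratio(binary_volume(blk, 0.5)), 6)   # 24*0.25/1
  # digitized sphere r = 5 um: within 15% of the smooth-sphere 3/r
  # (face counting overestimates smooth areas by ~1.5)
  sph <- ellipsoid_mask(c(5, 5, 5), spacing = 0.5, n = 25)
  expect_equal(sav_ratio(sph) / 1.5, 3 / 5, tolerance = 0.15)
})

test_that("ROC threshold maximizes Youden's J and recovers a changepoint", {
  # perfectly separated cohort: threshold inside the separating gap
  a_long <- c(runif(20, 0, 0.03), runif(20, 0.05, 0.1))
  pos <- rep(c(FALSE, TRUE), each = 20)
  th <- roc_threshold(a_long, pos)
  expect_gt(th$threshold, max(a_long[!pos]))  # inside the separating gap
  expect_lte(th$threshold, min(a_long[pos]))
  expect_equal(th$youden_j, 1)

  # planted changepoint at 0.04: recovered within 0.01 across seeds
  for (s in 1:3) {
    set.seed(s)
    a <- runif(300, 0, 0.1)
    p <- runif(300) < ifelse(a > 0.04, 0.95, 0.03)
    if (all(p) || !any(p)) next
    expect_lt(abs(roc_threshold(a, p)$threshold - 0.04), 0.01)
  }

  # cross-check J at the chosen threshold against pROC
  skip_if_not_installed("pROC")
  set.seed(5)
  a <- runif(200, 0, 0.1)
  p <- runif(200) < ifelse(a > 0.04, 0.85, 0.15)
  got <- roc_threshold(a, p)
  r <- pROC::roc(response = p, predictor = a, quiet = TRUE)
  best_j <- max(r$sensitivities + r$specificities - 1)
  expect_equal(got$youden_j, best_j, tolerance = 1e-9)

  expect_error(roc_threshold(a, rep(TRUE, 200)), "both outcome classes")
})
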