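#' @useDynLib shapemem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq median rpois rnorm runif quantile
NULL

# physical coordinates (um) of foreground voxel centers, n x 3
mask_coords <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  sweep(idx - 0.5, 2L, mask$spacing, `*`)
}

#' Moment-of-inertia tensor of a voxel mask
#'
#' Treats every foreground voxel as a unit point mass at its center (in
#' micrometres) and returns the standard moment-of-inertia tensor about the
#' center of mass: diagonal entries are summed squared distances to each
#' axis, off-diagonal entries are negated coordinate products.
#'
#' @param mask a [binary_volume()] with nonempty foreground.
#' @return List with `tensor` (symmetric 3x3, um^2 voxel) and `c_mass`
#'   (centroid, um).
#' @export
inertia_tensor <- function(mask) {
  xyz <- mask_coords(mask)
  c_mass <- colMeans(xyz)
  r <- sweep(xyz, 2L, c_mass)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  tensor <- matrix(c(
    sum(y^2 + z^2), -sum(x * y),     -sum(x * z),
    -sum(x * y),     sum(x^2 + z^2), -sum(y * z),
    -sum(x * z),    -sum(y * z),      sum(x^2 + y^2)), 3L, 3L)
  list(tensor = tensor, c_mass = c_mass)
}

#' Principal axes of an inertia tensor
#'
#' Eigen-decomposition of the (symmetric, positive semidefinite) inertia
#' tensor. The eigenvector of the smallest eigenvalue is the long axis (mass
#' far from that axis contributes most to the other two moments), the
#' largest eigenvalue gives the short axis.
#'
#' @param tensor symmetric 3x3 inertia tensor.
#' @param tol relative eigenvalue gap below which an axis is flagged
#'   degenerate.
#' @return List with unit eigenvectors `e_long`, `e_mid`, `e_short`,
#'   eigenvalues `lambda_long <= lambda_mid <= lambda_short`, and two
#'   flags: `degenerate` (the long axis is ill-defined because the two
#'   smallest eigenvalues are close, as for a sphere) and
#'   `transverse_degenerate` (the mid/short pair is close, as for any
#'   rotationally symmetric rod - harmless for long-axis work).
#' @export
principal_axes <- function(tensor, tol = 1e-3) {
  if (!isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-8)))
    stop("inertia tensor must be symmetric")
  eg <- eigen(tensor, symmetric = TRUE)  # values in decreasing order
  vals <- eg$values
  scale <- max(abs(vals), 1e-300)
  list(e_long  = eg$vectors[, 3], e_mid = eg$vectors[, 2],
       e_short = eg$vectors[, 1],
       lambda_long = vals[3], lambda_mid = vals[2], lambda_short = vals[1],
       degenerate = (vals[2] - vals[3]) / scale < tol,
       transverse_degenerate = (vals[1] - vals[2]) / scale < tol)
}

#' Asymmetry vector from mass center to bounding-box center
#'
#' Projects every foreground voxel center onto the three principal axes,
#' takes the midpoint of the min/max interval along each axis (the center of
#' the principal-axis-aligned minimum bounding box), maps it back to world
#' coordinates, and returns the displacement from the center of mass. For
#' centrosymmetric shapes this vector vanishes; for one-sided protrusions it
#' points toward the protruding (spiky) end.
#'
#' @param mask a [binary_volume()].
#' @param axes result of [principal_axes()] (or any list with `e_long`,
#'   `e_mid`, `e_short`).
#' @return List with `c_median` (bounding-box center, um) and `d_asym`
#'   (um).
#' @export
asymmetry_vector <- function(mask, axes) {
  xyz <- mask_coords(mask)
  c_mass <- colMeans(xyz)
  E <- cbind(axes$e_long, axes$e_mid, axes$e_short)
  p <- xyz %*% E
  mid <- (apply(p, 2L, min) + apply(p, 2L, max)) / 2
  c_median <- as.numeric(E %*% mid)
  list(c_median = c_median, d_asym = c_median - c_mass)
}

#' Orient principal axes along the asymmetry vector
#'
#' Flips each raw eigenvector so that its dot product with the asymmetry
#' vector is nonnegative; a vanishing dot product keeps the raw sign. The
#' oriented long axis then points toward the (+), spiky side of the cell.
#'
#' @param axes result of [principal_axes()].
#' @param d_asym asymmetry vector from [asymmetry_vector()].
#' @return List with unit vectors `a_long`, `a_middle`, `a_short` and a
#'   logical `degenerate` flag (true when `d_asym` is numerically zero).
#' @export
orient_axes <- function(axes, d_asym) {
  flip <- function(e) if (sum(e * d_asym) < 0) -e else e
  degenerate <- sqrt(sum(d_asym^2)) < 1e-12
  list(a_long = flip(axes$e_long), a_middle = flip(axes$e_mid),
       a_short = flip(axes$e_short),
       degenerate = degenerate || isTRUE(axes$degenerate))
}

#' Full shape descriptor of a voxelized cell
#'
#' Computes the center of mass, inertia principal axes, oriented axes,
#' bounding-box center and asymmetry vector, the asymmetric-elongation
#' scalar `d_long` (projection of the asymmetry vector on the oriented long
#' axis), and its scale-free normalization `a_long_index = d_long / r` where
#' `r` is the radius of the volume-equivalent sphere. Also reports volume,
#' exposed-face surface area, surface-area-to-volume ratio and `r`.
#'
#' @param mask a [binary_volume()] with nonempty foreground.
#' @return An object of class `shape_descriptor`.
#' @export
shape_descriptor <- function(mask) {
  it <- inertia_tensor(mask)
  axes <- principal_axes(it$tensor)
  asym <- asymmetry_vector(mask, axes)
  or <- orient_axes(axes, asym$d_asym)
  n_vox <- sum(mask$mask)
  volume <- n_vox * prod(mask$spacing)
  surface <- surface_area(mask)
  r <- (3 * volume / (4 * pi))^(1 / 3)
  d_long <- sum(asym$d_asym * or$a_long)
  out <- list(
    c_mass = it$c_mass, inertia = it$tensor,
    e_long = axes$e_long, e_mid = axes$e_mid, e_short = axes$e_short,
    lambda_long = axes$lambda_long, lambda_mid = axes$lambda_mid,
    lambda_short = axes$lambda_short,
    a_long = or$a_long, a_middle = or$a_middle, a_short = or$a_short,
    c_median = asym$c_median, d_asym = asym$d_asym,
    d_long = d_long, a_long_index = d_long / r,
    volume = volume, surface_area = surface, sav = surface / volume,
    equiv_radius = r, n_voxels = n_vox, degenerate = or$degenerate)
  class(out) <- "shape_descriptor"
  out
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat("<shape_descriptor>\n")
  cat(sprintf("  volume %.1f um^3 (%d voxels), equiv radius %.2f um\n",
              x$volume, x$n_voxels, x$equiv_radius))
  cat(sprintf("  surface %.1f um^2, SAV %.3f um^-1\n", x$surface_area, x$sav))
  cat(sprintf("  D_long %.3f um, A_long %.4f%s\n", x$d_long, x$a_long_index,
              if (x$degenerate) " (degenerate axes)" else ""))
  cat(sprintf("  a_long (%.3f, %.3f, %.3f)\n",
              x$a_long[1], x$a_long[2], x$a_long[3]))
  invisible(x)
}

# exposed-face surface area in um^2 (anisotropic spacings supported)
surface_area <- function(mask) {
  m <- mask$mask
  d <- dim(m)
  sp <- mask$spacing
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  faces <- function(shift_dim) {
    i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
    core <- pad[i, j, k, drop = FALSE]
    off <- switch(shift_dim,
      pad[i + 1, j, k, drop = FALSE] + pad[i - 1, j, k, drop = FALSE],
      pad[i, j + 1, k, drop = FALSE] + pad[i, j - 1, k, drop = FALSE],
      pad[i, j, k + 1, drop = FALSE] + pad[i, j, k - 1, drop = FALSE])
    sum((2L - off)[core])
  }
  faces(1) * sp[2] * sp[3] + faces(2) * sp[1] * sp[3] + faces(3) * sp[1] * sp[2]
}

#' Surface-area-to-volume ratio
#'
#' Exposed-face surface area divided by voxel volume, in 1/um.
#'
#' @param mask a [binary_volume()] with nonempty foreground.
#' @return SAV ratio in um^-1.
#' @export
sav_ratio <- function(mask) {
  if (!any(mask$mask)) stop("empty mask")
  surface_area(mask) / (sum(mask$mask) * prod(mask$spacing))
}

#' Angle between the long axis and the fate axis
#'
#' The fate axis points from the V2b daughter toward the V2a daughter. When
#' `cos(theta_fate) > 0` the daughter on the (+) side of the oriented long
#' axis is the V2a; when negative, the (+)-side daughter is the V2b. A zero
#' cosine is reported as a tie.
#'
#' @param a_long oriented unit long axis.
#' @param a_cd unit fate (division) axis, V2b -> V2a.
#' @return List with `theta_fate` (degrees in `[0, 180]`), `plus_side_fate`
#'   (`"V2a"`, `"V2b"` or `"tie"`) and `cos_theta`.
#' @export
theta_fate <- function(a_long, a_cd) {
  n1 <- sqrt(sum(a_long^2)); n2 <- sqrt(sum(a_cd^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length axis vector")
  ct <- sum(a_long * a_cd) / (n1 * n2)
  ct <- max(-1, min(1, ct))
  fate <- if (abs(ct) < 1e-12) "tie" else if (ct > 0) "V2a" else "V2b"
  list(theta_fate = acos(ct) * 180 / pi, plus_side_fate = fate,
       cos_theta = ct)
}

#' Angle between two cell long axes (as undirected lines)
#'
#' Axes before and after an event are compared as orientation-free lines, so
#' the angle lies in `[0, 90]` degrees; a change above 45 degrees counts as
#' a new axis.
#'
#' @param a_before,a_after unit axis vectors.
#' @return List with `angle` (degrees) and `changed` (angle > 45).
#' @export
axis_change_angle <- function(a_before, a_after) {
  n1 <- sqrt(sum(a_before^2)); n2 <- sqrt(sum(a_after^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length axis vector")
  ct <- abs(sum(a_before * a_after)) / (n1 * n2)
  ang <- acos(max(-1, min(1, ct))) * 180 / pi
  list(angle = ang, changed = ang > 45)
}

#' Protein-localization descriptor
#'
#' Intensity-weighted centroid of a fluorescence signal over the masked cell,
#' its displacement from the cell's center of mass, which side of the
#' oriented long axis the signal sits on, and the displacement normalized by
#' the equivalent-sphere radius.
#'
#' @param intensity an [intensity_volume()] congruent with `mask`.
#' @param mask a [binary_volume()].
#' @param shape the cell's [shape_descriptor()].
#' @return List with `b_sum`, `c_signal` (um), `d_signal` (um),
#'   `plus_side` (logical) and `d_norm` (dimensionless).
#' @export
localization_descriptor <- function(intensity, mask, shape) {
  stopifnot(inherits(intensity, "intensity_volume"),
            inherits(mask, "binary_volume"))
  if (!identical(dim(intensity$data), dim(mask$mask)))
    stop("intensity and mask dimensions differ")
  xyz <- mask_coords(mask)
  b <- intensity$data[mask$mask]
  b_sum <- sum(b)
  if (b_sum <= 0) stop("zero total intensity inside the mask")
  c_signal <- colSums(xyz * b) / b_sum
  d_signal <- c_signal - shape$c_mass
  list(b_sum = b_sum, c_signal = c_signal, d_signal = d_signal,
       plus_side = sum(shape$a_long * d_signal) > 0,
       d_norm = sqrt(sum(d_signal^2)) / shape$equiv_radius)
}

#' ROC threshold on the eccentricity index
#'
#' Scans every observed `a_long` value as a candidate cut for predicting the
#' positive outcome (`a_long >= threshold` predicts positive) and returns the
#' threshold maximizing Youden's J (sensitivity + specificity - 1), ties
#' broken toward the smaller threshold.
#'
#' @param a_long numeric eccentricity indices.
#' @param positive logical outcome per sample (e.g. plus-side daughter took
#'   the V2a fate).
#' @return List with `threshold`, `youden_j`, `sensitivity`, `specificity`.
#' @export
roc_threshold <- function(a_long, positive) {
  stopifnot(length(a_long) == length(positive), length(a_long) >= 2L)
  positive <- as.logical(positive)
  if (all(positive) || !any(positive))
    stop("both outcome classes must be present")
  cand <- sort(unique(a_long))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  j <- vapply(cand, function(th) {
    pred <- a_long >= th
    sum(pred & positive) / n_pos + sum(!pred & !positive) / n_neg - 1
  }, numeric(1))
  best <- which.max(j)  # first maximum = smallest threshold
  th <- cand[best]
  pred <- a_long >= th
  list(threshold = th, youden_j = j[best],
       sensitivity = sum(pred & positive) / n_pos,
       specificity = sum(!pred & !positive) / n_neg)
}
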