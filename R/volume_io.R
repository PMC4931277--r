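#' 3D intensity volume
#'
#' A 3D scalar field with a physical voxel spacing, the container for raw or
#' synthetic fluorescence stacks. Values must be finite and nonnegative.
#'
#' @param data numeric 3D array of nonnegative values.
#' @param spacing numeric length-3, voxel size per axis in micrometres.
#' @return An object of class `intensity_volume` with elements `data` and
#'   `spacing`.
#' @export
intensity_volume <- function(data, spacing = c(0.5, 0.5, 0.5)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in micrometres")
  if (any(!is.finite(data)) || any(data < 0))
    stop("voxel values must be finite and nonnegative")
  structure(list(data = data, spacing = spacing), class = "intensity_volume")
}

#' Binary voxel mask
#'
#' A segmented cell object: logical 3D mask plus voxel spacing in
#' micrometres.
#'
#' @param mask logical 3D array.
#' @param spacing numeric length-3 voxel size in micrometres.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing = c(0.5, 0.5, 0.5)) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask may not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in micrometres")
  structure(list(mask = mask, spacing = spacing), class = "binary_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat("<intensity_volume>", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 3), collapse = " x "),
      "um\n")
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("<binary_volume>", paste(dim(x$mask), collapse = " x "),
      "voxels,", sum(x$mask), "foreground, spacing",
      paste(signif(x$spacing, 3), collapse = " x "), "um\n")
  invisible(x)
}

#' Read a 3D volume from TIFF or NRRD
#'
#' Multi-page TIFF stacks (`.tif`/`.tiff`) and raw-encoded NRRD volumes
#' (`.nrrd`) are supported. NRRD files carry per-axis spacings; TIFF has no
#' reliable 3D spacing metadata, so `spacing_override` is required for TIFF
#' input.
#'
#' @param path file path.
#' @param spacing_override optional numeric length-3 spacing in micrometres;
#'   overrides any spacing found in the file.
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("TIFF has a single page: not a volume")
    if (length(dim(pages[[1]])) != 2L)
      stop("multi-channel TIFF pages are not supported")
    d <- dim(pages[[1]])
    data <- array(0, dim = c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) data[, , k] <- pages[[k]]
    if (is.null(spacing_override))
      stop("TIFF carries no voxel spacing; supply `spacing_override`")
    intensity_volume(data, spacing_override)
  } else if (ext == "nrrd") {
    vol <- read_nrrd(path)
    if (!is.null(spacing_override)) vol$spacing <- as.numeric(spacing_override)
    vol
  } else {
    stop("unsupported volume format: .", ext)
  }
}

#' Write a 3D volume to TIFF or NRRD
#'
#' NRRD (raw, little-endian double) round-trips values exactly and stores the
#' spacing; TIFF is written as 32-bit float pages and requires values in
#' `[0, 1]`.
#'
#' @param vol an [intensity_volume()] or [binary_volume()] (written as 0/1).
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_volume"))
    vol <- intensity_volume(array(as.numeric(vol$mask), dim(vol$mask)),
                            vol$spacing)
  if (!inherits(vol, "intensity_volume")) stop("not a volume object")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(vol$data) > 1)
      stop("TIFF output requires values in [0, 1]; rescale or use NRRD")
    pages <- lapply(seq_len(dim(vol$data)[3]), function(k) vol$data[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else if (ext == "nrrd") {
    write_nrrd(vol, path)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

# Minimal NRRD support (raw encoding, little endian, double/float/int types).
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- kv[2]
  }
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  if (length(sizes) != 3L) stop("NRRD is not a 3D volume")
  if (tolower(fields[["encoding"]]) != "raw")
    stop("only raw NRRD encoding is supported")
  type <- tolower(fields[["type"]])
  n <- prod(sizes)
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  data <- switch(type,
    "double" = readBin(con, "double", n, size = 8, endian = endian),
    "float"  = readBin(con, "double", n, size = 4, endian = endian),
    "int"    = ,
    "int32"  = ,
    "signed int" = readBin(con, "integer", n, size = 4, endian = endian),
    "short"  = ,
    "int16"  = readBin(con, "integer", n, size = 2, endian = endian),
    "uchar"  = ,
    "uint8"  = readBin(con, "integer", n, size = 1, signed = FALSE),
    stop("unsupported NRRD type: ", type))
  if (length(data) != n) stop("truncated NRRD data block")
  spacing <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
  else stop("NRRD has no spacings field; supply `spacing_override`")
  intensity_volume(array(data, dim = sizes), spacing)
}

write_nrrd <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    paste("sizes:", paste(dim(vol$data), collapse = " ")),
    paste("spacings:", paste(format(vol$spacing, digits = 17), collapse = " ")),
    "encoding: raw",
    "endian: little",
    "")
  writeLines(header, con, sep = "\n")
  writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  invisible(path)
}

#' 3D median filter
#'
#' Replaces each voxel by the median of its `(2r+1)^3` neighbourhood, with
#' nearest-border replication at the edges (which makes the filter a no-op
#' on constant volumes). The standard despeckling step applied to confocal
#' stacks before binarization.
#'
#' @param vol an [intensity_volume()].
#' @param radius neighbourhood radius in voxels (>= 1).
#' @return A filtered [intensity_volume()].
#' @export
median_filter_3d <- function(vol, radius = 1L) {
  stopifnot(inherits(vol, "intensity_volume"))
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("`radius` must be >= 1")
  out <- cpp_median_filter3d(vol$data, radius)
  intensity_volume(out, vol$spacing)
}

#' Discriminant-analysis (Otsu) binarization
#'
#' Thresholds the volume at the level maximizing the between-class variance
#' over all candidate thresholds (exhaustive scan over the sorted unique
#' values), i.e. Otsu's discriminant criterion. A manual threshold may be
#' supplied instead. Voxels strictly above the threshold are foreground; if
#' the background class is the brighter one (foreground darker than
#' background), the mask is inverted so the minority-bright object is
#' foreground when `invert = "auto"`.
#'
#' @param vol an [intensity_volume()] with at least two distinct values.
#' @param threshold `"otsu"` (default) or a numeric cut level.
#' @param invert `"auto"` (foreground = smaller class), `TRUE`, or `FALSE`
#'   (foreground = above-threshold voxels).
#' @return A [binary_volume()]; the chosen threshold is attached as
#'   attribute `"threshold"`.
#' @export
binarize_discriminant <- function(vol, threshold = "otsu", invert = "auto") {
  stopifnot(inherits(vol, "intensity_volume"))
  x <- as.numeric(vol$data)
  if (identical(threshold, "otsu")) {
    u <- sort(unique(x))
    if (length(u) < 2L)
      stop("constant volume: no discriminant threshold exists")
    threshold <- otsu_threshold(x, u)
  } else {
    threshold <- as.numeric(threshold)
  }
  mask <- vol$data > threshold
  if (identical(invert, "auto")) invert <- mean(mask) > 0.5
  if (isTRUE(invert)) mask <- !mask
  out <- binary_volume(mask, vol$spacing)
  attr(out, "threshold") <- threshold
  out
}

# Exact Otsu scan: candidate thresholds are the unique values; pick the one
# maximizing between-class variance w0*w1*(mu0-mu1)^2 (ties -> smallest).
otsu_threshold <- function(x, u = sort(unique(x))) {
  n <- length(x)
  cnt <- tabulate(findInterval(x, u), nbins = length(u))
  csum  <- cumsum(cnt)
  cmean <- cumsum(cnt * u)
  total <- cmean[length(u)]
  w0 <- csum[-length(u)] / n
  w1 <- 1 - w0
  mu0 <- cmean[-length(u)] / csum[-length(u)]
  mu1 <- (total - cmean[-length(u)]) / (n - csum[-length(u)])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  u[which.max(bcv)]
}

#' Keep the largest connected foreground component
#'
#' Labels foreground components under the requested connectivity and retains
#' only the largest one (ties broken in favour of the component whose first
#' voxel in array scan order comes first). Used to isolate a single cell
#' object before shape measurement.
#'
#' @param mask a [binary_volume()] with nonempty foreground.
#' @param connectivity 6, 18 or 26 (default).
#' @return A [binary_volume()] containing only the winning component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_volume"))
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6|18|26")
  if (!any(mask$mask)) stop("empty mask")
  lab <- cpp_label_components(mask$mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # first maximum = smallest lexicographic seed
  binary_volume(array(lab == keep, dim(mask$mask)), mask$spacing)
}
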