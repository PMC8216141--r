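# Voxel-level tissue mineral density analytics -----------------------------

#' Calibrated TMD voxel volume
#'
#' @param data 3D numeric array of calibrated density, mg HA/cm^3 (>= 0).
#' @param voxel_size isotropic voxel edge length, micrometers.
#' @param origin grid origin offset, micrometers (length 3).
#' @return Object of class \code{"voxel_volume"}.
#' @export
voxel_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array", call. = FALSE)
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive", call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("densities must be non-negative", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' Binary mask congruent with a voxel volume
#'
#' @param data 3D logical array.
#' @param label "whole" or "fracture_zone".
#' @return Object of class \code{"voxel_mask"}.
#' @export
voxel_mask <- function(data, label = c("whole", "fracture_zone")) {
  label <- match.arg(label)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  structure(list(data = array(as.logical(data), dim(data)), label = label),
            class = "voxel_mask")
}

check_congruent <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("mask shape does not match volume shape", call. = FALSE)
}

# separable 3D Gaussian smoothing with zero padding (matches the imaging
# convention of treating the background as air/fluid at zero density)
gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_along <- function(a, dimi) {
    d <- dim(a)
    perm <- switch(dimi, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    n <- nrow(m)
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    res <- array(out, db)
    aperm(res, order(perm))
  }
  for (dimi in 1:3) a <- conv_along(a, dimi)
  a
}

#' Segment a TMD volume by Gaussian smoothing and single-level threshold
#'
#' Smooths the volume with an isotropic Gaussian (default sigma = 1 voxel)
#' and thresholds at a single density level (default 490 mg HA/cm^3, which
#' keeps the fluid/bone border layer out of the mask).
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param sigma Gaussian standard deviation in voxels (>= 0; 0 = none).
#' @param threshold segmentation level, mg HA/cm^3 (> 0).
#' @return A \code{\link{voxel_mask}} labelled "whole". An empty mask
#'   raises a warning, not an error.
#' @export
segment_volume <- function(volume, sigma = 1, threshold = 490) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  sm <- gauss_smooth3d(volume$data, sigma)
  m <- sm > threshold
  if (!any(m)) warning("segmentation produced an empty mask")
  voxel_mask(m, "whole")
}

#' Normalized TMD histogram of a masked volume
#'
#' Histogram of the masked voxel densities, normalized by the total number
#' of nonzero masked voxels, so frequencies sum to one.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param mask a congruent \code{\link{voxel_mask}} (non-empty).
#' @param bin_width bin width, mg HA/cm^3 (default 10).
#' @return Object of class \code{"tmd_histogram"}: data.frame with
#'   \code{bin_lo}, \code{bin_hi}, \code{mid}, \code{frequency}.
#' @export
tmd_histogram <- function(volume, mask, bin_width = 10) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "voxel_mask"))
  check_congruent(volume, mask)
  vals <- volume$data[mask$data]
  vals <- vals[vals > 0]
  if (!length(vals))
    stop("mask selects no nonzero voxels", call. = FALSE)
  lo <- floor(min(vals) / bin_width) * bin_width
  edges <- seq(lo, max(vals) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(vals, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(data.frame(bin_lo = head(edges, -1L), bin_hi = edges[-1L],
                       mid = (head(edges, -1L) + edges[-1L]) / 2,
                       frequency = counts / length(vals)),
            class = c("tmd_histogram", "data.frame"))
}

#' Cross-sectional mean intensity profile through the mass centroid
#'
#' Within one axial cross-section (third array index), locates the mass
#' centroid of the masked density and samples the density along the two
#' orthogonal in-plane axes through the centroid. Positions are normalized
#' to [0, 1] by the local thickness (the chord of the mask through the
#' centroid along each axis); the two directional profiles are interpolated
#' onto a common normalized grid and averaged.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param mask a congruent \code{\link{voxel_mask}}.
#' @param slice_index axial (3rd dimension) slice index; must intersect the
#'   mask.
#' @param n_points points of the normalized output grid (default 50).
#' @return data.frame with \code{position} in [0, 1] and \code{density},
#'   mg HA/cm^3.
#' @export
intensity_profile <- function(volume, mask, slice_index, n_points = 50L) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "voxel_mask"))
  check_congruent(volume, mask)
  d <- dim(volume$data)
  if (slice_index < 1L || slice_index > d[3])
    stop("slice_index out of range", call. = FALSE)
  img <- volume$data[, , slice_index]
  msk <- mask$data[, , slice_index]
  if (!any(msk))
    stop("slice does not intersect the mask", call. = FALSE)

  w <- img * msk
  tot <- sum(w)
  ci <- if (tot > 0) sum(row(img) * w) / tot else mean(which(msk) %% d[1])
  cj <- if (tot > 0) sum(col(img) * w) / tot else NA
  ci <- round(ci); cj <- round(cj)

  grid <- seq(0, 1, length.out = n_points)
  profile_along <- function(vals, inside) {
    hits <- which(inside)
    if (length(hits) < 2L) return(NULL)
    span <- range(hits)
    pos <- (hits - span[1]) / (span[2] - span[1])
    approx(pos, vals[hits], xout = grid, rule = 2)$y
  }
  p1 <- profile_along(img[, cj], msk[, cj])
  p2 <- profile_along(img[ci, ], msk[ci, ])
  profs <- Filter(Negate(is.null), list(p1, p2))
  if (!length(profs))
    stop("mask chord through the centroid is degenerate", call. = FALSE)
  data.frame(position = grid,
             density = Reduce(`+`, profs) / length(profs))
}

#' Zone-wise TMD statistics
#'
#' Mean and SD of the masked density in the whole trabecula, in the
#' fracture zone, and in the non-fracture remainder, plus the paired
#' differences (whole minus fracture zone, and non-fracture remainder
#' minus fracture zone) used downstream in pairwise signed-rank testing.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param whole_mask whole-trabecula \code{\link{voxel_mask}}.
#' @param fracture_mask fracture-zone \code{\link{voxel_mask}}; must be a
#'   subset of the whole mask. May be empty (stats flagged).
#' @return list with per-zone \code{mean} and \code{sd} (\code{whole},
#'   \code{fracture}, \code{remainder}), \code{diff_whole_fracture},
#'   \code{diff_remainder_fracture}, and \code{fracture_empty} flag.
#' @export
zone_stats <- function(volume, whole_mask, fracture_mask) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(whole_mask, "voxel_mask"),
            inherits(fracture_mask, "voxel_mask"))
  check_congruent(volume, whole_mask)
  check_congruent(volume, fracture_mask)
  if (any(fracture_mask$data & !whole_mask$data))
    stop("fracture mask must be a subset of the whole mask", call. = FALSE)

  sd0 <- function(v) if (length(v) > 1L) sd(v) else 0
  vw <- volume$data[whole_mask$data]
  if (!length(vw)) stop("empty whole mask", call. = FALSE)
  empty_fx <- !any(fracture_mask$data)
  vf <- volume$data[fracture_mask$data]
  vr <- volume$data[whole_mask$data & !fracture_mask$data]
  list(whole = list(mean = mean(vw), sd = sd0(vw), n = length(vw)),
       fracture = if (empty_fx) list(mean = NA_real_, sd = NA_real_, n = 0L)
                  else list(mean = mean(vf), sd = sd0(vf), n = length(vf)),
       remainder = if (length(vr))
         list(mean = mean(vr), sd = sd0(vr), n = length(vr))
       else list(mean = NA_real_, sd = NA_real_, n = 0L),
       diff_whole_fracture = if (empty_fx) NA_real_ else mean(vw) - mean(vf),
       diff_remainder_fracture = if (empty_fx || !length(vr)) NA_real_
                                 else mean(vr) - mean(vf),
       fracture_empty = empty_fx)
}

#' Mean cross-sectional area of a masked trabecula
#'
#' Total masked volume divided by the axial length: \eqn{A_{mean} =
#' n_{vox} \cdot v^3 / L} with voxel edge v.
#'
#' @param mask a \code{\link{voxel_mask}} (non-empty).
#' @param voxel_size voxel edge length, micrometers.
#' @param axis_length axial specimen length, mm (> 0).
#' @return Mean cross-sectional area, mm^2.
#' @export
mean_cross_area <- function(mask, voxel_size, axis_length) {
  stopifnot(inherits(mask, "voxel_mask"))
  n <- sum(mask$data)
  if (n == 0L) stop("empty mask", call. = FALSE)
  if (!is.finite(axis_length) || axis_length <= 0)
    stop("axis_length must be positive", call. = FALSE)
  vol_mm3 <- n * (voxel_size * 1e-3)^3
  vol_mm3 / axis_length
}

# NRRD I/O ------------------------------------------------------------------
# Minimal NRRD support: 3D volumes, encodings "raw" (little endian) and
# "ascii"; types double, float, uint8, int16, uint16, int32. Enough for the
# pipeline's volumes and masks without an external reader.

nrrd_types <- list(
  double = list(size = 8L, what = "double", signed = TRUE),
  float = list(size = 4L, what = "double", signed = TRUE),
  uchar = list(size = 1L, what = "integer", signed = FALSE),
  `unsigned char` = list(size = 1L, what = "integer", signed = FALSE),
  uint8 = list(size = 1L, what = "integer", signed = FALSE),
  short = list(size = 2L, what = "integer", signed = TRUE),
  int16 = list(size = 2L, what = "integer", signed = TRUE),
  ushort = list(size = 2L, what = "integer", signed = FALSE),
  uint16 = list(size = 2L, what = "integer", signed = FALSE),
  int = list(size = 4L, what = "integer", signed = TRUE),
  int32 = list(size = 4L, what = "integer", signed = TRUE))

#' Write a voxel volume or mask as NRRD
#'
#' @param x a \code{\link{voxel_volume}} or \code{\link{voxel_mask}}.
#' @param path output file path (.nrrd).
#' @param encoding "raw" (little-endian, default) or "ascii".
#' @return path, invisibly.
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_mask <- inherits(x, "voxel_mask")
  a <- x$data
  d <- dim(a)
  vs <- if (is_mask) 1 else x$voxel_size
  type <- if (is_mask) "uint8" else "double"
  header <- c("NRRD0004",
              "# generated by trabmech",
              paste0("type: ", type),
              "dimension: 3",
              paste0("sizes: ", paste(d, collapse = " ")),
              paste0("spacings: ", paste(rep(vs, 3), collapse = " ")),
              paste0("encoding: ", encoding),
              if (encoding == "raw") "endian: little",
              paste0("content: ", if (is_mask) x$label else "tmd"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("", con)
  if (encoding == "ascii") {
    writeLines(paste(format(as.vector(if (is_mask) as.integer(a) else a),
                            digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  } else {
    if (is_mask)
      writeBin(as.integer(as.vector(a)), con, size = 1L, endian = "little")
    else
      writeBin(as.numeric(as.vector(a)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read an NRRD file as a voxel volume or mask
#'
#' @param path NRRD file path.
#' @param as_mask read as logical \code{\link{voxel_mask}} (nonzero = TRUE).
#' @param label mask label when \code{as_mask}.
#' @return \code{\link{voxel_volume}} or \code{\link{voxel_mask}}.
#' @export
read_nrrd <- function(path, as_mask = FALSE, label = "whole") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD"))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    if (startsWith(line, "#")) next
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    fields[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported", call. = FALSE)
  type <- fields$type
  enc <- fields$encoding
  n <- prod(sizes)
  if (identical(enc, "ascii") || identical(enc, "text") ||
      identical(enc, "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    vals <- vals[is.finite(vals) | is.na(vals)]
    vals <- vals[seq_len(n)]
  } else if (identical(enc, "raw")) {
    ti <- nrrd_types[[type]]
    if (is.null(ti)) stop("unsupported NRRD type: ", type, call. = FALSE)
    endian <- if (!is.null(fields$endian)) fields$endian else "little"
    vals <- readBin(con, what = ti$what, n = n, size = ti$size,
                    signed = if (ti$what == "integer" && ti$size < 4L)
                      ti$signed else TRUE,
                    endian = endian)
  } else stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  a <- array(vals, sizes)
  spc <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]])[1] else 1
  if (as_mask) voxel_mask(a != 0, label)
  else voxel_volume(a, voxel_size = spc)
}
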