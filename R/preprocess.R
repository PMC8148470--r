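#' Preprocessing parameters
#'
#' Free parameters of the image-processing front end: background estimation
#' by grayscale morphological opening, histogram bin count for Otsu
#' thresholding, and the majority (median) denoising radius.
#'
#' @param opening_radius_px Flat-disk radius (pixels) of the structuring
#'   element used for slice-wise background opening. Sized to exceed the
#'   footprint of a cell so that somata and processes are removed from the
#'   background estimate; default 50 px suits soma-scale structures at 20X.
#' @param median_radius_px Half-width of the cubic neighbourhood of the
#'   post-threshold majority filter; default 1 (a 3x3x3 cube).
#' @param otsu_bins Number of histogram bins for Otsu's method; default 256.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(opening_radius_px = 50L, median_radius_px = 1L,
                              otsu_bins = 256L) {
  opening_radius_px <- as.integer(opening_radius_px)
  median_radius_px <- as.integer(median_radius_px)
  otsu_bins <- as.integer(otsu_bins)
  if (opening_radius_px < 1L || median_radius_px < 1L) {
    stop("radii must be >= 1", call. = FALSE)
  }
  if (otsu_bins < 2L) stop("otsu_bins must be >= 2", call. = FALSE)
  structure(list(opening_radius_px = opening_radius_px,
                 median_radius_px = median_radius_px,
                 otsu_bins = otsu_bins),
            class = "preprocess_params")
}

# Grayscale morphology with a flat digital disk (offsets dy^2 + dx^2 <= r^2).
# Windows are clipped at the image border (equivalently: the image is padded
# with +Inf for erosion and -Inf for dilation), so a constant image is a
# fixed point of both operators.
# Implemented in src/morphology.cpp as monotonic-queue running extremes
# along each disk column, with cost independent of the radius.

.open_slice <- function(m, r) {
  disc_morph(disc_morph(m, r, FALSE), r, TRUE)
}

#' Estimate the image background by morphological opening
#'
#' Grayscale opening (erosion then dilation) with a flat disk is applied
#' independently in each z-plane; structures smaller than the disk -- cells
#' and their processes -- are flattened away, leaving the smooth illumination
#' background. Opening is anti-extensive, so the estimate never exceeds the
#' input. Windows are clipped at the image border, so a constant
#' image is reproduced exactly.
#'
#' @param stack An [image_stack()].
#' @param params A [preprocess_params()]; `opening_radius_px` must be smaller
#'   than the smaller in-plane dimension.
#' @return An [image_stack()] holding the background estimate.
#' @export
estimate_background <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "preprocess_params"))
  r <- params$opening_radius_px
  d <- dim(stack$voxels)
  if (r >= min(d[2], d[3])) {
    stop("opening_radius_px must be smaller than the in-plane dimensions",
         call. = FALSE)
  }
  out <- stack$voxels
  for (z in seq_len(d[1])) {
    out[z, , ] <- .open_slice(stack$voxels[z, , , drop = TRUE], r)
  }
  image_stack(out, stack$spacing, name = stack$name)
}

#' Subtract an estimated background from a raw stack
#'
#' Voxelwise `max(raw - background, 0)`: negative residuals are clamped at
#' zero because negative fluorescence is physically meaningless and would
#' distort the Otsu histogram.
#'
#' @param stack Raw [image_stack()].
#' @param background Background [image_stack()] of identical geometry.
#' @return An [image_stack()] of the same shape.
#' @export
subtract_background <- function(stack, background) {
  stopifnot(inherits(stack, "image_stack"), inherits(background, "image_stack"))
  if (!identical(dim(stack$voxels), dim(background$voxels))) {
    stop("stack and background differ in shape", call. = FALSE)
  }
  out <- pmax(stack$voxels - background$voxels, 0)
  image_stack(out, stack$spacing, name = stack$name)
}

# Otsu's threshold on a vector of values: histogram over `bins` equal-width
# bins spanning [min, max]; the returned threshold is the bin edge whose cut
# maximizes the between-class variance (smallest edge on ties). Values
# strictly above the threshold are foreground.
.otsu_from_values <- function(values, bins) {
  lo <- min(values)
  hi <- max(values)
  if (hi <= lo) {
    stop("Otsu thresholding needs >= 2 distinct intensity values",
         call. = FALSE)
  }
  breaks <- seq(lo, hi, length.out = bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- as.double(tabulate(idx, nbins = bins))
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  n <- length(values)
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * mids)
  total <- s0[bins]
  k <- seq_len(bins - 1L)
  w0k <- w0[k]
  w1k <- n - w0k
  valid <- w0k > 0 & w1k > 0
  bcv <- rep(-Inf, bins - 1L)
  bcv[valid] <- (total * w0k[valid] - n * s0[k][valid])^2 /
    (w0k[valid] * w1k[valid])
  kstar <- which.max(bcv)  # first maximum: deterministic tie-break
  list(threshold = breaks[kstar + 1L], bcv = bcv, breaks = breaks)
}

#' Global Otsu threshold of a stack
#'
#' The threshold maximizing the between-class variance of the pooled 3D voxel
#' histogram is computed once per stack (not per slice), so a single
#' consistent mask spans all z-planes. The mask keeps voxels strictly greater
#' than the threshold; ties at the threshold go to background, which makes
#' the binarization deterministic.
#'
#' @param stack An [image_stack()] with at least two distinct values.
#' @param params A [preprocess_params()] supplying `otsu_bins`.
#' @return A list with `threshold` (scalar) and `mask` (a [binary_mask()]).
#' @export
otsu_threshold <- function(stack, params = preprocess_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "preprocess_params"))
  ot <- .otsu_from_values(as.vector(stack$voxels), params$otsu_bins)
  mask <- binary_mask(stack$voxels > ot$threshold, stack$spacing)
  list(threshold = ot$threshold, mask = mask)
}

# Sliding box sum along the first array dimension with clipped windows.
.box_sum_dim1 <- function(a, r) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  cs <- apply(m, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = d[1])
  n <- d[1]
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r - 1L
  top <- cs[hi, , drop = FALSE]
  bot <- matrix(0, n, ncol(m))
  pos <- lo >= 1L
  if (any(pos)) bot[pos, ] <- cs[lo[pos], , drop = FALSE]
  array(top - bot, d)
}

.box_sum_3d <- function(a, r) {
  a <- .box_sum_dim1(a, r)
  a <- aperm(a, c(2L, 3L, 1L))
  a <- .box_sum_dim1(a, r)
  a <- aperm(a, c(2L, 3L, 1L))
  a <- .box_sum_dim1(a, r)
  aperm(a, c(2L, 3L, 1L))
}

#' Majority (median) filter of a binary mask
#'
#' Each voxel is replaced by the strict majority value of its (2r+1)^3 cube
#' neighbourhood; at the volume border the neighbourhood is clipped. For a
#' binary image the median filter and the majority filter coincide. Exact
#' ties (possible only in clipped border neighbourhoods) resolve to
#' background.
#'
#' @param mask A [binary_mask()].
#' @param params A [preprocess_params()] supplying `median_radius_px`.
#' @return A [binary_mask()] of the same geometry.
#' @export
median_denoise <- function(mask, params = preprocess_params()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(params, "preprocess_params"))
  r <- params$median_radius_px
  v <- mask$voxels
  s <- .box_sum_3d(array(as.double(v), dim(v)), r)
  nsize <- .box_sum_3d(array(1, dim(v)), r)
  binary_mask(2 * s > nsize, mask$spacing)
}
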