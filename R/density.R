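#' Maximum-intensity projection of a stack
#'
#' Collapses a z-stack to a 2D image whose pixel (y, x) is the maximum over
#' all z-planes, the standard en-face view for flat-mount quantification.
#'
#' @param stack An [image_stack()].
#' @return A 2D numeric matrix (y, x).
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$voxels, c(2L, 3L), max)
}

#' Fraction of stained area in a 2D image
#'
#' Fraction of pixels strictly above a threshold, either supplied as a fixed
#' intensity (e.g. a pooled-histogram Otsu threshold shared across an
#' experiment arm) or derived per image with Otsu's method.
#'
#' @param image 2D numeric matrix.
#' @param threshold Numeric scalar, or `"otsu"` for a per-image Otsu
#'   threshold (errors on a constant image).
#' @param otsu_bins Histogram bins when `threshold = "otsu"`.
#' @return A list with `area_fraction` in \[0, 1\] and the `threshold` used.
#' @export
stained_area_fraction <- function(image, threshold = "otsu",
                                  otsu_bins = 256L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a 2D numeric matrix", call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    threshold <- .otsu_from_values(as.vector(image), as.integer(otsu_bins))$threshold
  } else if (!is.numeric(threshold) || length(threshold) != 1L) {
    stop("`threshold` must be a scalar or \"otsu\"", call. = FALSE)
  }
  list(area_fraction = mean(image > threshold), threshold = threshold)
}

#' Normalize per-eye stained fractions to the control group
#'
#' Each eye's mean stained fraction is divided by the grand mean of the
#' control arm's per-eye fractions and expressed as a percentage, so the
#' control arm itself averages 100 by construction. The normalization is
#' scale-equivariant: rescaling all fractions by a common factor leaves the
#' percentages unchanged.
#'
#' @param eye_means Named numeric vector of per-eye mean fractions.
#' @param control_eye_means Numeric vector of the control arm's per-eye
#'   fractions (non-empty, nonzero mean).
#' @return Named numeric vector of normalized percentages.
#' @export
normalize_to_control <- function(eye_means, control_eye_means) {
  if (length(control_eye_means) == 0L) {
    stop("control group is empty", call. = FALSE)
  }
  cm <- mean(control_eye_means)
  if (!is.finite(cm) || cm == 0) {
    stop("control group mean is zero or undefined", call. = FALSE)
  }
  eye_means / cm * 100
}

#' OCT lesion-thickness ratio
#'
#' Lesion swelling relative to the adjacent choroid: `(b - c) / c`, where
#' `b` is the CNV lesion thickness and `c` the adjacent choroid thickness,
#' both in micrometres. Zero means no thickening.
#'
#' @param b Lesion thickness (um); vectorized.
#' @param c Adjacent choroid thickness (um); must be > 0.
#' @return `(b - c) / c`, dimensionless.
#' @examples
#' oct_ratio(300, 200)  # 0.5
#' @export
oct_ratio <- function(b, c) {
  if (any(!is.finite(c)) || any(c <= 0)) {
    stop("adjacent choroid thickness `c` must be > 0", call. = FALSE)
  }
  (b - c) / c
}
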