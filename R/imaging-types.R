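#' Physical voxel spacing
#'
#' Voxel edge lengths in micrometres along each axis. The axial step defaults
#' to 2.5 um, the z-path typically used when acquiring confocal z-stacks of
#' flat-mounted retina.
#'
#' @param dx,dy Lateral pixel size in um per voxel.
#' @param dz Axial step in um per z-plane (default 2.5).
#' @return An object of class `voxel_spacing` with fields `dx`, `dy`, `dz`.
#' @examples
#' voxel_spacing(1.25, 1.25)
#' @export
voxel_spacing <- function(dx, dy = dx, dz = 2.5) {
  for (v in list(dx, dy, dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("voxel spacing components must be single strictly positive numbers",
           call. = FALSE)
    }
  }
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx = %g um, dy = %g um, dz = %g um\n",
              x$dx, x$dy, x$dz))
  invisible(x)
}

.check_spacing <- function(spacing) {
  if (!inherits(spacing, "voxel_spacing")) {
    stop("`spacing` must be created with voxel_spacing()", call. = FALSE)
  }
  spacing
}

#' 3D intensity stack
#'
#' Container for a grayscale z-stack. Voxels are stored as a 3D numeric array
#' in (z, y, x) order (z fastest), matching the page-major layout of
#' multi-page TIFF files. Intensities must be finite and non-negative.
#'
#' @param voxels 3D numeric array, dimensions (nz, ny, nx), all >= 1.
#' @param spacing A [voxel_spacing()].
#' @param name Identifier string carried through the pipeline.
#' @return An object of class `image_stack`.
#' @examples
#' st <- image_stack(array(0, c(3, 8, 8)), voxel_spacing(1, 1, 2.5))
#' dim(st$voxels)
#' @export
image_stack <- function(voxels, spacing, name = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("all stack dimensions must be >= 1",
                                  call. = FALSE)
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0)) {
    stop("stack intensities must be finite and >= 0", call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = .check_spacing(spacing),
                 name = as.character(name)[1L]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack '%s': %d x %d x %d (z, y, x), range [%g, %g]\n",
              x$name, d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  print(x$spacing)
  invisible(x)
}

#' Binary voxel mask
#'
#' Boolean companion of an [image_stack()]: same (z, y, x) geometry, same
#' physical spacing.
#'
#' @param voxels 3D logical array in (z, y, x) order.
#' @param spacing A [voxel_spacing()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA", call. = FALSE)
  structure(list(voxels = voxels, spacing = .check_spacing(spacing)),
            class = "binary_mask")
}

#' Labelled segmentation volume
#'
#' Integer voxel labels sharing an [image_stack()]'s geometry: 0 is
#' background, objects are numbered contiguously 1..N in raster order of
#' their first voxel.
#'
#' @param labels 3D integer array in (z, y, x) order.
#' @param spacing A [voxel_spacing()].
#' @return An object of class `label_volume` with an `n_labels` field.
#' @export
label_volume <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array in (z, y, x) order", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  n <- if (length(labels)) max(labels) else 0L
  if (n > 0L) {
    present <- tabulate(labels[labels > 0L], nbins = n)
    if (any(present == 0L)) {
      stop("labels must form a contiguous range 1..N", call. = FALSE)
    }
  }
  structure(list(labels = labels, spacing = .check_spacing(spacing),
                 n_labels = as.integer(n)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d (z, y, x), %d object(s)\n",
              d[1], d[2], d[3], x$n_labels))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
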