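#' Segmentation parameters
#'
#' Cutoffs for the object- and cell-level filters and for bright-center seed
#' detection. The source procedure names the filters ("too small/big to be
#' an isolated cell", "shape and size filters") without numeric values; the
#' defaults here are sized for the synthetic generator's cell scale
#' (soma 6-8 um, lateral sampling ~1.25-1.5 um/px) and are all
#' config-overridable.
#'
#' @param min_object_voxels,max_object_voxels First size gate applied to
#'   connected objects (isolated cells or small cell clusters).
#' @param seed_smooth_sigma_px Gaussian sigma (pixels, xy only) used to
#'   smooth the intensity before looking for bright centers.
#' @param seed_min_distance_px Minimum xy separation between retained seeds.
#' @param seed_rel_intensity Fraction of an object's maximum smoothed
#'   intensity a local maximum must reach to qualify as a bright (soma)
#'   center; this is the operational definition of "bright" and keeps dim
#'   bumps along processes from fragmenting a cell.
#' @param min_cell_voxels,max_cell_voxels Per-cell size gate after splitting.
#' @param max_elongation Upper bound on the ratio of the longest to shortest
#'   principal-axis length (square roots of the voxel-coordinate covariance
#'   eigenvalues, in physical um). Fibers and vessel fragments exceed it.
#' @param min_extent Lower bound on voxel_count / bounding-box volume.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(min_object_voxels = 30L,
                                max_object_voxels = 100000L,
                                seed_smooth_sigma_px = 2,
                                seed_min_distance_px = 8,
                                seed_rel_intensity = 0.75,
                                min_cell_voxels = 50L,
                                max_cell_voxels = 20000L,
                                max_elongation = 12,
                                min_extent = 0.02) {
  stopifnot(min_object_voxels > 0, max_object_voxels > min_object_voxels,
            min_cell_voxels > 0, max_cell_voxels > min_cell_voxels,
            seed_smooth_sigma_px > 0, seed_min_distance_px >= 1,
            seed_rel_intensity >= 0, seed_rel_intensity <= 1,
            max_elongation > 1, min_extent > 0, min_extent < 1)
  structure(list(min_object_voxels = as.integer(min_object_voxels),
                 max_object_voxels = as.integer(max_object_voxels),
                 seed_smooth_sigma_px = seed_smooth_sigma_px,
                 seed_min_distance_px = seed_min_distance_px,
                 seed_rel_intensity = seed_rel_intensity,
                 min_cell_voxels = as.integer(min_cell_voxels),
                 max_cell_voxels = as.integer(max_cell_voxels),
                 max_elongation = max_elongation,
                 min_extent = min_extent),
            class = "segmentation_params")
}

#' Detect connected objects in a binary mask
#'
#' Connected-component labelling under 26-connectivity (voxels touching by
#' face, edge or corner belong together), which preserves the continuity of
#' thin diagonal processes. Labels are assigned in raster order of each
#' component's first voxel, so the labelling is deterministic.
#'
#' @param mask A [binary_mask()].
#' @return A [label_volume()].
#' @export
detect_objects <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$voxels)
  lab <- cc_label_26(as.vector(mask$voxels), as.integer(d))
  label_volume(array(lab, d), mask$spacing)
}

.relabel <- function(labels, keep_ids) {
  # keep_ids in ascending order preserves raster-first ordering
  map <- integer(max(labels, 1L))
  map[keep_ids] <- seq_along(keep_ids)
  out <- array(0L, dim(labels))
  pos <- labels > 0L
  kept <- map[labels[pos]]
  out[pos] <- kept
  out
}

#' Remove objects outside a size gate
#'
#' Objects whose voxel count is below `min_object_voxels` or above
#' `max_object_voxels` are discarded (debris and structures too small or big
#' to be an isolated cell or small cell cluster); survivors are relabelled
#' 1..N preserving order.
#'
#' @param labels A [label_volume()].
#' @param params A [segmentation_params()].
#' @return A filtered [label_volume()].
#' @export
filter_by_size <- function(labels, params = segmentation_params()) {
  stopifnot(inherits(labels, "label_volume"))
  if (labels$n_labels == 0L) return(labels)
  counts <- tabulate(labels$labels[labels$labels > 0L], nbins = labels$n_labels)
  keep <- which(counts >= params$min_object_voxels &
                  counts <= params$max_object_voxels)
  label_volume(.relabel(labels$labels, keep), labels$spacing)
}

# Separable Gaussian smoothing within each z-plane; edge handling by kernel
# renormalization (rows of the convolution matrix sum to 1).
.gauss_matrix <- function(n, sigma) {
  K <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(j - i, sd = sigma))
  K / rowSums(K)
}

.gauss_smooth_xy <- function(vox, sigma) {
  d <- dim(vox)
  Ky <- .gauss_matrix(d[2], sigma)
  Kx <- .gauss_matrix(d[3], sigma)
  out <- vox
  for (z in seq_len(d[1])) {
    out[z, , ] <- Ky %*% vox[z, , , drop = TRUE] %*% t(Kx)
  }
  out
}

#' Detect bright cell centers
#'
#' Somata appear as bright blobs within each object. The background-
#' subtracted intensity is Gaussian-smoothed within each z-plane only (the
#' axial step is much coarser than the lateral pixel size), local maxima
#' under 26-connectivity are collected inside labelled voxels, maxima dimmer
#' than `seed_rel_intensity` times their object's smoothed maximum are
#' dropped, and the survivors are greedily thinned so no two seeds lie
#' within `seed_min_distance_px` in xy (brighter seed wins; raster order
#' breaks exact ties). Every object keeps at least one seed: if thinning or
#' the brightness cut removed all of an object's maxima, its global smoothed
#' maximum is reinstated.
#'
#' @param stack Background-subtracted [image_stack()].
#' @param labels A [label_volume()] sharing the stack's geometry.
#' @param params A [segmentation_params()].
#' @return An object of class `seed_set`: a list with `points` (m x 3 matrix
#'   of (z, y, x) indices), `intensities` (smoothed values) and `object`
#'   (owning label per seed).
#' @export
detect_bright_centers <- function(stack, labels,
                                  params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"), inherits(labels, "label_volume"))
  if (!identical(dim(stack$voxels), dim(labels$labels))) {
    stop("stack and labels differ in shape", call. = FALSE)
  }
  d <- dim(stack$voxels)
  sm <- .gauss_smooth_xy(stack$voxels, params$seed_smooth_sigma_px)
  if (labels$n_labels == 0L) {
    return(structure(list(points = matrix(0L, 0L, 3L,
                                          dimnames = list(NULL, c("z", "y", "x"))),
                          intensities = numeric(0), object = integer(0),
                          smoothed = sm),
                     class = "seed_set"))
  }
  ismax <- array(local_max_26(as.vector(sm), as.integer(d)), d)
  inobj <- labels$labels > 0L
  pos <- which(inobj)
  mx <- vapply(split(sm[pos], labels$labels[pos]), max, numeric(1))
  obj_max <- numeric(labels$n_labels)
  obj_max[as.integer(names(mx))] <- mx
  cand <- which(ismax & inobj)
  if (length(cand)) {
    lab_c <- labels$labels[cand]
    bright <- sm[cand] >= params$seed_rel_intensity * obj_max[lab_c]
    cand <- cand[bright]
  }
  # greedy xy-distance thinning: brightest first, raster order on ties
  sel <- integer(0)
  if (length(cand)) {
    val <- sm[cand]
    ord <- order(-val, cand)
    cand <- cand[ord]
    ai <- arrayInd(cand, d)
    keep_y <- numeric(0); keep_x <- numeric(0)
    for (i in seq_along(cand)) {
      if (!length(keep_y) ||
          all((keep_y - ai[i, 2])^2 + (keep_x - ai[i, 3])^2 >=
                params$seed_min_distance_px^2)) {
        sel <- c(sel, cand[i])
        keep_y <- c(keep_y, ai[i, 2]); keep_x <- c(keep_x, ai[i, 3])
      }
    }
  }
  # fallback: every object retains its smoothed-intensity argmax
  have <- unique(labels$labels[sel])
  missing_obj <- setdiff(seq_len(labels$n_labels), have)
  for (l in missing_obj) {
    idx <- which(labels$labels == l)
    sel <- c(sel, idx[which.max(sm[idx])])
  }
  sel <- sel[order(sel)]
  pts <- arrayInd(sel, d)
  colnames(pts) <- c("z", "y", "x")
  structure(list(points = pts, intensities = sm[sel],
                 object = labels$labels[sel], smoothed = sm),
            class = "seed_set")
}

#' Split multi-seed objects into cells by seeded watershed
#'
#' Within each object, voxels are partitioned by a seeded watershed flooded
#' on the negated smoothed intensity (equivalently: the brightest fronts
#' advance first), constrained to the object's own voxels. Objects holding a
#' single seed pass through unchanged; the output holds exactly one label
#' per seed, renumbered 1..N in raster order of first voxels. Splitting is a
#' partition: the labelled voxel set is conserved.
#'
#' @param labels A [label_volume()].
#' @param seeds A seed set from [detect_bright_centers()].
#' @param stack Background-subtracted [image_stack()] (used for flooding
#'   priorities; smoothed with `params$seed_smooth_sigma_px`).
#' @param params A [segmentation_params()].
#' @return A [label_volume()] with one label per seed.
#' @export
split_cells <- function(labels, seeds, stack,
                        params = segmentation_params()) {
  stopifnot(inherits(labels, "label_volume"), inherits(seeds, "seed_set"),
            inherits(stack, "image_stack"))
  d <- dim(labels$labels)
  if (nrow(seeds$points) == 0L) return(labels)
  idx <- seeds$points[, 1] + d[1] * (seeds$points[, 2] - 1L) +
    d[1] * d[2] * (seeds$points[, 3] - 1L)
  if (any(labels$labels[idx] == 0L)) {
    stop("seed outside the labelled foreground", call. = FALSE)
  }
  sm <- seeds$smoothed
  if (is.null(sm)) sm <- .gauss_smooth_xy(stack$voxels,
                                          params$seed_smooth_sigma_px)
  out <- seeded_watershed(as.vector(sm), as.vector(labels$labels),
                          as.integer(idx), as.integer(d))
  out <- array(out, d)
  first <- vapply(split(seq_along(out)[out > 0L], out[out > 0L]), min,
                  numeric(1))
  ord_ids <- as.integer(names(sort(first)))
  label_volume(.relabel(out, ord_ids)[, , , drop = FALSE], labels$spacing)
}

.cell_shape_stats <- function(pts, spacing, dims) {
  phys <- cbind(pts[, 1] * spacing$dz, pts[, 2] * spacing$dy,
                pts[, 3] * spacing$dx)
  # each voxel is a box, not a point: add its uniform-density variance so a
  # single-plane cell has finite axial spread
  cv <- cov(phys) * (nrow(phys) - 1) / nrow(phys)
  if (nrow(phys) == 1L) cv <- matrix(0, 3, 3)
  cv <- cv + diag(c(spacing$dz^2, spacing$dy^2, spacing$dx^2)) / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  elong <- sqrt(max(ev) / min(ev))
  bbox <- apply(pts, 2L, function(v) diff(range(v)) + 1)
  extent <- nrow(pts) / prod(bbox)
  list(elongation = elong, extent = extent)
}

#' Discard non-cellular objects by shape and size
#'
#' Removes cells whose voxel count falls outside
#' `[min_cell_voxels, max_cell_voxels]`, whose principal-axis elongation
#' (ratio of longest to shortest axis length from the physical-coordinate
#' covariance) exceeds `max_elongation`, or whose extent (voxel count over
#' bounding-box volume) falls below `min_extent`. Survivors are relabelled
#' 1..N preserving order.
#'
#' @param labels A [label_volume()].
#' @param params A [segmentation_params()].
#' @return A filtered [label_volume()].
#' @export
filter_by_shape <- function(labels, params = segmentation_params()) {
  stopifnot(inherits(labels, "label_volume"))
  if (labels$n_labels == 0L) return(labels)
  d <- dim(labels$labels)
  pos <- which(labels$labels > 0L)
  byobj <- split(pos, labels$labels[pos])
  keep <- integer(0)
  for (l in seq_len(labels$n_labels)) {
    idx <- byobj[[as.character(l)]]
    n <- length(idx)
    if (n < params$min_cell_voxels || n > params$max_cell_voxels) next
    st <- .cell_shape_stats(arrayInd(idx, d), labels$spacing, d)
    if (st$elongation > params$max_elongation) next
    if (st$extent < params$min_extent) next
    keep <- c(keep, l)
  }
  label_volume(.relabel(labels$labels, keep), labels$spacing)
}

#' Flag cells touching the volume border
#'
#' Cells clipped by the field of view have truncated processes that inflate
#' solidity; this flags any cell with a voxel on the first or last plane of
#' any axis so downstream aggregation can exclude them.
#'
#' @param labels A [label_volume()].
#' @return A data.frame with columns `label` and `border_touching`.
#' @export
flag_border_cells <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  if (labels$n_labels == 0L) {
    return(data.frame(label = integer(0), border_touching = logical(0)))
  }
  d <- dim(labels$labels)
  pos <- which(labels$labels > 0L)
  ai <- arrayInd(pos, d)
  onb <- ai[, 1] == 1L | ai[, 1] == d[1] | ai[, 2] == 1L | ai[, 2] == d[2] |
    ai[, 3] == 1L | ai[, 3] == d[3]
  touch <- vapply(seq_len(labels$n_labels), function(l) {
    any(onb[labels$labels[pos] == l])
  }, logical(1))
  data.frame(label = seq_len(labels$n_labels), border_touching = touch)
}

#' Run the full processing and cell-isolation chain on one stack
#'
#' Convenience wrapper: background opening and subtraction, Otsu
#' binarization, majority denoising, object detection, size gating, bright-
#' center seeding, watershed splitting, and shape/size filtering.
#'
#' @param stack A raw [image_stack()].
#' @param pre A [preprocess_params()].
#' @param seg A [segmentation_params()].
#' @return A list with `labels` (final [label_volume()]), `threshold`,
#'   `subtracted` (background-subtracted stack), and `seeds`.
#' @export
segment_stack <- function(stack, pre = preprocess_params(),
                          seg = segmentation_params()) {
  bg <- estimate_background(stack, pre)
  sub <- subtract_background(stack, bg)
  ot <- otsu_threshold(sub, pre)
  mask <- median_denoise(ot$mask, pre)
  lab <- detect_objects(mask)
  lab <- filter_by_size(lab, seg)
  seeds <- detect_bright_centers(sub, lab, seg)
  lab <- split_cells(lab, seeds, sub, seg)
  lab <- filter_by_shape(lab, seg)
  list(labels = lab, threshold = ot$threshold, subtracted = sub,
       seeds = seeds)
}
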