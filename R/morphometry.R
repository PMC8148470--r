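#' Measure per-cell morphology
#'
#' One record per labelled cell, in label order: voxel count, physical
#' volume, convex-hull lattice count, tridimensional solidity
#' (voxel_count / convex_voxel_count), and a border-touching flag from
#' [flag_border_cells()].
#'
#' @param labels A [label_volume()].
#' @param spacing A [voxel_spacing()]; defaults to the volume's own.
#' @param lesion_id,eye_id Identifiers carried into the records.
#' @return A data.frame with columns cell_id, lesion_id, eye_id,
#'   voxel_count, volume_um3, convex_voxel_count, solidity, border_touching,
#'   plus centroid_z/centroid_y/centroid_x (voxel indices) for matching
#'   against ground truth.
#' @export
measure_cells <- function(labels, spacing = labels$spacing,
                          lesion_id = "lesion1", eye_id = "eye1") {
  stopifnot(inherits(labels, "label_volume"))
  spacing <- .check_spacing(spacing)
  if (labels$n_labels == 0L) {
    return(data.frame(cell_id = integer(0), lesion_id = character(0),
                      eye_id = character(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), convex_voxel_count = integer(0),
                      solidity = numeric(0), border_touching = logical(0),
                      centroid_z = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), stringsAsFactors = FALSE))
  }
  d <- dim(labels$labels)
  pos <- which(labels$labels > 0L)
  byobj <- split(pos, labels$labels[pos])
  border <- flag_border_cells(labels)
  vsize <- spacing$dx * spacing$dy * spacing$dz
  rows <- lapply(seq_len(labels$n_labels), function(l) {
    idx <- byobj[[as.character(l)]]
    pts <- arrayInd(idx, d)
    cvx <- convex_voxel_count(pts, spacing)
    data.frame(cell_id = l, lesion_id = lesion_id, eye_id = eye_id,
               voxel_count = length(idx),
               volume_um3 = length(idx) * vsize,
               convex_voxel_count = cvx,
               solidity = length(idx) / cvx,
               border_touching = border$border_touching[l],
               centroid_z = mean(pts[, 1]), centroid_y = mean(pts[, 2]),
               centroid_x = mean(pts[, 3]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean cell solidity per eye
#'
#' Aggregates per-cell solidities to one value per eye. The default pools
#' every cell of every lesion image of an eye before averaging; the
#' alternative first averages within each lesion and then averages the
#' lesion means. Border-touching cells are excluded by default because
#' truncated processes inflate solidity. Eyes left with zero eligible cells
#' are omitted from the output (reported missing, never NaN).
#'
#' @param cells Per-cell data.frame (rows from [measure_cells()], possibly
#'   many stacks; must carry `eye_id`, `solidity`, `border_touching` and,
#'   for lesion-level aggregation, `lesion_id`).
#' @param exclude_border Drop border-touching cells first (default TRUE).
#' @param aggregate `"pool"` (default) or `"lesion-mean"`.
#' @return A data.frame with columns eye_id, n_cells, mean_solidity.
#' @export
mean_solidity_per_eye <- function(cells, exclude_border = TRUE,
                                  aggregate = c("pool", "lesion-mean")) {
  aggregate <- match.arg(aggregate)
  cells <- as.data.frame(cells)
  if (!all(c("eye_id", "solidity") %in% names(cells))) {
    stop("`cells` must have eye_id and solidity columns", call. = FALSE)
  }
  if (exclude_border) {
    if (!"border_touching" %in% names(cells)) {
      stop("`cells` lacks border_touching; use exclude_border = FALSE",
           call. = FALSE)
    }
    cells <- cells[!cells$border_touching, , drop = FALSE]
  }
  if (nrow(cells) == 0L) {
    return(data.frame(eye_id = character(0), n_cells = integer(0),
                      mean_solidity = numeric(0), stringsAsFactors = FALSE))
  }
  if (aggregate == "pool") {
    agg <- aggregate(cells$solidity, by = list(eye_id = cells$eye_id), FUN = mean)
    n <- aggregate(cells$solidity, by = list(eye_id = cells$eye_id), FUN = length)
    out <- data.frame(eye_id = agg$eye_id, n_cells = n$x,
                      mean_solidity = agg$x, stringsAsFactors = FALSE)
  } else {
    les <- aggregate(cells$solidity,
                     by = list(eye_id = cells$eye_id,
                               lesion_id = cells$lesion_id), FUN = mean)
    agg <- aggregate(les$x, by = list(eye_id = les$eye_id), FUN = mean)
    n <- aggregate(cells$solidity, by = list(eye_id = cells$eye_id), FUN = length)
    out <- data.frame(eye_id = agg$eye_id,
                      n_cells = n$x[match(agg$eye_id, n$eye_id)],
                      mean_solidity = agg$x, stringsAsFactors = FALSE)
  }
  out[order(out$eye_id), , drop = FALSE]
}
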