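#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages become z-slices in acquisition order. Integer samples are returned
#' at their native scale (no rescaling to \[0, 1\]). Physical spacing is
#' supplied by the caller; TIFF metadata dialects are deliberately ignored.
#' RGB/multichannel files and files whose pages differ in size are rejected.
#'
#' @param path Path to an 8- or 16-bit grayscale TIFF.
#' @param spacing A [voxel_spacing()].
#' @param name Stack identifier; defaults to the file name.
#' @return An [image_stack()] of shape (n_pages, height, width).
#' @export
read_stack <- function(path, spacing, name = basename(path)) {
  if (!file.exists(path)) {
    stop(sprintf("input error: cannot read TIFF '%s': file not found", path),
         call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      stop(sprintf("input error: cannot read TIFF '%s': %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2L) {
      stop(sprintf(
        "input error: '%s' is not single-channel grayscale (multichannel input rejected)",
        path), call. = FALSE)
    }
  }
  shapes <- vapply(pages, dim, integer(2))
  if (length(pages) > 1L && any(shapes != shapes[, 1L])) {
    stop(sprintf("input error: pages of '%s' differ in size", path),
         call. = FALSE)
  }
  nz <- length(pages)
  vox <- array(0, c(nz, shapes[1, 1], shapes[2, 1]))
  for (z in seq_len(nz)) vox[z, , ] <- pages[[z]]
  image_stack(vox, spacing, name = name)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Voxel values are rounded to the nearest integer and written at 8 or 16
#' bits per sample (auto-selected from the value range unless given), so that
#' `read_stack(write_stack(x))` is the identity on integer-valued stacks.
#'
#' @param stack An [image_stack()] with values in \[0, 65535\].
#' @param path Output path; the parent directory must exist.
#' @param bits 8 or 16; `NULL` picks 8 when all values fit, else 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("input error: directory '%s' does not exist", dirname(path)),
         call. = FALSE)
  }
  v <- round(stack$voxels)
  if (max(v) > 65535) stop("stack values exceed 16-bit range", call. = FALSE)
  if (is.null(bits)) bits <- if (max(v) <= 255) 8L else 16L
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  top <- 2^bits - 1
  if (max(v) > top) stop("stack values exceed the requested bit depth",
                         call. = FALSE)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , , drop = TRUE] / top)
  pages <- lapply(pages, function(p) {
    if (is.null(dim(p))) dim(p) <- dim(v)[2:3]
    p
  })
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
    TRUE
  }, error = function(e) {
    stop(sprintf("input error: cannot write TIFF '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}

.cell_table_columns <- c("cell_id", "lesion_id", "eye_id", "voxel_count",
                         "volume_um3", "convex_voxel_count", "solidity",
                         "border_touching")

#' Write a per-cell morphology table as CSV
#'
#' Columns are written in a stable order (cell_id, lesion_id, eye_id,
#' voxel_count, volume_um3, convex_voxel_count, solidity, border_touching)
#' with a header row, comma separators and '.' decimals. Numeric fields keep
#' full precision (>= 6 significant digits).
#'
#' @param cells A data.frame as returned by [measure_cells()] (possibly
#'   row-bound across stacks); an empty data.frame yields a header-only file.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  if (is.null(cells) || nrow(as.data.frame(cells)) == 0L) {
    cells <- as.data.frame(setNames(
      lapply(.cell_table_columns, function(x) logical(0)),
      .cell_table_columns))
  }
  cells <- as.data.frame(cells)
  missing_cols <- setdiff(.cell_table_columns, names(cells))
  if (length(missing_cols)) {
    stop(sprintf("cell table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- cells[, .cell_table_columns, drop = FALSE]
  tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) {
             stop(sprintf("input error: cannot write '%s': %s", path,
                          conditionMessage(e)), call. = FALSE)
           })
  invisible(path)
}
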