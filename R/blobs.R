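# Blob detection: threshold a grayscale frame, label connected components,
# and carry a centred square crop per component. Coordinates are pixels,
# origin top-left, x right / y down, frames 0-based.

new_blob <- function(frame, centroid, pixel_count, bbox, crop, kind,
                     pixels = NULL, gt_id = NA_integer_) {
  structure(list(frame = as.integer(frame),
                 centroid = as.numeric(centroid),
                 pixel_count = as.numeric(pixel_count),
                 bbox = as.numeric(bbox),
                 crop = crop,
                 kind = kind,
                 pixels = pixels,
                 gt_id = gt_id),
            class = "pairtrack_blob")
}

#' Segment one frame into blobs
#'
#' Thresholds a grayscale frame, removes everything outside the region of
#' interest (pixels outside `roi_mask` are treated as background, which is how
#' occlusion masks are applied: no information is extracted from masked
#' pixels), labels 8-connected foreground components, discards components
#' below the minimum area, and extracts a centred square crop per component.
#'
#' @param frame Grayscale matrix, values in `[0,1]`, indexed `[y + 1, x + 1]`.
#' @param intensity_threshold Foreground threshold in `[0,1]`.
#' @param roi_mask Optional logical/0-1 matrix of the same shape; `FALSE`/0
#'   pixels are forced to background.
#' @param min_blob_area Discard components with fewer pixels than this.
#' @param crop_size Side of the square crop extracted around each centroid.
#' @param frame_index 0-based index stored in each blob.
#' @return A list of blobs (possibly empty). Each blob carries `centroid`
#'   (x, y), `pixel_count`, a half-open bounding box `(x0, y0, x1, y1)`, the
#'   crop, and its foreground pixel indices (for overlap-based linking).
#' @export
segment_frame <- function(frame, intensity_threshold, roi_mask = NULL,
                          min_blob_area = 10L, crop_size = 24L,
                          frame_index = 0L) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop_invalid_input("frame must be a non-empty matrix")
  if (intensity_threshold < 0 || intensity_threshold > 1)
    stop_invalid_input("intensity_threshold must lie in [0,1]")
  fg <- frame > intensity_threshold
  if (!is.null(roi_mask)) {
    if (!all(dim(roi_mask) == dim(frame)))
      stop_invalid_input("roi_mask shape must match the frame")
    fg <- fg & (roi_mask > 0)
  }
  if (!any(fg)) return(list())
  lab <- EBImage::bwlabel(fg)
  lab <- as.matrix(EBImage::imageData(lab))
  ncomp <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- which(sizes >= min_blob_area)
  out <- vector("list", length(keep))
  nr <- nrow(frame)
  for (k in seq_along(keep)) {
    comp <- keep[k]
    idx <- which(lab == comp)
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    cx <- mean(col) - 1; cy <- mean(row) - 1
    bbox <- c(min(col) - 1L, min(row) - 1L, max(col), max(row))
    crop <- extract_crop(frame, c(cx, cy), crop_size)
    out[[k]] <- new_blob(frame = frame_index, centroid = c(cx, cy),
                         pixel_count = sizes[comp], bbox = bbox,
                         crop = crop, kind = "individual", pixels = idx)
  }
  out
}

# Centred square crop, zero-padded at the frame borders.
extract_crop <- function(frame, centroid, L) {
  L <- as.integer(L)
  ox <- round(centroid[1]) - (L - 1L) %/% 2L
  oy <- round(centroid[2]) - (L - 1L) %/% 2L
  crop <- matrix(0, L, L)
  xs <- (ox + 1L):(ox + L)   # frame columns (1-based)
  ys <- (oy + 1L):(oy + L)
  vx <- xs >= 1L & xs <= ncol(frame)
  vy <- ys >= 1L & ys <= nrow(frame)
  crop[which(vy), which(vx)] <- frame[ys[vy], xs[vx], drop = FALSE]
  crop
}

#' Classify a blob as an individual or a crossing
#'
#' A blob is a crossing when its area exceeds `crossing_area_factor` times the
#' median single-animal area, or when its pixel extent overlaps two or more
#' distinct fragments alive in the previous frame (two animals merging without
#' a large area increase).
#'
#' @param blob A blob from [segment_frame()].
#' @param median_individual_area Median area of a single animal, pixels.
#' @param crossing_area_factor Area multiple above which a blob is a crossing.
#' @param n_overlapping_fragments Number of distinct previous-frame fragments
#'   whose blobs overlap this blob (0 when unknown).
#' @return `"crossing"` or `"individual"`.
#' @export
classify_blob <- function(blob, median_individual_area,
                          crossing_area_factor = 1.5,
                          n_overlapping_fragments = 0L) {
  if (median_individual_area <= 0)
    stop_invalid_input("median_individual_area must be positive")
  if (blob$pixel_count > crossing_area_factor * median_individual_area ||
      n_overlapping_fragments >= 2L) "crossing" else "individual"
}

#' @export
print.pairtrack_blob <- function(x, ...) {
  cat(sprintf("<blob frame %d, %s, centroid (%.1f, %.1f), %d px>\n",
              x$frame, x$kind, x$centroid[1], x$centroid[2],
              as.integer(x$pixel_count)))
  invisible(x)
}
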