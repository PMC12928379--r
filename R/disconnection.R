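# densify a polyline so consecutive samples are no more than `step` mm
# apart; returns the original vertices plus interpolated points, in order
densify_polyline <- function(points, step) {
  n <- nrow(points)
  if (n < 2L) return(points)
  segs <- points[-1L, , drop = FALSE] - points[-n, , drop = FALSE]
  len <- sqrt(rowSums(segs^2))
  ndiv <- pmax(1L, ceiling(len / step))
  seg_id <- rep.int(seq_len(n - 1L), ndiv)
  tt <- unlist(lapply(ndiv, function(k) seq_len(k) / k), use.names = FALSE)
  pts <- points[seg_id, , drop = FALSE] + segs[seg_id, , drop = FALSE] * tt
  rbind(points[1L, , drop = FALSE], pts)
}

#' Does a streamline pass through a lesion mask?
#'
#' True iff any sampled point of the streamline falls inside a lesioned
#' voxel. Each point is mapped from world mm to the voxel lattice through the
#' inverse affine and assigned to the nearest voxel index; before lookup the
#' polyline is subdivided so consecutive samples are at most half the minimum
#' voxel edge apart, so a segment spanning a thin lesion slab between two
#' distant vertices cannot step over it.
#'
#' @param streamline numeric n x 3 matrix of world-coordinate points (mm).
#' @param mask a [lesion_mask].
#' @return Logical scalar.
#' @export
streamline_hits_mask <- function(streamline, mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  step <- min(mask$grid$voxel_size) / 2
  pts <- densify_polyline(as.matrix(streamline), step)
  vox <- round(world_to_voxel(mask$grid, pts))
  s <- mask$grid$shape
  inb <- vox[, 1] >= 0 & vox[, 1] < s[1] &
         vox[, 2] >= 0 & vox[, 2] < s[2] &
         vox[, 3] >= 0 & vox[, 3] < s[3]
  if (!any(inb)) return(FALSE)
  any(mask$data[vox[inb, , drop = FALSE] + 1] == 1L)
}

#' Disconnection of one tract bundle by a lesion
#'
#' The disconnection index of a bundle is the percentage of its streamlines
#' that pass through the lesion (any-contact rule):
#' `100 * disconnected / total`.
#'
#' @param bundle a [tract_bundle].
#' @param mask a [lesion_mask].
#' @return One-row data frame with columns `tract_name`,
#'   `total_streamlines`, `disconnected_streamlines` and
#'   `disconnection_index`.
#' @export
tract_disconnection <- function(bundle, mask) {
  stopifnot(inherits(bundle, "tract_bundle"))
  total <- length(bundle$streamlines)
  if (total == 0L)
    stop("empty bundle: no streamlines to intersect", call. = FALSE)
  hits <- sum(vapply(bundle$streamlines, streamline_hits_mask,
                     logical(1), mask = mask))
  data.frame(tract_name = bundle$name,
             total_streamlines = total,
             disconnected_streamlines = as.integer(hits),
             disconnection_index = 100 * hits / total,
             stringsAsFactors = FALSE)
}

#' Per-tract disconnection table for a whole atlas
#'
#' Applies [tract_disconnection] to every bundle and returns one row per
#' bundle, sorted by descending disconnection index with ties broken by
#' bundle name.
#'
#' @param atlas non-empty list of [tract_bundle] objects.
#' @param mask a [lesion_mask].
#' @return A data frame of class `disconnection_table`.
#' @export
disconnection_report <- function(atlas, mask) {
  if (length(atlas) == 0L)
    stop("empty atlas: no tract bundles supplied", call. = FALSE)
  tab <- do.call(rbind, lapply(atlas, tract_disconnection, mask = mask))
  tab <- tab[order(-tab$disconnection_index, tab$tract_name), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("disconnection_table", "data.frame")
  tab
}

#' Write a disconnection table to CSV
#'
#' As for overlap tables, the index is written twice: rounded to one decimal
#' for display and at full precision for exact round-trips.
#'
#' @param table a `disconnection_table` from [disconnection_report].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_disconnection_table <- function(table, path) {
  stopifnot(inherits(table, "disconnection_table"))
  out <- data.frame(tract_name = table$tract_name,
                    total_streamlines = table$total_streamlines,
                    disconnected_streamlines = table$disconnected_streamlines,
                    disconnection_index =
                      sprintf("%.1f", table$disconnection_index),
                    disconnection_index_exact =
                      sprintf("%.17g", table$disconnection_index),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
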