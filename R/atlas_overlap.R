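#' Percent overlap of a binary map with every atlas parcel
#'
#' For each parcel of a labeled atlas, the percentage of that parcel's voxels
#' covered by the binary map: `100 * overlapped_voxels / parcel_voxels`
#' (parcel-normalized, so a small region fully inside a large lesion scores
#' near 100%). If the map is not on the parcellation's grid it is first
#' resampled there by nearest neighbour. One row is produced for every label
#' named in the lookup, including 0% rows; labels with no voxels in the
#' volume get 0 voxels and 0%.
#'
#' @param map a [lesion_mask] (e.g. the common lesion or a binarized
#'   subtraction map).
#' @param parc a [parcellation].
#' @return A data frame of class `parcel_overlap_table` with columns
#'   `label`, `region_name`, `parcel_voxels`, `overlapped_voxels` and
#'   `percent_overlap`, sorted by descending percent (ties by ascending
#'   label).
#' @export
parcel_overlap <- function(map, parc) {
  stopifnot(inherits(map, "lesion_mask"), inherits(parc, "parcellation"))
  if (length(parc$lookup) == 0L)
    stop("empty atlas: parcellation lookup names no parcels", call. = FALSE)
  if (!grids_compatible(map$grid, parc$grid))
    map <- resample_nearest(map, parc$grid)
  labels <- sort(as.integer(names(parc$lookup)))
  labels <- labels[labels != 0L]
  if (length(labels) == 0L)
    stop("empty atlas: no nonzero labels in lookup", call. = FALSE)
  fac <- factor(as.vector(parc$labels), levels = labels)
  parcel_voxels <- as.integer(table(fac))
  overlapped <- as.integer(
    tapply(as.vector(map$data), fac, sum, default = 0L))
  pct <- ifelse(parcel_voxels > 0L, 100 * overlapped / parcel_voxels, 0)
  tab <- data.frame(label = labels,
                    region_name = unname(parc$lookup[as.character(labels)]),
                    parcel_voxels = parcel_voxels,
                    overlapped_voxels = overlapped,
                    percent_overlap = pct,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$percent_overlap, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("parcel_overlap_table", "data.frame")
  tab
}

#' Write a parcel-overlap table to CSV
#'
#' Writes one row per parcel with the percentage twice: a display column
#' rounded to one decimal place and a machine column at full precision, so
#' the file both reads well and round-trips exactly.
#'
#' @param table a `parcel_overlap_table` from [parcel_overlap].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_overlap_table <- function(table, path) {
  stopifnot(inherits(table, "parcel_overlap_table"))
  out <- data.frame(label = table$label,
                    region_name = table$region_name,
                    parcel_voxels = table$parcel_voxels,
                    overlapped_voxels = table$overlapped_voxels,
                    percent_overlap = sprintf("%.1f", table$percent_overlap),
                    percent_overlap_exact =
                      sprintf("%.17g", table$percent_overlap),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a parcel-overlap CSV written by [write_overlap_table]
#'
#' @param path CSV path.
#' @return A `parcel_overlap_table` with machine-precision percentages.
#' @export
read_overlap_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- data.frame(label = as.integer(raw$label),
                    region_name = as.character(raw$region_name),
                    parcel_voxels = as.integer(raw$parcel_voxels),
                    overlapped_voxels = as.integer(raw$overlapped_voxels),
                    percent_overlap = as.numeric(raw$percent_overlap_exact),
                    stringsAsFactors = FALSE)
  class(tab) <- c("parcel_overlap_table", "data.frame")
  tab
}
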