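#' Cohort lesion count overlay
#'
#' Overlaps the individual lesions of a cohort: each voxel's value is the
#' number of subjects whose lesion includes that voxel.
#'
#' @param masks non-empty list of [lesion_mask] objects on one grid.
#' @return An object of class `count_overlay` with fields `grid`, `counts`
#'   (integer 3-D array, 0..n) and `n_subjects`.
#' @examples
#' g <- voxel_grid(c(4, 4, 4), diag(4))
#' m <- lesion_mask(array(1, c(4, 4, 4)), g)
#' count_overlay(list(m, m))$counts[1, 1, 1]
#' @export
count_overlay <- function(masks) {
  grid <- check_cohort_grids(masks)
  counts <- Reduce(`+`, lapply(masks, function(m) m$data))
  structure(list(grid = grid,
                 counts = array(as.integer(counts), dim = grid$shape),
                 n_subjects = length(masks)),
            class = "count_overlay")
}

#' @export
print.count_overlay <- function(x, ...) {
  cat(sprintf("<count_overlay> n = %d subjects, max overlap %d\n",
              x$n_subjects, max(x$counts)))
  invisible(x)
}

#' Cohort lesion proportion map
#'
#' The count overlay divided by the cohort size: each voxel holds the
#' fraction of subjects lesioned there, in [0, 1]. Proportions are computed
#' in exact-count space (integer tally, one division), so every value is an
#' exact integer multiple of 1/n.
#'
#' @param masks non-empty list of [lesion_mask] objects on one grid.
#' @param cohort_name label carried through to downstream maps and reports.
#' @return An object of class `proportion_map` with fields `grid`, `values`,
#'   `n_subjects` and `cohort_name`.
#' @export
proportion_map <- function(masks, cohort_name = "cohort") {
  co <- count_overlay(masks)
  structure(list(grid = co$grid,
                 values = co$counts / co$n_subjects,
                 n_subjects = co$n_subjects,
                 cohort_name = as.character(cohort_name)[1L]),
            class = "proportion_map")
}

#' @export
print.proportion_map <- function(x, ...) {
  cat(sprintf("<proportion_map> '%s': n = %d, max proportion %.4g\n",
              x$cohort_name, x$n_subjects, max(x$values)))
  invisible(x)
}

#' Threshold a proportion map into a binary common-lesion map
#'
#' Keeps the voxels lesioned in at least a fraction `tau` of the cohort
#' (inclusive: a voxel at exactly `tau` survives). With `tau = 0.80` on the
#' patient cohort this yields the common lesion — the core territory damaged
#' in at least 80% of subjects. The comparison is applied to the exact
#' rational proportions, not rounded percentages.
#'
#' @param pm a [proportion_map].
#' @param tau threshold fraction in [0, 1].
#' @return A [lesion_mask] whose `subject_id` records the cohort and
#'   threshold.
#' @export
threshold_map <- function(pm, tau) {
  stopifnot(inherits(pm, "proportion_map"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1)
    stop("'tau' must be a single value in [0, 1]", call. = FALSE)
  lesion_mask(pm$values >= tau, pm$grid,
              sprintf("%s_ge_%g", pm$cohort_name, tau))
}

#' Write a count overlay to NIfTI
#' @param overlay a [count_overlay].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_count_overlay <- function(overlay, path) {
  stopifnot(inherits(overlay, "count_overlay"))
  write_nifti_volume(overlay$counts, overlay$grid, path, datatype = "int32")
}

#' Write a proportion map to NIfTI
#' @param pm a [proportion_map].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_proportion_map <- function(pm, path) {
  stopifnot(inherits(pm, "proportion_map"))
  write_nifti_volume(pm$values, pm$grid, path, datatype = "double")
}

#' Load a proportion map from NIfTI
#' @param path float NIfTI volume of per-voxel fractions.
#' @param n_subjects cohort size the proportions were computed from.
#' @param cohort_name cohort label.
#' @return A [proportion_map].
#' @export
load_proportion_map <- function(path, n_subjects, cohort_name = "cohort") {
  v <- read_nifti_volume(path)
  if (min(v$data) < 0 || max(v$data) > 1)
    stop("proportion volume has values outside [0, 1]", call. = FALSE)
  structure(list(grid = v$grid, values = v$data,
                 n_subjects = as.integer(n_subjects),
                 cohort_name = as.character(cohort_name)[1L]),
            class = "proportion_map")
}
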