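#' Subtract two cohort proportion maps
#'
#' Voxelwise difference of two proportion maps (cohort A minus cohort B),
#' yielding values in [-1, 1]. Positive values mark voxels more commonly
#' lesioned in cohort A: e.g. a voxel lesioned in 70% of the patient cohort
#' but only 10% of the recovered cohort gets 0.7 - 0.1 = 0.6.
#'
#' @param pm_a,pm_b [proportion_map] objects on compatible grids.
#' @return An object of class `subtraction_map` with fields `grid`, `values`
#'   and the two cohort names.
#' @export
subtract_maps <- function(pm_a, pm_b) {
  stopifnot(inherits(pm_a, "proportion_map"), inherits(pm_b, "proportion_map"))
  if (!grids_compatible(pm_a$grid, pm_b$grid))
    stop("grid mismatch: the two proportion maps are not on the same grid",
         call. = FALSE)
  structure(list(grid = pm_a$grid,
                 values = pm_a$values - pm_b$values,
                 cohort_a = pm_a$cohort_name,
                 cohort_b = pm_b$cohort_name),
            class = "subtraction_map")
}

#' @export
print.subtraction_map <- function(x, ...) {
  cat(sprintf("<subtraction_map> %s - %s: range [%.4g, %.4g]\n",
              x$cohort_a, x$cohort_b, min(x$values), max(x$values)))
  invisible(x)
}

#' Max-difference threshold for a subtraction map
#'
#' The difference between the two cohorts' global maximum overlap values,
#' `max(pm_a) - max(pm_b)`. Thresholding the subtraction map at this value
#' compensates for disparities in overall lesion overlap between the cohorts
#' (on the motivating data, maxima of 0.97 and 0.42 give 0.55). The rule can
#' yield a negative value when cohort B overlaps more; that is allowed but
#' flagged with a warning.
#'
#' @param pm_a,pm_b [proportion_map] objects.
#' @return The threshold fraction.
#' @export
max_diff_threshold <- function(pm_a, pm_b) {
  stopifnot(inherits(pm_a, "proportion_map"), inherits(pm_b, "proportion_map"))
  tau <- max(pm_a$values) - max(pm_b$values)
  if (tau < 0)
    warning(sprintf(
      "max-difference threshold is negative (%.4g): cohort '%s' has the higher maximum overlap",
      tau, pm_b$cohort_name), call. = FALSE)
  tau
}

#' Binarize a subtraction map at a threshold
#'
#' Keeps the voxels whose difference value is at or above `tau` (inclusive),
#' producing the binary map of voxels preferentially lesioned in cohort A.
#'
#' @param sm a [subtraction_map].
#' @param tau threshold in [-1, 1], typically from [max_diff_threshold].
#' @return A [lesion_mask].
#' @export
binarize_map <- function(sm, tau) {
  stopifnot(inherits(sm, "subtraction_map"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < -1 || tau > 1)
    stop("'tau' must be a single value in [-1, 1]", call. = FALSE)
  lesion_mask(sm$values >= tau, sm$grid,
              sprintf("%s_minus_%s_ge_%g", sm$cohort_a, sm$cohort_b, tau))
}

#' Write a subtraction map to NIfTI
#' @param sm a [subtraction_map].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_subtraction_map <- function(sm, path) {
  stopifnot(inherits(sm, "subtraction_map"))
  write_nifti_volume(sm$values, sm$grid, path, datatype = "double")
}
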