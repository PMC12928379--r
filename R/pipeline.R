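#' Build a validated pipeline run configuration
#'
#' @param cohort_a_dir directory of cohort A lesion masks (required).
#' @param cohort_b_dir directory of cohort B masks, or `NULL` to skip the
#'   subtraction branch.
#' @param atlas_path,atlas_lut parcellation NIfTI and lookup TSV, or `NULL`
#'   to skip parcel overlap.
#' @param tracts_dir directory of tract bundles (.json / .tck), or `NULL`
#'   to skip disconnection.
#' @param out_dir output directory for all products.
#' @param common_lesion_tau proportion threshold for the common lesion
#'   (default 0.80).
#' @param subtraction_tau `"auto"` for the max-difference rule, or an
#'   explicit fraction in [-1, 1].
#' @param cohort_a_name,cohort_b_name cohort labels used in reports.
#' @param binarize_threshold passed to [load_mask] for every input mask.
#' @param log_level `"info"` for progress messages, `"quiet"` for none.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort_a_dir, cohort_b_dir = NULL,
                       atlas_path = NULL, atlas_lut = NULL,
                       tracts_dir = NULL, out_dir = "lesionmap_out",
                       common_lesion_tau = 0.80, subtraction_tau = "auto",
                       cohort_a_name = "cohort_a",
                       cohort_b_name = "cohort_b",
                       binarize_threshold = 0, log_level = "info") {
  if (!is.numeric(common_lesion_tau) || common_lesion_tau < 0 ||
      common_lesion_tau > 1)
    stop("'common_lesion_tau' must be in [0, 1]", call. = FALSE)
  if (!identical(subtraction_tau, "auto")) {
    if (!is.numeric(subtraction_tau) || subtraction_tau < -1 ||
        subtraction_tau > 1)
      stop("'subtraction_tau' must be \"auto\" or a value in [-1, 1]",
           call. = FALSE)
  }
  if (!is.null(atlas_path) && is.null(atlas_lut))
    stop("'atlas_lut' is required when 'atlas_path' is given", call. = FALSE)
  structure(list(cohort_a_dir = cohort_a_dir, cohort_b_dir = cohort_b_dir,
                 atlas_path = atlas_path, atlas_lut = atlas_lut,
                 tracts_dir = tracts_dir, out_dir = out_dir,
                 common_lesion_tau = common_lesion_tau,
                 subtraction_tau = subtraction_tau,
                 cohort_a_name = cohort_a_name,
                 cohort_b_name = cohort_b_name,
                 binarize_threshold = binarize_threshold,
                 log_level = match.arg(log_level, c("info", "quiet"))),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Keys are the arguments of [run_config]; unknown keys are rejected.
#'
#' @param path `.yaml` / `.yml` / `.json` config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(formals(run_config)))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(run_config, cfg)
}

#' Run the full lesion-mapping pipeline
#'
#' Executes, from files on disk to files on disk: cohort overlays (counts
#' and proportions) for each cohort; the common lesion (cohort A
#' thresholded at `common_lesion_tau`); if cohort B is present, the
#' subtraction map, its threshold (max-difference rule or explicit) and the
#' binarized subtraction map; parcel-overlap tables and tract-disconnection
#' tables for both binary maps; and a JSON run report with all parameters,
#' thresholds, map maxima and MD5 checksums of every product. A stage
#' failure aborts with a stage-named error; products written so far are
#' kept and the report carries a `FAILED` marker naming the stage.
#'
#' @param cfg a [run_config] or path to a YAML/JSON config file.
#' @return The run report, invisibly (also written to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  log_msg <- function(...) {
    if (cfg$log_level == "info") message(sprintf(...))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  products <- character(0)
  report <- list(parameters = cfg[setdiff(names(cfg), "log_level")],
                 status = "RUNNING")
  emit <- function() {
    report$products <- products
    report$checksums <- as.list(tools::md5sum(
      file.path(cfg$out_dir, products)))
    names(report$checksums) <- products
    jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  }
  add_product <- function(rel) products <<- c(products, rel)
  stage <- "setup"
  result <- tryCatch({
    stage <- "load_cohorts"
    log_msg("loading cohort A from %s", cfg$cohort_a_dir)
    masks_a <- load_cohort(cfg$cohort_a_dir, cfg$binarize_threshold)
    masks_b <- NULL
    if (!is.null(cfg$cohort_b_dir)) {
      log_msg("loading cohort B from %s", cfg$cohort_b_dir)
      masks_b <- load_cohort(cfg$cohort_b_dir, cfg$binarize_threshold)
    }

    stage <- "overlays"
    pm_a <- proportion_map(masks_a, cfg$cohort_a_name)
    write_count_overlay(count_overlay(masks_a),
                        file.path(cfg$out_dir, "counts_a.nii.gz"))
    add_product("counts_a.nii.gz")
    write_proportion_map(pm_a,
                         file.path(cfg$out_dir, "proportions_a.nii.gz"))
    add_product("proportions_a.nii.gz")
    report$n_subjects_a <- pm_a$n_subjects
    report$max_proportion_a <- max(pm_a$values)
    pm_b <- NULL
    if (!is.null(masks_b)) {
      pm_b <- proportion_map(masks_b, cfg$cohort_b_name)
      write_count_overlay(count_overlay(masks_b),
                          file.path(cfg$out_dir, "counts_b.nii.gz"))
      add_product("counts_b.nii.gz")
      write_proportion_map(pm_b,
                           file.path(cfg$out_dir, "proportions_b.nii.gz"))
      add_product("proportions_b.nii.gz")
      report$n_subjects_b <- pm_b$n_subjects
      report$max_proportion_b <- max(pm_b$values)
    }

    stage <- "common_lesion"
    log_msg("thresholding cohort A at %.2f", cfg$common_lesion_tau)
    common <- threshold_map(pm_a, cfg$common_lesion_tau)
    write_mask(common, file.path(cfg$out_dir, "common_lesion.nii.gz"))
    add_product("common_lesion.nii.gz")
    report$common_lesion_voxels <- sum(common$data)

    binarized <- NULL
    if (!is.null(pm_b)) {
      stage <- "subtraction"
      sm <- subtract_maps(pm_a, pm_b)
      tau <- if (identical(cfg$subtraction_tau, "auto"))
        max_diff_threshold(pm_a, pm_b) else cfg$subtraction_tau
      log_msg("subtraction threshold: %.4f", tau)
      report$subtraction_tau <- tau
      report$subtraction_range <- c(min(sm$values), max(sm$values))
      write_subtraction_map(sm,
                            file.path(cfg$out_dir, "subtraction.nii.gz"))
      add_product("subtraction.nii.gz")
      binarized <- binarize_map(sm, tau)
      write_mask(binarized,
                 file.path(cfg$out_dir, "binarized_subtraction.nii.gz"))
      add_product("binarized_subtraction.nii.gz")
      report$binarized_subtraction_voxels <- sum(binarized$data)
    }

    maps <- list(common_lesion = common)
    if (!is.null(binarized)) maps$binarized_subtraction <- binarized

    if (!is.null(cfg$atlas_path)) {
      stage <- "parcel_overlap"
      log_msg("computing parcel overlap against %s", cfg$atlas_path)
      parc <- load_parcellation(cfg$atlas_path, cfg$atlas_lut)
      for (nm in names(maps)) {
        rel <- sprintf("overlap_%s.csv", nm)
        write_overlap_table(parcel_overlap(maps[[nm]], parc),
                            file.path(cfg$out_dir, rel))
        add_product(rel)
      }
    }

    if (!is.null(cfg$tracts_dir)) {
      stage <- "disconnection"
      log_msg("computing tract disconnection against %s", cfg$tracts_dir)
      atlas <- read_tract_atlas(cfg$tracts_dir)
      for (nm in names(maps)) {
        rel <- sprintf("disconnection_%s.csv", nm)
        write_disconnection_table(disconnection_report(atlas, maps[[nm]]),
                                  file.path(cfg$out_dir, rel))
        add_product(rel)
      }
    }

    report$status <- "OK"
    emit()
  }, error = function(e) {
    report$status <<- "FAILED"
    report$failed_stage <<- stage
    report$error <<- conditionMessage(e)
    emit()
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  log_msg("pipeline complete: %d products in %s", length(result$products),
          cfg$out_dir)
  invisible(result)
}
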