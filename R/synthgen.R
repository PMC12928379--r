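#' Default synthetic grid
#'
#' A 64 x 64 x 64 lattice at 2 mm isotropic resolution, centred on the world
#' origin: small enough that a full cohort generates in well under a second,
#' large enough for nontrivial parcellations and tract corridors.
#'
#' @return A [voxel_grid].
#' @export
default_synth_grid <- function() {
  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- -63          # voxel centres span -63 .. +63 mm
  voxel_grid(c(64L, 64L, 64L), aff)
}

#' Specification of a synthetic lesion cohort
#'
#' Each subject's lesion is a sphere with jittered centre and random radius,
#' optionally unioned with a fixed spherical "core" territory with
#' probability `core_hit_rate`. Cohorts differing in radius, jitter and core
#' hit rate emulate the contrast between a large, spatially concentrated
#' patient cohort and a smaller, scattered recovered cohort.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param core_center world mm centre of the core territory.
#' @param core_radius core radius in mm (> 0).
#' @param core_hit_rate probability in [0, 1] that a subject's lesion
#'   includes the whole core.
#' @param lesion_radius_mean,lesion_radius_sd mean and sd (mm) of the
#'   per-subject sphere radius (truncated below at 1 mm).
#' @param jitter_sd sd (mm) of the isotropic Gaussian scatter of sphere
#'   centres around the core centre.
#' @param seed integer RNG seed; identical spec + seed reproduce the cohort
#'   bit-exactly.
#' @param name cohort label.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, core_center = c(-30, 10, 8),
                        core_radius = 12, core_hit_rate = 1,
                        lesion_radius_mean = 30, lesion_radius_sd = 6,
                        jitter_sd = 8, seed = 1L, name = "cohort") {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L)
    stop("'n_subjects' must be >= 1", call. = FALSE)
  if (core_hit_rate < 0 || core_hit_rate > 1)
    stop("'core_hit_rate' must be in [0, 1]", call. = FALSE)
  if (core_radius <= 0 || lesion_radius_mean <= 0 || lesion_radius_sd < 0)
    stop("radii must be positive", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 core_center = as.numeric(core_center),
                 core_radius = as.numeric(core_radius),
                 core_hit_rate = as.numeric(core_hit_rate),
                 lesion_radius_mean = as.numeric(lesion_radius_mean),
                 lesion_radius_sd = as.numeric(lesion_radius_sd),
                 jitter_sd = as.numeric(jitter_sd),
                 seed = as.integer(seed),
                 name = as.character(name)[1L]),
            class = "cohort_spec")
}

#' Cohort spec emulating the large concentrated patient cohort
#'
#' Defaults: 39 subjects, every lesion covering the core
#' (`core_hit_rate = 1`), sphere radius 37.6 +/- 6 mm (matching a mean
#' lesion volume around 223 cc), centre scatter 8 mm.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [cohort_spec].
#' @return A `cohort_spec`.
#' @export
broca_like_spec <- function(seed = 101L, ...) {
  args <- list(n_subjects = 39L, core_hit_rate = 1,
               lesion_radius_mean = 37.6, lesion_radius_sd = 6,
               jitter_sd = 8, seed = seed, name = "broca_like")
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

#' Cohort spec emulating the smaller scattered recovered cohort
#'
#' Defaults: 41 subjects, lesions never covering the core
#' (`core_hit_rate = 0`), sphere radius 24.3 +/- 8.5 mm (mean volume around
#' 60 cc), centre scatter 25 mm.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [cohort_spec].
#' @return A `cohort_spec`.
#' @export
wnl_like_spec <- function(seed = 202L, ...) {
  args <- list(n_subjects = 41L, core_hit_rate = 0,
               lesion_radius_mean = 24.3, lesion_radius_sd = 8.5,
               jitter_sd = 25, seed = seed, name = "wnl_like")
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

# 0/1 array of voxels whose centre lies within `radius` mm of `center`
sphere_voxels <- function(grid, center, radius, world = NULL) {
  if (is.null(world)) world <- grid_world_coords(grid)
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
        (world[, 3] - center[3])^2
  array(as.integer(d2 <= radius^2), dim = grid$shape)
}

#' Generate a synthetic lesion cohort with ground truth
#'
#' For each subject, in a fixed draw order (three normal deviates for the
#' centre jitter, one for the radius, one uniform for the core-hit
#' Bernoulli), a sphere lesion is placed and, with probability
#' `core_hit_rate`, unioned with the core territory. Spheres are truncated
#' at the grid bounds. The whole cohort is a pure function of (spec, seed).
#'
#' @param spec a [cohort_spec].
#' @param grid a [voxel_grid]; the core must lie inside its world bounds.
#' @return List with `masks` (list of [lesion_mask]) and `truth`: the core
#'   voxel array and linear indices, the per-subject centres, radii and
#'   core-hit flags, and the expected core proportion (`core_hit_rate`).
#' @export
make_cohort <- function(spec, grid = default_synth_grid()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(grid, "voxel_grid"))
  world <- grid_world_coords(grid)
  lo <- apply(world, 2L, min); hi <- apply(world, 2L, max)
  if (any(spec$core_center - spec$core_radius < lo) ||
      any(spec$core_center + spec$core_radius > hi))
    stop("core territory extends outside the grid", call. = FALSE)
  core <- sphere_voxels(grid, spec$core_center, spec$core_radius, world)
  subjects <- data.frame(subject_id = character(spec$n_subjects),
                         cx = 0, cy = 0, cz = 0, radius = 0,
                         core_hit = FALSE, stringsAsFactors = FALSE)
  masks <- vector("list", spec$n_subjects)
  withr::with_seed(spec$seed, {
    for (i in seq_len(spec$n_subjects)) {
      jitter <- stats::rnorm(3L, mean = 0, sd = spec$jitter_sd)
      center <- spec$core_center + jitter
      radius <- max(1, stats::rnorm(1L, spec$lesion_radius_mean,
                                    spec$lesion_radius_sd))
      hit <- stats::runif(1L) < spec$core_hit_rate
      data <- sphere_voxels(grid, center, radius, world)
      if (hit) data <- pmax(data, core)
      sid <- sprintf("%s_s%02d", spec$name, i)
      masks[[i]] <- lesion_mask(data, grid, sid)
      subjects[i, ] <- list(sid, center[1], center[2], center[3],
                            radius, hit)
    }
  })
  truth <- list(core = core,
                core_indices = which(core == 1L),
                subjects = subjects,
                expected_core_proportion = spec$core_hit_rate,
                spec = spec)
  list(masks = masks, truth = truth)
}

#' Generate a Voronoi parcellation of a grid
#'
#' Samples `k` distinct voxel centres as sites and labels every voxel with
#' its nearest site (world-space Euclidean distance; ties go to the
#' lowest-numbered site). Labels run 1..k and the lookup names them
#' `parcel_1` .. `parcel_k`; every voxel is labeled, so the parcels
#' partition the grid.
#'
#' @param grid a [voxel_grid].
#' @param k number of parcels, between 1 and the number of voxels.
#' @param seed RNG seed.
#' @return A [parcellation].
#' @export
make_parcellation <- function(grid = default_synth_grid(), k = 24L,
                              seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  nvox <- prod(grid$shape)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nvox)
    stop(sprintf("'k' must be between 1 and %d", nvox), call. = FALSE)
  world <- grid_world_coords(grid)
  labels <- withr::with_seed(seed, {
    sites <- world[sample.int(nvox, k), , drop = FALSE]
    best <- rep.int(1L, nvox)
    bestd <- (world[, 1] - sites[1, 1])^2 + (world[, 2] - sites[1, 2])^2 +
             (world[, 3] - sites[1, 3])^2
    if (k > 1L) for (s in 2:k) {
      d <- (world[, 1] - sites[s, 1])^2 + (world[, 2] - sites[s, 2])^2 +
           (world[, 3] - sites[s, 3])^2
      upd <- d < bestd        # strict: ties keep the lower label
      best[upd] <- s
      bestd[upd] <- d[upd]
    }
    best
  })
  parcellation(array(labels, dim = grid$shape), grid,
               stats::setNames(paste0("parcel_", seq_len(k)),
                               as.character(seq_len(k))))
}

#' Specification of one synthetic tract bundle
#'
#' @param name bundle name.
#' @param path numeric m x 3 matrix of corridor waypoints in world mm.
#' @param n_streamlines number of streamlines to generate.
#' @param spread sd (mm) of the per-streamline rigid offset from the
#'   corridor; 0 makes every streamline identical to the corridor.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(name, path, n_streamlines = 50L, spread = 2) {
  path <- as.matrix(path)
  if (ncol(path) != 3L || nrow(path) < 2L)
    stop("'path' must be an m x 3 matrix with m >= 2", call. = FALSE)
  structure(list(name = as.character(name)[1L], path = path,
                 n_streamlines = as.integer(n_streamlines),
                 spread = as.numeric(spread)),
            class = "bundle_spec")
}

#' Generate a synthetic streamline tract atlas
#'
#' Each bundle's streamlines are copies of its corridor polyline (densified
#' to steps of the minimum voxel edge) displaced by a per-streamline rigid
#' isotropic Gaussian offset of sd `spread` mm. Corridor waypoints must lie
#' within the grid's world bounds. Pure function of (specs, seed).
#'
#' @param grid a [voxel_grid] defining the world bounds.
#' @param bundle_specs list of [bundle_spec] objects.
#' @param seed RNG seed.
#' @return List of [tract_bundle] objects, one per spec.
#' @export
make_tract_atlas <- function(grid = default_synth_grid(), bundle_specs,
                             seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  world <- grid_world_coords(grid)
  lo <- apply(world, 2L, min); hi <- apply(world, 2L, max)
  for (bs in bundle_specs) {
    stopifnot(inherits(bs, "bundle_spec"))
    if (any(t(bs$path) < lo) || any(t(bs$path) > hi))
      stop(sprintf("corridor path of bundle '%s' leaves the grid bounds",
                   bs$name), call. = FALSE)
  }
  step <- min(grid$voxel_size)
  withr::with_seed(seed, {
    lapply(bundle_specs, function(bs) {
      base <- densify_polyline(bs$path, step)
      sl <- lapply(seq_len(bs$n_streamlines), function(i) {
        offset <- stats::rnorm(3L, 0, bs$spread)
        sweep(base, 2L, offset, `+`)
      })
      tract_bundle(bs$name, sl)
    })
  })
}

#' Default synthetic tract bundles
#'
#' Three corridors relative to a core territory: one threading straight
#' through the core centre, one grazing its edge, and one along the
#' opposite grid wall, far from any plausible lesion.
#'
#' @param core_center world mm core centre.
#' @param n_streamlines streamlines per bundle.
#' @param extent half-length (mm) of the corridors along their long axis;
#'   must stay within the target grid's world bounds.
#' @return List of [bundle_spec] objects.
#' @export
default_bundle_specs <- function(core_center = c(-30, 10, 8),
                                 n_streamlines = 50L, extent = 55) {
  through <- rbind(c(core_center[1], -extent, core_center[3]),
                   c(core_center[1], core_center[2], core_center[3]),
                   c(core_center[1], extent, core_center[3]))
  off <- min(20, 0.8 * extent)
  graze <- rbind(c(-extent, core_center[2] + off, core_center[3]),
                 c(extent, core_center[2] + off, core_center[3]))
  far <- rbind(c(extent, -extent, -extent), c(extent, extent, -extent))
  list(bundle_spec("core_tract", through, n_streamlines, spread = 2),
       bundle_spec("edge_tract", graze, n_streamlines, spread = 4),
       bundle_spec("far_tract", far, n_streamlines, spread = 1))
}

#' Write a complete ready-to-run synthetic dataset
#'
#' Emits a dataset directory holding everything the pipeline consumes: two
#' lesion cohorts (`cohort_a/`, `cohort_b/`, one NIfTI mask per subject), a
#' parcellation (`atlas.nii.gz` + `atlas.tsv`), a tract atlas (`tracts/`,
#' one JSON bundle per file) and machine-readable ground truth
#' (`truth.json`: core voxel indices, per-subject lesion parameters,
#' generator seeds).
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; cohort, parcellation and tract seeds are
#'   derived from it deterministically.
#' @param grid a [voxel_grid].
#' @param spec_a,spec_b cohort specs; defaults are [broca_like_spec] and
#'   [wnl_like_spec] reseeded from `seed`.
#' @param k_parcels number of Voronoi parcels.
#' @param n_streamlines streamlines per tract bundle.
#' @return The dataset directory path, invisibly.
#' @export
write_synth_dataset <- function(dir, seed = 1L,
                                grid = default_synth_grid(),
                                spec_a = NULL, spec_b = NULL,
                                k_parcels = 24L, n_streamlines = 50L) {
  seed <- as.integer(seed)
  if (is.null(spec_a)) spec_a <- broca_like_spec(seed = seed * 13L + 1L)
  if (is.null(spec_b)) spec_b <- wnl_like_spec(seed = seed * 13L + 2L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cohort_a"), showWarnings = FALSE)
  dir.create(file.path(dir, "cohort_b"), showWarnings = FALSE)
  dir.create(file.path(dir, "tracts"), showWarnings = FALSE)

  ca <- make_cohort(spec_a, grid)
  cb <- make_cohort(spec_b, grid)
  for (m in ca$masks)
    write_mask(m, file.path(dir, "cohort_a",
                            paste0(m$subject_id, ".nii.gz")))
  for (m in cb$masks)
    write_mask(m, file.path(dir, "cohort_b",
                            paste0(m$subject_id, ".nii.gz")))

  parc <- make_parcellation(grid, k_parcels, seed = seed * 13L + 3L)
  write_parcellation(parc, file.path(dir, "atlas.nii.gz"),
                     file.path(dir, "atlas.tsv"))

  world <- grid_world_coords(grid)
  ext <- min(c(-apply(world, 2L, min), apply(world, 2L, max)))
  atlas <- make_tract_atlas(grid,
                            default_bundle_specs(spec_a$core_center,
                                                 n_streamlines,
                                                 extent = max(0.6 * ext,
                                                              ext - 8)),
                            seed = seed * 13L + 4L)
  for (b in atlas)
    write_tract_json(b, file.path(dir, "tracts",
                                  paste0(b$name, ".json")))

  truth <- list(seed = seed,
                core_center = spec_a$core_center,
                core_radius = spec_a$core_radius,
                core_voxel_indices = ca$truth$core_indices,
                cohort_a = c(ca$truth$spec[setdiff(names(ca$truth$spec),
                                                   "core_center")],
                             list(core_center = spec_a$core_center)),
                cohort_b = c(cb$truth$spec[setdiff(names(cb$truth$spec),
                                                   "core_center")],
                             list(core_center = spec_b$core_center)),
                subjects_a = ca$truth$subjects,
                subjects_b = cb$truth$subjects)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
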