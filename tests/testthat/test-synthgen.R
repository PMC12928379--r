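# a compact grid keeps generator tests fast; world centres span -15..15 mm
synth_test_grid <- function() small_grid(c(16L, 16L, 16L), vox = 2,
                                         origin = c(-15, -15, -15))

test_spec <- function(...) {
  args <- list(n_subjects = 8L, core_center = c(0, 0, 0), core_radius = 5,
               lesion_radius_mean = 8, lesion_radius_sd = 2, jitter_sd = 3,
               seed = 77L, name = "test")
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}

test_that("cohort generation is a pure function of spec and seed", {
  g <- synth_test_grid()
  c1 <- make_cohort(test_spec(), g)
  c2 <- make_cohort(test_spec(), g)
  for (i in seq_along(c1$masks))
    expect_identical(c1$masks[[i]]$data, c2$masks[[i]]$data)
  expect_identical(c1$truth$subjects, c2$truth$subjects)
  c3 <- make_cohort(test_spec(seed = 78L), g)
  expect_false(all(vapply(seq_along(c1$masks), function(i)
    identical(c1$masks[[i]]$data, c3$masks[[i]]$data), logical(1))))
})

test_that("core_hit_rate 1 forces proportion 1 on every core voxel", {
  g <- synth_test_grid()
  co <- make_cohort(test_spec(core_hit_rate = 1), g)
  pm <- proportion_map(co$masks)
  expect_true(all(pm$values[co$truth$core_indices] == 1))
})

test_that("tiny scattered lesions with no core hits stay far from full overlap", {
  g <- synth_test_grid()
  co <- make_cohort(test_spec(core_hit_rate = 0, jitter_sd = 12,
                              lesion_radius_mean = 2.5,
                              lesion_radius_sd = 0.5, n_subjects = 12L), g)
  expect_lt(max(proportion_map(co$masks)$values), 0.6)
})

test_that("the seeded draw sequence is reproducible by an independent replay", {
  g <- synth_test_grid()
  spec <- test_spec(core_hit_rate = 0.6, n_subjects = 39L, seed = 7L)
  co <- make_cohort(spec, g)
  # replay the documented per-subject draw order with the same seed
  replay <- withr::with_seed(7L, {
    lapply(seq_len(39L), function(i) {
      jitter <- rnorm(3, 0, spec$jitter_sd)
      radius <- max(1, rnorm(1, spec$lesion_radius_mean,
                             spec$lesion_radius_sd))
      hit <- runif(1) < spec$core_hit_rate
      list(center = spec$core_center + jitter, radius = radius, hit = hit)
    })
  })
  expect_identical(co$truth$subjects$core_hit,
                   vapply(replay, `[[`, logical(1), "hit"))
  expect_equal(co$truth$subjects$radius,
               vapply(replay, `[[`, numeric(1), "radius"))
  expect_equal(co$truth$subjects$cx,
               vapply(replay, function(r) r$center[1], numeric(1)))
})

test_that("cores outside the grid are rejected", {
  g <- synth_test_grid()
  expect_error(make_cohort(test_spec(core_center = c(30, 0, 0)), g),
               "outside the grid")
  expect_error(make_cohort(test_spec(core_radius = 40), g),
               "outside the grid")
})

test_that("cohort_spec validates its parameters", {
  expect_error(test_spec(n_subjects = 0L), "n_subjects")
  expect_error(test_spec(core_hit_rate = 1.2), "core_hit_rate")
  expect_error(test_spec(core_radius = -1), "positive")
})

test_that("Voronoi parcellations partition the grid with labels 1..k", {
  g <- synth_test_grid()
  p1 <- make_parcellation(g, 1L, seed = 1)
  expect_true(all(p1$labels == 1L))

  p5 <- make_parcellation(g, 5L, seed = 2)
  counts <- table(factor(p5$labels, levels = 1:5))
  expect_identical(sum(counts), length(p5$labels))   # every voxel labeled
  expect_true(all(counts > 0))
  expect_identical(sort(unique(as.vector(p5$labels))), 1:5)
  expect_identical(unname(p5$lookup), paste0("parcel_", 1:5))

  tiny <- small_grid(c(2L, 2L, 2L))
  pall <- make_parcellation(tiny, 8L, seed = 3)
  expect_identical(sort(as.vector(pall$labels)), 1:8)  # one voxel per parcel

  expect_error(make_parcellation(g, 0L, seed = 1), "between")
  expect_error(make_parcellation(tiny, 9L, seed = 1), "between")
})

test_that("parcellation generation is deterministic in the seed", {
  g <- synth_test_grid()
  expect_identical(make_parcellation(g, 6L, seed = 5)$labels,
                   make_parcellation(g, 6L, seed = 5)$labels)
})

test_that("zero spread reproduces the corridor; same seed reproduces the atlas", {
  g <- synth_test_grid()
  path <- rbind(c(-10, 0, 0), c(10, 0, 0))
  specs <- list(bundle_spec("straight", path, n_streamlines = 5L, spread = 0))
  atlas <- make_tract_atlas(g, specs, seed = 9)
  base <- lesionmap:::densify_polyline(path, min(g$voxel_size))
  for (s in atlas[[1]]$streamlines) expect_equal(s, base)

  specs2 <- list(bundle_spec("jit", path, n_streamlines = 5L, spread = 3))
  a1 <- make_tract_atlas(g, specs2, seed = 10)
  a2 <- make_tract_atlas(g, specs2, seed = 10)
  expect_identical(a1[[1]]$streamlines, a2[[1]]$streamlines)

  bad <- list(bundle_spec("out", rbind(c(-40, 0, 0), c(10, 0, 0))))
  expect_error(make_tract_atlas(g, bad, seed = 1), "bounds")
})

test_that("a generated bundle crossing a slab matches the geometric oracle", {
  g <- synth_test_grid()
  d <- array(0L, dim = g$shape)
  d[8, , ] <- 1L                           # slab at world x = -1
  mask <- lesion_mask(d, g)
  path <- rbind(c(-14, 2, 2), c(14, 2, 2)) # crosses the slab by construction
  atlas <- make_tract_atlas(g, list(bundle_spec("through", path,
                                                n_streamlines = 10L,
                                                spread = 0)), seed = 4)
  row <- tract_disconnection(atlas[[1]], mask)
  expect_equal(row$disconnection_index, 100)
  expect_true(oracle_axis_streamline_hit(path, mask))
})

test_that("the pipeline recovers planted structure end to end", {
  g <- synth_test_grid()
  ca <- make_cohort(test_spec(core_hit_rate = 1, name = "a", seed = 31L), g)
  cb <- make_cohort(test_spec(core_hit_rate = 0, jitter_sd = 10,
                              lesion_radius_mean = 4, lesion_radius_sd = 1,
                              name = "b", seed = 32L), g)
  pa <- proportion_map(ca$masks, "a")
  pb <- proportion_map(cb$masks, "b")
  tau <- max_diff_threshold(pa, pb)
  bin <- binarize_map(subtract_maps(pa, pb), tau)
  expect_true(all(bin$data[ca$truth$core_indices] == 1L))

  # the parcel coinciding with the core tops the overlap table at 100%
  core <- ca$truth$core
  parc <- parcellation(core + 2L * (1L - core), g,
                       c(`1` = "core_parcel", `2` = "background_parcel"))
  tab <- parcel_overlap(bin, parc)
  expect_identical(tab$region_name[1], "core_parcel")
  expect_equal(tab$percent_overlap[1], 100)
})

test_that("write_synth_dataset emits a complete, internally consistent dataset", {
  dir <- withr::local_tempdir()
  g <- synth_test_grid()
  spec_a <- test_spec(name = "a", seed = 51L, n_subjects = 4L)
  spec_b <- test_spec(name = "b", seed = 52L, n_subjects = 3L,
                      core_hit_rate = 0)
  write_synth_dataset(dir, seed = 5L, grid = g, spec_a = spec_a,
                      spec_b = spec_b, k_parcels = 4L, n_streamlines = 5L)
  expect_length(list.files(file.path(dir, "cohort_a")), 4L)
  expect_length(list.files(file.path(dir, "cohort_b")), 3L)
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  expect_true(file.exists(file.path(dir, "atlas.tsv")))
  expect_gte(length(list.files(file.path(dir, "tracts"))), 1L)

  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  masks <- load_cohort(file.path(dir, "cohort_a"))
  pm <- proportion_map(masks)
  # every subject covered the core, and truth's indices point at those voxels
  expect_true(all(pm$values[truth$core_voxel_indices] == 1))
})
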