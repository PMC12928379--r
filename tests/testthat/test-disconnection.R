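# mask lesioned on a one-voxel-thick slab at the given 0-based x index
slab_mask <- function(grid, x_index) {
  d <- array(0L, dim = grid$shape)
  d[x_index + 1L, , ] <- 1L
  lesion_mask(d, grid)
}

test_that("streamlines far outside the lesion never hit", {
  g <- small_grid()
  mask <- slab_mask(g, 5L)
  s <- rbind(c(100, 100, 100), c(200, 100, 100))
  expect_false(streamline_hits_mask(s, mask))
})

test_that("a vertex at a lesioned voxel centre always hits", {
  g <- small_grid()
  d <- array(0L, dim = g$shape)
  d[4, 7, 2] <- 1L                      # world (3, 6, 1) on this grid
  mask <- lesion_mask(d, g)
  s <- rbind(c(3, 6, 1), c(3, 6, 9))
  expect_true(streamline_hits_mask(s, mask))
})

test_that("segment subdivision catches a thin slab between distant vertices", {
  g <- small_grid()
  mask <- slab_mask(g, 5L)              # slab at world x = 5
  # two vertices straddling the slab, both outside it
  s <- straight_streamline(1, from = 0, to = 9, cross = 4)
  expect_true(streamline_hits_mask(s, mask))
  # geometric oracle agrees
  expect_true(oracle_axis_streamline_hit(s, mask))
  # a parallel line that stops short of the slab misses it
  s2 <- straight_streamline(1, from = 0, to = 4.2, cross = 4)
  expect_false(streamline_hits_mask(s2, mask))
  expect_false(oracle_axis_streamline_hit(s2, mask))
})

test_that("axis-aligned streamlines agree with the analytic traversal oracle", {
  g <- small_grid()
  set.seed(1)
  for (rep in 1:20) {
    mask <- random_mask(g, 0.1)
    axis <- sample(1:3, 1)
    cross <- sample(0:9, 2, replace = TRUE)
    ends <- sort(runif(2, -1, 10))
    s <- straight_streamline(axis, ends[1], ends[2], cross)
    expect_identical(streamline_hits_mask(s, mask),
                     oracle_axis_streamline_hit(s, mask))
  }
})

test_that("hits are invariant to point-order reversal", {
  g <- small_grid()
  set.seed(2)
  mask <- random_mask(g, 0.15)
  for (rep in 1:10) {
    s <- matrix(runif(9, 0, 9), ncol = 3)
    expect_identical(streamline_hits_mask(s, mask),
                     streamline_hits_mask(s[nrow(s):1, ], mask))
  }
})

test_that("a bundle built to cross the slab 20 times out of 50 scores 40.0", {
  g <- small_grid(c(20L, 20L, 20L))
  mask <- slab_mask(g, 10L)
  # 20 streamlines cross the slab (full x traverse), 30 stay on the near side
  crossing <- lapply(1:20, function(i)
    straight_streamline(1, from = 0, to = 19, cross = c(i %% 19, i %/% 2)))
  stopping <- lapply(1:30, function(i)
    straight_streamline(1, from = 0, to = 8, cross = c(i %% 19, i %% 17)))
  bundle <- tract_bundle("constructed", c(crossing, stopping))
  # per-streamline oracle confirms the construction
  hits <- vapply(bundle$streamlines, oracle_axis_streamline_hit,
                 logical(1), mask = mask)
  expect_identical(sum(hits), 20L)
  row <- tract_disconnection(bundle, mask)
  expect_equal(row$disconnected_streamlines, 20L)
  expect_equal(row$disconnection_index, 40.0)
})

test_that("full-grid and empty masks give 100 and 0 for every bundle", {
  g <- small_grid()
  full <- lesion_mask(array(1L, dim = g$shape), g)
  empty <- lesion_mask(array(0L, dim = g$shape), g)
  atlas <- lapply(c("a", "b", "c"), function(nm)
    tract_bundle(nm, list(rbind(c(1, 1, 1), c(8, 8, 8)),
                          rbind(c(0, 5, 5), c(9, 5, 5)))))
  t_full <- disconnection_report(atlas, full)
  t_empty <- disconnection_report(atlas, empty)
  expect_equal(t_full$disconnection_index, c(100, 100, 100))
  expect_equal(t_empty$disconnection_index, c(0, 0, 0))
  # all-tie tables fall back to name order
  expect_identical(t_full$tract_name, c("a", "b", "c"))
})

test_that("constructed hit fractions come back as the exact indices, sorted", {
  g <- small_grid(c(20L, 20L, 20L))
  mask <- slab_mask(g, 10L)
  fractions <- c(1.0, 0.8, 0.5, 0.2, 0.0)
  atlas <- lapply(seq_along(fractions), function(b) {
    n_cross <- round(10 * fractions[b])
    sl <- c(
      lapply(seq_len(n_cross), function(i)
        straight_streamline(1, 0, 19, cross = c(i, b))),
      lapply(seq_len(10 - n_cross), function(i)
        straight_streamline(1, 0, 5, cross = c(i, b)))
    )
    tract_bundle(sprintf("bundle_%d", b), sl)
  })
  tab <- disconnection_report(atlas, mask)
  expect_equal(tab$disconnection_index, c(100, 80, 50, 20, 0))
  expect_identical(tab$tract_name, paste0("bundle_", 1:5))
})

test_that("duplicating every streamline leaves the index unchanged", {
  g <- small_grid()
  set.seed(3)
  mask <- random_mask(g, 0.2)
  sl <- lapply(1:8, function(i) matrix(runif(12, 0, 9), ncol = 3))
  b1 <- tract_bundle("x", sl)
  b2 <- tract_bundle("x", c(sl, sl))
  expect_equal(tract_disconnection(b1, mask)$disconnection_index,
               tract_disconnection(b2, mask)$disconnection_index)
})

test_that("growing the lesion never lowers a disconnection index", {
  g <- small_grid()
  set.seed(4)
  atlas <- lapply(1:3, function(b)
    tract_bundle(sprintf("b%d", b),
                 lapply(1:10, function(i) matrix(runif(12, 0, 9), ncol = 3))))
  base <- random_mask(g, 0.1)
  grown <- lesion_mask(pmax(base$data,
                            array(rbinom(1000, 1L, 0.15), dim = g$shape)), g)
  tb <- disconnection_report(atlas, base)
  tg <- disconnection_report(atlas, grown)
  tb <- tb[order(tb$tract_name), ]; tg <- tg[order(tg$tract_name), ]
  expect_true(all(tg$disconnection_index >= tb$disconnection_index))
})

test_that("degenerate inputs are rejected", {
  g <- small_grid()
  expect_error(tract_bundle("x", list()), "empty bundle")
  expect_error(tract_bundle("x", list(matrix(1, 1, 3))), "n >= 2")
  expect_error(tract_bundle("x", list(rbind(c(0, 0, 0), c(NA, 1, 1)))),
               "finite")
  expect_error(disconnection_report(list(), random_mask(g)), "empty atlas")
})

test_that("bundles round-trip through JSON and TCK files", {
  set.seed(5)
  sl <- lapply(1:4, function(i) matrix(runif(3 * (i + 2), -50, 50), ncol = 3))
  b <- tract_bundle("arcuate_fasciculus", sl)

  fj <- withr::local_tempfile(fileext = ".json")
  write_tract_json(b, fj)
  bj <- read_tract_json(fj)
  expect_identical(bj$name, b$name)
  expect_equal(bj$streamlines, b$streamlines)

  ft <- withr::local_tempfile(fileext = ".tck")
  write_tck(b, ft)
  bt <- read_tck(ft, name = b$name)
  expect_identical(bt$name, b$name)
  expect_equal(length(bt$streamlines), length(b$streamlines))
  for (i in seq_along(sl))   # float32 storage: ~7 significant digits
    expect_equal(bt$streamlines[[i]], b$streamlines[[i]], tolerance = 1e-5)
})

test_that("a directory of mixed bundle files loads as one atlas", {
  dir <- withr::local_tempdir()
  b1 <- tract_bundle("alpha", list(rbind(c(0, 0, 0), c(1, 1, 1))))
  b2 <- tract_bundle("beta", list(rbind(c(2, 2, 2), c(3, 3, 3))))
  write_tract_json(b1, file.path(dir, "alpha.json"))
  write_tck(b2, file.path(dir, "beta.tck"))
  atlas <- read_tract_atlas(dir)
  expect_identical(vapply(atlas, `[[`, character(1), "name"),
                   c("alpha", "beta"))
  expect_error(read_tract_atlas(withr::local_tempdir()), "no tract files")
})
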