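# shared fixture builders; everything is generated in code at test time

# axis-aligned grid with voxel centres at 0, vox, 2*vox, ... per axis
small_grid <- function(shape = c(10L, 10L, 10L), vox = 1, origin = c(0, 0, 0)) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- origin
  voxel_grid(shape, aff)
}

# Bernoulli(p) random mask on a grid
random_mask <- function(grid, p = 0.3, subject_id = "rand") {
  lesion_mask(array(stats::rbinom(prod(grid$shape), 1L, p),
                    dim = grid$shape), grid, subject_id)
}

# cohort of n random masks
random_cohort <- function(grid, n = 5L, p = 0.3) {
  lapply(seq_len(n), function(i)
    random_mask(grid, p, sprintf("rand_s%02d", i)))
}

# straight streamline along the given axis at a fixed cross position,
# with only two distant vertices (exercises segment subdivision)
straight_streamline <- function(axis, from, to, cross) {
  p1 <- numeric(3); p2 <- numeric(3)
  p1[axis] <- from; p2[axis] <- to
  others <- setdiff(1:3, axis)
  p1[others] <- cross; p2[others] <- cross
  rbind(p1, p2)
}
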