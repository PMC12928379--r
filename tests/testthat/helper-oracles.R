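# independent brute-force oracles: deliberately written as explicit
# voxel-by-voxel loops, sharing no code with the package internals

oracle_count_overlay <- function(masks) {
  s <- dim(masks[[1]]$data)
  out <- array(0L, dim = s)
  for (i in seq_len(s[1])) for (j in seq_len(s[2])) for (k in seq_len(s[3])) {
    tally <- 0L
    for (m in masks) if (m$data[i, j, k] == 1L) tally <- tally + 1L
    out[i, j, k] <- tally
  }
  out
}

oracle_proportion <- function(masks) {
  oracle_count_overlay(masks) / length(masks)
}

oracle_threshold_count <- function(values, tau) {
  s <- dim(values)
  n <- 0L
  for (i in seq_len(s[1])) for (j in seq_len(s[2])) for (k in seq_len(s[3]))
    if (values[i, j, k] >= tau) n <- n + 1L
  n
}

oracle_subtract <- function(va, vb) {
  s <- dim(va)
  out <- array(0, dim = s)
  for (i in seq_len(s[1])) for (j in seq_len(s[2])) for (k in seq_len(s[3]))
    out[i, j, k] <- va[i, j, k] - vb[i, j, k]
  out
}

# per-label (parcel_voxels, overlapped_voxels) tallied voxel by voxel
oracle_parcel_overlap <- function(map_data, labels, label_set) {
  pv <- stats::setNames(integer(length(label_set)), as.character(label_set))
  ov <- pv
  s <- dim(labels)
  for (i in seq_len(s[1])) for (j in seq_len(s[2])) for (k in seq_len(s[3])) {
    lab <- labels[i, j, k]
    if (lab == 0L) next
    key <- as.character(lab)
    pv[key] <- pv[key] + 1L
    if (map_data[i, j, k] == 1L) ov[key] <- ov[key] + 1L
  }
  list(parcel_voxels = pv, overlapped_voxels = ov,
       percent = ifelse(pv > 0, 100 * ov / pv, 0))
}

# analytic hit test for an axis-aligned straight streamline on an
# axis-aligned grid (affine diag(vox) + origin): the nearest-voxel cells
# the line traverses are enumerated directly from the geometry
oracle_axis_streamline_hit <- function(streamline, mask) {
  g <- mask$grid
  vox <- g$voxel_size
  origin <- g$affine[1:3, 4]
  p1 <- streamline[1, ]; p2 <- streamline[nrow(streamline), ]
  moving <- which(abs(p2 - p1) > 1e-12)
  stopifnot(length(moving) == 1L)   # oracle only covers axis-aligned lines
  fixed <- setdiff(1:3, moving)
  idx_fixed <- round((p1[fixed] - origin[fixed]) / vox[fixed])
  if (any(idx_fixed < 0) || any(idx_fixed > g$shape[fixed] - 1L))
    return(FALSE)
  lo <- min(p1[moving], p2[moving]); hi <- max(p1[moving], p2[moving])
  j_lo <- max(0, round((lo - origin[moving]) / vox[moving]))
  j_hi <- min(g$shape[moving] - 1, round((hi - origin[moving]) / vox[moving]))
  if (j_lo > j_hi) return(FALSE)
  for (j in j_lo:j_hi) {
    ijk <- integer(3)
    ijk[moving] <- j
    ijk[fixed] <- idx_fixed
    if (mask$data[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L] == 1L)
      return(TRUE)
  }
  FALSE
}
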