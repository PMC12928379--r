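#' Binary lesion mask
#'
#' Wraps a 3-D array of 0/1 values on a [voxel_grid], tagged with a subject
#' identifier. 1 marks a lesioned voxel, 0 a spared one. Any nonzero input is
#' coerced to 1.
#'
#' @param data 3-D numeric/logical array; nonzero means lesioned.
#' @param grid a [voxel_grid] matching `dim(data)`.
#' @param subject_id character scalar identifying the subject.
#' @return An object of class `lesion_mask` with fields `grid`, `data`
#'   (integer 0/1 array) and `subject_id`.
#' @export
lesion_mask <- function(data, grid, subject_id = "subject") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3-D array", call. = FALSE)
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("mask data dimensions do not match the grid shape", call. = FALSE)
  d <- array(as.integer(data != 0), dim = dim(data))
  structure(list(grid = grid, data = d,
                 subject_id = as.character(subject_id)[1L]),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> '%s': %d lesioned voxels on %s grid\n",
              x$subject_id, sum(x$data),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Integer-labeled parcellation
#'
#' A parcellation partitions (part of) a grid into named regions: a 3-D array
#' of non-negative integer labels (0 = background) plus a lookup table mapping
#' each label to a region name. Every nonzero label occurring in the volume
#' must be named in the lookup; the lookup may also name labels that happen
#' to occupy no voxels.
#'
#' @param labels 3-D array of non-negative integers.
#' @param grid a [voxel_grid] matching `dim(labels)`.
#' @param lookup named character vector: names are label integers (as
#'   strings), values are region names.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, grid, lookup) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(dim(labels)) != 3L)
    stop("parcellation labels must be a 3-D array", call. = FALSE)
  if (!identical(dim(labels), as.integer(grid$shape)))
    stop("label dimensions do not match the grid shape", call. = FALSE)
  lab <- array(as.integer(round(labels)), dim = dim(labels))
  if (any(lab < 0L))
    stop("parcellation labels must be non-negative", call. = FALSE)
  lookup <- stats::setNames(as.character(lookup), names(lookup))
  present <- setdiff(unique(as.vector(lab)), 0L)
  missing <- setdiff(as.character(present), names(lookup))
  if (length(missing) > 0L)
    stop(sprintf("labels present in volume but absent from lookup: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(grid = grid, labels = lab, lookup = lookup),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d named parcels on %s grid\n",
              length(x$lookup), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

# read a NIfTI file into (array, voxel_grid); drops trailing singleton dims
read_nifti_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L)
    stop(sprintf("'%s' is not a 3-D volume (dims: %s)", path,
                 paste(dim(arr), collapse = "x")), call. = FALSE)
  arr <- array(as.vector(arr), dim = d)   # drop niftiImage attributes
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = arr, grid = voxel_grid(d, aff))
}

# write an array + grid as NIfTI; datatype per content
write_nifti_volume <- function(data, grid, path,
                               datatype = c("auto", "uint8", "int32",
                                            "float", "double")) {
  datatype <- match.arg(datatype)
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Load a binary lesion mask from a NIfTI file
#'
#' Reads a (possibly gzip-compressed) NIfTI-1 volume and binarizes it: voxels
#' whose stored value exceeds `binarize_threshold` become 1, all others 0.
#' The default threshold 0 makes any nonzero voxel lesioned, which tolerates
#' interpolation residue in nominally binary tracings.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param binarize_threshold values strictly greater than this become 1
#'   (default 0).
#' @param subject_id subject identifier; defaults to the file stem.
#' @return A [lesion_mask].
#' @export
load_mask <- function(path, binarize_threshold = 0, subject_id = NULL) {
  v <- read_nifti_volume(path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(v$data > binarize_threshold, v$grid, subject_id)
}

#' Write a binary lesion mask to a NIfTI file
#'
#' @param mask a [lesion_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  write_nifti_volume(mask$data, mask$grid, path, datatype = "uint8")
}

#' Load all lesion masks in a directory as a cohort
#'
#' Reads every `.nii` / `.nii.gz` file in `dir` (sorted by name) with
#' [load_mask] and verifies they share one grid.
#'
#' @param dir directory containing one mask file per subject.
#' @param binarize_threshold passed to [load_mask].
#' @return A list of [lesion_mask] objects.
#' @export
load_cohort <- function(dir, binarize_threshold = 0) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no NIfTI files found in '%s'", dir), call. = FALSE)
  masks <- lapply(files, load_mask, binarize_threshold = binarize_threshold)
  check_cohort_grids(masks)
  masks
}

#' Read a label lookup table (TSV)
#'
#' Two tab-separated columns: integer label, region name. A header line is
#' detected (first field not an integer) and skipped.
#'
#' @param path path to the TSV file.
#' @return Named character vector mapping label (as string) to region name.
#' @export
read_lut <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][1L]
  if (is.na(suppressWarnings(as.integer(first)))) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(parts, function(p) as.integer(p[1L]), integer(1))
  names_ <- vapply(parts, function(p) p[2L], character(1))
  stats::setNames(names_, as.character(labels))
}

#' Write a label lookup table (TSV)
#'
#' @param lookup named character vector (label string -> region name).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_lut <- function(lookup, path) {
  writeLines(c("label\tname",
               paste(names(lookup), unname(lookup), sep = "\t")), path)
  invisible(path)
}

#' Load a parcellation from NIfTI + lookup TSV
#'
#' @param path integer-labeled NIfTI volume.
#' @param lut_path two-column TSV lookup table (see [read_lut]).
#' @return A [parcellation].
#' @export
load_parcellation <- function(path, lut_path) {
  v <- read_nifti_volume(path)
  parcellation(v$data, v$grid, read_lut(lut_path))
}

#' Write a parcellation to NIfTI + lookup TSV
#'
#' @param parc a [parcellation].
#' @param path output NIfTI path.
#' @param lut_path output TSV path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path, lut_path) {
  stopifnot(inherits(parc, "parcellation"))
  write_nifti_volume(parc$labels, parc$grid, path, datatype = "int32")
  write_lut(parc$lookup, lut_path)
  invisible(path)
}

# core nearest-neighbour resampler: each target voxel centre is mapped to
# world space, then to the source lattice; it takes the value of the nearest
# source voxel centre, or 0 outside the source field of view.
resample_array_nn <- function(src_data, src_grid, target) {
  idx <- grid_indices(target)
  world <- voxel_to_world(target, idx)
  src_idx <- round(world_to_voxel(src_grid, world))
  s <- src_grid$shape
  inb <- src_idx[, 1] >= 0 & src_idx[, 1] < s[1] &
         src_idx[, 2] >= 0 & src_idx[, 2] < s[2] &
         src_idx[, 3] >= 0 & src_idx[, 3] < s[3]
  out <- array(0L, dim = target$shape)
  out[inb] <- src_data[src_idx[inb, , drop = FALSE] + 1]
  out
}

#' Resample a mask or parcellation onto another grid (nearest neighbour)
#'
#' World-space nearest-neighbour resampling: each target voxel takes the value
#' of the source voxel whose centre is nearest in world coordinates; target
#' voxels falling outside the source field of view get 0. Nearest neighbour
#' keeps binary masks binary and never invents labels, which is why it is the
#' only interpolation offered for label data.
#'
#' @param source a [lesion_mask] or [parcellation].
#' @param target a [voxel_grid] to resample onto.
#' @return An object of the same class as `source`, on `target`.
#' @export
resample_nearest <- function(source, target) UseMethod("resample_nearest")

#' @export
resample_nearest.lesion_mask <- function(source, target) {
  stopifnot(inherits(target, "voxel_grid"))
  lesion_mask(resample_array_nn(source$data, source$grid, target),
              target, source$subject_id)
}

#' @export
resample_nearest.parcellation <- function(source, target) {
  stopifnot(inherits(target, "voxel_grid"))
  parcellation(resample_array_nn(source$labels, source$grid, target),
               target, source$lookup)
}
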