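#' Named bundle of streamlines
#'
#' A tract bundle is a named collection of streamlines, each an ordered
#' polyline of 3-D world-coordinate points (mm) representing a reconstructed
#' white-matter trajectory.
#'
#' @param name bundle name, e.g. `"arcuate_fasciculus"`.
#' @param streamlines non-empty list of numeric n x 3 matrices, each with
#'   at least 2 rows and finite coordinates.
#' @return An object of class `tract_bundle`.
#' @export
tract_bundle <- function(name, streamlines) {
  if (length(streamlines) == 0L)
    stop("empty bundle: a tract bundle needs at least one streamline",
         call. = FALSE)
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    if (ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline must be an n x 3 matrix with n >= 2",
           call. = FALSE)
    if (!all(is.finite(s)))
      stop("streamline coordinates must be finite", call. = FALSE)
    dimnames(s) <- NULL
    s
  })
  structure(list(name = as.character(name)[1L], streamlines = streamlines),
            class = "tract_bundle")
}

#' @export
print.tract_bundle <- function(x, ...) {
  cat(sprintf("<tract_bundle> '%s': %d streamlines\n",
              x$name, length(x$streamlines)))
  invisible(x)
}

#' Read a tract bundle from a JSON file
#'
#' Plain JSON dialect: `{"name": ..., "streamlines": [[[x,y,z], ...], ...]}`
#' with coordinates in world mm.
#'
#' @param path JSON path.
#' @return A [tract_bundle].
#' @export
read_tract_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  sl <- obj$streamlines
  if (is.array(sl) && length(dim(sl)) == 3L)      # rectangular: equal lengths
    sl <- lapply(seq_len(dim(sl)[1L]), function(i) sl[i, , ])
  name <- if (!is.null(obj$name)) obj$name else
    sub("\\.json$", "", basename(path))
  tract_bundle(name, sl)
}

#' Write a tract bundle to JSON
#'
#' @param bundle a [tract_bundle].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tract_json <- function(bundle, path) {
  stopifnot(inherits(bundle, "tract_bundle"))
  obj <- list(name = bundle$name,
              streamlines = lapply(bundle$streamlines, function(s)
                lapply(seq_len(nrow(s)), function(i) s[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tract bundle from a TCK streamline file
#'
#' MRtrix .tck format: a text header (`key: value` lines, terminated by
#' `END`) followed by binary float triples in world mm, with an all-NaN
#' triple separating streamlines and an all-Inf triple closing the stream.
#' Only `Float32LE` / `Float32BE` data are supported.
#'
#' @param path .tck path.
#' @param name bundle name; defaults to the file stem.
#' @return A [tract_bundle].
#' @export
read_tck <- function(path, name = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(magic), "mrtrix tracks"))
    stop(sprintf("'%s' is not a TCK file (bad magic line)", path),
         call. = FALSE)
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("'%s': unterminated TCK header", path), call. = FALSE)
    if (identical(trimws(line), "END")) break
    header <- c(header, line)
  }
  kv <- strsplit(header, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"),
                        character(1)))
  datatype <- vals[match("datatype", keys)]
  if (is.na(datatype) || !datatype %in% c("Float32LE", "Float32BE"))
    stop(sprintf("unsupported TCK datatype '%s'", datatype), call. = FALSE)
  endian <- if (datatype == "Float32LE") "little" else "big"
  offset <- as.numeric(sub("^\\.\\s*", "",
                           vals[match("file", keys)]))
  if (is.na(offset))
    stop("TCK header lacks a 'file: . <offset>' entry", call. = FALSE)
  seek(con, where = offset, origin = "start")
  raw_vals <- readBin(con, "numeric", n = file.size(path), size = 4L,
                      endian = endian)
  pts <- matrix(raw_vals[seq_len(3L * (length(raw_vals) %/% 3L))],
                ncol = 3L, byrow = TRUE)
  is_end <- apply(is.infinite(pts), 1L, all)
  if (any(is_end)) pts <- pts[seq_len(which(is_end)[1L] - 1L), , drop = FALSE]
  is_sep <- apply(is.nan(pts), 1L, all)
  grp <- cumsum(is_sep) + 1L
  sl <- split.data.frame(pts[!is_sep, , drop = FALSE], grp[!is_sep])
  sl <- lapply(unname(sl), as.matrix)
  if (is.null(name)) name <- sub("\\.tck$", "", basename(path))
  tract_bundle(name, sl)
}

#' Write a tract bundle to a TCK streamline file
#'
#' @param bundle a [tract_bundle].
#' @param path output .tck path.
#' @return The path, invisibly.
#' @export
write_tck <- function(bundle, path) {
  stopifnot(inherits(bundle, "tract_bundle"))
  head1 <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", length(bundle$streamlines)))
  # offset must count its own digits; iterate until stable
  offset <- 0L
  repeat {
    file_line <- sprintf("file: . %d", offset)
    hdr <- paste0(paste(c(head1, file_line, "END"), collapse = "\n"), "\n")
    n <- nchar(hdr, type = "bytes")
    if (n == offset) break
    offset <- n
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in bundle$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3L)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3L)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a directory of tract bundles
#'
#' Loads every `.json` and `.tck` file in `dir` as one named bundle each,
#' sorted by file name.
#'
#' @param dir directory of bundle files.
#' @return List of [tract_bundle] objects.
#' @export
read_tract_atlas <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(json|tck)$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no tract files (.json/.tck) found in '%s'", dir),
         call. = FALSE)
  lapply(files, function(f)
    if (grepl("\\.tck$", f)) read_tck(f) else read_tract_json(f))
}
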