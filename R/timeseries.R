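#' Read a parcellated time-series matrix
#'
#' Expects delimited text with a header row of region labels and one row per
#' frame (time point). All body cells must be finite numbers; ragged rows,
#' missing or non-numeric cells, and duplicate region labels are rejected
#' with the offending location named.
#'
#' @param path file path.
#' @param delim field delimiter; defaults to `","` for `.csv` files and tab
#'   otherwise.
#' @return a tibble with one numeric column per region, one row per frame
#'   (frame index is the row order, 0-based frame `r` = row `r + 1`).
#' @export
read_timeseries <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "vgfc_error_io")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_double()), na = character(),
      name_repair = "minimal", progress = FALSE))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("parse error at row %d, column %d: expected %s, got '%s'",
                  prob$row[1], prob$col[1], prob$expected[1], prob$actual[1]),
          class = "vgfc_error_parse")
  }
  if (anyDuplicated(names(df))) {
    dup <- unique(names(df)[duplicated(names(df))])
    abort(paste0("duplicate region label(s): ", paste(dup, collapse = ", ")),
          class = "vgfc_error_validation")
  }
  m <- as.matrix(df)
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("parse error: non-finite cell at row %d, region '%s'",
                  idx[1], names(df)[idx[2]]),
          class = "vgfc_error_parse")
  }
  as_tibble(df)
}

#' Write a parcellated time-series matrix
#'
#' Inverse of [read_timeseries()]: values survive a write/read round trip to
#' full double precision.
#'
#' @param ts data frame or matrix, frames x regions.
#' @param path output file.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, delim = "\t") {
  m <- ts_matrix(ts)
  readr::write_delim(as_tibble(m), path, delim = delim)
  invisible(path)
}

#' Read / write a framewise-displacement trace
#'
#' Single-column delimited text with header `fd_mm`, one row per frame.
#'
#' @param path file path.
#' @return `read_fd()`: a tibble with columns `frame` (0-based) and `fd_mm`.
#' @export
read_fd <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(fd_mm = readr::col_double()),
                        progress = FALSE)
  if (!"fd_mm" %in% names(df)) {
    abort("FD file must have a 'fd_mm' column", class = "vgfc_error_parse")
  }
  if (any(!is.finite(df$fd_mm)) || any(df$fd_mm < 0)) {
    abort("fd_mm must be finite and nonnegative", class = "vgfc_error_validation")
  }
  tibble(frame = seq_len(nrow(df)) - 1L, fd_mm = df$fd_mm)
}

#' @rdname read_fd
#' @param fd tibble with an `fd_mm` column (as returned by [read_fd()] or
#'   [compute_fd()]), or a bare numeric vector of FD values in mm.
#' @export
write_fd <- function(fd, path) {
  fd_mm <- if (is.numeric(fd)) fd else fd$fd_mm
  readr::write_tsv(tibble(fd_mm = fd_mm), path)
  invisible(path)
}

#' Read a rigid-body motion-parameter file
#'
#' Whitespace-delimited text, six columns per frame in the order
#' tx, ty, tz (mm), rx, ry, rz (rotations). This matches the HCP
#' `Movement_Regressors` layout (translations in mm, rotations in degrees);
#' the rotation unit is never guessed — it must be declared when the
#' parameters are converted to FD with [compute_fd()].
#'
#' @param path file path.
#' @return a numeric matrix with columns `tx, ty, tz, rx, ry, rz`.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) {
    abort(sprintf("motion-parameter file must have 6 columns, found %d", ncol(m)),
          class = "vgfc_error_validation")
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the head radius times the sum of absolute backward
#' differences of the three rotations in radians,
#' \deqn{FD(t) = \sum_i |\Delta d_i(t)| + r \sum_i |\Delta \theta_i(t)|,}
#' with `FD(0) = 0` (no predecessor frame). Rotations on a 50 mm sphere
#' approximate the displacement of cortical voxels.
#'
#' @param params T x 6 matrix, columns `(tx, ty, tz, rx, ry, rz)`.
#' @param rotation_unit `"radians"` or `"degrees"` — the unit of the three
#'   rotation columns. No default guessing: HCP movement regressors are in
#'   degrees, FSL parameter files in radians.
#' @param head_radius_mm sphere radius used to convert rotation to arc
#'   displacement (default 50 mm).
#' @return a tibble with columns `frame` (0-based) and `fd_mm`.
#' @export
compute_fd <- function(params, rotation_unit = c("radians", "degrees"),
                       head_radius_mm = 50) {
  rotation_unit <- match.arg(rotation_unit)
  params <- as.matrix(params)
  if (ncol(params) != 6) {
    abort(sprintf("motion parameters must have 6 columns, found %d", ncol(params)),
          class = "vgfc_error_validation")
  }
  if (any(!is.finite(params))) {
    abort("non-finite motion parameter", class = "vgfc_error_validation")
  }
  rot <- params[, 4:6, drop = FALSE]
  if (rotation_unit == "degrees") rot <- rot * pi / 180
  d <- abs(apply(params[, 1:3, drop = FALSE], 2, function(v) c(0, diff(v))))
  r <- abs(apply(rot, 2, function(v) c(0, diff(v))))
  fd <- rowSums(d) + head_radius_mm * rowSums(r)
  tibble(frame = seq_len(nrow(params)) - 1L, fd_mm = as.numeric(fd))
}

#' Concatenate fMRI runs within a session
#'
#' Row-binds runs in the given order (e.g. the two phase-encoding runs of an
#' HCP session) and renumbers frames `0..sum(T)-1`. Region labels must match
#' exactly, in order — no silent reordering. Run boundaries receive no
#' special handling; visibility across the seam is computed like any other
#' pair of frames.
#'
#' @param runs list of frames-x-regions data frames (or a single one).
#' @param motion optional list of matching FD tibbles/vectors, concatenated
#'   identically.
#' @return the concatenated tibble; if `motion` is supplied, a list with
#'   elements `series` and `motion`.
#' @export
concatenate_runs <- function(runs, motion = NULL) {
  if (is.data.frame(runs)) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  labs <- lapply(runs, function(r) colnames(ts_matrix(r)))
  for (k in seq_along(labs)[-1]) {
    if (!identical(labs[[k]], labs[[1]])) {
      bad <- union(setdiff(labs[[k]], labs[[1]]), setdiff(labs[[1]], labs[[k]]))
      if (length(bad) == 0) bad <- labs[[k]][labs[[k]] != labs[[1]]]
      abort(paste0("region labels differ between runs: ",
                   paste(unique(bad), collapse = ", ")),
            class = "vgfc_error_validation")
    }
  }
  series <- bind_rows(lapply(runs, as_tibble))
  if (is.null(motion)) return(series)
  fd <- unlist(lapply(motion, function(m) if (is.numeric(m)) m else m$fd_mm))
  if (length(fd) != nrow(series)) {
    abort("motion traces do not match concatenated series length",
          class = "vgfc_error_validation")
  }
  list(series = series,
       motion = tibble(frame = seq_along(fd) - 1L, fd_mm = fd))
}

#' Z-score each region's time series
#'
#' Rescales every region (column) to mean 0, sd 1. Binary visibility graphs
#' are unaffected (the edge set is affine-invariant), but weighted graphs
#' mix time (frames) and amplitude in one Euclidean distance, so a declared
#' amplitude convention is needed for weights to be comparable across
#' subjects and regions; z-scoring is that convention and is applied by
#' default before weighted-graph construction.
#'
#' @param ts frames x regions data frame or matrix.
#' @return a tibble of the same shape.
#' @export
zscore_regions <- function(ts) {
  m <- ts_matrix(ts)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance region(s): ",
                 paste(colnames(m)[sds == 0], collapse = ", ")),
          class = "vgfc_error_validation")
  }
  as_tibble(scale(m))
}

#' Fraction of motion-corrupted frames
#'
#' The subject-level QC statistic: the proportion of frames whose framewise
#' displacement strictly exceeds a threshold (0.2 mm by convention).
#'
#' @param fd FD tibble (column `fd_mm`) or numeric vector, mm.
#' @param fd_threshold_mm threshold in mm (default 0.2).
#' @return a fraction in \[0, 1\].
#' @export
motion_fraction <- function(fd, fd_threshold_mm = 0.2) {
  fd_mm <- if (is.numeric(fd)) fd else fd$fd_mm
  check_scalar(fd_threshold_mm, "fd_threshold_mm", lower = 0, strict_lower = TRUE)
  mean(fd_mm > fd_threshold_mm)
}
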