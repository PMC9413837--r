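# Recording-set persistence.
#
# The writable interchange format is an HDF5 layout with datasets
#   /data        (n_trials x n_channels x n_samples, double)
#   /fs          sampling rate (Hz)
#   /baseline_s  baseline duration (s)
#   /dialect     dialect tag
#   /subject_id  identifier
#   /ratings + /rating_names   (continuous-rating sets)  OR
#   /labels                    (discrete-label sets)
#   /channels    optional channel-name list
#
# MAT-v5 is supported read-only (the corpora ship as MAT files); variable
# names inside a distribution are configuration, not hard-coded.

#' Save a recording set in the HDF5 layout
#'
#' @param rec a [recording_set()].
#' @param path output file path (overwritten if present).
#' @return the path, invisibly.
#' @export
save_recording_set <- function(rec, path) {
  stopifnot(inherits(rec, "recording_set"))
  validate_recording_set(rec)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::H5close(), add = TRUE)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(as.integer(rec$fs), path, "fs")
  rhdf5::h5write(as.integer(rec$baseline_s), path, "baseline_s")
  rhdf5::h5write(rec$dialect, path, "dialect")
  rhdf5::h5write(rec$subject_id, path, "subject_id")
  if (!is.null(rec$ratings)) {
    rhdf5::h5write(as.matrix(rec$ratings), path, "ratings")
    rhdf5::h5write(names(rec$ratings), path, "rating_names")
  } else {
    rhdf5::h5write(as.integer(rec$discrete_labels), path, "labels")
  }
  if (!is.null(rec$channels))
    rhdf5::h5write(rec$channels, path, "channels")
  invisible(path)
}

#' Load a recording set from HDF5 or MAT-v5
#'
#' HDF5 files must follow the layout written by [save_recording_set()].
#' MAT-v5 files supply the data array (and ratings or labels) under
#' configurable variable names; the sampling rate and baseline duration
#' come from the dialect preset, or from `fs` / `baseline_s` for the
#' generic dialect. For the three corpus dialects the array must have the
#' corpus' exact `trials x channels x samples` shape.
#'
#' @param path input file.
#' @param dialect dialect tag, `"deap"`, `"dreamer"`, `"mped"` or
#'   `"generic"`.
#' @param format `"auto"` (by file extension), `"hdf5"` or `"mat"`.
#' @param mat_vars for MAT input: named list with `data` and one of
#'   `ratings` / `labels` giving the MAT variable names.
#' @param rating_names column names for a MAT ratings matrix (default
#'   valence, arousal, dominance, liking as needed).
#' @param fs,baseline_s layout for generic MAT input.
#' @return a [recording_set()].
#' @export
load_recording_set <- function(path, dialect = "generic",
                               format = c("auto", "hdf5", "mat"),
                               mat_vars = list(data = "data",
                                               ratings = "labels"),
                               rating_names = NULL, fs = 128,
                               baseline_s = NULL) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.mat$", path, ignore.case = TRUE)) "mat"
              else "hdf5"
  if (format == "hdf5") load_recording_h5(path, dialect)
  else load_recording_mat(path, dialect, mat_vars, rating_names, fs,
                          baseline_s)
}

load_recording_h5 <- function(path, dialect) {
  on.exit(rhdf5::H5close(), add = TRUE)
  have <- rhdf5::h5ls(path)$name
  for (need in c("data", "fs", "baseline_s", "dialect"))
    assert_that(need %in% have,
                "invalid recording file %s: missing dataset /%s",
                path, need)
  assert_that(any(c("ratings", "labels") %in% have),
              "invalid recording file %s: needs /ratings or /labels", path)
  data <- rhdf5::h5read(path, "data")
  stored_dialect <- as.character(rhdf5::h5read(path, "dialect"))
  if (!identical(dialect, "generic") &&
      !identical(dialect, stored_dialect))
    stop2("file %s stores dialect '%s' but '%s' was requested",
          path, stored_dialect, dialect)
  ratings <- NULL; labels <- NULL
  if ("ratings" %in% have) {
    ratings <- as.data.frame(rhdf5::h5read(path, "ratings"))
    names(ratings) <- as.character(rhdf5::h5read(path, "rating_names"))
  } else {
    labels <- as.integer(rhdf5::h5read(path, "labels"))
  }
  channels <- if ("channels" %in% have)
    as.character(rhdf5::h5read(path, "channels")) else NULL
  recording_set(data,
                fs = as.integer(rhdf5::h5read(path, "fs")),
                baseline_s = as.integer(rhdf5::h5read(path, "baseline_s")),
                ratings = ratings, discrete_labels = labels,
                dialect = stored_dialect,
                subject_id = as.character(rhdf5::h5read(path,
                                                        "subject_id")),
                channels = channels)
}

# Corpus file shapes (trials, channels, samples) for shape validation.
corpus_shape <- function(dialect) {
  switch(dialect,
    deap = c(40L, 32L, 8064L),
    dreamer = c(18L, 14L, 7808L),
    mped = c(28L, 62L, 15360L),
    NULL)
}

load_recording_mat <- function(path, dialect, mat_vars, rating_names,
                               fs, baseline_s) {
  vars <- read_mat_v5(path)
  assert_that(mat_vars$data %in% names(vars),
              "MAT file %s has no variable '%s' (found: %s)",
              path, mat_vars$data, paste(names(vars), collapse = ", "))
  data <- vars[[mat_vars$data]]
  assert_that(length(dim(data)) == 3,
              "MAT variable '%s' must be 3-d (trials x channels x samples)",
              mat_vars$data)
  want <- corpus_shape(dialect)
  if (!is.null(want))
    assert_that(identical(dim(data), as.integer(want)) ||
                  all(dim(data) == want),
                "dialect '%s' expects a %s array, found %s",
                dialect, paste(want, collapse = " x "),
                paste(dim(data), collapse = " x "))
  ds <- dialect_spec(dialect)
  if (!is.na(ds$baseline_s)) baseline_s <- ds$baseline_s
  assert_that(!is.null(baseline_s),
              "generic MAT input needs an explicit baseline_s")
  if (dialect %in% c("deap", "dreamer", "mped")) fs <- 128L

  ratings <- NULL; labels <- NULL
  if (dialect == "mped") {
    lv <- mat_vars$labels %||% mat_vars$ratings
    assert_that(!is.null(lv) && lv %in% names(vars),
                "MAT file %s: missing label variable '%s'", path,
                lv %||% "<unset>")
    labels <- as.integer(round(as.vector(vars[[lv]])))
    if (min(labels) == 1L) labels <- labels - 1L   # accept 1-based storage
  } else {
    rv <- mat_vars$ratings %||% mat_vars$labels
    assert_that(!is.null(rv) && rv %in% names(vars),
                "MAT file %s: missing ratings variable '%s'", path,
                rv %||% "<unset>")
    rmat <- vars[[rv]]
    if (is.null(dim(rmat))) rmat <- matrix(rmat, ncol = 1)
    if (length(dim(rmat)) > 2) rmat <- matrix(rmat, nrow = dim(rmat)[1])
    if (is.null(rating_names))
      rating_names <- c("valence", "arousal", "dominance",
                        "liking")[seq_len(ncol(rmat))]
    ratings <- as.data.frame(rmat)
    names(ratings) <- rating_names
  }
  recording_set(data, fs = fs, baseline_s = baseline_s,
                ratings = ratings, discrete_labels = labels,
                dialect = dialect,
                subject_id = sub("\\.mat$", "", basename(path),
                                 ignore.case = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal MAT-v5 container ---------------------------------------------
# Only what the corpora need: numeric arrays (double/single/int8..uint32),
# uncompressed or zlib-compressed data elements. Cell arrays, structs,
# character data and sparse matrices are out of scope.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mat_num_reader <- function(type) {
  switch(as.character(type),
         "1" = list(size = 1L, what = "integer", signed = TRUE),
         "2" = list(size = 1L, what = "integer", signed = FALSE),
         "3" = list(size = 2L, what = "integer", signed = TRUE),
         "4" = list(size = 2L, what = "integer", signed = FALSE),
         "5" = list(size = 4L, what = "integer", signed = TRUE),
         "6" = list(size = 4L, what = "integer", signed = FALSE),
         "7" = list(size = 4L, what = "double"),
         "9" = list(size = 8L, what = "double"),
         NULL)
}

#' Read numeric variables from a MAT-v5 file
#'
#' A minimal level-5 MAT reader covering what EEG corpus distributions
#' need: named numeric arrays of any dimensionality, stored plainly or
#' zlib-compressed. Logical/character/cell/struct/sparse variables are
#' skipped.
#'
#' @param path MAT file path.
#' @return named list of numeric arrays (with `dim` set for >= 2-d).
#' @export
read_mat_v5 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  assert_that(length(raw) > 128, "not a MAT-v5 file: %s (too short)", path)
  endian <- rawToChar(raw[127:128])
  assert_that(endian %in% c("IM", "MI"),
              "not a MAT-v5 file: %s (bad endian indicator)", path)
  en <- if (endian == "IM") "little" else "big"
  out <- list()
  pos <- 129L
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    type <- readBin(raw[pos:(pos + 3L)], "integer", 1, 4, endian = en)
    size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1, 4,
                    endian = en)
    body <- raw[(pos + 8L):(pos + 7L + size)]
    if (type == MI_COMPRESSED) {
      body <- memDecompress(body, type = "gzip")
      type <- readBin(body[1:4], "integer", 1, 4, endian = en)
      size2 <- readBin(body[5:8], "integer", 1, 4, endian = en)
      inner <- body[9:(8 + size2)]
      if (type == MI_MATRIX) {
        v <- parse_mi_matrix(inner, en)
        if (!is.null(v)) out[[v$name]] <- v$value
      }
    } else if (type == MI_MATRIX) {
      v <- parse_mi_matrix(body, en)
      if (!is.null(v)) out[[v$name]] <- v$value
    }
    pos <- pos + 8L + size
    pos <- pos + (-size %% 8L)                 # elements are 8-byte aligned
  }
  out
}

# Parse one miMATRIX element body; returns list(name, value) or NULL for
# unsupported classes.
parse_mi_matrix <- function(body, en) {
  read_sub <- function(at) {
    type <- readBin(body[at:(at + 3L)], "integer", 1, 4, endian = en)
    if (bitwAnd(type, bitwShiftL(65535L, 16L)) != 0L) {
      # small data element: size in the upper 16 bits, data in-place
      size <- bitwShiftR(type, 16L)
      type <- bitwAnd(type, 65535L)
      list(type = type, size = size,
           data = if (size > 0) body[(at + 4L):(at + 3L + size)] else raw(),
           next_at = at + 8L)
    } else {
      size <- readBin(body[(at + 4L):(at + 7L)], "integer", 1, 4,
                      endian = en)
      data <- if (size > 0) body[(at + 8L):(at + 7L + size)] else raw()
      list(type = type, size = size, data = data,
           next_at = at + 8L + size + (-size %% 8L))
    }
  }
  flags <- read_sub(1L)
  fl <- readBin(flags$data[1:4], "integer", 1, 4, endian = en)
  class_id <- bitwAnd(fl, 255L)
  # numeric array classes are 6..13 (double .. uint32)
  if (class_id < 6L || class_id > 13L) return(NULL)
  dims_el <- read_sub(flags$next_at)
  dims <- readBin(dims_el$data, "integer", dims_el$size / 4L, 4,
                  endian = en)
  name_el <- read_sub(dims_el$next_at)
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  data_el <- read_sub(name_el$next_at)
  rd <- mat_num_reader(data_el$type)
  if (is.null(rd)) return(NULL)
  n_el <- data_el$size / rd$size
  vals <- if (rd$what == "integer") {
    as.numeric(readBin(data_el$data, "integer", n_el, rd$size,
                       signed = if (rd$size < 4) isTRUE(rd$signed) else TRUE,
                       endian = en))
  } else {
    readBin(data_el$data, "double", n_el, rd$size, endian = en)
  }
  value <- array(vals, dim = dims)
  if (length(dims) == 2 && min(dims) == 1) value <- as.vector(value)
  list(name = name, value = value)
}

#' Write numeric variables to a MAT-v5 file
#'
#' Minimal uncompressed level-5 writer (double-precision arrays only);
#' the counterpart of [read_mat_v5()], used to build reader fixtures and
#' to export synthetic recordings for MAT-based pipelines.
#'
#' @param vars named list of numeric vectors/matrices/arrays.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mat_v5 <- function(vars, path) {
  assert_that(length(names(vars)) == length(vars) &&
                all(nzchar(names(vars))), "all variables must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf(
    "MATLAB 5.0 MAT-file, created by e2ennet on %s",
    format(Sys.time(), "%Y-%m-%d")))
  header <- c(header, rep(as.raw(0x20), 116 - length(header)))
  writeBin(header, con)
  writeBin(rep(as.raw(0), 8), con)              # subsystem offset
  writeBin(c(as.raw(0), as.raw(1)), con)        # version 0x0100
  writeBin(charToRaw("IM"), con)                # little-endian indicator

  pad8 <- function(nbytes) rep(as.raw(0), -nbytes %% 8)
  sub_element <- function(type, data_raw) {
    c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
      writeBin(as.integer(length(data_raw)), raw(), size = 4,
               endian = "little"),
      data_raw, pad8(length(data_raw)))
  }
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- if (is.null(dim(v))) c(length(v), 1L) else dim(v)
    flags <- writeBin(c(6L, 0L), raw(), size = 4, endian = "little")
    body <- c(
      sub_element(MI_UINT32, flags),
      sub_element(MI_INT32,
                  writeBin(as.integer(dims), raw(), size = 4,
                           endian = "little")),
      sub_element(MI_INT8, charToRaw(nm)),
      sub_element(MI_DOUBLE,
                  writeBin(as.double(v), raw(), size = 8,
                           endian = "little")))
    writeBin(as.integer(MI_MATRIX), con, size = 4, endian = "little")
    writeBin(as.integer(length(body)), con, size = 4, endian = "little")
    writeBin(body, con)
  }
  invisible(path)
}
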