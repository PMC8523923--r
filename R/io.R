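# Archive and results IO: epoch archives (raw float64 matrix + JSON
# metadata), results tables as CSV with JSON schema sidecars, a run
# configuration that round-trips losslessly, and line-delimited JSON
# logging.

#' Write / read an epoch archive
#'
#' An archive is a directory holding `epochs.bin` (row-major 64-bit float
#' matrix, input-referred uV) and `meta.json` (dimensions, sample rate,
#' polarity sequence, 0-based onset sample, units, stimulus metadata,
#' seed).  Reading validates shape and polarity and reports the offending
#' field on failure.
#'
#' @param epochs an [epoch_matrix()].
#' @param path archive directory (created if missing).
#' @param seed generating seed recorded in the metadata (optional).
#' @return `write_epoch_archive()` returns `path` invisibly;
#'   `read_epoch_archive()` returns an `epoch_matrix`.
#' @export
write_epoch_archive <- function(epochs, path, seed = NULL) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(path, "epochs.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(epochs$data)), con, size = 8, endian = "little")
  meta <- list(
    n_epochs = nrow(epochs$data), n_samples = ncol(epochs$data),
    sample_rate = epochs$sample_rate, polarity = epochs$polarity,
    onset_sample = epochs$onset_sample, invalid_edge = epochs$invalid_edge,
    units = "uV", layout = "row-major float64 little-endian",
    seed = seed)
  if (!is.null(epochs$stimulus)) meta$stimulus <- unclass(epochs$stimulus)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_epoch_archive
#' @export
read_epoch_archive <- function(path) {
  meta_path <- file.path(path, "meta.json")
  bin_path <- file.path(path, "epochs.bin")
  if (!file.exists(meta_path)) stop("archive has no meta.json", call. = FALSE)
  if (!file.exists(bin_path)) stop("archive has no epochs.bin", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("n_epochs", "n_samples", "sample_rate", "polarity",
                  "onset_sample")) {
    if (is.null(meta[[field]]))
      stop(sprintf("meta.json missing required field `%s`", field),
           call. = FALSE)
  }
  n_exp <- meta$n_epochs * meta$n_samples
  vals <- readBin(bin_path, "double", n = n_exp + 1, size = 8,
                  endian = "little")
  if (length(vals) != n_exp)
    stop(sprintf("epochs.bin length mismatch: expected %d values, found %d",
                 n_exp, length(vals)), call. = FALSE)
  data <- matrix(vals, nrow = meta$n_epochs, byrow = TRUE)
  stim <- NULL
  if (!is.null(meta$stimulus))
    stim <- do.call(tone_burst_spec,
                    meta$stimulus[c("frequency", "level", "duration_ms",
                                    "rise_fall_ms", "n_repetitions",
                                    "polarity_start", "sample_rate")])
  epoch_matrix(data, meta$sample_rate, meta$polarity,
               onset_sample = meta$onset_sample, stimulus = stim,
               invalid_edge = meta$invalid_edge %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run configuration with the pipeline's canonical constants
#'
#' Defaults are the analysis constants: 600-1600 Hz (ANOW) and 150-1500 Hz
#' (CAP) FIR passbands, quartile fence 3, smoothing coefficient 0.005,
#' 6 dB SNR criterion.  Every constant is overridable, and a configuration
#' round-trips losslessly through JSON.
#'
#' @param ... overrides of the default fields.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    anow_passband = c(600, 1600), cap_passband = c(150, 1500),
    artifact_fence = 3, smoothing = 0.005, snr_criterion = 6,
    sample_rate = 96000, levels = seq(10, 80, by = 5),
    frequencies = c(300, 480, 720, 1020), seed = 1L,
    out_dir = "results")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- modifyList(defaults, over)
  # canonical storage modes so a JSON round trip is lossless
  for (f in setdiff(names(cfg), c("seed", "out_dir")))
    cfg[[f]] <- as.numeric(cfg[[f]])
  cfg$seed <- as.integer(cfg$seed)
  cfg$out_dir <- as.character(cfg$out_dir)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every results
#' file so outputs name the configuration that produced them.  The output
#' directory is excluded: the hash identifies the analysis parameters, not
#' where results land.
#'
#' @param config any JSON-serializable object (typically a `run_config`).
#' @return hex string.
#' @export
config_hash <- function(config) {
  config <- unclass(config)
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write results tables as CSV with a JSON schema sidecar
#'
#' Each table is written with full numeric precision, a leading
#' `# config_hash:` comment line, and deterministic column order; the
#' sidecar records columns, types, row counts and the configuration hash.
#'
#' @param tables named list of data frames (e.g. `series`, `slopes`,
#'   `regressions`).
#' @param path output directory.
#' @param config configuration stamped into the outputs.
#' @return invisibly, the written file paths.
#' @export
write_results <- function(tables, path, config = run_config()) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  files <- character(0)
  schema <- list(config_hash = hash, tables = list())
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (!is.data.frame(df)) stop(sprintf("`%s` is not a data frame", nm),
                                 call. = FALSE)
    df <- df[, sort(names(df)), drop = FALSE]  # deterministic column order
    out <- df
    for (cn in names(out))
      if (is.numeric(out[[cn]]))
        out[[cn]] <- sprintf("%.17g", out[[cn]])
    f <- file.path(path, paste0(nm, ".csv"))
    con <- file(f, "w")
    writeLines(sprintf("# config_hash: %s", hash), con)
    write.csv(out, con, row.names = FALSE, quote = TRUE)
    close(con)
    files <- c(files, f)
    schema$tables[[nm]] <- list(
      columns = names(df),
      types = vapply(df, function(col) class(col)[1], character(1)),
      rows = nrow(df))
  }
  sidecar <- file.path(path, "results_schema.json")
  jsonlite::write_json(schema, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return data frame with numeric columns restored to full precision.
#' @export
read_results_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (cn in names(df)) {
    suppressWarnings(num <- as.numeric(df[[cn]]))
    if (!anyNA(num) || all(is.na(num) == (df[[cn]] %in% c("NA", ""))))
      df[[cn]] <- num
  }
  df
}

#' Emit one line-delimited JSON log record
#'
#' @param stage short stage name.
#' @param ... named fields to log (parameters in effect, counts, paths).
#' @param file connection or path; default standard error.
#' @export
log_event <- function(stage, ..., file = stderr()) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                stage = stage), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (is.character(file)) cat(line, "\n", sep = "", file = file,
                              append = TRUE)
  else writeLines(line, file)
  invisible(rec)
}
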