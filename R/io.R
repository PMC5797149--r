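#' Write / read an ECG record as CSV + JSON sidecar
#'
#' The waveform goes to \code{<base>.csv} (columns time_s, mv; unrecorded
#' samples empty) and the metadata (sampling rate, start clock time,
#' recorded segments) to \code{<base>.meta.json}.  The round trip is
#' lossless up to numeric printing precision.
#'
#' @param record an \code{ecg_record}.
#' @param base path without extension.
#' @return \code{base}, invisibly (write) or the record (read).
#' @export
write_record <- function(record, base) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(time_s = (seq_along(record$signal) - 1L) / record$fs,
                   mv = record$signal)
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  meta <- list(fs = record$fs, t0_clock = record$t0_clock,
               segments = record$segments)
  jsonlite::write_json(meta, paste0(base, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_record
#' @export
read_record <- function(base) {
  f <- paste0(base, ".csv")
  if (!file.exists(f)) stop("record file not found: ", f)
  df <- utils::read.csv(f)
  if (!all(c("time_s", "mv") %in% names(df)))
    stop("malformed record CSV (need columns time_s, mv): ", f)
  meta <- jsonlite::read_json(paste0(base, ".meta.json"), simplifyVector = TRUE)
  rec <- list(fs = meta$fs, signal = df$mv, t0_clock = meta$t0_clock,
              segments = as.data.frame(meta$segments), meta = list(),
              artifact_truth = NULL)
  class(rec) <- "ecg_record"
  rec
}

#' Write / read arrhythmia events
#'
#' JSON-lines (one event object per line) or CSV with identical columns;
#' the two representations convert losslessly into one another.
#'
#' @param events data.frame with at least (class, onset); extra columns are
#'   preserved.
#' @param path output file; format inferred from the extension (.jsonl /
#'   .csv) unless given.
#' @param format "jsonl" or "csv".
#' @return path invisibly (write) or the events data.frame (read).
#' @export
write_events <- function(events, path, format = NULL) {
  format <- format %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  if (format == "jsonl") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(events)))
      writeLines(jsonlite::toJSON(as.list(events[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
  } else {
    utils::write.csv(events, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  if (!file.exists(path)) stop("events file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path)
    if (!length(lines))
      return(data.frame(class = character(), onset = numeric()))
    rows <- lapply(seq_along(lines), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON at line ", i,
                                             " of ", path, ": ",
                                             conditionMessage(e)))
      as.data.frame(lapply(x, function(v) if (is.null(v)) NA else v))
    })
    do.call(rbind, rows)
  } else {
    utils::read.csv(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read beat annotations as CSV
#'
#' Columns: time_s, template_id, score, morphology, p_found plus any label
#' columns present.
#'
#' @param ann annotation data.frame.
#' @param path CSV path.
#' @return path invisibly / the data.frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  utils::read.csv(path)
}

#' Write / read a 5-min activity series as CSV
#' @param activity data.frame (epoch_start, value).
#' @param path CSV path.
#' @return path invisibly / the data.frame.
#' @export
write_activity <- function(activity, path) {
  utils::write.csv(activity[, c("epoch_start", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("epoch_start", "value") %in% names(df)))
    stop("malformed activity CSV: ", path)
  df
}

#' Default pipeline configuration
#'
#' Flat key hierarchy holding the study-design parameters and every
#' documented analysis threshold; round-trips losslessly through YAML.
#'
#' @param seed study seed.
#' @return named list of class \code{pipeline_config}.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_strain = c(6L, 6L, 6L, 5L),
    longterm_hours = 96,
    acute_minutes = 330,
    fs = 1000,
    day_start = 7, day_end = 19,
    detector_band_low = 10, detector_band_high = 50,
    detector_integration_ms = 12,
    detector_refractory_ms = 50,
    template_merge_threshold = 0.95,
    unmatched_threshold = 0.8,
    prematurity_frac = 0.8,
    pause_frac = 1.15,
    rr_reference_k = 5L,
    alpha = 0.05)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write / read a pipeline configuration (YAML)
#' @param config a \code{pipeline_config} list.
#' @param path YAML path.
#' @return path invisibly / the config.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(unclass(base), cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Run manifest for a pipeline invocation
#'
#' Records the configuration hash, package version, per-file checksums and a
#' timestamp; equal config hashes imply equal output checksums apart from
#' the timestamp.
#'
#' @param config the \code{pipeline_config} used.
#' @param files character vector of produced files.
#' @param path where to write the manifest JSON.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, files, path) {
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  man <- list(config_hash = config_hash(config),
              version = as.character(utils::packageVersion("telemarr")),
              checksums = as.list(sums),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE)
  invisible(man)
}
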