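#' Classify an annotated (ground-truth) beat stream
#'
#' The truth-bypass analysis path: runs the RR/criteria classifier directly
#' on generator beat annotations (skipping waveform detection) and carries
#' the truth VF episodes through, since VF precludes beat-level
#' classification by definition.
#'
#' @param beats truth beats data.frame (time, morph_atypical, p_present).
#' @param vf_events optional truth events; rows with class "VF" are appended.
#' @param ... thresholds for \code{\link{classify_beats}}.
#' @return list(beats = classified beats, events = event data.frame with
#'   onset/end/n_beats).
#' @export
classify_truth <- function(beats, vf_events = NULL, ...) {
  cls <- classify_beats(beats, ...)
  ev <- group_runs(cls$label, cls$time)
  if (!is.null(vf_events) && nrow(vf_events)) {
    vf <- vf_events[vf_events$class == "VF",
                    c("class", "onset", "end"), drop = FALSE]
    if (nrow(vf)) {
      vf$start_beat <- NA_integer_; vf$end_beat <- NA_integer_
      vf$n_beats <- NA_integer_
      ev <- rbind(ev, vf[, names(ev)])
      ev <- ev[order(ev$onset), , drop = FALSE]
    }
  }
  rownames(ev) <- NULL
  list(beats = cls, events = ev)
}

#' Full-waveform analysis of an ECG record
#'
#' The complete detection-and-classification chain on a sampled waveform:
#' QRS detection, template-library construction, morphology matching, P-wave
#' search, artifact flagging, RR-criteria classification, run grouping and
#' VF detection.  Beats inside artifact or VF intervals are excluded from
#' beat-level classification; VF episodes are reported as events.
#'
#' @param record an \code{ecg_record}.
#' @param activity optional activity series for artifact annotation.
#' @param config a \code{pipeline_config} (thresholds); default thresholds
#'   otherwise.
#' @return list(beats, events, annotations, artifacts, library).
#' @export
analyze_record <- function(record, activity = NULL, config = default_config()) {
  det <- detect_qrs(record,
                    band = c(config$detector_band_low,
                             config$detector_band_high),
                    integration_ms = config$detector_integration_ms,
                    refractory_ms = config$detector_refractory_ms)
  if (nrow(det) < 2L)
    return(list(beats = det, events = empty_truth_events()[0, ],
                annotations = det, artifacts = NULL, library = NULL))
  lib <- build_template_library(record, det,
                                merge_threshold = config$template_merge_threshold)
  ann <- match_beat_morphology(record, det, lib,
                               unmatched_threshold = config$unmatched_threshold)
  pw <- find_p_wave(record, det)
  art <- flag_artifacts(record, activity)
  vf <- detect_vf(record, ann,
                  match_threshold = config$unmatched_threshold)
  excl <- rep(FALSE, nrow(det))
  if (nrow(art))
    for (r in seq_len(nrow(art)))
      excl <- excl | (det$time >= art$start[r] & det$time < art$end[r])
  if (nrow(vf))
    for (r in seq_len(nrow(vf)))
      excl <- excl | (det$time >= vf$onset[r] & det$time < vf$end[r])
  # criterion 1 holds when the beat does not match the normal template:
  # both an abnormal-template match and a failed match are atypical shapes
  bdf <- data.frame(time = det$time,
                    morph_atypical = ann$morphology != "normal",
                    p_found = pw$p_found,
                    stringsAsFactors = FALSE)
  bdf <- bdf[!excl, , drop = FALSE]
  cls <- classify_beats(bdf,
                        premature_frac = config$prematurity_frac,
                        pause_frac = config$pause_frac,
                        k = config$rr_reference_k)
  ev <- group_runs(cls$label, cls$time)
  if (nrow(vf)) {
    vf$start_beat <- NA_integer_; vf$end_beat <- NA_integer_
    vf$n_beats <- NA_integer_
    ev <- rbind(ev, vf[, names(ev)])
    ev <- ev[order(ev$onset), , drop = FALSE]
  }
  rownames(ev) <- NULL
  list(beats = cls, events = ev, annotations = ann, artifacts = art,
       library = lib)
}

study_design_from_config <- function(config) {
  study_design(n_per_strain = config$n_per_strain,
               longterm_hours = config$longterm_hours,
               acute_minutes = config$acute_minutes,
               day_start = config$day_start, day_end = config$day_end,
               fs = config$fs, seed = config$seed)
}

#' Simulate a study and write it to disk
#'
#' Writes, per animal, the ground-truth beat annotations (CSV), realised
#' event schedules (JSON-lines), and activity logs (CSV) for every session,
#' plus the configuration and a checksummed run manifest.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  study <- simulate_study(study_design_from_config(config))
  files <- character(0)
  for (an in study$animals) {
    stem <- file.path(out_dir, gsub("[^A-Za-z0-9._-]", "_", an$animal_id))
    for (snm in names(an$sessions)) {
      s <- an$sessions[[snm]]
      f1 <- paste0(stem, "_", snm, "_beats.csv")
      write_annotations(s$beats, f1)
      f2 <- paste0(stem, "_", snm, "_activity.csv")
      write_activity(s$activity, f2)
      files <- c(files, f1, f2)
      if (!is.null(s$events)) {
        f3 <- paste0(stem, "_", snm, "_events.jsonl")
        write_events(s$events, f3)
        files <- c(files, f3)
      }
    }
  }
  cfgf <- file.path(out_dir, "config.yaml")
  write_config(config, cfgf)
  write_manifest(config, c(files, cfgf),
                 file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Run the analysis pipeline on a simulated study
#'
#' Chains classification (truth-bypass on the generator annotations),
#' arrhythmia counting over the 5-h post-injection window of the
#' isoproterenol session, long-term HR analysis of both 96-h phases, and the
#' group statistics, and assembles report tables in the layouts used for
#' such studies: per-strain minimal/maximal HR (mean +/- SEM) and per-strain
#' event counts with affected-animal fractions "(k/n)".
#'
#' @param study a \code{telemetry_study} from \code{\link{simulate_study}}.
#' @param config a \code{pipeline_config}.
#' @return list of class \code{study_report}: per-animal metrics, episode
#'   summary, HR table, formatted tables and the statistics objects.
#' @export
pipeline_run <- function(study, config = default_config()) {
  stopifnot(inherits(study, "telemetry_study"))
  counts <- list(); hrrows <- list()
  for (an in study$animals) {
    iso_nm <- if (an$sessions$acute_1$agent == "iso") "acute_1" else "acute_2"
    s <- an$sessions[[iso_nm]]
    cl <- classify_truth(s$beats, s$events,
                         premature_frac = config$prematurity_frac,
                         pause_frac = config$pause_frac,
                         k = config$rr_reference_k)
    ct <- count_events(cl$events, s$window)
    ct$group <- an$strain; ct$animal <- an$animal_id
    counts[[length(counts) + 1L]] <- ct

    hr <- list()
    for (ph in c("baseline", "metoprolol")) {
      ses <- an$sessions[[ph]]
      ep <- hr_epochs(ses$beats$time, ses$segments, t0_clock = ses$t0_clock,
                      day_start = config$day_start, day_end = config$day_end)
      hr[[ph]] <- daynight_summary(ep)
    }
    dl <- metoprolol_delta(hr$baseline, hr$metoprolol)
    hrrows[[length(hrrows) + 1L]] <- data.frame(
      animal = an$animal_id, group = an$strain,
      base_mean_day = hr$baseline$mean_day,
      base_mean_night = hr$baseline$mean_night,
      base_min = hr$baseline$min_hr, base_max = hr$baseline$max_hr,
      met_min = hr$metoprolol$min_hr, met_max = hr$metoprolol$max_hr,
      delta_day = dl$delta_day, delta_night = dl$delta_night)
  }
  counts <- do.call(rbind, counts)
  hrtab <- do.call(rbind, hrrows)
  episode_summary <- summarize_episodes(counts)
  stats <- list(
    total_events = tryCatch(
      kruskal_dunn(data.frame(group = counts$group, value = counts$total),
                   alpha = config$alpha), error = function(e) NULL),
    min_hr = tryCatch(
      one_way_anova_snk(data.frame(group = hrtab$group,
                                   value = hrtab$base_min),
                        alpha = config$alpha), error = function(e) NULL))
  structure(list(counts = counts, hr = hrtab,
                 episode_summary = episode_summary,
                 table_events = format_event_table(episode_summary),
                 table_hr = format_hr_table(hrtab),
                 stats = stats, config = config),
            class = "study_report")
}

format_event_table <- function(es) {
  classes <- c(pvb = "PVB", coupled = "Coupled beats", vt = "VT", vf = "VF",
               total = "Total events")
  groups <- unique(es$group)
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (cl in names(classes)) {
    sub <- es[es$class == cl, ]
    out[[classes[[cl]]]] <- vapply(groups, function(g) {
      r <- sub[sub$group == g, ]
      sprintf("%.1f ± %.1f (%d/%d)", r$mean, r$sem, r$n_affected, r$n)
    }, character(1))
  }
  out
}

format_hr_table <- function(hrtab) {
  groups <- unique(hrtab$group)
  msem <- function(v) sprintf("%.0f ± %.0f bpm", mean(v),
                              stats::sd(v) / sqrt(length(v)))
  data.frame(
    group = groups,
    baseline_min = vapply(groups, function(g)
      msem(hrtab$base_min[hrtab$group == g]), character(1)),
    baseline_max = vapply(groups, function(g)
      msem(hrtab$base_max[hrtab$group == g]), character(1)),
    metoprolol_min = vapply(groups, function(g)
      msem(hrtab$met_min[hrtab$group == g]), character(1)),
    metoprolol_max = vapply(groups, function(g)
      msem(hrtab$met_max[hrtab$group == g]), character(1)),
    delta_day = vapply(groups, function(g)
      msem(hrtab$delta_day[hrtab$group == g]), character(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", nrow(x$hr), "animals\n\n")
  cat("Heart rate (long-term recordings):\n")
  print(x$table_hr, row.names = FALSE)
  cat("\nVentricular arrhythmias, 5 h after isoproterenol:\n")
  print(x$table_events, row.names = FALSE)
  if (!is.null(x$stats$total_events))
    cat(sprintf("\nTotal events: Kruskal-Wallis H = %.2f, p = %.3g\n",
                x$stats$total_events$statistic, x$stats$total_events$p))
  invisible(x)
}
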