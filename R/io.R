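# Readers/writers and the end-to-end pipeline.
#
# Interchange format: a plain-text array container (TSV sample matrix,
# one column per channel) with a JSON sidecar carrying the sampling rate
# and channel labels, plus a delimited event table. Every report written
# by the pipeline embeds the configuration hash and master seed that
# produced it.

#' Write a recording to a text array container
#'
#' Writes `<path>.tsv` (samples x channels), `<path>.json` (sampling
#' rate, channel labels) and `<path>.events.tsv` (onset_sample, class,
#' condition).
#'
#' @param rec An [eeg_recording()].
#' @param path Base path (without extension).
#' @param digits Significant digits kept in the sample matrix
#'   (default 6).
#' @return Invisibly, the base path.
#' @export
write_recording <- function(rec, path, digits = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  dt <- data.table::as.data.table(signif(t(rec$data), digits))
  data.table::setnames(dt, rec$channel_labels)
  data.table::fwrite(dt, paste0(path, ".tsv"), sep = "\t")
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         n_samples = ncol(rec$data)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(rec$events, paste0(path, ".events.tsv"), sep = "\t")
  invisible(path)
}

#' Read a recording from a text array container
#'
#' Counterpart of [write_recording()]. A missing event table yields an
#' empty event list with a warning; an `fs` mismatch between the sidecar
#' and an explicit `expect_fs` is an error.
#'
#' @param path Base path (without extension).
#' @param expect_fs Optional sampling rate to validate against the
#'   sidecar.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, expect_fs = NULL) {
  tsv <- paste0(path, ".tsv")
  side <- paste0(path, ".json")
  if (!file.exists(tsv) || !file.exists(side))
    stop(sprintf("recording container '%s' not found (.tsv/.json)", path))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(expect_fs) && !isTRUE(all.equal(meta$fs, expect_fs)))
    stop(sprintf("sampling-rate mismatch: sidecar %s, expected %s",
                 meta$fs, expect_fs))
  dt <- data.table::fread(tsv, sep = "\t")
  if (!identical(names(dt), as.character(meta$channel_labels)))
    stop("channel labels in sidecar and sample matrix disagree")
  evf <- paste0(path, ".events.tsv")
  events <- if (file.exists(evf)) {
    as.data.frame(data.table::fread(evf, sep = "\t",
                                    colClasses = list(character = c("class", "condition"))))
  } else {
    warning("no event table found; loading with empty events")
    empty_events()
  }
  eeg_recording(t(as.matrix(dt)), meta$fs, meta$channel_labels, events)
}

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations of a full simulated session:
#' synthesis, tracking, scheduling, evaluation, spectral analysis and
#' classification. The condition selects the stimulation mode: `"RPS"` /
#' `"FPS"` gate on the rising / falling interval, `"CVS"` is open-loop
#' (no phase gating; the continuous waveform is synthesized instead),
#' `"PMI"` delivers no stimulation.
#'
#' @param condition One of `"PMI"`, `"CVS"`, `"RPS"`, `"FPS"`.
#' @param synth A [synth_config()] (its condition is overridden).
#' @param tracker_args,schedule_args,classify_args Named lists of
#'   overrides for the respective stages.
#' @param channel Tracked channel (default `"C4"`).
#' @param seed Master seed for every stage; defaults to the synth
#'   config's seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(condition = c("FPS", "RPS", "CVS", "PMI"),
                       synth = synth_config(), tracker_args = list(),
                       schedule_args = list(), classify_args = list(),
                       channel = "C4", seed = synth$seed) {
  condition <- match.arg(condition)
  synth$condition <- condition
  synth$seed <- as.integer(seed)
  structure(list(condition = condition, synth = synth,
                 tracker_args = tracker_args,
                 schedule_args = schedule_args,
                 classify_args = classify_args,
                 channel = channel, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full closed-loop simulation pipeline
#'
#' simulate -> track -> schedule -> evaluate -> ERSP -> classify, as
#' selected by the condition; writes the event table, PLV report, ERSP
#' maps (C3/C4) and cross-validation report under `out_dir`, each
#' stamped with the configuration hash and seed.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if missing); NULL to skip
#'   writing files.
#' @param stages Subset of `c("track", "evaluate", "ersp", "classify")`
#'   to run after simulation.
#' @return List with the recording, estimates, events, PLV report, ERSP
#'   maps and CV report (NULL for skipped stages).
#' @export
run_pipeline <- function(cfg, out_dir = NULL,
                         stages = c("track", "evaluate", "ersp",
                                    "classify")) {
  stopifnot(inherits(cfg, "run_config"))
  hash <- config_hash(cfg)
  stamp <- list(config_hash = hash, seed = cfg$seed,
                condition = cfg$condition)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rec <- generate_session(cfg$synth)
  trial_len <- cfg$synth$trial_len
  tw <- cfg$synth$task_window
  closed_loop <- cfg$condition %in% c("RPS", "FPS")

  estimates <- NULL; events <- NULL; plv_rep <- NULL
  if ("track" %in% stages && cfg$condition != "PMI") {
    tcfg <- do.call(tracker_config, c(list(fs = rec$fs), cfg$tracker_args))
    estimates <- track_stream(rec, cfg$channel, tcfg)
  }
  if (closed_loop && !is.null(estimates)) {
    iv <- if (cfg$condition == "RPS") rising_interval() else
      falling_interval()
    wins <- cbind(rec$events$onset_sample / rec$fs + tw[1],
                  rec$events$onset_sample / rec$fs + tw[2])
    events <- do.call(schedule,
                      c(list(estimates = estimates, iv = iv,
                             mode = cfg$condition, task_windows = wins),
                        cfg$schedule_args))
  } else {
    events <- structure(
      data.frame(onset = numeric(0), duration = numeric(0),
                 amplitude_factor = numeric(0), mode = character(0),
                 realized_phase = numeric(0)),
      class = c("stimulus_events", "data.frame"))
  }

  realized <- NULL
  if ("evaluate" %in% stages && !is.null(estimates)) {
    ph <- hilbert_phase(get_channel(rec, cfg$channel), rec$fs)
    k <- pmin(pmax(round(estimates$t * rec$fs) + 1, 1), n_samples(rec))
    plv_rep <- plv(estimates$phi, ph[k])
    if (nrow(events) > 0)
      realized <- realized_stimulus_phases(events, rec, cfg$channel)
  }

  ersp_maps <- NULL
  if ("ersp" %in% stages) {
    rec_car <- car_reference(rec)
    ersp_maps <- lapply(c(C3 = "C3", C4 = "C4"), function(ch) {
      ep <- epoch_channel(rec_car, ch, span = c(0, min(9, trial_len)),
                          classes = "MI")
      ersp(ep$trials, rec$fs, channel = ch)
    })
  }

  cv_rep <- NULL
  if ("classify" %in% stages) {
    rec_car <- car_reference(rec)
    ep <- epoch_for_classification(rec_car, task_start = tw[1])
    cv_rep <- do.call(crossvalidate,
                      c(list(epochs = ep, seed = cfg$seed),
                        cfg$classify_args))
  }

  if (!is.null(out_dir)) {
    ev_out <- if (!is.null(realized)) realized$events else
      as.data.frame(events)
    ev_out$config_hash <- hash; ev_out$seed <- cfg$seed
    data.table::fwrite(ev_out, file.path(out_dir, "events.tsv"),
                       sep = "\t")
    if (!is.null(plv_rep))
      jsonlite::write_json(c(stamp, unclass(plv_rep)),
                           file.path(out_dir, "plv.json"),
                           auto_unbox = TRUE, digits = NA)
    if (!is.null(ersp_maps))
      for (ch in names(ersp_maps))
        write_ersp(ersp_maps[[ch]],
                   file.path(out_dir, sprintf("ersp_%s.tsv", ch)))
    if (!is.null(cv_rep))
      jsonlite::write_json(
        c(stamp, list(mean_accuracy = cv_rep$mean_accuracy,
                      repeat_means = cv_rep$repeat_means,
                      fold_accuracies = cv_rep$fold_accuracies)),
        file.path(out_dir, "cv.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(stamp, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(recording = rec, estimates = estimates, events = events,
       plv = plv_rep, realized = realized, ersp = ersp_maps,
       cv = cv_rep, config_hash = hash)
}
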