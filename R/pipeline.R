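# End-to-end orchestration: screen -> filter -> normalize -> IEM ->
# delineate -> featurize, per non-overlapping 4-s window.  Streaming-replay
# mode feeds the same per-window computation complete 4-s chunks
# sequentially, so interior windows yield identical landmarks by
# construction; it exists to exercise the chunked interface a live monitor
# source would attach to.

#' Pipeline configuration
#'
#' Collects every stage's tunables in one list; all defaults follow the
#' recorded-mode analysis conventions (4-s windows, 4th-order 16 Hz
#' Butterworth, 25-sample Savitzky-Golay window at 256 Hz, beta = 0.1).
#'
#' @param window_seconds Analysis window length (s).
#' @param butter_cutoff_hz,butter_order Low-pass filter settings.
#' @param screen_min_peaks,screen_max_peaks,screen_percentile Artifact
#'   screening settings.
#' @param iem An [iem_params()] list (`sg_window = NULL` scales the default
#'   with the record's sampling rate).
#' @param landmarks A [landmark_params()] list.
#' @return A list of class `run_config`.
#' @export
run_config <- function(window_seconds = 4,
                       butter_cutoff_hz = 16, butter_order = 4,
                       screen_min_peaks = 3L, screen_max_peaks = 10L,
                       screen_percentile = 75,
                       iem = NULL, landmarks = landmark_params()) {
  structure(list(window_seconds = window_seconds,
                 butter_cutoff_hz = butter_cutoff_hz,
                 butter_order = butter_order,
                 screen_min_peaks = screen_min_peaks,
                 screen_max_peaks = screen_max_peaks,
                 screen_percentile = screen_percentile,
                 iem = iem, landmarks = landmarks),
            class = "run_config")
}

# delineate one preprocessed window; returns cycles with window-absolute
# start_index attached (cycles' indices stay window-relative)
.process_window <- function(norm, fs, cfg) {
  iemp <- cfg$iem %||% iem_params(sg_window = scale_sg_window(fs))
  dec <- iem_decompose(norm, iemp)
  cycles <- delineate_cycles(dec$nsts, fs, cfg$landmarks, signal = norm)
  list(decomposition = dec, cycles = cycles)
}

#' Run the full landmark-detection and featurization pipeline
#'
#' @param record A [waveform_record()].
#' @param mode `"recorded"` processes all windows of the record;
#'   `"stream_replay"` replays the record as sequential complete
#'   `window_seconds` chunks through the identical per-window computation.
#' @param config A [run_config()].
#' @param extract_features Compute the 852-feature table (slowest stage);
#'   set `FALSE` for landmark-only runs.
#' @return A list of class `pulsefeat_run`:
#'   * `landmarks` — annotation tibble (`landmark_type`, `sample_index`,
#'     record-absolute) plus per-cycle table `cycles` with window ids;
#'   * `features` — one row per cycle (metadata + 852 feature columns), or
#'     `NULL`;
#'   * `vitals` — per-cycle SBP/DBP/MAP for ABP records (else `NULL`);
#'   * `report` — window tallies (total, accepted, rejected by reason,
#'     cycles detected/featurized).
#' @examples
#' syn <- synth_pulse_train(synth_params(duration_s = 8, seed = 7))
#' run <- featurize_record(syn$record, extract_features = FALSE)
#' run$report
#' @export
featurize_record <- function(record, mode = c("recorded", "stream_replay"),
                             config = run_config(), extract_features = TRUE) {
  mode <- match.arg(mode)
  fs <- wf_fs(record)
  kind <- wf_kind(record)
  cfg <- config

  windows <- cut_windows(record, cfg$window_seconds)
  if (mode == "stream_replay") {
    # replay: consume the record chunk by chunk, building the same window
    # table incrementally (complete chunks only, no partial emission)
    len <- round(cfg$window_seconds * fs)
    buf <- numeric(0)
    consumed <- 0L
    rows <- list()
    src <- record$value
    pos <- 1L
    chunk <- max(1L, round(fs))  # 1-s transport chunks
    while (pos <= length(src)) {
      upper <- min(length(src), pos + chunk - 1L)
      buf <- c(buf, src[pos:upper])
      pos <- upper + 1L
      while (length(buf) >= len) {
        rows[[length(rows) + 1L]] <- tibble(
          window_id = length(rows) + 1L,
          start_index = consumed + 1L,
          n = len, samples = list(buf[1:len])
        )
        buf <- buf[-(1:len)]
        consumed <- consumed + len
      }
    }
    windows <- if (length(rows)) bind_rows(rows) else windows[0, ]
  }

  pre <- preprocess_windows(windows, fs,
                            cutoff = cfg$butter_cutoff_hz,
                            order = cfg$butter_order,
                            min_peaks = cfg$screen_min_peaks,
                            max_peaks = cfg$screen_max_peaks,
                            percentile = cfg$screen_percentile)

  all_cycles <- list()
  feats <- list()
  vitals <- list()
  manifest <- if (extract_features) build_manifest(kind) else NULL
  for (i in seq_len(nrow(pre))) {
    if (!pre$accepted[i]) next
    norm <- pre$normalized[[i]]
    res <- .process_window(norm, fs, cfg)
    cyc <- res$cycles
    if (!nrow(cyc)) next
    cyc$window_id <- pre$window_id[i]
    cyc$start_index <- pre$start_index[i]
    all_cycles[[length(all_cycles) + 1L]] <- cyc
    raw <- pre$samples[[i]]
    for (k in seq_len(nrow(cyc))) {
      ctx <- cycle_context(norm, raw, cyc[k, ], fs, kind)
      meta <- tibble(window_id = pre$window_id[i],
                     cycle_id = cyc$cycle_id[k],
                     spo = cyc$spo[k] + pre$start_index[i] - 1L,
                     spp = cyc$spp[k] + pre$start_index[i] - 1L,
                     dn = cyc$dn[k] + pre$start_index[i] - 1L,
                     dpp = cyc$dpp[k] + pre$start_index[i] - 1L,
                     dpe = cyc$dpe[k] + pre$start_index[i] - 1L)
      if (extract_features) {
        fv <- extract_cycle_features(ctx, manifest)
        feats[[length(feats) + 1L]] <-
          dplyr::bind_cols(meta, as_tibble(as.list(fv)))
      }
      if (kind == "ABP") {
        vitals[[length(vitals) + 1L]] <- dplyr::bind_cols(meta[, 1:2],
                                                          compute_vitals(ctx))
      }
    }
  }

  cycles_tbl <- if (length(all_cycles)) bind_rows(all_cycles) else
    tibble(cycle_id = integer(), spo = integer(), spp = integer(),
           dn = integer(), dpp = integer(), dpe = integer(),
           window_id = integer(), start_index = integer())
  landmarks <- landmarks_to_record(cycles_tbl, n_record = nrow(record))

  reasons <- table(factor(pre$reason[!pre$accepted],
                          levels = c("nonpositive_values", "too_few_peaks",
                                     "too_many_peaks")))
  report <- tibble(
    windows_total = nrow(pre),
    windows_accepted = sum(pre$accepted),
    windows_rejected = sum(!pre$accepted),
    rejected_nonpositive = as.integer(reasons[["nonpositive_values"]]),
    rejected_too_few_peaks = as.integer(reasons[["too_few_peaks"]]),
    rejected_too_many_peaks = as.integer(reasons[["too_many_peaks"]]),
    cycles_detected = nrow(cycles_tbl),
    cycles_featurized = length(feats)
  )

  structure(list(
    landmarks = landmarks,
    cycles = cycles_tbl,
    features = if (extract_features && length(feats)) bind_rows(feats)
    else if (extract_features) NULL else NULL,
    vitals = if (length(vitals)) bind_rows(vitals) else NULL,
    report = report,
    mode = mode, fs = fs, kind = kind
  ), class = "pulsefeat_run")
}

#' @export
print.pulsefeat_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("pulsefeat run (%s): %d/%d windows accepted, %d cycles detected\n",
              x$mode, r$windows_accepted, r$windows_total, r$cycles_detected))
  invisible(x)
}

#' @export
glance.pulsefeat_run <- function(x, ...) x$report

#' Desk-scale landmark-recovery benchmark on the synthetic corpus
#'
#' Generates `n_windows` independent 4-s synthetic windows with heart rates
#' drawn uniformly from `hr_range`, runs the detection pipeline on each,
#' and pools true/false positives per landmark type against the analytic
#' ground truth at the `tol_ms` tolerance.
#'
#' @param n_windows Number of 4-s windows.
#' @param hr_range Heart-rate range (bpm), sampled uniformly.
#' @param noise_frac Additive white-noise standard deviation as a fraction
#'   of the systolic amplitude (0 = clean).
#' @param drift_amp Drift amplitude passed to the generator.
#' @param fs Sampling rate (Hz).
#' @param tol_ms Matching tolerance (ms).
#' @param seed Base seed; window `i` uses `seed + i`.
#' @return A tibble of pooled per-landmark counts and metrics (from
#'   [compute_metrics()]), with attribute `n_windows`.
#' @export
landmark_benchmark <- function(n_windows = 200, hr_range = c(50, 110),
                               noise_frac = 0, drift_amp = 0, fs = 256,
                               tol_ms = 8, seed = 1L) {
  set.seed(seed)
  hrs <- runif(n_windows, hr_range[1], hr_range[2])
  cfg <- run_config()
  totals <- NULL
  for (i in seq_len(n_windows)) {
    p <- synth_params(fs = fs, duration_s = 4, heart_rate_bpm = hrs[i],
                      noise_sd = noise_frac * 40, drift_amp = drift_amp,
                      seed = seed + i)
    syn <- synth_pulse_train(p)
    run <- featurize_record(syn$record, config = cfg,
                            extract_features = FALSE)
    cnt <- match_landmarks(run$landmarks, syn$truth, fs, tol_ms = tol_ms)
    totals <- if (is.null(totals)) cnt else {
      m <- totals
      m$tp <- m$tp + cnt$tp; m$fp <- m$fp + cnt$fp; m$fn <- m$fn + cnt$fn
      m$n_reference <- m$n_reference + cnt$n_reference
      m$n_detected <- m$n_detected + cnt$n_detected
      m
    }
  }
  out <- compute_metrics(totals)
  attr(out, "n_windows") <- n_windows
  out
}
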