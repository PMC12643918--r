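# Tolerance-based scoring of detected landmarks against reference marks.
#
# A detection counts as a true positive when it falls within the tolerance
# (default +/-8 ms, i.e. 2 samples at 256 Hz) of an as-yet-unmatched
# reference mark; matching is greedy nearest-neighbour and one-to-one.

#' Match detected landmarks against reference annotations
#'
#' @param detected,reference Annotation tibbles (`landmark_type`,
#'   `sample_index`) on the same record and sampling rate.
#' @param fs Sampling rate in Hz.
#' @param tol_ms Matching tolerance in milliseconds (total half-width);
#'   converted to samples as `round(tol_ms * fs / 1000)`.
#' @param types Landmark types to score. The diastolic endpoint coincides
#'   with the next cycle's onset, so `DPE` is excluded by default.
#' @return A tibble with one row per landmark type: `landmark_type`, `tp`,
#'   `fp`, `fn`, `n_reference`, `n_detected`.
#' @export
match_landmarks <- function(detected, reference, fs, tol_ms = 8,
                            types = c("SPO", "SPP", "DN", "DPP")) {
  if (fs <= 0) abort("`fs` must be > 0.")
  tol <- round(tol_ms * fs / 1000)
  rows <- map(types, function(ty) {
    det <- sort(detected$sample_index[detected$landmark_type == ty])
    ref <- sort(reference$sample_index[reference$landmark_type == ty])
    used <- rep(FALSE, length(ref))
    tp <- 0L
    for (d in det) {
      if (!length(ref)) break
      cand <- which(!used)
      if (!length(cand)) break
      j <- cand[which.min(abs(ref[cand] - d))]
      if (abs(ref[j] - d) <= tol) {
        used[j] <- TRUE
        tp <- tp + 1L
      }
    }
    tibble(landmark_type = ty, tp = tp,
           fp = length(det) - tp, fn = length(ref) - tp,
           n_reference = length(ref), n_detected = length(det))
  })
  bind_rows(rows)
}

#' Detector performance metrics from TP/FP/FN counts
#'
#' Sensitivity `SE = TP/(TP+FN)`, positive predictive value
#' `PPV = TP/(TP+FP)`, `F1 = 2*SE*PPV/(SE+PPV)` and the error rate
#' `ER = (FP+FN)/(TP+FP)`. The error rate's asymmetric denominator is used
#' verbatim as printed in the field; set `symmetric_er = TRUE` for the
#' `(TP+FP+FN)`-denominator diagnostic alternative.
#'
#' @param counts Tibble with columns `tp`, `fp`, `fn` (e.g. from
#'   [match_landmarks()]); other columns are carried through.
#' @param symmetric_er Use `(FP+FN)/(TP+FP+FN)` instead of the printed
#'   asymmetric denominator.
#' @return `counts` with added columns `se`, `ppv`, `f1`, `er` (fractions
#'   in `[0, 1]`; `NaN` with a warning when a denominator is zero).
#' @export
compute_metrics <- function(counts, symmetric_er = FALSE) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  se  <- ifelse(tp + fn > 0, tp / (tp + fn), NaN)
  ppv <- ifelse(tp + fp > 0, tp / (tp + fp), NaN)
  f1  <- ifelse(is.finite(se) & is.finite(ppv) & (se + ppv) > 0,
                2 * se * ppv / (se + ppv), NaN)
  er_den <- if (symmetric_er) tp + fp + fn else tp + fp
  er <- ifelse(er_den > 0, (fp + fn) / er_den, NaN)
  if (any(!is.finite(se)) || any(!is.finite(ppv)) || any(!is.finite(er))) {
    warn("Undefined metric denominator (no detections and/or no references); reported as NaN.")
  }
  mutate(counts, se = se, ppv = ppv, f1 = f1, er = er)
}

#' Bland-Altman agreement between reference and detected landmark times
#'
#' Differences are `detected - reference` (seconds); bias is their mean and
#' the limits of agreement are `bias +/- 1.96 * sd` (sample sd, n-1).
#'
#' @param pairs A data frame with columns `reference_time_s` and
#'   `detected_time_s` (at least 2 rows).
#' @return An object of class `bland_altman` with `tidy()`, `glance()` and
#'   `autoplot()` methods; fields `n`, `bias`, `sd`, `loa_lower`,
#'   `loa_upper` and the per-pair table.
#' @export
bland_altman <- function(pairs) {
  if (!all(c("reference_time_s", "detected_time_s") %in% names(pairs))) {
    abort("`pairs` needs columns reference_time_s, detected_time_s.")
  }
  if (nrow(pairs) < 2L) abort("Bland-Altman needs at least 2 pairs.")
  d <- pairs$detected_time_s - pairs$reference_time_s
  m <- (pairs$detected_time_s + pairs$reference_time_s) / 2
  bias <- mean(d); s <- sd(d)
  structure(list(
    n = nrow(pairs), bias = bias, sd = s,
    loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
    pairs = tibble(mean_time_s = m, difference_s = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: n = %d, bias = %.4g s, LoA = [%.4g, %.4g] s\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd = x$sd,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$mean_time_s, y = .data$difference_s)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of reference and detected time (s)",
                  y = "detected - reference (s)")
}

#' Evaluate a detector against reference marks on one record
#'
#' Convenience wrapper: matches landmarks, computes metrics and pairs up
#' matched marks for Bland-Altman analysis.
#'
#' @inheritParams match_landmarks
#' @return A list with `counts` (metrics tibble) and `bland_altman` (object
#'   or `NULL` when fewer than 2 matched pairs exist).
#' @export
evaluate_detection <- function(detected, reference, fs, tol_ms = 8,
                               types = c("SPO", "SPP", "DN", "DPP")) {
  counts <- compute_metrics(match_landmarks(detected, reference, fs,
                                            tol_ms = tol_ms, types = types))
  tol <- round(tol_ms * fs / 1000)
  pair_rows <- list()
  for (ty in types) {
    det <- sort(detected$sample_index[detected$landmark_type == ty])
    ref <- sort(reference$sample_index[reference$landmark_type == ty])
    used <- rep(FALSE, length(ref))
    for (d in det) {
      cand <- which(!used)
      if (!length(cand)) break
      j <- cand[which.min(abs(ref[cand] - d))]
      if (abs(ref[j] - d) <= tol) {
        used[j] <- TRUE
        pair_rows[[length(pair_rows) + 1L]] <- tibble(
          landmark_type = ty,
          reference_time_s = (ref[j] - 1) / fs,
          detected_time_s = (d - 1) / fs
        )
      }
    }
  }
  pairs <- if (length(pair_rows)) bind_rows(pair_rows) else
    tibble(landmark_type = character(), reference_time_s = double(),
           detected_time_s = double())
  ba <- if (nrow(pairs) >= 2L) bland_altman(pairs) else NULL
  list(counts = counts, pairs = pairs, bland_altman = ba)
}

#' Restrict reference cycles to single analysis windows
#'
#' A windowed detector can only delineate cycles wholly contained in one
#' analysis window: cycles straddling a window cut, starting at its very
#' edge, or ending too close to its end are invisible to it by
#' construction. This mirrors the per-window annotation protocol used when
#' scoring detectors on continuous records.
#'
#' @param cycles Per-cycle tibble with `spo`, `dpe` (record-absolute
#'   indices), e.g. the synthetic generator's `cycles`.
#' @param window_seconds Analysis window length (s).
#' @param fs Sampling rate (Hz).
#' @param start_margin_s,end_margin_s Minimum distance of the cycle onset
#'   from the window start and of the endpoint from the window end (s).
#' @return The subset of `cycles` evaluable within single windows.
#' @export
cycles_in_windows <- function(cycles, window_seconds = 4, fs = 256,
                              start_margin_s = 0.2, end_margin_s = 0.2) {
  if (!nrow(cycles)) return(cycles)
  len <- round(window_seconds * fs)
  w_spo <- (cycles$spo - 1L) %/% len
  w_dpe <- (cycles$dpe - 1L) %/% len
  spo_rel <- cycles$spo - w_spo * len
  dpe_rel <- cycles$dpe - w_dpe * len
  keep <- w_spo == w_dpe &
    spo_rel > round(start_margin_s * fs) &
    dpe_rel <= len - round(end_margin_s * fs)
  cycles[keep, , drop = FALSE]
}
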