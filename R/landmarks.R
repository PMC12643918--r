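# Cardiac-cycle delineation on the non-stationary (NSTS) component.
#
# Sign conditions: the peaks taken as SPP and DPP must have NSTS value > 0;
# the valleys taken as SPO, DN and DPE must have NSTS value < 0.
# Separation conditions: DN must be at least `min_separation_s` after SPP,
# and DPP at least `min_separation_s` before DPE.

#' Delineation parameters
#'
#' @param min_separation_s Minimum separation between SPP and DN, and
#'   between DPP and DPE, in seconds. Default 0.1 s (25 samples at 256 Hz;
#'   converted with `floor(min_separation_s * fs)`).
#' @param min_cycle_s,max_cycle_s Physiologic cardiac-cycle length bounds in
#'   seconds (defaults 0.27 and 2.0, roughly 30-220 bpm).
#' @param spp_frac Fraction of the upper-quartile positive-peak amplitude a
#'   positive NSTS peak must reach to be a systolic-peak candidate;
#'   separates systolic from the smaller diastolic (reflection) peaks.
#' @return A list of class `landmark_params`.
#' @export
landmark_params <- function(min_separation_s = 0.1,
                            min_cycle_s = 0.27, max_cycle_s = 2.0,
                            spp_frac = 0.6) {
  if (min_separation_s <= 0) abort("`min_separation_s` must be > 0.")
  if (min_cycle_s >= max_cycle_s) abort("`min_cycle_s` must be < `max_cycle_s`.")
  structure(list(min_separation_s = min_separation_s,
                 min_cycle_s = min_cycle_s, max_cycle_s = max_cycle_s,
                 spp_frac = spp_frac),
            class = "landmark_params")
}

#' Find signed extrema of a signal
#'
#' All strict local maxima and minima in index order; plateaus collapse to
#' their first index; the boundary samples are never extrema.
#'
#' @param x Numeric vector (typically an NSTS component).
#' @return A tibble with columns `index`, `value`, `polarity`
#'   (`"peak"`/`"valley"`).
#' @export
find_signed_extrema <- function(x) {
  if (!length(x)) abort("`x` must be non-empty.")
  pk <- local_extrema_idx(x, "max")
  vl <- local_extrema_idx(x, "min")
  out <- tibble(
    index = c(pk, vl),
    value = x[c(pk, vl)],
    polarity = rep(c("peak", "valley"), c(length(pk), length(vl)))
  )
  arrange(out, .data$index)
}

#' Delineate cardiac cycles on an NSTS component
#'
#' Scans the NSTS left to right. Systolic peaks anchor the cycles:
#' positive peaks that dominate the positive-peak amplitude distribution,
#' spaced by at least the minimum cycle length. Each cycle's SPO is the
#' nearest negative valley before its systolic peak; the DPE is the next
#' cycle's SPO (with a period-based fallback for the final cycle). The DN
#' is the first negative valley at least `min_separation_s` after the SPP;
#' the DPP is the first positive peak after the DN, at least
#' `min_separation_s` before the DPE (absent DPP is tolerated and reported
#' as `NA`). Cycles missing SPO, SPP, DN or DPE, with out-of-bounds
#' length, or ending too close to the window edge are dropped.
#'
#' When the filtered, normalized window is supplied as `signal`, each
#' landmark identified on the NSTS is refined to the corresponding strict
#' local extremum of the waveform itself within a small radius (under half
#' the separation distance, so the ordering cannot change). The NSTS
#' decides *which* oscillations are landmarks — its role is exposing them,
#' notably for weak notches — while the waveform carries their exact
#' temporal position.
#'
#' @param nsts Numeric vector from [iem_decompose()] (`$nsts`).
#' @param fs Sampling rate in Hz.
#' @param params A [landmark_params()] list.
#' @param signal Optional filtered normalized window (same length as
#'   `nsts`) used to refine landmark positions.
#' @return A tibble with one row per complete cycle: `cycle_id`, `spo`,
#'   `spp`, `dn`, `dpp` (may be `NA`), `dpe` (1-based sample indices within
#'   `nsts`).
#' @export
delineate_cycles <- function(nsts, fs, params = landmark_params(),
                             signal = NULL) {
  empty <- tibble(cycle_id = integer(), spo = integer(), spp = integer(),
                  dn = integer(), dpp = integer(), dpe = integer())
  if (fs <= 0) abort("`fs` must be > 0.")
  min_sep   <- floor(params$min_separation_s * fs)
  min_cycle <- round(params$min_cycle_s * fs)
  max_cycle <- round(params$max_cycle_s * fs)

  ex <- find_signed_extrema(nsts)
  # extrema closer than the separation distance to a window edge can never
  # satisfy the separation conditions and are unreliable (envelope edge
  # effects); drop them up front
  ex <- ex[ex$index > min_sep & ex$index <= length(nsts) - min_sep, ]
  peaks   <- ex[ex$polarity == "peak"   & ex$value > 0, ]
  valleys <- ex[ex$polarity == "valley" & ex$value < 0, ]
  if (nrow(peaks) < 1L || nrow(valleys) < 2L) return(empty)

  # systolic peaks anchor the cycles: positive peaks reaching spp_frac of
  # the upper quartile of positive-peak amplitudes, spaced by at least the
  # minimum cycle length (taller peak wins). When the waveform is
  # available, a candidate must also reach the window's upper amplitude
  # quartile there -- systolic peaks top the pulse, diastolic peaks do not
  # (the same separation the artifact screen relies on).
  spp_thr <- params$spp_frac *
    unname(quantile(peaks$value, 0.75, type = 7))
  cand <- peaks[peaks$value >= spp_thr, ]
  if (!is.null(signal) && nrow(cand)) {
    amp_thr <- unname(quantile(signal, 0.75, type = 7))
    cand <- cand[signal[cand$index] > amp_thr, ]
  }
  keep <- rep(TRUE, nrow(cand))
  ord <- order(-cand$value)
  for (i in ord) {
    if (!keep[i]) next
    close_by <- abs(cand$index - cand$index[i]) < min_cycle &
      seq_len(nrow(cand)) != i
    keep[close_by & cand$value <= cand$value[i]] <- FALSE
  }
  spps <- sort(cand$index[keep])
  if (!length(spps)) return(empty)
  est_period <- if (length(spps) >= 2L) median(diff(spps)) else NA_real_

  # SPO of each cycle: nearest negative valley before its systolic peak;
  # the DPE is the next cycle's SPO (the shared boundary)
  spo_of <- vapply(spps, function(s) {
    prev <- valleys$index[valleys$index < s]
    if (length(prev)) prev[length(prev)] else NA_integer_
  }, integer(1))

  # cycles whose endpoint falls this close to the window edge are dropped:
  # the NSTS there lacks the next upstroke and is not trustworthy
  edge_keep <- length(nsts) - round(0.185 * fs)

  cycles <- list()
  for (k in seq_along(spps)) {
    spo <- spo_of[k]; spp <- spps[k]
    if (is.na(spo)) next
    dpe <- if (k < length(spps)) spo_of[k + 1L] else NA_integer_
    if (!is.na(dpe) && dpe <= spp) dpe <- NA_integer_
    if (!is.na(dpe) && !is.na(est_period) &&
        (dpe - spo < 0.6 * est_period)) dpe <- NA_integer_
    if (is.na(dpe)) {
      # fallback: endpoint is the deepest negative valley one period after
      # this onset (within beat-to-beat variation bounds)
      if (is.na(est_period)) next
      win <- valleys[valleys$index > spp &
                       valleys$index >= spo + 0.75 * est_period &
                       valleys$index <= spo + 1.35 * est_period, ]
      if (!nrow(win)) next
      dpe <- win$index[which.min(win$value)]
    }
    len <- dpe - spo
    if (len < min_cycle || len > max_cycle) next
    if (!is.na(est_period) && (len < 0.6 * est_period || len > 1.6 * est_period)) next
    if (dpe > edge_keep) next
    # DN: first negative valley >= min_sep after SPP, before DPE
    dn_cand <- valleys[valleys$index >= spp + min_sep & valleys$index < dpe, ]
    if (!nrow(dn_cand)) next
    dn <- dn_cand$index[1]
    # DPP: first positive peak after DN, at least min_sep before DPE and
    # within the diastolic-wave region (pre-onset rebound wiggles are not
    # diastolic peaks)
    dpp_lim <- if (is.na(est_period)) dpe - min_sep else
      min(dpe - min_sep, dn + 0.35 * est_period)
    dpp_cand <- peaks[peaks$index > dn & peaks$index <= dpp_lim, ]
    dpp <- if (nrow(dpp_cand)) dpp_cand$index[1] else NA_integer_
    if (!(spo < spp && spp < dn && dn < dpe)) next
    cycles[[length(cycles) + 1L]] <- tibble(
      spo = as.integer(spo), spp = as.integer(spp), dn = as.integer(dn),
      dpp = as.integer(dpp), dpe = as.integer(dpe)
    )
  }
  if (!length(cycles)) return(empty)
  out <- bind_rows(cycles)

  if (!is.null(signal)) {
    r <- min(floor(min_sep / 2), round(0.05 * fs))
    snap_sig <- function(i, dir) {
      if (is.na(i)) return(NA_integer_)
      lo <- max(1L, i - r); hi <- min(length(signal), i + r)
      cand <- local_extrema_idx(signal[lo:hi], dir) + lo - 1L
      if (!length(cand)) return(as.integer(i))
      as.integer(cand[which.min(abs(cand - i))])
    }
    # boundaries are shared between adjacent cycles: refine each once,
    # then align them jointly against the window's ensemble-average onset
    # shape (noise on the flat diastolic foot averages out across beats)
    bounds <- vapply(sort(unique(c(out$spo, out$dpe))),
                     function(b) snap_sig(b, "min"), integer(1))
    bounds_ref <- refine_boundaries(signal, bounds, fs)
    bmap <- stats::setNames(bounds_ref,
                            as.character(sort(unique(c(out$spo, out$dpe)))))
    out <- out |>
      mutate(spo = unname(bmap[as.character(.data$spo)]),
             dpe = unname(bmap[as.character(.data$dpe)]),
             spp = map_int(.data$spp, snap_sig, dir = "max"),
             dn  = map_int(.data$dn, snap_sig, dir = "min"),
             dpp = map_int(.data$dpp, snap_sig, dir = "max")) |>
      filter(.data$spo < .data$spp, .data$spp < .data$dn,
             .data$dn < .data$dpe,
             is.na(.data$dpp) | (.data$dpp > .data$dn & .data$dpp < .data$dpe))
    if (!nrow(out)) return(empty)
  }

  mutate(out, cycle_id = row_number(), .before = 1)
}

#' Convert window-relative cycle landmarks to record-absolute annotations
#'
#' Offsets each landmark index by the window's start, merges across windows,
#' sorts per landmark type and deduplicates (adjacent windows can both
#' report the shared boundary DPE/SPO index).
#'
#' @param cycles Tibble from [delineate_cycles()] (one window), or a
#'   row-bound set with a `start_index` column per cycle.
#' @param start_index 1-based offset of the window in the parent record
#'   (ignored when `cycles` already has a `start_index` column).
#' @param n_record Optional record length for range validation.
#' @return Annotation tibble with columns `landmark_type`, `sample_index`.
#' @export
landmarks_to_record <- function(cycles, start_index = 1L, n_record = NULL) {
  if (!nrow(cycles)) {
    return(tibble(landmark_type = character(), sample_index = integer()))
  }
  offs <- if ("start_index" %in% names(cycles)) cycles$start_index else start_index
  long <- cycles |>
    mutate(.offset = offs - 1L) |>
    tidyr::pivot_longer(cols = c("spo", "spp", "dn", "dpp", "dpe"),
                        names_to = "landmark_type", values_to = "rel") |>
    filter(!is.na(.data$rel)) |>
    mutate(landmark_type = toupper(.data$landmark_type),
           sample_index = as.integer(.data$rel + .data$.offset)) |>
    select("landmark_type", "sample_index")
  if (!is.null(n_record) && nrow(long) &&
      (min(long$sample_index) < 1L || max(long$sample_index) > n_record)) {
    abort("Landmark index out of record range.")
  }
  long |>
    dplyr::distinct() |>
    arrange(.data$landmark_type, .data$sample_index)
}


# Joint refinement of cycle-boundary (onset) positions: build the ensemble
# average of the waveform around all boundaries, locate its foot minimum,
# and re-anchor every boundary at the lag that best aligns its segment with
# the template. Individual onset minima wander over the flat diastolic foot
# under noise; the ensemble average suppresses that noise by roughly the
# square root of the number of beats while the steep upstroke pins the lag.
refine_boundaries <- function(signal, bounds, fs, reach_s = 0.1,
                              max_lag = 4L) {
  if (length(bounds) < 3L) return(bounds)
  m <- round(reach_s * fs)
  usable <- bounds[bounds - m - max_lag >= 1L &
                     bounds + m + max_lag <= length(signal)]
  if (length(usable) < 3L) return(bounds)
  seg <- vapply(usable, function(b) signal[(b - m):(b + m)],
                numeric(2L * m + 1L))
  tmpl <- rowMeans(seg)
  # template foot: minimum near the centre of the averaged segment
  ctr <- m + 1L
  win <- max(1L, ctr - max_lag - 2L):min(length(tmpl), ctr + max_lag + 2L)
  foot <- win[which.min(tmpl[win])] - ctr
  vapply(bounds, function(b) {
    if (b - m - max_lag < 1L || b + m + max_lag > length(signal)) return(b)
    lags <- -max_lag:max_lag
    sse <- vapply(lags, function(d) {
      sum((signal[(b + d - m):(b + d + m)] - tmpl)^2)
    }, numeric(1))
    ref <- as.integer(b + lags[which.min(sse)] + foot)
    # the per-beat minimum is exact on clean signals; only defer to the
    # ensemble position when the two disagree beyond lag quantization
    if (abs(ref - b) <= 1L) b else ref
  }, integer(1))
}
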