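# Per-cycle feature manifest (852 named features in 15 families) and the
# matching extractor.
#
# The 25 exemplar amplitude/duration features carry their field-standard
# names (<kind>_AM_* / <kind>_D_*). Family memberships beyond those are
# generated by the explicit deterministic rules below; every printed
# per-family count is reproduced exactly:
#   amplitude 30, amplitude ratio 210, duration 10, duration ratio 46,
#   average 40, median 20, RMS 20, skewness 1, kurtosis 1, area 40,
#   area ratio 180, width 36, frequency 12, first derivative 28,
#   second derivative 178  ->  852 total.

# Table-3 amplitude features (order matters): value at `at` minus value at
# `wrt` ("Zero" = the normalized-window zero level)
.AMP15 <- tibble::tribble(
  ~stub,              ~at,   ~wrt,
  "AM_SPO_wrtZero",   "SPO", "Zero",
  "AM_SPP_wrtSPO",    "SPP", "SPO",
  "AM_SPP_wrtZero",   "SPP", "Zero",
  "AM_SPP_wrtDN",     "SPP", "DN",
  "AM_SPP_wrtDPP",    "SPP", "DPP",
  "AM_SPP_wrtDPE",    "SPP", "DPE",
  "AM_DN_wrtZero",    "DN",  "Zero",
  "AM_DN_wrtSPO",     "DN",  "SPO",
  "AM_DN_wrtDPE",     "DN",  "DPE",
  "AM_DPP_wrtZero",   "DPP", "Zero",
  "AM_DPP_wrtSPO",    "DPP", "SPO",
  "AM_DPP_wrtDN",     "DPP", "DN",
  "AM_DPP_wrtDPE",    "DPP", "DPE",
  "AM_DPE_wrtSPO",    "DPE", "SPO",
  "AM_DPE_wrtZero",   "DPE", "Zero"
)

# Table-3 duration features: time at `to` minus time at `from`
.DUR10 <- tibble::tribble(
  ~stub,            ~from, ~to,
  "D_SPO_wrtSPP",   "SPO", "SPP",
  "D_SPO_wrtDN",    "SPO", "DN",
  "D_SPO_wrtDPP",   "SPO", "DPP",
  "D_SPO_wrtDPE",   "SPO", "DPE",
  "D_SPP_wrtDN",    "SPP", "DN",
  "D_SPP_wrtDPP",   "SPP", "DPP",
  "D_SPP_wrtDPE",   "SPP", "DPE",
  "D_DN_wrtDPP",    "DN",  "DPP",
  "D_DN_wrtDPE",    "DN",  "DPE",
  "D_DPP_wrtDPE",   "DPP", "DPE"
)

# the 10 landmark-delimited segments (unordered pairs, within-cycle order)
.SEG10 <- tibble::tribble(
  ~x, ~y,
  "SPO", "SPP", "SPO", "DN", "SPO", "DPP", "SPO", "DPE",
  "SPP", "DN", "SPP", "DPP", "SPP", "DPE",
  "DN", "DPP", "DN", "DPE",
  "DPP", "DPE"
)
.SEG4 <- .SEG10[c(1, 5, 8, 10), ]  # consecutive segments

.WAVES <- c("a", "b", "c", "d", "e")
.RISE_H  <- seq(10, 90, by = 10)
.DECAY_H <- seq(10, 95, by = 5)
.FULL_H  <- seq(10, 90, by = 10)
.FD_STUBS <- c("FD_fundamental_hz", "FD_H1_mag", "FD_H2_mag", "FD_H3_mag",
               "FD_H2H1_ratio", "FD_H3H1_ratio", "FD_H3H2_ratio",
               "FD_centroid_hz", "FD_bandwidth_hz", "FD_rolloff85_hz",
               "FD_flatness", "FD_total_power")
.D1_STUBS <- c("D1_max", "D1_max_t", "D1_min", "D1_min_t",
               "D1_at_SPO", "D1_at_SPP", "D1_at_DN", "D1_at_DPP", "D1_at_DPE",
               "D1_max_over_min", "D1_mean", "D1_median", "D1_rms", "D1_sd",
               "D1_max_t_frac", "D1_min_t_frac",
               "D1_at_frac25", "D1_at_frac50", "D1_at_frac75",
               "D1_zero_crossings", "D1_pos_area", "D1_neg_area",
               "D1_max_dia", "D1_max_dia_t", "D1_range",
               "D1_skew", "D1_kurt", "D1_energy")

.ordered_pairs <- function(items) {
  out <- expand.grid(j = items, i = items, stringsAsFactors = FALSE)
  out <- out[out$i != out$j, c("i", "j")]
  # enumerate row-major: i fixed, j varies
  out <- out[order(match(out$i, items), match(out$j, items)), ]
  rownames(out) <- NULL
  out
}

.unordered_pairs <- function(items) {
  n <- length(items)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))[order(unlist(lapply(1:(n - 1), function(a) rep(a, n - a))))]
  # simpler explicit construction
  res <- do.call(rbind, lapply(seq_len(n - 1), function(a) {
    data.frame(i = items[a], j = items[(a + 1):n], stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

.seg_name <- function(x, y) paste0(x, "_", y)

# second-derivative wave stubs ----------------------------------------------
.d2_stubs <- function() {
  w <- .WAVES
  op_amp <- .ordered_pairs(w); op_t <- .ordered_pairs(w)
  segs <- .seg_name(.SEG4$x, .SEG4$y)
  c(
    paste0("D2_", w, "_amp"),                                      # 5
    paste0("D2_", w, "_t"),                                        # 5
    paste0("D2_", w, "_tfrac"),                                    # 5
    paste0("D2_", op_amp$i, "_over_", op_amp$j, "_amp"),           # 20
    paste0("D2_", op_t$i, "_over_", op_t$j, "_t"),                 # 20
    paste0("D2_", op_amp$i, "_minus_", op_amp$j, "_amp"),          # 20
    paste0("D2_", op_t$i, "_minus_", op_t$j, "_t"),                # 20
    paste0("D2_at_", c("SPO", "SPP", "DN", "DPP", "DPE")),         # 5
    c("D2_max", "D2_max_t", "D2_min", "D2_min_t"),                 # 4
    c("D2_mean", "D2_median", "D2_rms", "D2_sd", "D2_skew", "D2_kurt"), # 6
    paste0("D2_mean_SEG_", segs),                                  # 4
    paste0("D2_median_SEG_", segs),                                # 4
    paste0("D2_rms_SEG_", segs),                                   # 4
    paste0("D2_sd_SEG_", segs),                                    # 4
    paste0("D2_", w, "_amp_norm"),                                 # 5
    "D2_aging_index",                                              # 1
    paste0("D2_slope_", w[-5], "_", w[-1]),                        # 4
    paste0("D2_at_frac", seq(10, 90, 10)),                         # 9
    paste0("D2_energy_SEG_", segs),                                # 4
    "D2_zero_crossings",                                           # 1
    c("D2_pos_area", "D2_neg_area", "D2_abs_area"),                # 3
    c("D2_max_sys", "D2_max_sys_t", "D2_min_sys", "D2_min_sys_t",
      "D2_max_dia", "D2_max_dia_t", "D2_min_dia", "D2_min_dia_t"), # 8
    paste0("D2_", w, "_amp_rel"),                                  # 5
    paste0("D2_", w, "_t_wrtSPP"),                                 # 5
    paste0("D2_", w, "_t_wrtDN"),                                  # 5
    c("D2_at_frac25", "D2_at_frac75")                              # 2
  )
}

# catalog of (stub, family, definition) -- kind-independent, built once
.feature_catalog <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rows <- list()
    add <- function(stub, family, definition) {
      rows[[length(rows) + 1L]] <<- tibble(stub = stub, family = family,
                                           definition = definition)
    }
    # 1 amplitude (30)
    add(.AMP15$stub, "amplitude",
        paste0("Normalized amplitude at ", .AMP15$at, " minus level at ",
               .AMP15$wrt))
    add(paste0(.AMP15$stub, "_raw"), "amplitude",
        paste0("Raw-scale amplitude at ", .AMP15$at, " minus level at ",
               .AMP15$wrt))
    # 2 amplitude ratio (210)
    ap <- .ordered_pairs(.AMP15$stub)
    add(paste0("AMR_", sub("^AM_", "", ap$i), "_over_", sub("^AM_", "", ap$j)),
        "amplitude_ratio",
        paste0("Ratio of amplitude features ", ap$i, " / ", ap$j))
    # 3 duration (10)
    add(.DUR10$stub, "duration",
        paste0("Time from ", .DUR10$from, " to ", .DUR10$to, " (s)"))
    # 4 duration ratio (46)
    dp <- .unordered_pairs(.DUR10$stub)
    add(paste0("DR_", sub("^D_", "", dp$i), "_over_", sub("^D_", "", dp$j)),
        "duration_ratio",
        paste0("Ratio of duration features ", dp$i, " / ", dp$j))
    add("DR_SPD_over_DPD", "duration_ratio",
        "Systolic phase duration (SPO to DN) over diastolic phase duration (DN to DPE)")
    # 5 average (40)
    segs <- .seg_name(.SEG10$x, .SEG10$y)
    add(paste0("AVG_SEG_", segs), "average",
        paste0("Mean of the normalized signal over segment ", segs))
    add(paste0("AVG_SEG_", segs, "_raw"), "average",
        paste0("Mean of the raw signal over segment ", segs))
    add(paste0("AVG_D1_SEG_", segs), "average",
        paste0("Mean of the first derivative over segment ", segs))
    add(paste0("AVG_D2_SEG_", segs), "average",
        paste0("Mean of the second derivative over segment ", segs))
    # 6 median (20)
    add(paste0("MED_SEG_", segs), "median",
        paste0("Median of the normalized signal over segment ", segs))
    add(paste0("MED_D1_SEG_", segs), "median",
        paste0("Median of the first derivative over segment ", segs))
    # 7 RMS (20)
    add(paste0("RMS_SEG_", segs), "rms",
        paste0("Root mean square of the normalized signal over segment ", segs))
    add(paste0("RMS_D1_SEG_", segs), "rms",
        paste0("Root mean square of the first derivative over segment ", segs))
    # 8-9 skewness / kurtosis (1 + 1)
    add("SKEW_cycle", "skewness", "Skewness of the normalized cycle samples")
    add("KURT_cycle", "kurtosis", "Excess kurtosis of the normalized cycle samples")
    # 10 area (40)
    add(paste0("AREA_SEG_", segs), "area",
        paste0("Trapezoidal area of the normalized signal over segment ", segs))
    add(paste0("AREA_SEG_", segs, "_raw"), "area",
        paste0("Trapezoidal area of the raw signal over segment ", segs))
    add(paste0("AREA_ABSD1_SEG_", segs), "area",
        paste0("Trapezoidal area of |first derivative| over segment ", segs))
    add(paste0("AREA_ABSD2_SEG_", segs), "area",
        paste0("Trapezoidal area of |second derivative| over segment ", segs))
    # 11 area ratio (180)
    sp <- .ordered_pairs(segs)
    add(paste0("AR_", sp$i, "_over_", sp$j), "area_ratio",
        paste0("Ratio of normalized-signal areas ", sp$i, " / ", sp$j))
    add(paste0("AR_", sp$i, "_over_", sp$j, "_raw"), "area_ratio",
        paste0("Ratio of raw-signal areas ", sp$i, " / ", sp$j))
    # 12 width (36)
    add(paste0("WIDTH_RISE_", .RISE_H), "width",
        paste0("Systolic rise width: time from the ", .RISE_H,
               "% height crossing to SPP (s)"))
    add(paste0("WIDTH_DECAY_", .DECAY_H), "width",
        paste0("Decay width: time from SPP to the falling ", .DECAY_H,
               "% height crossing (s)"))
    add(paste0("WIDTH_FULL_", .FULL_H), "width",
        paste0("Pulse width at ", .FULL_H,
               "% height: falling minus rising crossing (s)"))
    # 13 frequency (12)
    add(.FD_STUBS, "frequency", c(
      "Fundamental frequency, 1 / cycle duration (Hz)",
      "Spectral magnitude at the fundamental",
      "Spectral magnitude at the 2nd harmonic",
      "Spectral magnitude at the 3rd harmonic",
      "Harmonic magnitude ratio H2/H1",
      "Harmonic magnitude ratio H3/H1",
      "Harmonic magnitude ratio H3/H2",
      "Spectral centroid (Hz)",
      "Spectral bandwidth around the centroid (Hz)",
      "85% spectral rolloff frequency (Hz)",
      "Spectral flatness (geometric/arithmetic mean of power)",
      "Total power (mean square of the mean-removed cycle)"))
    # 14 first derivative (28)
    add(.D1_STUBS, "first_derivative",
        paste0("First-derivative feature: ", .D1_STUBS))
    # 15 second derivative (178)
    d2 <- .d2_stubs()
    add(d2, "second_derivative",
        paste0("Second-derivative (a-e wave) feature: ", d2))
    cache <<- bind_rows(rows)
    cache
  }
})

#' Build the per-cycle feature manifest
#'
#' The deterministic catalogue of 852 named per-cycle features across the
#' 15 families (amplitude, amplitude ratio, duration, duration ratio,
#' average, median, RMS, skewness, kurtosis, area, area ratio, width,
#' frequency-domain, first derivative, second derivative). Feature names
#' are prefixed with the signal kind (`ABP_` or `PPG_`); the first 25
#' entries are the field-standard exemplar amplitude and duration features.
#'
#' @param kind `"ABP"` or `"PPG"`.
#' @return A tibble with columns `feature`, `family`, `definition`
#'   (852 rows).
#' @examples
#' m <- build_manifest("ABP")
#' nrow(m)             # 852
#' table(m$family)
#' @export
build_manifest <- function(kind = c("ABP", "PPG")) {
  kind <- match.arg(kind)
  cat_ <- .feature_catalog()
  tibble(feature = paste0(kind, "_", cat_$stub),
         family = cat_$family, definition = cat_$definition)
}

#' Write the manifest as a plain-text FEATURES.md listing
#'
#' @param path Output path.
#' @inheritParams build_manifest
#' @return `path`, invisibly.
#' @export
write_manifest_md <- function(path, kind = "ABP") {
  m <- build_manifest(kind)
  lines <- c("# pulsefeat per-cycle feature manifest", "",
             sprintf("%d features in %d families.", nrow(m),
                     length(unique(m$family))), "")
  for (fam in unique(m$family)) {
    sub <- m[m$family == fam, ]
    lines <- c(lines, sprintf("## %s (n = %d)", fam, nrow(sub)), "",
               sprintf("- `%s` — %s", sub$feature, sub$definition), "")
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Bundle one cardiac cycle for feature extraction
#'
#' @param normalized Normalized window samples (`[0,1]`).
#' @param raw Raw (pre-normalization) window samples, same length.
#' @param landmarks One row from [delineate_cycles()] (window-relative
#'   indices; `dpp` may be `NA`).
#' @param fs Sampling rate in Hz.
#' @param kind `"ABP"` or `"PPG"`.
#' @return A list of class `cycle_context`: cycle-span `norm`/`raw`
#'   vectors, relative landmark indices `lm` (spo = 1), `fs`, `kind`.
#' @export
cycle_context <- function(normalized, raw, landmarks, fs,
                          kind = c("ABP", "PPG")) {
  kind <- match.arg(kind)
  spo <- landmarks$spo; dpe <- landmarks$dpe
  if (is.na(spo) || is.na(dpe) || dpe <= spo) abort("Invalid landmark span.")
  if (dpe > length(normalized)) abort("Landmarks outside the window.")
  if (dpe - spo + 1L < 4L) abort("Cycle shorter than 4 samples.")
  lm <- c(SPO = 1L,
          SPP = as.integer(landmarks$spp - spo + 1L),
          DN  = as.integer(landmarks$dn - spo + 1L),
          DPP = as.integer(landmarks$dpp - spo + 1L),
          DPE = as.integer(dpe - spo + 1L))
  structure(list(norm = as.numeric(normalized[spo:dpe]),
                 raw = as.numeric(raw[spo:dpe]),
                 lm = lm, fs = fs, kind = kind),
            class = "cycle_context")
}

# central-difference derivatives (per second); endpoints one-sided
.deriv1 <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * fs
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

.deriv2 <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

.sg_smooth_safe <- function(x, fs) {
  w <- scale_sg_window(fs)
  n <- length(x)
  wmax <- if (n %% 2L == 0L) n - 1L else n - 2L
  w <- min(w, wmax)
  if (w < 5L) return(x)
  if (w %% 2L == 0L) w <- w - 1L
  as.numeric(signal::sgolayfilt(x, p = min(3L, w - 2L), n = w))
}

.seg_idx <- function(lm, x, y) {
  a <- lm[[x]]; b <- lm[[y]]
  if (is.na(a) || is.na(b) || b <= a) return(NULL)
  a:b
}

.trap_area <- function(v, fs) {
  if (length(v) < 2L) return(NA_real_)
  sum((v[-1] + v[-length(v)]) / 2) / fs
}

.rms <- function(v) sqrt(mean(v^2))

.safe_div <- function(a, b) ifelse(is.na(a) | is.na(b) | b == 0, NA_real_, a / b)

# crossing time (s, relative to cycle start) of level h; rising edge
# searches [1, spp] for the last upward crossing, falling edge searches
# [spp, n] for the first downward crossing; linear interpolation
.cross_time <- function(y, fs, h, spp, edge) {
  n <- length(y)
  if (edge == "rise") {
    if (spp < 2L) return(NA_real_)
    seg <- 1:spp
    below <- y[seg] <= h
    up <- which(below[-length(seg)] & !below[-1])
    if (!length(up)) return(NA_real_)
    i <- seg[up[length(up)]]
  } else {
    if (spp > n - 1L) return(NA_real_)
    seg <- spp:n
    above <- y[seg] >= h
    dn <- which(above[-length(seg)] & !above[-1])
    if (!length(dn)) return(NA_real_)
    i <- seg[dn[1]]
  }
  frac <- (h - y[i]) / (y[i + 1] - y[i])
  ((i - 1) + frac) / fs
}

# locate the a-e waves on the smoothed second derivative
.d2_waves <- function(d2s, lm) {
  spp <- lm[["SPP"]]
  n <- length(d2s)
  out <- stats::setNames(rep(NA_integer_, 5L), .WAVES)
  sys_end <- min(spp + 1L, n)
  a <- which.max(d2s[1:sys_end])
  out["a"] <- a
  pk <- local_extrema_idx(d2s, "max")
  vl <- local_extrema_idx(d2s, "min")
  cur <- a
  for (w in c("b", "c", "d", "e")) {
    pool <- if (w %in% c("b", "d")) vl else pk
    nxt <- pool[pool > cur]
    if (!length(nxt)) break
    cur <- nxt[1]
    out[w] <- cur
  }
  out
}

# compute all 852 stub values for one cycle, in catalog order
.compute_stub_values <- function(ctx) {
  lm <- ctx$lm; fs <- ctx$fs
  y <- ctx$norm; r <- ctx$raw
  n <- length(y)
  t_rel <- (seq_len(n) - 1) / fs
  vals <- function(sig, at) if (is.na(lm[[at]])) NA_real_ else sig[lm[[at]]]
  lv <- function(at) if (at == "Zero") 0 else vals(y, at)
  lv_raw <- function(at) if (at == "Zero") 0 else vals(r, at)
  lt <- function(at) if (is.na(lm[[at]])) NA_real_ else t_rel[lm[[at]]]

  d1 <- .deriv1(y, fs)
  d2 <- .deriv2(y, fs)
  d2s <- .sg_smooth_safe(d2, fs)

  out <- c()
  push <- function(names, values) {
    out[names] <<- as.numeric(values)
  }

  # amplitude
  amp_norm <- map_dbl(seq_len(nrow(.AMP15)),
                      function(i) lv(.AMP15$at[i]) - lv(.AMP15$wrt[i]))
  amp_raw <- map_dbl(seq_len(nrow(.AMP15)),
                     function(i) lv_raw(.AMP15$at[i]) - lv_raw(.AMP15$wrt[i]))
  push(.AMP15$stub, amp_norm)
  push(paste0(.AMP15$stub, "_raw"), amp_raw)
  # amplitude ratio
  ap <- .ordered_pairs(.AMP15$stub)
  av <- stats::setNames(amp_norm, .AMP15$stub)
  push(paste0("AMR_", sub("^AM_", "", ap$i), "_over_", sub("^AM_", "", ap$j)),
       .safe_div(av[ap$i], av[ap$j]))
  # duration
  dur <- map_dbl(seq_len(nrow(.DUR10)),
                 function(i) lt(.DUR10$to[i]) - lt(.DUR10$from[i]))
  push(.DUR10$stub, dur)
  # duration ratio
  dp <- .unordered_pairs(.DUR10$stub)
  dv <- stats::setNames(dur, .DUR10$stub)
  push(paste0("DR_", sub("^D_", "", dp$i), "_over_", sub("^D_", "", dp$j)),
       .safe_div(dv[dp$i], dv[dp$j]))
  spd <- lt("DN") - lt("SPO"); dpd <- lt("DPE") - lt("DN")
  push("DR_SPD_over_DPD", .safe_div(spd, dpd))
  # segment stats
  segs <- .seg_name(.SEG10$x, .SEG10$y)
  seg_stat <- function(sig, f) {
    map_dbl(seq_len(nrow(.SEG10)), function(i) {
      idx <- .seg_idx(lm, .SEG10$x[i], .SEG10$y[i])
      if (is.null(idx) || length(idx) < 2L) NA_real_ else f(sig[idx])
    })
  }
  push(paste0("AVG_SEG_", segs), seg_stat(y, mean))
  push(paste0("AVG_SEG_", segs, "_raw"), seg_stat(r, mean))
  push(paste0("AVG_D1_SEG_", segs), seg_stat(d1, mean))
  push(paste0("AVG_D2_SEG_", segs), seg_stat(d2, mean))
  push(paste0("MED_SEG_", segs), seg_stat(y, median))
  push(paste0("MED_D1_SEG_", segs), seg_stat(d1, median))
  push(paste0("RMS_SEG_", segs), seg_stat(y, .rms))
  push(paste0("RMS_D1_SEG_", segs), seg_stat(d1, .rms))
  # skewness / kurtosis
  push("SKEW_cycle", e1071::skewness(y))
  push("KURT_cycle", e1071::kurtosis(y))
  # area
  area_stat <- function(sig) {
    map_dbl(seq_len(nrow(.SEG10)), function(i) {
      idx <- .seg_idx(lm, .SEG10$x[i], .SEG10$y[i])
      if (is.null(idx)) NA_real_ else .trap_area(sig[idx], fs)
    })
  }
  a_norm <- area_stat(y); a_raw <- area_stat(r)
  push(paste0("AREA_SEG_", segs), a_norm)
  push(paste0("AREA_SEG_", segs, "_raw"), a_raw)
  push(paste0("AREA_ABSD1_SEG_", segs), area_stat(abs(d1)))
  push(paste0("AREA_ABSD2_SEG_", segs), area_stat(abs(d2)))
  # area ratio
  sp <- .ordered_pairs(segs)
  an <- stats::setNames(a_norm, segs); ar <- stats::setNames(a_raw, segs)
  push(paste0("AR_", sp$i, "_over_", sp$j), .safe_div(an[sp$i], an[sp$j]))
  push(paste0("AR_", sp$i, "_over_", sp$j, "_raw"), .safe_div(ar[sp$i], ar[sp$j]))
  # widths (on the cycle rescaled to [0,1])
  ymin <- min(y); ymax <- max(y)
  yr <- if (ymax > ymin) (y - ymin) / (ymax - ymin) else rep(NA_real_, n)
  spp_i <- lm[["SPP"]]
  rise_t <- map_dbl(.RISE_H, function(h) .cross_time(yr, fs, h / 100, spp_i, "rise"))
  dec_t <- map_dbl(.DECAY_H, function(h) .cross_time(yr, fs, h / 100, spp_i, "fall"))
  t_spp <- t_rel[spp_i]
  push(paste0("WIDTH_RISE_", .RISE_H), t_spp - rise_t)
  push(paste0("WIDTH_DECAY_", .DECAY_H), dec_t - t_spp)
  full_dec <- map_dbl(.FULL_H, function(h) .cross_time(yr, fs, h / 100, spp_i, "fall"))
  push(paste0("WIDTH_FULL_", .FULL_H), full_dec - rise_t[match(.FULL_H, .RISE_H)])
  # frequency domain
  xc <- y - mean(y)
  sp_mag <- Mod(fft(xc))
  nh <- floor(n / 2)
  mag <- sp_mag[2:(nh + 1)]
  freqs <- (1:nh) * fs / n
  f0 <- fs / n  # one cycle per record span = 1 / cycle duration
  hbin <- function(k) {
    i <- which.min(abs(freqs - k * f0))
    mag[i]
  }
  h1 <- hbin(1); h2 <- hbin(2); h3 <- hbin(3)
  centroid <- sum(freqs * mag) / sum(mag)
  bandwidth <- sqrt(sum((freqs - centroid)^2 * mag) / sum(mag))
  pwr <- mag^2
  rolloff <- freqs[which(cumsum(pwr) >= 0.85 * sum(pwr))[1]]
  flatness <- exp(mean(log(pwr + 1e-300))) / mean(pwr)
  push(.FD_STUBS, c(f0, h1, h2, h3,
                    .safe_div(h2, h1), .safe_div(h3, h1), .safe_div(h3, h2),
                    centroid, bandwidth, rolloff, flatness, mean(xc^2)))
  # first derivative
  i_max <- which.max(d1); i_min <- which.min(d1)
  dur_cyc <- t_rel[n]
  dn_i <- lm[["DN"]]
  dia <- if (!is.na(dn_i) && dn_i < n) dn_i:n else NULL
  d1_dia_max <- if (is.null(dia)) NA_real_ else max(d1[dia])
  d1_dia_max_t <- if (is.null(dia)) NA_real_ else t_rel[dia[which.max(d1[dia])]]
  zc <- sum(diff(sign(d1[d1 != 0])) != 0)
  at_frac <- function(sig, f) sig[max(1L, min(n, round(f * (n - 1)) + 1L))]
  push(.D1_STUBS, c(
    d1[i_max], t_rel[i_max], d1[i_min], t_rel[i_min],
    vals(d1, "SPO"), vals(d1, "SPP"), vals(d1, "DN"), vals(d1, "DPP"),
    vals(d1, "DPE"),
    .safe_div(d1[i_max], d1[i_min]),
    mean(d1), median(d1), .rms(d1), sd(d1),
    t_rel[i_max] / dur_cyc, t_rel[i_min] / dur_cyc,
    at_frac(d1, 0.25), at_frac(d1, 0.50), at_frac(d1, 0.75),
    zc, .trap_area(pmax(d1, 0), fs), .trap_area(pmax(-d1, 0), fs),
    d1_dia_max, d1_dia_max_t, d1[i_max] - d1[i_min],
    e1071::skewness(d1), e1071::kurtosis(d1), mean(d1^2)
  ))
  # second derivative / a-e waves
  wv <- .d2_waves(d2s, lm)
  w_amp <- stats::setNames(ifelse(is.na(wv), NA_real_, d2s[wv]), .WAVES)
  w_t <- stats::setNames(ifelse(is.na(wv), NA_real_, t_rel[wv]), .WAVES)
  op <- .ordered_pairs(.WAVES)
  segs4 <- .seg_name(.SEG4$x, .SEG4$y)
  seg4_stat <- function(sig, f) {
    map_dbl(seq_len(nrow(.SEG4)), function(i) {
      idx <- .seg_idx(lm, .SEG4$x[i], .SEG4$y[i])
      if (is.null(idx) || length(idx) < 2L) NA_real_ else f(sig[idx])
    })
  }
  j_max <- which.max(d2); j_min <- which.min(d2)
  pulse_amp <- lv("SPP") - lv("SPO")
  sys_idx <- 1:spp_i
  dia_idx <- spp_i:n
  d2zc <- sum(diff(sign(d2[d2 != 0])) != 0)
  d2_range <- d2[j_max] - d2[j_min]
  push(.d2_stubs(), c(
    w_amp,                                                        # amp 5
    w_t,                                                          # t 5
    w_t / dur_cyc,                                                # tfrac 5
    .safe_div(w_amp[op$i], w_amp[op$j]),                          # amp ratios 20
    .safe_div(w_t[op$i], w_t[op$j]),                              # t ratios 20
    w_amp[op$i] - w_amp[op$j],                                    # amp diffs 20
    w_t[op$i] - w_t[op$j],                                        # t diffs 20
    vals(d2, "SPO"), vals(d2, "SPP"), vals(d2, "DN"),
    vals(d2, "DPP"), vals(d2, "DPE"),                             # at landmarks 5
    d2[j_max], t_rel[j_max], d2[j_min], t_rel[j_min],             # global 4
    mean(d2), median(d2), .rms(d2), sd(d2),
    e1071::skewness(d2), e1071::kurtosis(d2),                     # moments 6
    seg4_stat(d2, mean), seg4_stat(d2, median),
    seg4_stat(d2, .rms), seg4_stat(d2, sd),                       # seg stats 16
    .safe_div(w_amp, rep(pulse_amp, 5)),                          # amp_norm 5
    .safe_div(w_amp["b"] - w_amp["c"] - w_amp["d"] - w_amp["e"],
              w_amp["a"]),                                        # aging 1
    .safe_div(w_amp[c("b", "c", "d", "e")] - w_amp[c("a", "b", "c", "d")],
              w_t[c("b", "c", "d", "e")] - w_t[c("a", "b", "c", "d")]), # slopes 4
    map_dbl(seq(10, 90, 10) / 100, function(f) at_frac(d2, f)),   # frac 9
    seg4_stat(d2, function(v) mean(v^2)),                         # energy 4
    d2zc,                                                         # zc 1
    .trap_area(pmax(d2, 0), fs), .trap_area(pmax(-d2, 0), fs),
    .trap_area(abs(d2), fs),                                      # areas 3
    max(d2[sys_idx]), t_rel[sys_idx[which.max(d2[sys_idx])]],
    min(d2[sys_idx]), t_rel[sys_idx[which.min(d2[sys_idx])]],
    max(d2[dia_idx]), t_rel[dia_idx[which.max(d2[dia_idx])]],
    min(d2[dia_idx]), t_rel[dia_idx[which.min(d2[dia_idx])]],     # sys/dia 8
    .safe_div(w_amp, rep(d2_range, 5)),                           # amp_rel 5
    w_t - lt("SPP"),                                              # wrt SPP 5
    w_t - lt("DN"),                                               # wrt DN 5
    at_frac(d2, 0.25), at_frac(d2, 0.75)                          # 2
  ))
  out[!is.finite(out)] <- NA_real_
  out
}

#' Extract all manifest features for one cardiac cycle
#'
#' Evaluates every manifest entry on the cycle. Features that cannot be
#' computed (absent DPP, degenerate segments, missing second-derivative
#' waves, zero denominators) are reported as `NA` — never silently zero.
#'
#' @param ctx A [cycle_context()].
#' @param manifest Manifest from [build_manifest()]; must match `ctx$kind`.
#' @return A named numeric vector, names exactly the manifest's `feature`
#'   column, in manifest order.
#' @export
extract_cycle_features <- function(ctx, manifest = build_manifest(ctx$kind)) {
  vals <- .compute_stub_values(ctx)
  full <- paste0(ctx$kind, "_", names(vals))
  if (!identical(full, manifest$feature)) {
    # manifest from the other kind or reordered: align by name
    idx <- match(manifest$feature, full)
    if (anyNA(idx)) abort("Manifest does not match this cycle's signal kind.")
    vals <- vals[idx]
    full <- manifest$feature
  }
  stats::setNames(as.numeric(vals), full)
}

#' Per-cycle vital signs from an ABP cycle
#'
#' Systolic pressure = maximum raw value over the cycle, diastolic =
#' minimum, mean arterial pressure = arithmetic mean of the raw samples
#' (the full waveform is available, so the true mean is used rather than
#' the DBP + PP/3 approximation).
#'
#' @param ctx A [cycle_context()] with `kind == "ABP"` and raw samples in
#'   mmHg.
#' @return A tibble with columns `sbp`, `dbp`, `map` (mmHg).
#' @export
compute_vitals <- function(ctx) {
  if (ctx$kind != "ABP") abort("Vitals are defined for ABP cycles only.")
  if (length(ctx$raw) < 2L) abort("Cycle too short for vitals.")
  tibble(sbp = max(ctx$raw), dbp = min(ctx$raw), map = mean(ctx$raw))
}

#' Write a per-cycle feature table to CSV
#'
#' One row per cardiac cycle: metadata columns followed by the 852 feature
#' columns in manifest order. `NA` feature values (sentinels for
#' incomputable features) serialize as empty cells.
#'
#' @param features Tibble from [featurize_record()] (or any tibble whose
#'   feature columns follow one manifest).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}
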