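# Synthetic ABP/PPG-like pulse trains with analytic ground-truth landmarks.
#
# Each cardiac cycle is a fixed phase-parameterized template: a systolic
# wave with a sharp upstroke foot, a narrow incisura dip (the dicrotic
# notch, depth set by notch_depth), and a dicrotic wave whose exponential
# run-off decays across the cycle boundary into the next upstroke, giving
# the onset minimum a real left flank. Ground truth is computed on the
# noise-free, drift-free composite signal.

# template shape constants (phase units, fraction of the cycle)
.SYN_MU_S   <- 0.12   # systolic peak position
.SYN_SIG_SL <- 0.045  # systolic rise width (left of peak)
.SYN_SIG_SR <- 0.13   # systolic decay width (right of peak)
.SYN_STEP   <- 0.05   # smoothstep span gating the upstroke foot
.SYN_MU_N   <- 0.36   # incisura (dicrotic notch) dip position
.SYN_SIG_N  <- 0.014  # incisura dip width (sharp valve-closure transient)
.SYN_DEPTH  <- 0.20   # incisura dip amplitude at notch_depth = 1
.SYN_MU_D   <- 0.47   # dicrotic wave position
.SYN_SIG_D  <- 0.030  # dicrotic wave width at notch_depth = 1
.SYN_LAM_D  <- 0.32   # dicrotic run-off decay constant (diastolic runoff)

#' Synthetic pulse-train parameters
#'
#' Defaults emulate a clean adult radial ABP recording at the 256 Hz rate
#' of bedside monitors: ~75 bpm, 40 mmHg pulse pressure on a 75 mmHg
#' baseline, a clearly visible dicrotic notch, mild beat-to-beat period
#' jitter, no drift and no noise.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Record duration in seconds.
#' @param heart_rate_bpm Mean heart rate (20-240 bpm exclusive).
#' @param systolic_amp Systolic wave amplitude (mmHg for ABP).
#' @param dicrotic_amp Dicrotic wave amplitude relative to `systolic_amp`.
#' @param notch_depth In `[0, 1]`: 1 = fully developed notch, 0 = the notch
#'   is bridged over and disappears (DN-less morphology).
#' @param baseline_offset Additive baseline (e.g. diastolic pressure, mmHg).
#' @param drift_amp,drift_hz Amplitude and frequency of a slow sinusoidal
#'   baseline drift (same units as the signal; 0 disables).
#' @param noise_sd Standard deviation of additive white Gaussian noise.
#' @param hr_jitter_cv Coefficient of variation of per-cycle periods
#'   (log-normal); avoids exact periodicity degeneracies.
#' @param seed Integer seed; fixed seed reproduces samples and truth.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(fs = 256, duration_s = 10, heart_rate_bpm = 75,
                         systolic_amp = 40, dicrotic_amp = 0.30,
                         notch_depth = 0.8, baseline_offset = 75,
                         drift_amp = 0, drift_hz = 0.2, noise_sd = 0,
                         hr_jitter_cv = 0.02, seed = 1L) {
  if (fs <= 0) abort("`fs` must be > 0.")
  if (!(heart_rate_bpm > 20 && heart_rate_bpm < 240)) {
    abort("`heart_rate_bpm` must lie in (20, 240).")
  }
  if (notch_depth < 0 || notch_depth > 1) abort("`notch_depth` must be in [0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (hr_jitter_cv < 0) abort("`hr_jitter_cv` must be >= 0.")
  structure(as.list(environment()), class = "synth_params")
}

# per-cycle kernel evaluated at phase phi (vectorized; phi may exceed [0,1]).
# Components, each locally symmetric around its landmark so that zero-phase
# low-pass filtering does not displace the landmark:
#  * systolic wave: bi-Gaussian (fast rise, slow decay) gated by a
#    smoothstep at phi = 0, which gives the upstroke foot a sharp, well
#    localized onset corner;
#  * incisura: a narrow negative Gaussian dip whose amplitude is
#    notch_depth * .SYN_DEPTH -- the dicrotic notch; at notch_depth = 0 the
#    decay + dicrotic bump are slope-matched so no local minimum survives
#    (DN-less morphology);
#  * dicrotic wave: broad Gaussian, C1-matched to an exponential run-off
#    whose tail decays across the cycle boundary into the next upstroke,
#    giving the next onset minimum a genuine left flank.
.syn_kernel <- function(phi, period_s, dicrotic_amp, notch_depth) {
  s <- pmin(pmax(phi / .SYN_STEP, 0), 1)
  gate <- s * s * (3 - 2 * s)
  sig <- ifelse(phi < .SYN_MU_S, .SYN_SIG_SL, .SYN_SIG_SR)
  sys <- gate * exp(-(phi - .SYN_MU_S)^2 / (2 * sig^2))
  inc <- -notch_depth * .SYN_DEPTH *
    exp(-(phi - .SYN_MU_N)^2 / (2 * .SYN_SIG_N^2))
  # dicrotic bump: Gaussian up to the C1 junction, then an exponential
  # run-off whose tail decays across the cycle boundary into the next
  # upstroke. The bump broadens as the notch fades
  # (a smeared dicrotic shoulder is what DN-less cycles look like); at
  # notch_depth = 0 its maximal slope stays below the systolic decay slope,
  # so no local minimum survives.
  sig_d <- .SYN_SIG_D * (1 + 3.3 * (1 - notch_depth))
  phi_j <- .SYN_MU_D + sig_d^2 / .SYN_LAM_D
  g_j <- exp(-(phi_j - .SYN_MU_D)^2 / (2 * sig_d^2))
  dic <- ifelse(phi <= phi_j,
                exp(-(phi - .SYN_MU_D)^2 / (2 * sig_d^2)),
                g_j * exp(-(phi - phi_j) / .SYN_LAM_D))
  sys + inc + dicrotic_amp * dic
}

#' Generate a synthetic pulse train with ground-truth landmarks
#'
#' Builds the composite clean signal (baseline + overlapping per-cycle
#' kernels), derives ground-truth landmark indices from it, then adds drift
#' and noise to form the returned record. A virtual preceding cycle warms up
#' the start of the record so the first onset has a proper diastolic left
#' flank. A cycle enters the ground truth only when its endpoint (the next
#' onset minimum) lies inside the record, i.e. the next upstroke has begun.
#'
#' @param params A [synth_params()] list.
#' @return A list with elements:
#'   * `record` — a [waveform_record()] (`kind = "ABP"` scale by default);
#'   * `truth` — tibble (`cycle_id`, `landmark_type`, `sample_index`) of
#'     ground-truth marks for every complete cycle (`DPP`/`DN` absent rows
#'     are omitted when the morphology is DN-less);
#'   * `cycles` — per-cycle tibble (`cycle_id`, `spo`, `spp`, `dn`, `dpp`,
#'     `dpe`, `dn_visible`);
#'   * `clean` — the noise- and drift-free composite samples;
#'   * `params` — the parameters used.
#' @examples
#' out <- synth_pulse_train(synth_params(duration_s = 6, seed = 42))
#' out$cycles
#' @export
synth_pulse_train <- function(params = synth_params()) {
  p <- params
  set.seed(p$seed)
  n <- round(p$duration_s * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  T0 <- 60 / p$heart_rate_bpm

  # per-cycle periods (log-normal jitter), enough cycles to span the record
  # plus one closing upstroke; cycle 0 is virtual warm-up
  n_max <- ceiling(p$duration_s / T0) + 3L
  if (p$hr_jitter_cv > 0) {
    sdlog <- sqrt(log(1 + p$hr_jitter_cv^2))
    periods <- T0 * rlnorm(n_max, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    periods <- rep(T0, n_max)
  }
  starts <- c(-periods[1], -periods[1] + cumsum(periods))  # t_0, t_1, ...

  clean <- rep(p$baseline_offset, n)
  for (k in seq_along(starts)) {
    t_k <- starts[k]
    T_k <- if (k <= length(periods)) periods[k] else periods[length(periods)]
    if (t_k > p$duration_s) break
    lo <- max(1L, floor((t_k - 0.6 * T_k) * p$fs) + 1L)
    hi <- min(n, ceiling((t_k + 2.5 * T_k) * p$fs) + 1L)
    if (lo > hi) next
    phi <- (t[lo:hi] - t_k) / T_k
    clean[lo:hi] <- clean[lo:hi] +
      p$systolic_amp * .syn_kernel(phi, T_k, p$dicrotic_amp, p$notch_depth)
  }

  # ground-truth boundaries: argmin of the clean signal near each nominal
  # cycle start (real cycles are starts[2], starts[3], ...). A boundary
  # only counts when its minimum is genuinely in-record: at least the
  # 0.1-s separation distance away from both record edges and not pinned
  # to an edge of its search span (i.e. the surrounding upstroke/run-off
  # is present). The first nominal onset sits at time 0 and is therefore
  # excluded -- the record starts mid-upstroke of a partial cycle.
  margin <- round(0.2 * p$fs)
  real_starts <- starts[-1]
  bounds <- integer(0)
  for (t_k in real_starts) {
    if (t_k < -0.05 || t_k > p$duration_s) next
    lo <- max(1L, round(t_k * p$fs) + 1L - round(0.35 * T0 * p$fs))
    hi <- min(n, round(t_k * p$fs) + 1L + round(0.35 * T0 * p$fs))
    if (hi - lo < 3L) next
    b <- lo + which.min(clean[lo:hi]) - 1L
    if (b <= margin || b > n - margin) next
    if (b == lo || b == hi) next
    bounds <- c(bounds, b)
  }
  bounds <- unique(bounds)

  cycles <- list()
  if (length(bounds) >= 2L) {
    for (k in seq_len(length(bounds) - 1L)) {
      spo <- bounds[k]; dpe <- bounds[k + 1L]
      seg <- clean[spo:dpe]
      spp <- spo + which.max(seg) - 1L
      # interior extrema between SPP and DPE decide DN / DPP
      inner <- clean[spp:dpe]
      mins <- local_extrema_idx(inner, "min")
      dn <- dpp <- NA_integer_
      dn_visible <- FALSE
      if (length(mins)) {
        dn <- spp + mins[1] - 1L
        dn_visible <- TRUE
        after <- clean[dn:dpe]
        maxs <- local_extrema_idx(after, "max")
        if (length(maxs)) dpp <- dn + maxs[1] - 1L
      }
      cycles[[k]] <- tibble(
        cycle_id = k, spo = spo, spp = spp, dn = dn, dpp = dpp, dpe = dpe,
        dn_visible = dn_visible
      )
    }
  }
  cycles <- if (length(cycles)) bind_rows(cycles) else
    tibble(cycle_id = integer(), spo = integer(), spp = integer(),
           dn = integer(), dpp = integer(), dpe = integer(),
           dn_visible = logical())

  truth <- landmarks_to_record(
    cycles[, c("spo", "spp", "dn", "dpp", "dpe")],
    start_index = 1L, n_record = n
  )

  x <- clean
  if (p$drift_amp != 0) x <- x + p$drift_amp * sin(2 * pi * p$drift_hz * t)
  if (p$noise_sd > 0) x <- x + rnorm(n, 0, p$noise_sd)

  rec <- waveform_record(x, fs = p$fs, kind = "ABP",
                         label = sprintf("synthetic pulse train (seed %d)", p$seed))
  list(record = rec, truth = truth, cycles = cycles, clean = clean, params = p)
}
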