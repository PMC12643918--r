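test_that("parameter validation guards the generator", {
  expect_error(synth_params(heart_rate_bpm = 10), "heart_rate_bpm")
  expect_error(synth_params(notch_depth = 1.2), "notch_depth")
  expect_error(synth_params(noise_sd = -1), "noise_sd")
})

test_that("a 10-s record at 60 bpm holds 8 complete cycles", {
  # 10 nominal cycles fit, but the first onset sits inside the record-edge
  # margin and the 10th cycle closes exactly at the record end, so 8
  # cycles have both boundaries usable in-record
  syn <- synth_pulse_train(synth_params(duration_s = 10, heart_rate_bpm = 60,
                                        hr_jitter_cv = 0, seed = 3))
  expect_equal(nrow(syn$record), 2560)
  expect_equal(nrow(syn$cycles), 8)
  with(syn$cycles, {
    expect_true(all(spo < spp & spp < dn & dn < dpp & dpp < dpe))
  })
})

test_that("consecutive ground-truth cycles share their boundary", {
  syn <- synth_pulse_train(synth_params(duration_s = 10, seed = 8))
  cyc <- syn$cycles
  expect_equal(cyc$spo[-1], cyc$dpe[-nrow(cyc)])
})

test_that("the generator is deterministic for a fixed seed", {
  a <- synth_pulse_train(synth_params(duration_s = 6, noise_sd = 1, seed = 99))
  b <- synth_pulse_train(synth_params(duration_s = 6, noise_sd = 1, seed = 99))
  expect_identical(a$record$value, b$record$value)
  expect_identical(a$truth, b$truth)
})

test_that("notch_depth = 0 produces DN-less morphology", {
  syn <- synth_pulse_train(synth_params(duration_s = 8, notch_depth = 0,
                                        seed = 6))
  expect_true(nrow(syn$cycles) > 0)
  expect_false(any(syn$cycles$dn_visible))
  expect_true(all(is.na(syn$cycles$dn)))

  syn2 <- synth_pulse_train(synth_params(duration_s = 8, notch_depth = 0.8,
                                         seed = 6))
  expect_true(all(syn2$cycles$dn_visible))
})

test_that("samples stay positive at the default baseline", {
  syn <- synth_pulse_train(synth_params(duration_s = 8, noise_sd = 0.8,
                                        seed = 12))
  expect_true(all(syn$record$value > 0))
})

test_that("ground-truth timing scales with heart rate", {
  p1 <- synth_pulse_train(synth_params(duration_s = 10, heart_rate_bpm = 60,
                                       hr_jitter_cv = 0, seed = 1))
  p2 <- synth_pulse_train(synth_params(duration_s = 10, heart_rate_bpm = 120,
                                       hr_jitter_cv = 0, seed = 1))
  gap1 <- median(diff(p1$cycles$spo))
  gap2 <- median(diff(p2$cycles$spo))
  expect_equal(gap1 / gap2, 2, tolerance = 0.02)
})

test_that("the 16 Hz filter barely moves clean landmark positions", {
  # template spectral content sits below the cutoff, so zero-phase
  # filtering perturbs each landmark extremum by at most 2 samples
  syn <- synth_pulse_train(synth_params(duration_s = 6, seed = 10))
  filt <- lowpass_filter(syn$record$value, fs = 256)
  for (k in seq_len(nrow(syn$cycles))) {
    for (lm in c("spo", "spp", "dn", "dpp")) {
      i0 <- syn$cycles[[lm]][k]
      if (is.na(i0)) next
      lo <- max(1, i0 - 10); hi <- min(length(filt), i0 + 10)
      f <- if (lm %in% c("spo", "dn")) which.min else which.max
      expect_lte(abs(lo - 1 + f(filt[lo:hi]) - i0), 2)
    }
  }
})

test_that("truth annotations mirror the per-cycle table", {
  syn <- synth_pulse_train(synth_params(duration_s = 6, seed = 2))
  spo_truth <- syn$truth$sample_index[syn$truth$landmark_type == "SPO"]
  expect_setequal(spo_truth, syn$cycles$spo)
})
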