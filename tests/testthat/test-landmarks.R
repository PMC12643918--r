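test_that("find_signed_extrema classifies peaks and valleys in order", {
  t <- seq(0, 1, length.out = 257)[-257]
  x <- sin(2 * pi * t)
  ex <- find_signed_extrema(x)
  expect_equal(nrow(ex), 2)
  expect_equal(ex$polarity, c("peak", "valley"))
  expect_gt(ex$value[1], 0)
  expect_lt(ex$value[2], 0)

  expect_equal(nrow(find_signed_extrema(rep(1, 50))), 0)

  plateau <- c(0, 1, 2, 2, 2, 1, 0)
  ex2 <- find_signed_extrema(plateau)
  expect_equal(ex2$index, 3L)  # plateau collapses to its first index
})

# synthetic NSTS with bumps at controlled offsets: onset valleys every 300
# samples, SPP at +75, two notch-like valleys at +88 and +113 (0.05 s and
# 0.15 s after the SPP at 256 Hz), diastolic peak at +150
crafted_nsts <- function() {
  g <- function(n, c0, a, s) a * exp(-((1:n) - c0)^2 / (2 * s^2))
  n <- 1280
  x <- rep(0, n)
  for (on in c(50, 350, 650, 950)) {
    x <- x + g(n, on, -0.4, 8) + g(n, on + 75, 0.5, 10) +
      g(n, on + 88, -0.08, 5) + g(n, on + 113, -0.12, 5) +
      g(n, on + 150, 0.15, 10)
  }
  x
}

test_that("the 0.1-s separation rule rejects early notch candidates", {
  cyc <- delineate_cycles(crafted_nsts(), fs = 256)
  expect_equal(nrow(cyc), 3)
  # first valley after SPP sits 13 samples (0.05 s) away and is skipped;
  # the 38-sample (0.15 s) one is taken
  expect_equal(cyc$dn - cyc$spp, rep(38L, 3))
  expect_equal(cyc$spo, c(50L, 350L, 650L))
})

test_that("sign and separation conditions hold on the NSTS", {
  x <- crafted_nsts()
  cyc <- delineate_cycles(x, fs = 256)
  min_sep <- floor(0.1 * 256)
  for (k in seq_len(nrow(cyc))) {
    expect_gt(x[cyc$spp[k]], 0)
    expect_lt(x[cyc$spo[k]], 0)
    expect_lt(x[cyc$dn[k]], 0)
    expect_lt(x[cyc$dpe[k]], 0)
    if (!is.na(cyc$dpp[k])) expect_gt(x[cyc$dpp[k]], 0)
    expect_gte(cyc$dn[k] - cyc$spp[k], min_sep)
    if (!is.na(cyc$dpp[k])) expect_gte(cyc$dpe[k] - cyc$dpp[k], min_sep)
  }
})

test_that("degenerate NSTS inputs give an empty delineation", {
  expect_equal(nrow(delineate_cycles(rep(0, 1024), fs = 256)), 0)
  expect_equal(nrow(delineate_cycles(sin((1:100) / 5) * 0.001 - 1, 256)), 0)
})

test_that("landmarks are recovered within tolerance on synthetic cycles", {
  syn <- synth_pulse_train(synth_params(duration_s = 4, heart_rate_bpm = 85,
                                        seed = 9))
  run <- featurize_record(syn$record, extract_features = FALSE)
  expect_gte(nrow(run$cycles), 4)
  truth <- syn$truth
  # strict within-cycle ordering
  with(run$cycles, {
    expect_true(all(spo < spp & spp < dn & dn < dpe))
    expect_true(all(is.na(dpp) | (dpp > dn & dpp < dpe)))
  })
  m <- match_landmarks(run$landmarks, truth, 256)
  expect_equal(m$fn, rep(0L, 4))
})

test_that("consecutive cycles share their boundary index", {
  syn <- synth_pulse_train(synth_params(duration_s = 8, seed = 14))
  run <- featurize_record(syn$record, extract_features = FALSE)
  cyc <- run$cycles
  by_win <- split(cyc, cyc$window_id)
  for (w in by_win) {
    if (nrow(w) < 2) next
    expect_equal(w$spo[-1], w$dpe[-nrow(w)])
  }
})

test_that("landmarks_to_record offsets, merges and deduplicates", {
  cyc <- tibble::tibble(spo = 10L, spp = 40L, dn = 90L,
                        dpp = 120L, dpe = 200L)
  ann <- landmarks_to_record(cyc, start_index = 1025L)
  expect_equal(ann$sample_index[ann$landmark_type == "SPO"], 1034L)
  expect_equal(nrow(landmarks_to_record(cyc[0, ])), 0)

  # shared boundary appearing as DPE of one window and SPO of the next
  two <- tibble::tibble(spo = c(10L, 200L), spp = c(40L, 230L),
                        dn = c(90L, 280L), dpp = c(120L, 310L),
                        dpe = c(200L, 390L))
  ann2 <- landmarks_to_record(two)
  expect_equal(sum(ann2$sample_index == 200L), 2L)  # one SPO + one DPE row
  expect_error(landmarks_to_record(cyc, start_index = 1L, n_record = 100),
               "out of record range")
})
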