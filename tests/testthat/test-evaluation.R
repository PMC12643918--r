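ann <- function(type, idx) tibble::tibble(landmark_type = type,
                                          sample_index = as.integer(idx))

test_that("matching applies the +/-8 ms (2-sample) tolerance at 256 Hz", {
  ref <- ann("SPP", 100)
  hit <- match_landmarks(ann("SPP", 102), ref, fs = 256)
  expect_equal(hit$tp[hit$landmark_type == "SPP"], 1L)

  miss <- match_landmarks(ann("SPP", 103), ref, fs = 256)
  expect_equal(miss$tp[miss$landmark_type == "SPP"], 0L)
  expect_equal(miss$fp[miss$landmark_type == "SPP"], 1L)
  expect_equal(miss$fn[miss$landmark_type == "SPP"], 1L)
})

test_that("matching is one-to-one", {
  ref <- ann("DN", 100)
  det <- ann("DN", c(99, 101))
  m <- match_landmarks(det, ref, fs = 256)
  r <- m[m$landmark_type == "DN", ]
  expect_equal(r$tp, 1L)
  expect_equal(r$fp, 1L)
  expect_equal(r$fn, 0L)
})

test_that("count totals always partition references and detections", {
  set.seed(31)
  for (i in 1:25) {
    ref <- ann("SPO", sort(sample(1000, 8)))
    det <- ann("SPO", sort(sample(1000, 10)))
    m <- match_landmarks(det, ref, fs = 256)
    r <- m[m$landmark_type == "SPO", ]
    expect_equal(r$tp + r$fn, 8L)
    expect_equal(r$tp + r$fp, 10L)
  }
})

test_that("metric formulas reproduce closed-form values", {
  m <- compute_metrics(tibble::tibble(tp = 9L, fp = 1L, fn = 0L))
  expect_equal(m$se, 1)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$f1, 2 * 0.9 / 1.9)
  expect_equal(m$er, 0.1)

  m2 <- compute_metrics(tibble::tibble(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(unlist(m2[, c("se", "ppv", "f1", "er")]),
               c(se = 0.5, ppv = 0.5, f1 = 0.5, er = 1))

  expect_warning(m3 <- compute_metrics(tibble::tibble(tp = 0L, fp = 0L, fn = 0L)),
                 "Undefined")
  expect_true(all(is.nan(c(m3$se, m3$ppv, m3$f1, m3$er))))
})

test_that("metrics are invariant to proportional count scaling", {
  a <- compute_metrics(tibble::tibble(tp = 8L, fp = 2L, fn = 1L))
  b <- compute_metrics(tibble::tibble(tp = 80L, fp = 20L, fn = 10L))
  expect_equal(a[, c("se", "ppv", "f1", "er")],
               b[, c("se", "ppv", "f1", "er")])
})

test_that("the asymmetric error-rate denominator is used verbatim", {
  m <- compute_metrics(tibble::tibble(tp = 5L, fp = 0L, fn = 5L))
  expect_equal(m$er, 1)  # (0+5)/(5+0), not (0+5)/10
  ms <- compute_metrics(tibble::tibble(tp = 5L, fp = 0L, fn = 5L),
                        symmetric_er = TRUE)
  expect_equal(ms$er, 0.5)
})

test_that("Bland-Altman summary follows the closed form", {
  zeros <- tibble::tibble(reference_time_s = 1:5 / 2,
                          detected_time_s = 1:5 / 2)
  ba <- bland_altman(zeros)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)

  pm <- tibble::tibble(reference_time_s = c(1, 2),
                       detected_time_s = c(0, 3))
  ba2 <- bland_altman(pm)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt(2))
  expect_equal(ba2$loa_upper, 1.96 * sqrt(2))
  expect_equal(glance(ba2)$n, 2)
  expect_equal(nrow(tidy(ba2)), 2)

  expect_error(bland_altman(pm[1, ]), "at least 2")
})

test_that("evaluate_detection ties matching, metrics and agreement together", {
  syn <- synth_pulse_train(synth_params(duration_s = 8, seed = 4))
  run <- featurize_record(syn$record, extract_features = FALSE)
  ev <- evaluate_detection(run$landmarks, syn$truth, fs = 256)
  expect_true(all(c("se", "ppv", "f1", "er") %in% names(ev$counts)))
  expect_s3_class(ev$bland_altman, "bland_altman")
  # clean signal: agreement within the tolerance band
  expect_lt(abs(ev$bland_altman$bias), 2 / 256)
})

test_that("cycles_in_windows keeps only fully evaluable cycles", {
  cyc <- tibble::tibble(
    spo = c(100L, 900L, 1100L, 1030L),
    spp = c(150L, 950L, 1150L, 1080L),
    dn = c(200L, 1000L, 1200L, 1130L),
    dpp = c(220L, 1010L, 1220L, 1150L),
    dpe = c(350L, 1150L, 1350L, 1280L)
  )
  kept <- cycles_in_windows(cyc, window_seconds = 4, fs = 256)
  # cycle 2 straddles the 1024 cut; cycle 4 starts 6 samples into window 2
  expect_equal(kept$spo, c(100L, 1100L))
})
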