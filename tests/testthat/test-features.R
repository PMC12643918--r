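test_that("manifest has 852 uniquely named features with exact family sizes", {
  m <- build_manifest("ABP")
  expect_equal(nrow(m), 852)
  expect_equal(anyDuplicated(m$feature), 0)
  counts <- table(m$family)
  expected <- c(amplitude = 30, amplitude_ratio = 210, duration = 10,
                duration_ratio = 46, average = 40, median = 20, rms = 20,
                skewness = 1, kurtosis = 1, area = 40, area_ratio = 180,
                width = 36, frequency = 12, first_derivative = 28,
                second_derivative = 178)
  expect_equal(as.integer(counts[names(expected)]), unname(expected))
  expect_equal(sum(expected), 852)
})

test_that("manifest is deterministic and kind-prefixed", {
  expect_identical(build_manifest("PPG"), build_manifest("PPG"))
  m_abp <- build_manifest("ABP")
  m_ppg <- build_manifest("PPG")
  expect_true(all(startsWith(m_abp$feature, "ABP_")))
  expect_identical(sub("^ABP_", "", m_abp$feature),
                   sub("^PPG_", "", m_ppg$feature))
})

test_that("the 25 exemplar amplitude/duration features lead the manifest", {
  m <- build_manifest("ABP")
  exemplars <- c(
    "AM_SPO_wrtZero", "AM_SPP_wrtSPO", "AM_SPP_wrtZero", "AM_SPP_wrtDN",
    "AM_SPP_wrtDPP", "AM_SPP_wrtDPE", "AM_DN_wrtZero", "AM_DN_wrtSPO",
    "AM_DN_wrtDPE", "AM_DPP_wrtZero", "AM_DPP_wrtSPO", "AM_DPP_wrtDN",
    "AM_DPP_wrtDPE", "AM_DPE_wrtSPO", "AM_DPE_wrtZero",
    "D_SPO_wrtSPP", "D_SPO_wrtDN", "D_SPO_wrtDPP", "D_SPO_wrtDPE",
    "D_SPP_wrtDN", "D_SPP_wrtDPP", "D_SPP_wrtDPE", "D_DN_wrtDPP",
    "D_DN_wrtDPE", "D_DPP_wrtDPE"
  )
  expect_true(all(paste0("ABP_", exemplars) %in% m$feature))
  expect_equal(m$feature[1:15], paste0("ABP_", exemplars[1:15]))
})

test_that("exemplar features match hand arithmetic on a crafted cycle", {
  cc <- crafted_cycle()
  ctx <- cycle_context(cc$normalized, cc$raw, cc$landmarks, cc$fs, "ABP")
  fv <- extract_cycle_features(ctx)
  amp_expected <- c(
    ABP_AM_SPO_wrtZero = 0, ABP_AM_SPP_wrtSPO = 1, ABP_AM_SPP_wrtZero = 1,
    ABP_AM_SPP_wrtDN = 0.6, ABP_AM_SPP_wrtDPP = 0.45,
    ABP_AM_SPP_wrtDPE = 0.95, ABP_AM_DN_wrtZero = 0.4,
    ABP_AM_DN_wrtSPO = 0.4, ABP_AM_DN_wrtDPE = 0.35,
    ABP_AM_DPP_wrtZero = 0.55, ABP_AM_DPP_wrtSPO = 0.55,
    ABP_AM_DPP_wrtDN = 0.15, ABP_AM_DPP_wrtDPE = 0.5,
    ABP_AM_DPE_wrtSPO = 0.05, ABP_AM_DPE_wrtZero = 0.05
  )
  expect_equal(fv[names(amp_expected)], amp_expected, tolerance = 1e-12)
  dur_expected <- c(
    ABP_D_SPO_wrtSPP = 50, ABP_D_SPO_wrtDN = 120, ABP_D_SPO_wrtDPP = 150,
    ABP_D_SPO_wrtDPE = 220, ABP_D_SPP_wrtDN = 70, ABP_D_SPP_wrtDPP = 100,
    ABP_D_SPP_wrtDPE = 170, ABP_D_DN_wrtDPP = 30, ABP_D_DN_wrtDPE = 100,
    ABP_D_DPP_wrtDPE = 70
  ) / 256
  expect_equal(fv[names(dur_expected)], dur_expected, tolerance = 1e-12)
})

test_that("feature vector names equal the manifest in order", {
  cc <- crafted_cycle()
  ctx <- cycle_context(cc$normalized, cc$raw, cc$landmarks, cc$fs, "ABP")
  fv <- extract_cycle_features(ctx)
  expect_identical(names(fv), build_manifest("ABP")$feature)
  expect_true(all(is.na(fv) | is.finite(fv)))
})

test_that("duration features are invariant to raw amplitude scaling", {
  cc <- crafted_cycle()
  ctx1 <- cycle_context(cc$normalized, cc$raw, cc$landmarks, cc$fs, "ABP")
  ctx2 <- cycle_context(cc$normalized, 2.5 * cc$raw + 10, cc$landmarks,
                        cc$fs, "ABP")
  f1 <- extract_cycle_features(ctx1)
  f2 <- extract_cycle_features(ctx2)
  m <- build_manifest("ABP")
  dur <- m$feature[m$family == "duration"]
  expect_equal(f1[dur], f2[dur])
  # normalized-scale amplitudes are untouched by raw rescaling too
  amp_norm <- m$feature[m$family == "amplitude" & !grepl("_raw$", m$feature)]
  expect_equal(f1[amp_norm], f2[amp_norm])
})

test_that("a symmetric triangular cycle has near-zero skewness", {
  n <- 201
  y <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  lm <- tibble::tibble(spo = 1L, spp = 101L, dn = 150L, dpp = 170L,
                       dpe = 201L)
  ctx <- cycle_context(y, 75 + 40 * y, lm, 256, "ABP")
  fv <- extract_cycle_features(ctx)
  expect_lt(abs(fv[["ABP_SKEW_cycle"]]), 0.05)
})

test_that("absent DPP yields sentinels, not zeros", {
  cc <- crafted_cycle()
  lm <- cc$landmarks
  lm$dpp <- NA_integer_
  ctx <- cycle_context(cc$normalized, cc$raw, lm, cc$fs, "ABP")
  fv <- extract_cycle_features(ctx)
  expect_true(is.na(fv[["ABP_AM_DPP_wrtDN"]]))
  expect_true(is.na(fv[["ABP_D_DPP_wrtDPE"]]))
  expect_false(is.na(fv[["ABP_AM_SPP_wrtSPO"]]))
  expect_false(is.na(fv[["ABP_D_SPO_wrtDPE"]]))
})

test_that("vitals are the raw extrema and mean of an ABP cycle", {
  cc <- crafted_cycle()
  ctx <- cycle_context(cc$normalized, cc$raw, cc$landmarks, cc$fs, "ABP")
  v <- compute_vitals(ctx)
  expect_equal(v$sbp, max(cc$raw))
  expect_equal(v$dbp, min(cc$raw))
  expect_equal(v$map, mean(cc$raw))

  ctx_ppg <- cycle_context(cc$normalized, cc$raw, cc$landmarks, cc$fs, "PPG")
  expect_error(compute_vitals(ctx_ppg), "ABP")
})

test_that("feature CSV serializes one row per cycle with empty sentinels", {
  syn <- synth_pulse_train(synth_params(duration_s = 8, seed = 5))
  run <- featurize_record(syn$record)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(run$features, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(length(hdr), 7 + 852)
  expect_equal(length(readLines(path)) - 1, nrow(run$features))

  write_features(run$features[0, ], path)
  expect_equal(length(readLines(path)), 1)  # header only
})
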