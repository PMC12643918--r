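test_that("iem_params validates its fields", {
  expect_error(iem_params(sg_window = 24), "odd")
  expect_error(iem_params(beta = 1.5), "beta")
  expect_error(iem_params(max_iter = 0), "max_iter")
  expect_equal(scale_sg_window(256), 25L)
  expect_true(scale_sg_window(500) %% 2 == 1)
})

test_that("envelope mean of a zero-mean sine vanishes on the interior", {
  t <- seq(0, 4, by = 1 / 256)
  x <- sin(2 * pi * 2 * t)
  m <- envelope_mean(x)
  core <- 128:(length(x) - 128)
  expect_lt(max(abs(m[core])), 0.05)

  m2 <- envelope_mean(x + 0.3)
  expect_lt(max(abs(m2[core] - 0.3)), 0.05)
})

test_that("monotone ramp takes the degenerate chord path", {
  m <- envelope_mean(seq(0, 1, length.out = 200))
  expect_true(attr(m, "degenerate"))
})

test_that("decomposition conserves the input exactly", {
  set.seed(7)
  for (i in 1:20) {
    x <- cumsum(rnorm(400)) / 10 + sin(2 * pi * (1:400) / 50)
    dec <- iem_decompose(x)
    expect_lt(max(abs(dec$input - (dec$nsts + dec$sts))), 1e-12)
  }
})

test_that("constant input decomposes to zero NSTS immediately", {
  dec <- iem_decompose(rep(0.4, 300))
  expect_equal(dec$nsts, rep(0, 300))
  expect_equal(dec$sts, rep(0.4, 300))
  expect_true(dec$converged)
  expect_equal(dec$n_iter, 1L)
})

test_that("a symmetric oscillation passes through as the NSTS", {
  t <- seq(0, 4, by = 1 / 256)
  x <- sin(2 * pi * 2 * t)
  dec <- iem_decompose(x)
  core <- 128:(length(x) - 128)
  expect_lt(max(abs(dec$nsts[core] - x[core])), 0.05)
})

test_that("decomposing an NSTS again converges almost immediately", {
  syn <- synth_pulse_train(synth_params(duration_s = 4, seed = 3))
  pre <- preprocess_windows(cut_windows(syn$record), 256)
  dec <- iem_decompose(pre$normalized[[1]])
  dec2 <- iem_decompose(dec$nsts)
  expect_lte(dec2$n_iter, 2L)
})

test_that("near-symmetric oscillation plus slow drift splits cleanly", {
  # the decomposition's assumed regime: oscillation with symmetric
  # envelopes; the stationary component then recovers a slow drift
  fs <- 256
  t <- (0:2559) / fs
  drift <- 0.2 * sin(2 * pi * 0.2 * t)
  x <- 0.5 + 0.35 * sin(2 * pi * 1.25 * t) +
    0.05 * sin(2 * pi * 2.5 * t + 1) + drift
  dec <- iem_decompose(x)
  core <- 256:(length(x) - 256)
  err <- (dec$sts - mean(dec$sts[core])) - (drift - mean(drift[core]))
  expect_lt(sqrt(mean(err[core]^2)), 0.05)
})

test_that("input shorter than the smoothing window is rejected", {
  expect_error(iem_decompose(rnorm(20)), "shorter")
})

test_that("runtime grows roughly linearly in signal length", {
  # O(JN): at fixed iteration count, doubling N should not blow up time
  mk <- function(n) sin(2 * pi * (1:n) / 64) + 0.2 * sin(2 * pi * (1:n) / 500)
  p <- iem_params(max_iter = 2, beta = 0.5)
  t1 <- median(vapply(1:3, function(i)
    system.time(iem_decompose(mk(4096), p))["elapsed"], numeric(1)))
  t2 <- median(vapply(1:3, function(i)
    system.time(iem_decompose(mk(8192), p))["elapsed"], numeric(1)))
  expect_lt(t2, max(4 * t1, t1 + 0.25))
})

test_that("tidy and glance summarise a decomposition", {
  dec <- iem_decompose(sin(2 * pi * (1:512) / 64))
  td <- tidy(dec)
  expect_named(td, c("sample", "input", "nsts", "sts"))
  expect_equal(nrow(td), 512)
  gl <- glance(dec)
  expect_equal(gl$n, 512)
  expect_true(is.logical(gl$converged))
})
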