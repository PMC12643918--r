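# crafted single cycle with exactly known landmark values: piecewise-linear
# between landmarks at fixed indices, normalized values as given
crafted_cycle <- function(fs = 256) {
  idx <- c(spo = 1L, spp = 51L, dn = 121L, dpp = 151L, dpe = 221L)
  vals <- c(0.0, 1.0, 0.4, 0.55, 0.05)
  y <- approx(idx, vals, xout = seq_len(max(idx)))$y
  list(
    normalized = y,
    raw = 75 + 40 * y,
    landmarks = tibble::tibble(spo = 1L, spp = 51L, dn = 121L,
                               dpp = 151L, dpe = 221L),
    idx = idx, vals = vals, fs = fs
  )
}

# window of `k` smooth bumps above the 75th percentile on a positive base
bumpy_window <- function(k, n = 1024, amp = 50, base = 60) {
  x <- rep(base, n)
  if (k > 0) {
    centers <- round(seq(n / (k + 1), n - n / (k + 1), length.out = k))
    for (c0 in centers) {
      i <- max(1, c0 - 40):min(n, c0 + 40)
      x[i] <- x[i] + amp * exp(-(i - c0)^2 / (2 * 12^2))
    }
  }
  x
}
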