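# Iterative envelope mean (IEM) decomposition.
#
# Each iteration smooths the current residual with a Savitzky-Golay filter,
# locates the smoothed signal's local maxima/minima, interpolates the
# residual's values at those indices with a shape-preserving monotone cubic
# (upper and lower envelopes), and subtracts the sample-by-sample mean of
# the two envelopes from the residual.  The final residual is the
# non-stationary component (NSTS); the accumulated envelope means form the
# stationary component (STS).  nsts + sts == input holds exactly because
# sts is computed as input - nsts.

#' IEM decomposition parameters
#'
#' @param sg_window Savitzky-Golay window length in samples (odd). The
#'   default 25 corresponds to roughly twice the shortest inter-landmark
#'   duration at 256 Hz; use [scale_sg_window()] for other rates.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param beta Stopping accuracy: iteration stops when the maximum absolute
#'   envelope mean falls below `beta` times the input's range. Default 0.1.
#' @param max_iter Hard cap on iterations (J).
#' @return A list of class `iem_params`.
#' @export
iem_params <- function(sg_window = 25L, sg_polyorder = 3L,
                       beta = 0.1, max_iter = 50L) {
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_window < sg_polyorder + 2L) {
    abort("`sg_window` must be odd and >= sg_polyorder + 2.")
  }
  if (!(beta > 0 && beta < 1)) abort("`beta` must be in (0, 1).")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.")
  structure(list(sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
                 beta = beta, max_iter = as.integer(max_iter)),
            class = "iem_params")
}

#' Scale the Savitzky-Golay window to a sampling rate
#'
#' The default 25-sample window is defined at 256 Hz; other rates use
#' `round(25 * fs / 256)` forced odd.
#'
#' @param fs Sampling rate in Hz.
#' @param base Window length at 256 Hz.
#' @return Odd integer window length.
#' @export
scale_sg_window <- function(fs, base = 25L) {
  w <- max(5L, as.integer(round(base * fs / 256)))
  if (w %% 2L == 0L) w + 1L else w
}

# envelope through `knot_idx` extrema of x, mirrored to the edges;
# shape-preserving monotone cubic between knots avoids spline overshoot
# creating spurious oscillations in the envelope mean
interp_envelope <- function(x, knot_idx) {
  n <- length(x)
  idx <- knot_idx
  if (length(idx) == 0L || idx[1] != 1L) idx <- c(1L, idx)
  if (idx[length(idx)] != n) idx <- c(idx, n)
  vals <- x[idx]
  # boundary handling: the edge knots take the nearest extremum's value so
  # the envelope is flat, not extrapolated, outside the outermost extrema
  if (length(knot_idx) >= 1L) {
    vals[1] <- x[knot_idx[1]]
    vals[length(vals)] <- x[knot_idx[length(knot_idx)]]
  }
  if (length(idx) < 3L) {
    return(approx(idx, vals, xout = seq_len(n))$y)
  }
  f <- splinefun(idx, vals, method = "monoH.FC")
  f(seq_len(n))
}

#' Mean of the upper and lower envelopes of a signal
#'
#' Smooths the signal with a Savitzky-Golay filter, finds the smoothed
#' copy's local maxima and minima, and interpolates the *unsmoothed*
#' signal's values at those indices with a monotone shape-preserving cubic
#' to get the upper and lower envelopes; returns their sample-by-sample
#' mean. With fewer than 2 maxima or 2 minima the envelope degenerates to
#' the line through the first and last samples (attribute
#' `degenerate = TRUE`).
#'
#' @param x Numeric vector, longer than `params$sg_window`.
#' @param params An [iem_params()] list.
#' @return Numeric vector, same length as `x`.
#' @export
envelope_mean <- function(x, params = iem_params()) {
  n <- length(x)
  if (n <= params$sg_window) {
    abort("Signal must be longer than the Savitzky-Golay window.")
  }
  # reflect-pad so envelope knots exist beyond both window edges; the
  # padded envelopes are cropped back to the original span (keeps boundary
  # cycles from being distorted by edge effects)
  pad <- min(n - 1L, max(2L * params$sg_window, round(n / 4)))
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  sm <- as.numeric(signal::sgolayfilt(xp, p = params$sg_polyorder,
                                      n = params$sg_window))
  # the smoothed copy robustly *localizes* extrema; each knot is then
  # snapped to the residual's own extremum nearby so the envelopes pass
  # through true turning points
  snap <- function(idx, dir) {
    h <- params$sg_window %/% 2L
    out <- vapply(idx, function(i) {
      lo <- max(1L, i - h); hi <- min(length(xp), i + h)
      seg <- xp[lo:hi]
      lo - 1L + if (dir == "max") which.max(seg) else which.min(seg)
    }, integer(1))
    sort(unique(out))
  }
  mx <- snap(local_extrema_idx(sm, "max"), "max")
  mn <- snap(local_extrema_idx(sm, "min"), "min")
  if (length(mx) < 2L || length(mn) < 2L) {
    # degenerate path: no oscillatory structure; fall back to the chord
    line <- approx(c(1L, n), x[c(1L, n)], xout = seq_len(n))$y
    attr(line, "degenerate") <- TRUE
    return(line)
  }
  upper <- interp_envelope(xp, mx)
  lower <- interp_envelope(xp, mn)
  out <- (upper + lower)[(pad + 1L):(pad + n)] / 2
  attr(out, "degenerate") <- FALSE
  out
}

#' Decompose a signal into non-stationary and stationary components
#'
#' Iterates `r_{j+1} = r_j - m_j`, where `m_j` is the envelope mean of the
#' current residual, until `max|m_j| < beta * range(input)` or `max_iter`
#' iterations. The final residual is the NSTS; `sts = input - nsts`, so the
#' two components reconstruct the input exactly.
#'
#' @param x Numeric vector (recommended: a normalized `[0,1]` window),
#'   longer than `params$sg_window`.
#' @param params An [iem_params()] list.
#' @return An object of class `iem_decomposition`: list with `input`,
#'   `nsts`, `sts`, `n_iter`, `converged`, `params`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 4, by = 1/256)) + 0.3
#' dec <- iem_decompose(x)
#' max(abs(dec$input - (dec$nsts + dec$sts)))  # 0 by construction
#' @export
iem_decompose <- function(x, params = iem_params()) {
  x <- as.numeric(x)
  if (length(x) <= params$sg_window) {
    abort("Input shorter than the Savitzky-Golay window.")
  }
  rng <- diff(range(x))
  tol <- params$beta * rng
  r <- x
  converged <- FALSE
  j <- 0L
  if (rng == 0) {
    # constant input: envelopes coincide with the signal; NSTS is zero
    return(structure(list(input = x, nsts = rep(0, length(x)), sts = x,
                          n_iter = 1L, converged = TRUE, params = params),
                     class = "iem_decomposition"))
  }
  while (j < params$max_iter) {
    j <- j + 1L
    m <- envelope_mean(r, params)
    r <- r - m
    if (max(abs(m)) < tol) { converged <- TRUE; break }
  }
  r <- as.vector(r)
  structure(list(input = x, nsts = r, sts = x - r,
                 n_iter = j, converged = converged, params = params),
            class = "iem_decomposition")
}

#' @export
print.iem_decomposition <- function(x, ...) {
  cat("IEM decomposition: n =", length(x$input),
      "| iterations =", x$n_iter,
      "| converged =", x$converged, "\n")
  invisible(x)
}

#' @export
tidy.iem_decomposition <- function(x, ...) {
  tibble(sample = seq_along(x$input),
         input = x$input, nsts = x$nsts, sts = x$sts)
}

#' @export
glance.iem_decomposition <- function(x, ...) {
  tibble(n = length(x$input), n_iter = x$n_iter, converged = x$converged,
         sg_window = x$params$sg_window, beta = x$params$beta,
         max_abs_nsts = max(abs(x$nsts)))
}

#' @export
autoplot.iem_decomposition <- function(object, fs = NULL, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("input", "nsts", "sts"),
                        names_to = "component", values_to = "value") |>
    mutate(component = factor(.data$component, c("input", "nsts", "sts")))
  xcol <- "sample"
  if (!is.null(fs)) {
    df$time <- (df$sample - 1) / fs
    xcol <- "time"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xcol]], y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = if (xcol == "time") "time (s)" else "sample")
}
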