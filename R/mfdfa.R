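#' Cumulative profile of a time series
#'
#' Builds the mean-centered cumulative sum ("profile") that MF-DFA detrends:
#' \eqn{X(k) = \sum_{i \le k} (x_i - \bar x)}. The profile of any finite series
#' ends at zero (up to floating point), because deviations from the mean sum
#' to zero.
#'
#' @param x Numeric vector, the raw series (e.g. one marker coordinate).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' mf_profile(c(1, 2, 3)) # -1 -1 0
#' @export
mf_profile <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("`x` must be a numeric vector of length >= 2", call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0) {
    stop("non-finite value in `x` at index ", bad[1], call. = FALSE)
  }
  cumsum(x - mean(x))
}

#' Per-window detrending residual variances
#'
#' Partitions a profile into non-overlapping windows of length `s`, fits an
#' ordinary least-squares polynomial of degree `order` in each window, and
#' returns the mean squared residual \eqn{F^2(s, v)} per window.
#'
#' With `segmentation = "forward"` the profile is split from the start into
#' `floor(N / s)` windows and the tail remainder is discarded. With
#' `"bidirectional"` the split is repeated from the end of the profile as
#' well, giving `2 * floor(N / s)` windows so no samples are lost.
#'
#' @param profile Numeric vector, typically from [mf_profile()].
#' @param s Integer window length (scale); must satisfy `s >= order + 2`.
#' @param order Polynomial detrending degree (default 1, i.e. MF-DFA1).
#' @param segmentation `"forward"` or `"bidirectional"`.
#' @return Numeric vector of non-negative mean squared residuals, one per
#'   window.
#' @export
mf_segment_rss <- function(profile, s, order = 1L,
                           segmentation = c("forward", "bidirectional")) {
  segmentation <- match.arg(segmentation)
  n <- length(profile)
  s <- as.integer(s)
  if (s < order + 2L) stop("scale s = ", s, " must be >= order + 2", call. = FALSE)
  if (s > n) stop("scale s = ", s, " exceeds series length ", n, call. = FALSE)
  L <- n %/% s
  f2 <- .window_msr(profile[seq_len(L * s)], s, L, order)
  if (segmentation == "bidirectional") {
    rev_part <- profile[seq.int(n - L * s + 1L, n)]
    f2 <- c(f2, .window_msr(rev_part, s, L, order))
  }
  f2
}

# Mean squared OLS residual in each of L consecutive windows of length s.
# One QR decomposition of the shared Vandermonde design serves all windows.
.window_msr <- function(seg, s, L, order) {
  m <- matrix(seg, nrow = s, ncol = L)
  X <- outer(seq_len(s), 0:order, `^`)
  qrX <- qr(X)
  res <- m - X %*% qr.coef(qrX, m)
  colMeans(res^2)
}

#' q-th order fluctuation function for one scale
#'
#' Collapses the per-window residual variances \eqn{F^2(s, v)} into the
#' scalar fluctuation function \eqn{F_q(s)}: the generalized (power) mean
#' \deqn{F_q(s) = \left\{ \frac{1}{M}\sum_v [F^2(s,v)]^{q/2} \right\}^{1/q}}
#' for \eqn{q \ne 0}, and the logarithmic average
#' \eqn{F_0(s) = \exp\{\frac{1}{2M}\sum_v \ln F^2(s,v)\}} at \eqn{q = 0},
#' which is the \eqn{q \to 0} limit of the power mean.
#'
#' Windows with exactly zero residual variance make negative-order moments
#' (and the log average) undefined; they are dropped from the mean when
#' `zero_policy = "exclude"` (the count is attached as attribute
#' `"n_zero_dropped"`), or replaced by `floor` when `zero_policy = "floor"`.
#'
#' @param f2 Numeric vector of per-window mean squared residuals.
#' @param q Real moment order.
#' @param zero_policy `"exclude"` or `"floor"`.
#' @param floor Replacement value for zero residuals under `"floor"`.
#' @return A positive scalar.
#' @export
mf_fq <- function(f2, q, zero_policy = c("exclude", "floor"), floor = 1e-15) {
  zero_policy <- match.arg(zero_policy)
  if (any(f2 < 0)) stop("negative residual variance", call. = FALSE)
  n_zero <- 0L
  if (q <= 0 && any(f2 == 0)) {
    if (zero_policy == "exclude") {
      n_zero <- sum(f2 == 0)
      f2 <- f2[f2 > 0]
      if (length(f2) == 0) {
        stop("all windows have zero residual variance; q <= 0 moments undefined",
             call. = FALSE)
      }
    } else {
      f2 <- pmax(f2, floor)
    }
  }
  out <- if (q == 0) exp(mean(log(f2)) / 2) else mean(f2^(q / 2))^(1 / q)
  if (n_zero > 0) attr(out, "n_zero_dropped") <- n_zero
  out
}

#' Generalized Hurst exponents from a fluctuation surface
#'
#' Fits, separately for each moment order q, the log-log regression
#' \eqn{\log F_q(s) = h(q) \log s + c} across scales, returning the slope
#' `h` and the coefficient of determination of each fit.
#'
#' @param fluctuations A data frame with columns `q`, `s`, `fq` (as produced
#'   by [mfdfa()]).
#' @return A tibble with columns `q`, `h`, `r2`.
#' @export
mf_hurst <- function(fluctuations) {
  stopifnot(all(c("q", "s", "fq") %in% names(fluctuations)))
  if (length(unique(fluctuations$s)) < 3) {
    stop("need at least 3 scales to estimate h(q)", call. = FALSE)
  }
  if (any(fluctuations$fq <= 0)) stop("non-positive F_q(s)", call. = FALSE)
  wide <- tidyr::pivot_wider(fluctuations[, c("q", "s", "fq")],
                             names_from = "q", values_from = "fq")
  wide <- dplyr::arrange(wide, .data$s)
  qs <- as.numeric(names(wide)[-1])
  .hurst_fast(wide$s, as.matrix(wide[, -1]), qs)
}

# One multi-response OLS of log F_q(s) on log s: fq_mat is scales x q.
.hurst_fast <- function(scales, fq_mat, q) {
  X <- cbind(1, log(scales))
  Y <- log(fq_mat)
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  ssr <- colSums(res^2)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  coefs <- matrix(fit$coefficients, nrow = 2)
  tibble::tibble(q = q, h = unname(coefs[2, ]),
                 r2 = unname(ifelse(sst > 0, 1 - ssr / sst, 1)))
}

#' Singularity spectrum by Legendre transform
#'
#' Converts generalized Hurst exponents into the multifractal spectrum:
#' \eqn{\tau(q) = q\,h(q) - 1}, the singularity exponent
#' \eqn{\alpha = d\tau/dq} (central finite differences, one-sided at the
#' grid ends), and \eqn{f(\alpha) = q\alpha - \tau(q)}.
#'
#' @param hurst A data frame with columns `q`, `h` (from [mf_hurst()]).
#' @return A tibble with columns `q`, `h`, `tau`, `alpha`, `f_alpha`.
#' @export
mf_spectrum <- function(hurst) {
  stopifnot(all(c("q", "h") %in% names(hurst)))
  hurst <- dplyr::arrange(hurst, .data$q)
  q <- hurst$q
  if (length(q) < 3) stop("q grid needs at least 3 points", call. = FALSE)
  tau <- q * hurst$h - 1
  alpha <- .grad_central(q, tau)
  tibble::tibble(q = q, h = hurst$h, tau = tau, alpha = alpha,
                 f_alpha = q * alpha - tau)
}

# F_q over a whole q grid at once; same conventions as mf_fq().
.fq_vec <- function(f2, q, zero_policy, floor) {
  f2nz <- f2
  if (any(f2 == 0)) {
    if (zero_policy == "exclude") {
      f2nz <- f2[f2 > 0]
      if (length(f2nz) == 0 && any(q <= 0)) {
        stop("all windows have zero residual variance; q <= 0 moments ",
             "undefined", call. = FALSE)
      }
    } else {
      f2nz <- pmax(f2, floor)
    }
  }
  out <- numeric(length(q))
  for (j in seq_along(q)) {
    qi <- q[j]
    out[j] <- if (qi > 0) {
      mean(f2^(qi / 2))^(1 / qi)
    } else if (qi == 0) {
      exp(mean(log(f2nz)) / 2)
    } else {
      mean(f2nz^(qi / 2))^(1 / qi)
    }
  }
  out
}

# Gradient on a (possibly non-uniform) grid: three-point central differences
# in the interior, one-sided at the ends.
.grad_central <- function(x, y) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Stability summary of a singularity spectrum
#'
#' Reduces a spectrum to the generalized fractal parameters used as
#' motion-stability descriptors: `alpha_min`, `alpha_max` (extremes of the
#' singularity exponent over the q grid), `alpha_0` (the exponent where
#' \eqn{f(\alpha)} peaks), the spectrum width `delta_alpha = alpha_max -
#' alpha_min`, the arm-height contrast `delta_f = f(alpha_min) -
#' f(alpha_max)`, and the stability index
#' \deqn{D(\alpha) = |\alpha_{max} - \alpha_0| - |\alpha_{min} - \alpha_0|,}
#' the asymmetry between the spectrum's right and left arms. Lower
#' \eqn{D(\alpha)} indicates more stable motion. `d_alpha = "printed"`
#' selects the alternative form \eqn{|\alpha_{max} - \alpha_0| - \alpha_{min}
#' - \alpha_0} for comparison.
#'
#' A degenerate (monofractal) spectrum where all alpha coincide yields zero
#' width and zero asymmetry, flagged in the `monofractal` column.
#'
#' @param spectrum A data frame with columns `q`, `alpha`, `f_alpha`.
#' @param d_alpha `"arm_asymmetry"` (default) or `"printed"`.
#' @return A one-row tibble with columns `alpha_min`, `alpha_max`, `alpha_0`,
#'   `delta_alpha`, `delta_f`, `d_alpha`, `monofractal`.
#' @export
mf_summary <- function(spectrum, d_alpha = c("arm_asymmetry", "printed")) {
  d_alpha <- match.arg(d_alpha)
  stopifnot(all(c("alpha", "f_alpha") %in% names(spectrum)))
  a <- spectrum$alpha
  f <- spectrum$f_alpha
  if (any(!is.finite(a)) || any(!is.finite(f))) {
    stop("non-finite spectrum", call. = FALSE)
  }
  a_min <- min(a)
  a_max <- max(a)
  a0 <- a[which.max(f)]
  mono <- isTRUE(all.equal(a_min, a_max, tolerance = 1e-12))
  if (mono) {
    return(tibble::tibble(alpha_min = a_min, alpha_max = a_max, alpha_0 = a0,
                          delta_alpha = 0, delta_f = 0, d_alpha = 0,
                          monofractal = TRUE))
  }
  d <- if (d_alpha == "arm_asymmetry") {
    abs(a_max - a0) - abs(a_min - a0)
  } else {
    abs(a_max - a0) - a_min - a0
  }
  tibble::tibble(alpha_min = a_min, alpha_max = a_max, alpha_0 = a0,
                 delta_alpha = a_max - a_min,
                 delta_f = f[which.min(a)] - f[which.max(a)],
                 d_alpha = d, monofractal = FALSE)
}

#' Default analysis scales
#'
#' About `n_scales` geometrically spaced integer window lengths from
#' `max(16, order + 2)` to `floor(n / 4)`.
#'
#' @param n Series length.
#' @param order Detrending order (lower bound guard).
#' @param n_scales Target number of scales.
#' @return Sorted integer vector of distinct scales.
#' @export
mf_default_scales <- function(n, order = 1L, n_scales = 20L) {
  lo <- max(16L, order + 2L)
  hi <- n %/% 4L
  if (hi < lo + 2L) stop("series too short (n = ", n, ") for scale grid", call. = FALSE)
  unique(round(exp(seq(log(lo), log(hi), length.out = n_scales))))
}

#' Multifractal detrended fluctuation analysis
#'
#' Runs the full MF-DFA chain on a scalar series: profile construction,
#' windowed polynomial detrending at every scale, q-th order fluctuation
#' functions, log-log estimation of the generalized Hurst exponents h(q),
#' the Legendre singularity spectrum, and the stability summary including
#' the spectrum-asymmetry index D(alpha).
#'
#' The analysis is fully deterministic given the input and configuration;
#' all intermediates are returned for inspection and plotting.
#'
#' @param x Numeric series (e.g. one marker coordinate at 60 Hz).
#' @param scales Integer window lengths; default [mf_default_scales()].
#' @param q Moment orders; default a symmetric grid `seq(-5, 5, by = 0.5)`
#'   including 0 (handled by the logarithmic average).
#' @param order Polynomial detrending degree, default 1.
#' @param segmentation `"forward"` (remainder discarded, the default) or
#'   `"bidirectional"` (windows also taken from the tail).
#' @param d_alpha Passed to [mf_summary()].
#' @param zero_policy,floor Passed to [mf_fq()].
#' @return An object of class `"mfdfa"`: a list with tibbles
#'   `fluctuations` (q, s, fq, n_windows), `hurst` (q, h, r2),
#'   `spectrum` (q, h, tau, alpha, f_alpha), `summary` (one row), and the
#'   `config` used (provenance, including the q range that truncates
#'   alpha_min/alpha_max).
#' @examples
#' fit <- mfdfa(gen_fgn(1024, hurst = 0.5, seed = 1))
#' glance(fit)$d_alpha
#' @export
mfdfa <- function(x, scales = NULL, q = seq(-5, 5, by = 0.5), order = 1L,
                  segmentation = c("forward", "bidirectional"),
                  d_alpha = c("arm_asymmetry", "printed"),
                  zero_policy = c("exclude", "floor"), floor = 1e-15) {
  segmentation <- match.arg(segmentation)
  d_alpha <- match.arg(d_alpha)
  zero_policy <- match.arg(zero_policy)
  prof <- mf_profile(x)
  n <- length(prof)
  if (is.null(scales)) scales <- mf_default_scales(n, order)
  scales <- sort(unique(as.integer(scales)))
  if (min(scales) <= order + 1L) stop("min(scales) must exceed order + 1", call. = FALSE)
  if (max(scales) > n %/% 4L) stop("max(scales) must be <= n/4", call. = FALSE)
  if (length(q) < 3) stop("q grid needs at least 3 points", call. = FALSE)
  q <- sort(q)

  if (diff(range(x)) == 0) {
    # constant input: the profile is identically zero, every residual
    # vanishes, and the series is monofractal by convention
    return(structure(
      list(fluctuations = tidyr::expand_grid(q = q, s = scales) |>
             dplyr::mutate(fq = 0, n_windows = n %/% .data$s),
           hurst = tibble::tibble(q = q, h = NA_real_, r2 = NA_real_),
           spectrum = tibble::tibble(q = q, h = NA_real_, tau = NA_real_,
                                     alpha = NA_real_, f_alpha = NA_real_),
           summary = tibble::tibble(alpha_min = NA_real_, alpha_max = NA_real_,
                                    alpha_0 = NA_real_, delta_alpha = 0,
                                    delta_f = 0, d_alpha = 0,
                                    monofractal = TRUE),
           config = list(n = n, scales = scales, q_range = range(q),
                         q_step = if (length(q) > 1) diff(q)[1] else NA_real_,
                         order = order, segmentation = segmentation,
                         d_alpha = d_alpha, zero_policy = zero_policy)),
      class = "mfdfa"
    ))
  }

  fq_mat <- matrix(NA_real_, length(scales), length(q))
  n_windows <- integer(length(scales))
  for (i in seq_along(scales)) {
    s <- scales[i]
    f2 <- tryCatch(
      mf_segment_rss(prof, s, order, segmentation),
      error = function(e) stop("detrending stage at scale ", s, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    n_windows[i] <- length(f2)
    fq_mat[i, ] <- .fq_vec(f2, q, zero_policy, floor)
  }
  q_long <- rep(q, each = length(scales))
  s_long <- rep(scales, times = length(q))
  nw_long <- rep(n_windows, times = length(q))
  fluct <- tibble::tibble(q = q_long, s = s_long, fq = as.vector(fq_mat),
                          n_windows = nw_long)
  hurst <- .hurst_fast(scales, fq_mat, q)
  spectrum <- mf_spectrum(hurst)
  summ <- mf_summary(spectrum, d_alpha)
  structure(
    list(fluctuations = fluct, hurst = hurst, spectrum = spectrum,
         summary = summ,
         config = list(n = n, scales = scales, q_range = range(q),
                       q_step = if (length(q) > 1) diff(q)[1] else NA_real_,
                       order = order, segmentation = segmentation,
                       d_alpha = d_alpha, zero_policy = zero_policy)),
    class = "mfdfa"
  )
}

#' @export
print.mfdfa <- function(x, ...) {
  s <- x$summary
  cat("<mfdfa> n =", x$config$n, "| scales", min(x$config$scales), "..",
      max(x$config$scales), "| q in [", x$config$q_range[1], ",",
      x$config$q_range[2], "]\n")
  cat(sprintf("  h(2) = %.3f  delta_alpha = %.3f  D(alpha) = %.3f\n",
              x$hurst$h[x$hurst$q == 2][1], s$delta_alpha, s$d_alpha))
  invisible(x)
}

#' Tidy an mfdfa fit
#'
#' Returns the singularity spectrum as a tibble, one row per moment order q.
#' @param x An `mfdfa` object.
#' @param ... Unused.
#' @export
tidy.mfdfa <- function(x, ...) x$spectrum

#' One-row summary of an mfdfa fit
#'
#' Returns the stability summary (alpha extremes, spectrum width
#' `delta_alpha`, `delta_f`, and the asymmetry index `d_alpha`) together
#' with the h(2) estimate.
#' @param x An `mfdfa` object.
#' @param ... Unused.
#' @export
glance.mfdfa <- function(x, ...) {
  h2 <- x$hurst$h[which.min(abs(x$hurst$q - 2))]
  dplyr::mutate(x$summary, h2 = h2)
}

#' Plot an mfdfa singularity spectrum
#'
#' The classic inverted-bell f(alpha) curve; the peak marks alpha_0, and the
#' horizontal extent is the spectrum width delta_alpha.
#' @param object An `mfdfa` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mfdfa <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$spectrum, ggplot2::aes(x = .data$alpha, y = .data$f_alpha)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = s$alpha_0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(alpha), y = expression(f(alpha)),
                  title = sprintf("Singularity spectrum (D(alpha) = %.3f)",
                                  s$d_alpha)) +
    ggplot2::theme_minimal()
}

#' Export an mfdfa fit as tidy tables
#'
#' Writes the long spectrum table (q, h, tau, alpha, f_alpha joined with the
#' per-scale fluctuation functions) as a tab-separated file and the stability
#' summary plus configuration as a JSON sidecar.
#'
#' @param x An `mfdfa` object.
#' @param path Output path for the table; the JSON summary is written next to
#'   it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_mfdfa <- function(x, path) {
  wide <- tidyr::pivot_wider(x$fluctuations, id_cols = "q",
                             names_from = "s", values_from = "fq",
                             names_prefix = "F_s")
  tab <- dplyr::left_join(x$spectrum, wide, by = "q")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(as.list(x$summary[, c("alpha_min", "alpha_max", "alpha_0",
                                  "delta_alpha", "delta_f", "d_alpha")]),
            list(config = x$config))
  jsonlite::write_json(side, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
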