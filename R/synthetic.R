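#' The 42-marker body model
#'
#' The fixed set of 42 anatomical landmark names, in serial order, each
#' tracked in three planes (x = sagittal, y = coronal, z = transverse) for a
#' total of 126 scalar channels per subject. Serial numbers 1..126 follow
#' marker-major, plane-minor (x, y, z) order.
#'
#' @return A tibble with columns `serial`, `marker`, `plane`, `channel`
#'   (126 rows); `channel` is the canonical `"<marker>_<plane>"` column name
#'   with spaces replaced by underscores.
#' @export
marker_model <- function() {
  markers <- c(
    "R dorsum of foot", "L dorsum of foot",
    "R posterior aspect of the heel", "L posterior aspect of the heel",
    "R lateral malleoli", "L lateral malleoli",
    "R distal-lateral aspect of the shank", "L distal-lateral aspect of the shank",
    "R lateral femoral epicondyle", "L lateral femoral epicondyle",
    "R distal-lateral aspect of the thigh", "L distal-lateral aspect of the thigh",
    "R anterior superior iliac spine", "L anterior superior iliac spine",
    "sacral",
    "R scapular acromion", "L scapular acromion",
    "R lateral humeral epicondyles", "L lateral humeral epicondyles",
    "R dorsal wrist lines", "L dorsal wrist lines",
    "superior apex of the head",
    "R temple regions", "L temple regions",
    "R medial malleoli", "L medial malleoli",
    "R medial femoral epicondyles", "L medial femoral epicondyles",
    "A lower thorax", "P lower thorax",
    "A cervical vertebra", "P cervical vertebra",
    "perineum",
    "R toe", "L toe", "R heel", "L heel",
    "R finger tip", "L finger tip",
    "front head", "rear head",
    "R offset"
  )
  stopifnot(length(markers) == 42L)
  grid <- tidyr::expand_grid(marker = markers, plane = c("x", "y", "z"))
  grid$serial <- seq_len(nrow(grid))
  grid$channel <- paste(gsub("[ -]", "_", grid$marker), grid$plane, sep = "_")
  grid[, c("serial", "marker", "plane", "channel")]
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Exact spectral synthesis (Davies-Harte): the fGn autocovariance
#' \eqn{\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})} is
#' embedded in a circulant matrix whose eigenvalues are obtained by FFT,
#' giving a stationary Gaussian series with Hurst exponent `hurst`.
#'
#' @param n Series length, a power of two >= 64.
#' @param hurst Hurst exponent in (0, 1); 0.5 gives white noise.
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @return Numeric vector of length `n`, unit marginal variance.
#' @export
gen_fgn <- function(n, hurst, seed) {
  if (hurst <= 0 || hurst >= 1) stop("`hurst` must lie in (0, 1)", call. = FALSE)
  if (n < 64 || bitwAnd(n, n - 1L) != 0) {
    stop("`n` must be a power of two >= 64", call. = FALSE)
  }
  k <- 0:n
  gamma <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                    abs(k - 1)^(2 * hurst))
  row1 <- c(gamma, gamma[n:2])              # circulant of size 2n
  ev <- Re(stats::fft(row1))
  ev[ev < 0] <- 0                           # clip tiny negative round-off
  m <- 2L * n
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  w <- stats::fft(sqrt(ev / m) * z)
  Re(w)[seq_len(n)]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Binomial multiplicative cascade
#'
#' The canonical multifractal test measure: starting from mass 1 on one
#' interval, each refinement level splits every interval in two and
#' multiplies the halves by `a` and `1 - a` (deterministic) or by a per-node
#' random assignment of the two weights (`randomize = TRUE`). After `levels`
#' refinements the `2^levels` cell masses sum to 1. `a = 0.5` gives the
#' uniform (monofractal) measure; larger `a` widens the singularity
#' spectrum: the closed-form generalized Hurst exponent of the measure
#' series is \eqn{h(q) = 1/q - \log_2(a^q + (1-a)^q)/q}.
#'
#' @param levels Number of refinement levels (series length `2^levels`);
#'   capped at 20 as a size guard.
#' @param a Larger branch weight, in `[0.5, 1)`.
#' @param seed Integer seed, used only when `randomize = TRUE`.
#' @param randomize Shuffle the weight pair independently at every node.
#' @return Numeric vector of `2^levels` non-negative masses summing to 1.
#' @export
gen_cascade <- function(levels, a, seed = NULL, randomize = FALSE) {
  if (a < 0.5 || a >= 1) stop("`a` must lie in [0.5, 1)", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 1 || levels > 20) stop("`levels` must be in 1..20", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  if (randomize) {
    if (is.null(seed)) stop("`seed` required when randomize = TRUE", call. = FALSE)
    set.seed(as.integer(seed))
  }
  w <- 1
  for (l in seq_len(levels)) {
    flip <- if (randomize) stats::runif(length(w)) < 0.5 else rep(FALSE, length(w))
    left <- ifelse(flip, 1 - a, a)
    w <- as.vector(rbind(w * left, w * (1 - left)))
  }
  w
}

#' Closed-form h(q) of the binomial cascade
#'
#' Reference scaling exponents of the deterministic binomial measure,
#' \eqn{h(q) = 1/q - \log_2(a^q + (1-a)^q)/q} for \eqn{q \ne 0}, used as an
#' independent oracle for the MF-DFA estimator.
#'
#' @param q Moment orders (nonzero).
#' @param a Branch weight.
#' @return Numeric vector of exponents.
#' @export
cascade_hq <- function(q, a) {
  stopifnot(all(q != 0))
  1 / q - log2(a^q + (1 - a)^q) / q
}

#' Closed-form singularity exponent alpha(q) of the binomial cascade
#'
#' @param q Moment orders.
#' @param a Branch weight.
#' @return Numeric vector, \eqn{\alpha(q) = -d/dq\, \log_2(a^q + (1-a)^q)}.
#' @export
cascade_alpha <- function(q, a) {
  b <- 1 - a
  -(a^q * log(a) + b^q * log(b)) / ((a^q + b^q) * log(2))
}

# Canonical (non-conservative) binomial cascade: every child independently
# receives weight a with probability `bias`, else 1 - a. The branch bias
# breaks the left/right symmetry of the singularity spectrum, so the
# spectrum asymmetry D(alpha) of a signal modulated by this cascade grows
# with a. Returned masses are normalized to mean 1.
.canonical_cascade <- function(levels, a, bias, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  w <- 1
  for (l in seq_len(levels)) {
    w2 <- rep(w, each = 2)
    pick <- stats::runif(length(w2)) < bias
    w <- w2 * ifelse(pick, a, 1 - a)
  }
  w / mean(w)
}

#' One synthetic marker-coordinate trajectory
#'
#' Emulates the statistical structure the stability analysis assumes in a
#' gait recording: a quasi-periodic base -- a sinusoid near the typical
#' 1 Hz stride frequency whose amplitude and phase jitter from cycle to
#' cycle -- whose instantaneous amplitude is modulated by a canonical
#' binomial volatility cascade with weight `a` and a branch-selection bias
#' toward the larger weight. The bias makes the modulated signal's
#' singularity spectrum right-skewed, so both the spectrum width
#' delta_alpha and the asymmetry index D(alpha) grow with `a`; this is the
#' group-separation mechanism used by [gen_cohort()].
#'
#' `noise_sd` is the modulation depth: the amplitude envelope is
#' `w^noise_sd` (mean-normalized), so 0 disables the multifractal component
#' entirely (with `jitter = 0` the output is then a pure sinusoid) and 1 is
#' full cascade modulation.
#'
#' @param n_samples Series length (samples at `rate` Hz); at least 10 s.
#' @param a Cascade weight in `[0.5, 1)` controlling multifractal strength.
#' @param seed Integer seed.
#' @param rate Sampling rate in Hz (default 60).
#' @param stride_hz Mean stride frequency (default 1 Hz).
#' @param base_amp Sinusoid amplitude (default 1, arbitrary length units).
#' @param jitter Relative SD of the per-cycle amplitude/phase jitter
#'   (default 0.1; 0 disables it).
#' @param noise_sd Multifractal modulation depth in `[0, 1]` (default 1).
#' @param bias Cascade branch-selection bias in `[0.5, 1)` (default 0.8).
#' @return Numeric vector of length `n_samples`.
#' @export
gen_marker_trajectory <- function(n_samples, a, seed, rate = 60,
                                  stride_hz = 1, base_amp = 1,
                                  jitter = 0.1, noise_sd = 1, bias = 0.8) {
  if (n_samples < 10 * rate) stop("need at least 10 s of signal", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  t <- seq_len(n_samples) / rate
  n_cycles <- ceiling(max(t) * stride_hz) + 1L
  amp_j <- if (jitter > 0) stats::rnorm(n_cycles, 1, jitter) else rep(1, n_cycles)
  ph_j <- if (jitter > 0) stats::rnorm(n_cycles, 0, jitter) else rep(0, n_cycles)
  cycle <- pmin(floor(t * stride_hz) + 1L, n_cycles)
  base <- base_amp * amp_j[cycle] * sin(2 * pi * stride_hz * t + ph_j[cycle])
  if (noise_sd > 0) {
    levels <- as.integer(ceiling(log2(n_samples)))
    w <- .canonical_cascade(levels, a, bias, seed = as.integer(seed) + 1L)
    m <- w[seq_len(n_samples)]^noise_sd
    base <- base * (m / mean(m))
  }
  base
}

#' Cohort specification
#'
#' Bundles the parameters of a synthetic cohort: group sizes by sex and fall
#' status (defaults: 1 male + 8 female fallers, 17 male + 20 female
#' nofallers, i.e. 9 fallers vs 37 nofallers), recording duration, the
#' group-specific cascade weights that control the D(alpha) separation, the
#' fluctuation amplitude, and the master seed.
#'
#' @param n_faller_male,n_faller_female,n_nofaller_male,n_nofaller_female
#'   Group counts (non-negative).
#' @param duration Recording duration in seconds (default 60).
#' @param asymmetry_faller,asymmetry_nofaller Cascade weight `a` per group
#'   in `[0.5, 1)`; defaults 0.75 and 0.62.
#' @param noise_sd Multifractal modulation depth in `[0, 1]` (default 1).
#' @param seed Master seed; all subject-, marker-, and plane-level seeds are
#'   derived from it.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_faller_male = 1L, n_faller_female = 8L,
                        n_nofaller_male = 17L, n_nofaller_female = 20L,
                        duration = 60, asymmetry_faller = 0.75,
                        asymmetry_nofaller = 0.62, noise_sd = 1,
                        seed = 1L) {
  counts <- c(n_faller_male, n_faller_female, n_nofaller_male, n_nofaller_female)
  if (any(counts < 0)) stop("group counts must be >= 0", call. = FALSE)
  for (a in c(asymmetry_faller, asymmetry_nofaller)) {
    if (a < 0.5 || a >= 1) stop("asymmetry weights must lie in [0.5, 1)", call. = FALSE)
  }
  structure(list(n_faller_male = as.integer(n_faller_male),
                 n_faller_female = as.integer(n_faller_female),
                 n_nofaller_male = as.integer(n_nofaller_male),
                 n_nofaller_female = as.integer(n_nofaller_female),
                 duration = duration,
                 asymmetry_faller = asymmetry_faller,
                 asymmetry_nofaller = asymmetry_nofaller,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Reference baseline moments per sex-by-status cell: age (years) and BMI
# (kg/m^2) means and SDs used to sample subject covariates. The single male
# faller's values are fixed when that cell has exactly one subject.
.baseline_params <- function() {
  tibble::tibble(
    label = c("faller", "faller", "nofaller", "nofaller"),
    sex = c("male", "female", "male", "female"),
    age_mean = c(73, 69, 71.9, 71.6),
    age_sd = c(0, 5.10, 7.18, 7.44),
    bmi_mean = c(24.3, 23.2, 25.7, 25.6),
    bmi_sd = c(0, 2.79, 3.18, 3.01)
  )
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lo | x > hi)) {
    i <- which(x < lo | x > hi)
    x[i] <- stats::rnorm(length(i), mean, sd)
  }
  x
}

#' Generate a synthetic motion-capture cohort
#'
#' Produces one recording per subject -- 126 channels (42 markers x 3
#' planes) at 60 Hz -- with group-specific multifractal structure, plus a
#' baseline table of subject covariates (age and BMI drawn as truncated
#' normals from the per-cell reference moments; ages bounded below at 61).
#' Deterministic under the spec's master seed: per-subject seeds and
#' per-channel seeds are drawn from seeded RNG streams so any subject or
#' channel can be regenerated in isolation.
#'
#' @param spec A [cohort_spec()].
#' @param channels Optional subset of channel serial numbers (1..126) to
#'   generate; defaults to all. Restricting channels speeds up simulation
#'   studies without changing the retained channels' values.
#' @return A list of class `"mf_cohort"` with elements `subjects` (a tibble:
#'   subject_id, label, sex, age, bmi) and `recordings` (a named list of
#'   tibbles; each has a `time` column in seconds and one column per
#'   generated channel, named as in [marker_model()]), plus `rate` (60) and
#'   the `spec`.
#' @export
gen_cohort <- function(spec = cohort_spec(), channels = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  mm <- marker_model()
  if (is.null(channels)) channels <- mm$serial
  mm_sub <- mm[mm$serial %in% channels, ]
  rate <- 60
  n_samples <- as.integer(round(spec$duration * rate))

  cells <- tibble::tibble(
    label = rep(c("faller", "faller", "nofaller", "nofaller"),
                c(spec$n_faller_male, spec$n_faller_female,
                  spec$n_nofaller_male, spec$n_nofaller_female)),
    sex = rep(c("male", "female", "male", "female"),
              c(spec$n_faller_male, spec$n_faller_female,
                spec$n_nofaller_male, spec$n_nofaller_female))
  )
  n <- nrow(cells)
  if (n == 0) warning("cohort spec yields zero subjects")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))

  bp <- .baseline_params()
  subjects <- cells
  subjects$subject_id <- sprintf("S%03d", seq_len(n))
  subjects$age <- NA_real_
  subjects$bmi <- NA_real_
  for (i in seq_len(nrow(bp))) {
    idx <- which(subjects$label == bp$label[i] & subjects$sex == bp$sex[i])
    if (length(idx) == 0) next
    subjects$age[idx] <- round(.rtruncnorm(length(idx), bp$age_mean[i],
                                           bp$age_sd[i], 61, 95))
    subjects$bmi[idx] <- round(.rtruncnorm(length(idx), bp$bmi_mean[i],
                                           bp$bmi_sd[i], 15, 45), 1)
  }
  subjects <- subjects[, c("subject_id", "label", "sex", "age", "bmi")]

  recordings <- vector("list", n)
  names(recordings) <- subjects$subject_id
  for (i in seq_len(n)) {
    a <- if (subjects$label[i] == "faller") spec$asymmetry_faller else spec$asymmetry_nofaller
    set.seed(subject_seeds[i])
    all_ch_seeds <- sample.int(.Machine$integer.max - 1L, nrow(mm))
    ch_seeds <- all_ch_seeds[mm_sub$serial]  # invariant under channel subsetting
    series <- purrr::map2(ch_seeds, seq_len(nrow(mm_sub)), function(sd_i, j) {
      gen_marker_trajectory(n_samples, a = a, seed = sd_i, rate = rate,
                            noise_sd = spec$noise_sd)
    })
    names(series) <- mm_sub$channel
    recordings[[i]] <- tibble::as_tibble(
      c(list(time = seq_len(n_samples) / rate), series)
    )
  }
  structure(list(subjects = subjects, recordings = recordings,
                 rate = rate, channels = mm_sub, spec = spec),
            class = "mf_cohort")
}

#' @export
print.mf_cohort <- function(x, ...) {
  cat("<mf_cohort>", nrow(x$subjects), "subjects (",
      sum(x$subjects$label == "faller"), "fallers ),",
      nrow(x$channels), "channels at", x$rate, "Hz,",
      x$spec$duration, "s\n")
  invisible(x)
}
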