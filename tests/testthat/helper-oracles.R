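# Independent brute-force oracles, kept deliberately naive and separate from
# the package's vectorized implementations.

# F_q(s) by explicit loops: window-by-window polynomial fits via lm(), then
# the power mean (or log average at q = 0).
naive_fq <- function(x, s, q, order = 1) {
  prof <- cumsum(x - mean(x))
  L <- length(prof) %/% s
  f2 <- numeric(L)
  for (v in seq_len(L)) {
    seg <- prof[((v - 1) * s + 1):(v * s)]
    j <- seq_len(s)
    fit <- stats::lm(seg ~ stats::poly(j, degree = order, raw = TRUE))
    f2[v] <- mean(stats::residuals(fit)^2)
  }
  if (q == 0) exp(mean(log(f2)) / 2) else mean(f2^(q / 2))^(1 / q)
}

# Pooled-variance two-sample t-test from the textbook formulas.
naive_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Brute-force proximal objective for the L1/2 penalty, minimized on a grid
# refined by optimize().
naive_half_prox <- function(c, lambda) {
  obj <- function(z) 0.5 * (z - c)^2 + lambda * sqrt(abs(z))
  grid <- seq(min(0, 2 * c), max(0, 2 * c), length.out = 4001)
  z0 <- grid[which.min(vapply(grid, obj, numeric(1)))]
  ref <- stats::optimize(obj, c(z0 - 0.01, z0 + 0.01), tol = 1e-10)$minimum
  cand <- c(0, ref)
  cand[which.min(vapply(cand, obj, numeric(1)))]
}

# A small fabricated feature tibble (no MF-DFA involved) for statistics and
# classifier tests: `offset` shifts the faller group on every channel.
fake_features <- function(n_faller = 9, n_nofaller = 37, p = 6, offset = 0,
                          seed = 1) {
  set.seed(seed)
  n <- n_faller + n_nofaller
  lab <- rep(c("faller", "nofaller"), c(n_faller, n_nofaller))
  m <- matrix(rnorm(n * p), n, p)
  m[lab == "faller", ] <- m[lab == "faller", ] + offset
  mm <- mfgait::marker_model()[seq_len(p), ]
  colnames(m) <- sprintf("%03d_%s", mm$serial, mm$channel)
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), label = lab,
                   sex = rep_len(c("female", "male"), n),
                   age = round(runif(n, 65, 85)), bmi = round(runif(n, 20, 30), 1)),
    tibble::as_tibble(m)
  )
  attr(out, "channel_map") <- dplyr::mutate(mm, column = colnames(m))
  out
}

# A tiny synthetic cohort for io/pipeline tests.
tiny_cohort <- function(seed = 11, channels = 1:4, duration = 12) {
  mfgait::gen_cohort(
    mfgait::cohort_spec(n_faller_male = 1, n_faller_female = 2,
                        n_nofaller_male = 2, n_nofaller_female = 3,
                        duration = duration, seed = seed),
    channels = channels
  )
}
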