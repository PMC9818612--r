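test_that("profile is the cumulative sum of mean-centered values", {
  expect_equal(mf_profile(c(5, 5, 5, 5)), c(0, 0, 0, 0))
  expect_equal(mf_profile(c(1, 2, 3)), c(-1, -1, 0))
  set.seed(4)
  x <- rnorm(257, mean = 3)
  prof <- mf_profile(x)
  expect_length(prof, length(x))
  expect_lt(abs(prof[length(prof)]), 1e-9 * length(x) * max(abs(x)))
  expect_error(mf_profile(c(1, NA, 3)), "index 2")
})

test_that("window residuals match least squares and window counts", {
  # an exactly linear profile leaves zero residual under order-1 detrending
  lin <- 0.7 * (1:60) - 3
  expect_equal(mf_segment_rss(lin, 10, order = 1), rep(0, 6), tolerance = 1e-20)
  # symmetric sawtooth: the two windows are congruent up to reflection
  r <- mf_segment_rss(c(0, 1, 0, 1, 0, 1), 3, order = 1)
  expect_length(r, 2)
  expect_equal(r[1], r[2])
  # remainder discarded forward, recovered bidirectionally
  prof <- mf_profile(rnorm(100))
  expect_length(mf_segment_rss(prof, 30, segmentation = "forward"), 3)
  expect_length(mf_segment_rss(prof, 30, segmentation = "bidirectional"), 6)
  expect_error(mf_segment_rss(prof, 101), "exceeds")
  expect_error(mf_segment_rss(prof, 2, order = 1), ">= order")
})

test_that("fluctuation function is the q power mean with log-average q = 0", {
  # constant residuals collapse every q-norm to sqrt(c)
  for (q in c(-4, -1, 0, 0.5, 2)) {
    expect_equal(as.numeric(mf_fq(rep(9, 7), q)), 3)
  }
  # q = 2: RMS of the residual SDs, here sqrt((1 + 4)/2)
  expect_equal(as.numeric(mf_fq(c(1, 4), 2)), sqrt(2.5), tolerance = 1e-12)
  expect_equal(as.numeric(mf_fq(c(1, 4), 2)), 1.5811, tolerance = 1e-4)
})

test_that("F_q is non-decreasing in q (power-mean inequality)", {
  set.seed(7)
  qs <- seq(-5, 5, by = 0.5)
  for (i in 1:25) {
    f2 <- rexp(sample(3:12, 1))^2
    vals <- vapply(qs, function(q) as.numeric(mf_fq(f2, q)), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("zero-residual windows are excluded or floored for q <= 0", {
  f2 <- c(0, 1, 4)
  ex <- mf_fq(f2, -2)
  expect_equal(attr(ex, "n_zero_dropped"), 1L)
  expect_equal(as.numeric(ex), as.numeric(mf_fq(c(1, 4), -2)))
  fl <- mf_fq(f2, -2, zero_policy = "floor", floor = 1e-15)
  expect_true(is.finite(as.numeric(fl)))
  expect_error(mf_fq(c(0, 0), 0), "zero residual")
})

test_that("hurst regression recovers exact power laws", {
  s <- c(8, 16, 32, 64, 128)
  surf <- tidyr::expand_grid(q = c(-2, 0, 2), s = s) |>
    dplyr::mutate(fq = s^0.5)
  h <- mf_hurst(surf)
  expect_equal(h$h, rep(0.5, 3))
  expect_equal(h$r2, rep(1, 3))
  # multiplicative prefactor absorbed by the intercept
  surf$fq <- 3 * surf$s^0.8
  expect_equal(mf_hurst(surf)$h, rep(0.8, 3), tolerance = 1e-12)
  expect_error(mf_hurst(surf[surf$s < 20, ]), "3 scales")
})

test_that("Legendre transform obeys its identities", {
  q <- seq(-4, 4, by = 0.5)
  # monofractal: constant h gives alpha = H and f = 1 everywhere
  spec <- mf_spectrum(tibble::tibble(q = q, h = 0.62))
  expect_equal(spec$tau, q * 0.62 - 1)
  expect_equal(spec$alpha, rep(0.62, length(q)), tolerance = 1e-12)
  expect_equal(spec$f_alpha, rep(1, length(q)), tolerance = 1e-12)
  # f at q = 0 equals 1 whenever tau(0) = -1 (forced by the transform)
  hq <- tibble::tibble(q = q, h = 0.9 - 0.05 * q)
  sp2 <- mf_spectrum(hq)
  expect_equal(sp2$f_alpha[sp2$q == 0], 1, tolerance = 1e-9)
  expect_equal(sp2$tau, q * hq$h - 1)
  # alpha non-increasing when h is non-increasing
  expect_true(all(diff(sp2$alpha) <= 1e-12))
})

test_that("stability summary reduces the spectrum correctly", {
  sym <- tibble::tibble(q = c(-1, 0, 1), alpha = c(1.0, 0.6, 0.2),
                        f_alpha = c(0.5, 1, 0.5))
  expect_equal(mf_summary(sym)$d_alpha, 0)
  asym <- tibble::tibble(q = c(-1, 0, 1), alpha = c(1.0, 0.6, 0.4),
                         f_alpha = c(0.5, 1, 0.6))
  s <- mf_summary(asym)
  expect_equal(s$delta_alpha, 0.6)
  expect_equal(s$d_alpha, 0.4 - 0.2)
  expect_equal(s$delta_f, 0.6 - 0.5)   # f(alpha_min) - f(alpha_max)
  # printed variant differs by the missing absolute value
  expect_equal(mf_summary(asym, d_alpha = "printed")$d_alpha,
               abs(1.0 - 0.6) - 0.4 - 0.6)
  mono <- tibble::tibble(q = c(-1, 0, 1), alpha = rep(0.5, 3),
                         f_alpha = rep(1, 3))
  sm <- mf_summary(mono)
  expect_true(sm$monofractal)
  expect_equal(sm$delta_alpha, 0)
  expect_equal(sm$d_alpha, 0)
})

test_that("mfdfa is deterministic and enforces its preconditions", {
  x <- gen_fgn(512, 0.5, seed = 3)
  f1 <- mfdfa(x)
  f2 <- mfdfa(x)
  expect_identical(f1$fluctuations, f2$fluctuations)
  expect_identical(f1$summary, f2$summary)
  expect_error(mfdfa(x, scales = c(2, 8, 16)), "order \\+ 1")
  expect_error(mfdfa(x, scales = c(16, 32, 200)), "n/4")
  # glance/tidy surface the expected pieces
  expect_named(glance(f1), c("alpha_min", "alpha_max", "alpha_0",
                             "delta_alpha", "delta_f", "d_alpha",
                             "monofractal", "h2"))
  expect_identical(tidy(f1), f1$spectrum)
})

test_that("uniform cascade is narrower than a multifractal one", {
  w_mono <- gen_cascade(12, 0.5)
  w_multi <- gen_cascade(12, 0.7)
  d_mono <- mfdfa(w_mono, q = seq(-4, 4, 0.5))$summary$delta_alpha
  d_multi <- mfdfa(w_multi, q = seq(-4, 4, 0.5))$summary$delta_alpha
  expect_lt(d_mono, d_multi)
})

test_that("naive double-loop F_q matches the implementation", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(32:64, 1)
    x <- rnorm(n)
    s <- sample(6:12, 1)
    q <- sample(c(-3, -1, 0, 1, 2, 4), 1)
    got <- as.numeric(mf_fq(mf_segment_rss(mf_profile(x), s), q))
    ref <- naive_fq(x, s, q)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("spectrum export round-trips through the tidy table", {
  fit <- mfdfa(gen_fgn(512, 0.6, seed = 9))
  path <- file.path(withr::local_tempdir(), "spec.tsv")
  write_mfdfa(fit, path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(tab$alpha, fit$spectrum$alpha, tolerance = 1e-12)
  side <- jsonlite::read_json(sub("tsv$", "json", path))
  expect_equal(side$d_alpha, fit$summary$d_alpha, tolerance = 1e-12)
})
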