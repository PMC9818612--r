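test_that("channel t-tests match hand-computed and degenerate cases", {
  # one channel, textbook groups: A = 1,2,3 vs B = 4,5,6
  fe <- fake_features(n_faller = 3, n_nofaller = 3, p = 3, seed = 1)
  fc <- grep("^[0-9]{3}_", names(fe), value = TRUE)
  fe[[fc[1]]] <- c(1, 2, 3, 4, 5, 6)
  fe[[fc[2]]] <- rep(2, 6)                 # both groups constant and equal
  tab <- channel_ttests(fe, alpha_level = 0.05)
  expect_equal(tab$t[1], -3.674, tolerance = 1e-3)
  expect_equal(tab$p[1], 2 * stats::pt(-abs(tab$t[1]), 4), tolerance = 1e-12)
  expect_equal(round(tab$p[1], 3), 0.021)
  expect_equal(tab$df[1], 4)
  expect_equal(tab$t[2], 0)
  expect_equal(tab$p[2], 1)
  expect_true(tab$significant[1])
  # constant but unequal zero-variance groups are undefined
  fe[[fc[3]]] <- rep(c(1, 2), each = 3)
  expect_error(channel_ttests(fe), "undefined")
})

test_that("pooled t-tests equal the brute-force formulas", {
  set.seed(11)
  for (i in 1:100) {
    nx <- sample(3:9, 1); ny <- sample(3:9, 1)
    x <- rnorm(nx); y <- rnorm(ny, sd = runif(1, 0.5, 2))
    fe <- fake_features(n_faller = nx, n_nofaller = ny, p = 3, seed = i)
    fc <- grep("^[0-9]{3}_", names(fe), value = TRUE)
    fe[[fc[1]]] <- c(x, y)
    got <- channel_ttests(fe)[1, ]
    ref <- naive_pooled_t(x, y)
    expect_equal(got$t, ref$t, tolerance = 1e-10)
    expect_equal(got$p, ref$p, tolerance = 1e-10)
  }
})

test_that("per-channel p-values are uniform under the null", {
  ps <- unlist(lapply(1:150, function(i) {
    fe <- fake_features(n_faller = 9, n_nofaller = 12, p = 6, offset = 0,
                        seed = 1000 + i)
    channel_ttests(fe)$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("channel table keeps serial order and BH column", {
  fe <- fake_features(p = 9, offset = 0.5, seed = 5)
  tab <- channel_ttests(fe)
  expect_equal(tab$serial, sort(tab$serial))
  expect_true(all(tab$p_bh >= tab$p - 1e-15))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_named(tab, c("serial", "marker", "plane", "mean_faller",
                      "mean_nofaller", "t", "df", "p", "p_bh", "significant"))
})

test_that("sex-by-status comparison recovers injected separation", {
  fe <- fake_features(n_faller = 8, n_nofaller = 30, p = 6, offset = 2,
                      seed = 8)
  cmp <- sex_group_comparison(fe)
  cm <- cmp$cell_means
  expect_equal(nrow(cm), 4)
  for (sx in c("female", "male")) {
    expect_gt(cm$mean[cm$sex == sx & cm$label == "faller"],
              cm$mean[cm$sex == sx & cm$label == "nofaller"])
  }
  expect_true(all(cmp$tests$p < 0.005))
  # swapping labels negates the t statistics
  fe_sw <- fe
  fe_sw$label <- ifelse(fe$label == "faller", "nofaller", "faller")
  cmp_sw <- sex_group_comparison(fe_sw)
  expect_equal(cmp_sw$tests$t, -cmp$tests$t, tolerance = 1e-12)
  # a single shared value collapses all four cell means
  fc <- grep("^[0-9]{3}_", names(fe), value = TRUE)
  fe2 <- fe
  fe2[, fc] <- 0.4
  cm2 <- sex_group_comparison(fe2)$cell_means
  expect_equal(cm2$mean, rep(0.4, 4))
})

test_that("empty sex cells are reported, not tested", {
  fe <- fake_features(n_faller = 4, n_nofaller = 8, p = 3, seed = 3)
  fe$sex <- c(rep("female", 4), rep_len(c("female", "male"), 8))
  cmp <- sex_group_comparison(fe)
  expect_equal(cmp$cell_means$n[cmp$cell_means$sex == "male" &
                                  cmp$cell_means$label == "faller"], 0L)
  expect_true(is.na(cmp$tests$p[cmp$tests$comparison ==
                                  "faller vs nofaller (male)"]))
})

test_that("rank-sum test is exact for small groups and handles ties", {
  subj <- tibble::tibble(label = c("faller", "faller", "nofaller", "nofaller"),
                         age = c(1, 2, 3, 4), bmi = c(5, 5, 5, 5))
  rs <- baseline_ranksum(subj)
  expect_equal(rs$p[rs$variable == "age"], 1 / 3, tolerance = 1e-12)
  expect_equal(rs$method[1], "exact")
  expect_equal(rs$p[rs$variable == "bmi"], 1)        # all tied
  # identical groups: p = 1 under the exact test
  subj2 <- tibble::tibble(label = rep(c("faller", "nofaller"), each = 3),
                          age = c(1, 7, 13, 3, 9, 15), bmi = c(1, 7, 13, 3, 9, 15))
  expect_gt(baseline_ranksum(subj2)$p[1], 0.5)
})

test_that("exact and approximate rank-sum p agree for n = 8 vs 8", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, -1, 1))
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})
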