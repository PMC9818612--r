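test_that("confusion metrics satisfy their algebraic identities", {
  set.seed(101)
  for (i in 1:1000) {
    cm <- as.list(sample(0:20, 4, replace = TRUE))
    names(cm) <- c("tp", "fp", "fn", "tn")
    if (Reduce(`+`, cm) == 0) cm$tp <- 1
    m <- do.call(confusion_metrics, cm)
    n <- cm$tp + cm$fp + cm$fn + cm$tn
    expect_identical(m$accuracy, (cm$tp + cm$tn) / n)
    for (cl in c("faller", "nofaller")) {
      p <- m[[paste0("precision_", cl)]]
      r <- m[[paste0("recall_", cl)]]
      f <- m[[paste0("f1_", cl)]]
      ref <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      expect_equal(f, ref, tolerance = 1e-12)
    }
    expect_equal(m$rmse, sqrt((cm$fp + cm$fn) / n), tolerance = 1e-15)
  }
})

test_that("degenerate predictions use the zero-denominator convention", {
  all_pos <- confusion_metrics(tp = 9, fp = 37, fn = 0, tn = 0)
  expect_equal(all_pos$accuracy, 9 / 46)
  expect_equal(all_pos$precision_faller, 9 / 46)
  expect_equal(all_pos$recall_faller, 1)
  expect_equal(all_pos$precision_nofaller, 0)
  expect_equal(all_pos$recall_nofaller, 0)
  expect_equal(all_pos$f1_nofaller, 0)
  all_neg <- confusion_metrics(tp = 0, fp = 0, fn = 9, tn = 37)
  expect_equal(all_neg$accuracy, 37 / 46)
  expect_equal(all_neg$precision_faller, 0)
  expect_equal(all_neg$recall_faller, 0)
})

test_that("reference benchmark rows are reproduced from their confusion matrices", {
  # frozen reference rows for a 9-faller / 37-nofaller cohort:
  # (tp, fp, fn, tn) implied by each row's accuracy and recalls
  rows <- list(
    l12 = list(cm = c(6, 15, 3, 22),
               ref = c(0.6087, 0.2857, 0.88, 0.6667, 0.5946, 0.4, 0.7097)),
    svm = list(cm = c(9, 1, 0, 36),
               ref = c(0.9783, 0.9, 1, 1, 0.973, 0.9474, 0.9863)),
    gbdt = list(cm = c(9, 0, 0, 37), ref = c(1, 1, 1, 1, 1, 1, 1)),
    rf = list(cm = c(9, 3, 0, 34),
              ref = c(0.9348, 0.75, 1, 1, 0.9189, 0.8571, 0.9577)),
    dnn = list(cm = c(2, 13, 7, 24),
               ref = c(0.5652, 0.1333, 0.7742, 0.2222, 0.6486, 0.1667, 0.7059)),
    rnn = list(cm = c(9, 37, 0, 0),
               ref = c(0.1957, 0.1957, 0, 1, 0, 0.3273, 0))
  )
  for (r in rows) {
    m <- confusion_metrics(r$cm[1], r$cm[2], r$cm[3], r$cm[4])
    got <- c(m$accuracy, m$precision_faller, m$precision_nofaller,
             m$recall_faller, m$recall_nofaller, m$f1_faller, m$f1_nofaller)
    expect_equal(round(got, 4), r$ref)
    expect_equal(sum(r$cm[c(1, 3)]), 9)
    expect_equal(sum(r$cm[c(2, 4)]), 37)
  }
})

test_that("half-thresholding matches brute-force proximal minimization", {
  set.seed(55)
  for (i in 1:40) {
    c0 <- runif(1, -3, 3)
    lam <- runif(1, 0.01, 1)
    expect_equal(half_threshold(c0, lam), naive_half_prox(c0, lam),
                 tolerance = 1e-6)
  }
  # below the closed-form threshold the output is exactly zero
  lam <- 0.2
  thr <- 1.5 * lam^(2 / 3)
  expect_identical(half_threshold(0.99 * thr, lam), 0)
  expect_identical(half_threshold(-0.99 * thr, lam), 0)
  expect_gt(abs(half_threshold(1.5 * thr, lam)), 0)
})

test_that("sparse kernel fit respects the support constraint", {
  set.seed(66)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- ifelse(x[, 1] + 0.5 * x[, 2] > 0, "faller", "nofaller")
  fit <- l12_fit(x, y)
  expect_lte(length(fit$support), 3)
  expect_s3_class(fit, "l12_model")
  pred <- predict(fit, x)
  expect_true(all(pred %in% c("faller", "nofaller")))
})

test_that("unregularized dense fit approaches kernel least squares", {
  set.seed(77)
  x <- matrix(rnorm(20 * 3), 20, 3)
  y <- ifelse(rowSums(x) > 0, "faller", "nofaller")
  yv <- ifelse(y == "faller", 1, -1)
  fit <- l12_fit(x, y, lambda = 0, sparsity = nrow(x), max_iter = 2000)
  K <- (1 + tcrossprod(x))^2 / fit$kernel_norm
  res_fit <- mean((K %*% fit$beta - yv)^2)
  ridge <- solve(crossprod(K) + 0.1 * diag(nrow(x)), crossprod(K, yv))
  res_ridge <- mean((K %*% ridge - yv)^2)
  expect_lte(res_fit, res_ridge + 1e-8)
})

test_that("every classifier is deterministic under a fixed seed", {
  fe <- fake_features(n_faller = 9, n_nofaller = 17, p = 6, offset = 1.5,
                      seed = 12)
  for (sp in default_classifiers()) {
    p1 <- fit_predict(sp, fe, fe, seed = 31)
    p2 <- fit_predict(sp, fe, fe, seed = 31)
    expect_identical(p1, p2)
    expect_length(p1, nrow(fe))
  }
})

test_that("separable blobs are fit perfectly by svm and gbdt", {
  fe <- fake_features(n_faller = 10, n_nofaller = 12, p = 6, offset = 6,
                      seed = 13)
  for (m in c("svm", "gbdt")) {
    pred <- fit_predict(classifier_spec(m), fe, fe, seed = 2)
    expect_equal(pred, fe$label)
  }
  expect_error(
    fit_predict(classifier_spec("svm"), fe[fe$label == "faller", ], fe),
    "both classes"
  )
  expect_error(classifier_spec("gbdt", nonsense = 1), "unknown")
})

test_that("benchmark includes baselines and conserves fold sizes", {
  fe <- fake_features(n_faller = 9, n_nofaller = 21, p = 5, offset = 2,
                      seed = 14)
  b <- benchmark(fe, specs = list(gbdt = classifier_spec("gbdt")),
                 protocol = eval_protocol("stratified_kfold", folds = 5,
                                          seed = 3), seed = 5)
  expect_setequal(b$classifier, c("gbdt", "all_faller", "all_nofaller",
                                  "majority"))
  folds <- attr(b, "folds")
  gb <- folds[folds$classifier == "gbdt", ]
  expect_equal(sum(gb$tp + gb$fp + gb$fn + gb$tn), nrow(fe))
  # stratification: fold class counts differ by at most one subject
  fold_id <- mfgait:::.stratified_folds(fe$label, 5, 3)
  per_fold <- table(fold_id, fe$label)
  expect_lte(diff(range(per_fold[, "faller"])), 1)
  expect_lte(diff(range(per_fold[, "nofaller"])), 1)
  # constant baselines behave as expected
  expect_equal(b$accuracy[b$classifier == "all_faller"], 9 / 30)
  expect_equal(b$rmse[b$classifier == "all_nofaller"], sqrt(9 / 30))
})

test_that("label shuffling collapses cross-validated accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    fe <- fake_features(n_faller = 12, n_nofaller = 24, p = 5, offset = 3,
                        seed = 40 + s)
    set.seed(s)
    fe$label <- sample(fe$label)
    b <- benchmark(fe, specs = list(gbdt = classifier_spec("gbdt")),
                   protocol = eval_protocol("stratified_kfold", folds = 4,
                                            seed = s), seed = s)
    b$accuracy[b$classifier == "gbdt"]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 24 / 36), 0.15)
})

test_that("resubstitution on separable data yields a perfect method", {
  fe <- fake_features(n_faller = 8, n_nofaller = 16, p = 6, offset = 6,
                      seed = 15)
  b <- benchmark(fe, specs = list(svm = classifier_spec("svm"),
                                  gbdt = classifier_spec("gbdt")),
                 protocol = eval_protocol("resubstitution"), seed = 1)
  expect_true(any(b$accuracy[b$classifier %in% c("svm", "gbdt")] == 1))
})
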