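#' Confusion-matrix performance metrics
#'
#' Standard metrics with "faller" as the positive class: accuracy
#' `(tp + tn) / n`; per-class precision (correct / predicted) and recall
#' (correct / actual); F1 as their harmonic mean; and RMSE of the hard 0/1
#' label encoding (faller = 1), i.e. `sqrt(misclassification rate)`.
#' Zero-denominator precision/recall are defined as 0 (a classifier that
#' never predicts a class has precision 0 for it).
#'
#' @param tp,fp,fn,tn Confusion counts (faller positive).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`,
#'   `precision_faller`, `precision_nofaller`, `recall_faller`,
#'   `recall_nofaller`, `f1_faller`, `f1_nofaller`, `rmse`.
#' @examples
#' confusion_metrics(tp = 9, fp = 37, fn = 0, tn = 0)$accuracy # 9/46
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("confusion counts must be non-negative with n > 0", call. = FALSE)
  }
  n <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  prec_f <- safe_div(tp, tp + fp)
  prec_n <- safe_div(tn, tn + fn)
  rec_f <- safe_div(tp, tp + fn)
  rec_n <- safe_div(tn, tn + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / n,
                 precision_faller = prec_f, precision_nofaller = prec_n,
                 recall_faller = rec_f, recall_nofaller = rec_n,
                 f1_faller = f1(prec_f, rec_f), f1_nofaller = f1(prec_n, rec_n),
                 rmse = sqrt((fp + fn) / n))
}

#' Metrics from observed and predicted labels
#'
#' @param truth,predicted Character vectors of `"faller"` / `"nofaller"`.
#' @return A one-row tibble as in [confusion_metrics()].
#' @export
label_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_metrics(tp = sum(truth == "faller" & predicted == "faller"),
                    fp = sum(truth == "nofaller" & predicted == "faller"),
                    fn = sum(truth == "faller" & predicted == "nofaller"),
                    tn = sum(truth == "nofaller" & predicted == "nofaller"))
}

#' Classifier specifications
#'
#' The six benchmarked methods with their reference hyperparameters as
#' defaults: `l12_sparse` (polynomial-kernel L1/2 sparse iteration:
#' regularization 0.1, kernel degree 2, 100 iterations, step 0.1, sparsity
#' 3), `svm` (polynomial kernel degree 1, regularization 0.01), `gbdt`
#' (squared-error loss, depth 5, tolerance 0.01, step 0.1, 20 trees), `rf`
#' (32 feature bins, depth 5, 20 trees), `dnn` (one hidden layer of 4 ReLU
#' units, Xavier init, SGD with learning rate 0.01, L2 0.01, batch 16, 30
#' epochs) and `rnn` (a minimal recurrent cell with 4 hidden units reading
#' the features as a length-`p` scalar sequence in serial order, same
#' optimizer settings).
#'
#' @param method One of `"l12_sparse"`, `"svm"`, `"gbdt"`, `"rf"`,
#'   `"dnn"`, `"rnn"`.
#' @param ... Hyperparameter overrides; unknown names are rejected.
#' @return A list of class `"classifier_spec"`.
#' @export
classifier_spec <- function(method = c("l12_sparse", "svm", "gbdt", "rf",
                                       "dnn", "rnn"), ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    l12_sparse = list(lambda = 0.1, kernel_degree = 2, max_iter = 100,
                      step = 0.1, sparsity = 3),
    svm = list(cost = 0.01, kernel_degree = 1),
    gbdt = list(max_depth = 5, tolerance = 0.01, step = 0.1, n_trees = 20),
    rf = list(bins = 32, max_depth = 5, n_trees = 20),
    dnn = list(hidden = 4, lambda = 0.01, learning_rate = 0.01,
               batch_size = 16, epochs = 30),
    rnn = list(hidden = 4, lambda = 0.01, learning_rate = 0.01,
               batch_size = 16, epochs = 30)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", method, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(dots)] <- dots
  structure(list(method = method, params = defaults),
            class = "classifier_spec")
}

#' All six benchmark classifiers at their defaults
#' @return A named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function() {
  methods <- c("l12_sparse", "svm", "gbdt", "rf", "dnn", "rnn")
  stats::setNames(purrr::map(methods, classifier_spec), methods)
}

# --- internal helpers -------------------------------------------------------

.feature_matrix <- function(features) {
  fc <- feature_cols(features)
  if (length(fc) == 0) stop("no feature columns found", call. = FALSE)
  m <- as.matrix(features[, fc])
  storage.mode(m) <- "double"
  m
}

.label_pm1 <- function(labels) ifelse(labels == "faller", 1, -1)

# train-set standardization, applied to both train and test
.standardize <- function(train, test) {
  mu <- colMeans(train)
  sg <- apply(train, 2, stats::sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sg, "/"),
       test = sweep(sweep(test, 2, mu), 2, sg, "/"))
}

.poly_kernel <- function(x, y, degree) (1 + tcrossprod(x, y))^degree

#' Half-thresholding operator of the L1/2 penalty
#'
#' The proximal operator of \eqn{\lambda |z|^{1/2}}: the minimizer of
#' \eqn{\frac12 (z - c)^2 + \lambda |z|^{1/2}}. Inputs with magnitude at or
#' below the closed-form threshold \eqn{\frac32 \lambda^{2/3}} (equivalently
#' \eqn{(54^{1/3}/4)(2\lambda)^{2/3}}; the quoted constant depends on whether
#' the quadratic term carries the 1/2) map exactly to zero; above it, the
#' solution is
#' \eqn{z = \frac{2}{3} c\,(1 + \cos(\frac{2\pi}{3} - \frac{2}{3}\phi))}
#' with \eqn{\phi = \arccos\{(\lambda/4)(|c|/3)^{-3/2}\}}.
#'
#' @param c Numeric vector of unthresholded coefficients.
#' @param lambda Penalty weight (already scaled by any step size).
#' @return Numeric vector of thresholded coefficients.
#' @export
half_threshold <- function(c, lambda) {
  thr <- 1.5 * lambda^(2 / 3)
  out <- numeric(length(c))
  big <- abs(c) > thr
  if (any(big)) {
    cb <- c[big]
    phi <- acos(pmin(1, (lambda / 4) * (abs(cb) / 3)^(-3 / 2)))
    out[big] <- (2 / 3) * cb * (1 + cos(2 * pi / 3 - 2 * phi / 3))
  }
  out
}

#' L1/2-regularized sparse kernel classifier
#'
#' A polynomial-kernel expansion whose coefficients are estimated by
#' proximal gradient descent with the L1/2 half-thresholding operator
#' ([half_threshold()]); after each iteration all but the `sparsity`
#' largest-magnitude coefficients are zeroed (a hard top-k support
#' constraint). The Gram matrix is spectrally normalized so the fixed
#' iteration step is stable. Non-convergence within `max_iter` iterations
#' sets a warning flag on the model rather than failing.
#'
#' @param x Numeric feature matrix (rows = subjects), already standardized
#'   by the caller or raw.
#' @param y Labels, `"faller"` / `"nofaller"` (encoded internally as +1/-1).
#' @param lambda Regularization weight (default 0.1); 0 disables the
#'   penalty and the hard support constraint follows `sparsity`.
#' @param kernel_degree Polynomial kernel degree (default 2).
#' @param max_iter Maximum iterations (default 100).
#' @param step Iteration step size (default 0.1).
#' @param sparsity Maximum support size (default 3).
#' @param tol Convergence tolerance on the coefficient update (default 1e-8).
#' @return An object of class `"l12_model"` with the support indices,
#'   coefficients, training data reference, and a `converged` flag.
#' @export
l12_fit <- function(x, y, lambda = 0.1, kernel_degree = 2, max_iter = 100,
                    step = 0.1, sparsity = 3, tol = 1e-8) {
  x <- as.matrix(x)
  yv <- .label_pm1(y)
  n <- nrow(x)
  K <- .poly_kernel(x, x, kernel_degree)
  nrmK <- norm(K, "2")
  Kn <- K / nrmK
  beta <- numeric(n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- crossprod(Kn, Kn %*% beta - yv) / n
    z <- beta - step * as.vector(grad)
    beta_new <- if (lambda > 0) half_threshold(z, lambda * step) else z
    if (sparsity < n) {
      keep <- order(abs(beta_new), decreasing = TRUE)[seq_len(sparsity)]
      beta_new[-keep] <- 0
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(beta = beta, support = which(beta != 0), x_train = x,
                 kernel_degree = kernel_degree, kernel_norm = nrmK,
                 lambda = lambda, sparsity = sparsity,
                 converged = converged),
            class = "l12_model")
}

#' @export
predict.l12_model <- function(object, newdata, ...) {
  K <- .poly_kernel(as.matrix(newdata), object$x_train,
                    object$kernel_degree) / object$kernel_norm
  score <- as.vector(K %*% object$beta)
  ifelse(score >= 0, "faller", "nofaller")
}

# Tiny feed-forward net: p -> hidden ReLU -> 1 sigmoid, Xavier init,
# minibatch SGD with L2 weight decay. Written out longhand because the
# reference configuration (ReLU + Xavier + per-batch SGD) is not what
# nnet-style fitters expose.
.dnn_fit <- function(x, y01, hidden, lambda, lr, batch, epochs, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p <- ncol(x); n <- nrow(x)
  W1 <- matrix(stats::runif(hidden * p, -1, 1) * sqrt(6 / (p + hidden)),
               hidden, p)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::runif(hidden, -1, 1) * sqrt(6 / (hidden + 1)), 1, hidden)
  b2 <- 0
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      b_idx <- idx[start:min(start + batch - 1, n)]
      xb <- x[b_idx, , drop = FALSE]; yb <- y01[b_idx]; m <- length(b_idx)
      a1 <- xb %*% t(W1) + matrix(b1, m, hidden, byrow = TRUE)
      h1 <- pmax(a1, 0)
      z <- as.vector(h1 %*% t(W2)) + b2
      prob <- 1 / (1 + exp(-z))
      dz <- (prob - yb) / m                       # d(cross-entropy)/dz
      gW2 <- t(dz) %*% h1 + lambda * W2
      gb2 <- sum(dz)
      dh1 <- (dz %*% W2) * (a1 > 0)
      gW1 <- t(dh1) %*% xb + lambda * W1
      gb1 <- colSums(dh1)
      W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
      W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.dnn_predict <- function(model, x) {
  h1 <- pmax(x %*% t(model$W1) +
               matrix(model$b1, nrow(x), length(model$b1), byrow = TRUE), 0)
  z <- as.vector(h1 %*% t(model$W2)) + model$b2
  ifelse(z >= 0, "faller", "nofaller")
}

# Minimal recurrent cell over the features read as a scalar sequence in
# serial order: h_t = relu(Wx * x_t + Wh %*% h_{t-1} + b), sigmoid readout
# of the final state. Gradients by full BPTT, clipped for stability.
.rnn_fit <- function(x, y01, hidden, lambda, lr, batch, epochs, seed,
                     clip = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p <- ncol(x); n <- nrow(x)
  Wx <- stats::runif(hidden, -1, 1) * sqrt(6 / (1 + hidden))
  Wh <- matrix(stats::runif(hidden^2, -1, 1) * sqrt(6 / (2 * hidden)),
               hidden, hidden)
  bh <- numeric(hidden)
  Wo <- stats::runif(hidden, -1, 1) * sqrt(6 / (hidden + 1))
  bo <- 0
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      b_idx <- idx[start:min(start + batch - 1, n)]
      gWx <- numeric(hidden); gWh <- matrix(0, hidden, hidden)
      gbh <- numeric(hidden); gWo <- numeric(hidden); gbo <- 0
      for (i in b_idx) {
        xs <- x[i, ]
        H <- matrix(0, hidden, p + 1)           # states, col t+1 = h_t
        A <- matrix(0, hidden, p)               # pre-activations
        for (t in seq_len(p)) {
          A[, t] <- Wx * xs[t] + Wh %*% H[, t] + bh
          H[, t + 1] <- pmax(A[, t], 0)
        }
        z <- sum(Wo * H[, p + 1]) + bo
        prob <- 1 / (1 + exp(-z))
        dz <- prob - y01[i]
        gWo <- gWo + dz * H[, p + 1]; gbo <- gbo + dz
        dh <- dz * Wo
        for (t in rev(seq_len(p))) {
          da <- dh * (A[, t] > 0)
          gWx <- gWx + da * xs[t]
          gWh <- gWh + da %*% t(H[, t])
          gbh <- gbh + da
          dh <- as.vector(t(Wh) %*% da)
        }
      }
      m <- length(b_idx)
      cl <- function(g) pmax(pmin(g / m, clip), -clip)
      Wx <- Wx - lr * (cl(gWx) + lambda * Wx)
      Wh <- Wh - lr * (cl(gWh) + lambda * Wh)
      bh <- bh - lr * cl(gbh)
      Wo <- Wo - lr * (cl(gWo) + lambda * Wo)
      bo <- bo - lr * cl(gbo)
    }
  }
  list(Wx = Wx, Wh = Wh, bh = bh, Wo = Wo, bo = bo)
}

.rnn_predict <- function(model, x) {
  hidden <- length(model$Wx)
  apply(x, 1, function(xs) {
    h <- numeric(hidden)
    for (t in seq_along(xs)) {
      h <- pmax(model$Wx * xs[t] + as.vector(model$Wh %*% h) + model$bh, 0)
    }
    z <- sum(model$Wo * h) + model$bo
    if (z >= 0) "faller" else "nofaller"
  })
}

# Per-feature equal-width discretization into `bins` levels, cut points
# from the training data.
.bin_features <- function(train, test, bins) {
  cuts <- purrr::map(seq_len(ncol(train)), function(j) {
    r <- range(train[, j])
    if (r[1] == r[2]) r[2] <- r[1] + 1
    seq(r[1], r[2], length.out = bins + 1)
  })
  binned <- function(m) {
    out <- m
    for (j in seq_len(ncol(m))) {
      out[, j] <- findInterval(m[, j], cuts[[j]], all.inside = TRUE)
    }
    out
  }
  list(train = binned(train), test = binned(test))
}

#' Fit a classifier and predict test labels
#'
#' Dispatches on the spec's method: the L1/2 sparse kernel iteration
#' ([l12_fit()]), a polynomial-kernel SVM, gradient-boosted regression
#' trees on +/-1 targets with the sign of the prediction as the class
#' (squared-error reading of the boosting loss), a random forest on
#' 32-bin discretized features, and the small feed-forward and recurrent
#' networks. Deterministic given `seed`.
#'
#' @param spec A [classifier_spec()].
#' @param train,test Feature tibbles (as from [extract_features()]); `train`
#'   must contain both classes.
#' @param seed Integer seed for the stochastic fitters.
#' @return Character vector of predicted labels for the rows of `test`.
#' @export
fit_predict <- function(spec, train, test, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  ytr <- train$label
  if (length(unique(ytr)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  xtr <- .feature_matrix(train)
  xte <- .feature_matrix(test)
  p <- spec$params
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  switch(spec$method,
    l12_sparse = {
      std <- .standardize(xtr, xte)
      fit <- l12_fit(std$train, ytr, lambda = p$lambda,
                     kernel_degree = p$kernel_degree, max_iter = p$max_iter,
                     step = p$step, sparsity = p$sparsity)
      predict(fit, std$test)
    },
    svm = {
      fit <- e1071::svm(x = xtr, y = factor(ytr, c("faller", "nofaller")),
                        kernel = "polynomial", degree = p$kernel_degree,
                        gamma = 1, coef0 = 1, cost = p$cost, scale = TRUE)
      as.character(predict(fit, xte))
    },
    gbdt = {
      dtr <- xgboost::xgb.DMatrix(xtr, label = .label_pm1(ytr), nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = p$max_depth,
                      eta = p$step, lambda = 0, min_child_weight = 1,
                      base_score = 0, nthread = 1),
        data = dtr, nrounds = p$n_trees, verbose = 0
      )
      score <- predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
      ifelse(score >= 0, "faller", "nofaller")
    },
    rf = {
      bn <- .bin_features(xtr, xte, p$bins)
      fit <- randomForest::randomForest(
        x = bn$train, y = factor(ytr, c("faller", "nofaller")),
        ntree = p$n_trees, maxnodes = min(2^p$max_depth, nrow(bn$train))
      )
      as.character(predict(fit, bn$test))
    },
    dnn = {
      std <- .standardize(xtr, xte)
      fit <- .dnn_fit(std$train, as.integer(ytr == "faller"), p$hidden,
                      p$lambda, p$learning_rate, p$batch_size, p$epochs,
                      seed = as.integer(seed))
      .dnn_predict(fit, std$test)
    },
    rnn = {
      std <- .standardize(xtr, xte)
      fit <- .rnn_fit(std$train, as.integer(ytr == "faller"), p$hidden,
                      p$lambda, p$learning_rate, p$batch_size, p$epochs,
                      seed = as.integer(seed))
      .rnn_predict(fit, std$test)
    }
  )
}

#' Evaluation protocol
#'
#' How train/test splits are formed for [benchmark()]: `"resubstitution"`
#' evaluates each classifier on its own training data (optimistic, but the
#' natural reading of perfect reported scores on a 46-subject cohort);
#' `"stratified_kfold"` is seeded stratified cross-validation preserving
#' the class ratio within one subject per fold; `"holdout"` is a single
#' stratified split.
#'
#' @param mode `"resubstitution"`, `"stratified_kfold"` or `"holdout"`.
#' @param folds Number of folds (k-fold mode, default 5).
#' @param split Training fraction (holdout mode, default 0.7).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `"eval_protocol"`.
#' @export
eval_protocol <- function(mode = c("resubstitution", "stratified_kfold",
                                   "holdout"), folds = 5L, split = 0.7,
                          seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, folds = as.integer(folds), split = split,
                 seed = as.integer(seed)),
            class = "eval_protocol")
}

# Stratified fold ids: within each class, a seeded random permutation is
# dealt round-robin over folds, so fold class counts differ by at most 1.
.stratified_folds <- function(labels, k, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- rep_len(seq_len(k), length(ix))[sample.int(length(ix))]
  }
  fold
}

#' Benchmark classifiers on a feature matrix
#'
#' Runs every classifier spec under the given protocol and returns one
#' metrics row per classifier, with the three constant-predictor reference
#' rows (all-faller, all-nofaller, majority-class) always included.
#' Predictions are pooled over folds before computing metrics; per-fold
#' metrics are retained in the `"folds"` attribute.
#'
#' @param features A feature tibble with a `label` column.
#' @param specs Named list of [classifier_spec()]s; default all six.
#' @param protocol An [eval_protocol()].
#' @param seed Integer seed handed to the stochastic fitters.
#' @return A tibble: `classifier`, `protocol`, metric columns as in
#'   [confusion_metrics()].
#' @export
benchmark <- function(features, specs = default_classifiers(),
                      protocol = eval_protocol(), seed = 1L) {
  stopifnot(inherits(protocol, "eval_protocol"))
  lab <- features$label
  n <- nrow(features)
  splits <- switch(protocol$mode,
    resubstitution = list(list(train = seq_len(n), test = seq_len(n))),
    stratified_kfold = {
      fold <- .stratified_folds(lab, protocol$folds, protocol$seed)
      purrr::map(seq_len(protocol$folds),
                 function(k) list(train = which(fold != k),
                                  test = which(fold == k)))
    },
    holdout = {
      fold <- .stratified_folds(lab, 2L, protocol$seed)
      n_tr <- round(protocol$split * n)
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(protocol$seed)
      tr <- unlist(purrr::map(unique(lab), function(cl) {
        ix <- which(lab == cl)
        sample(ix, round(protocol$split * length(ix)))
      }))
      list(list(train = sort(tr), test = setdiff(seq_len(n), tr)))
    }
  )

  run_one <- function(name, predictor) {
    per_fold <- purrr::map(splits, function(sp) {
      pred <- predictor(features[sp$train, ], features[sp$test, ])
      tibble::tibble(truth = lab[sp$test], pred = pred)
    })
    pooled <- dplyr::bind_rows(per_fold)
    row <- label_metrics(pooled$truth, pooled$pred)
    fold_rows <- purrr::imap(per_fold,
                             ~ dplyr::mutate(label_metrics(.x$truth, .x$pred),
                                             fold = .y, classifier = name))
    dplyr::mutate(row, classifier = name, .before = 1) |>
      structure(folds = dplyr::bind_rows(fold_rows))
  }

  rows <- purrr::imap(specs, function(sp, name) {
    run_one(name, function(tr, te) fit_predict(sp, tr, te, seed = seed))
  })
  maj <- names(sort(table(lab), decreasing = TRUE))[1]
  baselines <- list(
    all_faller = function(tr, te) rep("faller", nrow(te)),
    all_nofaller = function(tr, te) rep("nofaller", nrow(te)),
    majority = function(tr, te) {
      m <- names(sort(table(tr$label), decreasing = TRUE))[1]
      rep(m, nrow(te))
    }
  )
  base_rows <- purrr::imap(baselines, function(fn, name) run_one(name, fn))
  fold_tabs <- purrr::map(c(rows, base_rows), ~ attr(.x, "folds"))
  out <- dplyr::bind_rows(c(rows, base_rows))
  out <- dplyr::mutate(out, protocol = protocol$mode, .after = "classifier")
  attr(out, "folds") <- dplyr::bind_rows(fold_tabs)
  attr(out, "protocol") <- protocol
  out
}

#' Write a benchmark table
#'
#' Tab-separated table in the usual benchmark layout (classifier, accuracy,
#' per-class precision/recall/F1, RMSE, protocol) plus a JSON provenance
#' sidecar with the protocol.
#'
#' @param bench A tibble from [benchmark()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  cols <- c("classifier", "accuracy", "precision_faller", "precision_nofaller",
            "recall_faller", "recall_nofaller", "f1_faller", "f1_nofaller",
            "rmse", "protocol")
  utils::write.table(bench[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  proto <- attr(bench, "protocol")
  if (!is.null(proto)) {
    jsonlite::write_json(unclass(proto), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
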