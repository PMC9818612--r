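#' Per-channel independent-samples t-tests
#'
#' For each stability channel, a two-sided independent-samples t-test of
#' faller vs nofaller. The default is the pooled-variance (Student) test;
#' `var_equal = FALSE` gives the Welch variant. No multiple-testing
#' correction is applied to the reported `p`; a Benjamini-Hochberg adjusted
#' column `p_bh` is appended additionally, clearly an extension of the raw
#' per-channel table.
#'
#' Degenerate channels where both groups are constant and equal are
#' reported with `t = 0, p = 1`; constant but unequal groups with zero
#' variance raise an error.
#'
#' @param features A feature tibble from [extract_features()] with a
#'   `label` column of `"faller"` / `"nofaller"`.
#' @param alpha_level Significance threshold for the `significant` flag
#'   (default 0.005).
#' @param var_equal Pooled variance (default `TRUE`) or Welch.
#' @return A tibble with one row per channel, in serial order: `serial`,
#'   `marker`, `plane`, `mean_faller`, `mean_nofaller`, `t`, `df`, `p`,
#'   `p_bh`, `significant`.
#' @export
channel_ttests <- function(features, alpha_level = 0.005, var_equal = TRUE) {
  fc <- feature_cols(features)
  lab <- features$label
  if (sum(lab == "faller") < 2 || sum(lab == "nofaller") < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  cmap <- attr(features, "channel_map")
  rows <- purrr::map(fc, function(col) {
    x <- features[[col]][lab == "faller"]
    y <- features[[col]][lab == "nofaller"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        return(tibble::tibble(column = col, mean_faller = mean(x),
                              mean_nofaller = mean(y), t = 0,
                              df = length(x) + length(y) - 2, p = 1))
      }
      stop("channel ", col, ": both groups constant with unequal means; ",
           "t statistic undefined", call. = FALSE)
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    tibble::tibble(column = col, mean_faller = mean(x),
                   mean_nofaller = mean(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha_level
  out$serial <- as.integer(substr(out$column, 1, 3))
  if (!is.null(cmap)) {
    out <- dplyr::left_join(out, cmap[, c("serial", "marker", "plane")],
                            by = "serial")
  } else {
    out$marker <- sub("_[xyz]$", "", sub("^[0-9]{3}_", "", out$column))
    out$plane <- sub("^.*_", "", out$column)
  }
  dplyr::arrange(
    dplyr::select(out, "serial", "marker", "plane", "mean_faller",
                  "mean_nofaller", "t", "df", "p", "p_bh", "significant"),
    .data$serial
  )
}

#' Sex-by-fall-status posture-stability comparison
#'
#' Computes each subject's posture stability, the mean per sex-by-status
#' cell (female-faller, male-faller, female-nofaller, male-nofaller), and
#' faller-vs-nofaller t-tests both within each sex and pooled across sexes.
#' Cells without subjects are reported with `NA` means and the affected
#' tests are skipped.
#'
#' @param features A feature tibble with `label` and `sex` columns.
#' @param mode Passed to [posture_stability()].
#' @param var_equal Pooled variance (default) or Welch.
#' @return A list with `cell_means` (tibble sex x label), `tests` (tibble:
#'   comparison, t, df, p), and `subjects` (per-subject posture stability).
#' @export
sex_group_comparison <- function(features, mode = c("joint", "grand"),
                                 var_equal = TRUE) {
  ps <- posture_stability(features, mode = match.arg(mode))
  cells <- ps |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$posture_stability),
                     sd = stats::sd(.data$posture_stability),
                     .by = c("sex", "label")) |>
    tidyr::complete(sex = c("female", "male"),
                    label = c("faller", "nofaller"),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$sex, .data$label)

  one_test <- function(dat, name) {
    x <- dat$posture_stability[dat$label == "faller"]
    y <- dat$posture_stability[dat$label == "nofaller"]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble::tibble(comparison = name, t = NA_real_, df = NA_real_,
                            p = NA_real_))
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0 &&
        isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble::tibble(comparison = name, t = 0,
                            df = length(x) + length(y) - 2, p = 1))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    tibble::tibble(comparison = name, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  }
  tests <- dplyr::bind_rows(
    one_test(ps[ps$sex == "female", ], "faller vs nofaller (female)"),
    one_test(ps[ps$sex == "male", ], "faller vs nofaller (male)"),
    one_test(ps, "faller vs nofaller (all)")
  )
  list(cell_means = cells, tests = tests, subjects = ps)
}

#' Baseline rank-sum checks
#'
#' Wilcoxon rank-sum tests of age and BMI between fallers and nofallers,
#' the usual baseline-balance check before group comparisons. Exact p for
#' small samples without ties; normal approximation with tie correction
#' otherwise (ties make the exact distribution unavailable).
#'
#' @param subjects A tibble with `label`, `age`, `bmi` columns (e.g.
#'   `cohort$subjects`).
#' @param variables Which columns to test (default `c("age", "bmi")`).
#' @return A tibble with columns `variable`, `W`, `p`, `method`.
#' @export
baseline_ranksum <- function(subjects, variables = c("age", "bmi")) {
  lab <- subjects$label
  if (sum(lab == "faller") < 2 || sum(lab == "nofaller") < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  purrr::map_dfr(variables, function(v) {
    x <- subjects[[v]][lab == "faller"]
    y <- subjects[[v]][lab == "nofaller"]
    if (length(unique(c(x, y))) == 1) {
      return(tibble::tibble(variable = v, W = length(x) * length(y) / 2,
                            p = 1, method = "all tied"))
    }
    has_ties <- anyDuplicated(c(x, y)) > 0
    small <- length(x) <= 10 && length(y) <= 10
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = small && !has_ties, correct = TRUE)
    )
    tibble::tibble(variable = v, W = unname(wt$statistic), p = wt$p.value,
                   method = if (small && !has_ties) "exact" else
                     "normal approximation")
  })
}
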