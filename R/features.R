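#' Extract the per-channel stability feature matrix
#'
#' Runs MF-DFA on every generated channel of every recording and collects
#' the spectrum-asymmetry index D(alpha) per channel, in serial order
#' (marker-major, plane-minor), together with the subject covariates. The
#' per-channel h(2) and spectrum width delta_alpha are retained as a
#' side table in the `"diagnostics"` attribute.
#'
#' With the full 42-marker model this is the subjects x 126 stability
#' feature matrix used for group statistics and classification.
#'
#' @param cohort An `mf_cohort` from [gen_cohort()] or [read_cohort()].
#' @param scales,q,order,segmentation,d_alpha Passed to [mfdfa()].
#' @param channels Optional serial-number subset; defaults to all channels
#'   present in the cohort.
#' @return A tibble with columns `subject_id`, `label`, `sex`, `age`, `bmi`
#'   and one numeric column per channel named `"<serial>_<channel>"`
#'   (zero-padded serial). The `"config"` attribute records the MF-DFA
#'   configuration; `"channel_map"` maps feature columns to marker/plane.
#' @export
extract_features <- function(cohort, scales = NULL, q = seq(-5, 5, by = 0.5),
                             order = 1L,
                             segmentation = c("forward", "bidirectional"),
                             d_alpha = c("arm_asymmetry", "printed"),
                             channels = NULL) {
  stopifnot(inherits(cohort, "mf_cohort"))
  segmentation <- match.arg(segmentation)
  d_alpha <- match.arg(d_alpha)
  cmap <- cohort$channels
  if (!is.null(channels)) cmap <- cmap[cmap$serial %in% channels, ]
  if (nrow(cmap) == 0) stop("no channels selected", call. = FALSE)
  feat_names <- sprintf("%03d_%s", cmap$serial, cmap$channel)

  diag_rows <- list()
  rows <- purrr::imap(cohort$recordings, function(rec, sid) {
    missing <- setdiff(cmap$channel, names(rec))
    if (length(missing) > 0) {
      stop("recording ", sid, " lacks channel(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    vals <- purrr::map(cmap$channel, function(ch) {
      x <- rec[[ch]]
      fit <- tryCatch(
        mfdfa(x, scales = scales, q = q, order = order,
              segmentation = segmentation, d_alpha = d_alpha),
        error = function(e) stop("channel ", ch, " of ", sid, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      g <- glance.mfdfa(fit)
      c(d = g$d_alpha, h2 = g$h2, da = g$delta_alpha)
    })
    m <- do.call(rbind, vals)
    diag_rows[[sid]] <<- tibble::tibble(subject_id = sid,
                                        serial = cmap$serial,
                                        channel = cmap$channel,
                                        h2 = m[, "h2"],
                                        delta_alpha = m[, "da"])
    stats::setNames(as.list(m[, "d"]), feat_names)
  })
  feats <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(cohort$subjects, feats)
  attr(out, "config") <- list(scales = scales, q_range = range(q),
                              order = order, segmentation = segmentation,
                              d_alpha = d_alpha)
  attr(out, "channel_map") <- dplyr::mutate(cmap, column = feat_names)
  attr(out, "diagnostics") <- dplyr::bind_rows(diag_rows)
  out
}

# Feature columns of a feature tibble, in serial order.
feature_cols <- function(features) {
  grep("^[0-9]{3}_", names(features), value = TRUE)
}

#' Posture stability of each subject
#'
#' The subject-level stability scalar: the average of per-joint stability,
#' where a joint's stability is the mean of its D(alpha) values over the
#' three planes (`mode = "joint"`, the default). With complete channels
#' this equals the grand mean of all 126 values (`mode = "grand"`); the two
#' differ only when channels are missing unevenly across planes.
#'
#' @param features A feature tibble from [extract_features()].
#' @param mode `"joint"` (plane-mean then joint-mean) or `"grand"`.
#' @return The input tibble's id columns plus a `posture_stability` column.
#' @export
posture_stability <- function(features, mode = c("joint", "grand")) {
  mode <- match.arg(mode)
  fc <- feature_cols(features)
  if (length(fc) == 0) stop("no feature columns found", call. = FALSE)
  m <- as.matrix(features[, fc])
  if (any(is.na(m))) stop("missing feature values", call. = FALSE)
  ps <- if (mode == "grand") {
    rowMeans(m)
  } else {
    marker_of <- sub("_[xyz]$", "", sub("^[0-9]{3}_", "", fc))
    joint_means <- vapply(split(seq_along(fc), marker_of),
                          function(ix) rowMeans(m[, ix, drop = FALSE]),
                          numeric(nrow(m)))
    if (is.null(dim(joint_means))) joint_means <- matrix(joint_means, nrow = 1)
    rowMeans(joint_means)
  }
  dplyr::bind_cols(features[, setdiff(names(features), fc)],
                   tibble::tibble(posture_stability = ps))
}

#' Per-channel histogram of stability values
#'
#' Counts, for each channel, how many subjects fall in each uniform bin of
#' width `bin_width` spanning the global observed range; mirrors the usual
#' per-channel frequency summary of the feature matrix.
#'
#' @param features A feature tibble from [extract_features()].
#' @param bin_width Bin width on the D(alpha) axis (default 0.5).
#' @return A tibble with columns `column`, `bin_lo`, `bin_hi`, `count`,
#'   with attributes `"range"` (global range) and `"modal_bin"`.
#' @export
feature_histogram <- function(features, bin_width = 0.5) {
  fc <- feature_cols(features)
  m <- as.matrix(features[, fc])
  rng <- range(m)
  lo <- floor(rng[1] / bin_width) * bin_width
  hi <- ceiling(rng[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  long <- tidyr::pivot_longer(features[, fc], dplyr::everything(),
                              names_to = "column", values_to = "value")
  out <- long |>
    dplyr::mutate(bin = cut(.data$value, breaks = breaks,
                            include.lowest = TRUE, right = FALSE)) |>
    dplyr::count(.data$column, .data$bin, name = "count", .drop = FALSE) |>
    dplyr::mutate(bin_lo = breaks[as.integer(.data$bin)],
                  bin_hi = breaks[as.integer(.data$bin) + 1L]) |>
    dplyr::select("column", "bin_lo", "bin_hi", "count")
  attr(out, "range") <- rng
  totals <- out |>
    dplyr::summarise(count = sum(.data$count), .by = c("bin_lo", "bin_hi"))
  attr(out, "modal_bin") <- unlist(totals[which.max(totals$count),
                                          c("bin_lo", "bin_hi")])
  out
}

#' Plot the per-channel stability distribution
#'
#' Stacked per-channel histogram in serial order, the usual overview of how
#' the 126 stability values distribute across the cohort.
#'
#' @param features A feature tibble from [extract_features()].
#' @param bin_width Bin width (default 0.5).
#' @return A ggplot.
#' @export
plot_feature_distribution <- function(features, bin_width = 0.5) {
  h <- feature_histogram(features, bin_width)
  h$serial <- as.integer(substr(h$column, 1, 3))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$serial, y = .data$count,
                                  fill = factor(.data$bin_lo))) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "channel serial number", y = "subjects",
                  fill = "D(alpha) bin") +
    ggplot2::theme_minimal()
}

#' Write / read a feature matrix
#'
#' Tab-separated table with the id columns and the serial-ordered feature
#' columns; the MF-DFA configuration is stored in a JSON sidecar named
#' `<path>.json`. Reading restores column order and the config attribute.
#'
#' @param features A feature tibble.
#' @param path Output path (e.g. `"features.tsv"`).
#' @return `path` invisibly for the writer; the feature tibble for the
#'   reader.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cfg <- attr(features, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                             check.names = FALSE,
                                             stringsAsFactors = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(out, "config") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  out
}
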