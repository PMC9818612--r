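#' Run configuration
#'
#' A single serializable configuration object tying the pipeline together:
#' the cohort specification, the MF-DFA settings, statistics options, the
#' classifier list, the evaluation protocol, and a master seed that fans
#' out to per-stage seeds. Round-trips through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param cohort A [cohort_spec()].
#' @param mfdfa A list of [mfdfa()] arguments (subset of `scales`, `q`,
#'   `order`, `segmentation`, `d_alpha`).
#' @param channels Optional channel serial subset for feature extraction.
#' @param alpha_level Significance threshold for the channel tests.
#' @param classifiers Character vector of classifier method names.
#' @param protocol An [eval_protocol()].
#' @param seed Master seed.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(), mfdfa = list(),
                       channels = NULL, alpha_level = 0.005,
                       classifiers = names(default_classifiers()),
                       protocol = eval_protocol(), seed = 1L) {
  known_mfdfa <- c("scales", "q", "order", "segmentation", "d_alpha")
  unknown <- setdiff(names(mfdfa), known_mfdfa)
  if (length(unknown) > 0) {
    stop("unknown mfdfa option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(cohort = cohort, mfdfa = mfdfa, channels = channels,
                 alpha_level = alpha_level, classifiers = classifiers,
                 protocol = protocol, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- list(cohort = unclass(config$cohort), mfdfa = config$mfdfa,
              channels = config$channels, alpha_level = config$alpha_level,
              classifiers = as.list(config$classifiers),
              protocol = unclass(config$protocol), seed = config$seed)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("cohort", "mfdfa", "channels", "alpha_level", "classifiers",
             "protocol", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  run_config(
    cohort = do.call(cohort_spec, raw$cohort),
    mfdfa = if (is.null(raw$mfdfa)) list() else raw$mfdfa,
    channels = if (is.null(raw$channels)) NULL else unlist(raw$channels),
    alpha_level = raw$alpha_level,
    classifiers = unlist(raw$classifiers),
    protocol = do.call(eval_protocol, raw$protocol),
    seed = raw$seed
  )
}

#' Write / read a synthetic cohort as plain text
#'
#' One wide tab-separated file per recording -- column 1 is `time` in
#' seconds, then one column per channel named `"<marker>_<plane>"` in
#' serial order -- plus a `manifest.tsv` (subject_id, label, sex, age, bmi,
#' file) in the same directory. [read_cohort()] reconstructs the
#' `mf_cohort` from a manifest path or directory.
#'
#' @param cohort An `mf_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly (writer); an `mf_cohort` (reader).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort$subjects))
  for (i in seq_along(cohort$recordings)) {
    sid <- names(cohort$recordings)[i]
    files[i] <- paste0(sid, ".tsv")
    utils::write.table(cohort$recordings[[i]], file.path(dir, files[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- dplyr::mutate(cohort$subjects, file = files)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname write_cohort
#' @param path Manifest path or the directory containing `manifest.tsv`.
#' @export
read_cohort <- function(path) {
  mpath <- if (dir.exists(path)) file.path(path, "manifest.tsv") else path
  if (!file.exists(mpath)) stop("manifest not found at ", mpath, call. = FALSE)
  dir <- dirname(mpath)
  manifest <- utils::read.table(mpath, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  recordings <- purrr::map(manifest$file, function(f) {
    tibble::as_tibble(utils::read.table(file.path(dir, f), sep = "\t",
                                        header = TRUE, check.names = FALSE))
  })
  names(recordings) <- manifest$subject_id
  mm <- marker_model()
  present <- intersect(mm$channel, names(recordings[[1]]))
  spec_path <- file.path(dir, "spec.json")
  spec <- if (file.exists(spec_path)) {
    do.call(cohort_spec, jsonlite::read_json(spec_path, simplifyVector = TRUE))
  } else {
    cohort_spec()
  }
  subjects <- tibble::as_tibble(manifest[, c("subject_id", "label", "sex",
                                             "age", "bmi")])
  structure(list(subjects = subjects, recordings = recordings,
                 rate = 60, channels = mm[mm$channel %in% present, ],
                 spec = spec),
            class = "mf_cohort")
}

# Stage seeds derived from the master seed with independent seeded draws,
# so each stage is reproducible in isolation.
.stage_seeds <- function(seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  draws <- sample.int(.Machine$integer.max - 1L, 2)
  list(cohort = seed, classify = draws[1], protocol = draws[2])
}

#' Run the full pipeline
#'
#' Simulate a cohort, extract the stability feature matrix, run the group
#' statistics, benchmark the classifiers, and (optionally) write every
#' table to `out_dir`. Deterministic under the config's master seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, the cohort,
#'   feature matrix, channel-test table, benchmark table, and config are
#'   written there as plain-text files.
#' @return A list: `cohort`, `features`, `channel_tests`, `sex_comparison`,
#'   `baseline`, `benchmark`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- .stage_seeds(config$seed)
  spec <- config$cohort
  spec$seed <- seeds$cohort
  cohort <- gen_cohort(spec, channels = config$channels)
  features <- do.call(extract_features,
                      c(list(cohort = cohort), config$mfdfa))
  ct <- channel_ttests(features, alpha_level = config$alpha_level)
  sx <- sex_group_comparison(features)
  bl <- baseline_ranksum(cohort$subjects)
  proto <- config$protocol
  proto$seed <- seeds$protocol
  specs <- purrr::map(config$classifiers, classifier_spec)
  names(specs) <- config$classifiers
  bench <- benchmark(features, specs, proto, seed = seeds$classify)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_features(features, file.path(out_dir, "features.tsv"))
    utils::write.table(ct, file.path(out_dir, "channel_tests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(bl, file.path(out_dir, "baseline_ranksum.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_benchmark(bench, file.path(out_dir, "benchmark.tsv"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  list(cohort = cohort, features = features, channel_tests = ct,
       sex_comparison = sx, baseline = bl, benchmark = bench)
}
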