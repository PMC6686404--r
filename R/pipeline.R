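# End-to-end orchestration: cohorts -> labels -> tree -> rule -> screening
# decisions -> metrics, with a reproducible run manifest.

#' Configuration of a full screening-rule derivation run
#'
#' The training and test sources are resolved independently: a generator
#' profile name (see [default_profiles]), a CSV path, or a
#' [generator_config]. Training and testing are by cohort (external
#' validation), never by random splitting within a cohort.
#'
#' @param train,test Cohort sources.
#' @param ear_mode `"better"` or `"worse"`.
#' @param criterion `"gini"` or `"shannon"`.
#' @param max_depth Tree depth limit (default 2).
#' @param level_rounding Tone-level rounding for rule extraction.
#' @param seed Global seed; per-stage sub-seeds are derived from it
#'   deterministically.
#' @param out_dir Output directory (created if needed).
#' @return A `run_config` object.
#' @export
run_config <- function(train = "communityA", test = "communityB",
                       ear_mode = c("better", "worse"),
                       criterion = c("gini", "shannon"),
                       max_depth = 2L,
                       level_rounding = c("floor", "nearest", "exact"),
                       seed = 1L, out_dir = tempfile("tonescreen_run_")) {
  structure(list(train = train, test = test,
                 ear_mode = match.arg(ear_mode),
                 criterion = match.arg(criterion),
                 max_depth = as.integer(max_depth),
                 level_rounding = match.arg(level_rounding),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, stage) {
  (as.double(seed) * 7919 + stage * 104729) %% 2147483647
}

.resolve_cohort <- function(source, seed, role) {
  if (inherits(source, "cohort")) return(source)
  if (inherits(source, "generator_config"))
    return(generate_cohort(source, seed = seed))
  if (is.character(source) && length(source) == 1L) {
    profiles <- default_profiles()
    if (source %in% names(profiles))
      return(generate_cohort(profiles[[source]], seed = seed))
    if (file.exists(source)) return(read_cohort(source))
    stop(sprintf("%s source '%s' is neither a known profile (%s) nor a file",
                 role, source, paste(names(profiles), collapse = ", ")),
         call. = FALSE)
  }
  stop(role, " source must be a cohort, generator_config, profile name or CSV path",
       call. = FALSE)
}

#' Run the full screening-rule study
#'
#' Resolves the training and test cohorts, labels them by selected-ear PTA,
#' fits the depth-limited tree on the training cohort, extracts the tone
#' protocol, screens both cohorts with it, and writes every artifact
#' (cohorts, tree, rule, decisions, metrics, manifest) under
#' `cfg$out_dir`. Identical config and seed produce identical outputs.
#'
#' @param cfg A [run_config].
#' @param verbose Log per-stage progress to stderr.
#' @return A `run_manifest` list: config snapshot, seed, package version,
#'   per-stage output paths with md5 checksums, timing, and the computed
#'   metrics.
#' @export
run_study <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("resolving cohorts (seed %d)", cfg$seed)
  train <- stage("train-cohort",
                 .resolve_cohort(cfg$train, derive_seed(cfg$seed, 1), "train"))
  test <- stage("test-cohort",
                .resolve_cohort(cfg$test, derive_seed(cfg$seed, 2), "test"))

  say("labeling (%s ear) and fitting %s tree", cfg$ear_mode, cfg$criterion)
  s_train <- make_labeled_samples(train, cfg$ear_mode)
  s_test <- make_labeled_samples(test, cfg$ear_mode)
  tree <- stage("fit-tree",
                fit_tree(s_train, criterion = cfg$criterion,
                         max_depth = cfg$max_depth))
  rule <- stage("extract-rule",
                extract_rule(tree, level_rounding = cfg$level_rounding,
                             ear_mode = cfg$ear_mode))

  say("screening both cohorts")
  dec_train <- screen_cohort(rule, train, cfg$ear_mode)
  dec_test <- screen_cohort(rule, test, cfg$ear_mode)
  m_train <- metrics(confusion(dec_train$decision, s_train$label),
                     source = "training cohort")
  m_test <- metrics(confusion(dec_test$decision, s_test$label),
                    source = "test cohort")

  paths <- list(train_cohort = file.path(cfg$out_dir, "train_cohort.csv"),
                test_cohort = file.path(cfg$out_dir, "test_cohort.csv"),
                tree = file.path(cfg$out_dir, "tree.json"),
                rule = file.path(cfg$out_dir, "rule.json"),
                decisions_train = file.path(cfg$out_dir, "decisions_train.csv"),
                decisions_test = file.path(cfg$out_dir, "decisions_test.csv"),
                metrics = file.path(cfg$out_dir, "metrics.json"))
  write_cohort(train, paths$train_cohort)
  write_cohort(test, paths$test_cohort)
  write_tree(tree, paths$tree)
  write_rule(rule, paths$rule)
  utils::write.csv(dec_train, paths$decisions_train, row.names = FALSE, quote = FALSE)
  utils::write.csv(dec_test, paths$decisions_test, row.names = FALSE, quote = FALSE)
  metrics_out <- list(
    train = list(sensitivity = m_train$sensitivity,
                 specificity = m_train$specificity,
                 accuracy = m_train$accuracy,
                 confusion = unclass(m_train$confusion)),
    test = list(sensitivity = m_test$sensitivity,
                specificity = m_test$specificity,
                accuracy = m_test$accuracy,
                confusion = unclass(m_test$confusion)))
  jsonlite::write_json(metrics_out, paths$metrics, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  describe_source <- function(src) {
    if (inherits(src, "cohort")) attr(src, "provenance")
    else if (inherits(src, "generator_config")) unclass(src)
    else src
  }
  cfg_snapshot <- unclass(cfg)
  cfg_snapshot$train <- describe_source(cfg$train)
  cfg_snapshot$test <- describe_source(cfg$test)
  manifest <- list(
    config = cfg_snapshot,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("tonescreen")),
    outputs = lapply(paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    metrics = metrics_out,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, manifest_path)  # atomic write at run end
  manifest$path <- manifest_path
  manifest$tree <- tree
  manifest$rule <- rule
  say("done in %.1fs", manifest$elapsed_sec)
  invisible(structure(manifest, class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Screening study run (seed %d, %s ear, %s impurity)\n",
              x$seed, x$config$ear_mode, x$config$criterion))
  cat(sprintf("  training: sens %.2f%% spec %.2f%% acc %.2f%%\n",
              x$metrics$train$sensitivity, x$metrics$train$specificity,
              x$metrics$train$accuracy))
  cat(sprintf("  held-out: sens %.2f%% spec %.2f%% acc %.2f%%\n",
              x$metrics$test$sensitivity, x$metrics$test$specificity,
              x$metrics$test$accuracy))
  cat("  outputs in", x$config$out_dir, "\n")
  invisible(x)
}
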