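#' Load and validate a study configuration
#'
#' Reads a YAML study configuration: a list of tests (sensitivity and
#' specificity in percent, optional CIs, optional externally reported
#' likelihood ratios, biomarker thresholds), pre-test strata (label and
#' pretest percent, associated CURB-65 scores), the test `sequence`, the
#' `rounding_policy`, and optional disposition rules (`default` or an
#' explicit rule list).  Probabilities in configuration files are
#' percentages, matching clinical presentation; the in-memory API works
#' in proportions and converts only at this boundary.
#'
#' Validation is eager and field-named: missing fields, out-of-range
#' probabilities and sequence entries that do not resolve to a
#' configured test each raise an error identifying the offending field.
#' A missing `rounding_policy` defaults to `"nomogram"` and the default
#' is logged to stderr.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `study_config`: `tests` (named list of
#'   [test_accuracy()]), `thresholds` (per-biomarker), `strata`,
#'   `sequence`, `rounding_policy`, `dispositions`
#'   ([disposition_rules()]), `printed` (published values for
#'   verification, if any), `md5` (hash of the canonical dump), and
#'   `raw` (the normalised list, used by [dump_config()]).
#' @examples
#' cfg <- load_config(system.file("extdata", "pneumonia_case_study.yaml",
#'                                package = "bayesdx"))
#' names(cfg$tests)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  need <- function(x, field, where) {
    if (is.null(x)) stop(sprintf("missing field '%s' in %s",
                                 field, where), call. = FALSE)
    x
  }
  pct <- function(x, field, where, lo = 0, hi = 100,
                  lo_open = TRUE, hi_open = FALSE) {
    if (!is.numeric(x) ||
        (lo_open && x <= lo) || (!lo_open && x < lo) ||
        (hi_open && x >= hi) || (!hi_open && x > hi))
      stop(sprintf(
        "field '%s' in %s: expected a percentage in %s%g, %g%s, got %s",
        field, where, if (lo_open) "(" else "[", lo, hi,
        if (hi_open) ")" else "]", deparse(x)), call. = FALSE)
    x / 100
  }

  if (is.null(raw$tests) || !length(raw$tests))
    stop("missing field 'tests'", call. = FALSE)
  tests <- list()
  thresholds <- list()
  for (i in seq_along(raw$tests)) {
    t <- raw$tests[[i]]
    where <- sprintf("tests[%d]", i)
    nm <- need(t$name, "name", where)
    tests[[nm]] <- test_accuracy(
      nm,
      pct(need(t$sensitivity_pct, "sensitivity_pct", where),
          "sensitivity_pct", where),
      pct(need(t$specificity_pct, "specificity_pct", where),
          "specificity_pct", where),
      sens_ci = if (!is.null(t$sens_ci_pct)) t$sens_ci_pct / 100,
      spec_ci = if (!is.null(t$spec_ci_pct)) t$spec_ci_pct / 100,
      positivity = t$positivity,
      lr_positive = t$printed_lr_positive,
      lr_negative = t$printed_lr_negative)
    if (!is.null(t$thresholds)) thresholds[[nm]] <- t$thresholds
  }

  if (is.null(raw$strata) || !length(raw$strata))
    stop("missing field 'strata'", call. = FALSE)
  strata <- lapply(seq_along(raw$strata), function(i) {
    s <- raw$strata[[i]]
    where <- sprintf("strata[%d]", i)
    list(label = need(s$label, "label", where),
         pretest = pct(need(s$pretest_pct, "pretest_pct", where),
                       "pretest_pct", where, hi_open = TRUE),
         curb65 = s$curb65)
  })

  sequence <- raw$sequence %||% names(tests)
  bad <- setdiff(unlist(sequence), names(tests))
  if (length(bad))
    stop("field 'sequence': unresolved test name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  if (is.null(raw$rounding_policy)) {
    message("rounding_policy not set; defaulting to 'nomogram'")
    raw$rounding_policy <- "nomogram"
  }
  if (!raw$rounding_policy %in% c("nomogram", "none"))
    stop("field 'rounding_policy' must be 'nomogram' or 'none'",
         call. = FALSE)

  disp <- raw$dispositions %||% "default"
  dispositions <- if (identical(disp, "default"))
    default_disposition_rules()
  else disposition_rules(disp)

  raw$sequence <- unlist(sequence)
  raw$dispositions <- disp
  cfg <- structure(
    list(study = raw$study %||% "unnamed-study",
         tests = tests, thresholds = thresholds, strata = strata,
         sequence = unlist(sequence),
         rounding_policy = raw$rounding_policy,
         dispositions = dispositions,
         printed = raw$printed, raw = raw),
    class = "study_config")
  cfg$md5 <- config_md5(cfg)
  cfg
}

#' @rdname load_config
#' @param config A `study_config` object.
#' @param path Destination file.
#' @return `dump_config()` writes the canonical YAML form and returns
#'   `path` invisibly; loading the dump reproduces an identical
#'   configuration.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(config$raw, path, precision = 12)
  invisible(path)
}

config_md5 <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config$raw, tmp, precision = 12)
  unname(tools::md5sum(tmp))
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %s\n", x$study))
  cat("  tests:", paste(names(x$tests), collapse = ", "), "\n")
  cat("  strata:",
      paste(vapply(x$strata, function(s)
        sprintf("%s (%.1f%%)", s$label, 100 * s$pretest),
        character(1)), collapse = ", "), "\n")
  cat("  sequence:", paste(x$sequence, collapse = " -> "), "\n")
  cat("  rounding:", x$rounding_policy, "  md5:", x$md5, "\n")
  invisible(x)
}

#' The embedded pneumonia case-study configuration
#'
#' Loads the packaged fixture: pooled procalcitonin and lactate
#' accuracies with their published likelihood ratios, the CURB-65
#' intermediate (14.0%) and high (27.8%) pre-test strata, the
#' PCT-then-lactate sequence, default disposition rules, and the
#' published table values consumed by the verification mode of
#' [run_case_study()].
#'
#' @return A `study_config` object.
#' @examples
#' case_study_config()
#' @export
case_study_config <- function() {
  load_config(system.file("extdata", "pneumonia_case_study.yaml",
                          package = "bayesdx", mustWork = TRUE))
}
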