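#' Diagnostic test accuracy
#'
#' Bundle a test's sensitivity and specificity (as proportions), optional
#' 95% confidence intervals, and a free-text positivity definition into a
#' validated object.  All downstream likelihood-ratio and posterior
#' computations start from one of these.
#'
#' @param name Test name (e.g. `"PCT"`, `"lactate"`).
#' @param sensitivity,specificity Proportions in (0, 1].
#' @param sens_ci,spec_ci Optional length-2 numeric `(low, high)` intervals,
#'   each in (0, 1] and bracketing the point estimate.
#' @param positivity Optional text describing the positivity criterion
#'   (e.g. `"lactate > 2 mmol/L"`).
#' @param lr_positive,lr_negative Optional externally reported likelihood
#'   ratios.  When supplied they are carried alongside the recomputed
#'   values with provenance `"printed"` and are used by table-reproduction
#'   code; `likelihood_ratios()` always recomputes from sensitivity and
#'   specificity as well.
#'
#' @return An object of class `test_accuracy`.
#' @examples
#' pct <- test_accuracy("PCT", 0.88, 0.81, positivity = "PCT > 2.0 ng/mL")
#' likelihood_ratios(pct)
#' @export
test_accuracy <- function(name, sensitivity, specificity,
                          sens_ci = NULL, spec_ci = NULL,
                          positivity = NULL,
                          lr_positive = NULL, lr_negative = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_prop <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1)
      stop(sprintf("%s must be a single proportion in (0, 1], got %s",
                   what, deparse(x)), call. = FALSE)
    x
  }
  check_ci <- function(ci, point, what) {
    if (is.null(ci)) return(NULL)
    if (!is.numeric(ci) || length(ci) != 2L || any(is.na(ci)))
      stop(sprintf("%s must be a numeric (low, high) pair", what),
           call. = FALSE)
    if (ci[1L] > ci[2L] || ci[1L] <= 0 || ci[2L] > 1)
      stop(sprintf("%s must satisfy 0 < low <= high <= 1", what),
           call. = FALSE)
    if (point < ci[1L] || point > ci[2L])
      stop(sprintf("%s does not bracket the point estimate", what),
           call. = FALSE)
    as.numeric(ci)
  }
  sensitivity <- check_prop(sensitivity, "sensitivity")
  specificity <- check_prop(specificity, "specificity")
  structure(
    list(name = name,
         sensitivity = sensitivity,
         specificity = specificity,
         sens_ci = check_ci(sens_ci, sensitivity, "sens_ci"),
         spec_ci = check_ci(spec_ci, specificity, "spec_ci"),
         positivity = positivity,
         printed_lr_positive = lr_positive,
         printed_lr_negative = lr_negative),
    class = "test_accuracy")
}

#' @export
print.test_accuracy <- function(x, ...) {
  cat(sprintf("<test_accuracy> %s: sens %.1f%%, spec %.1f%%\n",
              x$name, 100 * x$sensitivity, 100 * x$specificity))
  if (!is.null(x$positivity)) cat("  positive if:", x$positivity, "\n")
  invisible(x)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' Computes the positive and negative likelihood ratios
#' \eqn{LR^+ = sens / (1 - spec)} and \eqn{LR^- = (1 - sens) / spec}.
#' A perfectly specific test yields `lr_positive = Inf` (propagated as a
#' first-class value, never capped); a perfectly sensitive test yields
#' `lr_negative = 0`.
#'
#' When the accuracy object carries confidence intervals, approximate LR
#' intervals are attached by evaluating the LR formulas at all four
#' (sensitivity, specificity) CI corners and taking the range.  This is a
#' bounding approximation: without the underlying 2x2 counts the standard
#' log-scale interval cannot be computed, so the corner intervals are
#' labelled `approximate`.
#'
#' @param acc A [test_accuracy()] object.
#' @return An object of class `likelihood_ratios` with elements
#'   `lr_positive`, `lr_negative`, optional `lr_positive_ci` /
#'   `lr_negative_ci`, and any printed values carried on the input.
#' @examples
#' likelihood_ratios(test_accuracy("PCT", 0.88, 0.81))
#' @export
likelihood_ratios <- function(acc) {
  stopifnot(inherits(acc, "test_accuracy"))
  lr_pos <- if (acc$specificity == 1) Inf else
    acc$sensitivity / (1 - acc$specificity)
  lr_neg <- (1 - acc$sensitivity) / acc$specificity
  out <- list(test = acc$name,
              lr_positive = lr_pos, lr_negative = lr_neg,
              printed_lr_positive = acc$printed_lr_positive,
              printed_lr_negative = acc$printed_lr_negative)
  if (!is.null(acc$sens_ci) && !is.null(acc$spec_ci)) {
    corners <- expand.grid(sens = acc$sens_ci, spec = acc$spec_ci)
    pos <- ifelse(corners$spec == 1, Inf,
                  corners$sens / (1 - corners$spec))
    neg <- (1 - corners$sens) / corners$spec
    out$lr_positive_ci <- range(pos)
    out$lr_negative_ci <- range(neg)
    out$ci_method <- "approximate (accuracy-CI corners; no 2x2 counts)"
  }
  structure(out, class = "likelihood_ratios")
}

#' @export
print.likelihood_ratios <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "Inf" else sprintf("%.2f", v)
  cat(sprintf("<likelihood_ratios> %s: LR+ %s, LR- %s\n",
              x$test, fmt(x$lr_positive), fmt(x$lr_negative)))
  if (!is.null(x$lr_positive_ci))
    cat(sprintf("  LR+ interval [%s, %s], LR- interval [%s, %s] (%s)\n",
                fmt(x$lr_positive_ci[1]), fmt(x$lr_positive_ci[2]),
                fmt(x$lr_negative_ci[1]), fmt(x$lr_negative_ci[2]),
                x$ci_method))
  if (!is.null(x$printed_lr_positive))
    cat(sprintf("  source-reported: LR+ %s, LR- %s\n",
                fmt(x$printed_lr_positive), fmt(x$printed_lr_negative)))
  invisible(x)
}
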