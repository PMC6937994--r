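#' One-way ANOVA across model stages
#'
#' Classical fixed-effects one-way analysis of variance,
#' \eqn{F = (SSB/(k-1)) / (SSW/(N-k))}, used to compare the probability
#' stages of the sequential model (pre-test alone, after the first
#' biomarker, after the full chain).  The fit is delegated to
#' [stats::lm()] / [stats::anova()]; a degenerate panel with zero
#' within-group variance but non-zero between-group spread is reported
#' explicitly as `f_statistic = Inf`, `p_value = 0`.
#'
#' @param groups A list of at least two numeric vectors (observations per
#'   group); at least two within-group degrees of freedom in total.
#' @return An object of class `anova_result`: `f_statistic`,
#'   `df_between` (k-1), `df_within` (N-k), `p_value` (upper tail of the
#'   F distribution), `group_means`, `ss_between`, `ss_within`.
#' @examples
#' one_way_anova(list(c(14, 27.8), c(43, 64), c(93, 97)))
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (!all(vapply(groups, is.numeric, logical(1))))
    stop("groups must be numeric vectors", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("empty group", call. = FALSE)
  k <- length(groups)
  n <- sum(sizes)
  if (n - k < 2L)
    stop("need at least two within-group degrees of freedom",
         call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep.int(seq_len(k), sizes))
  # the zero-noise panel would make the lm fit perfect (and its F-test
  # meaningless), so handle it before fitting
  if (all(vapply(groups, function(gr) all(gr == gr[1L]), logical(1)))) {
    grand <- mean(y)
    ssb <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
    ssw <- 0
    f <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    tab <- stats::anova(stats::lm(y ~ g))
    ssb <- tab$`Sum Sq`[1L]
    ssw <- tab$`Sum Sq`[2L]
    if (ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- tab$`F value`[1L]
      p <- tab$`Pr(>F)`[1L]
    }
  }
  structure(list(f_statistic = f,
                 df_between = k - 1L, df_within = n - k,
                 p_value = p,
                 group_means = vapply(groups, mean, numeric(1)),
                 ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.2f, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  cat("  group means:", paste(sprintf("%.2f", x$group_means),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Stage groups for the sequential-model ANOVA
#'
#' Builds the three comparison groups used to test whether the chained
#' model separates the probability scale: each group holds the
#' intermediate- and high-stratum values of one stage (n = 2 per group).
#' Stage 1 is the pre-test probability alone, stage 2 the posterior after
#' the first test, stage 3 the posterior after the full sequence.
#' Posteriors are rounded to whole percents under the `"nomogram"`
#' policy, matching the tabulated stage values.
#'
#' @param strata List of strata (`label`, `pretest` proportion).
#' @param tests List of [test_accuracy()] objects forming the sequence.
#' @param direction `"positive"` (LR+ chain) or `"negative"` (LR- chain).
#' @param rounding `"nomogram"` or `"none"`.
#' @return A list of numeric vectors (percent scale), one per stage,
#'   suitable for [one_way_anova()].
#' @examples
#' panel <- list(
#'   test_accuracy("PCT", 0.88, 0.81, lr_positive = 4.63, lr_negative = 0.15),
#'   test_accuracy("lactate", 0.727, 0.962, lr_positive = 19, lr_negative = 0.28))
#' strata <- list(list(label = "intermediate", pretest = 0.14),
#'                list(label = "high", pretest = 0.278))
#' one_way_anova(stage_groups(strata, panel))
#' @export
stage_groups <- function(strata, tests,
                         direction = c("positive", "negative"),
                         rounding = c("nomogram", "none")) {
  direction <- match.arg(direction)
  rounding <- match.arg(rounding)
  lr_of <- function(test) {
    lrs <- likelihood_ratios(test)
    if (direction == "positive") {
      if (!is.null(lrs$printed_lr_positive)) lrs$printed_lr_positive
      else lrs$lr_positive
    } else {
      if (!is.null(lrs$printed_lr_negative)) lrs$printed_lr_negative
      else lrs$lr_negative
    }
  }
  lrs <- vapply(tests, lr_of, numeric(1))
  maybe_round <- function(p)
    if (rounding == "nomogram") round_percent(p) else p
  groups <- vector("list", length(tests) + 1L)
  for (s in seq_along(strata)) {
    p0 <- strata[[s]]$pretest
    groups[[1L]] <- c(groups[[1L]], 100 * p0)
    trace <- sequential_posterior(p0, lrs)$step_posteriors
    for (i in seq_along(trace))
      groups[[i + 1L]] <- c(groups[[i + 1L]],
                            100 * maybe_round(trace[i]))
  }
  groups
}
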