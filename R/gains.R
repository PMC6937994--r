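#' Bayesian Diagnostic Gains
#'
#' The absolute diagnostic gain (ADG) is the post-test minus pre-test
#' probability, expressed in percentage points with its sign preserved.
#' The relative diagnostic gain (RDG) is the ADG as a percentage of the
#' pre-test probability; it is reported as a magnitude with a direction
#' flag (`"gain"` or `"loss"`), the convention used when a negative ADG
#' is tabulated alongside a positive RDG.
#'
#' @param pretest,posttest Probabilities as proportions in \[0, 1\];
#'   `relative_gain()` additionally requires `pretest > 0`.
#' @return `absolute_gain()`: signed percentage points.
#'   `relative_gain()`: the RDG magnitude in percent, with attribute
#'   `direction` (`"gain"`, `"loss"`, or `"none"`).
#' @examples
#' absolute_gain(0.14, 0.43)   # 29 percentage points
#' relative_gain(0.14, 0.43)   # 207.1% gain
#' relative_gain(0.14, 0.04)   # 71.4% loss
#' @export
absolute_gain <- function(pretest, posttest) {
  stopifnot(all(pretest >= 0 & pretest <= 1),
            all(posttest >= 0 & posttest <= 1))
  100 * (posttest - pretest)
}

#' @rdname absolute_gain
#' @export
relative_gain <- function(pretest, posttest) {
  if (any(pretest <= 0))
    stop("relative gain is undefined for pretest = 0", call. = FALSE)
  stopifnot(all(pretest <= 1), all(posttest >= 0 & posttest <= 1))
  delta <- posttest - pretest
  structure(100 * abs(delta) / pretest,
            direction = ifelse(delta > 0, "gain",
                               ifelse(delta < 0, "loss", "none")))
}

#' Bayesian Number Needed to Diagnose
#'
#' The reciprocal of the absolute diagnostic gain taken as a proportion:
#' `NND = 1 / ADG`.  An analogue of the number needed to treat, it reads
#' as the number of patients one must test to net one additional correct
#' severity classification; the ideal value is 1.  Defined only for a
#' positive gain.
#'
#' @param adg Absolute diagnostic gain as a proportion in (0, 1\]
#'   (e.g. `0.29` for 29 percentage points).
#' @return A list with `bnnd` (the reciprocal) and `bnnd_rounded`
#'   (nearest whole number, the integer presentation used alongside the
#'   two-decimal value in published tables).
#' @examples
#' bayesian_nnd(0.29)   # 3.45, presented as 3
#' @export
bayesian_nnd <- function(adg) {
  stopifnot(is.numeric(adg), length(adg) == 1L)
  if (is.na(adg) || adg <= 0)
    stop("B-NND is undefined for a non-positive absolute gain",
         call. = FALSE)
  list(bnnd = 1 / adg, bnnd_rounded = as.integer(round(1 / adg)))
}

round_percent <- function(p) round(100 * p) / 100

#' Assemble a diagnostic-gains table across strata, tests and sequences
#'
#' Builds one record per (stratum x step x outcome): every single test's
#' positive and negative result, followed by every outcome branch of the
#' sequential panel when the sequence has two or more tests.  Likelihood
#' ratios for each step are the test's reported ("printed") values when
#' present on the [test_accuracy()] object, otherwise recomputed from
#' sensitivity and specificity.
#'
#' Under `rounding = "nomogram"` (the default) every posterior is rounded
#' to the nearest whole percent before gains are computed, emulating
#' values read off a Fagan nomogram — this is the policy under which the
#' published gains and B-NND values are self-consistent (e.g. an ADG of
#' 79 points arises only as 93 - 14 on whole percents, where unrounded
#' chaining gives 93.47).  `rounding = "none"` keeps full precision, so
#' that ADG + pretest equals the posterior exactly.
#'
#' @param strata A list of strata, each a list with `label` and `pretest`
#'   (proportion in (0, 1)).
#' @param tests A list of [test_accuracy()] objects.
#' @param sequence Character vector of test names defining the sequential
#'   panel; defaults to all tests in order.
#' @param rounding `"nomogram"` or `"none"`.
#' @return A data frame with columns `stratum`, `step`, `outcome`,
#'   `pretest_pct`, `posttest_pct`, `adg_pp`, `rdg_pct`, `bnnd`
#'   (`NA` where the gain is not positive).
#' @examples
#' panel <- list(
#'   test_accuracy("PCT", 0.88, 0.81, lr_positive = 4.63, lr_negative = 0.15),
#'   test_accuracy("lactate", 0.727, 0.962, lr_positive = 19, lr_negative = 0.28))
#' strata <- list(list(label = "intermediate", pretest = 0.14),
#'                list(label = "high", pretest = 0.278))
#' gains_table(strata, panel)
#' @export
gains_table <- function(strata, tests, sequence = NULL,
                        rounding = c("nomogram", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(length(strata) >= 1L, length(tests) >= 1L)
  test_names <- vapply(tests, `[[`, character(1), "name")
  names(tests) <- test_names
  if (is.null(sequence)) sequence <- test_names
  if (!all(sequence %in% test_names))
    stop("sequence refers to unknown test(s): ",
         paste(setdiff(sequence, test_names), collapse = ", "),
         call. = FALSE)

  step_lr <- function(test, outcome) {
    lrs <- likelihood_ratios(test)
    if (outcome == "positive") {
      if (!is.null(lrs$printed_lr_positive)) lrs$printed_lr_positive
      else lrs$lr_positive
    } else {
      if (!is.null(lrs$printed_lr_negative)) lrs$printed_lr_negative
      else lrs$lr_negative
    }
  }

  rows <- list()
  add_row <- function(stratum, step, outcome, pretest, posterior) {
    post_eff <- if (rounding == "nomogram") round_percent(posterior)
                else posterior
    adg <- absolute_gain(pretest, post_eff)
    rdg <- relative_gain(pretest, post_eff)
    bnnd <- if (adg > 0) bayesian_nnd(adg / 100)$bnnd else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = stratum, step = step, outcome = outcome,
      pretest_pct = 100 * pretest, posttest_pct = 100 * post_eff,
      adg_pp = adg, rdg_pct = as.numeric(rdg), bnnd = bnnd,
      stringsAsFactors = FALSE)
  }

  for (st in strata) {
    p0 <- st$pretest
    for (nm in test_names)
      for (outcome in c("positive", "negative"))
        add_row(st$label, nm, outcome, p0,
                posttest_probability(p0, step_lr(tests[[nm]], outcome)))
    if (length(sequence) >= 2L) {
      combos <- expand.grid(
        rev(replicate(length(sequence), c("positive", "negative"),
                      simplify = FALSE)), stringsAsFactors = FALSE)
      combos <- combos[, rev(seq_along(sequence)), drop = FALSE]
      step_label <- paste(sequence, collapse = "+")
      for (b in seq_len(nrow(combos))) {
        outcomes <- unlist(combos[b, ], use.names = FALSE)
        lrs <- mapply(function(nm, oc) step_lr(tests[[nm]], oc),
                      sequence, outcomes)
        add_row(st$label, step_label,
                paste(ifelse(outcomes == "positive", "+", "-"),
                      collapse = ""),
                p0, sequential_posterior(p0, lrs)$final)
      }
    }
  }
  do.call(rbind, rows)
}
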