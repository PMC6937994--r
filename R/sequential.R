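#' Chain a pre-test probability through a sequence of likelihood ratios
#'
#' Applies the odds-form Bayesian update once per likelihood ratio, in
#' order, carrying each intermediate posterior forward as the next step's
#' pre-test probability.  Under conditional independence of the tests
#' given disease status this equals a single update by the product of the
#' LRs, so the final posterior is invariant to the order of the sequence.
#'
#' @param pretest Pre-test probability (proportion in \[0, 1\]).
#' @param lrs Numeric vector of non-negative likelihood ratios, one per
#'   test result, in testing order.  May be empty.
#' @return An object of class `posterior_trace`: a list with `pretest`,
#'   `lrs`, `step_posteriors` (posterior after each step) and `final`
#'   (equal to the last step posterior, or `pretest` when `lrs` is empty).
#' @examples
#' # CURB-65 intermediate stratum, PCT+ then lactate+
#' sequential_posterior(0.14, c(4.63, 19.0))$final   # 0.9347 -> "93%"
#' @export
sequential_posterior <- function(pretest, lrs = numeric()) {
  stopifnot(is.numeric(pretest), length(pretest) == 1L)
  if (length(lrs) && any(lrs < 0, na.rm = TRUE))
    stop("likelihood ratios must be non-negative", call. = FALSE)
  steps <- numeric(length(lrs))
  p <- pretest
  for (i in seq_along(lrs)) {
    p <- posttest_probability(p, lrs[i])
    steps[i] <- p
  }
  structure(list(pretest = pretest, lrs = as.numeric(lrs),
                 step_posteriors = steps, final = p),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat(sprintf("<posterior_trace> pretest %.1f%%\n", 100 * x$pretest))
  for (i in seq_along(x$lrs))
    cat(sprintf("  step %d: LR %.3g -> %.1f%%\n",
                i, x$lrs[i], 100 * x$step_posteriors[i]))
  cat(sprintf("  final: %.1f%%\n", 100 * x$final))
  invisible(x)
}

#' Enumerate all outcome branches of a sequential test panel
#'
#' For `k` tests applied in order to one pre-test stratum, enumerates all
#' `2^k` positive/negative outcome combinations.  Each branch carries the
#' chained posterior (LR+ for a positive result, LR- for a negative one,
#' recomputed from each test's sensitivity and specificity) and its
#' marginal branch probability under the generative accuracy model
#' \deqn{P(results) = p \prod_i P(r_i | D) + (1-p) \prod_i P(r_i | \bar D),}
#' with results independent across tests given disease status.  Branch
#' probabilities over the panel sum to 1, and the posterior-weighted sum
#' of branch probabilities returns the pre-test probability (law of total
#' probability); both identities are exercised in the test suite.
#'
#' Branches are ordered deterministically: tests in the supplied order,
#' and within each test positive before negative, so the first branch is
#' all-positive and the last all-negative.
#'
#' @param pretest Pre-test probability (proportion in (0, 1)).
#' @param tests A list of [test_accuracy()] objects (at least one).
#' @param stratum Optional stratum label recorded in the output.
#' @param use_printed_lr Chain any externally reported likelihood ratios
#'   carried on the accuracy objects instead of recomputing them from
#'   sensitivity and specificity.  Useful to reproduce published branch
#'   annotations whose printed LRs were rounded; note the law of total
#'   probability (posterior-weighted branch probabilities returning the
#'   pretest) holds exactly only for the recomputed default, since
#'   branch probabilities always come from sensitivity and specificity.
#' @return A data frame with one row per branch: `stratum`, `pattern`
#'   (e.g. `"PCT+/lactate-"`), one `outcome_<test>` column per test,
#'   `posterior`, and `branch_probability`.
#' @examples
#' panel <- list(test_accuracy("PCT", 0.88, 0.81),
#'               test_accuracy("lactate", 0.727, 0.962))
#' enumerate_branches(0.14, panel, stratum = "intermediate")
#' @export
enumerate_branches <- function(pretest, tests, stratum = NA_character_,
                               use_printed_lr = FALSE) {
  if (!length(tests)) stop("at least one test is required", call. = FALSE)
  if (!all(vapply(tests, inherits, logical(1), "test_accuracy")))
    stop("tests must be a list of test_accuracy objects", call. = FALSE)
  stopifnot(is.numeric(pretest), length(pretest) == 1L,
            pretest >= 0, pretest <= 1)
  k <- length(tests)
  names_k <- vapply(tests, `[[`, character(1), "name")
  # expand.grid varies the first factor fastest; we want the first test
  # to vary slowest (all-positive branch first), so build reversed and
  # flip the columns back.
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, c("positive", "negative"),
                                  simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_len(k)), drop = FALSE]
  names(grid) <- paste0("outcome_", names_k)

  posterior <- numeric(nrow(grid))
  branch_prob <- numeric(nrow(grid))
  for (b in seq_len(nrow(grid))) {
    lik_d <- 1; lik_h <- 1; odds <- prob_to_odds(pretest)
    lr_chain <- 1
    for (j in seq_len(k)) {
      acc <- tests[[j]]
      lrs <- likelihood_ratios(acc)
      if (grid[b, j] == "positive") {
        lik_d <- lik_d * acc$sensitivity
        lik_h <- lik_h * (1 - acc$specificity)
        lr_chain <- lr_chain *
          (if (use_printed_lr && !is.null(lrs$printed_lr_positive))
             lrs$printed_lr_positive else lrs$lr_positive)
      } else {
        lik_d <- lik_d * (1 - acc$sensitivity)
        lik_h <- lik_h * acc$specificity
        lr_chain <- lr_chain *
          (if (use_printed_lr && !is.null(lrs$printed_lr_negative))
             lrs$printed_lr_negative else lrs$lr_negative)
      }
    }
    branch_prob[b] <- pretest * lik_d + (1 - pretest) * lik_h
    posterior[b] <- if (use_printed_lr)
      posttest_probability(pretest, lr_chain)
    else if (pretest == 0) 0
    else odds_to_prob(if (lik_h == 0) Inf else odds * lik_d / lik_h)
  }
  sign_chr <- ifelse(as.matrix(grid) == "positive", "+", "-")
  pattern <- apply(sign_chr, 1L, function(s)
    paste0(names_k, s, collapse = "/"))
  cbind(data.frame(stratum = stratum, pattern = pattern,
                   stringsAsFactors = FALSE),
        grid,
        data.frame(posterior = posterior,
                   branch_probability = branch_prob))
}
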