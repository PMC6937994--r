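#' Probability / odds conversions
#'
#' The odds form of Bayes' theorem underlying the Fagan nomogram:
#' post-test odds = pre-test odds x likelihood ratio.  These helpers are
#' vectorised.  `prob_to_odds(1)` is `Inf`; `odds_to_prob(Inf)` is 1.
#'
#' @param p Probabilities in \[0, 1\].
#' @param odds Non-negative odds (`Inf` allowed).
#' @return Numeric vector of odds, or of probabilities.
#' @examples
#' prob_to_odds(0.14)
#' odds_to_prob(prob_to_odds(0.14) * 4.63)
#' @export
prob_to_odds <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  ifelse(p == 1, Inf, p / (1 - p))
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(odds) {
  if (any(odds < 0, na.rm = TRUE))
    stop("odds must be non-negative", call. = FALSE)
  ifelse(is.infinite(odds), 1, odds / (1 + odds))
}

#' Single-step post-test probability (Fagan-nomogram update)
#'
#' Updates a pre-test probability by one likelihood ratio in odds form.
#' Identical to the direct Bayes ratio
#' \eqn{p \cdot sens / (p \cdot sens + (1-p)(1-spec))} when `lr` is the
#' test's LR+.  Pre-test probabilities of exactly 0 or 1 are absorbing:
#' no finite likelihood ratio moves them.  An infinite `lr` drives any
#' non-zero pre-test probability to 1.
#'
#' @param pretest Pre-test probability in \[0, 1\] (proportion).
#' @param lr Non-negative likelihood ratio (`Inf` allowed).
#' @return Post-test probability (proportion), vectorised over inputs.
#' @examples
#' posttest_probability(0.14, 4.63)   # 0.4298 -> "43%" on the nomogram
#' @export
posttest_probability <- function(pretest, lr) {
  if (any(pretest < 0 | pretest > 1, na.rm = TRUE))
    stop("pretest must lie in [0, 1]", call. = FALSE)
  if (any(lr < 0, na.rm = TRUE))
    stop("likelihood ratio must be non-negative", call. = FALSE)
  n <- max(length(pretest), length(lr))
  pretest <- rep_len(pretest, n)
  lr <- rep_len(lr, n)
  out <- odds_to_prob(prob_to_odds(pretest) * lr)
  # an uninformative result must leave the probability bit-identical,
  # which the odds round trip does not guarantee
  out[lr == 1] <- pretest[lr == 1]
  # boundary absorption: 0 * Inf and Inf * 0 are NaN in IEEE arithmetic
  out[pretest == 0] <- 0
  out[pretest == 1] <- 1
  out
}

#' Posterior probability interval from a likelihood-ratio interval
#'
#' Evaluates the odds-form update at the two endpoints of an LR interval.
#' Because the update is monotone increasing in the likelihood ratio, the
#' endpoint images bound the posterior for any LR inside the interval.
#'
#' @param pretest Pre-test probability in \[0, 1\].
#' @param lr_interval Numeric `(low, high)` with `0 < low <= high`.
#' @return Numeric `(low, high)` posterior probabilities.
#' @examples
#' posterior_interval(0.14, c(2, 9))
#' @export
posterior_interval <- function(pretest, lr_interval) {
  if (!is.numeric(lr_interval) || length(lr_interval) != 2L)
    stop("lr_interval must be a numeric (low, high) pair", call. = FALSE)
  if (lr_interval[1L] <= 0 || lr_interval[1L] > lr_interval[2L])
    stop("lr_interval must satisfy 0 < low <= high", call. = FALSE)
  c(posttest_probability(pretest, lr_interval[1L]),
    posttest_probability(pretest, lr_interval[2L]))
}
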