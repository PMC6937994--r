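#' Simulate a patient cohort under the generative accuracy model
#'
#' Draws disease status `Bernoulli(prevalence)` per patient, then each
#' test result conditionally on status — positive with probability
#' `sensitivity` if diseased and `1 - specificity` if healthy —
#' independently across tests given status.  This is the same
#' conditional-independence model under which likelihood-ratio chaining
#' is exact, so the simulator serves as an empirical oracle for the
#' analytic posteriors and branch probabilities.  Fully reproducible
#' from `seed`; the caller's random-number state is left untouched.
#'
#' @param n_patients Positive integer.
#' @param prevalence Disease prevalence, proportion in (0, 1).
#' @param tests List of [test_accuracy()] objects.
#' @param seed Integer seed.
#' @return An object of class `cohort_counts`: a data frame with one row
#'   per outcome branch (same deterministic order as
#'   [enumerate_branches()]) and columns `pattern`, the `outcome_<test>`
#'   columns, `diseased`, `healthy`, `n_branch`,
#'   `empirical_posterior` (`NA` for empty branches), `se`,
#'   `analytic_posterior`, `analytic_branch_probability`.  Attributes
#'   `n_patients`, `prevalence`, `seed` record the configuration.
#' @examples
#' panel <- list(test_accuracy("PCT", 0.88, 0.81),
#'               test_accuracy("lactate", 0.727, 0.962))
#' simulate_cohort(5000, 0.14, panel, seed = 1)
#' @export
simulate_cohort <- function(n_patients, prevalence, tests, seed) {
  stopifnot(n_patients >= 1, prevalence >= 0, prevalence <= 1,
            length(tests) >= 1)
  if (!all(vapply(tests, inherits, logical(1), "test_accuracy")))
    stop("tests must be test_accuracy objects", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  k <- length(tests)
  diseased <- stats::runif(n_patients) < prevalence
  results <- matrix(FALSE, n_patients, k)
  for (j in seq_len(k)) {
    p_pos <- ifelse(diseased, tests[[j]]$sensitivity,
                    1 - tests[[j]]$specificity)
    results[, j] <- stats::runif(n_patients) < p_pos
  }

  branches <- enumerate_branches(prevalence, tests)
  outcome_cols <- grep("^outcome_", names(branches), value = TRUE)
  want <- as.matrix(branches[, outcome_cols, drop = FALSE]) == "positive"
  d_count <- integer(nrow(branches))
  h_count <- integer(nrow(branches))
  # branch index per patient: binary code over test results
  code <- results %*% (2L ^ ((k - 1L):0L))
  branch_code <- want %*% (2L ^ ((k - 1L):0L))
  for (b in seq_len(nrow(branches))) {
    in_b <- code == branch_code[b]
    d_count[b] <- sum(in_b & diseased)
    h_count[b] <- sum(in_b & !diseased)
  }
  n_branch <- d_count + h_count
  emp <- ifelse(n_branch > 0, d_count / n_branch, NA_real_)
  se <- ifelse(n_branch > 0, sqrt(emp * (1 - emp) / n_branch), NA_real_)

  out <- data.frame(pattern = branches$pattern,
                    branches[, outcome_cols, drop = FALSE],
                    diseased = d_count, healthy = h_count,
                    n_branch = n_branch,
                    empirical_posterior = emp, se = se,
                    analytic_posterior = branches$posterior,
                    analytic_branch_probability =
                      branches$branch_probability,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cohort_counts", "data.frame"),
            n_patients = n_patients, prevalence = prevalence,
            seed = seed)
}

#' Empirical posterior probability in one branch
#'
#' The observed diseased fraction among patients whose results match a
#' branch pattern, with its binomial standard error
#' \eqn{\sqrt{\hat p (1 - \hat p) / n}}.  An empty branch has no defined
#' posterior and raises an error.
#'
#' @param counts A `cohort_counts` object from [simulate_cohort()].
#' @param pattern Branch pattern string (e.g. `"PCT+/lactate-"`).
#' @return A list with `posterior`, `se`, `n_branch`, `diseased`,
#'   `healthy`.
#' @export
empirical_posterior <- function(counts, pattern) {
  stopifnot(inherits(counts, "cohort_counts"))
  row <- counts[counts$pattern == pattern, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown branch pattern: ", pattern, call. = FALSE)
  if (row$n_branch == 0L)
    stop("branch ", pattern,
         " is empty: empirical posterior undefined", call. = FALSE)
  list(posterior = row$empirical_posterior, se = row$se,
       n_branch = row$n_branch, diseased = row$diseased,
       healthy = row$healthy)
}
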