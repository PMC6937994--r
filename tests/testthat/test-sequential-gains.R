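test_that("sequential posteriors reproduce the published chain values", {
  # intermediate stratum (14%), PCT+ then lactate+ / lactate-
  expect_equal(round(100 * sequential_posterior(0.14, c(4.63, 19))$final), 93)
  expect_equal(round(100 * sequential_posterior(0.14, c(4.63, 0.28))$final), 17)
  # high stratum (27.8%)
  expect_equal(round(100 * sequential_posterior(0.278, c(4.63, 19))$final), 97)
  expect_equal(round(100 * sequential_posterior(0.278, c(4.63, 0.28))$final), 33)
})

test_that("sequential chaining equals a single product-LR update and is
          order-invariant", {
  expect_equal(sequential_posterior(0.14, numeric())$final, 0.14)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(1, 0.02, 0.98)
    lrs <- exp(runif(sample(1:5, 1), log(0.05), log(20)))
    trace <- sequential_posterior(p, lrs)
    expect_equal(trace$final, posttest_probability(p, prod(lrs)),
                 tolerance = 1e-12)
    expect_equal(trace$final,
                 sequential_posterior(p, rev(lrs))$final,
                 tolerance = 1e-12)
    expect_equal(trace$final,
                 trace$step_posteriors[length(lrs)])
  }
  expect_error(sequential_posterior(0.5, c(2, -1)), "non-negative")
})

test_that("branch enumeration: order, conservation, degenerate panels", {
  br <- enumerate_branches(0.14, case_panel(), stratum = "intermediate")
  expect_equal(nrow(br), 4L)
  # deterministic order: first test slowest, positive before negative
  expect_equal(br$pattern,
               c("PCT+/lactate+", "PCT+/lactate-",
                 "PCT-/lactate+", "PCT-/lactate-"))
  expect_equal(sum(br$branch_probability), 1, tolerance = 1e-12)
  # law of total probability
  expect_equal(sum(br$branch_probability * br$posterior), 0.14,
               tolerance = 1e-10)

  # a perfect test splits the cohort exactly by disease status
  perfect <- list(test_accuracy("gold", 1, 1))
  bp <- enumerate_branches(0.3, perfect)
  expect_equal(bp$branch_probability, c(0.3, 0.7))
  expect_equal(bp$posterior, c(1, 0))

  expect_error(enumerate_branches(0.14, list()), "at least one")
})

test_that("conservation holds across random panels and pretests", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(1:3, 1)
    tests <- lapply(seq_len(k), function(j)
      test_accuracy(paste0("t", j), runif(1, 0.3, 0.99),
                    runif(1, 0.3, 0.99)))
    p <- runif(1, 0.02, 0.98)
    br <- enumerate_branches(p, tests)
    expect_equal(sum(br$branch_probability), 1, tolerance = 1e-12)
    expect_equal(sum(br$branch_probability * br$posterior), p,
                 tolerance = 1e-10)
  }
})

test_that("printed-LR chaining reproduces the published branch figures", {
  br <- enumerate_branches(0.14, case_panel(), stratum = "intermediate",
                           use_printed_lr = TRUE)
  expect_equal(round(100 * br$posterior[br$pattern == "PCT+/lactate+"]), 93)
  expect_equal(round(100 * br$posterior[br$pattern == "PCT+/lactate-"]), 17)
})

test_that("absolute and relative gains match the published tables", {
  expect_equal(absolute_gain(0.14, 0.43), 29)
  expect_equal(absolute_gain(0.278, 0.05), -22.8)
  expect_equal(absolute_gain(0.37, 0.37), 0)

  rdg <- relative_gain(0.14, 0.43)
  expect_equal(round(as.numeric(rdg), 1), 207.1)
  expect_equal(attr(rdg, "direction"), "gain")
  rdg_loss <- relative_gain(0.14, 0.04)
  expect_equal(round(as.numeric(rdg_loss), 1), 71.4)
  expect_equal(attr(rdg_loss, "direction"), "loss")
  expect_equal(as.numeric(relative_gain(0.2, 0.2)), 0)
  expect_error(relative_gain(0, 0.5), "pretest")
})

test_that("B-NND is the reciprocal gain with the published presentation", {
  expect_equal(round(bayesian_nnd(0.29)$bnnd, 2), 3.45)
  expect_equal(round(bayesian_nnd(0.79)$bnnd, 2), 1.27)
  expect_equal(round(bayesian_nnd(0.62)$bnnd, 2), 1.61)
  expect_equal(bayesian_nnd(1)$bnnd, 1)
  expect_equal(bayesian_nnd(0.29)$bnnd_rounded, 3L)
  expect_equal(bayesian_nnd(0.79)$bnnd_rounded, 1L)
  expect_equal(bayesian_nnd(0.62)$bnnd_rounded, 2L)
  expect_error(bayesian_nnd(0), "undefined")
  expect_error(bayesian_nnd(-0.2), "undefined")

  # reciprocal identity
  for (adg in c(0.01, 0.3, 0.77, 1))
    expect_equal(bayesian_nnd(adg)$bnnd * adg, 1, tolerance = 1e-12)
})

test_that("gains table reproduces the published rows under nomogram
          rounding", {
  g <- gains_table(case_strata(), case_panel())
  pick <- function(stratum, step, outcome)
    g[g$stratum == stratum & g$step == step & g$outcome == outcome, ]

  r <- pick("intermediate", "PCT", "positive")
  expect_equal(r$posttest_pct, 43)
  expect_equal(r$adg_pp, 29)
  expect_equal(round(r$rdg_pct, 1), 207.1)
  expect_equal(round(r$bnnd, 2), 3.45)

  expect_equal(pick("high", "PCT", "positive")$posttest_pct, 64)
  expect_equal(pick("intermediate", "PCT", "negative")$posttest_pct, 2)
  expect_equal(pick("high", "PCT", "negative")$posttest_pct, 5)

  r4 <- pick("intermediate", "lactate", "positive")
  expect_equal(r4$posttest_pct, 76)
  expect_equal(r4$adg_pp, 62)
  expect_equal(round(r4$rdg_pct, 1), 442.9)
  expect_equal(round(r4$bnnd, 2), 1.61)
  expect_equal(pick("high", "lactate", "positive")$posttest_pct, 88)
  expect_equal(pick("intermediate", "lactate", "negative")$posttest_pct, 4)
  expect_equal(pick("high", "lactate", "negative")$posttest_pct, 10)

  seq_pos <- pick("intermediate", "PCT+lactate", "++")
  expect_equal(seq_pos$posttest_pct, 93)
  expect_equal(seq_pos$adg_pp, 79)
  expect_equal(round(seq_pos$bnnd, 2), 1.27)
  expect_equal(pick("high", "PCT+lactate", "++")$posttest_pct, 97)

  # negative gains leave B-NND undefined
  expect_true(all(is.na(g$bnnd[g$adg_pp <= 0])))
})

test_that("gains identities are exact without rounding", {
  g <- gains_table(case_strata(), case_panel(), rounding = "none")
  expect_equal(g$pretest_pct + g$adg_pp, g$posttest_pct)

  # LR = 1 leaves everything unchanged
  flat <- gains_table(list(list(label = "s", pretest = 0.2)),
                      list(test_accuracy("coin", 0.5, 0.5)),
                      rounding = "none")
  expect_equal(flat$adg_pp, c(0, 0))
  expect_equal(flat$rdg_pct, c(0, 0))
  expect_true(all(is.na(flat$bnnd)))
})
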