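test_that("CURB-65 scoring follows the printed criteria and boundaries", {
  none <- curb65_score(FALSE, 10, 16, 120, 80, 40)
  expect_equal(none$score, 0L)
  expect_equal(none$stratum, "outpatient")

  all5 <- curb65_score(TRUE, 25, 32, 85, 55, 70)
  expect_equal(all5$score, 5L)
  expect_equal(all5$stratum, "high")

  # strict boundary battery: BUN > 19 (exactly 19 does not score),
  # DBP <= 60 and age >= 65 (exactly on the limit both score)
  edge <- curb65_score(FALSE, 19, 16, 120, 60, 65)
  expect_equal(edge$score, 2L)
  expect_equal(edge$stratum, "discretion")
  expect_equal(curb65_score(FALSE, 19.1, 16, 120, 80, 40)$score, 1L)
  expect_equal(curb65_score(FALSE, 10, 30, 120, 80, 40)$score, 1L)
  expect_equal(curb65_score(FALSE, 10, 29.9, 120, 80, 40)$score, 0L)
  expect_equal(curb65_score(FALSE, 10, 16, 89.9, 80, 40)$score, 1L)
  # BP criterion counts once even when both limbs are met
  expect_equal(curb65_score(FALSE, 10, 16, 85, 55, 40)$score, 1L)

  expect_equal(curb65_score(FALSE, 25, 30, 120, 80, 65)$stratum,
               "intermediate")
  expect_equal(curb65_score(TRUE, 25, 30, 120, 80, 65)$stratum, "high")
  expect_error(curb65_score(FALSE, -1, 16, 120, 80, 40), "bun")
  expect_error(curb65_score("yes", 10, 16, 120, 80, 40), "logical")
})

test_that("CURB-65 score is monotone in its criteria", {
  base <- list(confusion = FALSE, bun = 10, rr = 16, sbp = 120,
               dbp = 80, age = 40)
  flips <- list(confusion = TRUE, bun = 25, rr = 35, sbp = 80,
                dbp = 50, age = 80)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  score_of <- function(mask) {
    args <- base
    for (j in which(unlist(mask))) {
      nm <- names(base)[j]
      # sbp and dbp flips both trigger the single BP criterion
      args[[nm]] <- flips[[nm]]
    }
    do.call(curb65_score, args)$score
  }
  scores <- apply(combos, 1L, score_of)
  expect_true(all(scores >= 0 & scores <= 5))
  # adding one more criterion never decreases the score
  for (r in seq_len(nrow(combos))) {
    for (j in which(!unlist(combos[r, ]))) {
      up <- combos[r, ]
      up[j] <- TRUE
      expect_gte(score_of(up), scores[r])
    }
  }
})

test_that("biomarker categorisation partitions the value axis", {
  expect_equal(classify_biomarker("PCT", 0.3), "negative")
  expect_equal(classify_biomarker("PCT", 1.0), "indeterminate")
  expect_equal(classify_biomarker("PCT", 2.5), "positive")
  # closed indeterminate band
  expect_equal(classify_biomarker("PCT", 0.5), "indeterminate")
  expect_equal(classify_biomarker("PCT", 2.0), "indeterminate")

  expect_equal(classify_biomarker("lactate", 2.5), "positive")
  expect_equal(classify_biomarker("lactate", 2.0), "negative")
  expect_equal(classify_biomarker("lactate", 0), "negative")

  expect_error(classify_biomarker("troponin", 1), "unknown biomarker")
  expect_error(classify_biomarker("PCT", -1), "non-negative")

  # every non-negative value maps to exactly one outcome
  grid <- seq(0, 10, by = 0.05)
  for (marker in c("PCT", "lactate")) {
    out <- classify_biomarker(marker, grid)
    expect_equal(length(out), length(grid))
    expect_true(all(out %in% c("negative", "indeterminate", "positive")))
  }
})

test_that("default rules send intermediate PCT+/lactate+ to the ICU", {
  branches <- enumerate_branches(0.14, case_panel(),
                                 stratum = "intermediate")
  assigned <- assign_disposition(branches, default_disposition_rules())
  expect_equal(
    assigned$disposition[assigned$pattern == "PCT+/lactate+"], "ICU")
  expect_equal(assigned$matched_rule[assigned$pattern == "PCT+/lactate+"],
               1L)
  # PCT+/lactate- posterior (~0.18) falls in the observation band
  expect_equal(
    assigned$disposition[assigned$pattern == "PCT+/lactate-"],
    "Observation")
  # total and deterministic
  expect_true(all(nzchar(assigned$disposition)))
  expect_identical(assign_disposition(branches,
                                      default_disposition_rules()),
                   assigned)
})

test_that("rule sets validate totality and structure", {
  wildcard <- disposition_rules(list(
    list(disposition = "Ward")))
  branches <- enumerate_branches(0.3, case_panel(), stratum = "s")
  expect_equal(unique(assign_disposition(branches, wildcard)$disposition),
               "Ward")

  expect_error(disposition_rules(list(
    list(stratum = "intermediate", disposition = "ICU"))),
    "not total")
  expect_error(disposition_rules(list(
    list(min_posterior = 0.5, disposition = "ICU"))),
    "not total")
  expect_error(disposition_rules(list(
    list(disposition = "Helipad"))), "disposition must be")
  expect_error(disposition_rules(list(
    list(min_posterior = 0.9, max_posterior = 0.1,
         disposition = "ICU"))), "inverted")
})

test_that("tree export renders the branches and round-trips via JSON", {
  branches <- enumerate_branches(0.14, case_panel(),
                                 stratum = "intermediate",
                                 use_printed_lr = TRUE)
  rules <- default_disposition_rules()
  tree <- export_tree(branches, rules)

  expect_match(tree$dot, "digraph disposition")
  expect_match(tree$dot, "CURB-65: intermediate")
  # published figure annotations on the intermediate branches
  expect_match(tree$dot, "posterior 93%", fixed = TRUE)
  expect_match(tree$dot, "posterior 17%", fixed = TRUE)
  expect_match(tree$dot, "ICU")

  leaves <- import_tree_json(tree$json)
  assigned <- assign_disposition(branches, rules)
  expect_equal(leaves$disposition, assigned$disposition)
  expect_equal(leaves$pattern, assigned$pattern)
  expect_equal(leaves$posterior, assigned$posterior)

  # deterministic output
  expect_identical(export_tree(branches, rules)$dot, tree$dot)
})

test_that("an empty test panel exports a single leaf", {
  stub <- data.frame(stratum = "intermediate", pattern = "(no tests)",
                     posterior = 0.14, branch_probability = 1,
                     stringsAsFactors = FALSE)
  tree <- export_tree(stub, default_disposition_rules())
  expect_match(tree$dot, "leaf_1")
  expect_match(tree$dot, "posterior 14%", fixed = TRUE)
  expect_false(grepl("leaf_2", tree$dot))
})
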