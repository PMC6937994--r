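#' Disposition rule sets
#'
#' A disposition rule set is an ordered list of rules mapping enumerated
#' test-outcome branches to care levels.  Each rule matches on an
#' optional stratum pattern, an optional outcome pattern (one entry per
#' test, `"*"` as wildcard), and an optional half-open posterior interval
#' `[min_posterior, max_posterior)`; the first matching rule wins.  A
#' rule set must be *total*: `disposition_rules()` verifies that the
#' fully-wildcarded threshold rules jointly cover the whole posterior
#' axis \[0, 1\], so every possible branch receives a disposition.
#'
#' The default rule set encodes the published admission logic for the
#' panel: an intermediate-risk patient with positive procalcitonin and
#' positive lactate warrants ICU admission.  The remaining branches fall
#' through to posterior-threshold rules that are a package default, not
#' taken from any source: posterior >= 0.90 ICU, \[0.50, 0.90) StepDown,
#' \[0.15, 0.50) Observation, < 0.15 Ward.  All thresholds are
#' overridable.
#'
#' @param rules A list of rules; each rule a list with optional
#'   `stratum`, optional `outcomes` (character vector, `"*"` wildcards),
#'   optional `min_posterior` / `max_posterior`, and a mandatory
#'   `disposition` in `{"ICU", "StepDown", "Observation", "Ward",
#'   "Outpatient"}`.
#' @return An object of class `disposition_rules`.
#' @examples
#' rules <- default_disposition_rules()
#' panel <- list(test_accuracy("PCT", 0.88, 0.81),
#'               test_accuracy("lactate", 0.727, 0.962))
#' branches <- enumerate_branches(0.14, panel, stratum = "intermediate")
#' assign_disposition(branches, rules)
#' @export
disposition_rules <- function(rules) {
  levels_ok <- c("ICU", "StepDown", "Observation", "Ward", "Outpatient")
  if (!is.list(rules) || !length(rules))
    stop("rules must be a non-empty list", call. = FALSE)
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (is.null(r$disposition) || !r$disposition %in% levels_ok)
      stop(sprintf("rule %d: disposition must be one of %s", i,
                   paste(levels_ok, collapse = ", ")), call. = FALSE)
    rules[[i]]$min_posterior <- r$min_posterior %||% 0
    rules[[i]]$max_posterior <- r$max_posterior %||% 1
    if (rules[[i]]$min_posterior > rules[[i]]$max_posterior)
      stop(sprintf("rule %d: inverted posterior interval", i),
           call. = FALSE)
  }
  # totality: the unconditional (no stratum, no outcome pattern) rules
  # must cover [0, 1] on the posterior axis
  uncond <- Filter(function(r)
    is.null(r$stratum) && is.null(r$outcomes), rules)
  if (!length(uncond))
    stop("rule set is not total: add unconditional threshold rules",
         call. = FALSE)
  ivs <- do.call(rbind, lapply(uncond, function(r)
    c(r$min_posterior, r$max_posterior)))
  ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
  covered_to <- -Inf
  for (j in seq_len(nrow(ivs))) {
    if (ivs[j, 1L] > max(covered_to, 0))
      stop("rule set is not total: posterior gap below ",
           ivs[j, 1L], call. = FALSE)
    covered_to <- max(covered_to, ivs[j, 2L])
  }
  if (covered_to < 1)
    stop("rule set is not total: posterior gap above ", covered_to,
         call. = FALSE)
  structure(rules, class = "disposition_rules")
}

#' @rdname disposition_rules
#' @export
default_disposition_rules <- function() {
  disposition_rules(list(
    list(stratum = "intermediate",
         outcomes = c("positive", "positive"),
         disposition = "ICU"),
    list(min_posterior = 0.90, max_posterior = 1, disposition = "ICU"),
    list(min_posterior = 0.50, max_posterior = 0.90,
         disposition = "StepDown"),
    list(min_posterior = 0.15, max_posterior = 0.50,
         disposition = "Observation"),
    list(min_posterior = 0, max_posterior = 0.15, disposition = "Ward")))
}

rule_matches <- function(r, stratum, outcomes, posterior) {
  if (!is.null(r$stratum) && r$stratum != "*" &&
      !identical(r$stratum, stratum)) return(FALSE)
  if (!is.null(r$outcomes)) {
    if (length(r$outcomes) != length(outcomes)) return(FALSE)
    ok <- r$outcomes == "*" | r$outcomes == outcomes
    if (!all(ok)) return(FALSE)
  }
  # threshold rules use a half-open [min, max) interval, closed at 1
  posterior >= r$min_posterior &&
    (posterior < r$max_posterior ||
       (r$max_posterior == 1 && posterior == 1))
}

#' Assign dispositions to enumerated branches
#'
#' Applies an ordered [disposition_rules()] set to each row of a branch
#' table from [enumerate_branches()] (first matching rule wins).  The
#' assignment is deterministic and total — a validated rule set
#' guarantees every branch matches at least one rule.
#'
#' @param branches Data frame from [enumerate_branches()].
#' @param rules A [disposition_rules()] object.
#' @return The branch table with `disposition` and `matched_rule`
#'   (1-based rule index) columns appended.
#' @export
assign_disposition <- function(branches, rules) {
  stopifnot(inherits(rules, "disposition_rules"),
            is.data.frame(branches))
  outcome_cols <- grep("^outcome_", names(branches), value = TRUE)
  disposition <- character(nrow(branches))
  matched <- integer(nrow(branches))
  for (b in seq_len(nrow(branches))) {
    outcomes <- unlist(branches[b, outcome_cols], use.names = FALSE)
    hit <- 0L
    for (i in seq_along(rules)) {
      if (rule_matches(rules[[i]], branches$stratum[b], outcomes,
                       branches$posterior[b])) { hit <- i; break }
    }
    if (hit == 0L)  # unreachable for a validated rule set
      stop("no rule matched branch ", branches$pattern[b],
           call. = FALSE)
    disposition[b] <- rules[[hit]]$disposition
    matched[b] <- hit
  }
  branches$disposition <- disposition
  branches$matched_rule <- matched
  branches
}

#' Export the disposition tree
#'
#' Renders the branch-to-disposition mapping as a decision tree: a root
#' stratum node, one split per test in order, and leaves annotated with
#' the branch posterior and assigned care level.  Two serialisations are
#' produced: Graphviz DOT (for rendering) and JSON (lossless; re-import
#' with [import_tree_json()] reproduces the identical assignments).
#' Node ordering is deterministic.
#'
#' @param branches Data frame from [enumerate_branches()].
#' @param rules A [disposition_rules()] object.
#' @return A list with elements `dot` (character scalar) and `json`
#'   (character scalar).
#' @export
export_tree <- function(branches, rules) {
  assigned <- assign_disposition(branches, rules)
  outcome_cols <- grep("^outcome_", names(assigned), value = TRUE)
  tests <- sub("^outcome_", "", outcome_cols)
  stratum <- unique(assigned$stratum)
  stopifnot(length(stratum) == 1L)

  lines <- c("digraph disposition {",
             "  rankdir=LR;",
             "  node [shape=box];",
             sprintf('  root [label="CURB-65: %s"];', stratum))
  node_id <- function(prefix, path)
    paste0(prefix, gsub("[^A-Za-z0-9]", "_", paste(path, collapse = "_")))
  emit <- function(parent, depth, path) {
    if (depth > length(tests)) return(invisible(NULL))
    for (oc in c("positive", "negative")) {
      new_path <- c(path, paste0(tests[depth], "_", oc))
      if (depth == length(tests)) {
        sel <- rep(TRUE, nrow(assigned))
        full <- c(path, paste0(tests[depth], "_", oc))
        for (d in seq_along(tests)) {
          want <- sub(paste0("^", tests[d], "_"), "", full[d])
          sel <- sel & assigned[[outcome_cols[d]]] == want
        }
        leaf <- assigned[sel, , drop = FALSE]
        id <- node_id("leaf_", new_path)
        lines <<- c(lines, sprintf(
          '  %s [shape=ellipse, label="%s\\nposterior %.0f%%\\n%s"];',
          id, leaf$pattern, 100 * leaf$posterior, leaf$disposition))
        lines <<- c(lines, sprintf('  %s -> %s [label="%s %s"];',
                                   parent, id, tests[depth], oc))
      } else {
        id <- node_id("n_", new_path)
        lines <<- c(lines, sprintf('  %s [label="%s: %s"];',
                                   id, tests[depth], oc))
        lines <<- c(lines, sprintf('  %s -> %s [label="%s %s"];',
                                   parent, id, tests[depth], oc))
        emit(id, depth + 1L, new_path)
      }
    }
  }
  if (length(tests) == 0L) {
    # degenerate panel: the stratum itself is the single leaf
    for (b in seq_len(nrow(assigned)))
      lines <- c(lines, sprintf(
        '  leaf_%d [shape=ellipse, label="posterior %.0f%%\\n%s"];',
        b, 100 * assigned$posterior[b], assigned$disposition[b]),
        sprintf("  root -> leaf_%d;", b))
  } else {
    emit("root", 1L, character())
  }
  lines <- c(lines, "}")

  json <- jsonlite::toJSON(
    list(stratum = stratum, tests = tests,
         leaves = assigned[, c("pattern", outcome_cols, "posterior",
                               "branch_probability", "disposition",
                               "matched_rule")]),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  list(dot = paste(lines, collapse = "\n"), json = as.character(json))
}

#' @rdname export_tree
#' @param json JSON produced by `export_tree()`.
#' @return `import_tree_json()`: a data frame of leaves with their
#'   dispositions, equal to the assignment table the export was built
#'   from.
#' @export
import_tree_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  leaves <- obj$leaves
  leaves$stratum <- obj$stratum
  leaves
}
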