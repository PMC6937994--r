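#' CURB-65 pneumonia severity score
#'
#' One point each for Confusion, blood urea nitrogen > 19 mg/dL,
#' respiratory rate >= 30 breaths/min, systolic blood pressure < 90 mmHg
#' or diastolic <= 60 mmHg (the pressure criterion counts once even when
#' both limbs are met), and age >= 65 years.  Boundary conventions follow
#' the printed inequalities strictly: BUN of exactly 19 does not score;
#' diastolic pressure of exactly 60 and age of exactly 65 do.
#'
#' Score-to-stratum mapping: 0-1 `"outpatient"`, 2 `"discretion"`
#' (physician's discretion — no pre-test stratum is attached and the
#' patient is excluded from Bayesian chaining), 3 `"intermediate"`,
#' 4-5 `"high"`.
#'
#' @param confusion Logical.
#' @param bun Blood urea nitrogen, mg/dL.
#' @param rr Respiratory rate, breaths/min.
#' @param sbp,dbp Systolic / diastolic blood pressure, mmHg.
#' @param age Years.
#' @return A data frame (one row per patient; inputs recycle) with
#'   integer `score` in 0..5 and character `stratum`.
#' @examples
#' curb65_score(TRUE, 25, 32, 85, 55, 70)                # 5, high
#' curb65_score(FALSE, 19, 16, 120, 60, 65)              # 2, discretion
#' @export
curb65_score <- function(confusion, bun, rr, sbp, dbp, age) {
  num <- list(bun = bun, rr = rr, sbp = sbp, dbp = dbp, age = age)
  for (nm in names(num)) {
    if (!is.numeric(num[[nm]]) || any(num[[nm]] < 0, na.rm = TRUE))
      stop(nm, " must be non-negative numeric", call. = FALSE)
  }
  if (!is.logical(confusion))
    stop("confusion must be logical", call. = FALSE)
  n <- max(lengths(list(confusion, bun, rr, sbp, dbp, age)))
  confusion <- rep_len(confusion, n)
  bun <- rep_len(bun, n); rr <- rep_len(rr, n)
  sbp <- rep_len(sbp, n); dbp <- rep_len(dbp, n)
  age <- rep_len(age, n)
  score <- as.integer(confusion) +
    as.integer(bun > 19) +
    as.integer(rr >= 30) +
    as.integer(sbp < 90 | dbp <= 60) +
    as.integer(age >= 65)
  stratum <- c("outpatient", "outpatient", "discretion",
               "intermediate", "high", "high")[score + 1L]
  data.frame(score = score, stratum = stratum, stringsAsFactors = FALSE)
}

#' Categorise a biomarker reading
#'
#' Default thresholds: procalcitonin < 0.5 ng/mL negative, > 2.0 ng/mL
#' positive, the 0.5-2.0 band an explicit `"indeterminate"` outcome
#' (kept visible rather than collapsed into either side; downstream
#' rules treat it as negative for likelihood-ratio purposes but it is
#' flagged for clinical review).  Lactate > 2 mmol/L positive, otherwise
#' negative.  Every non-negative value maps to exactly one outcome.
#'
#' @param name Biomarker name: `"PCT"` or `"lactate"` under the default
#'   threshold set (case-insensitive).
#' @param value Concentration (ng/mL for PCT, mmol/L for lactate);
#'   vectorised.
#' @param thresholds Named list of per-biomarker threshold definitions;
#'   each entry is a list with `negative_below` and/or `positive_above`.
#'   Values in the closed band between them are `"indeterminate"`.
#' @return Character vector in `{"negative", "indeterminate", "positive"}`.
#' @examples
#' classify_biomarker("PCT", c(0.3, 1.0, 2.5))
#' classify_biomarker("lactate", c(2, 2.5))
#' @export
classify_biomarker <- function(name, value,
                               thresholds = default_biomarker_thresholds()) {
  key <- tolower(name)
  names(thresholds) <- tolower(names(thresholds))
  if (!key %in% names(thresholds))
    stop("unknown biomarker: ", name, call. = FALSE)
  if (any(value < 0, na.rm = TRUE))
    stop("biomarker values must be non-negative", call. = FALSE)
  th <- thresholds[[key]]
  lo <- th$negative_below %||% th$positive_above
  hi <- th$positive_above %||% th$negative_below
  if (lo == hi)  # binary cut: no indeterminate band
    ifelse(value > hi, "positive", "negative")
  else
    ifelse(value > hi, "positive",
           ifelse(value < lo, "negative", "indeterminate"))
}

#' @rdname classify_biomarker
#' @export
default_biomarker_thresholds <- function() {
  list(pct = list(negative_below = 0.5, positive_above = 2.0),
       lactate = list(positive_above = 2.0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
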