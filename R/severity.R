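#' Interaction severity ladder
#'
#' Severity of a drug--gene or drug--drug interaction is an ordered category:
#' `none < monitor < moderate < major < contraindicated`. Only interactions of
#' moderate or worse severity are considered clinically actionable; a
#' monitor-level interaction would not change management and is excluded from
#' probability scoring.
#'
#' @return `severity_levels()` returns the five levels in increasing order.
#' @export
#' @examples
#' severity_levels()
#' is_actionable("moderate")
severity_levels <- function() {
  SEVERITY_LEVELS
}

SEVERITY_LEVELS <- c("none", "monitor", "moderate", "major", "contraindicated")

#' @describeIn severity_levels Integer rank of a severity label
#'   (0 = none ... 4 = contraindicated). Vectorised; unknown labels error.
#' @param severity character vector of severity labels.
#' @export
severity_rank <- function(severity) {
  r <- match(severity, SEVERITY_LEVELS) - 1L
  if (anyNA(r)) {
    stopf("unknown severity label(s): %s",
          paste(unique(severity[is.na(r)]), collapse = ", "))
  }
  r
}

#' @describeIn severity_levels TRUE when the severity is moderate, major or
#'   contraindicated.
#' @export
is_actionable <- function(severity) {
  severity_rank(severity) >= 2L
}

# escalate a severity by `steps` levels, capped at contraindicated; never
# de-escalates (negative steps are treated as 0)
escalate_severity <- function(severity, steps) {
  lv <- severity_levels()
  i <- severity_rank(severity) + pmax(as.integer(steps), 0L)
  lv[pmin(i, 4L) + 1L]
}

#' Evidence sources that qualify an interaction rule as evidence-based
#'
#' Actionable guidance must be backed by FDA drug labeling or CPIC guidelines
#' of category A or B; rules with evidence `"other"` are retained in a
#' knowledge base for display but never contribute to PIP scores or to
#' actionable-interaction detection.
#'
#' @return `evidence_sources()` returns the recognised labels.
#' @export
#' @examples
#' is_evidence_based(c("FDA_label", "other"))
evidence_sources <- function() {
  c("FDA_label", "CPIC_A", "CPIC_B", "other")
}

#' @describeIn evidence_sources TRUE for FDA label or CPIC A/B evidence.
#' @param source character vector of evidence-source labels.
#' @export
is_evidence_based <- function(source) {
  bad <- setdiff(unique(source), evidence_sources())
  if (length(bad)) stopf("unknown evidence source(s): %s", paste(bad, collapse = ", "))
  source %in% c("FDA_label", "CPIC_A", "CPIC_B")
}
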