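# Categorical AUC-change scale.
#
# Exposure changes (area under the plasma concentration-time curve) are binned
# per direction, ordered by magnitude:
#   decrease: -0-30%, -31-50%, -51-80%, -81-100%   (bins 1..4)
#   increase: +0-25%, +26-75%, +76-200%, >200%     (bins 1..4)
#   none:     a single neutral bin
# The asymmetric bin edges follow the published categorisation of inhibition /
# induction strength: an inhibitor can raise exposure many-fold, a reduction
# is bounded at -100%.

AUC_DECREASE <- c("-0-30%", "-31-50%", "-51-80%", "-81-100%")
AUC_INCREASE <- c("+0-25%", "+26-75%", "+76-200%", ">200%")

#' AUC-change categories
#'
#' All recognised categorical labels for a change in drug exposure (AUC).
#' Decrease bins: `-0-30%`, `-31-50%`, `-51-80%`, `-81-100%`; increase bins:
#' `+0-25%`, `+26-75%`, `+76-200%`, `>200%`; plus the neutral `none`.
#'
#' @return character vector of the nine labels.
#' @export
#' @examples
#' auc_categories()
#' auc_direction("-31-50%")
#' auc_bin(">200%")
auc_categories <- function() {
  c("none", AUC_DECREASE, AUC_INCREASE)
}

AUC_ALL <- c("none", AUC_DECREASE, AUC_INCREASE)

check_auc <- function(x) {
  m <- match(x, AUC_ALL)
  if (anyNA(m)) {
    stopf("unknown AUC category label(s): %s",
          paste(unique(x[is.na(m)]), collapse = ", "))
  }
  invisible(x)
}

#' @describeIn auc_categories direction of a category: `"decrease"`,
#'   `"increase"` or `"none"`. Vectorised.
#' @param x character vector of AUC category labels.
#' @export
auc_direction <- function(x) {
  check_auc(x)
  ifelse(x %in% AUC_DECREASE, "decrease",
         ifelse(x %in% AUC_INCREASE, "increase", "none"))
}

#' @describeIn auc_categories ordinal magnitude bin within its direction
#'   (1 = mildest, 4 = most extreme; 0 for `none`). Vectorised.
#' @export
auc_bin <- function(x) {
  check_auc(x)
  b <- match(x, AUC_DECREASE)
  b[is.na(b)] <- match(x[is.na(b)], AUC_INCREASE)
  b[is.na(b)] <- 0L
  as.integer(b)
}

# label for (direction, bin); bin clamped to 1..4
auc_label <- function(direction, bin) {
  bin <- min(max(as.integer(bin), 1L), 4L)
  switch(direction,
         decrease = AUC_DECREASE[bin],
         increase = AUC_INCREASE[bin],
         none = "none",
         stopf("unknown AUC direction: %s", direction))
}

#' Combine two categorical AUC changes
#'
#' Ordinal escalation rule for the cumulative exposure impact of a genetic
#' phenotype and a co-medication (or of two modifiers) acting on the same
#' drug:
#' * `none` is the identity element;
#' * two same-direction inputs escalate to the bin one step more extreme than
#'   the stronger input, capped at the scale's extreme bin;
#' * opposite-direction inputs partially cancel: the stronger input is
#'   de-escalated by one bin, floored at the mildest bin of its direction.
#'   When the two bins are equal the result is the mildest decrease bin
#'   (net attenuation), which keeps the operation commutative.
#'
#' The operation is commutative and monotone: a same-direction combination is
#' never milder than either input.
#'
#' @param a,b single AUC category labels (see [auc_categories()]).
#' @return a single AUC category label.
#' @export
#' @examples
#' combine_auc("-31-50%", "-31-50%")  # escalates to "-51-80%"
#' combine_auc("-31-50%", "+26-75%")  # partial cancellation: "-0-30%"
#' combine_auc("none", ">200%")       # identity
combine_auc <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  check_auc(c(a, b))
  if (a == "none") return(b)
  if (b == "none") return(a)
  da <- auc_direction(a); db <- auc_direction(b)
  ba <- auc_bin(a); bb <- auc_bin(b)
  if (da == db) {
    auc_label(da, min(max(ba, bb) + 1L, 4L))
  } else if (ba > bb) {
    auc_label(da, max(ba - 1L, 1L))
  } else if (bb > ba) {
    auc_label(db, max(bb - 1L, 1L))
  } else {
    auc_label("decrease", 1L)
  }
}

#' Severity escalation under a combined AUC change
#'
#' When co-medication pushes the combined exposure change beyond the bin of
#' the underlying drug--gene rule, the interaction's severity escalates: one
#' level per extra magnitude bin, at most two levels, capped at
#' `contraindicated`. A combined change that is no more extreme than the
#' rule's own AUC bin leaves the severity unchanged; severity never drops
#' below the rule's stated level.
#'
#' @param severity the rule's stated severity label.
#' @param rule_auc the rule's stated AUC category.
#' @param combined_auc the combined AUC category after co-medication.
#' @return a severity label.
#' @export
#' @examples
#' interaction_severity("moderate", "-31-50%", "-51-80%")  # "major"
interaction_severity <- function(severity, rule_auc, combined_auc) {
  delta <- auc_bin(combined_auc) - auc_bin(rule_auc)
  escalate_severity(severity, min(max(delta, 0L), 2L))
}
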