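# Phenoconversion: co-medication shifting the effective metabolizer phenotype,
# and translation of stored modifier effects into drug-component AUC
# categories.

#' Metabolizer phenotype ladder
#'
#' Interpreted phenotypes of a drug-metabolising enzyme, ordered by activity:
#' `poor < intermediate < normal < rapid < ultrarapid`.
#'
#' @return character vector of the five phenotypes in increasing activity.
#' @export
#' @examples
#' metabolizer_ladder()
metabolizer_ladder <- function() {
  c("poor", "intermediate", "normal", "rapid", "ultrarapid")
}

#' Effective phenotype under co-medication
#'
#' Phenoconversion: enzyme inhibitors reduce, and inducers increase, the
#' effective metabolic activity, so a patient's observed phenotype can differ
#' from the genotype-predicted one. Each inhibitory co-medication shifts the
#' phenotype one ladder step toward `poor`; each inducer shifts one step
#' toward `ultrarapid`. Modifiers are applied in the order given and shifts
#' saturate at the ladder ends.
#'
#' @param genetic genotype-predicted phenotype; must be on
#'   [metabolizer_ladder()]. Non-ladder phenotypes (e.g. carrier status of an
#'   HLA allele) cannot be phenoconverted and raise an error.
#' @param modifiers character vector of modifier actions, each `"inhibitor"`
#'   or `"inducer"`, one entry per co-medication acting on the same gene. May
#'   also be a data frame with an `action` column (as stored in a knowledge
#'   base).
#' @return the effective phenotype label.
#' @export
#' @examples
#' effective_phenotype("normal", c("inhibitor", "inhibitor"))
#' effective_phenotype("intermediate", "inhibitor")
effective_phenotype <- function(genetic, modifiers = character()) {
  if (is.data.frame(modifiers)) modifiers <- modifiers$action
  ladder <- metabolizer_ladder()
  i <- match(genetic, ladder)
  if (is.na(i)) {
    stopf("phenotype '%s' is not on the metabolizer ladder and cannot be phenoconverted",
          genetic)
  }
  bad <- setdiff(modifiers, c("inhibitor", "inducer"))
  if (length(bad)) stopf("unknown modifier action(s): %s", paste(bad, collapse = ", "))
  for (m in modifiers) {
    i <- if (m == "inhibitor") max(i - 1L, 1L) else min(i + 1L, 5L)
  }
  ladder[i]
}

#' Drug-component AUC category of a modifier
#'
#' A modifier's effect is stored in the knowledge base as an action
#' (`inhibitor` or `inducer`) plus an ordinal strength bin (1--4). For a
#' parent-drug substrate, inhibition raises exposure (increase bins) and
#' induction lowers it (decrease bins). For a prodrug rule -- where the
#' interaction concerns the active metabolite -- the direction is mirrored at
#' the same bin index: inhibiting the activating enzyme lowers metabolite
#' exposure.
#'
#' @param action `"inhibitor"` or `"inducer"`.
#' @param strength integer magnitude bin 1--4.
#' @param prodrug TRUE when the affected rule concerns a prodrug's active
#'   metabolite.
#' @return an AUC category label (never `none`).
#' @export
#' @examples
#' modifier_auc_component("inhibitor", 2)                 # "+26-75%"
#' modifier_auc_component("inhibitor", 2, prodrug = TRUE) # "-31-50%"
modifier_auc_component <- function(action, strength, prodrug = FALSE) {
  if (!action %in% c("inhibitor", "inducer")) {
    stopf("unknown modifier action: %s", action)
  }
  strength <- as.integer(strength)
  if (is.na(strength) || strength < 1L || strength > 4L) {
    stopf("modifier strength must be an integer in 1..4")
  }
  increase <- (action == "inhibitor")
  if (prodrug) increase <- !increase
  auc_label(if (increase) "increase" else "decrease", strength)
}
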