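# PIP engine.
#
# The PIP score is the probability, under independent per-gene phenotype
# draws from the population prevalence table, that a patient's medication
# list yields at least one evidence-based actionable interaction. The
# computation factorises over gene clusters: genes are coupled only by
# two-gene rules, so disjoint clusters contribute independent
# "at least one" probabilities that multiply through their complements.

# strongest gene-free drug-drug severity rank for an unordered pair, 0 if none
ddi_pair_rank <- function(kb, a, b) {
  d <- kb$ddi
  hit <- is.na(d$drug3) &
    ((d$drug1 == a & d$drug2 == b) | (d$drug1 == b & d$drug2 == a))
  if (!any(hit)) 0L else max(severity_rank(d$severity[hit]))
}

check_known_drugs <- function(meds, kb, strict) {
  unknown <- setdiff(meds, kb_drugs(kb))
  if (length(unknown)) {
    if (strict) stopf("unknown drug name(s): %s", paste(unknown, collapse = ", "))
    meds <- setdiff(meds, unknown)
  }
  meds
}

#' Enumerate actionable interaction opportunities
#'
#' Finds every evidence-based interaction rule reachable from a medication
#' list within a gene set, paired with the co-medication modifier effects
#' acting on the rule's gene, and applies the scoring exclusion filters:
#' rules whose evidence is not FDA label / CPIC A-B, rules whose
#' post-phenoconversion severity is below moderate (monitoring-only findings
#' would not change management), and two-drug opportunities whose severity
#' does not exceed the strongest gene-free drug--drug rule for the same pair
#' (genotype information would add nothing). Each retained modifier pairing
#' is a separate `DDGI` opportunity with its combined AUC category and
#' escalated severity; the bare rule is a `DGI` (or `DGGI`) opportunity.
#'
#' @param meds character vector of drug names (case-insensitive; duplicates
#'   removed). Must be non-empty.
#' @param kb a [pip_kb()] knowledge base.
#' @param gene_set genes to consider (default: all KB genes).
#' @param strict if TRUE, medication names unknown to the KB raise an error;
#'   by default they are ignored (vitamins and supplements carry no rules).
#' @return data frame with one row per surviving opportunity: `kind`, `drug`,
#'   `modifier`, `gene`, `phenotype`, `second_gene`, `second_phenotype`,
#'   `rule_severity`, `severity` (post-phenoconversion), `combined_auc`,
#'   `evidence`.
#' @export
#' @examples
#' demo <- demo_kb()
#' interaction_opportunities(c("clopidogrel", "tramadol"), demo$kb,
#'                           gene_set = "CYP2C19")
interaction_opportunities <- function(meds, kb, gene_set = kb_genes(kb),
                                      strict = FALSE) {
  meds <- normalize_meds(meds)
  if (!length(meds)) stopf("medication list is empty")
  meds <- check_known_drugs(meds, kb, strict)

  rules <- kb$rules
  keep <- rules$drug %in% meds & rules$gene %in% gene_set &
    (is.na(rules$second_gene) | rules$second_gene %in% gene_set) &
    is_evidence_based(rules$evidence)
  rules <- rules[keep, , drop = FALSE]

  kind <- drug <- modifier <- gene <- phenotype <- second_gene <-
    second_phenotype <- rule_severity <- severity <- combined_auc <-
    evidence <- character()
  add <- function(.kind, i, .modifier, .combined, .severity) {
    kind <<- c(kind, .kind); drug <<- c(drug, rules$drug[i])
    modifier <<- c(modifier, .modifier); gene <<- c(gene, rules$gene[i])
    phenotype <<- c(phenotype, rules$phenotype[i])
    second_gene <<- c(second_gene, rules$second_gene[i])
    second_phenotype <<- c(second_phenotype, rules$second_phenotype[i])
    rule_severity <<- c(rule_severity, rules$severity[i])
    severity <<- c(severity, .severity)
    combined_auc <<- c(combined_auc, .combined)
    evidence <<- c(evidence, rules$evidence[i])
  }

  prodrug_of <- stats::setNames(kb$drugs$prodrug, kb$drugs$drug)
  for (i in seq_len(nrow(rules))) {
    r_drug <- rules$drug[i]; r_gene <- rules$gene[i]
    r_auc <- rules$auc_change[i]; r_sev <- rules$severity[i]
    add(if (is.na(rules$second_gene[i])) "DGI" else "DGGI",
        i, NA_character_, r_auc, r_sev)
    if (is.na(rules$second_gene[i])) {
      msel <- which(kb$modifiers$gene == r_gene &
                      kb$modifiers$drug %in% meds &
                      kb$modifiers$drug != r_drug)
      for (j in msel) {
        comp <- modifier_auc_component(kb$modifiers$action[j],
                                       kb$modifiers$strength[j],
                                       prodrug_of[[r_drug]])
        comb <- combine_auc(r_auc, comp)
        sev <- interaction_severity(r_sev, r_auc, comb)
        # genotype must add information beyond the gene-free drug-drug rule
        if (severity_rank(sev) <= ddi_pair_rank(kb, r_drug, kb$modifiers$drug[j])) next
        add("DDGI", i, kb$modifiers$drug[j], comb, sev)
      }
    }
  }
  opps <- data.frame(kind = kind, drug = drug, modifier = modifier,
                     gene = gene, phenotype = phenotype,
                     second_gene = second_gene,
                     second_phenotype = second_phenotype,
                     rule_severity = rule_severity, severity = severity,
                     combined_auc = combined_auc, evidence = evidence,
                     stringsAsFactors = FALSE)
  opps <- opps[is_actionable(opps$severity), , drop = FALSE]
  rownames(opps) <- NULL
  opps
}

# partition the genes touched by a set of opportunities into clusters
# coupled by two-gene rules (connected components; singletons are common)
opportunity_clusters <- function(opps) {
  genes <- unique(stats::na.omit(c(opps$gene, opps$second_gene)))
  if (!length(genes)) return(list())
  parent <- stats::setNames(genes, genes)
  find <- function(g) { while (parent[[g]] != g) g <- parent[[g]]; g }
  two <- !is.na(opps$second_gene)
  for (i in which(two)) parent[[find(opps$gene[i])]] <- find(opps$second_gene[i])
  roots <- vapply(genes, find, "")
  unname(lapply(split(genes, roots), sort))
}

#' Probability that a gene cluster yields an actionable interaction
#'
#' Exact probability, under independent phenotype draws per gene from the
#' prevalence table, that at least one of the cluster's opportunities is
#' triggered (its required phenotype -- and second phenotype, for a two-gene
#' rule -- is drawn). Computed by enumerating the Cartesian product of the
#' cluster genes' phenotype distributions; within-gene correlation across
#' co-substrate drugs is thereby handled exactly.
#'
#' @param genes character vector of the cluster's gene symbols.
#' @param opps opportunity rows (from [interaction_opportunities()]) whose
#'   genes all lie in `genes`.
#' @param prev a `pip_prevalence` table covering `genes`.
#' @return probability in `[0, 1]`.
#' @export
cluster_actionable_probability <- function(genes, opps, prev) {
  if (!nrow(opps)) return(0)
  missing <- setdiff(genes, names(prev))
  if (length(missing)) stopf("no prevalence for gene(s): %s", paste(missing, collapse = ", "))
  if (length(genes) == 1L && all(is.na(opps$second_gene))) {
    return(sum(prev[[genes]][unique(opps$phenotype)]))
  }
  grid <- expand.grid(lapply(stats::setNames(genes, genes),
                             function(g) names(prev[[g]])),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  w <- Reduce(`*`, lapply(genes, function(g) unname(prev[[g]][grid[[g]]])))
  hit <- rep(FALSE, nrow(grid))
  for (i in seq_len(nrow(opps))) {
    m <- grid[[opps$gene[i]]] == opps$phenotype[i]
    if (!is.na(opps$second_gene[i])) {
      m <- m & grid[[opps$second_gene[i]]] == opps$second_phenotype[i]
    }
    hit <- hit | m
  }
  sum(w[hit])
}

pip_from_opportunities <- function(opps, prev) {
  clusters <- opportunity_clusters(opps)
  probs <- vapply(clusters, function(genes) {
    sel <- opps$gene %in% genes |
      (!is.na(opps$second_gene) & opps$second_gene %in% genes)
    cluster_actionable_probability(genes, opps[sel, , drop = FALSE], prev)
  }, numeric(1))
  names(probs) <- vapply(clusters, paste, "", collapse = "+")
  list(p = 1 - prod(1 - probs), per_cluster = probs)
}

#' Compute a PIP score
#'
#' The pharmacogenomic interaction probability: the chance that testing the
#' full gene panel would reveal at least one evidence-based actionable
#' interaction for this medication list, given population phenotype
#' prevalences. Also returns the adjusted PIP, restricted to the genes the
#' patient actually had tested; restricting the gene set can only remove
#' opportunities, so the adjusted score never exceeds the full score.
#'
#' @inheritParams interaction_opportunities
#' @param prev a `pip_prevalence` table covering the knowledge-base genes.
#' @param tested_genes genes on the patient's ordered panel (default: all
#'   KB genes, making `adjusted_pip` equal `pip`).
#' @return an object of class `pip_result`: list with `pip`, `adjusted_pip`,
#'   `per_cluster` (actionable probability per gene cluster, full panel),
#'   `opportunity_count`, `opportunities` (the filtered opportunity table),
#'   `meds`, `tested_genes`.
#' @export
#' @examples
#' demo <- demo_kb()
#' compute_pip("metoprolol", demo$kb, demo$prevalence)$pip  # 0.48
compute_pip <- function(meds, kb, prev, tested_genes = kb_genes(kb),
                        strict = FALSE) {
  opps <- interaction_opportunities(meds, kb, gene_set = kb_genes(kb),
                                    strict = strict)
  full <- pip_from_opportunities(opps, prev)
  adj_sel <- opps$gene %in% tested_genes &
    (is.na(opps$second_gene) | opps$second_gene %in% tested_genes)
  adj <- pip_from_opportunities(opps[adj_sel, , drop = FALSE], prev)
  structure(list(pip = full$p, adjusted_pip = adj$p,
                 per_cluster = full$per_cluster,
                 opportunity_count = nrow(opps), opportunities = opps,
                 meds = normalize_meds(meds),
                 tested_genes = tested_genes),
            class = "pip_result")
}

#' @export
print.pip_result <- function(x, ...) {
  cat(sprintf("PIP score: %.1f%% (adjusted to tested panel: %.1f%%)\n",
              100 * x$pip, 100 * x$adjusted_pip))
  cat(sprintf("  %d actionable interaction opportunit%s across %d gene cluster%s\n",
              x$opportunity_count, if (x$opportunity_count == 1) "y" else "ies",
              length(x$per_cluster), if (length(x$per_cluster) == 1) "" else "s"))
  for (nm in names(x$per_cluster)) {
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$per_cluster[[nm]]))
  }
  invisible(x)
}

#' Brute-force PIP oracle
#'
#' Exact reference computation of the (adjusted) PIP score by a different
#' route: enumerate every joint phenotype assignment over the relevant
#' tested genes, hand each assignment to the interaction detector as a
#' genotyped patient, and accumulate the probability mass of assignments
#' with at least one actionable finding ([has_eadgi()]). Relevant genes are
#' read directly off the rule table, independently of the engine's
#' opportunity filtering.
#'
#' @inheritParams compute_pip
#' @param max_combinations guard on the enumeration size.
#' @return probability; equals `compute_pip(...)$adjusted_pip` (and `$pip`
#'   when `tested_genes` is the full panel) to within numerical noise.
#' @export
pip_bruteforce <- function(meds, kb, prev, tested_genes = kb_genes(kb),
                           strict = FALSE, max_combinations = 1e6) {
  meds <- normalize_meds(meds)
  if (!length(meds)) stopf("medication list is empty")
  meds <- check_known_drugs(meds, kb, strict)
  r <- kb$rules[kb$rules$drug %in% meds, , drop = FALSE]
  genes <- intersect(unique(stats::na.omit(c(r$gene, r$second_gene))), tested_genes)
  if (!length(genes)) return(0)
  sizes <- vapply(genes, function(g) length(prev[[g]]), numeric(1))
  if (prod(sizes) > max_combinations) {
    stopf("joint phenotype enumeration too large (%g combinations)", prod(sizes))
  }
  grid <- expand.grid(lapply(stats::setNames(genes, genes),
                             function(g) names(prev[[g]])),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  w <- Reduce(`*`, lapply(genes, function(g) unname(prev[[g]][grid[[g]]])))
  p <- 0
  for (i in seq_len(nrow(grid))) {
    phenos <- stats::setNames(unlist(grid[i, , drop = FALSE], use.names = FALSE),
                              genes)
    patient <- patient_record("oracle", meds, tested_genes = tested_genes,
                              phenotypes = phenos)
    if (has_eadgi(patient, kb)) p <- p + w[i]
  }
  p
}
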