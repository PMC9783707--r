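# Interaction detector for genotyped patients, plus the cohort-level
# severity / clinical-area / top-medication tabulations.

#' Patient record
#'
#' A patient as seen by the scoring and detection functions: a non-empty
#' medication list, the set of genes actually tested, and -- for genotyped
#' patients -- the interpreted phenotype of each tested gene. Age and sex are
#' annotations only; they never enter scoring.
#'
#' @param patient_id identifier string.
#' @param meds character vector of drug names (case-insensitive); must be
#'   non-empty.
#' @param tested_genes genes on the ordered panel.
#' @param phenotypes named character vector, gene -> interpreted phenotype;
#'   names must be a subset of `tested_genes`.
#' @param age,sex optional annotations.
#' @return an object of class `pip_patient`.
#' @export
#' @examples
#' patient_record("p1", c("clopidogrel", "tramadol"),
#'                tested_genes = "CYP2C19",
#'                phenotypes = c(CYP2C19 = "intermediate"))
patient_record <- function(patient_id, meds, tested_genes = character(),
                           phenotypes = NULL, age = NULL, sex = NULL) {
  meds <- normalize_meds(meds)
  if (!length(meds)) stopf("patient %s: medication list is empty", patient_id)
  phenotypes <- phenotypes %||% stats::setNames(character(), character())
  extra <- setdiff(names(phenotypes), tested_genes)
  if (length(extra)) {
    stopf("patient %s: phenotypes reported for untested gene(s): %s",
          patient_id, paste(extra, collapse = ", "))
  }
  structure(list(patient_id = as.character(patient_id), meds = meds,
                 tested_genes = tested_genes, phenotypes = phenotypes,
                 age = age, sex = sex),
            class = "pip_patient")
}

# Precedence used only to break ties at equal severity: gene-involving kinds
# first, then three-drug over two-drug.
KIND_PRECEDENCE <- c(DGGI = 5L, DDGI = 4L, DGI = 3L, DDDI = 2L, DDI = 1L)

empty_interactions <- function() {
  data.frame(kind = character(), drug = character(), drug2 = character(),
             drug3 = character(), gene = character(), phenotype = character(),
             gene2 = character(), phenotype2 = character(),
             severity = character(), combined_auc = character(),
             clinical_area = character(), eadgi = logical(),
             stringsAsFactors = FALSE)
}

# All interactions reachable from a medication list within a gene set,
# before phenotype matching: every rule match (any evidence, any severity),
# every (rule, modifier) pairing with its combined AUC and escalated
# severity, and every gene-free drug-drug(-drug) rule. The eadgi column
# holds the phenotype-independent part of actionability (evidence-based,
# severity >= moderate, and -- for two-drug opportunities -- exceeding the
# gene-free pair severity); a row becomes a detection when the patient's
# phenotypes match its requirements.
detection_table <- function(meds, kb, gene_set) {
  area_of <- stats::setNames(kb$drugs$clinical_area, kb$drugs$drug)
  rules <- kb$rules
  keep <- rules$drug %in% meds & rules$gene %in% gene_set &
    (is.na(rules$second_gene) | rules$second_gene %in% gene_set)
  rules <- rules[keep, , drop = FALSE]

  # column accumulators (tables are tiny; data.frame built once at the end)
  kind <- drug <- drug2 <- drug3 <- gene <- phenotype <- gene2 <-
    phenotype2 <- severity <- combined <- character()
  eadgi <- logical()
  add <- function(.kind, .drug, .drug2, .drug3, .gene, .phenotype, .gene2,
                  .phenotype2, .severity, .combined, .eadgi) {
    kind <<- c(kind, .kind); drug <<- c(drug, .drug)
    drug2 <<- c(drug2, .drug2); drug3 <<- c(drug3, .drug3)
    gene <<- c(gene, .gene); phenotype <<- c(phenotype, .phenotype)
    gene2 <<- c(gene2, .gene2); phenotype2 <<- c(phenotype2, .phenotype2)
    severity <<- c(severity, .severity); combined <<- c(combined, .combined)
    eadgi <<- c(eadgi, .eadgi)
  }

  prodrug_of <- stats::setNames(kb$drugs$prodrug, kb$drugs$drug)
  for (i in seq_len(nrow(rules))) {
    r_drug <- rules$drug[i]; r_gene <- rules$gene[i]
    r_sev <- rules$severity[i]; r_auc <- rules$auc_change[i]
    r_g2 <- rules$second_gene[i]
    based <- is_evidence_based(rules$evidence[i])
    add(if (is.na(r_g2)) "DGI" else "DGGI",
        r_drug, NA_character_, NA_character_, r_gene, rules$phenotype[i],
        r_g2, rules$second_phenotype[i], r_sev, r_auc,
        based && is_actionable(r_sev))
    if (is.na(r_g2)) {
      msel <- which(kb$modifiers$gene == r_gene &
                      kb$modifiers$drug %in% meds &
                      kb$modifiers$drug != r_drug)
      for (j in msel) {
        comp <- modifier_auc_component(kb$modifiers$action[j],
                                       kb$modifiers$strength[j],
                                       prodrug_of[[r_drug]])
        comb <- combine_auc(r_auc, comp)
        sev <- interaction_severity(r_sev, r_auc, comb)
        add("DDGI", r_drug, kb$modifiers$drug[j], NA_character_, r_gene,
            rules$phenotype[i], NA_character_, NA_character_, sev, comb,
            based && is_actionable(sev) &&
              severity_rank(sev) > ddi_pair_rank(kb, r_drug, kb$modifiers$drug[j]))
      }
    }
  }

  d <- kb$ddi
  for (i in seq_len(nrow(d))) {
    dr <- c(d$drug1[i], d$drug2[i], d$drug3[i])
    dr <- dr[!is.na(dr)]
    if (!all(dr %in% meds)) next
    add(if (length(dr) == 3) "DDDI" else "DDI",
        dr[1], dr[2], if (length(dr) == 3) dr[3] else NA_character_,
        NA_character_, NA_character_, NA_character_, NA_character_,
        d$severity[i], "none", FALSE)
  }

  if (!length(kind)) return(empty_interactions())
  data.frame(kind = kind, drug = drug, drug2 = drug2, drug3 = drug3,
             gene = gene, phenotype = phenotype, gene2 = gene2,
             phenotype2 = phenotype2, severity = severity,
             combined_auc = combined, clinical_area = unname(area_of[drug]),
             eadgi = eadgi, stringsAsFactors = FALSE)
}

#' Detect interactions for a genotyped patient
#'
#' Matches the patient's medications and interpreted phenotypes against the
#' knowledge base and returns every interaction present: drug--gene (DGI) and
#' drug--gene--gene (DGGI) matches, drug--drug--gene (DDGI) pairings with
#' their phenoconversion-combined AUC category and escalated severity, and
#' gene-free drug--drug (DDI) / drug--drug--drug (DDDI) rules. Detection is
#' restricted to genes with a reported phenotype (mirroring the adjusted-PIP
#' restriction to tested genes). Output order is deterministic: severity
#' descending, then affected drug, then kind precedence.
#'
#' The `eadgi` column flags evidence-based actionable findings: a
#' gene-involving interaction of moderate or worse severity, backed by FDA
#' label or CPIC A/B evidence, that for a DDGI exceeds the severity of the
#' corresponding gene-free drug--drug rule.
#'
#' @param patient a [patient_record()].
#' @param kb a [pip_kb()] knowledge base.
#' @param strict if TRUE, unknown drug names raise an error.
#' @return data frame of detected interactions (class `pip_interactions`).
#' @export
#' @examples
#' demo <- demo_kb()
#' p <- patient_record("p1", c("clopidogrel", "tramadol"),
#'                     tested_genes = "CYP2C19",
#'                     phenotypes = c(CYP2C19 = "intermediate"))
#' detect_interactions(p, demo$kb)
detect_interactions <- function(patient, kb, strict = FALSE) {
  stopifnot(inherits(patient, "pip_patient"))
  meds <- check_known_drugs(patient$meds, kb, strict)
  genes <- names(patient$phenotypes)
  tab <- detection_table(meds, kb, gene_set = genes)
  if (nrow(tab)) {
    ph <- patient$phenotypes
    m1 <- is.na(tab$gene) | (ph[tab$gene] == tab$phenotype)
    m2 <- is.na(tab$gene2) | (ph[tab$gene2] == tab$phenotype2)
    tab <- tab[!is.na(m1) & m1 & !is.na(m2) & m2, , drop = FALSE]
  }
  tab <- tab[order(-severity_rank(tab$severity), tab$drug,
                   -KIND_PRECEDENCE[tab$kind]), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("pip_interactions", class(tab))
  tab
}

#' Does the patient have at least one actionable finding?
#'
#' TRUE when [detect_interactions()] finds at least one evidence-based
#' actionable gene-involving interaction (DGI, DDGI or DGGI of moderate or
#' worse severity). Gene-free DDIs/DDDIs never qualify, nor do
#' monitoring-only or non-evidence-based matches.
#'
#' @inheritParams detect_interactions
#' @return logical scalar.
#' @export
has_eadgi <- function(patient, kb, strict = FALSE) {
  any(detect_interactions(patient, kb, strict = strict)$eadgi)
}

#' Most severe interaction class
#'
#' Reduces a patient's detected interactions to the single most severe one,
#' for frequency analyses where each patient counts once. Ties at equal
#' severity break by kind precedence (`DGGI > DDGI > DGI > DDDI > DDI`:
#' gene-involving kinds first), then by lexical order of the affected drug.
#' An empty list yields `("none", "none")`.
#'
#' @param interactions data frame from [detect_interactions()].
#' @return list with elements `kind` and `severity`.
#' @export
highest_severity_class <- function(interactions) {
  if (is.null(interactions) || !nrow(interactions)) {
    return(list(kind = "none", severity = "none"))
  }
  o <- order(-severity_rank(interactions$severity),
             -KIND_PRECEDENCE[interactions$kind], interactions$drug)
  top <- interactions[o[1], ]
  list(kind = top$kind, severity = top$severity)
}

#' Tabulate actionable interactions by clinical area
#'
#' Counts interactions per clinical area in three columns -- moderate,
#' major-or-contraindicated, and all -- with percentages relative to each
#' column total (rounded half-up to one decimal). When the input carries an
#' `eadgi` column only flagged rows are tabulated.
#'
#' @param interactions data frame with columns `clinical_area` and `severity`
#'   (e.g. detections pooled over a cohort).
#' @return data frame with one row per clinical area plus counts and
#'   percentages; column sums of the counts equal the totals.
#' @export
tabulate_by_area <- function(interactions) {
  if (!is.null(interactions$eadgi)) {
    interactions <- interactions[interactions$eadgi, , drop = FALSE]
  }
  areas <- clinical_areas()
  area <- factor(interactions$clinical_area, levels = areas)
  mod <- interactions$severity == "moderate"
  mc <- severity_rank(interactions$severity) >= 3L
  cnt <- function(sel) as.integer(table(area[sel]))
  pct <- function(n) if (sum(n) == 0) rep(0, length(n)) else
    round_half_up(100 * n / sum(n), 1)
  moderate_n <- cnt(mod); major_contra_n <- cnt(mc)
  all_n <- cnt(rep(TRUE, length(area)))
  data.frame(clinical_area = areas,
             moderate_n = moderate_n, moderate_pct = pct(moderate_n),
             major_contra_n = major_contra_n,
             major_contra_pct = pct(major_contra_n),
             all_n = all_n, all_pct = pct(all_n),
             stringsAsFactors = FALSE)
}

#' Rank medications by actionable-interaction count
#'
#' Summarises pooled cohort detections per affected medication: interaction
#' count, proportion of all interactions in the input, the medication-level
#' PIP score (single-drug score against the full panel), the number needed
#' to test one interaction (`1 / PIP`), and an optional prescribing-frequency
#' rank supplied by the caller.
#'
#' @param interactions pooled detections (rows with an `eadgi` column are
#'   filtered to flagged ones).
#' @param kb,prev knowledge base and prevalence used for the per-medication
#'   PIP scores.
#' @param ranking optional named integer vector, drug -> prescribing rank.
#' @param top_n number of rows to return (by descending count).
#' @return data frame: `drug`, `clinical_area`, `n`, `proportion_pct`,
#'   `pip_pct`, `nnt`, `rank`.
#' @export
top_medications <- function(interactions, kb, prev, ranking = NULL,
                            top_n = 5) {
  if (!is.null(interactions$eadgi)) {
    interactions <- interactions[interactions$eadgi, , drop = FALSE]
  }
  if (!nrow(interactions)) {
    return(data.frame(drug = character(), clinical_area = character(),
                      n = integer(), proportion_pct = numeric(),
                      pip_pct = numeric(), nnt = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- sort(table(interactions$drug), decreasing = TRUE)
  total <- sum(counts)
  counts <- counts[seq_len(min(top_n, length(counts)))]
  drugs <- names(counts)
  pip <- vapply(drugs, function(d) compute_pip(d, kb, prev)$pip, numeric(1))
  area_of <- stats::setNames(kb$drugs$clinical_area, kb$drugs$drug)
  data.frame(drug = drugs,
             clinical_area = unname(area_of[drugs]),
             n = as.integer(counts),
             proportion_pct = round_half_up(100 * as.integer(counts) / total, 1),
             pip_pct = round_half_up(100 * pip, 0),
             nnt = ifelse(pip > 0, round_half_up(1 / pip, 1), NA_real_),
             rank = if (is.null(ranking)) NA_integer_ else
               as.integer(ranking[drugs]),
             stringsAsFactors = FALSE, row.names = NULL)
}
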