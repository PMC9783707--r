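# Synthetic cohort simulator.
#
# Emulates the statistical structure the validation assumes: a mix of 3/5/
# 14/25-gene panel orders, an over-dispersed per-patient medication count
# (mean 9.4, range 1-62, supplements included), a two-stage prescription
# model (clinical area, then drug within area) over the knowledge-base
# drugs plus inert filler medications, and phenotypes drawn independently
# per tested gene from the prevalence table.

FILLER_MEDS <- c("multivitamin", "vitamin-d", "vitamin-b12", "vitamin-c",
                 "fish-oil", "calcium", "magnesium", "melatonin", "zinc",
                 "iron", "folic-acid", "biotin", "probiotic", "coq10",
                 sprintf("supplement-%02d", 1:56))

default_panel_mix <- function() {
  # exclusive panel proportions derived from the nested panel counts
  # 36,511 / 28,613 / 3,192 / 2,068
  n <- c(36511, 28613, 3192, 2068)
  stats::setNames(c(n[1] - n[2], n[2] - n[3], n[3] - n[4], n[4]) / n[1],
                  c("3", "5", "14", "25"))
}

default_area_weights <- function() {
  # all-actionable-interaction clinical-area proportions
  c("behavioral health" = 0.191, "cardiology" = 0.419,
    "pain management" = 0.094, "hematology and oncology" = 0.004,
    "infectious disease" = 0.001, "gastroenterology" = 0.269,
    "urology" = 0.011, "transplant" = 0.001,
    "reproductive and sexual health" = 0.002, "neurology" = 0.004,
    "miscellaneous" = 0.004)
}

#' Cohort simulation configuration
#'
#' Defaults encode the reference cohort structure: panel mix from the nested
#' panel counts, medication count distributed as 1 plus a negative binomial
#' (size 2, mean 8.4) truncated to `[1, 62]` (giving mean 9.4), a 17%
#' chance per medication slot of drawing a pharmacogenomically active drug
#' (so roughly 83% of patients take at least one), and clinical-area weights
#' proportional to the observed actionable-interaction distribution.
#'
#' @param n_patients number of patients to simulate.
#' @param panel_mix named probability vector over panel sizes
#'   `c("3","5","14","25")`; must sum to 1.
#' @param med_mean target mean medications per patient (supplements
#'   included).
#' @param med_size negative-binomial size (dispersion) parameter.
#' @param med_range inclusive truncation bounds of the medication count.
#' @param prob_pgx probability that a medication slot holds a drug from the
#'   knowledge base rather than an inert filler.
#' @param area_weights named sampling weights over clinical areas for
#'   knowledge-base drugs; areas absent from the KB are dropped and weights
#'   renormalised.
#' @param seed integer seed fixing the whole cohort.
#' @return an object of class `pip_cohort_config`.
#' @export
cohort_config <- function(n_patients, panel_mix = default_panel_mix(),
                          med_mean = 9.4, med_size = 2,
                          med_range = c(1, 62), prob_pgx = 0.17,
                          area_weights = default_area_weights(),
                          seed = 1L) {
  stopifnot(n_patients >= 0, med_range[1] >= 1, med_range[2] >= med_range[1])
  if (abs(sum(panel_mix) - 1) > 1e-9) stopf("panel_mix must sum to 1")
  if (!all(names(panel_mix) %in% c("3", "5", "14", "25"))) {
    stopf("panel_mix names must be among 3, 5, 14, 25")
  }
  if (med_mean - 1 <= 0) stopf("med_mean must exceed 1")
  structure(list(n_patients = as.integer(n_patients), panel_mix = panel_mix,
                 med_mean = med_mean, med_size = med_size,
                 med_range = as.integer(med_range), prob_pgx = prob_pgx,
                 area_weights = area_weights, seed = as.integer(seed)),
            class = "pip_cohort_config")
}

#' Sample phenotypes for a gene set
#'
#' Independent categorical draws, one per gene, from the prevalence table.
#' Uses R's global random number generator; fix `set.seed()` for
#' reproducibility.
#'
#' @param genes gene symbols to draw for.
#' @param prev a `pip_prevalence` table covering `genes`.
#' @return named character vector, gene -> phenotype.
#' @export
#' @examples
#' demo <- demo_kb()
#' set.seed(1)
#' sample_phenotypes(c("CYP2D6", "CYP2C19"), demo$prevalence)
sample_phenotypes <- function(genes, prev) {
  missing <- setdiff(genes, names(prev))
  if (length(missing)) stopf("no prevalence for gene(s): %s", paste(missing, collapse = ", "))
  vapply(genes, function(g) {
    v <- prev[[g]]
    sample(names(v), 1L, prob = v)
  }, character(1))
}

#' Simulate a synthetic cohort
#'
#' Generates `config$n_patients` patient rows: a panel size drawn from the
#' panel mix, a medication list drawn from the two-stage prescription model
#' (drug counts per patient from the truncated negative binomial; each slot
#' is a knowledge-base drug with probability `prob_pgx`, area-weighted, else
#' an inert filler), phenotypes for every panelled gene drawn from the
#' prevalence table, and age/sex annotations. The whole cohort is a
#' deterministic function of `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param kb a [pip_kb()] knowledge base.
#' @param prev a `pip_prevalence` covering the panelled genes.
#' @return a data frame of class `pip_cohort`: columns `patient_id`, `age`,
#'   `sex`, `panel_size`, `tested_genes` (`;`-separated), `meds`
#'   (`;`-separated), `n_meds`, and one `pheno_<gene>` column per gene
#'   (NA when untested). The config is attached as attribute `config`.
#' @export
simulate_cohort <- function(config, kb, prev) {
  stopifnot(inherits(config, "pip_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  all_genes <- sort(unique(unlist(lapply(c(3, 5, 14, 25), pgx_panel))))

  empty <- data.frame(patient_id = character(), age = integer(),
                      sex = character(), panel_size = integer(),
                      tested_genes = character(), meds = character(),
                      n_meds = integer(), stringsAsFactors = FALSE)
  if (n == 0L) {
    for (g in all_genes) empty[[paste0("pheno_", g)]] <- character()
    class(empty) <- c("pip_cohort", class(empty))
    attr(empty, "config") <- config
    return(empty)
  }

  # panels (nested: larger panels contain the smaller ones)
  panel_size <- as.integer(sample(names(config$panel_mix), n, replace = TRUE,
                                  prob = config$panel_mix))

  # medication counts: shifted negative binomial, resampled into range
  lo <- config$med_range[1]; hi <- config$med_range[2]
  n_meds <- 1L + stats::rnbinom(n, size = config$med_size,
                                mu = config$med_mean - 1)
  while (any(bad <- n_meds < lo | n_meds > hi)) {
    n_meds[bad] <- 1L + stats::rnbinom(sum(bad), size = config$med_size,
                                       mu = config$med_mean - 1)
  }

  # drug pools per clinical area (drugs carrying rules or modifier effects)
  active <- union(kb$rules$drug, kb$modifiers$drug)
  pool <- split(active, kb$drugs$clinical_area[match(active, kb$drugs$drug)])
  w <- stats::setNames(as.numeric(config$area_weights[names(pool)]), names(pool))
  w[is.na(w)] <- min(config$area_weights[config$area_weights > 0])
  w <- w / sum(w)
  # per-drug sampling weight: area weight split evenly within the area
  drug_pool <- unlist(pool, use.names = FALSE)
  drug_w <- unlist(lapply(names(pool),
                          function(a) rep(w[[a]] / length(pool[[a]]),
                                          length(pool[[a]]))))

  meds <- character(n)
  for (i in seq_len(n)) {
    k <- stats::rbinom(1L, n_meds[i], config$prob_pgx)
    k <- min(k, length(drug_pool))
    pgx <- if (k > 0) sample(drug_pool, k, prob = drug_w) else character()
    fill <- sample(FILLER_MEDS, n_meds[i] - k)
    meds[i] <- paste(c(pgx, fill), collapse = ";")
  }

  age <- pmin(pmax(round(stats::rnorm(n, mean = 61, sd = 18)), 0L), 110L)
  sex <- sample(c("female", "male", "unknown"), n, replace = TRUE,
                prob = c(0.563, 0.393, 0.044))

  cohort <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)), age = as.integer(age),
    sex = sex, panel_size = panel_size,
    tested_genes = vapply(panel_size, function(s) paste(pgx_panel(s), collapse = ";"), ""),
    meds = meds, n_meds = as.integer(n_meds), stringsAsFactors = FALSE)

  for (g in all_genes) {
    col <- rep(NA_character_, n)
    tested <- panel_size >= min(c(3, 5, 14, 25)[vapply(c(3, 5, 14, 25),
                    function(s) g %in% pgx_panel(s), logical(1))])
    if (any(tested)) {
      v <- prev[[g]]
      col[tested] <- sample(names(v), sum(tested), replace = TRUE, prob = v)
    }
    cohort[[paste0("pheno_", g)]] <- col
  }

  class(cohort) <- c("pip_cohort", class(cohort))
  attr(cohort, "config") <- config
  cohort
}

#' Extract one cohort row as a patient record
#'
#' @param cohort a `pip_cohort` data frame.
#' @param i row index.
#' @return a [patient_record()].
#' @export
cohort_patient <- function(cohort, i) {
  genes <- strsplit(cohort$tested_genes[i], ";", fixed = TRUE)[[1]]
  ph <- vapply(genes, function(g) cohort[[paste0("pheno_", g)]][i], "")
  ph <- ph[!is.na(ph)]
  patient_record(cohort$patient_id[i],
                 strsplit(cohort$meds[i], ";", fixed = TRUE)[[1]],
                 tested_genes = genes, phenotypes = ph,
                 age = cohort$age[i], sex = cohort$sex[i])
}

#' Generate a small randomized knowledge base
#'
#' A fuzzing utility for property-based testing: a few ladder-phenotype
#' genes with strictly positive random prevalences, drugs with random
#' clinical areas and prodrug flags, random interaction rules (including
#' monitor-severity, non-evidence-based, and two-gene rules), random
#' modifier effects and random gene-free drug--drug rules. Uses the global
#' RNG.
#'
#' @param n_genes,n_drugs table sizes.
#' @param p_dggi probability that a drug gets an intrinsic two-gene rule.
#' @return list with elements `kb` and `prevalence`.
#' @export
random_kb <- function(n_genes = 3, n_drugs = 4, p_dggi = 0.3) {
  ladder <- metabolizer_ladder()
  gsym <- sprintf("G%02d", seq_len(n_genes))
  genes <- data.frame(gene = gsym, reference = "normal", stringsAsFactors = FALSE)
  genes$phenotypes <- rep(list(ladder), n_genes)
  prev <- stats::setNames(lapply(gsym, function(g) {
    v <- stats::runif(5, 0.05, 1)
    stats::setNames(v / sum(v), ladder)
  }), gsym)

  dn <- sprintf("drug-%s", letters[seq_len(n_drugs)])
  drugs <- data.frame(drug = dn,
                      clinical_area = sample(clinical_areas(), n_drugs, replace = TRUE),
                      prodrug = stats::runif(n_drugs) < 0.15,
                      stringsAsFactors = FALSE)

  variant <- setdiff(ladder, "normal")
  sev <- c("monitor", "moderate", "major", "contraindicated")
  auc <- setdiff(auc_categories(), "none")
  ev <- c("FDA_label", "CPIC_A", "CPIC_B", "other")
  rows <- list()
  for (d in dn) {
    for (k in seq_len(sample(0:3, 1))) {
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, gene = sample(gsym, 1), phenotype = sample(variant, 1),
        second_gene = NA_character_, second_phenotype = NA_character_,
        severity = sample(sev, 1), auc_change = sample(auc, 1),
        evidence = sample(ev, 1, prob = c(0.3, 0.25, 0.25, 0.2)),
        stringsAsFactors = FALSE)
    }
    if (n_genes >= 2 && stats::runif(1) < p_dggi) {
      gg <- sample(gsym, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, gene = gg[1], phenotype = sample(variant, 1),
        second_gene = gg[2], second_phenotype = sample(variant, 1),
        severity = sample(sev, 1), auc_change = sample(auc, 1),
        evidence = sample(ev, 1), stringsAsFactors = FALSE)
    }
  }
  rules <- if (length(rows)) do.call(rbind, rows) else empty_rules()
  key <- with(rules, paste(drug, gene, phenotype, second_gene, second_phenotype))
  rules <- rules[!duplicated(key), , drop = FALSE]

  mods <- list()
  for (d in dn) {
    if (stats::runif(1) < 0.5) {
      mods[[length(mods) + 1L]] <- data.frame(
        drug = d, gene = sample(gsym, 1),
        action = sample(c("inhibitor", "inducer"), 1),
        strength = sample(1:4, 1), stringsAsFactors = FALSE)
    }
  }
  modifiers <- if (length(mods)) do.call(rbind, mods) else NULL
  if (!is.null(modifiers)) {
    modifiers <- modifiers[!duplicated(paste(modifiers$drug, modifiers$gene)), ,
                           drop = FALSE]
  }

  ddi <- NULL
  if (n_drugs >= 2 && stats::runif(1) < 0.5) {
    pair <- sample(dn, 2)
    ddi <- data.frame(drug1 = pair[1], drug2 = pair[2], drug3 = NA_character_,
                      severity = sample(c("monitor", "moderate", "major"), 1),
                      stringsAsFactors = FALSE)
  }

  list(kb = pip_kb(genes, drugs, rules, modifiers, ddi, prev), prevalence = as_prevalence(prev))
}
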