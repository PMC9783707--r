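# Cohort-level scoring.
#
# Patients sharing a knowledge-base medication subset and panel get identical
# scores and identical detection tables, so the cohort is scored by unique
# (medication subset, panel) key: compute_pip once per key, then vectorised
# phenotype matching over the key's patients. An optional cache environment
# carries the per-key work across repeated calls (e.g. replicate studies).

#' Score a simulated or imported cohort
#'
#' Adds per-patient scoring columns to a cohort: `pip` (full-panel score),
#' `adjusted_pip` (restricted to the patient's tested genes), and `eadgi`
#' (whether the patient's sampled phenotypes actually trigger at least one
#' evidence-based actionable interaction, as [has_eadgi()] would report).
#' With `classify = TRUE` also adds `top_kind` / `top_severity`, the
#' patient's single most severe detected interaction class (including
#' gene-free and monitoring-only interactions), as used for threshold-bin
#' frequency analyses.
#'
#' @param cohort a `pip_cohort` data frame (see [simulate_cohort()]).
#' @param kb a [pip_kb()] knowledge base.
#' @param prev a `pip_prevalence` table.
#' @param classify also compute the highest-severity interaction class.
#' @param cache optional environment reused across calls to memoise per-key
#'   computations.
#' @return the cohort with scoring columns appended.
#' @export
score_cohort <- function(cohort, kb, prev, classify = FALSE, cache = NULL) {
  n <- nrow(cohort)
  cohort$pip <- numeric(n)
  cohort$adjusted_pip <- numeric(n)
  cohort$eadgi <- logical(n)
  if (classify) {
    cohort$top_kind <- rep("none", n)
    cohort$top_severity <- rep("none", n)
  }
  if (!n) return(cohort)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  kbdrugs <- kb_drugs(kb)
  all_genes <- kb_genes(kb)
  med_list <- strsplit(cohort$meds, ";", fixed = TRUE)
  medkey <- vapply(med_list, function(m) {
    paste(sort(intersect(unique(m), kbdrugs)), collapse = "|")
  }, "")
  keyvec <- paste(medkey, cohort$panel_size, sep = "@")

  kind_prec <- KIND_PRECEDENCE
  groups <- split(seq_len(n), keyvec)
  for (key in names(groups)) {
    idx <- groups[[key]]
    first <- idx[1]

    ent <- cache[[key]]
    if (is.null(ent)) {
      mk <- medkey[first]
      # heavy per-medication-subset work is shared across panels
      base <- cache[[paste0("meds:", mk)]]
      if (is.null(base)) {
        meds <- strsplit(mk, "|", fixed = TRUE)[[1]]
        if (length(meds)) {
          opps <- interaction_opportunities(meds, kb)
          base <- list(pip = pip_from_opportunities(opps, prev)$p,
                       opps = opps,
                       tab = detection_table(meds, kb, gene_set = all_genes))
        } else {
          base <- list(pip = 0, opps = NULL, tab = empty_interactions())
        }
        cache[[paste0("meds:", mk)]] <- base
      }
      tested <- strsplit(cohort$tested_genes[first], ";", fixed = TRUE)[[1]]
      if (is.null(base$opps) || !nrow(base$opps)) {
        adjusted <- 0
        tab <- base$tab
      } else {
        sel <- base$opps$gene %in% tested &
          (is.na(base$opps$second_gene) | base$opps$second_gene %in% tested)
        adjusted <- pip_from_opportunities(base$opps[sel, , drop = FALSE], prev)$p
        tsel <- is.na(base$tab$gene) |
          (base$tab$gene %in% tested &
             (is.na(base$tab$gene2) | base$tab$gene2 %in% tested))
        tab <- base$tab[tsel, , drop = FALSE]
      }
      ent <- list(pip = base$pip, adjusted_pip = adjusted, tab = tab)
      cache[[key]] <- ent
    }
    cohort$pip[idx] <- ent$pip
    cohort$adjusted_pip[idx] <- ent$adjusted_pip

    tab <- ent$tab
    if (!nrow(tab)) next
    k <- length(idx)
    eadgi <- rep(FALSE, k)
    best <- rep(-1L, k)
    for (r in seq_len(nrow(tab))) {
      if (is.na(tab$gene[r])) {
        hit <- rep(TRUE, k)                      # gene-free DDI/DDDI
      } else {
        ph <- cohort[[paste0("pheno_", tab$gene[r])]][idx]
        hit <- !is.na(ph) & ph == tab$phenotype[r]
        if (!is.na(tab$gene2[r])) {
          ph2 <- cohort[[paste0("pheno_", tab$gene2[r])]][idx]
          hit <- hit & !is.na(ph2) & ph2 == tab$phenotype2[r]
        }
      }
      if (!any(hit)) next
      if (tab$eadgi[r]) eadgi <- eadgi | hit
      if (classify) {
        score <- severity_rank(tab$severity[r]) * 10L + kind_prec[[tab$kind[r]]]
        best[hit] <- pmax(best[hit], score)
      }
    }
    cohort$eadgi[idx] <- eadgi
    if (classify) {
      pos <- best >= 0L
      cohort$top_severity[idx[pos]] <- severity_levels()[best[pos] %/% 10L + 1L]
      cohort$top_kind[idx[pos]] <-
        names(kind_prec)[match(best[pos] %% 10L, kind_prec)]
    }
  }
  cohort
}

#' Pool per-patient detections over a cohort
#'
#' Runs [detect_interactions()] for every patient and stacks the results
#' with a `patient_id` column, for clinical-area and top-medication
#' tabulations.
#'
#' @inheritParams score_cohort
#' @return data frame of detections across the cohort.
#' @export
detect_cohort <- function(cohort, kb) {
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    det <- detect_interactions(cohort_patient(cohort, i), kb)
    if (nrow(det)) {
      det$patient_id <- cohort$patient_id[i]
      out[[i]] <- det
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    e <- empty_interactions()
    e$patient_id <- character()
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
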