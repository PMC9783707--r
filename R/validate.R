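# Validation statistics and report layer: number needed to test,
# one-proportion z-test, panel subgroup summaries, score-threshold bins,
# and delimited-text report files.

#' Number needed to test
#'
#' How many patients must be tested to find one with an actionable
#' interaction: `n / count`. Returned unrounded; the report layer rounds
#' half-up to one decimal.
#'
#' @param n number of patients tested.
#' @param eadgi_count number of patients with at least one actionable
#'   finding; must be at least 1 (a zero count leaves the NNT undefined and
#'   raises an error of class `pipscore_undefined_nnt`).
#' @return numeric scalar.
#' @export
#' @examples
#' nnt(36511, 8174)  # 4.467; 4.5 after report rounding
nnt <- function(n, eadgi_count) {
  if (eadgi_count < 1) {
    stop(structure(class = c("pipscore_undefined_nnt", "error", "condition"),
                   list(message = "NNT undefined: no patients with an actionable finding",
                        call = sys.call())))
  }
  n / eadgi_count
}

#' One-proportion z-test
#'
#' Tests an observed proportion `count / n` against a fixed population
#' proportion `p0` with the normal approximation:
#' `z = (count/n - p0) / sqrt(p0 (1 - p0) / n)`, two-sided p-value from the
#' standard normal tail. No continuity correction is applied.
#'
#' @param count number of successes (0..n).
#' @param n number of trials.
#' @param p0 null proportion, strictly between 0 and 1.
#' @return list with elements `z` and `p_value`.
#' @export
#' @examples
#' one_prop_ztest(60, 100, 0.5)  # z = 2, p ~ 0.0455
one_prop_ztest <- function(count, n, p0) {
  if (p0 <= 0 || p0 >= 1) stopf("p0 must lie strictly between 0 and 1")
  if (count < 0 || count > n) stopf("count must lie in 0..n")
  z <- (count / n - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Panel subgroup summary
#'
#' Restricts a scored cohort to patients whose tested genes cover at least
#' the given minimum panel and summarises the headline comparison: mean full
#' and adjusted PIP score, observed actionable-finding rate and count, the
#' number needed to test, and the one-proportion z-test of the observed rate
#' against the mean adjusted PIP as the null proportion.
#'
#' @param scored a cohort from [score_cohort()].
#' @param min_genes minimum panel: one of 3, 5, 14, 25.
#' @return list of class `pip_panel_summary`: `min_genes`, `n`, `mean_pip`,
#'   `mean_adjusted_pip`, `eadgi_count`, `eadgi_rate`, `nnt` (NA when the
#'   count is zero), `z`, `p_value`.
#' @export
panel_summary <- function(scored, min_genes) {
  panel <- pgx_panel(min_genes)
  covered <- vapply(strsplit(scored$tested_genes, ";", fixed = TRUE),
                    function(g) all(panel %in% g), logical(1))
  sub <- scored[covered, , drop = FALSE]
  if (!nrow(sub)) stopf("no patients tested with at least the %d-gene panel", min_genes)
  count <- sum(sub$eadgi)
  p0 <- mean(sub$adjusted_pip)
  zt <- if (p0 > 0 && p0 < 1) one_prop_ztest(count, nrow(sub), p0) else
    list(z = NA_real_, p_value = NA_real_)
  structure(list(min_genes = min_genes, n = nrow(sub),
                 mean_pip = mean(sub$pip), mean_adjusted_pip = p0,
                 eadgi_count = count, eadgi_rate = count / nrow(sub),
                 nnt = if (count > 0) nnt(nrow(sub), count) else NA_real_,
                 z = zt$z, p_value = zt$p_value),
            class = "pip_panel_summary")
}

#' @export
print.pip_panel_summary <- function(x, ...) {
  cat(sprintf(">=%d genes: n=%d, mean PIP %.1f%%, mean adjusted PIP %.1f%%, rate %.1f%% (%d), NNT %s, p=%.4f\n",
              x$min_genes, x$n, 100 * x$mean_pip, 100 * x$mean_adjusted_pip,
              100 * x$eadgi_rate, x$eadgi_count,
              ifelse(is.na(x$nnt), "-", sprintf("%.1f", round_half_up(x$nnt, 1))),
              x$p_value))
  invisible(x)
}

#' Score-threshold bins
#'
#' Stratifies a classified cohort into adjusted-PIP bands -- low `[0, 0.25)`,
#' moderate `[0.25, 0.50]`, high `(0.50, 1]` (boundary convention: 0.25 and
#' 0.50 both fall in the moderate band) -- and tabulates the per-band
#' frequency of each highest-severity interaction class plus the fraction of
#' patients with any interaction and with an actionable finding. In a
#' calibrated cohort the any-interaction fraction is non-decreasing across
#' bands; this is reported, not enforced, so a sampling fluctuation cannot
#' abort a report run.
#'
#' @param scored a cohort from [score_cohort()] with `classify = TRUE`.
#' @return data frame with one row per band: `bin`, `n`, a `pct_<kind>`
#'   column per interaction class (percent of the band's patients whose
#'   single most severe interaction is of that kind), `frac_any_interaction`
#'   and `frac_eadgi`.
#' @export
threshold_bins <- function(scored) {
  if (is.null(scored$top_kind)) {
    stopf("threshold_bins needs a cohort scored with classify = TRUE")
  }
  band <- ifelse(scored$adjusted_pip < 0.25, "<25%",
                 ifelse(scored$adjusted_pip <= 0.50, "25-50%", ">50%"))
  band <- factor(band, levels = c("<25%", "25-50%", ">50%"))
  kinds <- c("none", "DDI", "DDDI", "DGI", "DDGI", "DGGI")
  out <- data.frame(bin = levels(band), n = as.integer(table(band)),
                    stringsAsFactors = FALSE)
  for (k in kinds) {
    out[[paste0("pct_", k)]] <- vapply(levels(band), function(b) {
      sel <- band == b
      if (!any(sel)) return(0)
      round_half_up(100 * mean(scored$top_kind[sel] == k), 1)
    }, numeric(1))
  }
  out$frac_any_interaction <- vapply(levels(band), function(b) {
    sel <- band == b
    if (!any(sel)) return(0)
    mean(scored$top_kind[sel] != "none")
  }, numeric(1))
  out$frac_eadgi <- vapply(levels(band), function(b) {
    sel <- band == b
    if (!any(sel)) return(0)
    mean(scored$eadgi[sel])
  }, numeric(1))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "-")
}

#' Write a full study report
#'
#' Scores and detects over a cohort and writes the study tables as
#' tab-separated text: `panel_summary.tsv` (one row per minimum panel with
#' means, rate, NNT and z-test), `by_area.tsv` (actionable interactions per
#' clinical area and severity column), `top_medications.tsv` and
#' `top_major.tsv` (medication rankings over all and over
#' major/contraindicated findings), `threshold_bins.tsv`, and
#' `manifest.json` recording the simulation seed, configuration and an MD5
#' checksum of the canonical knowledge base. Percentages and NNT are rounded
#' half-up to one decimal at this layer only. Output is deterministic:
#' re-running on the same inputs reproduces every file byte for byte.
#'
#' @param cohort a `pip_cohort`.
#' @param kb,prev knowledge base and prevalence.
#' @param out_dir output directory (created if needed).
#' @param ranking optional drug -> prescribing-rank mapping passed to
#'   [top_medications()].
#' @return invisibly, the paths written.
#' @export
report <- function(cohort, kb, prev, out_dir, ranking = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scored <- score_cohort(cohort, kb, prev, classify = TRUE)

  rows <- list()
  for (s in c(3, 5, 14, 25)) {
    ps <- tryCatch(panel_summary(scored, s), error = function(e) NULL)
    if (is.null(ps)) next
    rows[[length(rows) + 1L]] <- data.frame(
      min_genes = ps$min_genes, n = ps$n,
      mean_pip_pct = round_half_up(100 * ps$mean_pip, 1),
      mean_adjusted_pip_pct = round_half_up(100 * ps$mean_adjusted_pip, 1),
      eadgi_rate_pct = round_half_up(100 * ps$eadgi_rate, 1),
      eadgi_count = ps$eadgi_count,
      nnt = if (is.na(ps$nnt)) NA_real_ else round_half_up(ps$nnt, 1),
      p_value = round(ps$p_value, 4), stringsAsFactors = FALSE)
  }
  files <- character()
  p <- file.path(out_dir, "panel_summary.tsv")
  write_tsv(do.call(rbind, rows), p); files <- c(files, p)

  det <- detect_cohort(cohort, kb)
  ead <- det[det$eadgi, , drop = FALSE]
  p <- file.path(out_dir, "by_area.tsv")
  write_tsv(tabulate_by_area(ead), p); files <- c(files, p)
  p <- file.path(out_dir, "top_medications.tsv")
  write_tsv(top_medications(ead, kb, prev, ranking = ranking), p)
  files <- c(files, p)
  major <- ead[severity_rank(ead$severity) >= 3L, , drop = FALSE]
  p <- file.path(out_dir, "top_major.tsv")
  write_tsv(top_medications(major, kb, prev, ranking = ranking), p)
  files <- c(files, p)
  p <- file.path(out_dir, "threshold_bins.tsv")
  write_tsv(threshold_bins(scored), p); files <- c(files, p)

  kb_file <- tempfile(fileext = ".json")
  save_kb(kb, kb_file)
  cfg <- attr(cohort, "config")
  manifest <- list(
    package = "pipscore",
    n_patients = nrow(cohort),
    seed = if (!is.null(cfg)) cfg$seed else NA,
    config = if (!is.null(cfg)) cfg[setdiff(names(cfg), "seed")] else NULL,
    kb_md5 = unname(tools::md5sum(kb_file)))
  unlink(kb_file)
  p <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = 2,
                              digits = NA), p, useBytes = TRUE)
  files <- c(files, p)
  invisible(files)
}
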