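# Demo knowledge base.
#
# A small open knowledge base covering the 25 commonly panelled
# pharmacogenes and eighteen high-impact medications, calibrated so that the
# single-medication PIP scores equal the published per-medication values
# (metoprolol 48%, amitriptyline 50%, tramadol/codeine 9%, clopidogrel /
# omeprazole / pantoprazole 29%, (es)citalopram 32%) and so that the ten most
# common phenoconversion pairs reproduce their published cumulative AUC
# categories. Actionable-phenotype sets and the CYP2D6/CYP2C19 prevalences
# are a documented fixture convention (the published sources give no
# per-phenotype breakdown); co-substrate overlap on a gene is the maximal
# overlap of the smaller set. Prevalences for the remaining genes are
# plausible placeholder marginals used only by the cohort simulator.

LADDER_GENES <- c("CYP1A2", "CYP2B6", "CYP2C19", "CYP2C9", "CYP2D6",
                  "CYP3A4", "CYP3A5", "CYP4F2")

demo_gene_table <- function() {
  ladder <- metabolizer_ladder()
  carrier <- c("non-carrier", "carrier")
  fn3 <- c("poor", "intermediate", "normal")
  g <- list(
    # gene, vocabulary, reference phenotype, prevalence
    list("CYP2D6",  ladder, "normal",
         c(poor = 0.06, intermediate = 0.39, normal = 0.50, rapid = 0.02, ultrarapid = 0.03)),
    list("CYP2C19", ladder, "normal",
         c(poor = 0.03, intermediate = 0.26, normal = 0.64, rapid = 0.03, ultrarapid = 0.04)),
    list("CYP2C9",  ladder, "normal",
         c(poor = 0.02, intermediate = 0.33, normal = 0.65, rapid = 0, ultrarapid = 0)),
    list("CYP3A4",  ladder, "normal",
         c(poor = 0.01, intermediate = 0.25, normal = 0.74, rapid = 0, ultrarapid = 0)),
    list("CYP3A5",  ladder, "normal",
         c(poor = 0.80, intermediate = 0.12, normal = 0.08, rapid = 0, ultrarapid = 0)),
    list("CYP2B6",  ladder, "normal",
         c(poor = 0.06, intermediate = 0.30, normal = 0.60, rapid = 0.03, ultrarapid = 0.01)),
    list("CYP1A2",  ladder, "normal",
         c(poor = 0.02, intermediate = 0.08, normal = 0.50, rapid = 0.35, ultrarapid = 0.05)),
    list("CYP4F2",  ladder, "normal",
         c(poor = 0.02, intermediate = 0.33, normal = 0.65, rapid = 0, ultrarapid = 0)),
    list("NAT2",    c("slow", "intermediate", "rapid"), "rapid",
         c(slow = 0.45, intermediate = 0.35, rapid = 0.20)),
    list("TPMT",    fn3, "normal", c(poor = 0.003, intermediate = 0.097, normal = 0.90)),
    list("DPYD",    fn3, "normal", c(poor = 0.002, intermediate = 0.048, normal = 0.95)),
    list("UGT1A1",  fn3, "normal", c(poor = 0.10, intermediate = 0.35, normal = 0.55)),
    list("SLCO1B1", c("poor_function", "decreased_function", "normal_function"),
         "normal_function",
         c(poor_function = 0.02, decreased_function = 0.25, normal_function = 0.73)),
    list("VKORC1",  carrier, "non-carrier", c(`non-carrier` = 0.42, carrier = 0.58)),
    list("HLA-B*57:01", carrier, "non-carrier", c(`non-carrier` = 0.94, carrier = 0.06)),
    list("IFNL3",   c("favorable", "unfavorable"), "favorable",
         c(favorable = 0.40, unfavorable = 0.60)),
    list("ADRA2A",  carrier, "non-carrier", c(`non-carrier` = 0.65, carrier = 0.35)),
    list("COMT",    carrier, "non-carrier", c(`non-carrier` = 0.40, carrier = 0.60)),
    list("F2",      carrier, "non-carrier", c(`non-carrier` = 0.97, carrier = 0.03)),
    list("F5",      carrier, "non-carrier", c(`non-carrier` = 0.95, carrier = 0.05)),
    list("GRIK4",   carrier, "non-carrier", c(`non-carrier` = 0.70, carrier = 0.30)),
    list("HTR2A",   carrier, "non-carrier", c(`non-carrier` = 0.60, carrier = 0.40)),
    list("HTR2C",   carrier, "non-carrier", c(`non-carrier` = 0.70, carrier = 0.30)),
    list("MTHFR",   carrier, "non-carrier", c(`non-carrier` = 0.55, carrier = 0.45)),
    list("OPRM1",   carrier, "non-carrier", c(`non-carrier` = 0.75, carrier = 0.25))
  )
  genes <- data.frame(gene = vapply(g, `[[`, "", 1),
                      reference = vapply(g, `[[`, "", 3),
                      stringsAsFactors = FALSE)
  genes$phenotypes <- lapply(g, `[[`, 2)
  prevalence <- stats::setNames(lapply(g, `[[`, 4), genes$gene)
  list(genes = genes, prevalence = prevalence)
}

#' Demo knowledge base and prevalence table
#'
#' A self-contained knowledge base whose single-medication PIP scores match
#' the published per-medication values for eight drugs (metoprolol 48%,
#' omeprazole 29%, escitalopram and citalopram 32%, clopidogrel 29%,
#' pantoprazole 29%, tramadol 9%, codeine 9%, amitriptyline 50%) and whose
#' modifier table reproduces the ten most common published phenoconversion
#' pairs with their cumulative AUC categories. Escitalopram and citalopram
#' are separate drug entries sharing one rule set. Phenotype prevalences for
#' CYP2D6/CYP2C19 are fixture calibration values; the remaining 23 genes
#' carry plausible marginals used only for cohort simulation.
#'
#' A canonical serialisation of this object ships as
#' `system.file("extdata", "demo_kb.json", package = "pipscore")`.
#'
#' @return list with elements `kb` (a [pip_kb()]) and `prevalence`
#'   (a `pip_prevalence`; also embedded in the KB as `kb$prevalence`).
#' @export
#' @examples
#' demo <- demo_kb()
#' compute_pip("metoprolol", demo$kb, demo$prevalence)$pip
demo_kb <- function() {
  gt <- demo_gene_table()

  drugs <- data.frame(
    drug = c("metoprolol", "clopidogrel", "dronedarone",
             "omeprazole", "pantoprazole", "esomeprazole",
             "escitalopram", "citalopram", "amitriptyline", "bupropion",
             "fluvoxamine",
             "tramadol", "codeine", "oxycodone", "morphine", "hydrocodone",
             "simvastatin", "warfarin"),
    clinical_area = c("cardiology", "cardiology", "cardiology",
                      "gastroenterology", "gastroenterology", "gastroenterology",
                      "behavioral health", "behavioral health",
                      "behavioral health", "behavioral health",
                      "behavioral health",
                      "pain management", "pain management", "pain management",
                      "pain management", "pain management",
                      "cardiology", "hematology and oncology"),
    prodrug = c(FALSE, TRUE, FALSE,
                FALSE, FALSE, FALSE,
                FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, TRUE, FALSE, FALSE, FALSE,
                FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  rule <- function(drug, gene, phenotype, severity, auc, evidence = "CPIC_A") {
    data.frame(drug = drug, gene = gene, phenotype = phenotype,
               second_gene = NA_character_, second_phenotype = NA_character_,
               severity = severity, auc_change = auc, evidence = evidence,
               stringsAsFactors = FALSE)
  }
  ssri_rules <- function(drug) rbind(
    rule(drug, "CYP2C19", "intermediate", "moderate", "+26-75%"),
    rule(drug, "CYP2C19", "poor",         "major",    "+76-200%"),
    rule(drug, "CYP2C19", "rapid",        "moderate", "-31-50%")
  )
  ppi_rules <- function(drug) rbind(
    rule(drug, "CYP2C19", "intermediate", "moderate", "+26-75%"),
    rule(drug, "CYP2C19", "poor",         "moderate", "+76-200%")
  )
  opioid_rules <- function(drug) rbind(
    rule(drug, "CYP2D6", "poor",       "major",           "-51-80%"),
    rule(drug, "CYP2D6", "ultrarapid", "contraindicated", "+76-200%", "FDA_label")
  )
  rules <- rbind(
    rule("metoprolol", "CYP2D6", "intermediate", "moderate", "+76-200%"),
    rule("metoprolol", "CYP2D6", "poor",         "moderate", ">200%"),
    rule("metoprolol", "CYP2D6", "ultrarapid",   "moderate", "-31-50%"),
    rule("amitriptyline", "CYP2D6", "intermediate", "moderate", "+26-75%"),
    rule("amitriptyline", "CYP2D6", "poor",         "major",    "+76-200%"),
    rule("amitriptyline", "CYP2D6", "rapid",        "moderate", "-31-50%"),
    rule("amitriptyline", "CYP2D6", "ultrarapid",   "major",    "-51-80%"),
    opioid_rules("tramadol"),
    opioid_rules("codeine"),
    rule("clopidogrel", "CYP2C19", "intermediate", "major", "-31-50%", "FDA_label"),
    rule("clopidogrel", "CYP2C19", "poor",         "major", "-51-80%", "FDA_label"),
    ssri_rules("escitalopram"),
    ssri_rules("citalopram"),
    ppi_rules("omeprazole"),
    ppi_rules("pantoprazole"),
    # transporter gene outside the 3/5-gene panels: statin myopathy risk
    rule("simvastatin", "SLCO1B1", "decreased_function", "moderate",
         "+26-75%"),
    rule("simvastatin", "SLCO1B1", "poor_function", "major", "+76-200%"),
    # anticoagulant sensitivity: metabolizer plus an intrinsic two-gene rule
    rule("warfarin", "CYP2C9", "intermediate", "moderate", "+26-75%"),
    data.frame(drug = "warfarin", gene = "CYP2C9", phenotype = "poor",
               second_gene = "VKORC1", second_phenotype = "carrier",
               severity = "contraindicated", auc_change = ">200%",
               evidence = "CPIC_A", stringsAsFactors = FALSE)
  )

  modifiers <- data.frame(
    drug = c("tramadol", "oxycodone", "morphine", "hydrocodone",
             "esomeprazole", "fluvoxamine", "bupropion", "dronedarone"),
    gene = c(rep("CYP2C19", 6), "CYP2D6", "CYP2D6"),
    action = "inhibitor",
    strength = 2L,
    stringsAsFactors = FALSE
  )

  ddi <- data.frame(
    drug1 = c("citalopram", "clopidogrel", "amitriptyline"),
    drug2 = c("omeprazole", "tramadol", "bupropion"),
    drug3 = c(NA, NA, "fluvoxamine"),
    severity = c("monitor", "monitor", "monitor"),
    stringsAsFactors = FALSE
  )

  kb <- pip_kb(gt$genes, drugs, rules, modifiers, ddi, gt$prevalence)
  list(kb = kb, prevalence = kb$prevalence)
}
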