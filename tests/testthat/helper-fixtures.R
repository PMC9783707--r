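# Shared fixtures built in code.

# Minimal two-gene knowledge base with known probability structure:
#   drug-x on G1: actionable on {poor (major), intermediate (moderate)}
#   drug-y on G1: actionable on {poor} (nested in drug-x's set)
#   drug-z on G2: actionable on {ultrarapid}
#   drug-m: pure modifier (inhibitor of G1, strength 2); no substrate rules
#   drug-w on G1: monitor-only rule (excluded from scoring unless escalated)
#   drug-o on G1: actionable severity but evidence "other" (never counts)
tiny_kb <- function() {
  ladder <- metabolizer_ladder()
  genes <- data.frame(gene = c("G1", "G2"), reference = "normal",
                      stringsAsFactors = FALSE)
  genes$phenotypes <- list(ladder, ladder)
  prev <- as_prevalence(list(
    G1 = c(poor = 0.10, intermediate = 0.20, normal = 0.55,
           rapid = 0.10, ultrarapid = 0.05),
    G2 = c(poor = 0.05, intermediate = 0.15, normal = 0.60,
           rapid = 0.12, ultrarapid = 0.08)))
  drugs <- data.frame(
    drug = c("drug-x", "drug-y", "drug-z", "drug-m", "drug-w", "drug-o"),
    clinical_area = c("cardiology", "cardiology", "behavioral health",
                      "gastroenterology", "neurology", "urology"),
    prodrug = FALSE, stringsAsFactors = FALSE)
  rules <- data.frame(
    drug = c("drug-x", "drug-x", "drug-y", "drug-z", "drug-w", "drug-o"),
    gene = c("G1", "G1", "G1", "G2", "G1", "G1"),
    phenotype = c("poor", "intermediate", "poor", "ultrarapid",
                  "intermediate", "poor"),
    severity = c("major", "moderate", "moderate", "moderate", "monitor",
                 "major"),
    auc_change = c("+76-200%", "+26-75%", "-31-50%", "-51-80%", "+0-25%",
                   "+26-75%"),
    evidence = c("CPIC_A", "CPIC_A", "FDA_label", "CPIC_B", "CPIC_A",
                 "other"),
    stringsAsFactors = FALSE)
  modifiers <- data.frame(drug = "drug-m", gene = "G1", action = "inhibitor",
                          strength = 2L, stringsAsFactors = FALSE)
  list(kb = pip_kb(genes, drugs, rules, modifiers), prev = prev)
}

# knowledge base with an intrinsic two-gene rule coupling G1 and G2
dggi_kb <- function() {
  ladder <- metabolizer_ladder()
  genes <- data.frame(gene = c("G1", "G2", "G3"), reference = "normal",
                      stringsAsFactors = FALSE)
  genes$phenotypes <- list(ladder, ladder, ladder)
  prev <- as_prevalence(list(
    G1 = c(poor = 0.2, intermediate = 0.2, normal = 0.4, rapid = 0.1,
           ultrarapid = 0.1),
    G2 = c(poor = 0.3, intermediate = 0.1, normal = 0.5, rapid = 0.05,
           ultrarapid = 0.05),
    G3 = c(poor = 0.25, intermediate = 0.25, normal = 0.5, rapid = 0,
           ultrarapid = 0)))
  drugs <- data.frame(drug = c("drug-a", "drug-b"),
                      clinical_area = "cardiology", prodrug = FALSE,
                      stringsAsFactors = FALSE)
  rules <- data.frame(
    drug = c("drug-a", "drug-a", "drug-b"),
    gene = c("G1", "G1", "G3"),
    phenotype = c("poor", "poor", "poor"),
    second_gene = c("G2", NA, NA),
    second_phenotype = c("poor", NA, NA),
    severity = c("major", "monitor", "moderate"),
    auc_change = c(">200%", "+0-25%", "-31-50%"),
    evidence = "CPIC_A", stringsAsFactors = FALSE)
  list(kb = pip_kb(genes, drugs, rules), prev = prev)
}

# the ten published phenoconversion rows: gene component, co-medication
# component, expected combined category, and the patient configuration that
# reproduces the row end to end against the demo knowledge base
phenoconversion_rows <- function() {
  data.frame(
    drug = c("clopidogrel", "citalopram", "clopidogrel", "amitriptyline",
             "clopidogrel", "metoprolol", "clopidogrel", "clopidogrel",
             "amitriptyline", "citalopram"),
    gene = c("CYP2C19", "CYP2C19", "CYP2C19", "CYP2D6", "CYP2C19", "CYP2D6",
             "CYP2C19", "CYP2C19", "CYP2D6", "CYP2C19"),
    phenotype = c("intermediate", "rapid", "intermediate", "intermediate",
                  "intermediate", "intermediate", "intermediate", "poor",
                  "poor", "rapid"),
    drug2 = c("tramadol", "esomeprazole", "oxycodone", "bupropion",
              "morphine", "dronedarone", "hydrocodone", "tramadol",
              "bupropion", "fluvoxamine"),
    gene_auc = c("-31-50%", "-31-50%", "-31-50%", "+26-75%", "-31-50%",
                 "+76-200%", "-31-50%", "-51-80%", "+76-200%", "-31-50%"),
    drug_auc = c("-31-50%", "+26-75%", "-31-50%", "+26-75%", "-31-50%",
                 "+26-75%", "-31-50%", "-31-50%", "+26-75%", "+26-75%"),
    combined = c("-51-80%", "-0-30%", "-51-80%", "+76-200%", "-51-80%",
                 ">200%", "-51-80%", "-81-100%", ">200%", "-0-30%"),
    stringsAsFactors = FALSE)
}

# independent half-up rounding used to check report output
round_half_up_for_tests <- function(x, d) floor(x * 10^d + 0.5) / 10^d

empty_rules_for_tests <- function() {
  data.frame(drug = character(), gene = character(), phenotype = character(),
             severity = character(), auc_change = character(),
             evidence = character(), stringsAsFactors = FALSE)
}

expect_no_diagnostics <- function(kb) {
  expect_identical(validate_kb(kb), character(0))
}
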