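# Detector: matching, actionability flag, ordering, tabulations.

test_that("published phenoconversion pairs are detected with their combined AUC", {
  demo <- demo_kb()
  rows <- phenoconversion_rows()
  for (i in seq_len(nrow(rows))) {
    p <- patient_record("p", c(rows$drug[i], rows$drug2[i]),
                        tested_genes = rows$gene[i],
                        phenotypes = stats::setNames(rows$phenotype[i],
                                                     rows$gene[i]))
    det <- detect_interactions(p, demo$kb)
    ddgi <- det[det$kind == "DDGI" & det$drug == rows$drug[i] &
                  det$drug2 == rows$drug2[i], ]
    expect_identical(nrow(ddgi), 1L)
    expect_identical(ddgi$combined_auc, rows$combined[i])
    expect_true(ddgi$eadgi)
  }
})

test_that("actionability needs a gene, moderate severity, and qualifying evidence", {
  fix <- tiny_kb()
  # reference phenotypes, no drug-drug rules -> nothing at all
  p <- patient_record("p", c("drug-x", "drug-z"),
                      tested_genes = c("G1", "G2"),
                      phenotypes = c(G1 = "normal", G2 = "normal"))
  expect_identical(nrow(detect_interactions(p, fix$kb)), 0L)
  expect_false(has_eadgi(p, fix$kb))
  # monitor-severity match is detected but not actionable
  p <- patient_record("p", "drug-w", tested_genes = "G1",
                      phenotypes = c(G1 = "intermediate"))
  det <- detect_interactions(p, fix$kb)
  expect_identical(det$severity, "monitor")
  expect_false(has_eadgi(p, fix$kb))
  # non-evidence-based match is detected but not actionable
  p <- patient_record("p", "drug-o", tested_genes = "G1",
                      phenotypes = c(G1 = "poor"))
  det <- detect_interactions(p, fix$kb)
  expect_identical(det$severity, "major")
  expect_false(has_eadgi(p, fix$kb))
  # a moderate drug-gene match is actionable
  p <- patient_record("p", "drug-y", tested_genes = "G1",
                      phenotypes = c(G1 = "poor"))
  expect_true(has_eadgi(p, fix$kb))
  # untested gene contributes nothing even with matching medication
  p <- patient_record("p", "drug-z", tested_genes = "G1",
                      phenotypes = c(G1 = "poor"))
  expect_false(has_eadgi(p, fix$kb))
})

test_that("gene-free interactions are reported but never actionable", {
  demo <- demo_kb()
  p <- patient_record("p", c("citalopram", "omeprazole"),
                      tested_genes = "CYP2C19",
                      phenotypes = c(CYP2C19 = "normal"))
  det <- detect_interactions(p, demo$kb)
  expect_identical(det$kind, "DDI")
  expect_false(any(det$eadgi))
  expect_false(has_eadgi(p, demo$kb))
  p3 <- patient_record("p", c("amitriptyline", "bupropion", "fluvoxamine"),
                       tested_genes = "CYP2D6",
                       phenotypes = c(CYP2D6 = "normal"))
  det3 <- detect_interactions(p3, demo$kb)
  expect_true("DDDI" %in% det3$kind)
})

test_that("detection order is deterministic and severity-sorted", {
  demo <- demo_kb()
  p <- patient_record("p", c("clopidogrel", "tramadol", "metoprolol"),
                      tested_genes = c("CYP2C19", "CYP2D6"),
                      phenotypes = c(CYP2C19 = "intermediate",
                                     CYP2D6 = "intermediate"))
  d1 <- detect_interactions(p, demo$kb)
  d2 <- detect_interactions(p, demo$kb)
  expect_identical(d1, d2)
  expect_true(all(diff(severity_rank(d1$severity)) <= 0))
})

test_that("highest severity class keeps the single worst finding with kind tie-breaks", {
  mk <- function(kind, drug, severity) {
    data.frame(kind = kind, drug = drug, severity = severity,
               stringsAsFactors = FALSE)
  }
  expect_identical(highest_severity_class(mk("DGI", "a", "moderate")[0, ]),
                   list(kind = "none", severity = "none"))
  x <- rbind(mk("DGI", "a", "moderate"), mk("DDGI", "b", "major"))
  expect_identical(highest_severity_class(x),
                   list(kind = "DDGI", severity = "major"))
  # equal severity: gene-involving and more-drug kinds take precedence
  kinds <- c("DDI", "DDDI", "DGI", "DDGI", "DGGI")
  for (i in seq_along(kinds)) {
    for (j in seq_along(kinds)) {
      x <- rbind(mk(kinds[i], "a", "moderate"), mk(kinds[j], "b", "moderate"))
      want <- kinds[max(i, j)]
      expect_identical(highest_severity_class(x)$kind, want)
    }
  }
  # full tie: lexical drug order decides
  x <- rbind(mk("DGI", "zeta", "moderate"), mk("DGI", "alpha", "moderate"))
  expect_identical(highest_severity_class(x)$kind, "DGI")
  expect_identical(
    highest_severity_class(rbind(mk("DGI", "zeta", "moderate"),
                                 mk("DGI", "alpha", "moderate")))$severity,
    "moderate")
})

test_that("clinical-area tabulation conserves counts and reproduces printed percentages", {
  # counts per area and severity column as published
  area_counts <- list(
    "behavioral health" = c(765, 1106), "cardiology" = c(3230, 877),
    "pain management" = c(470, 456), "hematology and oncology" = c(37, 3),
    "infectious disease" = c(0, 2), "gastroenterology" = c(2634, 0),
    "urology" = c(108, 0), "transplant" = c(8, 0),
    "reproductive and sexual health" = c(16, 0), "neurology" = c(42, 0),
    "rheumatology" = c(0, 0), "endocrinology" = c(0, 0),
    "miscellaneous" = c(50, 0))
  rows <- do.call(rbind, lapply(names(area_counts), function(a) {
    n <- area_counts[[a]]
    data.frame(clinical_area = rep(a, sum(n)),
               severity = c(rep("moderate", n[1]), rep("major", n[2])),
               stringsAsFactors = FALSE)
  }))
  tab <- tabulate_by_area(rows)
  expect_identical(sum(tab$moderate_n), 7360L)
  expect_identical(sum(tab$major_contra_n), 2444L)
  expect_identical(sum(tab$all_n), 9804L)
  bh <- tab[tab$clinical_area == "behavioral health", ]
  expect_equal(bh$moderate_pct, 10.4)
  expect_equal(bh$major_contra_pct, 45.3)
  expect_equal(bh$all_pct, 19.1)
  card <- tab[tab$clinical_area == "cardiology", ]
  expect_equal(card$major_contra_pct, 35.9)
  expect_equal(card$all_pct, 41.9)
  expect_equal(tab[tab$clinical_area == "pain management", ]$major_contra_pct,
               18.7)
  # percentage columns close under rounding slack
  expect_lt(abs(sum(tab$moderate_pct) - 100), 0.2)
  expect_lt(abs(sum(tab$major_contra_pct) - 100), 0.2)
  expect_lt(abs(sum(tab$all_pct) - 100), 0.2)
  # degenerate inputs
  empty <- tabulate_by_area(rows[0, ])
  expect_true(all(empty$all_n == 0L))
  single <- tabulate_by_area(data.frame(clinical_area = "urology",
                                        severity = "moderate",
                                        stringsAsFactors = FALSE))
  expect_equal(single[single$clinical_area == "urology", ]$all_pct, 100.0)
})

test_that("top-medication ranking combines counts, proportions, PIP and NNT", {
  demo <- demo_kb()
  counts <- c(metoprolol = 2852, omeprazole = 1673, escitalopram = 1038,
              clopidogrel = 872, pantoprazole = 635, codeine = 600,
              tramadol = 600, amitriptyline = 600, morphine = 500,
              dronedarone = 434)
  stopifnot(sum(counts) == 9804)
  inter <- data.frame(drug = rep(names(counts), counts),
                      stringsAsFactors = FALSE)
  ranking <- c(metoprolol = 5, omeprazole = 8, escitalopram = 19,
               clopidogrel = 36, pantoprazole = 16)
  top <- top_medications(inter, demo$kb, demo$prevalence, ranking = ranking)
  expect_identical(top$drug[1:5], c("metoprolol", "omeprazole",
                                    "escitalopram", "clopidogrel",
                                    "pantoprazole"))
  expect_equal(top$proportion_pct, c(29.1, 17.1, 10.6, 8.9, 6.5))
  expect_equal(top$pip_pct, c(48, 29, 32, 29, 29))
  expect_equal(top$nnt, c(2.1, 3.4, 3.1, 3.4, 3.4))
  expect_identical(top$rank[1], 5L)
  # single-drug input: proportion 100%
  one <- top_medications(data.frame(drug = rep("codeine", 7),
                                    stringsAsFactors = FALSE),
                         demo$kb, demo$prevalence)
  expect_equal(one$proportion_pct, 100.0)
  expect_equal(one$pip_pct, 9)
  expect_equal(one$nnt, 11.1)
})
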