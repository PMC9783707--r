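# PIP engine: opportunity filters, cluster probabilities, score properties.

test_that("opportunities apply the exclusion filters", {
  fix <- tiny_kb()
  # no substrate among the meds -> empty
  expect_identical(nrow(interaction_opportunities("drug-m", fix$kb)), 0L)
  # monitor-severity rule excluded on its own ...
  expect_identical(nrow(interaction_opportunities("drug-w", fix$kb)), 0L)
  # ... but its modifier-escalated pairing (monitor -> major, two bins
  # beyond the rule's category) survives
  opps <- interaction_opportunities(c("drug-w", "drug-m"), fix$kb)
  expect_identical(opps$kind, "DDGI")
  expect_identical(opps$severity, "major")
  # non-evidence-based rules never become opportunities
  expect_identical(nrow(interaction_opportunities("drug-o", fix$kb)), 0L)
  # unknown drugs: lenient by default, strict on request
  expect_silent(interaction_opportunities(c("drug-x", "vitamin-q"), fix$kb))
  expect_error(interaction_opportunities(c("drug-x", "vitamin-q"), fix$kb,
                                         strict = TRUE), "vitamin-q")
  expect_error(interaction_opportunities(character(), fix$kb), "empty")
})

test_that("two-drug opportunities must exceed the gene-free pair severity", {
  fix <- tiny_kb()
  kb2 <- pip_kb(fix$kb$genes, fix$kb$drugs, fix$kb$rules, fix$kb$modifiers,
                ddi = data.frame(drug1 = "drug-w", drug2 = "drug-m",
                                 drug3 = NA, severity = "major",
                                 stringsAsFactors = FALSE))
  # escalated severity (major) no longer exceeds the drug-drug severity
  expect_identical(nrow(interaction_opportunities(c("drug-w", "drug-m"), kb2)), 0L)
})

test_that("cluster probability is the union mass over phenotype draws", {
  fix <- tiny_kb()
  opps <- interaction_opportunities(c("drug-x", "drug-y"), fix$kb)
  # nested actionable sets: union is the larger set {poor, intermediate}
  expect_equal(cluster_actionable_probability("G1", opps, fix$prev), 0.30)
  expect_equal(cluster_actionable_probability("G1", opps[0, ], fix$prev), 0)
})

test_that("disjoint gene clusters combine as independent events", {
  fix <- tiny_kb()
  r <- compute_pip(c("drug-x", "drug-z"), fix$kb, fix$prev)
  expect_equal(r$pip, 1 - (1 - 0.30) * (1 - 0.08))   # 0.3560
  expect_equal(sort(names(r$per_cluster)), c("G1", "G2"))
  expect_equal(r$adjusted_pip, r$pip)
  # restricting the panel to one gene drops the other cluster
  r1 <- compute_pip(c("drug-x", "drug-z"), fix$kb, fix$prev,
                    tested_genes = "G2")
  expect_equal(r1$adjusted_pip, 0.08)
  expect_equal(r1$pip, r$pip)
})

test_that("a medication list with no actionable opportunities scores zero", {
  fix <- tiny_kb()
  r <- compute_pip(c("drug-w", "vitamin-q"), fix$kb, fix$prev)
  expect_identical(r$opportunity_count, 0L)
  expect_identical(r$pip, 0)
  # pip == 0 iff opportunity_count == 0
  r2 <- compute_pip("drug-x", fix$kb, fix$prev)
  expect_gt(r2$opportunity_count, 0L)
  expect_gt(r2$pip, 0)
})

test_that("two-gene rules couple genes into one exactly-enumerated cluster", {
  fix <- dggi_kb()
  r <- compute_pip("drug-a", fix$kb, fix$prev)
  expect_identical(names(r$per_cluster), "G1+G2")
  expect_equal(r$pip, 0.2 * 0.3)   # joint poor/poor
  expect_equal(pip_bruteforce("drug-a", fix$kb, fix$prev), r$pip)
  # dropping the second gene from the panel removes the coupled opportunity
  expect_equal(compute_pip("drug-a", fix$kb, fix$prev,
                           tested_genes = "G1")$adjusted_pip, 0)
})

test_that("engine equals the detector-based brute-force oracle on random knowledge bases", {
  set.seed(202)
  for (i in 1:40) {
    rk <- random_kb()
    meds <- sample(kb_drugs(rk$kb), sample(2:4, 1))
    r <- compute_pip(meds, rk$kb, rk$prevalence)
    expect_equal(r$pip, pip_bruteforce(meds, rk$kb, rk$prevalence),
                 tolerance = 1e-9)
    tested <- sample(kb_genes(rk$kb), 2)
    ra <- compute_pip(meds, rk$kb, rk$prevalence, tested_genes = tested)
    expect_equal(ra$adjusted_pip,
                 pip_bruteforce(meds, rk$kb, rk$prevalence,
                                tested_genes = tested),
                 tolerance = 1e-9)
  }
})

test_that("scores are monotone in medications and tested genes, with adjusted <= full", {
  demo <- demo_kb()
  set.seed(303)
  drugs <- kb_drugs(demo$kb)
  genes <- kb_genes(demo$kb)
  for (i in 1:25) {
    meds <- sample(drugs, sample(1:4, 1))
    extra <- sample(setdiff(drugs, meds), 1)
    tested <- sample(genes, sample(1:10, 1))
    r <- compute_pip(meds, demo$kb, demo$prevalence, tested_genes = tested)
    expect_gte(r$pip, r$adjusted_pip)
    expect_gte(r$adjusted_pip, 0)
    expect_lte(r$pip, 1)
    r_more_meds <- compute_pip(c(meds, extra), demo$kb, demo$prevalence,
                               tested_genes = tested)
    expect_gte(r_more_meds$pip + 1e-12, r$pip)
    bigger <- union(tested, sample(genes, 5))
    r_more_genes <- compute_pip(meds, demo$kb, demo$prevalence,
                                tested_genes = bigger)
    expect_gte(r_more_genes$adjusted_pip + 1e-12, r$adjusted_pip)
  }
})

test_that("brute-force oracle refuses oversized enumerations", {
  demo <- demo_kb()
  expect_error(pip_bruteforce(c("metoprolol", "escitalopram"), demo$kb,
                              demo$prevalence, max_combinations = 3),
               "too large")
})

test_that("simulated phenotypes hit actionable findings at the predicted rate", {
  # calibration identity: the indicator of >=1 actionable finding is
  # Bernoulli(pip) by construction; check at n = 10,000 within 3 binomial SE
  demo <- demo_kb()
  meds <- c("escitalopram", "clopidogrel", "tramadol", "metoprolol")
  r <- compute_pip(meds, demo$kb, demo$prevalence)
  n <- 10000
  set.seed(404)
  genes <- kb_genes(demo$kb)
  cohort <- data.frame(patient_id = sprintf("S%05d", 1:n),
                       panel_size = 25L,
                       tested_genes = paste(sort(genes), collapse = ";"),
                       meds = paste(meds, collapse = ";"),
                       stringsAsFactors = FALSE)
  for (g in genes) {
    v <- demo$prevalence[[g]]
    cohort[[paste0("pheno_", g)]] <- sample(names(v), n, replace = TRUE,
                                            prob = v)
  }
  scored <- score_cohort(cohort, demo$kb, demo$prevalence)
  se <- sqrt(r$pip * (1 - r$pip) / n)
  expect_lt(abs(mean(scored$eadgi) - r$pip), 3 * se)
  # spot-check the fast path against the per-patient detector
  for (i in sample(n, 20)) {
    genes_i <- strsplit(cohort$tested_genes[i], ";", fixed = TRUE)[[1]]
    ph <- vapply(genes_i, function(g) cohort[[paste0("pheno_", g)]][i], "")
    p <- patient_record(cohort$patient_id[i], meds, tested_genes = genes_i,
                        phenotypes = ph)
    expect_identical(scored$eadgi[i], has_eadgi(p, demo$kb))
  }
})
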