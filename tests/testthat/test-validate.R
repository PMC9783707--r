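# Validation statistics and report layer.

test_that("number needed to test is n over count, undefined at zero", {
  expect_equal(nnt(100, 100), 1.0)
  expect_equal(nnt(36511, 8174) * 8174, 36511)      # exact before rounding
  expect_equal(round(nnt(36511, 8174), 6), round(4.46672, 5), tolerance = 1e-4)
  expect_error(nnt(100, 0), class = "pipscore_undefined_nnt")
  set.seed(1)
  for (i in 1:20) {
    n <- sample(10:10000, 1); c <- sample(seq_len(n), 1)
    expect_equal(nnt(n, c) * c, n)
  }
})

test_that("one-proportion z-test matches the closed-form normal tail", {
  z <- one_prop_ztest(60, 100, 0.5)
  expect_equal(z$z, 2.0)
  expect_equal(z$p_value, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(z$p_value, 0.0455, tolerance = 1e-3)
  z0 <- one_prop_ztest(50, 100, 0.5)
  expect_equal(z0$z, 0)
  expect_equal(z0$p_value, 1.0)
  zneg <- one_prop_ztest(0, 10, 0.5)
  expect_equal(zneg$z, -sqrt(10), tolerance = 1e-12)
  expect_equal(zneg$p_value, 0.00157, tolerance = 1e-2)
  expect_error(one_prop_ztest(5, 10, 0), "strictly between")
  expect_error(one_prop_ztest(5, 10, 1), "strictly between")
  expect_error(one_prop_ztest(11, 10, 0.5), "0..n")
})

test_that("z-test p-value is symmetric under complementation", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(20:5000, 1)
    count <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    a <- one_prop_ztest(count, n, p0)
    b <- one_prop_ztest(n - count, n, 1 - p0)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
  }
})

test_that("panel summaries are calibrated on simulated cohorts", {
  demo <- demo_kb()
  coh <- simulate_cohort(cohort_config(8000, seed = 21), demo$kb,
                         demo$prevalence)
  scored <- score_cohort(coh, demo$kb, demo$prevalence)
  for (s in c(3, 5)) {
    ps <- panel_summary(scored, s)
    expect_gte(ps$mean_pip, ps$mean_adjusted_pip)
    expect_equal(ps$eadgi_rate, ps$eadgi_count / ps$n)
    expect_equal(ps$nnt * ps$eadgi_count, ps$n)
    se <- sqrt(ps$mean_adjusted_pip * (1 - ps$mean_adjusted_pip) / ps$n)
    expect_lt(abs(ps$eadgi_rate - ps$mean_adjusted_pip), 3 * se)
    expect_gt(ps$p_value, 0.05)
  }
  # the 25-gene subgroup contains only 25-gene panels; full == adjusted there
  ps25 <- panel_summary(scored, 25)
  expect_equal(ps25$mean_pip, ps25$mean_adjusted_pip)
})

test_that("a zero-score subgroup reports rate zero and undefined NNT", {
  demo <- demo_kb()
  scored <- data.frame(patient_id = c("a", "b"),
                       tested_genes = paste(pgx_panel(3), collapse = ";"),
                       pip = 0, adjusted_pip = 0, eadgi = FALSE,
                       stringsAsFactors = FALSE)
  ps <- panel_summary(scored, 3)
  expect_identical(ps$eadgi_count, 0L)
  expect_equal(ps$eadgi_rate, 0)
  expect_true(is.na(ps$nnt))
  expect_error(panel_summary(scored, 25), "no patients")
})

test_that("removing zero-score patients raises mean score and rate together", {
  demo <- demo_kb()
  coh <- simulate_cohort(cohort_config(6000, seed = 23), demo$kb,
                         demo$prevalence)
  scored <- score_cohort(coh, demo$kb, demo$prevalence)
  nz <- scored[scored$adjusted_pip > 0, ]
  expect_gt(mean(nz$adjusted_pip), mean(scored$adjusted_pip))
  p <- mean(nz$adjusted_pip)
  se <- sqrt(p * (1 - p) / nrow(nz))
  expect_lt(abs(mean(nz$eadgi) - p), 3 * se)
  # patients with score zero never carry an actionable finding
  expect_false(any(scored$eadgi[scored$adjusted_pip == 0]))
})

test_that("threshold bins use the documented boundary convention", {
  demo <- demo_kb()
  scored <- data.frame(
    patient_id = sprintf("p%d", 1:5),
    tested_genes = paste(pgx_panel(3), collapse = ";"),
    pip = c(0, 0.25, 0.5, 0.51, 0.9),
    adjusted_pip = c(0, 0.25, 0.5, 0.51, 0.9),
    eadgi = c(FALSE, TRUE, FALSE, TRUE, TRUE),
    top_kind = c("none", "DGI", "DDGI", "DGI", "DDGI"),
    top_severity = c("none", "moderate", "major", "moderate", "major"),
    stringsAsFactors = FALSE)
  bins <- threshold_bins(scored)
  expect_identical(bins$bin, c("<25%", "25-50%", ">50%"))
  expect_identical(bins$n, c(1L, 2L, 2L))   # 0.25 and 0.50 in the middle band
  expect_error(threshold_bins(scored[, setdiff(names(scored), "top_kind")]),
               "classify")
  # all-zero cohort: everyone in the low band, no interactions
  zero <- scored[1, ][rep(1, 4), ]
  bz <- threshold_bins(zero)
  expect_identical(bz$n, c(4L, 0L, 0L))
  expect_equal(bz$frac_any_interaction, c(0, 0, 0))
})

test_that("interaction burden grows across score bands in a calibrated cohort", {
  demo <- demo_kb()
  coh <- simulate_cohort(cohort_config(6000, seed = 25), demo$kb,
                         demo$prevalence)
  scored <- score_cohort(coh, demo$kb, demo$prevalence, classify = TRUE)
  bins <- threshold_bins(scored)
  occupied <- bins$n > 0
  expect_true(all(diff(bins$frac_eadgi[occupied]) > -1e-9))
  expect_true(all(diff(bins$frac_any_interaction[occupied]) > -1e-9))
})

test_that("report writes deterministic study tables and a manifest", {
  demo <- demo_kb()
  coh <- simulate_cohort(cohort_config(400, seed = 31), demo$kb,
                         demo$prevalence)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- report(coh, demo$kb, demo$prevalence, d1)
  f2 <- report(coh, demo$kb, demo$prevalence, d2)
  want <- c("panel_summary.tsv", "by_area.tsv", "top_medications.tsv",
            "top_major.tsv", "threshold_bins.tsv", "manifest.json")
  expect_setequal(basename(f1), want)
  for (f in want) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  ps <- utils::read.delim(file.path(d1, "panel_summary.tsv"))
  expect_true("nnt" %in% names(ps))
  expect_equal(ps$nnt, round_half_up_for_tests(ps$n / ps$eadgi_count, 1))
  man <- jsonlite::fromJSON(file.path(d1, "manifest.json"))
  expect_identical(man$seed, 31L)
  # manifest checksum tracks the knowledge base content
  kb2 <- demo_kb()$kb
  kb2$drugs$clinical_area[1] <- "miscellaneous"
  d3 <- withr::local_tempdir()
  report(coh, kb2, demo$prevalence, d3)
  man3 <- jsonlite::fromJSON(file.path(d3, "manifest.json"))
  expect_false(identical(man$kb_md5, man3$kb_md5))
})
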