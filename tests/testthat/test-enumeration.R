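# Sample enumeration, analytical-validation statistics, diagnostics,
# group comparisons and recurrence analysis.

callRow <- function(x, y, is_ctc = TRUE, nuclei = 1, diam = 12) {
  data.frame(x = x, y = y, is_ctc = is_ctc, nuclei_count = nuclei,
             eq_diameter_um = diam)
}

test_that("enumeration counts CTCs and microemboli by the cluster rule", {
  iso <- rbind(callRow(10, 10), callRow(100, 100), callRow(200, 50))
  r <- enumerateSample(iso)
  expect_equal(r$ctc_count, 3); expect_equal(r$ctm_count, 0)

  clus <- callRow(50, 50, nuclei = 3)
  r2 <- enumerateSample(clus)
  expect_equal(r2$ctc_count, 3); expect_equal(r2$ctm_count, 1)

  r3 <- enumerateSample(callRow(1, 1)[0, ])
  expect_equal(r3$ctc_count, 0); expect_equal(r3$ctm_count, 0)

  # two adjoining singletons are one microembolus, not two
  adj <- rbind(callRow(50, 50), callRow(58, 50), callRow(200, 200))
  r4 <- enumerateSample(adj)
  expect_equal(r4$ctc_count, 3); expect_equal(r4$ctm_count, 1)

  # counts normalized to 5 mL
  r5 <- enumerateSample(iso, blood_volume_ml = 10)
  expect_equal(r5$ctc_per_5ml, 1.5)
})

test_that("recovery rate and %CV follow their formulas", {
  expect_equal(recoveryRate(15, 20), 75)
  expect_equal(recoveryRate(20, 20), 100)
  expect_error(recoveryRate(5, 0), "undefined")
  expect_warning(recoveryRate(25, 20), "100")

  sim <- spikeInExperiment(c(10, 50, 100, 250), recovery_prob = 0.756,
                           replicates = 2500, seed = 3)
  expect_lt(abs(mean(recoveryRate(sim$recovered, sim$n_spiked)) - 75.6),
            1)

  expect_equal(cvPercent(c(8, 10, 12)), 20)
  expect_equal(cvPercent(rep(4, 6)), 0)
  v <- c(14, 17, 15, 20, 16)
  expect_equal(cvPercent(v), cvPercent(2 * v))  # scale-free
  expect_error(cvPercent(5), "at least 2")
  # operator-replicate precision at the validated spike level is of the
  # order of the platform's reported low-teens %CV
  ops <- spikeInExperiment(20, 0.756, replicates = 9, seed = 4)
  cv <- cvPercent(ops$recovered)
  expect_lt(cv, 35); expect_gt(cv, 1)
})

test_that("positivity rates reproduce printed tallies", {
  coh <- data.frame(
    group = rep(c("HCC", "HD"), c(145, 125)),
    ctc_count = c(countsFromTally(86, 145), countsFromTally(1, 125)))
  expect_equal(round(positivityRate(coh, "HCC")$percent, 1), 59.3)
  expect_equal(round(positivityRate(coh, "HD")$percent, 1), 0.8)
  zero <- data.frame(group = "G", ctc_count = rep(0, 10))
  expect_equal(positivityRate(zero, "G")$percent, 0)
  expect_error(positivityRate(zero, "missing"), "empty group")
})

test_that("diagnostic sensitivity/specificity and their edge cases", {
  cases <- countsFromTally(4, 6); controls <- countsFromTally(1, 8)
  dm <- diagnosticMetrics(cases, controls, threshold = 1)
  expect_equal(dm$sensitivity, 4 / 6)
  expect_equal(dm$specificity, 7 / 8)
  expect_equal(diagnosticMetrics(cases, controls, 0)$sensitivity, 1)
  expect_equal(diagnosticMetrics(cases, rep(0, 5), 1)$specificity, 1)
  expect_true(dm$sens_ci[1] <= dm$sensitivity &
                dm$sensitivity <= dm$sens_ci[2])
})

test_that("count ROC AUC equals brute-force pairwise counting", {
  expect_equal(rocAucCounts(c(2, 3), c(0, 1), ci_method = "none")$auc, 1)
  expect_equal(rocAucCounts(c(1, 0), c(0, 0), ci_method = "none")$auc,
               0.75)
  expect_equal(rocAucCounts(c(1, 2, 3), c(1, 2, 3),
                            ci_method = "none")$auc, 0.5)
  set.seed(11)
  for (i in 1:20) {
    a <- rpois(sample(3:12, 1), 2); b <- rpois(sample(3:12, 1), 1)
    expect_equal(rocAucCounts(a, b, ci_method = "none")$auc,
                 aucOracle(a, b))
  }
  d <- rocAucCounts(rpois(40, 2), rpois(40, 1))
  expect_true(d$ci[1] <= d$auc & d$auc <= d$ci[2])
})

test_that("group comparisons dispatch to the right exact/asymptotic tests", {
  mw <- compareGroups(c(1, 2), c(3, 4), "mann-whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1 / 3)

  chi <- compareGroups(matrix(c(43, 16, 38, 48), 2), test = "chi2")
  expect_equal(round(chi$p_value, 3), 0.001)

  ident <- compareGroups(c(1, 2, 3), c(1, 2, 3), "wilcoxon-paired")
  expect_equal(ident$p_value, 1)
  expect_error(compareGroups(1:3, 1:4, "wilcoxon-paired"), "equal-length")

  f <- compareGroups(matrix(c(8, 1, 2, 9), 2), test = "fisher")
  expect_lt(f$p_value, 0.05)
})

test_that("Kaplan-Meier recurrence handles the textbook cases", {
  none <- data.frame(ttr = c(5, 8, 12), recurrence = 0,
                     ctc_status = "CTC=0")
  k0 <- kmRecurrence(none)
  expect_true(all(k0$curves$surv == 1) || nrow(k0$curves) == 0)
  expect_true(is.na(k0$median_ttr[["CTC=0"]]))

  h <- data.frame(ttr = c(1, 2, 3), recurrence = 1, ctc_status = "g")
  kh <- kmRecurrence(h)
  s2 <- kh$curves$surv[kh$curves$time == 2]
  expect_equal(s2, 1 / 3)

  two <- data.frame(ttr = rep(c(2, 4, 6, 9), 2),
                    recurrence = rep(c(1, 0, 1, 1), 2),
                    ctc_status = rep(c("a", "b"), each = 4))
  kt <- kmRecurrence(two)
  expect_gt(kt$logrank_p, 0.99)
  expect_lt(kt$logrank_chisq, 1e-8)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(21)
  for (i in 1:5) {
    t_ <- sample(1:40, 25, replace = TRUE)
    df <- data.frame(ttr = t_, recurrence = 1, ctc_status = "g")
    km <- kmRecurrence(df)
    for (r in seq_len(nrow(km$curves)))
      expect_equal(km$curves$surv[r], mean(t_ > km$curves$time[r]))
  }
})

test_that("the CTC + AFP logistic reconstruction improves on CTC alone", {
  coh <- simulateCohort(cohortSpec(), n_per_group = c(
    HCC = 400, CHB_LC = 100, BHL = 100, HD = 300), seed = 11)
  # near-separable simulated arms can saturate fitted probabilities
  cmb <- suppressWarnings(combinedCtcAfp(coh))
  expect_true(cmb$auc_combined >= cmb$auc_ctc - 1e-9)
  expect_true(cmb$auc_combined >= cmb$auc_afp - 1e-9)
  expect_gt(cmb$auc_combined, 0.5)
  expect_error(combinedCtcAfp(coh[, c("group", "ctc_count")]), "missing")
})

test_that("cohort report assembles all sections deterministically", {
  coh <- simulateCohort(cohortSpec(), n_per_group = c(
    HCC = 2000, CHB_LC = 50, BHL = 50, HD = 2000), seed = 5)
  rep1 <- cohortReport(coh)
  expect_named(rep1$groups, c("HCC", "CHB_LC", "BHL", "HD"))
  expect_false(is.null(rep1$diagnostics))
  expect_false(is.null(rep1$survival))
  spec <- cohortSpec()$groups$HCC
  closed <- 100 * zinbPositivity(spec$pi, spec$mu, spec$k)
  expect_lt(abs(rep1$groups$HCC$positivity_percent - closed), 3.5)

  noout <- coh[, c("id", "group", "ctc_count")]
  rep2 <- cohortReport(noout)
  expect_null(rep2$survival)

  tf <- tempfile(fileext = ".json")
  writeCohortReport(rep1, tf)
  expect_true(file.exists(tf))
  parsed <- jsonlite::read_json(tf)
  expect_equal(parsed$groups$HCC$n, 2000)
  unlink(tf)
})
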