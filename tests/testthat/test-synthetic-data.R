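# Synthetic-data generators: determinism, count conservation, generative
# formula checks and closed-form calibration.

test_that("renderField honours counts, dimensions and the empty case", {
  blank <- renderField(fieldSpec(width = 128, height = 128, n_wbc = 0,
                                 n_ctc = 0, n_debris = 0,
                                 illumination_gradient = 0,
                                 noise_sd = 10, seed = 3))
  expect_equal(nrow(blank$truth), 0)
  d <- getChannel(blank$field, "DAPI")
  expect_equal(dim(d), c(128, 128))
  # baseline + noise only
  expect_lt(abs(mean(d) - 500), 5)
  expect_lt(sd(d), 15)

  out <- renderField(smallFieldSpec(n_wbc = 100, n_ctc = 5, n_debris = 7,
                                    seed = 2))
  expect_equal(sum(out$truth$class == "CTC"), 5)
  expect_equal(sum(out$truth$class == "WBC"), 100)
  expect_equal(sum(out$truth$class == "debris"), 7)
  expect_true(all(vapply(out$field@channels,
                         function(m) identical(dim(m), c(256L, 256L)),
                         logical(1))))
})

test_that("renderField is bit-reproducible under a fixed seed", {
  a <- renderField(smallFieldSpec(seed = 11))
  b <- renderField(smallFieldSpec(seed = 11))
  expect_identical(a$field@channels, b$field@channels)
  expect_identical(a$truth, b$truth)
  c <- renderField(smallFieldSpec(seed = 12))
  expect_false(identical(a$field@channels, c$field@channels))
})

test_that("rendered pixel at a cell center follows the generative formula", {
  spec <- fieldSpec(width = 128, height = 128, n_wbc = 0, n_ctc = 1,
                    n_debris = 0, noise_sd = 2,
                    illumination_gradient = 0.4, seed = 21)
  out <- renderField(spec)
  tr <- out$truth
  px <- round(tr$x); py <- round(tr$y)
  sig <- tr$radius_px / 2
  d2 <- (px - tr$x)^2 + (py - tr$y)^2
  expected <- out$illumination[py, px] *
    (spec$baseline + tr$amp_CK * exp(-d2 / (2 * sig^2)))
  got <- getChannel(out$field, "CK")[py, px]
  expect_lt(abs(got - expected), 3 * spec$noise_sd + 1)
})

test_that("renderField errors on impossible placement and bad specs", {
  expect_error(fieldSpec(width = 0), "positive")
  expect_error(fieldSpec(n_wbc = -1), ">= 0")
  expect_error(
    renderField(fieldSpec(width = 64, height = 64, n_wbc = 500,
                          n_ctc = 0, n_debris = 0, seed = 1)),
    "crowded")
})

test_that("sampleFeatureTable is deterministic with stated prevalence", {
  ps <- populationSpec(prevalence = 0.5)
  a <- sampleFeatureTable(ps, n = 10, seed = 9)
  b <- sampleFeatureTable(ps, n = 10, seed = 9)
  expect_identical(a, b)
  big <- sampleFeatureTable(ps, n = 4000, seed = 1)
  expect_lt(abs(mean(big$label == "CTC") - 0.5), 0.03)
  expect_true(all(big$area_um2 > 0))
  expect_true(all(big$solidity > 0 & big$solidity <= 1))
})

test_that("separation 0 gives exchangeable classes; 6 sd separates them", {
  ps0 <- populationSpec(separation = 0)
  t0 <- sampleFeatureTable(ps0, n = 3000, seed = 4)
  pos <- t0$label == "CTC"
  for (col in c("ck_corr_mean", "cd45_corr_mean", "area_um2")) {
    auc <- ctcflow:::aucRank(t0[[col]], pos)
    expect_gt(auc, 0.45); expect_lt(auc, 0.55)
  }
  t6 <- sampleFeatureTable(populationSpec(separation = 6), n = 3000,
                           seed = 4)
  lck <- log(t6$ck_corr_mean)
  gap <- mean(lck[t6$label == "CTC"]) - mean(lck[t6$label == "WBC"])
  expect_gt(gap / sd(lck[t6$label == "WBC"]), 5)
  # truncated draws: no class overlap in the CK coordinate at 6 sd
  expect_gt(min(lck[t6$label == "CTC"]), max(lck[t6$label == "WBC"]))
})

test_that("simulateCohort matches its degenerate and closed-form limits", {
  allzero <- cohortSpec(groups = list(
    G = list(pi = 1, mu = 5, k = 2, hazard = 0)))
  cz <- simulateCohort(allzero, 200, seed = 1)
  expect_true(all(cz$ctc_count == 0))

  poissonish <- cohortSpec(groups = list(
    G = list(pi = 0, mu = 3, k = 1e9, hazard = 0)))
  cp <- simulateCohort(poissonish, 20000, seed = 2)
  expect_lt(abs(mean(cp$ctc_count) - 3), 3 * sqrt(3 / 20000))

  # default HCC-like group converges to the closed-form zero mass
  spec <- cohortSpec()
  coh <- simulateCohort(spec, c(HCC = 100000, CHB_LC = 1, BHL = 1,
                                HD = 1), seed = 3)
  p <- spec$groups$HCC
  expect_lt(abs(positivityRate(coh, "HCC")$percent / 100 -
                  zinbPositivity(p$pi, p$mu, p$k)), 0.01)
})

test_that("cohort group sizes equal n_per_group and outcomes are sane", {
  coh <- simulateCohort(cohortSpec(), n_per_group = 50, seed = 7)
  expect_equal(as.integer(table(coh$group)[c("HCC", "HD")]), c(50L, 50L))
  expect_true(all(coh$ttr > 0))
  expect_true(all(coh$recurrence %in% 0:1))
  expect_error(simulateCohort(cohortSpec(), 0), ">= 1")
})

test_that("spike-in replicates are binomial", {
  exact <- spikeInExperiment(20, recovery_prob = 1, replicates = 5,
                             seed = 1)
  expect_true(all(exact$recovered == 20))
  zero <- spikeInExperiment(0, recovery_prob = 0.7, replicates = 3,
                            seed = 1)
  expect_true(all(zero$recovered == 0))
  big <- spikeInExperiment(250, recovery_prob = 0.756,
                           replicates = 10000, seed = 2)
  expect_lt(abs(mean(big$recovered) / 250 - 0.756), 0.01)
  expect_error(spikeInExperiment(10, recovery_prob = 1.2), "recovery_prob")
})

test_that("simulated bin counts follow the NB model", {
  flat <- groundTruthCN(data.frame(chrom = c("chr1", "chr2", "chr3"),
                                   start = 0, end = 3e7, cn = 2))
  p <- simulateBinCounts(flat, mean_depth = 100, dispersion = 10,
                         seed = 1)
  cnt <- S4Vectors::mcols(bins(p))$count
  se <- sqrt((100 + 100^2 / 10) / length(cnt))
  expect_lt(abs(mean(cnt) - 100), 3 * se)

  pois <- simulateBinCounts(flat, mean_depth = 50, dispersion = Inf,
                            seed = 2)
  q <- profileQuality(pois)
  expect_lt(abs(q$index_of_dispersion - 1),
            3 * sqrt(2 / length(bins(pois))))

  tr <- exampleTruthCN()
  p0 <- simulateBinCounts(tr, mean_depth = 100, dispersion = 10, seed = 3)
  cn0 <- S4Vectors::mcols(bins(p0))$true_cn == 0
  expect_true(any(cn0))
  expect_true(all(S4Vectors::mcols(bins(p0))$count[cn0] == 0))

  a <- simulateBinCounts(tr, seed = 5); b <- simulateBinCounts(tr, seed = 5)
  expect_identical(S4Vectors::mcols(bins(a))$count,
                   S4Vectors::mcols(bins(b))$count)
})

test_that("ground-truth CN validates tiling and field I/O round-trips", {
  expect_error(groundTruthCN(data.frame(
    chrom = "chr1", start = c(0, 5e6), end = c(6e6, 1e7), cn = 2)),
    "tile")
  out <- renderField(smallFieldSpec(n_wbc = 5, n_ctc = 1, seed = 8))
  tf <- tempfile(fileext = ".tiff")
  writeField(out$field, tf)
  back <- readField(tf)
  expect_equal(getChannel(back, "CK"), getChannel(out$field, "CK"))
  expect_equal(pixelSize(back), pixelSize(out$field))
  unlink(c(tf, paste0(tf, ".json")))
})
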