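# Image pipeline: illumination correction, denoising, Otsu, segmentation,
# features, debris filtering.

test_that("illumination correction is exact on flat images and warns on zeros", {
  flat <- matrix(100, 64, 64)
  expect_lt(max(abs(correctIllumination(flat) - flat) / 100), 1e-6)
  expect_warning(z <- correctIllumination(matrix(0, 8, 8)), "all-zero")
  expect_equal(z, matrix(0, 8, 8))
})

test_that("illumination correction flattens the generator's gradient", {
  spec <- fieldSpec(width = 256, height = 256, n_wbc = 30, n_ctc = 0,
                    n_debris = 0, illumination_gradient = 0.8,
                    noise_sd = 10, seed = 14)
  out <- renderField(spec)
  raw <- getChannel(out$field, "DAPI")
  cor <- correctIllumination(raw)
  half <- function(m) c(median(m[, 1:128]), median(m[, 129:256]))
  hr <- half(raw); hc <- half(cor)
  # background medians differ with the gradient, agree after correction
  expect_gt(abs(hr[1] - hr[2]) / mean(hr), 0.05)
  expect_lt(abs(hc[1] - hc[2]) / mean(hc), 0.05)
  # idempotence at the generator's default gradient: a second pass
  # changes almost nothing
  dflt <- renderField(fieldSpec(width = 256, height = 256, n_wbc = 30,
                                n_ctc = 0, n_debris = 0, noise_sd = 10,
                                seed = 15))
  c1 <- correctIllumination(getChannel(dflt$field, "DAPI"))
  c2 <- correctIllumination(c1)
  expect_lt(median(abs(c2 - c1) / pmax(c1, 1)), 0.01)
})

test_that("median denoising behaves like a median filter", {
  const <- matrix(7, 32, 32)
  expect_equal(denoiseImage(const), const)
  imp <- matrix(10, 32, 32); imp[16, 16] <- 1000
  expect_equal(denoiseImage(imp)[16, 16], 10)
  set.seed(1)
  noisy <- matrix(rnorm(64 * 64, 100, 20), 64, 64)
  expect_lt(sd(denoiseImage(noisy)), sd(noisy))
  expect_error(denoiseImage(noisy, size = 4), "odd")
})

test_that("Otsu threshold equals the exhaustive between-class-variance search", {
  expect_equal(otsuThreshold(list(counts = c(4, 2, 0, 0, 3, 5),
                                  values = 0:5)),
               otsuOracle(c(4, 2, 0, 0, 3, 5), 0:5))
  # equal twin spikes: every cut ties; smallest threshold wins
  spikes <- c(5, 0, 0, 0, 0, 0, 0, 0, 0, 5)
  expect_equal(otsuThreshold(list(counts = spikes, values = 0:9)), 0)
  expect_error(otsuThreshold(matrix(3, 5, 5)), "degenerate")
  set.seed(42)
  for (i in 1:30) {
    counts <- rpois(256, exp(runif(1, 0, 3)))
    if (sum(counts > 0) < 2) next
    vals <- seq_len(256)
    expect_equal(otsuThreshold(list(counts = counts, values = vals)),
                 otsuOracle(counts, vals))
  }
})

test_that("segmentation recovers disjoint disks and flags clusters", {
  f2 <- diskField(rbind(c(25, 30), c(70, 60)))
  seg <- segmentObjects(f2)
  expect_equal(nrow(seg$table), 2)
  got <- seg$table[order(seg$table$x), ]
  expect_lt(max(abs(got$x - c(25, 70))), 1)
  expect_lt(max(abs(got$y - c(30, 60))), 1)

  blank <- FluorescentField(matrix(500, 64, 64), matrix(500, 64, 64),
                            matrix(500, 64, 64))
  expect_equal(nrow(segmentObjects(blank)$table), 0)

  noisy <- renderField(fieldSpec(width = 96, height = 96, n_wbc = 0,
                                 n_ctc = 0, n_debris = 0, noise_sd = 30,
                                 illumination_gradient = 0, seed = 5))
  expect_equal(nrow(segmentObjects(noisy$field)$table), 0)

  clus <- renderField(fieldSpec(width = 256, height = 256, n_wbc = 0,
                                n_ctc = 0, n_debris = 0,
                                cluster_spec = list(n = 1, size = 3),
                                noise_sd = 15, seed = 31))
  cseg <- segmentObjects(preprocessField(clus$field))
  expect_equal(nrow(cseg$table), 1)
  expect_gte(cseg$table$nuclei_count, 2)
})

test_that("extracted features match analytic values on painted objects", {
  f <- diskField(cbind(40, 40), radius = 10, v = 5000, bg = 0)
  seg <- segmentObjects(f)
  ft <- extractFeatures(f, seg)
  expect_equal(nrow(ft), 1)
  expect_lt(abs(ft$area_um2 - 100 * pi) / (100 * pi), 0.05)
  expect_gt(ft$form_factor, 0.85)
  expect_lt(ft$form_factor, 1.05)
  expect_lt(ft$eccentricity, 0.25)
  # constant value v on zero background
  expect_equal(ft$dapi_corr_mean, 5000)
  expect_equal(ft$dapi_integrated, 5000 * ft$area_um2)
  expect_equal(ft$dapi_bg, 0)
})

test_that("feature table respects pixel size units", {
  f2 <- diskField(cbind(40, 40), radius = 10, pixelSize = 0.5)
  ft <- extractFeatures(f2, segmentObjects(f2))
  expect_lt(abs(ft$area_um2 - 100 * pi * 0.25) / (100 * pi * 0.25), 0.05)
  expect_lt(abs(ft$eq_diameter_um - 10 * 0.5 * 2) / 10, 0.1)
})

test_that("debris filtering partitions its input exactly", {
  tab <- data.frame(area_um2 = c(10, 50, 900, 60),
                    solidity = c(0.9, 0.95, 0.9, 0.5),
                    dapi_fold = c(5, 5, 5, 5))
  fl <- filterDebris(tab, debrisFilterSpec())
  expect_equal(nrow(fl$kept), 1)
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(tab))
  expect_equal(sort(c(fl$kept$area_um2, fl$removed$area_um2)),
               sort(tab$area_um2))
  allpass <- data.frame(area_um2 = 100, solidity = 0.9, dapi_fold = 3)
  fl2 <- filterDebris(allpass)
  expect_equal(nrow(fl2$removed), 0)
  empty <- filterDebris(tab[0, ], debrisFilterSpec())
  expect_equal(nrow(empty$kept), 0)
  expect_error(debrisFilterSpec(min_area = 10, max_area = 5), "min_area")
})

test_that("debris specks are removed while cells are kept", {
  # well-stained cells comfortably above the debris-filter bounds
  tight <- list(CTC = list(DAPI = c(12000, 1000), CK = c(15000, 2000),
                           CD45 = c(100, 50)),
                WBC = list(DAPI = c(10000, 1000), CK = c(120, 60),
                           CD45 = c(9000, 1500)),
                debris = list(DAPI = c(250, 100), CK = c(400, 200),
                              CD45 = c(300, 150)))
  radii <- list(CTC = c(8, 0.8), WBC = c(5.5, 0.5), debris = c(1.5, 0.3))
  out <- renderField(smallFieldSpec(n_wbc = 15, n_ctc = 5, n_debris = 30,
                                    seed = 17, intensity_spec = tight,
                                    cell_radius_spec = radii))
  res <- processField(out$field)
  expect_equal(nrow(res$features), 20)
})

test_that("segmentation recovers counts and centroids across seeds", {
  tight <- list(CTC = list(DAPI = c(12000, 1000), CK = c(15000, 2000),
                           CD45 = c(100, 50)),
                WBC = list(DAPI = c(10000, 1000), CK = c(120, 60),
                           CD45 = c(9000, 1500)),
                debris = list(DAPI = c(250, 100), CK = c(400, 200),
                              CD45 = c(300, 150)))
  errs <- numeric(0); counts_ok <- logical(0)
  for (s in 1:20) {
    out <- renderField(smallFieldSpec(n_wbc = 20, n_ctc = 2,
                                      intensity_spec = tight, seed = s))
    seg <- segmentObjects(preprocessField(out$field))
    counts_ok <- c(counts_ok, nrow(seg$table) == 22)
    tr <- out$truth
    d <- sqrt(outer(seg$table$x, tr$x, "-")^2 +
                outer(seg$table$y, tr$y, "-")^2)
    errs <- c(errs, apply(d, 1, min))
  }
  expect_true(all(counts_ok))
  expect_lte(mean(errs), 1)
})
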