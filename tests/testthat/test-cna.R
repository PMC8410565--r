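# Copy-number profiling: library QC, normalization, segmentation, integer
# calls, coverage-quality metrics, concordance and driver annotation.

qcRecord <- function(n_good, ct_bad = 35) {
  data.frame(locus = paste0("L", 1:12),
             tm_ok = c(rep(TRUE, n_good), rep(FALSE, 12 - n_good)),
             ct = c(rep(25, n_good), rep(ct_bad, 12 - n_good)))
}

test_that("library QC applies the 8-of-12, Ct < 30 rule strictly", {
  expect_true(qcLibrary(qcRecord(8))$pass)
  expect_false(qcLibrary(qcRecord(7))$pass)
  rec <- qcRecord(9)
  rec$ct[1] <- 30  # boundary: Ct exactly 30 fails that locus
  q <- qcLibrary(rec)
  expect_false(q$locus_pass[1])
  expect_equal(q$n_pass, 8)
  expect_true(q$pass)
  expect_error(qcLibrary(qcRecord(8)[1:11, ]), "12 loci")
})

test_that("normalization yields mean-1 ratios and removes GC bias", {
  flat <- groundTruthCN(data.frame(chrom = c("chr1", "chr2", "chr3"),
                                   start = 0, end = 3e7, cn = 2))
  uni <- simulateBinCounts(flat, mean_depth = 2500, dispersion = Inf,
                           seed = 1)
  # constant-ish counts, uniform effect: ratios all ~1
  nu <- normalizeBins(uni)
  r <- S4Vectors::mcols(bins(nu))$ratio
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_lt(max(abs(r - 1)), 0.2)

  biased <- simulateBinCounts(flat, mean_depth = 5000, dispersion = Inf,
                              gc_bias_coeffs = c(1, 5), seed = 2)
  raw_ratio <- with(as.data.frame(S4Vectors::mcols(bins(biased))),
                    count / mean(count))
  gc <- S4Vectors::mcols(bins(biased))$gc
  pre_slope <- unname(coef(lm(raw_ratio ~ gc))[2])
  nb <- normalizeBins(biased)
  post_slope <- unname(coef(lm(S4Vectors::mcols(bins(nb))$ratio ~ gc))[2])
  expect_gt(abs(pre_slope), 0.5)
  expect_lt(abs(post_slope), 0.02)

  tr <- exampleTruthCN()
  p <- normalizeBins(simulateBinCounts(tr, mean_depth = 200,
                                       dispersion = 20, seed = 3))
  mc <- S4Vectors::mcols(bins(p))
  m4 <- mean(mc$ratio[mc$true_cn == 4])
  m2 <- mean(mc$ratio[mc$true_cn == 2])
  expect_lt(abs(m4 / m2 - 2), 0.15)
})

test_that("segmentation finds real breakpoints and nothing in noise", {
  flat <- groundTruthCN(data.frame(chrom = c("chr1", "chr2", "chr3"),
                                   start = 0, end = 3e7, cn = 2))
  cp <- simulateBinCounts(flat, mean_depth = 100, dispersion = 1e9,
                          seed = 4)
  sp <- segmentProfile(normalizeBins(cp))
  expect_equal(length(cnaSegments(sp)), 3)  # one per chromosome

  tr <- exampleTruthCN()
  p <- callCNAProfile(simulateBinCounts(tr, mean_depth = 100,
                                        dispersion = 10, seed = 5))
  segs <- cnaSegments(p)
  # chr2 amplification: breakpoints within 2 bins (1 Mb) of truth
  ch2 <- segs[GenomicRanges::seqnames(segs) == "chr2"]
  amp <- ch2[S4Vectors::mcols(ch2)$cn == 4]
  expect_equal(length(amp), 1)
  expect_lt(abs(GenomicRanges::start(amp) - 1e7), 2 * 5e5)
  expect_lt(abs(GenomicRanges::end(amp) - 2e7), 2 * 5e5)

  # destroying spatial order collapses the segmentation
  nb <- normalizeBins(simulateBinCounts(tr, mean_depth = 100,
                                        dispersion = 10, seed = 6))
  b <- bins(nb)
  set.seed(1)
  S4Vectors::mcols(b)$ratio <- sample(S4Vectors::mcols(b)$ratio)
  shuf <- methods::initialize(nb, bins = b)
  n_shuf <- length(cnaSegments(segmentProfile(shuf)))
  n_orig <- length(cnaSegments(segmentProfile(nb)))
  expect_lt(n_shuf, n_orig)
})

test_that("integer calls approach the true-boundary oracle and segments partition the bins", {
  # oracle: integer calls computed with the *true* segment boundaries;
  # the blind pipeline cannot beat it, and should sit close to it
  tr <- exampleTruthCN()
  hits <- numeric(0); oracle <- numeric(0)
  for (s in 1:20) {
    sim <- simulateBinCounts(tr, mean_depth = 100, dispersion = 10,
                             seed = s)
    p <- callCNAProfile(sim)
    mc <- S4Vectors::mcols(bins(p))
    hits <- c(hits, mean(mc$cn == mc$true_cn))
    nb <- S4Vectors::mcols(bins(normalizeBins(sim)))
    base <- median(nb$ratio[nb$ratio > 0])
    segid <- cumsum(c(1, diff(nb$true_cn) != 0))
    sm <- tapply(nb$ratio, segid, mean)
    ocn <- pmax(round(2 * sm[segid] / base), 0)
    oracle <- c(oracle, mean(ocn == nb$true_cn))
    segs <- cnaSegments(p)
    expect_true(all(S4Vectors::mcols(segs)$cn >= 0))
    # partition: every bin falls in exactly one segment
    ov <- GenomicRanges::countOverlaps(bins(p), segs)
    expect_true(all(ov == 1))
    expect_equal(sum(S4Vectors::mcols(segs)$n_bins), length(bins(p)))
  }
  expect_gte(mean(hits), mean(oracle) - 0.05)
  expect_gte(mean(hits), 0.85)
})

test_that("copy-number recovery degrades monotonically with depth", {
  rec <- vapply(c(100, 25, 6), function(depth) {
    mean(vapply(1:6, function(s) {
      p <- callCNAProfile(simulateBinCounts(exampleTruthCN(),
                                            mean_depth = depth,
                                            dispersion = 10,
                                            seed = 100 + s))
      mc <- S4Vectors::mcols(bins(p))
      mean(mc$cn == mc$true_cn)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rec) <= 0.02))  # non-increasing up to noise
  expect_gt(rec[1], rec[3])
})

test_that("coverage quality metrics match closed forms", {
  expect_error(profileQuality(rep(5, 1)), ">= 2")
  qc <- profileQuality(rep(7, 50))
  expect_equal(qc$index_of_dispersion, 0)
  expect_equal(qc$gini, 0)
  expect_equal(qc$lorenz$count_share, qc$lorenz$bin_share)

  set.seed(8)
  qp <- profileQuality(rpois(2000, 60))
  expect_lt(abs(qp$index_of_dispersion - 1), 3 * sqrt(2 / 2000))

  n <- 40
  point <- profileQuality(c(rep(0, n - 1), 1000))
  expect_equal(point$gini, (n - 1) / n)

  # Lorenz monotone, convex, endpoints (0,0) and (1,1); Gini scale-free
  set.seed(9)
  cnt <- rnbinom(300, mu = 50, size = 2)
  q1 <- profileQuality(cnt); q2 <- profileQuality(cnt * 7)
  expect_equal(q1$gini, q2$gini)
  expect_equal(q1$lorenz$count_share[1], 0)
  expect_equal(tail(q1$lorenz$count_share, 1), 1)
  expect_true(all(diff(q1$lorenz$count_share) >= 0))
  expect_true(all(diff(diff(q1$lorenz$count_share)) >= -1e-12))
})

test_that("profile concordance behaves like a correlation", {
  tr <- exampleTruthCN()
  p <- callCNAProfile(simulateBinCounts(tr, mean_depth = 100,
                                        dispersion = 10, seed = 12))
  expect_equal(profileConcordance(p, p), 1)

  # reflection around ploidy
  b <- bins(p)
  S4Vectors::mcols(b)$cn <- as.integer(2 * ploidy(p) -
                                         S4Vectors::mcols(b)$cn)
  refl <- methods::initialize(p, bins = b)
  expect_equal(profileConcordance(p, refl), -1)

  # single-cell simulation vs its noise-free truth (the acceptance suite
  # additionally checks the r >= 0.95 bar across seeds)
  truth_profile <- p
  bt <- bins(truth_profile)
  S4Vectors::mcols(bt)$cn <- S4Vectors::mcols(bt)$true_cn
  truth_profile <- methods::initialize(truth_profile, bins = bt)
  expect_gte(profileConcordance(p, truth_profile), 0.90)

  # two independent cells of the same truth agree better (margin > 0.2)
  # than cells of a different, rearranged truth
  q <- callCNAProfile(simulateBinCounts(tr, mean_depth = 100,
                                        dispersion = 10, seed = 13))
  other_truth <- groundTruthCN(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr3"),
    start = c(0, 1.5e7, 0, 0, 2e7),
    end   = c(1.5e7, 3e7, 3e7, 2e7, 3e7),
    cn    = c(4, 2, 1, 2, 3)))
  other <- callCNAProfile(simulateBinCounts(other_truth,
                                            mean_depth = 100,
                                            dispersion = 10, seed = 14))
  expect_gt(profileConcordance(p, q),
            profileConcordance(p, other) + 0.2)
})

test_that("driver annotation reports gains/losses by maximal overlap", {
  tr <- exampleTruthCN()
  p <- callCNAProfile(simulateBinCounts(tr, mean_depth = 300,
                                        dispersion = 50, seed = 15))
  genes <- data.frame(
    chrom = c("chr2", "chr3", "chr1", "chr2"),
    start = c(1.4e7, 2e6, 1e6, 0.95e7),
    end = c(1.5e7, 2.5e6, 1.5e6, 1.15e7),
    gene = c("AMP_IN", "LOSS_IN", "NEUTRAL", "SPANNER"))
  ann <- annotateDrivers(p, genes)
  expect_true("AMP_IN" %in% ann$gene)
  expect_equal(ann$direction[ann$gene == "AMP_IN"], "gained")
  expect_equal(ann$direction[ann$gene == "LOSS_IN"], "lost")
  expect_false("NEUTRAL" %in% ann$gene)
  sp <- ann[ann$gene == "SPANNER", ]
  expect_equal(nrow(sp), 1)
  expect_true(sp$boundary_spanning)
  expect_equal(sp$cn, 4)  # maximal overlap lies in the amplification

  empty <- annotateDrivers(p, genes[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(annotateDrivers(p, transform(genes, end = start)),
               "malformed")
})

test_that("bin-count tables round-trip through the BED-like TSV schema", {
  tr <- exampleTruthCN()
  p <- simulateBinCounts(tr, mean_depth = 100, dispersion = 10, seed = 16)
  tf <- tempfile(fileext = ".tsv")
  writeBinCounts(p, tf)
  back <- readBinCounts(tf)
  expect_equal(S4Vectors::mcols(bins(back))$count,
               S4Vectors::mcols(bins(p))$count)
  expect_equal(GenomicRanges::start(bins(back)),
               GenomicRanges::start(bins(p)))
  unlink(tf)
})
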