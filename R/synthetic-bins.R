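#' Ground-truth copy-number profile
#'
#' Builds the integer copy-number truth used to simulate binned read
#' counts. Segments must tile each chromosome without overlap.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, base pairs) and integer `cn >= 0`.
#' @param ploidy genome baseline ploidy.
#' @return `GRanges` with metadata column `cn` and attribute `ploidy`.
#' @export
groundTruthCN <- function(segments, ploidy = 2) {
  assertCols(segments, c("chrom", "start", "end", "cn"), "truth table")
  if (any(segments$cn < 0) || any(segments$cn != round(segments$cn)))
    stop("cn must be non-negative integers")
  gr <- GenomicRanges::GRanges(segments$chrom,
    IRanges::IRanges(start = segments$start + 1L, end = segments$end),
    cn = as.integer(segments$cn))
  gr <- GenomicRanges::sort(gr)
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[GenomicRanges::seqnames(gr) == ch]
    if (length(g) > 1L &&
        any(GenomicRanges::start(g)[-1L] !=
            GenomicRanges::end(g)[-length(g)] + 1L))
      stop("segments must tile chromosome ", ch, " without gaps/overlap")
  }
  attr(gr, "ploidy") <- ploidy
  gr
}

#' A miniature three-chromosome truth profile
#'
#' Toy diploid genome (three 30-Mb chromosomes) with one amplification
#' (CN 4), one single-copy loss (CN 1), one homozygous deletion (CN 0) and
#' one CN 3 gain, used throughout the tests and examples as a known truth
#' for copy-number recovery.
#'
#' @param bin_width bin width in bp (used to align segment boundaries).
#' @return a [groundTruthCN()] `GRanges`.
#' @export
exampleTruthCN <- function(bin_width = 5e5) {
  L <- 3e7
  seg <- rbind(
    data.frame(chrom = "chr1", start = 0,       end = 2e7,  cn = 2),
    data.frame(chrom = "chr1", start = 2e7,     end = L,    cn = 3),
    data.frame(chrom = "chr2", start = 0,       end = 1e7,  cn = 2),
    data.frame(chrom = "chr2", start = 1e7,     end = 2e7,  cn = 4),
    data.frame(chrom = "chr2", start = 2e7,     end = L,    cn = 2),
    data.frame(chrom = "chr3", start = 0,       end = 1e7,  cn = 1),
    data.frame(chrom = "chr3", start = 1e7,     end = 2.2e7, cn = 2),
    data.frame(chrom = "chr3", start = 2.2e7,   end = 2.5e7, cn = 0),
    data.frame(chrom = "chr3", start = 2.5e7,   end = L,    cn = 2))
  groundTruthCN(seg, ploidy = 2)
}

#' Fixed-width bins over a toy genome with a smooth GC landscape
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param bin_width bin width (bp).
#' @param seed seed for the (deterministic, smooth) GC fractions.
#' @return `GRanges` with metadata column `gc` in `[0.25, 0.65]`.
#' @export
toyGenomeBins <- function(chrom_lengths = c(chr1 = 3e7, chr2 = 3e7,
                                            chr3 = 3e7),
                          bin_width = 5e5, seed = 1L) {
  starts <- lapply(names(chrom_lengths), function(ch)
    seq(0, chrom_lengths[[ch]] - bin_width, by = bin_width))
  gr <- GenomicRanges::GRanges(
    rep(names(chrom_lengths), lengths(starts)),
    IRanges::IRanges(start = unlist(starts) + 1L,
                     end = unlist(starts) + bin_width))
  localSeed(seed, {
    # smooth sinusoidal GC landscape + small jitter, clamped to [0.25,0.65]
    n <- length(gr)
    ph <- stats::runif(3, 0, 2 * pi)
    i <- seq_len(n)
    gc <- 0.45 + 0.08 * sin(i / 9 + ph[1]) + 0.05 * sin(i / 23 + ph[2]) +
      stats::rnorm(n, 0, 0.01)
    S4Vectors::mcols(gr)$gc <- pmin(pmax(gc, 0.25), 0.65)
  })
  gr
}

#' Simulate negative-binomial bin counts from a copy-number truth
#'
#' Per-bin counts are drawn as
#' `NB(mean = mean_depth * CN/ploidy * g(gc), size = dispersion)`, where
#' `g` is a quadratic GC response normalized to mean 1 over the bins and
#' `dispersion` is the NB size parameter (`Var = mu + mu^2/size`;
#' `dispersion = Inf` gives the Poisson limit). Bins on CN 0 segments have
#' mean exactly 0 and therefore count exactly 0.
#'
#' @param truth a [groundTruthCN()] `GRanges` (attribute `ploidy`).
#' @param bins `GRanges` of sorted, non-overlapping bins with `gc` metadata
#'   (e.g. [toyGenomeBins()]); bins must fall inside the truth tiling.
#' @param mean_depth expected reads per bin at `CN == ploidy` and neutral
#'   GC.
#' @param dispersion NB size parameter (>0, or `Inf` for Poisson).
#' @param gc_bias_coeffs `c(b1, b2)`: linear and quadratic GC-bias
#'   coefficients; `c(0, 0)` disables GC bias.
#' @param seed integer seed.
#' @return a [CNAProfile-class] whose bins carry `gc`, `count` and the
#'   per-bin `true_cn` (kept for oracle tests).
#' @examples
#' tr <- exampleTruthCN()
#' p <- simulateBinCounts(tr, toyGenomeBins(), mean_depth = 100,
#'                        dispersion = 10, seed = 1)
#' p
#' @export
simulateBinCounts <- function(truth, bins = toyGenomeBins(),
                              mean_depth = 100, dispersion = 10,
                              gc_bias_coeffs = c(0, 0), seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (length(bins) > 1L && !S4Vectors::isSorted(bins))
    stop("bins must be sorted and non-overlapping")
  pl <- attr(truth, "ploidy") %||% 2
  ov <- GenomicRanges::findOverlaps(bins, truth, select = "first")
  if (anyNA(ov)) stop("bins do not tile the truth's genome")
  cn <- S4Vectors::mcols(truth)$cn[ov]
  gc <- S4Vectors::mcols(bins)$gc
  gcc <- gc - mean(gc)
  g <- 1 + gc_bias_coeffs[1] * gcc + gc_bias_coeffs[2] * gcc^2
  g <- pmax(g, 0.05)
  g <- g / mean(g)
  mu <- mean_depth * cn / pl * g
  localSeed(seed, {
    cnt <- if (is.infinite(dispersion)) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), size = dispersion, mu = mu)
    gr <- bins
    S4Vectors::mcols(gr)$count <- as.integer(cnt)
    S4Vectors::mcols(gr)$true_cn <- cn
    CNAProfile(gr, ploidy = pl)
  })
}
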