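#' Single-cell library quality control
#'
#' A whole-genome-amplified single-cell library is sequenced only when at
#' least 8 of its 12 control qPCR loci amplified at the expected melting
#' temperature with a cycle threshold strictly below 30.
#'
#' @param record data.frame with exactly 12 rows and columns `locus`,
#'   `tm_ok` (logical: amplified at expected Tm) and `ct` (cycle
#'   threshold, > 0; may be NA when amplification failed).
#' @param min_pass minimum passing loci (default 8).
#' @param ct_max cycle-threshold bound (strict `<`; default 30).
#' @return list: `pass` (logical), `n_pass`, `locus_pass` (logical vector),
#'   `reasons` (character).
#' @examples
#' rec <- data.frame(locus = paste0("L", 1:12),
#'                   tm_ok = c(rep(TRUE, 9), rep(FALSE, 3)),
#'                   ct = c(rep(25, 9), rep(35, 3)))
#' qcLibrary(rec)$pass
#' @export
qcLibrary <- function(record, min_pass = 8L, ct_max = 30) {
  assertCols(record, c("locus", "tm_ok", "ct"), "QC record")
  if (nrow(record) != 12L)
    stop("QC record must contain exactly 12 loci (got ", nrow(record), ")")
  if (any(!is.na(record$ct) & record$ct <= 0))
    stop("Ct values must be > 0")
  lp <- record$tm_ok & !is.na(record$ct) & record$ct < ct_max
  n <- sum(lp)
  reasons <- character(0)
  if (n < min_pass)
    reasons <- sprintf("only %d/12 loci amplified at expected Tm with Ct < %g (need >= %d)",
                       n, ct_max, min_pass)
  list(pass = n >= min_pass, n_pass = n, locus_pass = lp,
       reasons = reasons)
}

#' Normalize bin counts and correct GC bias
#'
#' Counts are scaled to mean 1, then divided by a lowess fit of ratio
#' against GC fraction (the smooth multiplicative GC response), and
#' rescaled to mean 1 again. Zero-count bins are retained.
#'
#' @param profile a [CNAProfile-class] with raw counts.
#' @param gc_span lowess span for the GC fit.
#' @param gc_correct set `FALSE` to skip GC correction.
#' @return the profile with a `ratio` metadata column on its bins.
#' @export
normalizeBins <- function(profile, gc_span = 0.3, gc_correct = TRUE) {
  stopifnot(is(profile, "CNAProfile"))
  b <- profile@bins
  if (length(b) < 100L) stop("need >= 100 bins")
  cnt <- S4Vectors::mcols(b)$count
  if (all(cnt == 0)) stop("all-zero counts")
  ratio <- cnt / mean(cnt)
  if (gc_correct) {
    gc <- S4Vectors::mcols(b)$gc
    # fit the GC response on putatively copy-neutral bins (ratio within a
    # factor 2 of the median) so focal gains/losses do not bend the curve
    med <- stats::median(ratio[ratio > 0])
    neutral <- ratio > 0.5 * med & ratio < 2 * med
    if (sum(neutral) < 50L) neutral <- ratio > 0
    # correct only when a quadratic GC response is actually present:
    # on GC-flat libraries the smoother would merely re-inject its own
    # fitting noise into the profile
    qf <- stats::lm(ratio[neutral] ~ gc[neutral] + I(gc[neutral]^2))
    pvals <- summary(qf)$coefficients[-1, 4]
    if (any(pvals < 0.01)) {
      fit <- stats::lowess(gc[neutral], ratio[neutral], f = gc_span)
      g <- stats::approx(fit$x, fit$y, xout = gc, rule = 2)$y
      g <- pmax(g, 0.05)
      ratio <- ratio / g
      ratio <- ratio / mean(ratio)
    }
  }
  S4Vectors::mcols(b)$ratio <- ratio
  methods::initialize(profile, bins = b)
}

# Exact penalized changepoint detection of one numeric series by optimal
# partitioning: minimizes total within-segment SSE + penalty per
# breakpoint over ALL segmentations (O(n^2) dynamic program; chromosomes
# hold at most a few hundred bins). Greedy binary splitting can commit to
# a poor first cut at low SNR; the exact optimum cannot. Returns sorted
# breakpoints (last index of each left segment).
segmentSeries <- function(x, penalty, min_size = 3L) {
  n <- length(x)
  if (n < 2L * min_size) return(integer(0))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {  # sum of squared residuals of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    max(s2 - s^2 / (j - i + 1), 0)
  }
  # F[j+1]: optimal cost of x[1..j]; last[j+1]: previous breakpoint
  F <- rep(Inf, n + 1L); F[1] <- -penalty
  last <- integer(n + 1L)
  for (j in seq_len(n)) {
    if (j < min_size) next
    starts <- 0:(j - min_size)
    starts <- starts[starts == 0L | starts >= min_size]
    for (i in starts) {
      if (!is.finite(F[i + 1L])) next
      cost <- F[i + 1L] + penalty + sse(i + 1L, j)
      if (cost < F[j + 1L]) { F[j + 1L] <- cost; last[j + 1L] <- i }
    }
  }
  bps <- integer(0)
  j <- n
  while (j > 0L) {
    i <- last[j + 1L]
    if (i > 0L) bps <- c(i, bps)
    j <- i
  }
  bps
}

#' Segment a normalized copy-number profile
#'
#' Per-chromosome penalized changepoint detection on log2 ratios: exact
#' optimal partitioning under a per-breakpoint penalty of
#' `penalty_scale * sigma^2 * log(n)`, with `sigma` estimated robustly
#' from successive differences (median absolute difference / sqrt(2)
#' scaling). Before segmentation, isolated outliers are shrunk toward a
#' running median (single low-count bins otherwise masquerade as
#' breakpoints; genuine multi-bin shifts are untouched). Segments never
#' cross chromosome boundaries.
#'
#' @param profile a normalized [CNAProfile-class] (see [normalizeBins()]).
#' @param penalty_scale multiplier on the BIC-like penalty (default 2).
#' @param min_size minimum segment length in bins (default 3).
#' @param transform scale on which changepoints are sought: `"log2"`
#'   (default; floored at `min_ratio` to guard zero-count bins) or
#'   `"sqrt"`.
#' @param undo_sd undo a split whose flanking segment means differ by
#'   fewer than this many standard errors (0 disables).
#' @param min_ratio floor applied before taking log2.
#' @return the profile with populated `segments` (`GRanges` with
#'   `n_bins`, `mean_ratio`).
#' @export
segmentProfile <- function(profile, penalty_scale = 2, min_size = 3L,
                           transform = c("log2", "sqrt"),
                           undo_sd = 3, min_ratio = 0.01) {
  transform <- match.arg(transform)
  stopifnot(is(profile, "CNAProfile"))
  b <- profile@bins
  if (is.null(S4Vectors::mcols(b)$ratio))
    stop("profile must be normalized first (see normalizeBins)")
  chroms <- unique(as.character(GenomicRanges::seqnames(b)))
  segs <- list()
  for (ch in chroms) {
    sel <- as.character(GenomicRanges::seqnames(b)) == ch
    idx <- which(sel)
    r <- S4Vectors::mcols(b)$ratio[idx]
    if (length(r) < 2L)
      stop("need >= 2 bins per chromosome (", ch, ")")
    x <- if (transform == "sqrt") sqrt(pmax(r, 0))
         else log2(pmax(r, min_ratio))
    dif <- diff(x)
    sigma <- max(stats::median(abs(dif)) / (sqrt(2) * stats::qnorm(0.75)),
                 1e-3)
    # smooth isolated outliers against a running median (true level
    # shifts span several bins and are untouched)
    rm_ <- stats::runmed(x, k = min(5L, length(x) - (1 - length(x) %% 2)))
    res <- x - rm_
    xw <- rm_ + pmin(pmax(res, -2.5 * sigma), 2.5 * sigma)
    pen <- penalty_scale * sigma^2 * log(length(x))
    bps <- segmentSeries(xw, penalty = pen, min_size = min_size)
    # undo splits whose flanking means differ by less than undo_sd
    # standard errors (selection inflates the apparent shift of short
    # noise runs; genuine copy-number steps clear this bar)
    while (length(bps)) {
      bounds <- c(0L, bps, length(x))
      tt <- vapply(seq_along(bps), function(q) {
        i <- bounds[q] + 1L; k <- bounds[q + 1L]; j <- bounds[q + 2L]
        n1 <- k - i + 1L; n2 <- j - k
        abs(mean(xw[i:k]) - mean(xw[(k + 1L):j])) /
          (sigma * sqrt(1 / n1 + 1 / n2))
      }, numeric(1))
      if (min(tt) < undo_sd) bps <- bps[-which.min(tt)] else break
    }
    bounds <- c(0L, bps, length(x))
    for (s in seq_len(length(bounds) - 1L)) {
      i <- idx[bounds[s] + 1L]; j <- idx[bounds[s + 1L]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch,
        start = GenomicRanges::start(b)[i],
        end = GenomicRanges::end(b)[j],
        n_bins = bounds[s + 1L] - bounds[s],
        mean_ratio = mean(r[(bounds[s] + 1L):bounds[s + 1L]]))
    }
  }
  sd_ <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(sd_$chrom,
    IRanges::IRanges(start = sd_$start, end = sd_$end),
    n_bins = sd_$n_bins, mean_ratio = sd_$mean_ratio)
  methods::initialize(profile, segments = gr)
}

#' Call integer copy numbers per segment
#'
#' `CN = round(ploidy * segment mean ratio / baseline)`, clamped at zero,
#' where the baseline is the median per-bin ratio: under the near-diploid
#' assumption the modal bin sits at `CN = ploidy`, and recentering on it
#' removes the downward bias that mean-scaling suffers on aneuploid
#' genomes (gains inflate the mean, pushing every ratio below its integer
#' target). An optional grid search over a global ploidy scaling
#' (minimizing the bin-weighted distance of scaled segment ratios to
#' integers) is available but off by default for determinism.
#'
#' @param profile a segmented [CNAProfile-class].
#' @param ploidy assumed baseline ploidy (default the profile's).
#' @param recenter rescale so the median bin ratio maps to `ploidy`
#'   (default TRUE).
#' @param ploidy_grid optional numeric vector of candidate ploidies to
#'   search (e.g. `seq(1.5, 4, by = 0.05)`); `NULL` (default) uses
#'   `ploidy` as is; overrides `recenter`.
#' @return the profile with `cn` on its segments and `cn` per bin.
#' @export
callIntegerCN <- function(profile, ploidy = NULL, recenter = TRUE,
                          ploidy_grid = NULL) {
  stopifnot(is(profile, "CNAProfile"))
  if (!length(profile@segments))
    stop("profile must be segmented first (see segmentProfile)")
  pl <- ploidy %||% profile@ploidy
  s <- profile@segments
  mr <- S4Vectors::mcols(s)$mean_ratio
  w <- S4Vectors::mcols(s)$n_bins
  baseline <- 1
  if (!is.null(ploidy_grid)) {
    err <- vapply(ploidy_grid, function(p)
      sum(w * (p * mr - round(p * mr))^2), numeric(1))
    pl <- ploidy_grid[which.min(err)]
  } else if (recenter) {
    br <- S4Vectors::mcols(profile@bins)$ratio
    baseline <- stats::median(br[br > 0])
  }
  cn <- pmax(round(pl * mr / baseline), 0)
  S4Vectors::mcols(s)$cn <- as.integer(cn)
  # propagate to bins
  b <- profile@bins
  ov <- GenomicRanges::findOverlaps(b, s, select = "first")
  S4Vectors::mcols(b)$cn <- as.integer(cn[ov])
  methods::initialize(profile, segments = s, bins = b, ploidy = pl)
}

#' Coverage-uniformity quality metrics
#'
#' Index of dispersion (sample variance / mean of raw bin counts), the
#' Lorenz curve of cumulative count share versus cumulative bin share
#' (counts sorted ascending), and the Gini coefficient from the
#' trapezoidal area under the Lorenz curve, plus a read-count histogram.
#'
#' @param profile a [CNAProfile-class] (raw counts), or a numeric count
#'   vector.
#' @param hist_breaks breaks for the count histogram.
#' @return list of class `CoverageQuality`: `index_of_dispersion`,
#'   `lorenz` (data.frame `bin_share`, `count_share` including (0,0)),
#'   `gini`, `histogram` (an [graphics::hist()] object, not plotted).
#' @export
profileQuality <- function(profile, hist_breaks = 30) {
  cnt <- if (is(profile, "CNAProfile"))
    S4Vectors::mcols(profile@bins)$count else as.numeric(profile)
  if (length(cnt) < 2L) stop("need >= 2 bins")
  m <- mean(cnt)
  if (m == 0) stop("mean count is zero")
  iod <- stats::var(cnt) / m
  s <- sort(cnt)
  n <- length(s)
  lor <- data.frame(bin_share = c(0, seq_len(n) / n),
                    count_share = c(0, cumsum(s) / sum(s)))
  area <- sum(diff(lor$bin_share) *
                (lor$count_share[-1] + lor$count_share[-(n + 1)]) / 2)
  gini <- 1 - 2 * area
  h <- graphics::hist(cnt, breaks = hist_breaks, plot = FALSE)
  structure(list(index_of_dispersion = iod, lorenz = lor,
                 gini = gini, histogram = h),
            class = "CoverageQuality")
}

#' @export
print.CoverageQuality <- function(x, ...) {
  cat(sprintf("CoverageQuality: index of dispersion %.3f, Gini %.3f\n",
              x$index_of_dispersion, x$gini))
  invisible(x)
}

#' Concordance between two copy-number profiles
#'
#' Pearson correlation over shared bins, computed on integer copy numbers
#' (default) or on normalized log2 ratios.
#'
#' @param a,b two [CNAProfile-class] objects on identical bin grids.
#' @param on `"cn"` or `"ratio"`.
#' @param min_ratio floor before log2 when `on = "ratio"`.
#' @return Pearson r.
#' @export
profileConcordance <- function(a, b, on = c("cn", "ratio"),
                               min_ratio = 0.01) {
  on <- match.arg(on)
  ga <- a@bins; gb <- b@bins
  if (length(ga) != length(gb) ||
      !all(as.character(GenomicRanges::seqnames(ga)) ==
             as.character(GenomicRanges::seqnames(gb))) ||
      !all(GenomicRanges::start(ga) == GenomicRanges::start(gb)))
    stop("profiles are on different bin grids")
  va <- S4Vectors::mcols(ga)[[on]]
  vb <- S4Vectors::mcols(gb)[[on]]
  if (is.null(va) || is.null(vb))
    stop("both profiles need a '", on, "' bin column")
  if (on == "ratio") {
    va <- log2(pmax(va, min_ratio)); vb <- log2(pmax(vb, min_ratio))
  }
  stats::cor(va, vb)
}

#' Annotate driver genes on gained and lost segments
#'
#' Interval-overlap join (half-open BED semantics) of a gene table against
#' the called segments. A gene overlapping several segments is assigned the
#' maximal-overlap segment (ties to the higher copy number) and flagged as
#' boundary-spanning. Only genes on non-neutral segments (CN different
#' from ploidy) are reported.
#'
#' @param profile a called [CNAProfile-class].
#' @param genes data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `gene` name, or a `GRanges` with a `gene` column.
#' @return data.frame: `gene`, `chrom`, `start`, `end`, `cn`, `direction`
#'   (`gained`/`lost`), `boundary_spanning`.
#' @export
annotateDrivers <- function(profile, genes) {
  stopifnot(is(profile, "CNAProfile"))
  s <- profile@segments
  if (!length(s) || is.null(S4Vectors::mcols(s)$cn))
    stop("profile must have called segments (see callIntegerCN)")
  if (is.data.frame(genes)) {
    assertCols(genes, c("chrom", "start", "end", "gene"), "gene table")
    if (!nrow(genes))
      return(data.frame(gene = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        cn = integer(), direction = character(),
                        boundary_spanning = logical()))
    if (any(genes$end <= genes$start)) stop("malformed BED: end <= start")
    gr <- GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      gene = genes$gene)
  } else gr <- genes
  ov <- GenomicRanges::findOverlaps(gr, s)
  if (!length(ov))
    return(data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric(), cn = integer(),
                      direction = character(),
                      boundary_spanning = logical()))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ovw <- GenomicRanges::width(GenomicRanges::pintersect(gr[qh], s[sh]))
  cn <- S4Vectors::mcols(s)$cn[sh]
  pl <- profile@ploidy
  rows <- lapply(unique(qh), function(q) {
    i <- which(qh == q)
    # maximal overlap; ties go to the higher copy number
    best <- i[order(-ovw[i], -cn[i])][1]
    data.frame(gene = S4Vectors::mcols(gr)$gene[q],
               chrom = as.character(GenomicRanges::seqnames(gr))[q],
               start = GenomicRanges::start(gr)[q] - 1L,
               end = GenomicRanges::end(gr)[q],
               cn = cn[best],
               direction = if (cn[best] > pl) "gained"
                           else if (cn[best] < pl) "lost" else "neutral",
               boundary_spanning = length(i) > 1L)
  })
  out <- do.call(rbind, rows)
  out[out$direction != "neutral", , drop = FALSE]
}

#' Run the full copy-number pipeline on raw bin counts
#'
#' [normalizeBins()], [segmentProfile()], [callIntegerCN()] in sequence.
#'
#' @param profile raw [CNAProfile-class].
#' @param ... passed to [segmentProfile()].
#' @inheritParams callIntegerCN
#' @return called profile.
#' @export
callCNAProfile <- function(profile, ploidy = NULL, ploidy_grid = NULL,
                           ...) {
  p <- normalizeBins(profile)
  p <- segmentProfile(p, ...)
  callIntegerCN(p, ploidy = ploidy, ploidy_grid = ploidy_grid)
}
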