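#' @importFrom EBImage opening makeBrush gblur resize bwlabel fillHull
#'   dilate medianFilter
NULL

#' Correct uneven illumination in one channel
#'
#' Estimates the smooth multiplicative background as a heavy Gaussian blur
#' (default sigma = 1/8 of the smaller image dimension) of the
#' morphologically opened image, divides it out, and rescales so the global
#' median is preserved. The blur is evaluated on a block-mean downsampled
#' grid (the background is smooth by construction) and bilinearly
#' upsampled, which changes nothing on flat images and keeps the operation
#' cheap on large fields.
#'
#' @param img numeric matrix (one channel).
#' @param sigma Gaussian sigma of the background estimate, pixels; default
#'   `min(dim(img)) / 8`.
#' @param opening_size diameter (px) of the disc structuring element used
#'   to suppress foreground objects before background estimation.
#' @return corrected matrix, same dimensions.
#' @examples
#' flat <- matrix(100, 64, 64)
#' max(abs(correctIllumination(flat) - flat))
#' @export
correctIllumination <- function(img, sigma = NULL,
                                opening_size = 15) {
  if (!length(img)) stop("empty image")
  if (all(img == 0)) {
    warning("all-zero image; returned unchanged")
    return(img)
  }
  if (is.null(sigma)) sigma <- min(dim(img)) / 8
  # EBImage morphology assumes intensities in [0,1]; rescale around it
  mx <- max(img)
  op <- EBImage::opening(img / mx,
                         EBImage::makeBrush(opening_size, "disc")) * mx
  f <- max(1L, floor(sigma / 16))
  if (f > 1L) {
    small <- blockMean(op, f)
    bg <- normBlur(small, sigma / f)
    bg <- EBImage::resize(bg, w = nrow(img), h = ncol(img))
  } else {
    bg <- normBlur(op, sigma)
  }
  bg <- pmax(bg, 1e-8)
  out <- img / bg
  med <- stats::median(out)
  if (med > 0) out <- out * (stats::median(img) / med)
  matrix(pmax(out, 0), nrow(img), ncol(img))
}

# Gaussian blur with normalized convolution (zero padding divided by the
# blurred support), so the local average is unbiased at image borders
normBlur <- function(m, sigma) {
  num <- EBImage::gblur(m, sigma = sigma, boundary = 0)
  den <- EBImage::gblur(matrix(1, nrow(m), ncol(m)), sigma = sigma,
                        boundary = 0)
  num / pmax(den, 1e-12)
}

# block-mean downsampling by integer factor f (pads the far edges by
# replication so dimensions need not divide evenly)
blockMean <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  H <- ceiling(h / f) * f; W <- ceiling(w / f) * f
  if (H != h) m <- m[c(seq_len(h), rep(h, H - h)), , drop = FALSE]
  if (W != w) m <- m[, c(seq_len(w), rep(w, W - w)), drop = FALSE]
  # average over f x f tiles
  m1 <- rowsum(m, rep(seq_len(H / f), each = f))
  t(rowsum(t(m1), rep(seq_len(W / f), each = f))) / f^2
}

#' Apply illumination correction and denoising to every channel
#'
#' @param field a [FluorescentField-class].
#' @param denoise_size median-filter kernel edge (odd), or 0 to skip.
#' @param ... passed to [correctIllumination()].
#' @return a preprocessed [FluorescentField-class].
#' @export
preprocessField <- function(field, denoise_size = 3, ...) {
  ch <- lapply(field@channels, function(m) {
    m <- correctIllumination(m, ...)
    if (denoise_size > 0) m <- denoiseImage(m, size = denoise_size)
    m
  })
  FluorescentField(DAPI = ch$DAPI, CK = ch$CK, CD45 = ch$CD45,
                   pixelSize = field@pixelSize)
}

#' Median-filter denoising
#'
#' 3x3 kernels use an exact vectorized median-of-9 sorting network with
#' replicated borders; larger odd kernels delegate to
#' [EBImage::medianFilter()]. Output values stay within the input range.
#'
#' @param img numeric matrix.
#' @param size odd kernel edge length (default 3).
#' @return filtered matrix.
#' @export
denoiseImage <- function(img, size = 3) {
  if (size %% 2 == 0) stop("kernel size must be odd")
  if (size == 1) return(img)
  if (size == 3) return(median3x3(img))
  mx <- max(img)
  if (mx == 0) return(img)
  EBImage::medianFilter(img / mx, (size - 1L) / 2) * mx
}

# exact 3x3 median (C kernel, replicated borders)
median3x3 <- function(m) {
  storage.mode(m) <- "double"
  .Call(C_median3x3, m)
}

#' Otsu threshold over a 256-bin histogram
#'
#' Exhaustively maximizes the between-class variance over all cut points of
#' a 256-bin histogram (regardless of image bit depth); ties are broken
#' toward the smallest threshold. Foreground is `intensity > t`.
#'
#' @param x numeric matrix/vector of intensities, or a discrete histogram
#'   given as `list(counts =, values =)` (equal-width ordered bins).
#' @param nbins histogram bins used for image input.
#' @return threshold `t` on the intensity scale (the upper edge of the last
#'   background bin for image input; the bin value of the last background
#'   bin for histogram input).
#' @examples
#' otsuThreshold(list(counts = c(4, 2, 0, 0, 3, 5), values = 0:5))
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  if (is.list(x)) {
    counts <- as.numeric(x$counts); vals <- as.numeric(x$values)
    edges <- NULL
  } else {
    r <- range(x)
    if (r[1] == r[2]) stop("degenerate histogram: constant image")
    edges <- seq(r[1], r[2], length.out = nbins + 1L)
    counts <- tabulate(pmin(pmax(
      findInterval(x, edges, rightmost.closed = TRUE), 1L), nbins), nbins)
    vals <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  }
  n <- length(counts)
  if (sum(counts > 0) < 2L) stop("degenerate histogram: constant image")
  p <- counts / sum(counts)
  w0 <- cumsum(p)[-n]
  m0 <- cumsum(p * vals)[-n]
  mt <- sum(p * vals)
  w1 <- 1 - w0
  sb <- numeric(n - 1L)
  ok <- w0 > 0 & w1 > 0
  sb[ok] <- (mt * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  k <- which.max(sb)  # which.max takes the first (smallest) maximizer
  if (is.null(edges)) vals[k] else edges[k + 1L]
}

#' Segment nucleated objects from the DAPI channel
#'
#' Thresholds the DAPI channel with [otsuThreshold()] (floored at a robust
#' background level, median + 5 MAD, so featureless fields yield zero
#' objects rather than split noise), fills holes, labels 8-connected
#' components, flags border-touching objects, and counts DAPI local maxima
#' per object as the nucleus count (>= 2 marks a multi-nucleated object,
#' the circulating-tumor-microemboli candidate signal). Touching nuclei are
#' deliberately not watershed-split.
#'
#' @param field a (preprocessed) [FluorescentField-class].
#' @param min_area_px discard components smaller than this (pixels).
#' @param maxima_sigma Gaussian scale (px) for the nucleus-maxima search.
#' @return an object of class `SegmentationResult`: list with `labels`
#'   (integer matrix, 0 = background), `table` (data.frame: `label`, `x`,
#'   `y`, `area_px`, `border`, `nuclei_count`), `threshold`, `pixel_size`.
#' @export
segmentObjects <- function(field, min_area_px = 5L, maxima_sigma = 2) {
  dapi <- getChannel(field, "DAPI")
  t <- tryCatch(otsuThreshold(dapi), error = function(e) NA_real_)
  empty <- list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                table = data.frame(label = integer(), x = numeric(),
                                   y = numeric(), area_px = integer(),
                                   border = logical(),
                                   nuclei_count = integer()),
                threshold = t, pixel_size = field@pixelSize)
  class(empty) <- "SegmentationResult"
  if (is.na(t)) return(empty)
  floorT <- stats::median(dapi) + 5 * stats::mad(dapi)
  t <- max(t, floorT)
  mask <- dapi > t
  if (!any(mask)) return(empty)
  mask <- EBImage::fillHull(mask)
  L <- label8(mask)
  # drop sub-minimal specks, relabel consecutively
  areas <- tabulate(L[L > 0L])
  keep <- which(areas >= min_area_px)
  if (!length(keep)) return(empty)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- L > 0L
  L[pos] <- remap[L[pos]]
  K <- length(keep)

  ind <- which(L > 0L)
  lab <- L[ind]
  h <- nrow(L)
  rows <- (ind - 1L) %% h + 1L
  cols <- (ind - 1L) %/% h + 1L
  area <- tabulate(lab, K)
  cx <- rowsum(as.numeric(cols), lab)[, 1] / area
  cy <- rowsum(as.numeric(rows), lab)[, 1] / area
  border <- rowsum(as.numeric(rows == 1L | rows == h |
                              cols == 1L | cols == ncol(L)), lab)[, 1] > 0

  nuc <- countNuclei(dapi, L, K, t, maxima_sigma)

  res <- list(labels = L,
              table = data.frame(label = seq_len(K), x = cx, y = cy,
                                 area_px = area, border = border,
                                 nuclei_count = nuc),
              threshold = t, pixel_size = field@pixelSize)
  class(res) <- "SegmentationResult"
  res
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  storage.mode(L) <- "integer"
  K <- max(L)
  if (K < 2L) return(L)
  h <- nrow(L); w <- ncol(L)
  a1 <- L[-h, -w]; b1 <- L[-1, -1]   # NW-SE diagonal pairs
  a2 <- L[-h, -1]; b2 <- L[-1, -w]   # NE-SW diagonal pairs
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (!nrow(pairs)) return(L)
  parent <- seq_len(K)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(K), find, integer(1))
  remap <- match(root, sort(unique(root)))
  pos <- L > 0L
  L[pos] <- remap[L[pos]]
  L
}

# count well-separated local maxima of the smoothed DAPI signal per object
countNuclei <- function(dapi, L, K, t, sigma = 2, min_sep = 3) {
  sm <- EBImage::gblur(dapi, sigma = sigma, boundary = "replicate")
  storage.mode(sm) <- "double"
  nb <- .Call(C_max8, sm)
  isMax <- sm >= nb & L > 0L & dapi > t
  h <- nrow(sm)
  idx <- which(isMax)
  if (!length(idx)) return(rep(1L, K))
  lab <- L[idx]
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  nuc <- rep(1L, K)
  for (g in unique(lab)) {
    sel <- lab == g
    if (sum(sel) == 1L) { nuc[g] <- 1L; next }
    pts <- cbind(rows[sel], cols[sel])
    # single-link clustering: maxima closer than min_sep are one nucleus
    d <- as.matrix(stats::dist(pts)) < min_sep
    comp <- seq_len(nrow(pts))
    repeat {
      new <- apply(d, 1, function(r) min(comp[r]))
      if (identical(new, comp)) break
      comp <- new
    }
    nuc[g] <- length(unique(comp))
  }
  nuc
}

#' Extract per-object morphology and intensity features
#'
#' One feature vector per segmented object: morphology (area, perimeter by
#' Vossepoel-Smeulders-corrected contour length, equivalent diameter,
#' eccentricity from second moments, solidity against the convex hull, form
#' factor `4*pi*A/P^2`) and, per channel, mean / median / max / integrated
#' intensity, the local background (median of a 2-5 px annulus around the
#' object, excluding all object pixels), the background-corrected mean and
#' the fold-over-background ratio used by the marker gate.
#'
#' @param field the [FluorescentField-class] the objects came from.
#' @param seg a `SegmentationResult` from [segmentObjects()].
#' @return data.frame, one row per object; micrometer units for lengths and
#'   areas, intensity units for signals.
#' @export
extractFeatures <- function(field, seg) {
  stopifnot(inherits(seg, "SegmentationResult"))
  L <- seg$labels
  K <- nrow(seg$table)
  px <- field@pixelSize
  if (K == 0L) return(emptyFeatureTable())
  ind <- which(L > 0L)
  lab <- L[ind]
  if (any(tabulate(lab, K) == 0L)) stop("object with empty pixel set")
  h <- nrow(L)
  rows <- (ind - 1L) %% h + 1L
  cols <- (ind - 1L) %/% h + 1L
  area <- tabulate(lab, K)
  cx <- rowsum(as.numeric(cols), lab)[, 1] / area
  cy <- rowsum(as.numeric(rows), lab)[, 1] / area
  # central second moments (+1/12 pixel-integration term)
  mxx <- rowsum(cols^2, lab)[, 1] / area - cx^2 + 1 / 12
  myy <- rowsum(rows^2, lab)[, 1] / area - cy^2 + 1 / 12
  mxy <- rowsum(rows * cols, lab)[, 1] / area - cx * cy
  tr <- mxx + myy
  dd <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + dd) / 2; l2 <- pmax((tr - dd) / 2, 0)
  ecc <- sqrt(pmax(1 - l2 / pmax(l1, 1e-12), 0))

  per <- perimeterAndHull(L, K)
  perim_px <- per$perimeter
  solidity <- pmin(pmax(area / pmax(per$hull_area, area), 1e-6), 1)
  ff <- pmin(4 * pi * area / pmax(perim_px, 1e-9)^2, 1.2)

  out <- data.frame(label = seq_len(K), x = cx, y = cy,
                    border = seg$table$border,
                    nuclei_count = seg$table$nuclei_count,
                    area_um2 = area * px^2,
                    perimeter_um = perim_px * px,
                    eq_diameter_um = 2 * sqrt(area / pi) * px,
                    eccentricity = ecc,
                    solidity = solidity,
                    form_factor = ff)

  ringlab <- annulusLabels(L)
  bgmask <- which(L == 0L)
  for (nm in c("DAPI", "CK", "CD45")) {
    chm <- getChannel(field, nm)
    v <- chm[ind]
    pre <- tolower(nm)
    int_ <- rowsum(v, lab)[, 1]
    mean_ <- int_ / area
    gs <- groupStats(v, lab, K)
    med_ <- gs$median; max_ <- gs$max
    bg <- rep(stats::median(chm[bgmask]), K)  # fallback: global background
    bgs <- groupStats(chm[ringlab$ind], ringlab$lab, K)
    got <- which(!is.na(bgs$median))
    bg[got] <- bgs$median[got]
    out[[paste0(pre, "_mean")]] <- mean_
    out[[paste0(pre, "_median")]] <- med_
    out[[paste0(pre, "_max")]] <- max_
    out[[paste0(pre, "_integrated")]] <- int_
    out[[paste0(pre, "_bg")]] <- bg
    out[[paste0(pre, "_corr_mean")]] <- pmax(mean_ - bg, 0)
    out[[paste0(pre, "_fold")]] <- mean_ / pmax(bg, 1e-8)
  }
  out
}

# groupwise median and max via one radix sort (labels must be in 1..K);
# groups with no elements return NA
groupStats <- function(v, lab, K) {
  n <- tabulate(lab, K)
  ord <- order(lab, v, method = "radix")
  vo <- v[ord]
  ends <- cumsum(n)
  starts <- ends - n + 1L
  med <- rep(NA_real_, K); mx <- rep(NA_real_, K)
  got <- n > 0L
  m1 <- starts + (n - 1L) %/% 2L
  m2 <- starts + n %/% 2L
  med[got] <- (vo[m1[got]] + vo[m2[got]]) / 2
  mx[got] <- vo[ends[got]]
  list(median = med, max = mx)
}

emptyFeatureTable <- function() {
  cols <- c("label", "x", "y", "border", "nuclei_count", "area_um2",
            "perimeter_um", "eq_diameter_um", "eccentricity", "solidity",
            "form_factor",
            as.vector(outer(c("dapi", "ck", "cd45"),
                            c("_mean", "_median", "_max", "_integrated",
                              "_bg", "_corr_mean", "_fold"), paste0)))
  df <- as.data.frame(stats::setNames(
    replicate(length(cols), numeric(0), simplify = FALSE), cols))
  df$border <- logical(0); df$label <- integer(0)
  df$nuclei_count <- integer(0)
  df
}

# perimeter (marching-squares iso-contour length, C kernel) and convex
# hull area per object (hull of boundary pixels, with pixel-coverage
# correction)
perimeterAndHull <- function(L, K) {
  perimeter <- .Call(C_perimLabel, L, as.integer(K))
  h <- nrow(L); w <- ncol(L)
  # boundary pixels: any 4-neighbor differs (zero-padded borders)
  Lp <- matrix(0L, h + 2L, w + 2L)
  Lp[2:(h + 1L), 2:(w + 1L)] <- L
  ctr <- Lp[2:(h + 1L), 2:(w + 1L)]
  bnd <- ctr > 0L & (Lp[1:h, 2:(w + 1L)] != ctr |
                     Lp[3:(h + 2L), 2:(w + 1L)] != ctr |
                     Lp[2:(h + 1L), 1:w] != ctr |
                     Lp[2:(h + 1L), 3:(w + 2L)] != ctr)
  bi <- which(bnd)
  blab <- ctr[bi]
  brow <- (bi - 1L) %% h + 1L
  bcol <- (bi - 1L) %/% h + 1L
  ordb <- order(blab, method = "radix")
  blab <- blab[ordb]; brow <- brow[ordb]; bcol <- bcol[ordb]
  nb <- tabulate(blab, K)
  ends <- cumsum(nb); starts <- ends - nb + 1L
  hull_area <- numeric(K)
  for (g in seq_len(K)) {
    if (nb[g] == 0L) { hull_area[g] <- 1; next }
    px <- bcol[starts[g]:ends[g]]; py <- brow[starts[g]:ends[g]]
    if (nb[g] <= 2L) { hull_area[g] <- nb[g]; next }
    hp <- grDevices::chull(px, py)
    hx <- px[hp]; hy <- py[hp]
    a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    hullPerim <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    hull_area[g] <- a + hullPerim / 2 + 1  # pixel-coverage correction
  }
  list(perimeter = perimeter, hull_area = hull_area)
}

# assign each pixel of the 2-5 px annulus around every object to that
# object (grayscale max-dilation of the label image, rescaled to [0,1]
# for EBImage); pixels within 2 px of any object are excluded
annulusLabels <- function(L) {
  K <- max(L)
  if (K == 0L) return(list(ind = integer(0), lab = integer(0)))
  Ls <- L / K
  outer5 <- round(EBImage::dilate(Ls, EBImage::makeBrush(11, "disc")) * K)
  inner2 <- EBImage::dilate(Ls, EBImage::makeBrush(5, "disc"))
  ind <- which(outer5 > 0 & inner2 == 0)
  list(ind = ind, lab = as.integer(outer5[ind]))
}

#' Debris filter specification
#'
#' Measurement bounds used to exclude non-cellular objects. Defaults (area
#' 30-700 um^2, solidity >= 0.7, DAPI fold-over-background >= 2) are
#' deliberate, configurable placeholders: real deployments tune them on
#' their own optics.
#'
#' @param min_area,max_area object area bounds, um^2.
#' @param min_solidity minimum solidity.
#' @param min_dapi_fold minimum DAPI mean / local background ratio
#'   (nucleation evidence).
#' @return list of class `DebrisFilterSpec`.
#' @export
debrisFilterSpec <- function(min_area = 30, max_area = 700,
                             min_solidity = 0.7, min_dapi_fold = 2) {
  if (min_area >= max_area) stop("min_area must be < max_area")
  structure(list(min_area = min_area, max_area = max_area,
                 min_solidity = min_solidity,
                 min_dapi_fold = min_dapi_fold),
            class = "DebrisFilterSpec")
}

#' Partition a feature table into cells and debris
#'
#' @param table feature table from [extractFeatures()].
#' @param spec a [debrisFilterSpec()].
#' @return list with `kept` and `removed` data.frames; the two partition
#'   the input exactly.
#' @export
filterDebris <- function(table, spec = debrisFilterSpec()) {
  stopifnot(inherits(spec, "DebrisFilterSpec"))
  if (!nrow(table))
    return(list(kept = table, removed = table))
  assertCols(table, c("area_um2", "solidity", "dapi_fold"),
             "feature table")
  pass <- table$area_um2 >= spec$min_area &
    table$area_um2 <= spec$max_area &
    table$solidity >= spec$min_solidity &
    table$dapi_fold >= spec$min_dapi_fold
  list(kept = table[pass, , drop = FALSE],
       removed = table[!pass, , drop = FALSE])
}

#' Run the full image pipeline on a raw field
#'
#' Convenience wrapper: [preprocessField()], [segmentObjects()],
#' [extractFeatures()], [filterDebris()].
#'
#' @param field raw [FluorescentField-class].
#' @param filter_spec a [debrisFilterSpec()].
#' @param ... passed to [segmentObjects()].
#' @return list: `features` (kept rows), `debris` (removed rows),
#'   `segmentation` (the `SegmentationResult`).
#' @export
processField <- function(field, filter_spec = debrisFilterSpec(), ...) {
  pf <- preprocessField(field)
  seg <- segmentObjects(pf, ...)
  feats <- extractFeatures(pf, seg)
  fl <- filterDebris(feats, filter_spec)
  list(features = fl$kept, debris = fl$removed, segmentation = seg)
}
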