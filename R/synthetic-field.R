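#' Specify a synthetic immunofluorescence field
#'
#' Builds the parameter object consumed by [renderField()]. The defaults
#' emulate a high-content screening field after negative enrichment of 5 mL
#' blood: a 16-bit camera with a dim flat background, nucleated leukocytes
#' (DAPI+/CD45+), rare large epithelial tumor cells (DAPI+/CK+/CD45-),
#' sub-cellular debris, a smooth multiplicative illumination gradient and
#' additive Gaussian camera noise.
#'
#' Per-class staining amplitudes are truncated-normal draws (per channel);
#' each cell is rendered as an isotropic Gaussian blob of scale
#' `radius / 2`, truncated at three blob sigmas, so the nominal radius
#' encloses essentially all of the signal mass.
#'
#' @param width,height field size in pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_wbc,n_ctc,n_debris number of leukocytes, tumor cells and debris
#'   specks to place.
#' @param cluster_spec `list(n, size)`: number of CTC clusters (circulating
#'   tumor microemboli) and cells per cluster; cluster members are placed
#'   adjacent/overlapping on purpose. Cluster cells are *additional* to
#'   `n_ctc`.
#' @param illumination_gradient amplitude of the multiplicative low-order
#'   polynomial illumination field (0 = perfectly flat), unitless, >= 0.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param baseline camera offset, intensity units.
#' @param intensity_spec per-class, per-channel amplitude mean/sd
#'   (intensity units); see the default for the structure.
#' @param cell_radius_spec per-class radius mean/sd in micrometers.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return a list of class `FieldSpec`.
#' @seealso [renderField()]
#' @export
fieldSpec <- function(width = 1024, height = 1024, pixel_size = 1,
                      n_wbc = 200, n_ctc = 2, n_debris = 30,
                      cluster_spec = list(n = 0, size = 3),
                      illumination_gradient = 0.3,
                      noise_sd = 30, baseline = 500,
                      intensity_spec = list(
                        CTC    = list(DAPI = c(12000, 2000),
                                      CK   = c(15000, 3000),
                                      CD45 = c(100, 80)),
                        WBC    = list(DAPI = c(10000, 2000),
                                      CK   = c(120, 80),
                                      CD45 = c(9000, 2000)),
                        debris = list(DAPI = c(250, 150),
                                      CK   = c(400, 300),
                                      CD45 = c(300, 250))),
                      cell_radius_spec = list(
                        CTC = c(8, 1.2), WBC = c(5, 0.8),
                        debris = c(1.5, 0.5)),
                      seed = 1L) {
  if (width <= 0 || height <= 0)
    stop("field dimensions must be positive")
  if (n_wbc < 0 || n_ctc < 0 || n_debris < 0 || cluster_spec$n < 0)
    stop("object counts must be >= 0")
  if (illumination_gradient < 0)
    stop("illumination_gradient must be >= 0")
  if (any(vapply(intensity_spec, function(cl)
        any(vapply(cl, `[`, numeric(1), 1) < 0), logical(1))))
    stop("intensity means must be >= 0")
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 n_wbc = n_wbc, n_ctc = n_ctc, n_debris = n_debris,
                 cluster_spec = cluster_spec,
                 illumination_gradient = illumination_gradient,
                 noise_sd = noise_sd, baseline = baseline,
                 intensity_spec = intensity_spec,
                 cell_radius_spec = cell_radius_spec,
                 seed = seed),
            class = "FieldSpec")
}

# truncated-at-zero normal draw
rtnorm0 <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0)

# smooth multiplicative illumination field, mean 1
illuminationField <- function(width, height, amplitude) {
  u <- matrix(rep(seq(0, 1, length.out = width), each = height),
              height, width)
  v <- matrix(rep(seq(0, 1, length.out = height), width), height, width)
  a <- stats::runif(5, -1, 1)
  p <- a[1] * u + a[2] * v + a[3] * u * v + a[4] * u^2 + a[5] * v^2
  f <- 1 + amplitude * (p - mean(p))
  f <- pmax(f, 0.05)
  f / mean(f)
}

# Rejection-sampled non-overlapping centers. footprint = exclusion radius
# per object (px). Returns matrix [x, y] or errors after bounded retries.
placeCenters <- function(n, width, height, footprint, retries = 100L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- numeric(n); ys <- numeric(n)
  cell <- max(footprint) * 2 + 1
  gx <- max(1L, ceiling(width / cell)); gy <- max(1L, ceiling(height / cell))
  buckets <- vector("list", gx * gy)
  bidx <- function(x, y) {
    (pmin(gy, pmax(1L, ceiling(y / cell))) - 1L) * gx +
      pmin(gx, pmax(1L, ceiling(x / cell)))
  }
  for (i in seq_len(n)) {
    m <- footprint[i] + 1
    placed <- FALSE
    for (try in seq_len(retries)) {
      x <- stats::runif(1, m, width - m); y <- stats::runif(1, m, height - m)
      bx <- ceiling(x / cell); by <- ceiling(y / cell)
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        cx <- bx + dx; cy <- by + dy
        if (cx < 1 || cx > gx || cy < 1 || cy > gy) next
        for (j in buckets[[(cy - 1L) * gx + cx]]) {
          if ((x - xs[j])^2 + (y - ys[j])^2 <
              (footprint[i] + footprint[j])^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        xs[i] <- x; ys[i] <- y
        b <- bidx(x, y)
        buckets[[b]] <- c(buckets[[b]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping objects after ",
           retries, " retries each; field too crowded (placed ", i - 1L, ")")
  }
  cbind(x = xs, y = ys)
}

# Gaussian blob patch (truncated at 3 sigma): returns row ids, col ids and
# the weight matrix so the caller can add it in place per channel.
blobPatch <- function(h, w, x, y, sigma) {
  r <- ceiling(3 * sigma)
  c0 <- max(1L, floor(x - r)); c1 <- min(w, ceiling(x + r))
  r0 <- max(1L, floor(y - r)); r1 <- min(h, ceiling(y + r))
  if (c0 > c1 || r0 > r1) return(NULL)
  cc <- c0:c1; rr <- r0:r1
  d2 <- outer((rr - y)^2, (cc - x)^2, "+")
  wgt <- exp(-d2 / (2 * sigma^2))
  wgt[d2 > (3 * sigma)^2] <- 0
  list(rr = rr, cc = cc, wgt = wgt)
}

#' Render a synthetic multi-channel field with ground truth
#'
#' Places the requested numbers of leukocyte-like, tumor-like and debris
#' objects without overlap (rejection sampling; CTC cluster members are
#' deliberately adjacent), renders each as a truncated Gaussian blob with
#' class-dependent per-channel amplitudes, applies the multiplicative
#' illumination gradient to the stained signal and adds Gaussian camera
#' noise on top of the camera baseline. Pixel values are rounded and clamped
#' to the 16-bit range.
#'
#' The generative model for a pixel is
#' `I(x,y) = illum(x,y) * (baseline + sum_cells A_c * exp(-d^2 / (2*s_c^2)))
#'  + N(0, noise_sd)`.
#'
#' @param spec a [fieldSpec()].
#' @return a list with elements `field` (a [FluorescentField-class]),
#'   `truth` (data.frame: `class`, `x`, `y` in pixels, `radius_um`,
#'   `radius_px`, `cluster_id`, `amp_DAPI`, `amp_CK`, `amp_CD45`) and
#'   `illumination` (the multiplicative field, for oracle tests).
#' @examples
#' out <- renderField(fieldSpec(width = 256, height = 256, n_wbc = 20,
#'                              n_ctc = 1, n_debris = 5, seed = 7))
#' table(out$truth$class)
#' @export
renderField <- function(spec) {
  stopifnot(inherits(spec, "FieldSpec"))
  localSeed(spec$seed, {
    w <- spec$width; h <- spec$height; px <- spec$pixel_size
    ncl <- spec$cluster_spec$n %||% 0
    csz <- if (ncl > 0) spec$cluster_spec$size else 0

    classes <- c(rep("CTC", spec$n_ctc), rep("WBC", spec$n_wbc),
                 rep("debris", spec$n_debris))
    rs <- spec$cell_radius_spec
    radius_um <- numeric(length(classes))
    for (cl in unique(classes)) {
      idx <- classes == cl
      radius_um[idx] <- pmax(rtnorm0(sum(idx), rs[[cl]][1], rs[[cl]][2]),
                             0.5)
    }
    radius_px <- radius_um / px
    # exclusion radius: the 3-sigma blob support (sigma = r/2)
    foot <- 1.5 * radius_px
    # clusters occupy a disk of ~2 CTC radii around the anchor
    clR_um <- pmax(stats::rnorm(ncl, rs$CTC[1], rs$CTC[2]), 0.5)
    anchorFoot <- if (ncl > 0) 1.5 * (clR_um / px) + 2.5 * rs$CTC[1] / px
                  else numeric(0)
    pts <- placeCenters(length(classes) + ncl, w, h,
                        c(foot, anchorFoot))

    truth <- data.frame(class = classes,
                        x = pts[seq_along(classes), "x"],
                        y = pts[seq_along(classes), "y"],
                        radius_um = radius_um, radius_px = radius_px,
                        cluster_id = rep(NA_integer_, length(classes)),
                        stringsAsFactors = FALSE)
    # cluster members: adjacent CTCs around each anchor
    if (ncl > 0) {
      for (k in seq_len(ncl)) {
        ax <- pts[length(classes) + k, "x"]
        ay <- pts[length(classes) + k, "y"]
        rk <- pmax(rtnorm0(csz, rs$CTC[1], rs$CTC[2]), 0.5) / px
        ang <- stats::runif(csz, 0, 2 * pi)
        # chain each member off the previous one so the cluster is a
        # connected string of touching cells (centers at 3/4 of the
        # summed radii: overlapping but individually resolvable nuclei)
        step <- c(0, (rk[-csz] + rk[-1]) * 0.75)
        mx <- ax + cumsum(step * cos(ang))
        my <- ay + cumsum(step * sin(ang))
        truth <- rbind(truth, data.frame(
          class = "CTC", x = mx, y = my, radius_um = rk * px,
          radius_px = rk, cluster_id = k, stringsAsFactors = FALSE))
      }
    }

    chn <- c("DAPI", "CK", "CD45")
    for (ch in chn) {
      amp <- numeric(nrow(truth))
      for (cl in unique(truth$class)) {
        idx <- truth$class == cl
        ms <- spec$intensity_spec[[cl]][[ch]]
        amp[idx] <- rtnorm0(sum(idx), ms[1], ms[2])
      }
      truth[[paste0("amp_", ch)]] <- amp
    }

    sigD <- matrix(0, h, w); sigK <- matrix(0, h, w)
    sig45 <- matrix(0, h, w)
    if (nrow(truth)) {
      aD <- truth$amp_DAPI; aK <- truth$amp_CK; a45 <- truth$amp_CD45
      for (i in seq_len(nrow(truth))) {
        p <- blobPatch(h, w, truth$x[i], truth$y[i], truth$radius_px[i] / 2)
        if (is.null(p)) next
        sigD[p$rr, p$cc] <- sigD[p$rr, p$cc] + aD[i] * p$wgt
        sigK[p$rr, p$cc] <- sigK[p$rr, p$cc] + aK[i] * p$wgt
        sig45[p$rr, p$cc] <- sig45[p$rr, p$cc] + a45[i] * p$wgt
      }
    }
    signal <- list(DAPI = sigD, CK = sigK, CD45 = sig45)

    illum <- if (spec$illumination_gradient > 0)
      illuminationField(w, h, spec$illumination_gradient)
    else matrix(1, h, w)

    imgs <- lapply(signal, function(s) {
      v <- round(illum * (spec$baseline + s) +
                   stats::rnorm(length(s), 0, spec$noise_sd))
      v[v < 0] <- 0
      v[v > 65535] <- 65535
      v
    })

    list(field = FluorescentField(DAPI = imgs$DAPI, CK = imgs$CK,
                                  CD45 = imgs$CD45, pixelSize = px),
         truth = truth, illumination = illum)
  })
}
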