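#' Specify a two-class cell-feature population
#'
#' Defines the class-conditional distributions used by
#' [sampleFeatureTable()] as a stand-in for a manually annotated cell
#' gallery. Features are drawn as Gaussians on log (intensities, area) and
#' logit (shape) scales, so positivity/range constraints hold by
#' construction, and are reported back-transformed on the natural scale.
#'
#' `separation` rescales the inter-class mean-difference vector; its units
#' are within-class standard deviations of the most informative channel
#' (the CK marker), i.e. `separation = 6` puts the class means 6 CK-sds
#' apart (and proportionally in the other coordinates). At `separation = 0`
#' the two class-conditional distributions are identical. Draws are
#' truncated at 3 within-class sds per coordinate (staining intensity and
#' shape scores are physically bounded), so at `separation >= 6` the two
#' classes do not overlap in any informative coordinate and the Bayes
#' error is zero.
#'
#' @param prevalence fraction of CTC rows, in (0, 1).
#' @param separation unitless multiplier on the inter-class mean distance
#'   (see Details); default 6, a cleanly separable population.
#' @param sds per-feature within-class standard deviations on the
#'   transformed scale (named numeric vector).
#' @return a list of class `PopulationSpec`.
#' @export
populationSpec <- function(prevalence = 0.10, separation = 6,
                           sds = c(dapi = 0.45, ck = 0.60, cd45 = 0.60,
                                   area = 0.35, ecc = 0.70, sol = 0.50,
                                   ff = 0.50)) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  if (any(sds < 0)) stop("sds must be >= 0")
  if (separation < 0) stop("separation must be >= 0")
  # common center on transformed scales
  center <- c(dapi = log(10000), ck = log(1500), cd45 = log(1200),
              area = log(110), ecc = -0.2, sol = 2.9, ff = 2.2)
  # inter-class direction, in units of per-feature sd; CK carries weight 1
  # so `separation` reads as CK-sds between class means
  direction <- c(dapi = 0.25, ck = 1, cd45 = -1, area = 0.5,
                 ecc = -0.3, sol = 0.2, ff = 0.2)
  structure(list(prevalence = prevalence, separation = separation,
                 center = center, direction = direction, sds = sds),
            class = "PopulationSpec")
}

#' Draw a labeled synthetic cell-feature table
#'
#' @param spec a [populationSpec()].
#' @param n number of rows (>= 2).
#' @param seed integer seed; fixed spec + seed reproduces the table exactly.
#' @return data.frame with a `label` factor (`WBC`, `CTC`) and natural-scale
#'   feature columns `dapi_corr_mean`, `ck_corr_mean`, `cd45_corr_mean`
#'   (intensity units), `area_um2`, `eccentricity`, `solidity`,
#'   `form_factor`.
#' @examples
#' tab <- sampleFeatureTable(populationSpec(), n = 100, seed = 1)
#' table(tab$label)
#' @export
sampleFeatureTable <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "PopulationSpec"))
  if (n < 2) stop("n must be >= 2")
  if (spec$separation == 0 && all(spec$sds == 0))
    warning("degenerate population: zero variance and zero separation")
  localSeed(seed, {
    lab <- factor(ifelse(stats::runif(n) < spec$prevalence, "CTC", "WBC"),
                  levels = c("WBC", "CTC"))
    delta <- spec$separation * spec$direction * spec$sds
    k <- length(spec$center)
    # truncated normal (|z| <= 3): staining intensities and shape scores
    # are physically bounded, so class-conditional tails do not cross
    # once the means are >= 6 sd apart
    pb <- stats::pnorm(c(-3, 3))
    z <- matrix(stats::qnorm(stats::runif(n * k, pb[1], pb[2])), n, k) %*%
      diag(spec$sds, k)
    mu <- matrix(rep(spec$center, each = n), n, k)
    sgn <- ifelse(lab == "CTC", 0.5, -0.5)
    x <- mu + outer(sgn, delta) + z
    colnames(x) <- names(spec$center)
    data.frame(label = lab,
               dapi_corr_mean = exp(x[, "dapi"]),
               ck_corr_mean   = exp(x[, "ck"]),
               cd45_corr_mean = exp(x[, "cd45"]),
               area_um2       = exp(x[, "area"]),
               eccentricity   = stats::plogis(x[, "ecc"]),
               solidity       = stats::plogis(x[, "sol"]),
               form_factor    = stats::plogis(x[, "ff"]))
  })
}
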