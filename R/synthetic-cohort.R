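#' Specify a simulated clinical cohort
#'
#' Per-group parameters for [simulateCohort()]: CTC counts follow a
#' zero-inflated negative binomial (structural-zero probability `pi`,
#' NB mean `mu` and size/dispersion `k`, so `Var = mu + mu^2/k` in the NB
#' component); recurrence event times are exponential with the group hazard
#' and independently right-censored at a uniform follow-up time.
#'
#' The default `HCC` group is calibrated so that the closed-form positivity
#' `1 - (pi + (1-pi) * (k/(k+mu))^k)` equals 59.3% and the marginal mean
#' `(1-pi)*mu` equals 1.37 CTC per 5 mL; the healthy-donor group is
#' calibrated to 0.8% positivity. Benign liver-disease groups sit in
#' between. Within the ZINB family those two HCC constraints cap the
#' attainable count SD near 1.7, below the heavier spread real cohorts
#' show; see the methods vignette.
#'
#' @param groups named list; each element is
#'   `list(pi=, mu=, k=, hazard=, afp=)` with `pi` in `[0,1]`, `mu >= 0`,
#'   `k > 0`, `hazard` the monthly exponential recurrence hazard (0 = no
#'   events) and `afp` the (meanlog, sdlog) of a log-normal serum AFP in
#'   ng/mL.
#' @param censor_range uniform censoring window in months.
#' @return a list of class `CohortSpec`.
#' @export
cohortSpec <- function(groups = list(
                         HCC    = list(pi = 0.15, mu = 1.6118, k = 2.1,
                                       hazard = 0.030, afp = c(4.6, 2.0)),
                         CHB_LC = list(pi = 0.0,  mu = 0.10,   k = 0.5,
                                       hazard = 0, afp = c(2.2, 1.0)),
                         BHL    = list(pi = 0.0,  mu = 0.03,   k = 0.5,
                                       hazard = 0, afp = c(1.6, 0.8)),
                         HD     = list(pi = 0.0,  mu = 0.00803, k = 10,
                                       hazard = 0, afp = c(1.2, 0.6))),
                       censor_range = c(6, 33)) {
  for (g in names(groups)) {
    p <- groups[[g]]
    if (p$pi < 0 || p$pi > 1) stop("pi must be in [0,1] (group ", g, ")")
    if (p$mu < 0) stop("mu must be >= 0 (group ", g, ")")
    if (p$k <= 0) stop("k must be > 0 (group ", g, ")")
  }
  structure(list(groups = groups, censor_range = censor_range),
            class = "CohortSpec")
}

#' Closed-form CTC positivity of a zero-inflated negative binomial
#'
#' `1 - (pi + (1 - pi) * P_NB(0; mu, k))`, the exact probability of a
#' non-zero count; used as the oracle the simulated positivity must
#' converge to.
#'
#' @param pi structural-zero probability.
#' @param mu,k negative-binomial mean and size.
#' @return probability of count >= 1.
#' @export
zinbPositivity <- function(pi, mu, k) {
  1 - (pi + (1 - pi) * (k / (k + mu))^k)
}

#' Simulate a per-subject cohort table
#'
#' @param spec a [cohortSpec()].
#' @param n_per_group integer, subjects per group (recycled over groups, or
#'   a named vector).
#' @param seed integer seed.
#' @return data.frame: `id`, `group`, `ctc_count`, `afp` (ng/mL),
#'   `recurrence` (0/1), `ttr` (months, time to recurrence or censoring).
#' @examples
#' coh <- simulateCohort(cohortSpec(), n_per_group = 50, seed = 1)
#' aggregate(ctc_count ~ group, coh, mean)
#' @export
simulateCohort <- function(spec, n_per_group, seed = 1L) {
  stopifnot(inherits(spec, "CohortSpec"))
  gn <- names(spec$groups)
  if (is.null(names(n_per_group)))
    n_per_group <- stats::setNames(rep_len(n_per_group, length(gn)), gn)
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1")
  localSeed(seed, {
    out <- do.call(rbind, lapply(gn, function(g) {
      p <- spec$groups[[g]]
      n <- n_per_group[[g]]
      zero <- stats::runif(n) < p$pi
      cnt <- ifelse(zero, 0L,
                    stats::rnbinom(n, size = p$k, mu = p$mu))
      ev_time <- if (p$hazard > 0) stats::rexp(n, rate = p$hazard)
                 else rep(Inf, n)
      cens <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
      afp <- if (!is.null(p$afp))
        stats::rlnorm(n, p$afp[1], p$afp[2]) else rep(NA_real_, n)
      data.frame(group = g, ctc_count = as.integer(cnt),
                 afp = afp,
                 recurrence = as.integer(ev_time <= cens),
                 ttr = pmin(ev_time, cens),
                 stringsAsFactors = FALSE)
    }))
    out$id <- sprintf("S%04d", seq_len(nrow(out)))
    out[, c("id", "group", "ctc_count", "afp", "recurrence", "ttr")]
  })
}

#' Simulate a spike-in recovery experiment
#'
#' Each replicate recovers `Binomial(n_spiked, recovery_prob)` of the cells
#' spiked into healthy-donor blood, the generative model behind
#' recovery-rate and precision (%CV) validation.
#'
#' @param n_spiked number of cells spiked (scalar or vector; vectors are
#'   crossed with replicates).
#' @param recovery_prob per-cell recovery probability in `[0, 1]`.
#' @param replicates replicates per spike level.
#' @param seed integer seed.
#' @return data.frame: `n_spiked`, `replicate`, `recovered`.
#' @examples
#' spikeInExperiment(20, 0.756, replicates = 3, seed = 2)
#' @export
spikeInExperiment <- function(n_spiked, recovery_prob = 0.756,
                              replicates = 5, seed = 1L) {
  if (recovery_prob < 0 || recovery_prob > 1)
    stop("recovery_prob must be in [0, 1]")
  if (any(n_spiked < 0)) stop("n_spiked must be >= 0")
  localSeed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        n_spiked = n_spiked)[, 2:1]
    grid$recovered <- stats::rbinom(nrow(grid), grid$n_spiked,
                                    recovery_prob)
    grid
  })
}
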