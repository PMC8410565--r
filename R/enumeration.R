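#' @importFrom survival Surv survfit survdiff
NULL

#' Enumerate CTCs and microemboli in one sample
#'
#' CTC count: each final-label CTC object contributes its nucleus count (a
#' multi-nucleated cluster object counts every nucleus). CTM (circulating
#' tumor microemboli) count: one per cluster of two or more adjoining CTCs
#' -- every multi-nucleated CTC object is one CTM, and singleton CTC
#' objects whose centroids fall within `adjacency_um` of each other are
#' grouped into connected components, each component of two or more
#' counting once.
#'
#' @param calls classified table (from [classifyCells()]) for one sample:
#'   needs `is_ctc`, `x`, `y`, `nuclei_count`, `eq_diameter_um`.
#' @param cells_screened total objects screened for this sample (defaults
#'   to `nrow(calls)`).
#' @param sample_id sample identifier.
#' @param blood_volume_ml processed blood volume; counts are also reported
#'   normalized to 5 mL.
#' @param adjacency_um centroid distance treated as adjoining; default one
#'   mean cell diameter of the called CTCs.
#' @param pixel_size um/px used when `x`/`y` are in pixels.
#' @return list of class `SampleResult`: `sample_id`, `cells_screened`,
#'   `ctc_count`, `ctm_count`, `blood_volume_ml`, `ctc_per_5ml`,
#'   `ctm_per_5ml`.
#' @export
enumerateSample <- function(calls, cells_screened = nrow(calls),
                            sample_id = "sample", blood_volume_ml = 5,
                            adjacency_um = NULL, pixel_size = 1) {
  if (nrow(calls) == 0 || !any(calls$is_ctc)) {
    res <- list(sample_id = sample_id, cells_screened = cells_screened,
                ctc_count = 0L, ctm_count = 0L,
                blood_volume_ml = blood_volume_ml,
                ctc_per_5ml = 0, ctm_per_5ml = 0)
    class(res) <- "SampleResult"
    return(res)
  }
  assertCols(calls, c("is_ctc", "x", "y", "nuclei_count"), "calls table")
  ctc <- calls[calls$is_ctc, , drop = FALSE]
  ctc_count <- sum(pmax(ctc$nuclei_count, 1L))
  multi <- ctc$nuclei_count >= 2L
  if (is.null(adjacency_um)) {
    adjacency_um <- if ("eq_diameter_um" %in% names(ctc))
      mean(ctc$eq_diameter_um) else 15
  }
  # cluster singleton CTC objects by centroid adjacency
  single <- which(!multi)
  n_clusters <- 0L
  if (length(single) >= 2L) {
    pts <- cbind(ctc$x[single], ctc$y[single]) * pixel_size
    adj <- as.matrix(stats::dist(pts)) <= adjacency_um
    comp <- seq_len(nrow(pts))
    repeat {
      new <- apply(adj, 1, function(r) min(comp[r]))
      if (identical(new, comp)) break
      comp <- new
    }
    n_clusters <- sum(table(comp) >= 2L)
  }
  ctm_count <- sum(multi) + n_clusters
  res <- list(sample_id = sample_id, cells_screened = cells_screened,
              ctc_count = as.integer(ctc_count),
              ctm_count = as.integer(ctm_count),
              blood_volume_ml = blood_volume_ml,
              ctc_per_5ml = ctc_count * 5 / blood_volume_ml,
              ctm_per_5ml = ctm_count * 5 / blood_volume_ml)
  class(res) <- "SampleResult"
  res
}

#' @export
print.SampleResult <- function(x, ...) {
  cat(sprintf("SampleResult %s: %d CTC, %d CTM (of %d screened, %g mL)\n",
              x$sample_id, x$ctc_count, x$ctm_count, x$cells_screened,
              x$blood_volume_ml))
  invisible(x)
}

#' Spike-in recovery rate
#'
#' `recovered / spiked * 100`. Values above 100 are allowed with a warning
#' (possible miscount); `spiked = 0` is undefined and an error.
#'
#' @param recovered,spiked cell counts (vectorized).
#' @return percent recovery.
#' @examples recoveryRate(15, 20)
#' @export
recoveryRate <- function(recovered, spiked) {
  if (any(spiked == 0))
    stop("recovery rate undefined for spiked = 0")
  r <- recovered / spiked * 100
  if (any(r > 100))
    warning("recovery rate above 100%: possible miscount")
  r
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, mean != 0.
#' @return percent CV.
#' @examples cvPercent(c(8, 10, 12))
#' @export
cvPercent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("%CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' CTC positivity rate of a cohort group
#'
#' @param cohort cohort table with `group` and `ctc_count`.
#' @param group group label to summarize.
#' @param threshold positivity cut (count >= threshold; default 1).
#' @return list: `percent`, `positive`, `n`.
#' @examples
#' coh <- data.frame(group = "HCC", ctc_count = c(0, 1, 3, 0))
#' positivityRate(coh, "HCC")
#' @export
positivityRate <- function(cohort, group, threshold = 1) {
  assertCols(cohort, c("group", "ctc_count"), "cohort table")
  counts <- cohort$ctc_count[cohort$group == group]
  if (!length(counts)) stop("empty group: ", group)
  pos <- sum(counts >= threshold)
  list(percent = 100 * pos / length(counts), positive = pos,
       n = length(counts))
}

# exact binomial (Clopper-Pearson) 95% CI helper
binomCI <- function(x, n, conf = 0.95) {
  as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
}

#' Count-threshold diagnostic sensitivity and specificity
#'
#' @param cases,controls CTC counts in the two arms.
#' @param threshold test positive iff count >= threshold.
#' @return list of class `DiagnosticSummary`: `threshold`, `sensitivity`,
#'   `specificity` (fractions), `sens_ci`, `spec_ci` (exact binomial 95%
#'   CIs), and the underlying counts.
#' @examples
#' diagnosticMetrics(c(0, 1, 2, 5), c(0, 0, 0, 1), threshold = 1)
#' @export
diagnosticMetrics <- function(cases, controls, threshold = 1) {
  if (!length(cases) || !length(controls))
    stop("both arms must be nonempty")
  tp <- sum(cases >= threshold); fn <- length(cases) - tp
  tn <- sum(controls < threshold); fp <- length(controls) - tn
  structure(list(threshold = threshold,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 sens_ci = binomCI(tp, tp + fn),
                 spec_ci = binomCI(tn, tn + fp),
                 TP = tp, FN = fn, TN = tn, FP = fp),
            class = "DiagnosticSummary")
}

#' @export
print.DiagnosticSummary <- function(x, ...) {
  cat(sprintf(
    "DiagnosticSummary (count >= %g): sens %.1f%% [%.1f, %.1f], spec %.1f%% [%.1f, %.1f]\n",
    x$threshold, 100 * x$sensitivity, 100 * x$sens_ci[1],
    100 * x$sens_ci[2], 100 * x$specificity, 100 * x$spec_ci[1],
    100 * x$spec_ci[2]))
  invisible(x)
}

#' ROC AUC for count-valued diagnostics
#'
#' The Mann-Whitney probability that a random case exceeds a random
#' control, ties counted one half (equivalently the trapezoidal area under
#' the ROC curve swept over all thresholds). The 95% CI uses DeLong's
#' method (via pROC) or a stratified bootstrap.
#'
#' @param cases,controls count vectors.
#' @param ci_method `"delong"`, `"bootstrap"` or `"none"`.
#' @param boot number of bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return list: `auc`, `ci` (or NULL), `ci_method`.
#' @examples
#' rocAucCounts(c(2, 3), c(0, 1))
#' @export
rocAucCounts <- function(cases, controls,
                         ci_method = c("delong", "bootstrap", "none"),
                         boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (!length(cases) || !length(controls))
    stop("both arms must be nonempty")
  scores <- c(cases, controls)
  pos <- c(rep(TRUE, length(cases)), rep(FALSE, length(controls)))
  auc <- aucRank(scores, pos)
  ci <- NULL
  if (ci_method == "delong") {
    r <- suppressMessages(pROC::roc(
      response = pos, predictor = scores, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE)))
    ci <- as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  } else if (ci_method == "bootstrap") {
    localSeed(seed, {
      bs <- replicate(boot, {
        aucRank(c(sample(cases, replace = TRUE),
                  sample(controls, replace = TRUE)),
                pos)
      })
    })
    ci <- as.numeric(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  list(auc = auc, ci = ci, ci_method = ci_method)
}

#' Youden-optimal integer threshold for a count diagnostic
#'
#' @param cases,controls count vectors.
#' @return list: `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youdenThreshold <- function(cases, controls) {
  cand <- sort(unique(c(cases, controls)))
  cand <- unique(pmax(cand, 1))
  best <- NULL
  for (t in cand) {
    sens <- mean(cases >= t); spec <- mean(controls < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$J)
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   J = j)
  }
  best
}

#' Two-group comparisons used in cohort reporting
#'
#' Thin dispatch over the standard tests: Mann-Whitney U (unpaired
#' Wilcoxon; exact p for small tie-free samples), paired Wilcoxon
#' signed-rank (all-tied pairs return p = 1 by convention), Student's t,
#' chi-squared (continuity-corrected for 2x2 by default) and Fisher's
#' exact test.
#'
#' @param x,y numeric vectors, or for `chi2`/`fisher` a 2x2 matrix passed
#'   as `x` (`y` ignored).
#' @param test one of `"mann-whitney"`, `"wilcoxon-paired"`, `"t"`,
#'   `"chi2"`, `"fisher"`.
#' @param correct continuity correction for the chi-squared test.
#' @return list: `test`, `statistic`, `p_value`.
#' @examples
#' compareGroups(c(1, 2), c(3, 4), "mann-whitney")
#' compareGroups(matrix(c(43, 16, 38, 48), 2), test = "chi2")
#' @export
compareGroups <- function(x, y = NULL,
                          test = c("mann-whitney", "wilcoxon-paired", "t",
                                   "chi2", "fisher"),
                          correct = TRUE) {
  test <- match.arg(test)
  res <- switch(test,
    "mann-whitney" = {
      h <- stats::wilcox.test(x, y)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    "wilcoxon-paired" = {
      if (length(x) != length(y))
        stop("paired test requires equal-length vectors")
      d <- x - y
      if (all(d == 0)) list(statistic = 0, p = 1)  # all ties: no evidence
      else {
        h <- stats::wilcox.test(x, y, paired = TRUE)
        list(statistic = unname(h$statistic), p = h$p.value)
      }
    },
    "t" = {
      h <- stats::t.test(x, y)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    "chi2" = {
      h <- stats::chisq.test(x, correct = correct)
      list(statistic = unname(h$statistic), p = h$p.value)
    },
    "fisher" = {
      h <- stats::fisher.test(x)
      list(statistic = unname(h$estimate %||% NA_real_), p = h$p.value)
    })
  list(test = test, statistic = res$statistic, p_value = res$p)
}

#' Kaplan-Meier recurrence analysis stratified by CTC status
#'
#' Product-limit estimates of recurrence-free fraction per group, the
#' log-rank test between groups, and median time to recurrence (the first
#' time the curve reaches 0.5; `NA` = not reached).
#'
#' @param cohort table with `ttr` (> 0), `recurrence` (0/1) and a grouping
#'   column.
#' @param group_col grouping column name; default stratifies by
#'   `ctc_count >= 1` when the column is absent.
#' @return list: `fit` (a [survival::survfit] object), `curves`
#'   (data.frame: group, time, surv), `logrank_chisq`, `logrank_p`,
#'   `median_ttr` (named vector), `cumulative_recurrence` (1 - final
#'   survival per group).
#' @export
kmRecurrence <- function(cohort, group_col = "ctc_status") {
  assertCols(cohort, c("ttr", "recurrence"), "cohort table")
  if (any(cohort$ttr <= 0)) stop("times must be > 0")
  if (!all(cohort$recurrence %in% c(0, 1)))
    stop("recurrence must be 0/1")
  df <- cohort
  if (!group_col %in% names(df)) {
    assertCols(df, "ctc_count", "cohort table")
    df[[group_col]] <- ifelse(df$ctc_count >= 1, "CTC>=1", "CTC=0")
  }
  if (any(table(df[[group_col]]) == 0)) stop("a group has zero subjects")
  df$.grp <- factor(df[[group_col]])
  fit <- survival::survfit(survival::Surv(ttr, recurrence) ~ .grp,
                           data = df)
  sm <- summary(fit)
  if (nlevels(df$.grp) > 1L) {
    grp <- if (!is.null(sm$strata)) sub("^\\.grp=", "", sm$strata)
           else rep(levels(df$.grp), 0)
  } else grp <- rep(levels(df$.grp), length(sm$time))
  curves <- data.frame(group = grp, time = sm$time, surv = sm$surv)
  lev <- levels(df$.grp)
  med <- vapply(lev, function(g) {
    cc <- curves[curves$group == g, , drop = FALSE]
    i <- which(cc$surv <= 0.5)
    if (length(i)) cc$time[min(i)] else NA_real_
  }, numeric(1))
  cum <- vapply(lev, function(g) {
    cc <- curves[curves$group == g, , drop = FALSE]
    if (nrow(cc)) 1 - min(cc$surv) else 0
  }, numeric(1))
  lr_chisq <- NA_real_; lr_p <- NA_real_
  if (nlevels(df$.grp) > 1L) {
    sd_ <- survival::survdiff(survival::Surv(ttr, recurrence) ~ .grp,
                              data = df)
    lr_chisq <- unname(sd_$chisq)
    lr_p <- stats::pchisq(sd_$chisq, df = nlevels(df$.grp) - 1,
                          lower.tail = FALSE)
  }
  list(fit = fit, curves = curves, logrank_chisq = lr_chisq,
       logrank_p = lr_p, median_ttr = med, cumulative_recurrence = cum)
}

#' Combined CTC + AFP logistic diagnosis (reconstruction)
#'
#' Logistic combination of the CTC count and log serum alpha-fetoprotein
#' for case/control discrimination, with the in-sample ROC AUC of the
#' combined score and of each component. This reconstructs a described
#' analysis form -- the original fitted coefficients were never released
#' -- so its AUC is illustrative, not a validated clinical model.
#'
#' @param cohort table with `group`, `ctc_count` and `afp` (ng/mL).
#' @param case_groups,control_groups group labels for the two arms.
#' @return list: `model` (a [stats::glm] fit), `auc_combined`,
#'   `auc_ctc`, `auc_afp`.
#' @export
combinedCtcAfp <- function(cohort, case_groups = "HCC",
                           control_groups = c("CHB_LC", "BHL", "HD")) {
  assertCols(cohort, c("group", "ctc_count", "afp"), "cohort table")
  df <- cohort[cohort$group %in% c(case_groups, control_groups), ,
               drop = FALSE]
  df <- df[!is.na(df$afp), , drop = FALSE]
  if (!nrow(df)) stop("no rows with AFP in the requested groups")
  df$case <- as.integer(df$group %in% case_groups)
  if (length(unique(df$case)) < 2L) stop("need both arms")
  fit <- stats::glm(case ~ ctc_count + log1p(afp), data = df,
                    family = stats::binomial())
  score <- stats::fitted(fit)
  list(model = fit,
       auc_combined = aucRank(score, df$case == 1),
       auc_ctc = aucRank(df$ctc_count, df$case == 1),
       auc_afp = aucRank(df$afp, df$case == 1))
}

#' Assemble a cohort-level report
#'
#' Per-group count summaries (mean, SD and median are reported side by
#' side), positivity, case/control diagnostics (ROC AUC with CI,
#' Youden-optimal threshold, sensitivity/specificity at the configured
#' cut) and -- when outcome columns are present -- Kaplan-Meier recurrence
#' by CTC status. Deterministic given its inputs.
#'
#' @param cohort cohort table (`group`, `ctc_count`, optional `recurrence`,
#'   `ttr`).
#' @param case_groups,control_groups group labels pooled as cases/controls
#'   for the diagnostic section (defaults: every non-`HD` group vs `HD`).
#' @param threshold positivity/diagnostic count threshold.
#' @return nested list of class `CohortReport` with sections `groups`,
#'   `diagnostics`, `survival` (NULL when outcomes are absent).
#' @export
cohortReport <- function(cohort, case_groups = NULL, control_groups = "HD",
                         threshold = 1) {
  assertCols(cohort, c("group", "ctc_count"), "cohort table")
  gs <- unique(cohort$group)
  if (is.null(case_groups)) case_groups <- setdiff(gs, control_groups)
  groups <- lapply(gs, function(g) {
    cnt <- cohort$ctc_count[cohort$group == g]
    pr <- positivityRate(cohort, g, threshold)
    list(group = g, n = length(cnt), mean = mean(cnt),
         sd = stats::sd(cnt), median = stats::median(cnt),
         positivity_percent = pr$percent, positive = pr$positive)
  })
  names(groups) <- gs
  cases <- cohort$ctc_count[cohort$group %in% case_groups]
  controls <- cohort$ctc_count[cohort$group %in% control_groups]
  diagnostics <- NULL
  if (length(cases) && length(controls)) {
    dm <- diagnosticMetrics(cases, controls, threshold)
    diagnostics <- list(
      auc = rocAucCounts(cases, controls),
      at_threshold = dm,
      youden = youdenThreshold(cases, controls))
  }
  surv <- NULL
  if (all(c("recurrence", "ttr") %in% names(cohort)) &&
      any(!is.na(cohort$recurrence))) {
    cc <- cohort[!is.na(cohort$recurrence) & !is.na(cohort$ttr) &
                   cohort$group %in% case_groups, , drop = FALSE]
    if (nrow(cc) && length(unique(cc$ctc_count >= threshold)) == 2L)
      surv <- kmRecurrence(transform(
        cc, ctc_status = ifelse(ctc_count >= threshold,
                                "CTC>=1", "CTC=0")))
  }
  structure(list(groups = groups, diagnostics = diagnostics,
                 survival = surv, threshold = threshold),
            class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport (positivity threshold >=", x$threshold, "CTC)\n")
  for (g in x$groups)
    cat(sprintf("  %-8s n=%3d  mean %.2f +/- %.2f, median %g, pos %.1f%%\n",
                g$group, g$n, g$mean, g$sd, g$median,
                g$positivity_percent))
  if (!is.null(x$diagnostics))
    cat(sprintf("  diagnosis: AUC %.3f [%.3f, %.3f]; Youden t=%g (sens %.1f%%, spec %.1f%%)\n",
                x$diagnostics$auc$auc, x$diagnostics$auc$ci[1],
                x$diagnostics$auc$ci[2], x$diagnostics$youden$threshold,
                100 * x$diagnostics$youden$sensitivity,
                100 * x$diagnostics$youden$specificity))
  if (!is.null(x$survival))
    cat(sprintf("  recurrence: log-rank p = %.4g\n", x$survival$logrank_p))
  invisible(x)
}
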