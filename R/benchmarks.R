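#' Five-family classifier benchmark on the default synthetic population
#'
#' Draws the default separable labeled cell-feature table, performs the
#' stratified 75/25 split, trains the five classifier families with
#' 10-fold cross-validated hyperparameter selection on the training
#' portion, and evaluates every family on the held-out 25%.
#'
#' @param n table size (default 4000).
#' @param prevalence CTC prevalence (default 0.10).
#' @param separation class separation, CK-sds (default 6).
#' @param seed integer seed driving the draw, the split and the training.
#' @param families families to run (default all five).
#' @return list: `metrics` (data.frame with one row per family: held-out
#'   `auc`, `recall`, `precision`, `accuracy`, `F1`, `FPR`), `models`,
#'   `split`.
#' @export
classifierBenchmark <- function(n = 4000, prevalence = 0.10,
                                separation = 6, seed = 1L,
                                families = c("GBM", "ADABOOST", "SVM",
                                             "RF", "XGB")) {
  tab <- sampleFeatureTable(
    populationSpec(prevalence = prevalence, separation = separation),
    n = n, seed = childSeed(seed, 11))
  sp <- splitDataset(tab, 0.75, seed = childSeed(seed, 12))
  models <- trainClassifiers(sp$train, families = families,
                             seed = childSeed(seed, 13))
  rows <- lapply(families, function(fam) {
    prob <- predict(models[[fam]], sp$test)
    ev <- evaluateClassifier(prob, sp$test$label, positive = "CTC")
    data.frame(family = fam, auc = ev$auc, recall = ev$recall,
               precision = ev$precision, accuracy = ev$accuracy,
               F1 = ev$F1, FPR = ev$FPR)
  })
  list(metrics = do.call(rbind, rows), models = models, split = sp)
}

# Render a set of training fields with known classes, run the image
# pipeline, and label extracted objects by nearest ground-truth centroid.
labeledTrainingFeatures <- function(n_fields = 2, n_wbc = 400, n_ctc = 60,
                                    n_debris = 40, width = 768,
                                    height = 768, pixel_size = 1.3,
                                    seed = 1L, match_px = 4) {
  out <- list()
  for (k in seq_len(n_fields)) {
    fs <- fieldSpec(width = width, height = height,
                    pixel_size = pixel_size, n_wbc = n_wbc,
                    n_ctc = n_ctc, n_debris = n_debris,
                    seed = childSeed(seed, 20 + k))
    r <- renderField(fs)
    pf <- processField(r$field)
    ft <- pf$features
    if (!nrow(ft)) next
    tr <- r$truth[r$truth$class != "debris", , drop = FALSE]
    d2 <- outer(ft$x, tr$x, "-")^2 + outer(ft$y, tr$y, "-")^2
    nearest <- apply(d2, 1, which.min)
    dist <- sqrt(d2[cbind(seq_len(nrow(ft)), nearest)])
    ft$label <- factor(
      ifelse(dist <= match_px & tr$class[nearest] == "CTC", "CTC", "WBC"),
      levels = c("WBC", "CTC"))
    out[[k]] <- ft
  }
  do.call(rbind, out)
}

#' Limit-of-detection analogue: one tumor cell among ten thousand
#' leukocytes
#'
#' For each replicate, renders fields totalling `n_wbc_total`
#' leukocyte-like cells plus exactly one CTC-like cell (default field
#' intensities, noise and illumination gradient), runs the full detection
#' pipeline -- preprocess, segment, featurize, debris-filter, marker gate
#' plus a classifier trained once on labeled synthetic fields -- and
#' enumerates CTCs.
#'
#' @param replicates number of independent replicates (default 20).
#' @param n_wbc_total leukocyte-like cells per replicate (default 10000).
#' @param seed integer seed.
#' @param family classifier family for the detection model (default XGB).
#' @param fields_per_replicate how many fields the cells are spread over.
#' @param width,height,pixel_size field geometry.
#' @return data.frame: `replicate`, `ctc_count`, `ctm_count`,
#'   `cells_screened`.
#' @export
lodExperiment <- function(replicates = 20, n_wbc_total = 10000, seed = 1L,
                          family = "XGB", fields_per_replicate = 4,
                          width = 1024, height = 1024, pixel_size = 1.3) {
  train <- labeledTrainingFeatures(seed = childSeed(seed, 1))
  train_cols <- c("label", setdiff(names(train),
                                   c("label", "x", "y", "border")))
  model <- trainClassifiers(train[train_cols], families = family,
                            seed = childSeed(seed, 2))[[family]]
  per_field <- rep(n_wbc_total %/% fields_per_replicate,
                   fields_per_replicate)
  per_field[1] <- per_field[1] + n_wbc_total %% fields_per_replicate
  res <- lapply(seq_len(replicates), function(rep) {
    calls <- list()
    screened <- 0L
    for (k in seq_len(fields_per_replicate)) {
      fs <- fieldSpec(width = width, height = height,
                      pixel_size = pixel_size,
                      n_wbc = per_field[k],
                      n_ctc = if (k == 1) 1L else 0L,
                      n_debris = 0L,
                      seed = childSeed(seed, 1000 + 37 * rep + k))
      r <- renderField(fs)
      pf <- processField(r$field)
      if (!nrow(pf$features)) next
      screened <- screened + nrow(pf$features)
      calls[[k]] <- classifyCells(model, pf$features)
    }
    calls <- do.call(rbind, calls)
    sr <- enumerateSample(calls, cells_screened = screened,
                          sample_id = sprintf("rep%02d", rep),
                          pixel_size = pixel_size)
    data.frame(replicate = rep, ctc_count = sr$ctc_count,
               ctm_count = sr$ctm_count, cells_screened = screened)
  })
  do.call(rbind, res)
}
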