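#' Marker gate specification
#'
#' Fold-over-background thresholds implementing the operational CTC
#' definition: a nucleated (DAPI+) intact cell, positive for the epithelial
#' marker (CK/EpCAM) and negative for the leukocyte marker (CD45).
#'
#' @param dapi_pos_fold DAPI mean/background fold at or above which a cell
#'   counts as nucleated.
#' @param ck_pos_fold CK fold at or above which the epithelial marker is
#'   positive.
#' @param cd45_neg_fold CD45 fold *below* which the cell is CD45-negative
#'   (at or above it the cell is CD45-positive, i.e. a leukocyte). The
#'   default 3 sits between residual tumor-cell CD45 spillover (< 2.6x
#'   background under the default population) and genuine leukocyte
#'   expression (> 3.4x).
#' @param min_solidity,min_area,max_area intactness bounds (um^2).
#' @return list of class `GateSpec`.
#' @export
gateSpec <- function(dapi_pos_fold = 2, ck_pos_fold = 2,
                     cd45_neg_fold = 3, min_solidity = 0.7,
                     min_area = 30, max_area = 700) {
  if (any(c(dapi_pos_fold, ck_pos_fold, cd45_neg_fold) <= 0))
    stop("fold thresholds must be > 0")
  structure(list(dapi_pos_fold = dapi_pos_fold,
                 ck_pos_fold = ck_pos_fold,
                 cd45_neg_fold = cd45_neg_fold,
                 min_solidity = min_solidity,
                 min_area = min_area, max_area = max_area),
            class = "GateSpec")
}

# fold columns from whatever the table carries: *_fold directly, else
# reconstructed from background-corrected means over a nominal background
gateFolds <- function(table, background = 500) {
  out <- list()
  for (ch in c("dapi", "ck", "cd45")) {
    fc <- paste0(ch, "_fold"); cc <- paste0(ch, "_corr_mean")
    if (fc %in% names(table)) out[[ch]] <- table[[fc]]
    else if (cc %in% names(table))
      out[[ch]] <- (table[[cc]] + background) / background
    else stop("feature table is missing required column(s): ", fc,
              " (or ", cc, ")")
  }
  out
}

#' Gate cells by marker expression and intactness
#'
#' `CTC-candidate` iff DAPI+ and CK+ and CD45- and intact;
#' `WBC` iff DAPI+ and CD45+ (regardless of CK); `excluded` otherwise.
#'
#' @param table feature table with `*_fold` (or `*_corr_mean`) columns plus
#'   `solidity` and `area_um2`.
#' @param gate a [gateSpec()].
#' @param background nominal background used when only corrected means are
#'   available.
#' @return factor of per-row gate labels, levels
#'   `c("CTC-candidate", "WBC", "excluded")`.
#' @export
gateCells <- function(table, gate = gateSpec(), background = 500) {
  stopifnot(inherits(gate, "GateSpec"))
  assertCols(table, c("solidity", "area_um2"), "feature table")
  f <- gateFolds(table, background)
  dapi_pos <- f$dapi >= gate$dapi_pos_fold
  ck_pos <- f$ck >= gate$ck_pos_fold
  cd45_pos <- f$cd45 >= gate$cd45_neg_fold
  intact <- table$solidity >= gate$min_solidity &
    table$area_um2 >= gate$min_area & table$area_um2 <= gate$max_area
  lab <- rep("excluded", nrow(table))
  lab[dapi_pos & cd45_pos] <- "WBC"
  lab[dapi_pos & ck_pos & !cd45_pos & intact] <- "CTC-candidate"
  factor(lab, levels = c("CTC-candidate", "WBC", "excluded"))
}

#' Stratified train/test split
#'
#' Random split stratified by class; per-class training sizes are chosen by
#' largest remainder so the total training fraction is exact up to one row.
#'
#' @param table labeled table.
#' @param train_fraction fraction assigned to training (default 0.75).
#' @param seed integer seed; the same seed reproduces the split.
#' @param label_col name of the class column.
#' @return list with `train` and `test` data.frames (a partition of the
#'   input rows).
#' @export
splitDataset <- function(table, train_fraction = 0.75, seed = 1L,
                         label_col = "label") {
  assertCols(table, label_col, "labeled table")
  y <- table[[label_col]]
  tab <- table(y)
  if (any(tab < 2)) stop("every class needs >= 2 members to split")
  target <- round(train_fraction * nrow(table))
  raw <- train_fraction * as.numeric(tab)
  k <- floor(raw)
  rem <- raw - k
  add <- target - sum(k)
  if (add > 0) {
    ord <- order(rem, as.numeric(tab), decreasing = TRUE)
    k[ord[seq_len(add)]] <- k[ord[seq_len(add)]] + 1L
  }
  names(k) <- names(tab)
  localSeed(seed, {
    tr_idx <- unlist(lapply(names(tab), function(cl) {
      idx <- which(y == cl)
      sample(idx, k[[cl]])
    }))
  })
  tr_idx <- sort(tr_idx)
  list(train = table[tr_idx, , drop = FALSE],
       test = table[-tr_idx, , drop = FALSE])
}

#' Default hyperparameter grids for the five classifier families
#'
#' Small fixed grids searched by 10-fold cross-validation; the families are
#' stochastic gradient boosting (GBM), AdaBoost classification trees
#' (ADABOOST), radial-kernel support vector machines (SVM), random forest
#' (RF) and extreme gradient boosting (XGB).
#'
#' @return named list of data.frame grids.
#' @export
defaultGrids <- function() {
  list(GBM = expand.grid(n_trees = 100, depth = c(1, 2), shrinkage = 0.1),
       ADABOOST = expand.grid(n_trees = 100, depth = c(1, 2)),
       SVM = expand.grid(cost = c(0.1, 1, 10)),
       RF = expand.grid(ntree = 200, mtry_frac = c(0.35, 0.7)),
       XGB = expand.grid(nrounds = 60, max_depth = c(2, 4), eta = 0.3))
}

fitFamily <- function(family, x, y01, params, seed) {
  x <- as.matrix(x)
  switch(family,
    GBM = fitGradientBoost(x, y01, n_trees = params$n_trees,
                           depth = params$depth,
                           shrinkage = params$shrinkage, seed = seed),
    ADABOOST = fitAdaBoost(x, ifelse(y01 == 1, 1, -1),
                           n_trees = params$n_trees, depth = params$depth,
                           seed = seed),
    SVM = e1071::svm(x, factor(y01, levels = c(0, 1)), kernel = "radial",
                     cost = params$cost, scale = TRUE),
    RF = localSeed(seed, randomForest::randomForest(
      x, factor(y01, levels = c(0, 1)), ntree = params$ntree,
      mtry = max(1L, floor(params$mtry_frac * ncol(x))))),
    XGB = localSeed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y01, nthread = 1),
      nrounds = params$nrounds, verbose = 0)),
    stop("unknown family: ", family))
}

predictFamily <- function(family, fit, x) {
  x <- as.matrix(x)
  switch(family,
    GBM = predictGradBoost(fit, x),
    ADABOOST = predictAdaBoost(fit, x),
    SVM = {
      # deterministic probability surrogate: logistic of the signed
      # decision value (monotone in the margin, calibrated to [0,1])
      pr <- stats::predict(fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sgn <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
      stats::plogis(sgn * dv[, 1])
    },
    RF = stats::predict(fit, x, type = "prob")[, "1"],
    XGB = stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1)))
}

# stratified fold assignment, 1..k per row
stratifiedFolds <- function(y01, k, seed) {
  fold <- integer(length(y01))
  localSeed(seed, {
    for (cl in unique(y01)) {
      idx <- sample(which(y01 == cl))
      if (length(idx) < k)
        stop("a class has fewer members than folds; cannot stratify")
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train the five-family classifier battery
#'
#' For each requested family, selects hyperparameters from a small fixed
#' grid by stratified k-fold cross-validated AUC on the training set, then
#' refits on the full training set. All randomness derives from `seed`, so
#' reruns reproduce identical models and predictions.
#'
#' @param train labeled training table (from [splitDataset()]).
#' @param families subset of `c("GBM","ADABOOST","SVM","RF","XGB")`.
#' @param cv_folds folds for cross-validation (default 10).
#' @param seed integer seed.
#' @param label_col,positive class column and positive level.
#' @param grids named list of grids, see [defaultGrids()].
#' @return named list of `ctcModel` objects; each has a `cv` data.frame of
#'   per-grid-point CV AUC and accuracy, and the chosen parameter row.
#' @export
trainClassifiers <- function(train, families = c("GBM", "ADABOOST", "SVM",
                                                 "RF", "XGB"),
                             cv_folds = 10, seed = 1L, label_col = "label",
                             positive = "CTC", grids = defaultGrids()) {
  assertCols(train, label_col, "training table")
  feats <- setdiff(names(train), label_col)
  num <- vapply(train[feats], is.numeric, logical(1))
  feats <- feats[num]
  x <- as.matrix(train[feats])
  y01 <- as.integer(train[[label_col]] == positive)
  if (length(unique(y01)) < 2L) stop("training data must contain both classes")
  fold <- stratifiedFolds(y01, cv_folds, childSeed(seed, 1))

  models <- list()
  for (fi in seq_along(families)) {
    fam <- families[fi]
    grid <- grids[[fam]]
    cv <- data.frame(grid, auc = NA_real_, accuracy = NA_real_)
    for (gi in seq_len(nrow(grid))) {
      prob <- numeric(length(y01))
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        fit <- fitFamily(fam, x[tr, , drop = FALSE], y01[tr],
                         grid[gi, , drop = FALSE],
                         seed = childSeed(seed, 100 * fi + gi))
        prob[!tr] <- predictFamily(fam, fit, x[!tr, , drop = FALSE])
      }
      cv$auc[gi] <- aucRank(prob, y01 == 1)
      cv$accuracy[gi] <- mean((prob >= 0.5) == (y01 == 1))
    }
    best <- which.max(cv$auc)
    fit <- fitFamily(fam, x, y01, grid[best, , drop = FALSE],
                     seed = childSeed(seed, 1000 + fi))
    models[[fam]] <- structure(
      list(family = fam, params = grid[best, , drop = FALSE], fit = fit,
           features = feats, positive = positive, cv = cv),
      class = "ctcModel")
  }
  models
}

#' @export
predict.ctcModel <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("feature schema mismatch; missing: ", paste(miss, collapse = ", "))
  predictFamily(object$family, object$fit,
                as.matrix(newdata[object$features]))
}

#' @export
print.ctcModel <- function(x, ...) {
  cat("ctcModel:", x$family, "| features:", length(x$features),
      "| CV AUC:", sprintf("%.4f", max(x$cv$auc)), "\n")
  invisible(x)
}

# rank-based AUC, ties counted 1/2 (Mann-Whitney probability)
aucRank <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate classifier scores against truth
#'
#' Confusion counts at the stated probability threshold plus the
#' threshold-free ROC AUC (Mann-Whitney with ties counted one half).
#'
#' @param scores numeric probabilities/scores.
#' @param truth logical, or factor/character with `positive` naming the
#'   positive level.
#' @param threshold decision threshold (score >= threshold is called
#'   positive).
#' @param positive positive level when `truth` is not logical.
#' @return list of class `EvalMetrics`: `TP`, `FP`, `TN`, `FN`, `accuracy`,
#'   `precision`, `recall`, `F1`, `TPR`, `FPR`, `auc` (NA when truth has
#'   one class).
#' @examples
#' evaluateClassifier(c(.9, .8, .4, .3, .2),
#'                    c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' @export
evaluateClassifier <- function(scores, truth, threshold = 0.5,
                               positive = "CTC") {
  if (!is.logical(truth)) truth <- truth == positive
  if (length(scores) != length(truth) || !length(scores))
    stop("scores and truth must be the same nonzero length")
  pred <- scores >= threshold
  TP <- sum(pred & truth); FP <- sum(pred & !truth)
  TN <- sum(!pred & !truth); FN <- sum(!pred & truth)
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 accuracy = (TP + TN) / length(truth),
                 precision = precision, recall = recall, F1 = f1,
                 TPR = recall,
                 FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
                 auc = aucRank(scores, truth)),
            class = "EvalMetrics")
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf(
    "EvalMetrics: acc %.3f prec %.3f recall %.3f F1 %.3f FPR %.3f AUC %s\n",
    x$accuracy, x$precision, x$recall, x$F1, x$FPR,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Classify cells with the marker gate as a hard veto
#'
#' The machine-learning probability narrows candidates; the definitional
#' marker gate vetoes: the final label is CTC only when the model
#' probability reaches the threshold *and* the row gates as CTC-candidate.
#' An optional review table (the pathologist-confirmation hook) can flip
#' final labels afterwards.
#'
#' @param model a `ctcModel` from [trainClassifiers()].
#' @param table feature table (schema compatible with the model).
#' @param gate a [gateSpec()].
#' @param threshold probability threshold (default 0.5).
#' @param review optional data.frame with columns `row` (row number in
#'   `table`) and `is_ctc` (logical): manual overrides applied last.
#' @param background nominal background for fold reconstruction, see
#'   [gateCells()].
#' @return `table` with added columns `gate_label`, `ml_prob`, `is_ctc`
#'   and `reviewed`.
#' @export
classifyCells <- function(model, table, gate = gateSpec(), threshold = 0.5,
                          review = NULL, background = 500) {
  stopifnot(inherits(model, "ctcModel"))
  out <- table
  out$gate_label <- gateCells(table, gate, background)
  out$ml_prob <- if (nrow(table)) predict(model, table) else numeric(0)
  out$is_ctc <- out$gate_label == "CTC-candidate" & out$ml_prob >= threshold
  out$reviewed <- FALSE
  if (!is.null(review) && nrow(review)) {
    assertCols(review, c("row", "is_ctc"), "review table")
    out$is_ctc[review$row] <- review$is_ctc
    out$reviewed[review$row] <- TRUE
  }
  out
}
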