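# In-package boosting learners over rpart weak learners.
#
# Two of the five classifier families in the comparison protocol are
# boosted tree ensembles for which no fitting package is declared here:
# stochastic gradient boosting (logistic loss, bagged gradient steps on
# shallow regression trees; Friedman 2002) and AdaBoost.M1 (discrete
# boosting of depth-limited classification trees). Both are implemented
# directly -- they are small, and keeping them in-package pins the exact
# protocol and its determinism.

#' @importFrom rpart rpart rpart.control
NULL

# y01: 0/1 numeric response
fitGradientBoost <- function(x, y01, n_trees = 100, depth = 2,
                             shrinkage = 0.1, bag_fraction = 0.5,
                             seed = NULL) {
  df <- as.data.frame(x)
  n <- nrow(df)
  p0 <- min(max(mean(y01), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 10,
                               minbucket = 5, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  localSeed(seed, {
    for (m in seq_len(n_trees)) {
      p <- 1 / (1 + exp(-f))
      r <- y01 - p  # negative gradient of the binomial deviance
      sub <- sort(sample.int(n, max(2L, floor(bag_fraction * n))))
      dat <- df[sub, , drop = FALSE]
      dat$.r <- r[sub]
      tr <- rpart::rpart(.r ~ ., data = dat, method = "anova",
                         control = ctrl)
      trees[[m]] <- tr
      f <- f + shrinkage * stats::predict(tr, df)
    }
  })
  structure(list(f0 = f0, trees = trees, shrinkage = shrinkage),
            class = "gradBoost")
}

predictGradBoost <- function(object, newdata) {
  nd <- as.data.frame(newdata)
  f <- rep(object$f0, nrow(nd))
  for (tr in object$trees) f <- f + object$shrinkage * stats::predict(tr, nd)
  1 / (1 + exp(-f))
}

# ypm: -1/+1 response (AdaBoost.M1 / discrete AdaBoost)
fitAdaBoost <- function(x, ypm, n_trees = 100, depth = 1, seed = NULL) {
  df <- as.data.frame(x)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 10,
                               minbucket = 5, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(colnames(df), collapse = " + ")))
  localSeed(seed, {
    dat <- df
    dat$.y <- factor(ypm, levels = c(-1, 1))
    for (m in seq_len(n_trees)) {
      dat$.w <- w
      tr <- rpart::rpart(fml, data = dat, weights = .w,
                         method = "class", control = ctrl)
      h <- ifelse(stats::predict(tr, dat, type = "class") == "1", 1, -1)
      err <- sum(w * (h != ypm))
      if (err >= 0.5) break
      err <- max(err, 1e-10)
      a <- 0.5 * log((1 - err) / err)
      trees[[length(trees) + 1L]] <- tr
      alphas <- c(alphas, a)
      if (err <= 1e-10) break  # perfect weak learner: margin saturated
      w <- w * exp(-a * ypm * h)
      w <- w / sum(w)
    }
  })
  structure(list(trees = trees, alphas = alphas), class = "adaBoost")
}

predictAdaBoost <- function(object, newdata) {
  nd <- as.data.frame(newdata)
  f <- numeric(nrow(nd))
  for (m in seq_along(object$trees)) {
    h <- ifelse(stats::predict(object$trees[[m]], nd,
                               type = "class") == "1", 1, -1)
    f <- f + object$alphas[m] * h
  }
  tot <- sum(abs(object$alphas))
  if (tot > 0) f <- f / tot
  1 / (1 + exp(-4 * f))  # logistic squash of the normalized margin
}
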