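# Culture-age classification: random forest (compact CART forest in src/)
# or linear discriminant analysis, with a stratified 2/3-1/3 split and
# 10-fold cross-validated hyperparameter choice on the training set.

stratified_split <- function(y, fraction) {
  train <- integer(0)
  for (l in levels(y)) {
    ix <- which(y == l)
    n_tr <- max(1L, round(length(ix) * fraction))
    train <- c(train, sample(ix, n_tr))
  }
  sort(train)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    ix <- sample(which(y == l))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

rf_fit <- function(X, y, ntree, mtry) {
  cpp_grow_forest(X, as.integer(y) - 1L, nlevels(y), ntree, mtry)
}

rf_predict <- function(forest, X, K, ntree_use = length(forest)) {
  votes <- cpp_forest_votes(forest, X, K, ntree_use)
  max.col(votes, ties.method = "first")
}

#' Train a culture-age classifier
#'
#' Splits the rows into a stratified training (2/3) and test (1/3) set. For
#' the random forest, the number of trees and the number of descriptors
#' tried per split (mtry) are chosen by stratified 10-fold cross-validation
#' on the training set; the best setting is refit on the full training set
#' and evaluated once on the test set. LDA has no tuned hyperparameters and
#' uses the same split.
#'
#' @param tab descriptor table (raw values; rows with missing descriptors
#'   are dropped).
#' @param class_col column holding the age class (coerced to factor).
#' @param method "random_forest" or "lda".
#' @param seed integer seed (recorded in the result).
#' @param ntree_grid candidate forest sizes (default 100, 250, 500, 1000).
#' @param mtry_grid candidate descriptors-per-split values (default around
#'   sqrt(p)).
#' @param cv_folds cross-validation folds (default 10).
#' @param test_fraction held-out fraction (default 1/3).
#' @return object of class `age_classifier`: method, fitted model, chosen
#'   hyperparameters, cross-validation table, test-set `confusion` matrix
#'   and misclassification rate `mcr`, class levels, descriptor names and
#'   seed.
#' @export
train_age_classifier <- function(tab, class_col = "DIV",
                                 method = c("random_forest", "lda"),
                                 seed = 1L,
                                 ntree_grid = c(100L, 250L, 500L, 1000L),
                                 mtry_grid = NULL, cv_folds = 10L,
                                 test_fraction = 1 / 3) {
  method <- match.arg(method)
  dcols <- descriptor_columns(tab)
  X <- as.matrix(tab[dcols])
  keep_col <- colSums(is.finite(X)) > 0
  X <- X[, keep_col, drop = FALSE]
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- droplevels(factor(tab[[class_col]][ok]))
  if (nlevels(y) < 2L) stop("need >= 2 age classes")
  if (any(table(y) < 3L)) stop("every class needs >= 3 rows")
  K <- nlevels(y)
  p <- ncol(X)
  if (is.null(mtry_grid))
    mtry_grid <- unique(pmax(1L, pmin(p, round(sqrt(p) * c(0.5, 1, 2)))))

  with_seed(seed, {
    tr <- stratified_split(y, 1 - test_fraction)
    te <- setdiff(seq_along(y), tr)
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    Xte <- X[te, , drop = FALSE]; yte <- y[te]

    cv_tab <- NULL
    desc_used <- colnames(X)
    if (method == "random_forest") {
      folds <- stratified_folds(ytr, cv_folds)
      err <- array(0, dim = c(length(ntree_grid), length(mtry_grid)))
      cnt <- 0L
      for (f in seq_len(cv_folds)) {
        hold <- folds == f
        if (!any(hold) || length(unique(ytr[!hold])) < K) next
        cnt <- cnt + sum(hold)
        for (mi in seq_along(mtry_grid)) {
          forest <- rf_fit(Xtr[!hold, , drop = FALSE], ytr[!hold],
                           max(ntree_grid), mtry_grid[mi])
          for (ti in seq_along(ntree_grid)) {
            pred <- rf_predict(forest, Xtr[hold, , drop = FALSE], K,
                               ntree_grid[ti])
            err[ti, mi] <- err[ti, mi] +
              sum(pred != as.integer(ytr[hold]))
          }
        }
      }
      cv_tab <- expand.grid(ntree = ntree_grid, mtry = mtry_grid)
      cv_tab$cv_mcr <- as.vector(err) / max(cnt, 1L)
      best <- cv_tab[order(cv_tab$cv_mcr, cv_tab$ntree, cv_tab$mtry), ][1, ]
      model <- rf_fit(Xtr, ytr, best$ntree, best$mtry)
      pred <- levels(y)[rf_predict(model, Xte, K, best$ntree)]
      hyper <- list(ntree = best$ntree, mtry = best$mtry,
                    cv_mcr = best$cv_mcr)
    } else {
      # lda rejects variables that are constant within every class
      pooled_sd <- apply(Xtr, 2, function(v)
        sqrt(mean(tapply(v, ytr, stats::var), na.rm = TRUE)))
      keep <- is.finite(pooled_sd) & pooled_sd > 1e-12
      if (!any(keep)) stop("no descriptor varies within classes")
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
      desc_used <- colnames(Xtr)
      model <- MASS::lda(Xtr, grouping = ytr)
      pred <- as.character(stats::predict(model, Xte)$class)
      hyper <- list()
    }
    confusion <- table(truth = yte, predicted = factor(pred,
                                                       levels = levels(y)))
    mcr <- mean(pred != as.character(yte))
    structure(list(method = method, model = model, hyper = hyper,
                   cv_results = cv_tab, confusion = confusion, mcr = mcr,
                   levels = levels(y), descriptors = desc_used,
                   train_index = tr, seed = seed),
              class = "age_classifier")
  })
}

#' Predict age classes for new rows
#' @param object an `age_classifier`.
#' @param newdata data.frame containing the training descriptors.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.age_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$descriptors])
  if (object$method == "random_forest") {
    object$levels[rf_predict(object$model, X, length(object$levels),
                             object$hyper$ntree)]
  } else {
    as.character(stats::predict(object$model, X)$class)
  }
}

#' @export
print.age_classifier <- function(x, ...) {
  cat("Culture-age classifier (", x$method, ")\n", sep = "")
  if (length(x$hyper) > 0)
    cat("  chosen by 10-fold CV: ntree = ", x$hyper$ntree, ", mtry = ",
        x$hyper$mtry, " (CV MCR ", sprintf("%.3f", x$hyper$cv_mcr), ")\n",
        sep = "")
  cat("  test-set misclassification rate: ", sprintf("%.3f", x$mcr), "\n",
      sep = "")
  cat("  confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
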