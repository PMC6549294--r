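# The connectivity score: a weighted average of z-scored descriptors whose
# weights are their average correlation with culture age, after pruning
# inter-correlated (|r| > 0.75) and intensity-class descriptors.

#' Fit a connectivity score model
#'
#' Four steps: (1) per experiment, the Pearson correlation of every
#' descriptor with culture age (DIV) on control rows, averaged across
#' experiments; (2) pairwise descriptor inter-correlation on the merged
#' control + treated data; (3) descriptors ranked by absolute average age
#' correlation; (4) the ranked list filtered top-down, skipping any
#' descriptor whose absolute inter-correlation with an already retained one
#' exceeds `cutoff`. Intensity-class descriptors are excluded up front.
#' Weights are the signed average age correlations of the retained set.
#'
#' @param controls z-scored descriptor table of control rows, with
#'   `experiment` and DIV columns.
#' @param merged optional table (controls plus treated) for the
#'   inter-correlation step; defaults to `controls`.
#' @param div_col culture-age column name (numeric).
#' @param cutoff maximal allowed absolute inter-correlation (default 0.75).
#' @param exclude_intensity drop intensity-class descriptors (default TRUE).
#' @return object of class `score_model`: `selected`, `weights`, `cutoff`,
#'   `div_correlations` (per experiment), `intercorrelation` matrix and
#'   provenance.
#' @export
fit_score_model <- function(controls, merged = NULL, div_col = "DIV",
                            cutoff = 0.75, exclude_intensity = TRUE) {
  stopifnot(div_col %in% names(controls))
  div <- controls[[div_col]]
  if (!is.numeric(div)) stop(div_col, " must be numeric")
  if (length(unique(div)) < 2L) stop("need >= 2 culture-age levels")
  merged <- merged %||% controls
  dcols <- descriptor_columns(controls)
  if (exclude_intensity) dcols <- dcols[!is_intensity_descriptor(dcols)]

  exps <- unique(as.character(controls$experiment))
  corr_mat <- matrix(NA_real_, length(exps), length(dcols),
                     dimnames = list(exps, dcols))
  for (e in exps) {
    sel <- controls$experiment == e
    for (cl in dcols) {
      x <- controls[[cl]][sel]
      ok <- is.finite(x) & is.finite(div[sel])
      if (sum(ok) >= 3L && stats::sd(x[ok]) > 0)
        corr_mat[e, cl] <- stats::cor(x[ok], div[sel][ok])
    }
  }
  avg_corr <- colMeans(corr_mat, na.rm = TRUE)
  avg_corr <- avg_corr[is.finite(avg_corr)]
  if (length(avg_corr) == 0L)
    stop("no descriptor has a defined age correlation")

  inter <- suppressWarnings(
    stats::cor(as.matrix(merged[names(avg_corr)]),
               use = "pairwise.complete.obs"))
  ranked <- names(sort(abs(avg_corr), decreasing = TRUE))
  selected <- character(0)
  for (cl in ranked) {
    if (length(selected) == 0L) {
      selected <- cl
      next
    }
    ic <- abs(inter[cl, selected])
    if (all(is.na(ic) | ic <= cutoff)) selected <- c(selected, cl)
  }
  structure(list(selected = selected, weights = avg_corr[selected],
                 cutoff = cutoff, div_correlations = corr_mat,
                 intercorrelation = inter,
                 provenance = list(experiments = exps, div_col = div_col,
                                   n_control_rows = nrow(controls),
                                   n_merged_rows = nrow(merged))),
            class = "score_model")
}

#' Connectivity scores for a z-scored table
#'
#' Per row: `sum(w_i z_i) / sum(|w_i|)` over the model's selected
#' descriptors that are non-missing in that row (the normalizer adapts to
#' the descriptors actually present). Rows with no selected descriptor give
#' `NA`.
#'
#' @param object a fitted [fit_score_model()] object.
#' @param newdata z-scored descriptor table.
#' @param ... unused.
#' @return numeric vector of scores, one per row.
#' @export
predict.score_model <- function(object, newdata, ...) {
  w <- object$weights
  have <- intersect(names(w), names(newdata))
  if (length(have) == 0L) stop("newdata contains none of the selected descriptors")
  Z <- as.matrix(newdata[have])
  W <- matrix(w[have], nrow(Z), length(have), byrow = TRUE)
  W[!is.finite(Z)] <- NA
  Z[!is.finite(Z)] <- NA
  num <- rowSums(W * Z, na.rm = TRUE)
  den <- rowSums(abs(W), na.rm = TRUE)
  score <- num / den
  score[den == 0] <- NA_real_
  score
}

#' Convenience wrapper: scores of a z-scored table
#' @param ztab z-scored descriptor table.
#' @param model a `score_model`.
#' @export
connectivity_score <- function(ztab, model) predict(model, ztab)

#' @export
coef.score_model <- function(object, ...) object$weights

#' @export
print.score_model <- function(x, ...) {
  cat("Connectivity score model\n")
  cat("  inter-correlation cutoff: ", x$cutoff, "\n", sep = "")
  cat("  fitted on ", x$provenance$n_control_rows, " control rows, ",
      length(x$provenance$experiments), " experiment(s)\n", sep = "")
  cat("  selected descriptors (weight = mean correlation with age):\n")
  for (nm in x$selected)
    cat(sprintf("    %-28s %+0.3f\n", nm, x$weights[[nm]]))
  invisible(x)
}
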