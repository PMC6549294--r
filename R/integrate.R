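# Descriptor-table integration: filtering, well averaging, z-scoring,
# control normalization, connectivity-score fitting and group statistics.

MORPHOFUN_METADATA <- c("plate", "well", "field", "recording", "DIV",
                        "cell_type", "condition", "dose", "experiment",
                        "replicate", "seed", "assay")

#' Descriptor columns of a table
#'
#' All numeric columns that are not plate-layout metadata.
#' @param tab data.frame.
#' @export
descriptor_columns <- function(tab) {
  cand <- setdiff(names(tab), MORPHOFUN_METADATA)
  cand[vapply(tab[cand], is.numeric, logical(1))]
}

#' Descriptor class of descriptor names
#'
#' Classes are "nuclei", "dendrite", "synapse" and "functional", inferred
#' from the naming convention of the pipeline's descriptor vectors.
#' @param names character vector of descriptor names.
#' @export
descriptor_class <- function(names) {
  cls <- rep("other", length(names))
  cls[grepl("^(nuclei|neuronal|non_neuronal)", names)] <- "nuclei"
  cls[grepl("^dendrite", names)] <- "dendrite"
  cls[grepl("^(pre|post|synapse)", names)] <- "synapse"
  cls[grepl("^(pct_active|burst|network)", names)] <- "functional"
  cls
}

#' Is a descriptor intensity-class?
#'
#' Intensity-class descriptors (computed from raw fluorescence) are
#' outlier-sensitive and excluded from connectivity-score fitting.
#' @param names character vector of descriptor names.
#' @export
is_intensity_descriptor <- function(names) grepl("intensity", names)

#' Remove unusable fields and debris nuclei
#'
#' Drops morphology rows lacking nuclei or dendrite (zero counts / zero
#' dendrite area). Reports removal counts as a message.
#'
#' @param tab per-field descriptor table with `nuclei_count` and
#'   `dendrite_density` columns.
#' @return filtered data.frame (attribute `n_removed` records the count).
#' @export
filter_fields <- function(tab) {
  stopifnot(all(c("nuclei_count", "dendrite_density") %in% names(tab)))
  bad <- is.na(tab$nuclei_count) | tab$nuclei_count == 0 |
         is.na(tab$dendrite_density) | tab$dendrite_density == 0
  if (any(bad)) message("filter_fields: removed ", sum(bad),
                        " field(s) lacking nuclei or dendrites")
  out <- tab[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Exclude debris by the 5-sd projected-area rule
#'
#' Nucleus records whose projected area exceeds the group mean by more than
#' `k` standard deviations (computed per plate) are treated as false
#' segmentations (debris) and removed before well averaging.
#'
#' @param nuclei data.frame of nucleus records with a `projected_area_um2`
#'   column.
#' @param k sd multiplier (default 5).
#' @param group_key optional column name to group by (e.g. "plate").
#' @return filtered data.frame (attribute `n_removed`).
#' @export
filter_debris_nuclei <- function(nuclei, k = 5, group_key = NULL) {
  area <- nuclei$projected_area_um2
  grp <- if (!is.null(group_key) && group_key %in% names(nuclei))
    nuclei[[group_key]] else rep(1L, nrow(nuclei))
  keep <- rep(TRUE, nrow(nuclei))
  for (g in unique(grp)) {
    sel <- grp == g
    mu <- mean(area[sel]); s <- stats::sd(area[sel])
    if (is.finite(s) && s > 0) keep[sel] <- area[sel] <= mu + k * s
  }
  out <- nuclei[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Average morphology rows per well
#'
#' Wells are the technical replicates of the morphological assay: all fields
#' of a well are averaged into one row. Functional tables pass through
#' unchanged (each recording stays a technical replicate).
#'
#' @param tab descriptor table.
#' @param assay "morphology" (average per well) or "functional"
#'   (pass-through).
#' @return data.frame.
#' @export
aggregate_wells <- function(tab, assay = c("morphology", "functional")) {
  assay <- match.arg(assay)
  if (assay == "functional") return(tab)
  stopifnot("well" %in% names(tab))
  keys <- intersect(setdiff(MORPHOFUN_METADATA, c("field", "seed")),
                    names(tab))
  dcols <- descriptor_columns(tab)
  kf <- interaction(tab[keys], drop = TRUE)
  agg <- lapply(split(seq_len(nrow(tab)), kf), function(ix) {
    row <- tab[ix[1], keys, drop = FALSE]
    means <- lapply(tab[ix, dcols, drop = FALSE], mean, na.rm = TRUE)
    cbind(row, as.data.frame(means))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Z-score descriptors within experiment/replicate groups
#'
#' Per group and descriptor: `(x - mean) / sd`. Descriptors with zero sd in
#' a group, and groups of a single row, are emitted as missing.
#'
#' @param tab descriptor table.
#' @param group_keys metadata columns defining the normalization groups.
#' @return data.frame with the descriptor columns replaced by z-scores.
#' @export
zscore_table <- function(tab, group_keys = c("experiment", "replicate")) {
  group_keys <- intersect(group_keys, names(tab))
  dcols <- descriptor_columns(tab)
  grp <- if (length(group_keys) > 0)
    interaction(tab[group_keys], drop = TRUE) else factor(rep(1L, nrow(tab)))
  out <- tab
  for (g in levels(grp)) {
    sel <- grp == g
    if (sum(sel) < 2L) {
      warning("zscore_table: group '", g, "' has a single row; emitted missing")
      out[sel, dcols] <- NA_real_
      next
    }
    for (cl in dcols) {
      x <- tab[[cl]][sel]
      s <- stats::sd(x, na.rm = TRUE)
      out[[cl]][sel] <- if (!is.finite(s) || s == 0) NA_real_
        else (x - mean(x, na.rm = TRUE)) / s
    }
  }
  out
}

#' Normalize z-scores to a reference condition
#'
#' Within each group the reference-condition mean is subtracted from every
#' row, so reference rows average zero and treated rows read as deviations
#' from control.
#'
#' @param ztab z-scored descriptor table.
#' @param reference_condition value of `condition_col` marking the
#'   reference rows.
#' @param condition_col condition column name.
#' @param group_keys grouping columns (default experiment, replicate, DIV).
#' @return data.frame.
#' @export
normalize_to_reference <- function(ztab, reference_condition,
                                   condition_col = "condition",
                                   group_keys = c("experiment", "replicate",
                                                  "DIV")) {
  group_keys <- intersect(group_keys, names(ztab))
  grp <- interaction(ztab[group_keys], drop = TRUE)
  missing_ref <- character(0)
  dcols <- descriptor_columns(ztab)
  out <- ztab
  for (g in levels(grp)) {
    sel <- grp == g
    ref <- sel & ztab[[condition_col]] == reference_condition
    if (!any(ref)) {
      missing_ref <- c(missing_ref, g)
      next
    }
    for (cl in dcols)
      out[[cl]][sel] <- ztab[[cl]][sel] - mean(ztab[[cl]][ref], na.rm = TRUE)
  }
  if (length(missing_ref) > 0)
    stop("groups missing reference condition '", reference_condition, "': ",
         paste(missing_ref, collapse = ", "))
  out
}

#' Principal component analysis of a z-scored table
#'
#' @param ztab z-scored descriptor table.
#' @param descriptors optional descriptor subset (default: all descriptor
#'   columns with any finite values).
#' @return list with `projections` (scores data.frame with metadata),
#'   `loadings`, `explained_variance` (fractions) and the `prcomp` object.
#' @export
run_pca <- function(ztab, descriptors = NULL) {
  dcols <- descriptors %||% descriptor_columns(ztab)
  X <- as.matrix(ztab[dcols])
  keep_col <- colSums(is.finite(X)) > 0
  X <- X[, keep_col, drop = FALSE]
  keep_row <- stats::complete.cases(X)
  X <- X[keep_row, , drop = FALSE]
  if (ncol(X) < 2L || nrow(X) < 3L)
    stop("PCA needs >= 2 descriptors and >= 3 complete rows")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- ztab[keep_row, intersect(MORPHOFUN_METADATA, names(ztab)),
               drop = FALSE]
  list(projections = cbind(meta, as.data.frame(pc$x)),
       loadings = pc$rotation, explained_variance = ev, prcomp = pc)
}

#' Pairwise Wilcoxon tests with Bonferroni correction
#'
#' All pairwise two-sided rank-sum tests of one descriptor across groups;
#' p-values are multiplied by the number of pairs (capped at 1).
#' Shapiro-Wilk (per group) and Bartlett (across groups) assumption checks
#' are attached as attributes.
#'
#' @param tab data.frame.
#' @param descriptor descriptor column name.
#' @param grouping grouping column name.
#' @return data.frame: group1, group2, n1, n2, p_raw, p_bonferroni.
#' @export
group_tests <- function(tab, descriptor, grouping) {
  x <- tab[[descriptor]]
  g <- factor(tab[[grouping]])
  lv <- levels(g)
  if (length(lv) < 2L) stop("need >= 2 groups")
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  res <- lapply(seq_len(n_pairs), function(k) {
    a <- x[g == pairs[1, k]]; b <- x[g == pairs[2, k]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) {
      warning("group_tests: degenerate pair ", pairs[1, k], " vs ",
              pairs[2, k], " skipped")
      p <- NA_real_
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               n1 = length(a), n2 = length(b), p_raw = p,
               p_bonferroni = pmin(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  shapiro <- vapply(lv, function(l) {
    v <- x[g == l & is.finite(x)]
    if (length(v) >= 3L && length(v) <= 5000L && stats::sd(v) > 0)
      stats::shapiro.test(v)$p.value else NA_real_
  }, numeric(1))
  ok <- is.finite(x) & !is.na(g)
  bart <- tryCatch(stats::bartlett.test(x[ok], g[ok])$p.value,
                   error = function(e) NA_real_)
  attr(out, "shapiro_p") <- shapiro
  attr(out, "bartlett_p") <- bart
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
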