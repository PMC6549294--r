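# Table integration: filters, z-scores, score model, PCA, classifier, stats.

make_tab <- function(seed = 1) simulate_descriptor_table(seed = seed)

test_that("field filter drops rows lacking nuclei or dendrites", {
  tab <- make_tab()
  tab$nuclei_count[3] <- 0
  tab$dendrite_density[5] <- 0
  out <- suppressMessages(filter_fields(tab))
  expect_identical(nrow(out), nrow(tab) - 2L)
  expect_identical(attr(out, "n_removed"), 2L)
  clean <- make_tab()
  expect_identical(nrow(suppressMessages(filter_fields(clean))), nrow(clean))
})

test_that("5-sd debris rule excludes an injected giant nucleus only", {
  set.seed(4)
  nuc <- data.frame(plate = "P1",
                    projected_area_um2 = rnorm(200, mean = 3, sd = 0.4))
  mu <- mean(nuc$projected_area_um2); s <- sd(nuc$projected_area_um2)
  nuc$projected_area_um2[77] <- mu + 6 * s
  out <- filter_debris_nuclei(nuc, k = 5, group_key = "plate")
  expect_identical(attr(out, "n_removed"), 1L)
  expect_false((mu + 6 * s) %in% out$projected_area_um2)
})

test_that("well averaging collapses morphology fields, passes functional through", {
  tab <- make_tab()
  # expand each well into 3 pseudo-fields
  tab3 <- tab[rep(seq_len(nrow(tab)), each = 3), ]
  tab3$field <- rep(1:3, nrow(tab))
  dcols <- descriptor_columns(tab3)
  tab3[dcols] <- tab3[dcols] * rep(c(0.9, 1.0, 1.1), nrow(tab))
  agg <- aggregate_wells(tab3, "morphology")
  expect_identical(nrow(agg), nrow(tab))
  i <- which(agg$well == tab$well[1])
  expect_equal(agg$nuclei_count[i], tab$nuclei_count[1],
               tolerance = 1e-9)
  expect_identical(nrow(aggregate_wells(tab3, "functional")), nrow(tab3))
})

test_that("z-scores have mean 0 / sd 1 per group and are idempotent", {
  tab <- make_tab()
  z <- zscore_table(tab)
  for (e in unique(tab$experiment)) {
    sel <- z$experiment == e
    expect_equal(mean(z$dendrite_density[sel]), 0, tolerance = 1e-9)
    expect_equal(sd(z$dendrite_density[sel]), 1, tolerance = 1e-9)
  }
  z2 <- zscore_table(z)
  expect_equal(z2$dendrite_density, z$dendrite_density, tolerance = 1e-9)
  # constant descriptor -> missing
  tab$burst_amplitude <- 1
  zc <- zscore_table(tab)
  expect_true(all(is.na(zc$burst_amplitude)))
  # two groups on different scales end with identical z-distributions
  g2 <- tab
  sel <- g2$experiment == "E2"
  g2$dendrite_density[sel] <- g2$dendrite_density[sel] * 50 + 7
  zg <- zscore_table(g2)
  expect_equal(sort(zg$dendrite_density[sel]),
               sort(z$dendrite_density[z$experiment == "E2"]),
               tolerance = 1e-9)
})

test_that("reference normalization zeroes controls and preserves shifts", {
  tab <- make_tab()
  treated <- tab
  treated$condition <- "drug"
  dcols <- descriptor_columns(tab)
  z <- zscore_table(rbind(tab, treated))
  delta <- 0.8
  z[z$condition == "drug", dcols] <- z[z$condition == "drug", dcols] + delta
  norm <- normalize_to_reference(z, "control")
  ctl <- norm$condition == "control"
  for (cl in c("dendrite_density", "burst_correlation")) {
    for (g in unique(norm$experiment)) {
      gs <- norm$experiment == g
      expect_equal(mean(norm[[cl]][ctl & gs]), 0, tolerance = 1e-9)
    }
    expect_equal(mean(norm[[cl]][!ctl]) - mean(norm[[cl]][ctl]), delta,
                 tolerance = 1e-9)
  }
  z_missing <- z[!(z$condition == "control" & z$DIV == 3), ]
  expect_error(normalize_to_reference(z_missing, "control"), "missing reference")
})

test_that("score model honors the inter-correlation cutoff and weight signs", {
  # constructed table: d1 drives DIV, d2 = d1 (r = 1), d3 independent,
  # d4 anti-correlated with DIV, i5 intensity-flagged
  set.seed(9)
  n <- 60
  div <- rep(c(3, 7, 10, 14, 18), each = n / 5)
  d1 <- div + rnorm(n, 0, 1)
  tab <- data.frame(experiment = rep(c("E1", "E2"), n / 2), DIV = div,
                    condition = "control",
                    d1 = d1, d2 = d1, d3 = rnorm(n),
                    d4 = -2 * div + rnorm(n, 0, 14),
                    i5_mean_intensity = div + rnorm(n))
  m <- fit_score_model(tab, div_col = "DIV")
  expect_true("d1" %in% m$selected)
  expect_false("d2" %in% m$selected)        # r = 1 with retained d1
  expect_true("d4" %in% m$selected)
  expect_lt(m$weights[["d4"]], 0)           # sign survives into the weight
  expect_false(any(is_intensity_descriptor(m$selected)))
  ic <- m$intercorrelation[m$selected, m$selected]
  expect_lte(max(abs(ic[upper.tri(ic)])), 0.75)
})

test_that("connectivity score: renormalized weighted average with missing values", {
  m <- structure(list(selected = c("a", "b"),
                      weights = c(a = 0.8, b = -0.4), cutoff = 0.75),
                 class = "score_model")
  tab <- data.frame(a = c(2, 0, NA), b = c(0, 0, 1))
  sc <- connectivity_score(tab, m)
  expect_equal(sc[1], 0.8 * 2 / 1.2)
  expect_equal(sc[2], 0)
  expect_equal(sc[3], -0.4 * 1 / 0.4)      # renormalized to present weights
  tab2 <- data.frame(a = NA_real_, b = NA_real_)
  expect_true(is.na(connectivity_score(tab2, m)))
})

test_that("PCA: collinear data load on PC1; orthogonal transforms preserve variance", {
  set.seed(5)
  t_par <- rnorm(40)
  tab <- data.frame(experiment = "E1", DIV = 1,
                    d1 = 2 * t_par, d2 = -t_par, d3 = 0.5 * t_par)
  p <- run_pca(tab)
  expect_gt(p$explained_variance[1], 0.999)
  X <- matrix(rnorm(40 * 3), 40)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  t1 <- cbind(data.frame(experiment = "E1", DIV = 1),
              as.data.frame(`colnames<-`(X, c("d1", "d2", "d3"))))
  t2 <- cbind(data.frame(experiment = "E1", DIV = 1),
              as.data.frame(`colnames<-`(X %*% q, c("d1", "d2", "d3"))))
  expect_equal(run_pca(t1)$explained_variance, run_pca(t2)$explained_variance,
               tolerance = 1e-9)
})

test_that("age classifier separates well-separated classes and respects the split", {
  set.seed(7)
  n <- 20
  tab <- data.frame(DIV = rep(c(3, 10, 18), each = n),
                    d1 = rep(c(0, 5, 10), each = n) + rnorm(3 * n, 0, 0.3),
                    d2 = rep(c(4, 0, -4), each = n) + rnorm(3 * n, 0, 0.3))
  clf <- train_age_classifier(tab, seed = 3, ntree_grid = c(100L),
                              cv_folds = 5L)
  expect_equal(clf$mcr, 0)
  expect_identical(sum(clf$confusion), length(setdiff(seq_len(3 * n),
                                                      clf$train_index)))
  # same seed reproduces the same confusion matrix
  clf2 <- train_age_classifier(tab, seed = 3, ntree_grid = c(100L),
                               cv_folds = 5L)
  expect_identical(clf$confusion, clf2$confusion)
  # LDA route agrees on separable data
  lda <- train_age_classifier(tab, method = "lda", seed = 3)
  expect_equal(lda$mcr, 0)
  expect_error(train_age_classifier(tab[c(1:2, 21:40, 41:60), ]),
               ">= 3 rows")
})

test_that("pairwise Wilcoxon with Bonferroni: identical, shifted, K=3 counts", {
  set.seed(11)
  x <- rnorm(40)
  tab <- data.frame(v = c(x, x), g = rep(c("a", "b"), each = 40))
  r <- group_tests(tab, "v", "g")
  expect_identical(nrow(r), 1L)
  expect_gt(r$p_bonferroni, 0.9)
  tab2 <- data.frame(v = c(rnorm(20), rnorm(20) + 5), g = rep(c("a", "b"),
                                                              each = 20))
  expect_lt(group_tests(tab2, "v", "g")$p_bonferroni, 0.01)
  tab3 <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
  r3 <- group_tests(tab3, "v", "g")
  expect_identical(nrow(r3), 3L)
  expect_equal(r3$p_bonferroni, pmin(1, r3$p_raw * 3))
  expect_length(attr(r3, "shapiro_p"), 3L)
})
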