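# Low-level image operations against independent brute-force oracles.

test_that("max projection equals the per-pixel loop oracle", {
  expect_identical(max_project(matrix(1:6, 2)), matrix(1:6, 2))
  st <- array(c(0, 5, 3, 1), dim = c(1, 2, 2))
  expect_equal(max_project(st), matrix(c(3, 5), 1))
  set.seed(11)
  st <- array(rnorm(8 * 7 * 3), dim = c(8, 7, 3))
  oracle <- matrix(0, 8, 7)
  for (r in 1:8) for (c in 1:7) oracle[r, c] <- max(st[r, c, ])
  expect_equal(max_project(st), oracle)
  expect_error(max_project(array(0, dim = c(4, 4, 0))), "n_z")
})

test_that("sharpest slice is the argmax of per-slice intensity sd", {
  st <- array(1, dim = c(6, 6, 3))
  st[, , 2] <- matrix(rep(c(0, 10), 18), 6)
  expect_identical(select_sharpest_slice(st), 2L)
  expect_identical(select_sharpest_slice(matrix(0, 4, 4)), 1L)
  set.seed(3)
  st <- array(rnorm(10 * 10 * 5, sd = rep(runif(5, 0.5, 2), each = 100)),
              dim = c(10, 10, 5))
  sds <- vapply(1:5, function(z) sd(as.vector(st[, , z])), numeric(1))
  expect_identical(select_sharpest_slice(st), which.max(sds))
  # ties -> lowest index
  st <- array(0, dim = c(4, 4, 3))
  expect_identical(select_sharpest_slice(st), 1L)
})

test_that("connected-component labeling and dilation behave on known masks", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[7:8, 7:8] <- TRUE
  lab <- label_components(m)
  expect_identical(max(lab), 2L)
  # diagonal touch: one component under 8-conn, two under 4-conn
  d <- matrix(FALSE, 4, 4)
  d[1, 1] <- d[2, 2] <- TRUE
  expect_identical(max(label_components(d, 8L)), 1L)
  expect_identical(max(label_components(d, 4L)), 2L)
  # dilation is a superset and adds exactly the disk neighborhood
  dil <- dilate_mask(m, 2)
  expect_true(all(dil[m]))
  oracle <- matrix(FALSE, 10, 10)
  for (r in 1:10) for (c in 1:10) if (m[r, c])
    for (dr in -2:2) for (dc in -2:2)
      if (dr^2 + dc^2 <= 4 && r + dr >= 1 && r + dr <= 10 &&
          c + dc >= 1 && c + dc <= 10) oracle[r + dr, c + dc] <- TRUE
  expect_identical(unname(dil == oracle), matrix(TRUE, 10, 10))
})

test_that("distance transform matches the exhaustive nearest-background scan", {
  set.seed(5)
  m <- matrix(runif(12 * 12) > 0.4, 12, 12)
  d <- distance_transform(m)
  bg <- which(!m, arr.ind = TRUE)
  for (idx in which(m)) {
    r <- (idx - 1) %% 12 + 1; c <- (idx - 1) %/% 12 + 1
    if (nrow(bg) == 0) break
    exact <- min(sqrt((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
    # chamfer (1, sqrt 2) approximates Euclidean within ~8%
    expect_lt(abs(d[r, c] - exact), 0.09 * exact + 1e-9)
  }
  expect_true(all(d[!m] == 0))
})

test_that("skeleton of a straight ridge has the right length", {
  img <- matrix(0, 64, 130)
  img[32, 10:109] <- 1000         # 100-px horizontal ridge
  img <- gaussian_blur(img, 2)
  seg <- segment_dendrites(img, max(img) / 2, 0.99)
  len <- skeleton_length(seg$skeleton, 1)
  expect_lt(abs(len - 100) / 100, 0.10)
  # diagonal ridge: sqrt(2) weighting keeps the length right
  img2 <- matrix(0, 80, 80)
  for (s in 0:49) img2[15 + s, 15 + s] <- 1
  expect_equal(skeleton_length(img2 > 0, 1), 49 * sqrt(2))
})

test_that("branch-node counting: line 0, Y-junction 1, clustered junctions once", {
  line <- matrix(FALSE, 9, 9)
  line[5, 2:8] <- TRUE
  expect_identical(count_nodes(line), 0L)
  y <- matrix(FALSE, 11, 11)
  y[6, 2:6] <- TRUE                 # stem
  for (s in 1:4) { y[6 - s, 6 + s] <- TRUE; y[6 + s, 6 + s] <- TRUE }
  expect_identical(count_nodes(y), 1L)
})

test_that("watershed splits touching discs and is deterministic", {
  m <- disc_mask(40, 60, 20, 20, 9) | disc_mask(40, 60, 36, 20, 9)
  lab <- watershed_split(m)
  expect_identical(max(lab), 2L)
  expect_true(all((lab > 0) == m))
  expect_identical(lab, watershed_split(m))
  # single disc stays single
  expect_identical(max(watershed_split(disc_mask(30, 30, 15, 15, 8))), 1L)
})

test_that("Frangi vesselness prefers ridges over blobs and flat areas", {
  img <- matrix(0, 60, 60)
  img[30, 10:50] <- 800
  img <- gaussian_blur(img, 2)
  blob <- matrix(0, 60, 60)
  blob[30, 30] <- 800 * 40        # similar total energy, isotropic
  blob <- gaussian_blur(blob, 6)
  v_ridge <- frangi_vesselness(img)
  v_blob <- frangi_vesselness(blob)
  expect_gt(max(v_ridge[30, 20:40]), 0.5)
  expect_lt(max(v_blob[25:35, 25:35]), max(v_ridge[30, 20:40]))
  expect_true(all(frangi_vesselness(matrix(1, 20, 20)) == 0))
})
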