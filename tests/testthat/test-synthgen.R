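# Synthetic generators: determinism, truth consistency, maturation ramps.

test_that("field generation is bit-identical for identical (params, seed)", {
  fp <- quick_field_params()
  a <- generate_field(fp, seed = 7)
  b <- generate_field(fp, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  c <- generate_field(fp, seed = 8)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("zero puncta leave the synaptic channels at background/noise", {
  fp <- noiseless(quick_field_params(n_pre = 0L, n_post = 0L,
                                     n_true_synapses = 0L))
  fld <- generate_field(fp, seed = 3)
  expect_identical(fld$truth$n_true_synapses, 0L)
  pre <- channel_stack(fld$image, "presynaptic")
  expect_equal(max(pre), fp$background, tolerance = 1e-9)
})

test_that("truth invariants hold across seeds", {
  fp <- quick_field_params()
  for (s in 1:4) {
    tr <- generate_field(fp, seed = s)$truth
    expect_lte(tr$n_true_synapses, min(tr$n_pre_spots, tr$n_post_spots))
    expect_true(all(c(tr$n_neuronal_nuclei, tr$n_glial_nuclei,
                      tr$n_pre_spots, tr$n_post_spots,
                      tr$n_branch_nodes) >= 0))
    expect_gt(tr$dendrite_total_length, 0)
  }
})

test_that("parameter errors name the offending field", {
  expect_error(field_params(n_true_synapses = 50L, n_pre = 10L, n_post = 90L),
               "n_true_synapses")
  expect_error(field_params(n_pre = -1L), "n_pre")
  expect_error(field_params(width = 32L), "64")
  # unrenderable request: far more puncta than dendrite can carry
  fp <- field_params(dendrite_total_px = 220, n_pre = 400L, n_post = 400L,
                     n_true_synapses = 200L)
  expect_error(generate_field(fp, seed = 1), "renderable")
})

test_that("plate layout counts and determinism", {
  model <- maturation_model(div_levels = c(7, 14))
  pl <- generate_plate(model, n_wells_per_div = 3L, n_fields_per_well = 2L,
                       seed = 5, noise = FALSE)
  expect_length(pl$fields, 12L)
  expect_identical(nrow(pl$metadata), 12L)
  expect_identical(sort(unique(pl$metadata$DIV)), c(7, 14))
  expect_false(anyDuplicated(paste(pl$metadata$well, pl$metadata$field)) > 0)
  pl2 <- generate_plate(model, n_wells_per_div = 3L, n_fields_per_well = 2L,
                        seed = 5, noise = FALSE)
  expect_identical(pl$metadata, pl2$metadata)
  expect_identical(pl$fields[[1]]$truth, pl2$fields[[1]]$truth)
})

test_that("maturation ramps are monotone in the stated directions", {
  model <- maturation_model()
  tr <- lapply(model$div_levels, model$truth_at)
  get <- function(f) vapply(tr, `[[`, numeric(1), f)
  len <- get("dendrite_total_px")
  expect_true(all(diff(len) > 0))
  expect_true(all(diff(get("n_neuronal")) <= 0))
  expect_true(all(diff(get("n_true_synapses")) >= 0))
  expect_true(all(diff(get("synchrony_fraction")) >= 0))
  expect_true(all(diff(get("burst_rate")) > 0))
  # densities per dendrite length also ramp upward
  expect_true(all(diff(get("n_true_synapses") / len) >= -1e-9))
  # mean true dendrite length strictly increases with pseudo-DIV
  pl <- generate_plate(model, n_wells_per_div = 1L, n_fields_per_well = 1L,
                       seed = 2, noise = FALSE)
  lens <- vapply(pl$fields, function(f) f$truth$dendrite_total_length,
                 numeric(1))
  expect_true(all(diff(lens[order(pl$metadata$DIV)]) > 0))
})

test_that("calcium truth: default frame count is 360 (2 fps x 3 min)", {
  sim <- simulate_calcium_traces(calcium_params(n_neurons = 3L), seed = 1)
  expect_identical(ncol(sim$traces$values), 360L)
  expect_equal(sim$traces$frame_rate, 2)
})

test_that("full synchrony with zero noise gives identical burst trains", {
  p <- calcium_params(n_neurons = 6L, synchrony_fraction = 1, noise_sd = 0)
  sim <- simulate_calcium_traces(p, seed = 9)
  trains <- sim$truth$burst_onsets
  expect_gt(length(trains[[1]]), 0)
  for (i in 2:6) expect_identical(trains[[i]], trains[[1]])
})

test_that("zero synchrony gives chance-level burst-time overlap", {
  p <- calcium_params(n_neurons = 12L, synchrony_fraction = 0,
                      burst_rate = 0.05)
  sim <- simulate_calcium_traces(p, seed = 4)
  trains <- sim$truth$burst_onsets
  # observed pairwise coincidence (within 1 s) vs a circular-shift null
  coinc <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) return(0)
    sum(outer(a, b, function(x, y) abs(x - y) <= 1))
  }
  obs <- 0
  for (i in 1:11) for (j in (i + 1):12) obs <- obs + coinc(trains[[i]],
                                                           trains[[j]])
  set.seed(1)
  null <- replicate(200, {
    tot <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      shift <- runif(1, 0, 180)
      tot <- tot + coinc(trains[[i]], (trains[[j]] + shift) %% 180)
    }
    tot
  })
  expect_lte(obs, quantile(null, 0.995))
  expect_gte(obs, quantile(null, 0.005))
})

test_that("calcium parameter contracts", {
  expect_error(calcium_params(n_neurons = 0L), "n_neurons")
  expect_error(calcium_params(synchrony_fraction = 1.5), "synchrony")
  expect_error(calcium_params(duration = 0.4, frame_rate = 2), "2 frames")
})

test_that("rendered calcium recording is deterministic and has disjoint somata", {
  p <- calcium_params(n_neurons = 8L, duration = 30)
  a <- generate_calcium(p, seed = 2)
  b <- generate_calcium(p, seed = 2)
  expect_identical(a$recording$frames, b$recording$frames)
  expect_identical(a$recording$reference, b$recording$reference)
  lab <- segment_somata(a$recording$reference, 250)
  expect_identical(max(lab), 8L)
})
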