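test_that("effect size zero collapses every class onto the tray edge", {
  cfg <- sim_config(n_bands = 20, effect_size = 0, seed = 5)
  lib <- make_library(cfg)
  edge <- lib$classes[["tray-edge"]]$mean
  for (cl in impurity_classes())
    expect_equal(lib$classes[[cl]]$mean, edge)
})

test_that("the spectral library is deterministic and linear in effect size", {
  cfg1 <- sim_config(n_bands = 24, effect_size = 1, seed = 9)
  expect_equal(make_library(cfg1), make_library(cfg1))

  cfg2 <- sim_config(n_bands = 24, effect_size = 2, seed = 9)
  lib1 <- make_library(cfg1); lib2 <- make_library(cfg2)
  edge <- lib1$classes[["tray-edge"]]$mean
  for (cl in impurity_classes()) {
    d1 <- sqrt(sum((lib1$classes[[cl]]$mean - edge)^2))
    d2 <- sqrt(sum((lib2$classes[[cl]]$mean - edge)^2))
    expect_equal(d2, 2 * d1, tolerance = 1e-9)
    expect_gt(d1, 0)
  }
  # dispersion strictly positive, means smooth (bounded second difference)
  for (cl in names(lib1$classes)) {
    expect_true(all(lib1$classes[[cl]]$sd > 0))
    expect_lt(max(abs(diff(lib1$classes[[cl]]$mean, differences = 2))), 0.05)
  }
  expect_equal(length(lib1$classes), 13L)
})

test_that("noise-free ROIs reproduce the class means exactly", {
  cfg <- sim_config(roi_size = 12, n_bands = 8, noise_sd = 0, illum_sd = 0,
                    blob_radius = c(2, 3), seed = 3)
  lib <- make_library(cfg)
  normal <- simulate_roi(lib, "normal", cfg = cfg, seed = 4)
  for (k in 1:8)
    expect_true(all(normal$cube$values[, , k] ==
                      lib$classes[["tray-edge"]]$mean[k]))

  faulty <- simulate_roi(lib, "faulty", "cork", cfg = cfg, seed = 5)
  expect_true(any(faulty$blob_mask))
  sig <- spectral_signature(faulty$cube, faulty$blob_mask)
  expect_equal(sig$mean, lib$classes[["cork"]]$mean)
  expect_equal(sig$sd, rep(0, 8))
})

test_that("ROI labeling rules are enforced", {
  cfg <- sim_config(roi_size = 12, n_bands = 6, seed = 1)
  lib <- make_library(cfg)
  expect_error(simulate_roi(lib, "faulty", cfg = cfg), "anomaly_class")
  expect_error(simulate_roi(lib, "normal", "cork", cfg = cfg),
               "must not carry")
  tiny <- sim_config(roi_size = 6, n_bands = 6, blob_radius = c(4, 5), seed = 1)
  expect_error(simulate_roi(make_library(tiny), "faulty", "hair", cfg = tiny,
                            seed = 2), "cannot fit")
})

test_that("blob pixel counts agree with a Monte-Carlo geometry oracle", {
  cfg <- sim_config(roi_size = 30, n_bands = 4, blob_radius = c(3, 5),
                    noise_sd = 0, illum_sd = 0, seed = 11)
  lib <- make_library(cfg)
  counts <- vapply(1:300, function(i)
    sum(simulate_roi(lib, "faulty", "sugar", cfg, seed = 1000 + i)$blob_mask),
    numeric(1))

  # independent oracle: rejection-free lattice count of a random ellipse
  set.seed(202)
  oracle <- vapply(1:3000, function(i) {
    r1 <- runif(1, 3, 5); r2 <- runif(1, 3, 5); th <- runif(1, 0, pi)
    cx <- runif(1, 1 + max(r1, r2), 30 - max(r1, r2))
    cy <- runif(1, 1 + max(r1, r2), 30 - max(r1, r2))
    n <- 0
    for (x in 1:30) for (y in 1:30) {
      u <- ((x - cx) * cos(th) + (y - cy) * sin(th)) / r1
      v <- (-(x - cx) * sin(th) + (y - cy) * cos(th)) / r2
      if (u^2 + v^2 <= 1) n <- n + 1
    }
    n
  }, numeric(1))
  se <- sqrt(var(counts) / length(counts) + var(oracle) / length(oracle))
  expect_lt(abs(mean(counts) - mean(oracle)), 3 * se + 1e-9)
})

test_that("the dataset composition mirrors the study counts and cycling", {
  comp <- dataset_composition(sim_config())
  expect_equal(nrow(comp), 2112)
  expect_equal(sum(comp$label == "normal"), 1123)
  expect_equal(sum(comp$label == "faulty"), 989)
  expect_equal(sum(comp$split == "validation"), 337)
  tab <- table(comp$anomaly_class[comp$label == "faulty"])
  expect_equal(length(tab), 11L)
  expect_lte(max(tab) - min(tab), 1)
  expect_true(all(is.na(comp$anomaly_class[comp$label == "normal"])))
})

test_that("simulated datasets are reproducible byte for byte", {
  cfg <- sim_config(roi_size = 10, n_bands = 5, n_normal = 6, n_faulty = 5,
                    blob_radius = c(2, 3), seed = 17)
  d1 <- simulate_dataset(cfg = cfg)
  d2 <- simulate_dataset(cfg = cfg)
  expect_identical(d1$patches, d2$patches)
  expect_equal(nrow(d1$manifest), 11)
  # int16 quantization path produces as-acquired style cubes
  cfg16 <- sim_config(roi_size = 10, n_bands = 5, n_normal = 2, n_faulty = 2,
                      blob_radius = c(2, 3), quantize_int16 = TRUE, seed = 18)
  d3 <- simulate_dataset(cfg = cfg16)
  expect_identical(d3$patches[[1]]$cube$dtype_origin, "int16")
  expect_true(all(d3$patches[[1]]$cube$values == round(d3$patches[[1]]$cube$values)))
})
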