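test_that("max_value_select keeps the largest-magnitude coefficient", {
  img <- matrix(rnorm(16 * 16), 16, 16)
  st <- decompose_band(img, "dwt", 2, "haar")

  # L = 1 identity
  expect_equal(max_value_select(list(st)), st)

  # band with coefficients -2c dominates band with c, sign preserved
  st2 <- decompose_band(-2 * img, "dwt", 2, "haar")
  fused <- max_value_select(list(st, st2))
  expect_equal(fused$approx$LL, st2$approx$LL)
  expect_equal(fused$detail[[1]]$HH, st2$detail[[1]]$HH)

  # loop oracle on three random bands
  sts <- lapply(1:3, function(s) {
    set.seed(100 + s)
    decompose_band(matrix(rnorm(256), 16, 16), "dwt", 2, "haar")
  })
  fz <- max_value_select(sts)
  for (l in 1:2) for (or in c("LH", "HL", "HH")) {
    mats <- lapply(sts, function(s) s$detail[[l]][[or]])
    got <- fz$detail[[l]][[or]]
    for (i in seq_len(nrow(got))) for (j in seq_len(ncol(got))) {
      vals <- c(mats[[1]][i, j], mats[[2]][i, j], mats[[3]][i, j])
      expect_identical(got[i, j], vals[which.max(abs(vals))])
    }
  }

  # structural mismatch rejected
  other <- decompose_band(img, "dwt", 1, "haar")
  expect_error(max_value_select(list(st, other)), "structurally different")
})

test_that("identical-band cubes fuse back to the band for all transforms", {
  set.seed(41)
  B <- matrix(rnorm(16 * 16), 16, 16)
  cube <- datacube(array(rep(B, 4), c(16, 16, 4)))
  rng <- diff(range(B))
  for (m in c("dwt", "sidwt", "dtcwt")) {
    fz <- fuse_wavelet(cube, m, levels = 2)
    expect_lt(max(abs(fz$values - B)), 1e-6 * rng)
  }
  expect_lt(max(abs(fuse_laplacian(cube, T = 2)$values - B)), 1e-6 * rng)

  # single-band cube: fusion is the identity
  one <- datacube(array(B, c(16, 16, 1)))
  for (m in c("dwt", "sidwt", "dtcwt"))
    expect_lt(max(abs(fuse_wavelet(one, m, levels = 2)$values - B)), 1e-6 * rng)
})

test_that("two-level Haar fusion equals an end-to-end hand-rolled oracle", {
  set.seed(42)
  cube <- rand_cube(16, 16, 3, seed = 42)
  got <- fuse_wavelet(cube, "dwt", levels = 2, family = "haar")$values

  # oracle built entirely from the block-arithmetic Haar helpers
  dec <- lapply(1:3, function(k) {
    l1 <- haar_block_forward(cube$values[, , k])
    l2 <- haar_block_forward(l1$LL)
    list(l1 = l1, l2 = l2)
  })
  pick <- function(mats) {
    out <- mats[[1]]
    for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
      vals <- vapply(mats, function(m) m[i, j], numeric(1))
      out[i, j] <- vals[which.max(abs(vals))]
    }
    out
  }
  f2 <- list(LL = pick(lapply(dec, function(d) d$l2$LL)),
             LH = pick(lapply(dec, function(d) d$l2$LH)),
             HL = pick(lapply(dec, function(d) d$l2$HL)),
             HH = pick(lapply(dec, function(d) d$l2$HH)))
  ll1 <- haar_block_inverse(f2)
  f1 <- list(LL = ll1,
             LH = pick(lapply(dec, function(d) d$l1$LH)),
             HL = pick(lapply(dec, function(d) d$l1$HL)),
             HH = pick(lapply(dec, function(d) d$l1$HH)))
  oracle <- haar_block_inverse(f1)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("transform fusion is band-permutation invariant and homogeneous", {
  cube <- rand_cube(16, 16, 4, seed = 43)
  perm <- c(3, 1, 4, 2)
  pcube <- datacube(cube$values[, , perm])
  scube <- datacube(2.5 * cube$values)
  for (m in c("dwt", "sidwt", "dtcwt")) {
    fz <- fuse_wavelet(cube, m, levels = 2)$values
    expect_equal(fuse_wavelet(pcube, m, levels = 2)$values, fz,
                 tolerance = 1e-9)
    expect_equal(fuse_wavelet(scube, m, levels = 2)$values, 2.5 * fz,
                 tolerance = 1e-9)
  }
  fl <- fuse_laplacian(cube, T = 2)$values
  expect_equal(fuse_laplacian(datacube(cube$values[, , perm]), T = 2)$values,
               fl, tolerance = 1e-9)
  expect_equal(fuse_laplacian(scube, T = 2)$values, 2.5 * fl,
               tolerance = 1e-9)
})

test_that("a coefficient-dominant band is reconstructed by fusion", {
  set.seed(44)
  weak <- array(rnorm(16 * 16 * 3, sd = 0.01), c(16, 16, 3))
  strong <- matrix(rnorm(256, sd = 10), 16, 16)
  cube <- datacube(array(c(weak[, , 1], strong, weak[, , 3]), c(16, 16, 3)))
  rng <- diff(range(strong))
  for (m in c("dwt", "sidwt", "laplacian")) {
    fz <- if (m == "laplacian") fuse_laplacian(cube, T = 2)
          else fuse_wavelet(cube, m, levels = 2, family = "haar")
    expect_lt(max(abs(fz$values - strong)), 1e-2 * rng)
  }
})

test_that("laplacian fusion matches a compositional pyramid oracle", {
  cube <- rand_cube(16, 16, 3, seed = 45)
  got <- fuse_laplacian(cube, T = 3)$values
  pyrs <- lapply(1:3, function(k) build_laplacian_pyramid(cube$values[, , k], 3))
  pick <- function(mats) {
    out <- mats[[1]]
    for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
      vals <- vapply(mats, function(m) m[i, j], numeric(1))
      out[i, j] <- vals[which.max(abs(vals))]
    }
    out
  }
  fused <- pyrs[[1]]
  for (t in 1:3) fused$laplacian[[t]] <- pick(lapply(pyrs, function(p) p$laplacian[[t]]))
  fused$top <- pick(lapply(pyrs, function(p) p$top))
  expect_equal(got, reconstruct_laplacian_pyramid(fused), tolerance = 1e-12)
})
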