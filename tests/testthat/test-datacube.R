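test_that("datacube construction enforces its invariants", {
  v <- array(1:24, c(2, 3, 4))
  cube <- datacube(v, c(100, 200, 300, 400))
  expect_s3_class(cube, "hsi_cube")
  expect_identical(dim(cube), c(2L, 3L, 4L))

  expect_error(datacube(matrix(1:4, 2)), "3-D")
  expect_error(datacube(v, c(1, 2, 3)), "equal the number of bands")
  expect_error(datacube(v, c(4, 3, 2, 1)), "strictly increasing")
  expect_error(datacube(array(1e6, c(1, 1, 1)), dtype_origin = "int16"),
               "16-bit")
})

test_that("filter_bands keeps exactly the bands inside the closed interval", {
  cube <- rand_cube(3, 3, 10, wl = seq(100, 1000, by = 100))
  # full span is the identity
  full <- filter_bands(cube, c(100, 1000))
  expect_equal(full$values, cube$values)
  # forced inclusive-interval example
  mid <- filter_bands(cube, c(300, 700))
  expect_identical(mid$wavelengths, seq(300, 700, by = 100))
  expect_equal(dim(mid)[3], 5L)
  expect_error(filter_bands(cube, c(2000, 3000)), "no bands retained")

  # brute-force membership oracle on random axes/intervals
  set.seed(42)
  for (rep in 1:20) {
    wl <- sort(runif(12, 0, 100))
    c2 <- rand_cube(2, 2, 12, seed = rep, wl = wl)
    lohi <- sort(runif(2, 0, 100))
    keep <- vapply(wl, function(w) w >= lohi[1] && w <= lohi[2], logical(1))
    if (!any(keep)) {
      expect_error(filter_bands(c2, lohi), "no bands")
    } else {
      got <- filter_bands(c2, lohi)
      expect_identical(got$wavelengths, wl[keep])
      expect_equal(got$values, c2$values[, , keep, drop = FALSE])
      # idempotence under the same interval
      again <- filter_bands(got, lohi)
      expect_identical(again$wavelengths, got$wavelengths)
    }
  }
})

test_that("extract_roi uses 0-based half-open windows with no clipping", {
  cube <- rand_cube(10, 12, 3)
  expect_equal(extract_roi(cube, 0, 0, 10, 12)$values, cube$values)
  px <- extract_roi(cube, 3, 4, 1, 1)
  expect_equal(as.vector(px$values), cube$values[4, 5, ])
  expect_error(extract_roi(cube, 5, 0, 6, 2), "out of bounds")
  expect_error(extract_roi(cube, -1, 0, 2, 2), "out of bounds")

  # non-overlapping 4x4 windows share no source values
  a <- extract_roi(cube, 0, 0, 4, 4)
  b <- extract_roi(cube, 4, 4, 4, 4)
  expect_identical(dim(a), c(4L, 4L, 3L))
  expect_identical(dim(b), c(4L, 4L, 3L))
})

test_that("spectral_signature computes per-band mean and population sd", {
  cube <- datacube(array(7, c(3, 3, 2)))
  mask <- matrix(TRUE, 3, 3)
  sig <- spectral_signature(cube, mask)
  expect_equal(sig$mean, c(7, 7))
  expect_equal(sig$sd, c(0, 0))

  # two-pixel mask with band values {1, 3}: mean 2, population sd 1
  v <- array(0, c(2, 2, 1)); v[1, 1, 1] <- 1; v[2, 1, 1] <- 3
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  sig2 <- spectral_signature(datacube(v), m2)
  expect_equal(sig2$mean, 2)
  expect_equal(sig2$sd, 1)

  expect_error(spectral_signature(cube, matrix(FALSE, 3, 3)), "empty mask")

  # naive per-band loop oracle on a random mask
  c3 <- rand_cube(5, 5, 4, seed = 9)
  set.seed(10)
  mask3 <- matrix(runif(25) < 0.5, 5, 5)
  mask3[1, 1] <- TRUE
  sig3 <- spectral_signature(c3, mask3)
  for (k in 1:4) {
    vals <- c()
    for (i in 1:5) for (j in 1:5) if (mask3[i, j])
      vals <- c(vals, c3$values[i, j, k])
    expect_equal(sig3$mean[k], mean(vals))
    expect_equal(sig3$sd[k], sqrt(mean((vals - mean(vals))^2)))
  }
})

test_that("signature of a union mask lies between the part means", {
  cube <- rand_cube(6, 6, 3, seed = 4)
  m1 <- matrix(FALSE, 6, 6); m1[1:3, ] <- TRUE
  m2 <- !m1
  s1 <- spectral_signature(cube, m1)$mean
  s2 <- spectral_signature(cube, m2)$mean
  su <- spectral_signature(cube, m1 | m2)$mean
  expect_true(all(su >= pmin(s1, s2) - 1e-12 & su <= pmax(s1, s2) + 1e-12))
})

test_that("normalize_cube maps ranges as documented", {
  cube <- rand_cube(4, 4, 3, seed = 5)
  cube$values[1, 1, 1] <- -100; cube$values[2, 2, 2] <- 300
  mm <- normalize_cube(cube, "minmax")
  expect_equal(range(mm$values), c(0, 1))
  expect_identical(mm$dtype_origin, "real")

  zs <- normalize_cube(cube, "zscore")
  expect_lt(abs(mean(zs$values)), 1e-9)
  expect_lt(abs(mean(zs$values^2) - 1), 1e-9)

  expect_equal(normalize_cube(cube, "none"), cube)
  flat <- datacube(array(3, c(2, 2, 2)))
  expect_error(normalize_cube(flat, "zscore"), "constant")
})
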