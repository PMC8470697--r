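# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

rand_cube <- function(M = 8, N = 8, L = 4, seed = 1, wl = NULL) {
  set.seed(seed)
  datacube(array(rnorm(M * N * L), c(M, N, L)), wl)
}

# small two-class image set separated by a constant offset (extreme
# margin). Offset classes are only separable without per-image min-max
# normalization, so tests using this fixture train with normalize = FALSE.
margin_set <- function(n_per_class = 20, size = 12, offset = 5, seed = 1) {
  set.seed(seed)
  imgs <- array(rnorm(size * size * 2 * n_per_class), c(size, size, 2 * n_per_class))
  imgs[, , seq_len(n_per_class)] <- imgs[, , seq_len(n_per_class)] + offset
  image_set(imgs, rep(c("normal", "faulty"), each = n_per_class))
}

# two-class set where the positive class carries a bright central block;
# separable through the default per-image min-max normalization
pattern_set <- function(n_per_class = 12, size = 8, amp = 4, seed = 1) {
  set.seed(seed)
  imgs <- array(rnorm(size * size * 2 * n_per_class),
                c(size, size, 2 * n_per_class))
  blk <- (size %/% 2 - 1):(size %/% 2 + 1)
  for (i in seq_len(n_per_class)) imgs[blk, blk, i] <- imgs[blk, blk, i] + amp
  image_set(imgs, rep(c("normal", "faulty"), each = n_per_class))
}

# pure-noise image set with random labels (no signal)
noise_set <- function(n = 40, size = 12, seed = 1) {
  set.seed(seed)
  imgs <- array(rnorm(size * size * n), c(size, size, n))
  image_set(imgs, sample(c("normal", "faulty"), n, replace = TRUE,
                         prob = c(0.5, 0.5)))
}

# independent single-level 2-D Haar step used as a hand oracle: explicit
# 2x2 block arithmetic, no shared code with the package internals.
haar_block_forward <- function(x) {
  nr <- nrow(x) / 2; nc <- ncol(x) / 2
  LL <- LH <- HL <- HH <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    p <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    LL[i, j] <- (p[1, 1] + p[2, 1] + p[1, 2] + p[2, 2]) / 2
    LH[i, j] <- (p[1, 1] + p[2, 1] - p[1, 2] - p[2, 2]) / 2
    HL[i, j] <- (p[1, 1] - p[2, 1] + p[1, 2] - p[2, 2]) / 2
    HH[i, j] <- (p[1, 1] - p[2, 1] - p[1, 2] + p[2, 2]) / 2
  }
  list(LL = LL, LH = LH, HL = HL, HH = HH)
}

haar_block_inverse <- function(sb) {
  nr <- nrow(sb$LL); nc <- ncol(sb$LL)
  x <- matrix(0, 2 * nr, 2 * nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ll <- sb$LL[i, j]; lh <- sb$LH[i, j]; hl <- sb$HL[i, j]; hh <- sb$HH[i, j]
    x[2 * i - 1, 2 * j - 1] <- (ll + lh + hl + hh) / 2
    x[2 * i,     2 * j - 1] <- (ll + lh - hl - hh) / 2
    x[2 * i - 1, 2 * j]     <- (ll - lh + hl - hh) / 2
    x[2 * i,     2 * j]     <- (ll - lh - hl + hh) / 2
  }
  x
}
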