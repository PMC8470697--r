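# Periodic (circular) multilevel 2-D wavelet transforms: decimated DWT,
# undecimated SIDWT (a trous), and a dual-tree complex transform built from
# two orthonormal trees. Circular extension is used throughout: it makes
# every analysis operator exactly orthogonal, so synthesis is its transpose
# and reconstruction is exact to machine precision at any depth, and it is
# the extension under which the shift-invariant transform commutes exactly
# with circular shifts.

#' Orthonormal wavelet analysis filters
#'
#' Returns the lowpass/highpass analysis pair of an orthonormal Daubechies
#' family: `haar` (= db1), `db2` or `db4`. The highpass is the standard
#' alternating-sign mirror of the lowpass.
#'
#' @param family filter family name.
#' @return List with numeric vectors `h0` (lowpass) and `h1` (highpass).
#' @export
wavelet_filters <- function(family = c("haar", "db1", "db2", "db4")) {
  family <- match.arg(family)
  h0 <- switch(family,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(-0.129409522550921, 0.224143868041857,
            0.836516303737469, 0.482962913144690),
    db4 = c(-0.010597401784997, 0.032883011666983, 0.030841381835987,
            -0.187034811718881, -0.027983769416984, 0.630880767929590,
            0.714846570552542, 0.230377813308855))
  n <- seq_along(h0) - 1L
  h1 <- (-1)^n * rev(h0)
  list(h0 = h0, h1 = h1, family = family)
}

# --- 1-D building blocks (operate on the first dimension of a matrix) ----

# decimated analysis step: A[k,] = sum_n f[n] X[(2k + n + off) mod N, ]
conv_down <- function(X, f, off = 0L) {
  N <- nrow(X)
  if (N %% 2L != 0L) stop("signal length must be even for a decimated step")
  K <- N %/% 2L
  out <- matrix(0, K, ncol(X))
  base <- 2L * (seq_len(K) - 1L)
  for (n in seq_along(f)) {
    idx <- (base + (n - 1L) + off) %% N + 1L
    out <- out + f[n] * X[idx, , drop = FALSE]
  }
  out
}

# transpose of conv_down: Y[(2k + n + off) mod N, ] += f[n] A[k, ]
conv_up_add <- function(Y, A, f, off = 0L) {
  N <- nrow(Y)
  base <- 2L * (seq_len(nrow(A)) - 1L)
  for (n in seq_along(f)) {
    idx <- (base + (n - 1L) + off) %% N + 1L
    Y[idx, ] <- Y[idx, , drop = FALSE] + f[n] * A
  }
  Y
}

# undecimated (a trous) correlation with filter upsampled by `dil`:
# A[m,] = sum_n f[n] X[(m + dil*n) mod N, ]
conv_atrous <- function(X, f, dil) {
  N <- nrow(X)
  out <- matrix(0, N, ncol(X))
  base <- seq_len(N) - 1L
  for (n in seq_along(f)) {
    idx <- (base + dil * (n - 1L)) %% N + 1L
    out <- out + f[n] * X[idx, , drop = FALSE]
  }
  out
}

# adjoint of conv_atrous: Y[m,] = sum_n f[n] A[(m - dil*n) mod N, ]
conv_atrous_adj <- function(A, f, dil) {
  N <- nrow(A)
  out <- matrix(0, N, ncol(A))
  base <- seq_len(N) - 1L
  for (n in seq_along(f)) {
    idx <- (base - dil * (n - 1L)) %% N + 1L
    out <- out + f[n] * A[idx, , drop = FALSE]
  }
  out
}

# --- one 2-D level --------------------------------------------------------

# decimated: rows then columns; returns LL, LH, HL, HH (each half size)
dwt2_step <- function(img, f, off_r = 0L, off_c = 0L) {
  lo <- conv_down(img, f$h0, off_r)            # filter first dim (rows)
  hi <- conv_down(img, f$h1, off_r)
  ll <- t(conv_down(t(lo), f$h0, off_c)); lh <- t(conv_down(t(lo), f$h1, off_c))
  hl <- t(conv_down(t(hi), f$h0, off_c)); hh <- t(conv_down(t(hi), f$h1, off_c))
  list(LL = ll, LH = lh, HL = hl, HH = hh)
}

idwt2_step <- function(sb, f, off_r = 0L, off_c = 0L) {
  nr <- 2L * nrow(sb$LL); nc <- 2L * ncol(sb$LL)
  # undo the column transform first (rows still at half resolution) ...
  lo <- t(conv_up_add(conv_up_add(matrix(0, nc, nr %/% 2L), t(sb$LL), f$h0, off_c),
                      t(sb$LH), f$h1, off_c))
  hi <- t(conv_up_add(conv_up_add(matrix(0, nc, nr %/% 2L), t(sb$HL), f$h0, off_c),
                      t(sb$HH), f$h1, off_c))
  # ... then the row transform
  conv_up_add(conv_up_add(matrix(0, nr, nc), lo, f$h0, off_r), hi, f$h1, off_r)
}

# undecimated level with dilation 2^(level-1); all subbands full size
sidwt2_step <- function(img, f, dil) {
  lo <- conv_atrous(img, f$h0, dil); hi <- conv_atrous(img, f$h1, dil)
  list(LL = t(conv_atrous(t(lo), f$h0, dil)),
       LH = t(conv_atrous(t(lo), f$h1, dil)),
       HL = t(conv_atrous(t(hi), f$h0, dil)),
       HH = t(conv_atrous(t(hi), f$h1, dil)))
}

# inverse undecimated level: 1/4 of the adjoint (|H|^2 + |G|^2 = 2 per dim)
isidwt2_step <- function(sb, f, dil) {
  lo <- t(conv_atrous_adj(t(sb$LL), f$h0, dil)) +
        t(conv_atrous_adj(t(sb$LH), f$h1, dil))
  hi <- t(conv_atrous_adj(t(sb$HL), f$h0, dil)) +
        t(conv_atrous_adj(t(sb$HH), f$h1, dil))
  (conv_atrous_adj(lo, f$h0, dil) + conv_atrous_adj(hi, f$h1, dil)) / 4
}

# --- multilevel single-band decompositions --------------------------------

check_depth <- function(d, levels, transform) {
  if (levels < 1L) stop("levels must be >= 1")
  if (transform %in% c("dwt", "dtcwt") && any(d[1:2] %% 2L^levels != 0L))
    stop("image of size ", d[1], " x ", d[2], " cannot be decomposed to ",
         levels, " decimated levels (dimensions must be divisible by 2^levels)")
  if (any(d[1:2] < 2L^levels))
    stop("image too small for ", levels, " levels")
}

#' Multilevel 2-D wavelet decomposition of a single band
#'
#' Decomposes an image with one of three transforms under periodic
#' extension: `dwt` (decimated), `sidwt` (undecimated / shift-invariant,
#' a trous) or `dtcwt` (dual-tree complex: four parallel orthonormal
#' chains — tree b is the one-sample-delayed imaginary tree — combined
#' into six oriented complex detail subbands per level).
#'
#' @param image numeric matrix.
#' @param transform `"dwt"`, `"sidwt"` or `"dtcwt"`.
#' @param levels decomposition depth (default 3).
#' @param family orthonormal filter family, see [wavelet_filters()].
#' @return An object of class `wavelet_stack`: list with `transform`,
#'   `levels`, `family`, `dims`, per-level `detail` coefficient arrays and
#'   the final approximation `approx` (complex for `dtcwt` details).
#' @export
decompose_band <- function(image, transform = c("dwt", "sidwt", "dtcwt"),
                           levels = 3L, family = NULL) {
  transform <- match.arg(transform)
  if (!is.matrix(image)) stop("`image` must be a matrix")
  if (is.null(family)) family <- if (transform == "dtcwt") "db4" else "haar"
  f <- wavelet_filters(family)
  check_depth(dim(image), levels, transform)
  st <- switch(transform,
    dwt = {
      detail <- vector("list", levels); cur <- image
      for (l in seq_len(levels)) {
        sb <- dwt2_step(cur, f)
        detail[[l]] <- sb[c("LH", "HL", "HH")]
        cur <- sb$LL
      }
      list(detail = detail, approx = list(LL = cur))
    },
    sidwt = {
      detail <- vector("list", levels); cur <- image
      for (l in seq_len(levels)) {
        sb <- sidwt2_step(cur, f, 2L^(l - 1L))
        detail[[l]] <- sb[c("LH", "HL", "HH")]
        cur <- sb$LL
      }
      list(detail = detail, approx = list(LL = cur))
    },
    dtcwt = dtcwt_forward(image, f, levels))
  structure(c(st, list(transform = transform, levels = levels,
                       family = family, dims = dim(image))),
            class = "wavelet_stack")
}

#' Inverse of [decompose_band()]
#'
#' @param stack a `wavelet_stack`.
#' @return The reconstructed image matrix; for an unmodified stack this
#'   reproduces the decomposed image to near machine precision.
#' @export
reconstruct_band <- function(stack) {
  if (!inherits(stack, "wavelet_stack")) stop("expected a `wavelet_stack`")
  f <- wavelet_filters(stack$family)
  switch(stack$transform,
    dwt = {
      cur <- stack$approx$LL
      for (l in rev(seq_len(stack$levels))) {
        sb <- stack$detail[[l]]; sb$LL <- cur
        cur <- idwt2_step(sb, f)
      }
      cur
    },
    sidwt = {
      cur <- stack$approx$LL
      for (l in rev(seq_len(stack$levels))) {
        sb <- stack$detail[[l]]; sb$LL <- cur
        cur <- isidwt2_step(sb, f, 2L^(l - 1L))
      }
      cur
    },
    dtcwt = dtcwt_inverse(stack, f))
}

# --- dual-tree complex transform -----------------------------------------
# Four chains indexed by (row tree, col tree) in {a, b}; tree b applies the
# same orthonormal filters with a one-sample delay, giving an approximate
# quadrature pair. Each chain is an exactly invertible decimated transform;
# the inverse averages the four chain reconstructions. Detail coefficients
# of the four chains are combined unitarily into two complex subbands per
# orientation (six oriented subbands per level).

dtcwt_forward <- function(image, f, levels) {
  chains <- list(aa = image, ab = image, ba = image, bb = image)
  offs <- c(a = 0L, b = 1L)
  detail <- vector("list", levels)
  for (l in seq_len(levels)) {
    sbs <- lapply(names(chains), function(key) {
      rt <- substr(key, 1, 1); ct <- substr(key, 2, 2)
      dwt2_step(chains[[key]], f, offs[[rt]], offs[[ct]])
    })
    names(sbs) <- names(chains)
    detail[[l]] <- lapply(c(LH = "LH", HL = "HL", HH = "HH"), function(or) {
      waa <- sbs$aa[[or]]; wab <- sbs$ab[[or]]
      wba <- sbs$ba[[or]]; wbb <- sbs$bb[[or]]
      # unitary (up to scale) pairing into two oriented complex subbands
      list(p = matrix(complex(real = (waa - wbb) / 2,
                              imaginary = (wba + wab) / 2), nrow(waa)),
           m = matrix(complex(real = (waa + wbb) / 2,
                              imaginary = (wba - wab) / 2), nrow(waa)))
    })
    chains <- lapply(sbs, `[[`, "LL")
  }
  list(detail = detail, approx = chains)
}

dtcwt_split_complex <- function(cw) {
  # invert the unitary pairing back to the four real chain coefficients
  list(aa = Re(cw$p) + Re(cw$m), bb = Re(cw$m) - Re(cw$p),
       ab = Im(cw$p) - Im(cw$m), ba = Im(cw$p) + Im(cw$m))
}

dtcwt_inverse <- function(stack, f) {
  offs <- c(a = 0L, b = 1L)
  chains <- stack$approx
  for (l in rev(seq_len(stack$levels))) {
    lvl <- stack$detail[[l]]
    real_sb <- lapply(c(LH = "LH", HL = "HL", HH = "HH"),
                      function(or) dtcwt_split_complex(lvl[[or]]))
    chains <- lapply(names(chains), function(key) {
      rt <- substr(key, 1, 1); ct <- substr(key, 2, 2)
      sb <- list(LL = chains[[key]],
                 LH = real_sb$LH[[key]], HL = real_sb$HL[[key]],
                 HH = real_sb$HH[[key]])
      idwt2_step(sb, f, offs[[rt]], offs[[ct]])
    })
    names(chains) <- c("aa", "ab", "ba", "bb")
  }
  Reduce(`+`, chains) / 4
}
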