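# Gaussian / Laplacian pyramid with the 5-tap binomial (Burt-Adelson,
# a = 0.375) generating kernel, symmetric boundary extension, ceiling
# halving for odd sizes. Reconstruction is exact by construction: each
# Laplacian level stores the residual of its own expand step.

lp_kernel <- c(0.0625, 0.25, 0.375, 0.25, 0.0625)

# symmetric (half-point reflect) index for i possibly outside 1..n
reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

# separable smoothing along the first dimension, symmetric extension
smooth_dim1 <- function(X, kern = lp_kernel) {
  n <- nrow(X); half <- (length(kern) - 1L) %/% 2L
  out <- matrix(0, n, ncol(X))
  for (j in seq_along(kern)) {
    idx <- reflect_idx(seq_len(n) + (j - 1L - half), n)
    out <- out + kern[j] * X[idx, , drop = FALSE]
  }
  out
}

lp_smooth <- function(img, kern = lp_kernel) t(smooth_dim1(t(smooth_dim1(img, kern)), kern))

# smooth then keep odd-indexed rows/cols (ceiling halving)
lp_reduce <- function(img) {
  s <- lp_smooth(img)
  s[seq(1L, nrow(s), by = 2L), seq(1L, ncol(s), by = 2L), drop = FALSE]
}

# upsample by zero insertion then smooth with 2x the kernel per dimension
# (polyphase form: low-res sample i sits at upsampled position 2i-1, and
# boundary reflection happens in the low-res domain so that constants are
# preserved up to the image edge), cropped to the lower-level shape
expand_dim1 <- function(G, n_out, kern = lp_kernel) {
  n_low <- nrow(G)
  out <- matrix(0, n_out, ncol(G))
  m <- seq_len(n_out)
  for (j in seq_along(kern)) {
    pos <- m + j - 3L              # tap position in the upsampled domain
    odd <- pos %% 2L == 1L         # only odd positions carry samples
    if (!any(odd)) next
    i <- (pos[odd] + 1L) %/% 2L
    idx <- reflect_idx(i, n_low)
    out[m[odd], ] <- out[m[odd], , drop = FALSE] +
      2 * kern[j] * G[idx, , drop = FALSE]
  }
  out
}

lp_expand <- function(img, target_dim) {
  t(expand_dim1(t(expand_dim1(img, target_dim[1])), target_dim[2]))
}

#' Build a Laplacian pyramid
#'
#' The image is the bottom Gaussian level `G1`; each next Gaussian level is
#' a smooth-and-downsample of the previous one; Laplacian level `t` is
#' `G_t - expand(G_{t+1})`. The stack stores the `T` Laplacian levels plus
#' the top Gaussian level, from which the image can be reconstructed
#' exactly by the backward recurrence.
#'
#' @param image numeric matrix.
#' @param T number of Laplacian levels (default 3).
#' @return An object of class `pyramid_stack`: list with `laplacian` (list
#'   of `T` matrices), `top` (top Gaussian level), `T`, `dims`.
#' @export
build_laplacian_pyramid <- function(image, T = 3L) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  if (T < 1L) stop("T must be >= 1")
  if (2L^T > min(dim(image)))
    stop("image of size ", nrow(image), " x ", ncol(image),
         " is too small for ", T, " pyramid levels")
  lap <- vector("list", T)
  g <- image
  for (t in seq_len(T)) {
    g_next <- lp_reduce(g)
    lap[[t]] <- g - lp_expand(g_next, dim(g))
    g <- g_next
  }
  structure(list(laplacian = lap, top = g, T = T, dims = dim(image)),
            class = "pyramid_stack")
}

#' Reconstruct an image from its Laplacian pyramid
#'
#' Backward recurrence: starting from the top Gaussian level, repeatedly
#' expand and add the Laplacian level below.
#'
#' @param stack a `pyramid_stack`.
#' @return The reconstructed image matrix (exact for an unmodified stack).
#' @export
reconstruct_laplacian_pyramid <- function(stack) {
  if (!inherits(stack, "pyramid_stack")) stop("expected a `pyramid_stack`")
  g <- stack$top
  for (t in rev(seq_len(stack$T)))
    g <- stack$laplacian[[t]] + lp_expand(g, dim(stack$laplacian[[t]]))
  g
}
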