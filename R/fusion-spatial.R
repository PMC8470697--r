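#' @title Fused image container
#' @description Internal constructor for the result of any fusion rule:
#'   an `M x N` real matrix tagged with the method that produced it.
#' @keywords internal
fused_image <- function(values, method, params = list()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (any(!is.finite(values))) stop("fused image contains non-finite values")
  structure(list(values = values, method = method, params = params),
            class = "hsi_fused")
}

#' @export
print.hsi_fused <- function(x, ...) {
  cat(sprintf("<hsi_fused> %d x %d, method = %s\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' @export
dim.hsi_fused <- function(x) dim(x$values)

# cube values as an (M*N) x L matrix of pixel spectra
cube_mat <- function(cube) {
  d <- dim(cube$values)
  matrix(cube$values, d[1] * d[2], d[3])
}

#' Spatial fusion: per-pixel band average
#'
#' `F(i,j) = mean_k I(i,j,k)` — each pixel's spectrum collapses to its mean.
#'
#' @param cube an `hsi_cube`.
#' @return An `hsi_fused` image of the cube's spatial size.
#' @export
fuse_average <- function(cube) {
  assert_cube(cube)
  d <- dim(cube$values)
  fused_image(matrix(rowMeans(cube_mat(cube)), d[1], d[2]), "average")
}

#' Spatial fusion: per-pixel band minimum
#'
#' `F(i,j) = min_k I(i,j,k)` — the lowest value in the spectral dimension.
#'
#' @inheritParams fuse_average
#' @return An `hsi_fused` image.
#' @export
fuse_min <- function(cube) {
  assert_cube(cube)
  d <- dim(cube$values)
  m <- cube_mat(cube)
  fused_image(matrix(do.call(pmin, asplit(m, 2)), d[1], d[2]), "min")
}

#' Spatial fusion: per-pixel band maximum
#'
#' `F(i,j) = max_k I(i,j,k)` — the highest value in the spectral dimension.
#'
#' @inheritParams fuse_average
#' @return An `hsi_fused` image.
#' @export
fuse_max <- function(cube) {
  assert_cube(cube)
  d <- dim(cube$values)
  m <- cube_mat(cube)
  fused_image(matrix(do.call(pmax, asplit(m, 2)), d[1], d[2]), "max")
}

#' Spatial fusion: PCA band projection
#'
#' Treats each pixel spectrum as an observation of `L` band variables:
#' (1) reshape the cube to an `(M*N) x L` matrix `A`; (2) form the band
#' covariance matrix; (3) eigendecompose it; (4) keep the eigenvectors of
#' the `d` largest eigenvalues; (5) project `A` onto them, giving `d` score
#' images; (6) average the `d` score images into the fused image.
#'
#' The eigenvector sign ambiguity is resolved deterministically: each
#' retained eigenvector is flipped so its largest-magnitude loading is
#' positive. Ties in eigenvalues keep the symmetric eigensolver's order.
#'
#' @param cube an `hsi_cube` with at least two pixels.
#' @param d number of retained components (`1 <= d <= L`). When `NULL`,
#'   `d` is the smallest number of components whose cumulative explained
#'   variance reaches `var_threshold`.
#' @param var_threshold cumulative explained-variance fraction in `(0, 1]`
#'   used when `d` is `NULL` (default 0.99).
#' @param center mean-centre the band variables before projecting
#'   (default `TRUE`, standard PCA).
#' @return An `hsi_fused` image; the chosen `d`, eigenvalues and loadings
#'   are stored in `$params`.
#' @export
fuse_pca <- function(cube, d = NULL, var_threshold = 0.99, center = TRUE) {
  assert_cube(cube)
  dm <- dim(cube$values)
  if (dm[1] * dm[2] < 2) stop("PCA fusion needs at least two pixels")
  L <- dm[3]
  if (!is.null(d) && (d < 1 || d > L)) stop("`d` must lie in 1..L = ", L)
  A <- cube_mat(cube)
  Ac <- if (center) sweep(A, 2, colMeans(A)) else A
  C <- crossprod(Ac) / (nrow(Ac) - 1)
  eg <- eigen(C, symmetric = TRUE)       # eigenvalues non-increasing
  evals <- pmax(eg$values, 0)
  if (is.null(d)) {
    tot <- sum(evals)
    if (tot == 0) {
      warning("zero-variance cube: fused image is identically zero")
      d <- 1L
    } else {
      cum <- cumsum(evals) / tot
      d <- which(cum >= var_threshold - 1e-12)[1]
    }
  }
  P <- eg$vectors[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|loading| entry made positive
  for (j in seq_len(d)) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  H <- Ac %*% P
  fused_image(matrix(rowMeans(H), dm[1], dm[2]), "pca",
              params = list(d = d, eigenvalues = evals, loadings = P,
                            center = center))
}

#' Apply a fusion method by name
#'
#' Dispatcher over the eight pixel-level fusion rules: four spatial
#' (`average`, `min`, `max`, `pca`) and four transform-domain (`dwt`,
#' `sidwt`, `dtcwt`, `laplacian`).
#'
#' @param cube an `hsi_cube`.
#' @param method fusion method name.
#' @param ... method parameters passed through (`d`, `levels`, `family`,
#'   `approx_rule`, ...).
#' @return An `hsi_fused` image.
#' @export
fuse <- function(cube, method = c("average", "min", "max", "pca",
                                  "dwt", "sidwt", "dtcwt", "laplacian"),
                 ...) {
  method <- match.arg(method)
  switch(method,
    average   = fuse_average(cube),
    min       = fuse_min(cube),
    max       = fuse_max(cube),
    pca       = fuse_pca(cube, ...),
    dwt       = fuse_wavelet(cube, transform = "dwt", ...),
    sidwt     = fuse_wavelet(cube, transform = "sidwt", ...),
    dtcwt     = fuse_wavelet(cube, transform = "dtcwt", ...),
    laplacian = fuse_laplacian(cube, ...))
}

#' Names of all eight fusion methods
#' @return Character vector: the four spatial rules then the four
#'   transform-domain rules.
#' @export
fusion_methods <- function() {
  c("average", "min", "max", "pca", "dwt", "sidwt", "dtcwt", "laplacian")
}
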