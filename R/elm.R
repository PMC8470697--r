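#' Train an extreme learning machine
#'
#' A single-hidden-layer feed-forward network whose input weights and
#' biases are drawn once from a seeded uniform distribution and never
#' trained; the hidden activation matrix `H = g(XW + b)` is formed and the
#' output weights are the minimum-norm least-squares solution
#' `beta = H^+ Y` via the Moore-Penrose pseudo-inverse, with one-hot class
#' targets. There is no iterative training loop.
#'
#' Input weights are uniform on `[-s, s]` with `s = weight_scale /
#' sqrt(p)` for `p` input pixels (fan-in scaling). This keeps the
#' pre-activations of order one for images in [0, 1] regardless of image
#' size, so the activation works in its responsive range instead of
#' saturating; with thousands of input pixels an unscaled uniform draw
#' turns every hidden unit into a saturated random bit and destroys
#' generalization.
#'
#' @param data an [image_set()] with both classes present.
#' @param h number of hidden neurons (the study grid uses
#'   300/500/700/900/1000).
#' @param activation one of `"sigmoid"`, `"tribas"`, `"sine"`,
#'   `"hardlim"`, `"radbas"`; see [elm_activation()].
#' @param weight_scale input-weight scale before fan-in division
#'   (default 2).
#' @param seed RNG seed for the input weights.
#' @param normalize min-max each image to [0, 1] before flattening
#'   (default `TRUE`).
#' @return An `hsi_model` of family `"elm"`.
#' @export
train_elm <- function(data, h = 500L, activation = "sigmoid",
                      weight_scale = 2, seed = 1L, normalize = TRUE) {
  check_trainable(data)
  if (h < 1L) stop("h must be >= 1")
  g <- elm_activation(activation)
  images <- if (normalize) normalize_images(data$images) else data$images
  X <- flatten_images(images)
  p <- ncol(X)
  params <- local_seed(seed, {
    W <- matrix(runif(p * h, -1, 1), p, h) * (weight_scale / sqrt(p))
    b <- runif(h, -1, 1)
    list(W = W, b = b)
  })
  H <- g(sweep(X %*% params$W, 2, params$b, "+"))
  Y <- one_hot(data$labels)
  params$beta <- MASS::ginv(H) %*% Y
  params$activation <- activation
  new_model("elm", params, list(h = h, activation = activation, seed = seed),
            dim(data$images)[1:2], normalize)
}

elm_scores <- function(model, images) {
  X <- flatten_images(model_input(model, images))
  g <- elm_activation(model$params$activation)
  H <- g(sweep(X %*% model$params$W, 2, model$params$b, "+"))
  scores <- H %*% model$params$beta
  colnames(scores) <- class_levels
  scores
}
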