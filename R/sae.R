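# Sparse stacked autoencoder. Each layer is a tied-weight sigmoid
# autoencoder h = f(W x + b_h), y = f(W' h + b_y) pretrained greedily on
# the cost
#   J = (1/m) sum_i 1/2 ||x_i - y_i||^2  +  lambda/2 sum W^2
#       + beta * sum_j KL(rho || rho_hat_j),
# where rho_hat_j is the mean activation of hidden unit j over the batch
# and KL is the Bernoulli Kullback-Leibler divergence driving hidden units
# toward the sparsity target rho. The pretrained encoders are stacked under
# a softmax layer and the whole network is fine-tuned by backpropagation.

kl_bernoulli <- function(rho, rho_hat) {
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

# cost and gradient of one tied-weight sparse autoencoder layer.
# W: p x m; X: n x p rows = samples.
sae_cost_grad <- function(W, bh, by, X, rho, beta, lambda) {
  n <- nrow(X)
  H <- sigmoid(sweep(X %*% W, 2, bh, "+"))          # n x m
  Yh <- sigmoid(sweep(tcrossprod(H, W), 2, by, "+"))  # n x p  (H %*% t(W))
  rho_hat <- colMeans(H)
  rho_hat <- pmin(pmax(rho_hat, 1e-8), 1 - 1e-8)
  recon <- sum((X - Yh)^2) / (2 * n)
  cost <- recon + lambda / 2 * sum(W^2) + beta * kl_bernoulli(rho, rho_hat)
  D <- ((Yh - X) / n) * Yh * (1 - Yh)               # n x p
  gby <- colSums(D)
  kl_grad <- beta * (-rho / rho_hat + (1 - rho) / (1 - rho_hat)) / n
  dH <- (D %*% W + matrix(kl_grad, n, length(bh), byrow = TRUE)) * H * (1 - H)
  gbh <- colSums(dH)
  gW <- crossprod(X, dH) + crossprod(D, H) + lambda * W
  list(cost = cost, grads = list(W = gW, bh = gbh, by = gby),
       H = H, recon = recon, rho_hat = rho_hat)
}

# full-batch gradient descent with momentum on one autoencoder layer
pretrain_layer <- function(X, m, rho, beta, lambda, epochs, lr, momentum,
                           seed) {
  p <- ncol(X)
  init <- local_seed(seed, matrix(runif(p * m, -1, 1) * sqrt(6 / (p + m)),
                                  p, m))
  W <- init; bh <- rep(0, m); by <- rep(0, p)
  vW <- W * 0; vbh <- bh; vby <- by
  for (ep in seq_len(epochs)) {
    cg <- sae_cost_grad(W, bh, by, X, rho, beta, lambda)
    if (!is.finite(cg$cost)) stop("sae pretraining diverged (non-finite cost)")
    vW <- momentum * vW - lr * cg$grads$W;   W <- W + vW
    vbh <- momentum * vbh - lr * cg$grads$bh; bh <- bh + vbh
    vby <- momentum * vby - lr * cg$grads$by; by <- by + vby
  }
  list(W = W, bh = bh, by = by)
}

# forward through stacked sigmoid encoders + softmax; returns activations
mlp_forward <- function(net, X) {
  acts <- list(X)
  for (l in seq_along(net$W)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    acts[[l + 1L]] <- sigmoid(z)
  }
  logits <- sweep(acts[[length(acts)]] %*% net$Ws, 2, net$bs, "+")
  list(acts = acts, probs = softmax_rows(logits))
}

# cross-entropy loss + grads for the stacked sigmoid net
mlp_loss_grad <- function(net, X, Y, freeze_lower = FALSE) {
  fw <- mlp_forward(net, X)
  n <- nrow(X)
  loss <- -mean(rowSums(Y * log(fw$probs + 1e-12)))
  top <- fw$acts[[length(fw$acts)]]
  dlogits <- (fw$probs - Y) / n
  gWs <- crossprod(top, dlogits); gbs <- colSums(dlogits)
  gW <- vector("list", length(net$W)); gb <- vector("list", length(net$W))
  if (!freeze_lower) {
    delta <- tcrossprod(dlogits, net$Ws) * top * (1 - top)
    for (l in rev(seq_along(net$W))) {
      gW[[l]] <- crossprod(fw$acts[[l]], delta)
      gb[[l]] <- colSums(delta)
      if (l > 1L)
        delta <- tcrossprod(delta, net$W[[l]]) *
          fw$acts[[l]] * (1 - fw$acts[[l]])
    }
  } else {
    for (l in seq_along(net$W)) { gW[[l]] <- net$W[[l]] * 0; gb[[l]] <- net$b[[l]] * 0 }
  }
  list(loss = loss, gWs = gWs, gbs = gbs, gW = gW, gb = gb)
}

# minibatch SGD-with-momentum fine-tuning of the stacked net
finetune_mlp <- function(net, X, Y, epochs, lr, momentum, batch_size, seed,
                         freeze_lower = FALSE) {
  n <- nrow(X)
  vWs <- net$Ws * 0; vbs <- net$bs * 0
  vW <- lapply(net$W, function(w) w * 0); vb <- lapply(net$b, function(b) b * 0)
  hist <- numeric(epochs)
  local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      eploss <- 0
      for (bi in batches) {
        lg <- mlp_loss_grad(net, X[bi, , drop = FALSE], Y[bi, , drop = FALSE],
                            freeze_lower)
        if (!is.finite(lg$loss)) stop("fine-tuning diverged (non-finite loss)")
        eploss <- eploss + lg$loss * length(bi)
        vWs <- momentum * vWs - lr * lg$gWs; net$Ws <- net$Ws + vWs
        vbs <- momentum * vbs - lr * lg$gbs; net$bs <- net$bs + vbs
        if (!freeze_lower) for (l in seq_along(net$W)) {
          vW[[l]] <- momentum * vW[[l]] - lr * lg$gW[[l]]
          net$W[[l]] <- net$W[[l]] + vW[[l]]
          vb[[l]] <- momentum * vb[[l]] - lr * lg$gb[[l]]
          net$b[[l]] <- net$b[[l]] + vb[[l]]
        }
      }
      hist[ep] <- eploss / n
    }
  })
  net$loss_history <- hist
  net
}

#' Train the sparse stacked autoencoder classifier
#'
#' Greedy layer-wise pretraining of tied-weight sigmoid autoencoders with
#' an L2 weight penalty and a KL-divergence sparsity penalty (target
#' activation `rho`, weight `beta`), followed by stacking under a softmax
#' output and end-to-end fine-tuning by backpropagation.
#'
#' @param data an [image_set()] with both classes.
#' @param hidden_sizes hidden layer widths (default `c(256, 64, 32)`).
#' @param rho sparsity target in (0, 1) (default 0.15).
#' @param beta sparsity penalty weight (default 2; study range 1-4).
#' @param lambda L2 weight decay (default 0.003; study range 0.001-0.006).
#' @param pretrain_epochs full-batch pretraining epochs per layer
#'   (default 100; study range 100-800).
#' @param finetune_epochs fine-tuning epochs (default 100).
#' @param lr,momentum,batch_size optimizer settings.
#' @param seed RNG seed.
#' @param normalize min-max each image to [0, 1] first (default `TRUE`).
#' @return An `hsi_model` of family `"sae"`.
#' @export
train_sae <- function(data, hidden_sizes = c(256L, 64L, 32L), rho = 0.15,
                      beta = 2, lambda = 0.003, pretrain_epochs = 100L,
                      finetune_epochs = 100L, lr = 0.1, momentum = 0.9,
                      batch_size = 32L, seed = 1L, normalize = TRUE) {
  check_trainable(data)
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly inside (0, 1)")
  if (beta < 0 || lambda < 0) stop("beta and lambda must be >= 0")
  cfg <- list(hidden_sizes = hidden_sizes, rho = rho, beta = beta,
              lambda = lambda, pretrain_epochs = pretrain_epochs,
              finetune_epochs = finetune_epochs, lr = lr,
              momentum = momentum, batch_size = batch_size, seed = seed)
  images <- if (normalize) normalize_images(data$images) else data$images
  X <- flatten_images(images)
  Y <- one_hot(data$labels)
  W <- list(); b <- list()
  cur <- X
  for (l in seq_along(hidden_sizes)) {
    ae <- pretrain_layer(cur, hidden_sizes[l], rho, beta, lambda,
                         pretrain_epochs, lr, momentum, seed + l)
    W[[l]] <- ae$W; b[[l]] <- ae$bh
    cur <- sigmoid(sweep(cur %*% ae$W, 2, ae$bh, "+"))
  }
  top_w <- local_seed(seed + 100L,
                      matrix(runif(tail(hidden_sizes, 1) * 2, -1, 1) * 0.1,
                             tail(hidden_sizes, 1), 2))
  net <- list(W = W, b = b, Ws = top_w, bs = rep(0, 2))
  net <- finetune_mlp(net, X, Y, finetune_epochs, lr, momentum, batch_size,
                      seed + 200L)
  new_model("sae", net, cfg, dim(data$images)[1:2], normalize)
}

sae_scores <- function(model, images) {
  X <- flatten_images(model_input(model, images))
  probs <- mlp_forward(model$params, X)$probs
  colnames(probs) <- class_levels
  probs
}
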