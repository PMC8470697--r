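# Deep belief network: a greedy stack of restricted Boltzmann machines.
# Each RBM is a bipartite layer pair (no visible-visible or hidden-hidden
# edges). The bottom RBM has Gaussian visible units for real-valued fused
# images (unit variance, linear reconstruction mean); upper RBMs are
# Bernoulli-Bernoulli. Pretraining is contrastive divergence (CD-k, seeded
# Gibbs sampling); the stack plus a softmax top layer is then fine-tuned
# by backpropagation.

# one CD-k update step on a minibatch. V: nb x p. Returns gradient
# *estimates* (positive phase minus negative phase), not yet scaled by lr.
rbm_cd_grad <- function(W, bv, bh, V, k = 1L, visible = c("gaussian", "bernoulli")) {
  visible <- match.arg(visible)
  nb <- nrow(V)
  ph0 <- sigmoid(sweep(V %*% W, 2, bh, "+"))
  h <- (matrix(runif(length(ph0)), nb) < ph0) + 0
  for (step in seq_len(k)) {
    vrec <- sweep(tcrossprod(h, W), 2, bv, "+")
    if (visible == "bernoulli") vrec <- sigmoid(vrec)
    # mean-field reconstruction (no visible sampling) for stability
    ph <- sigmoid(sweep(vrec %*% W, 2, bh, "+"))
    h <- if (step < k) (matrix(runif(length(ph)), nb) < ph) + 0 else ph
  }
  list(dW = (crossprod(V, ph0) - crossprod(vrec, ph)) / nb,
       dbv = colMeans(V) - colMeans(vrec),
       dbh = colMeans(ph0) - colMeans(ph))
}

train_rbm <- function(V, m, epochs, lr, momentum, batch_size, cd_steps,
                      visible, seed) {
  p <- ncol(V); n <- nrow(V)
  W <- local_seed(seed, matrix(rnorm(p * m, sd = 0.05), p, m))
  bv <- rep(0, p); bh <- rep(0, m)
  vW <- W * 0; vbv <- bv; vbh <- bh
  local_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (bi in split(ord, ceiling(seq_along(ord) / batch_size))) {
        g <- rbm_cd_grad(W, bv, bh, V[bi, , drop = FALSE], cd_steps, visible)
        vW <- momentum * vW + lr * g$dW;   W <- W + vW
        vbv <- momentum * vbv + lr * g$dbv; bv <- bv + vbv
        vbh <- momentum * vbh + lr * g$dbh; bh <- bh + vbh
      }
    }
  })
  list(W = W, bv = bv, bh = bh)
}

#' Train the deep belief network classifier
#'
#' Greedy contrastive-divergence pretraining of a stack of restricted
#' Boltzmann machines (Gaussian visible units at the bottom for
#' real-valued images, Bernoulli units above), then supervised fine-tuning
#' of the unrolled sigmoid network with a softmax top layer.
#'
#' @param data an [image_set()] with both classes.
#' @param hidden_sizes RBM hidden layer widths (default
#'   `c(512, 256, 128, 64, 32)`).
#' @param epochs CD pretraining epochs per RBM (default 100; study range
#'   100-800).
#' @param lr CD learning rate (default 0.05; study range 0.01-0.06).
#' @param momentum CD/fine-tune momentum (default 0.5; the printed study
#'   range is read as 0-0.8).
#' @param batch_size minibatch size for CD (default 5; study range 1-5).
#' @param cd_steps Gibbs steps per CD update (default 1).
#' @param finetune_epochs supervised fine-tuning epochs (default 100).
#' @param finetune_lr,finetune_momentum,finetune_batch fine-tuning
#'   optimizer settings (default lr 0.3, momentum 0.9; sigmoid stacks need
#'   a larger rate than ReLU nets).
#' @param freeze_lower fine-tune only the softmax layer (default `FALSE`:
#'   full backpropagation through all layers).
#' @param seed RNG seed (initialization, Gibbs sampling, shuffling).
#' @param normalize min-max each image to [0, 1] first (default `TRUE`).
#' @return An `hsi_model` of family `"dbn"`.
#' @export
train_dbn <- function(data, hidden_sizes = c(512L, 256L, 128L, 64L, 32L),
                      epochs = 100L, lr = 0.05, momentum = 0.5,
                      batch_size = 5L, cd_steps = 1L, finetune_epochs = 100L,
                      finetune_lr = 0.3, finetune_momentum = 0.9,
                      finetune_batch = 32L,
                      freeze_lower = FALSE, seed = 1L, normalize = TRUE) {
  check_trainable(data)
  if (lr <= 0) stop("learning rate must be > 0")
  cfg <- list(hidden_sizes = hidden_sizes, epochs = epochs, lr = lr,
              momentum = momentum, batch_size = batch_size,
              cd_steps = cd_steps, finetune_epochs = finetune_epochs,
              freeze_lower = freeze_lower, seed = seed)
  images <- if (normalize) normalize_images(data$images) else data$images
  X <- flatten_images(images)
  Y <- one_hot(data$labels)
  W <- list(); b <- list()
  cur <- X
  for (l in seq_along(hidden_sizes)) {
    rbm <- train_rbm(cur, hidden_sizes[l], epochs, lr, momentum, batch_size,
                     cd_steps, if (l == 1L) "gaussian" else "bernoulli",
                     seed + 10L * l)
    W[[l]] <- rbm$W; b[[l]] <- rbm$bh
    cur <- sigmoid(sweep(cur %*% rbm$W, 2, rbm$bh, "+"))
  }
  top_w <- local_seed(seed + 500L,
                      matrix(runif(tail(hidden_sizes, 1) * 2, -1, 1) * 0.1,
                             tail(hidden_sizes, 1), 2))
  net <- list(W = W, b = b, Ws = top_w, bs = rep(0, 2))
  net <- finetune_mlp(net, X, Y, finetune_epochs, finetune_lr,
                      finetune_momentum, finetune_batch, seed + 600L,
                      freeze_lower)
  new_model("dbn", net, cfg, dim(data$images)[1:2], normalize)
}

dbn_scores <- function(model, images) {
  X <- flatten_images(model_input(model, images))
  probs <- mlp_forward(model$params, X)$probs
  colnames(probs) <- class_levels
  probs
}

# exact log-likelihood gradient of a tiny Bernoulli-Bernoulli RBM by
# enumerating all visible/hidden states; used as an oracle for CD updates.
rbm_exact_grad <- function(W, bv, bh, V) {
  p <- ncol(V); m <- ncol(W)
  vis_states <- as.matrix(expand.grid(rep(list(0:1), p)))
  energy_free <- function(v) {
    # unnormalized log p(v) = bv.v + sum_j log(1 + exp(bh_j + v.W_j))
    as.vector(v %*% bv) + rowSums(log1p(exp(sweep(v %*% W, 2, bh, "+"))))
  }
  lw <- energy_free(vis_states)
  pr <- exp(lw - max(lw)); pr <- pr / sum(pr)
  ph_all <- sigmoid(sweep(vis_states %*% W, 2, bh, "+"))
  model_W <- crossprod(vis_states * pr, ph_all)
  model_bv <- colSums(vis_states * pr)
  model_bh <- colSums(ph_all * pr)
  ph_data <- sigmoid(sweep(V %*% W, 2, bh, "+"))
  list(dW = crossprod(V, ph_data) / nrow(V) - model_W,
       dbv = colMeans(V) - model_bv,
       dbh = colMeans(ph_data) - model_bh)
}
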