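# Wasserstein GAN with gradient penalty for tabular PC-score augmentation.
#
# Generator and critic are small two-hidden-layer MLPs (ReLU) trained with
# the Wasserstein objective plus the gradient penalty
# lambda * (||grad_x critic(x_hat)|| - 1)^2 on points interpolated between
# real and generated rows. Backpropagation, including the double backprop
# through the gradient penalty, is written out analytically: with ReLU
# activations the second-derivative terms vanish and the penalty gradient
# has a closed form. Sized for ~5-dimensional inputs at desk scale; no GPU,
# no external deep-learning dependency.

mlp_init <- function(sizes, seed_state_unused = NULL) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    sd <- sqrt(2 / sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0, sd),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

relu <- function(x) pmax(x, 0)

# forward pass keeping activations; hidden layers ReLU, output linear
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A[[l]] <- sweep(H[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    H[[l + 1L]] <- if (l < L) relu(A[[l]]) else A[[l]]
  }
  list(A = A, H = H, out = H[[L + 1L]])
}

# gradient of scalar loss with dL/d(out) = dOut; returns param grads and
# dL/dX for chaining into the generator
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (fw$A[[l]] > 0)
    gW[[l]] <- crossprod(fw$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(gW = gW, gb = gb, dX = delta)
}

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0), t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}

# per-sample input gradients of a 2-hidden-layer ReLU critic, plus the
# closed-form parameter gradients of the penalty mean((||g|| - 1)^2)
critic_gradient_penalty <- function(net, Xhat, lambda_gp) {
  m <- nrow(Xhat)
  fw <- mlp_forward(net, Xhat)
  s1 <- fw$A[[1L]] > 0            # m x h1
  s2 <- fw$A[[2L]] > 0            # m x h2
  w3 <- as.vector(net$W[[3L]])    # h2
  # r1[i, ] = W2 (s2_i * w3): m x h1
  r1 <- (s2 * matrix(w3, m, length(w3), byrow = TRUE)) %*% t(net$W[[2L]])
  # g[i, ] = W1 (s1_i * r1_i): m x d
  g <- (s1 * r1) %*% t(net$W[[1L]])
  gnorm <- sqrt(rowSums(g^2)) + 1e-12
  penalty <- mean((gnorm - 1)^2)
  # v[i, ] = dP/dg_i = 2 (||g||-1) g / (||g|| m)
  v <- (2 * (gnorm - 1) / (gnorm * m)) * g
  u1 <- v %*% net$W[[1L]]                       # m x h1 (= W1^T v per sample)
  su1 <- s1 * u1
  gW1 <- crossprod(v, s1 * r1)                  # d x h1
  gW2 <- crossprod(su1, s2 * matrix(w3, m, length(w3), byrow = TRUE))
  gw3 <- matrix(colSums(s2 * (su1 %*% net$W[[2L]])), ncol = 1L)
  zero_b <- lapply(net$b, function(b) b * 0)
  list(penalty = lambda_gp * penalty,
       gW = lapply(list(gW1, gW2, gw3), function(x) lambda_gp * x),
       gb = zero_b)
}

add_grads <- function(a, b) {
  list(gW = Map(`+`, a$gW, b$gW), gb = Map(`+`, a$gb, b$gb))
}

#' WGAN-GP augmentation of a PC-score class
#'
#' Trains a small Wasserstein GAN with gradient penalty on the class rows
#' (standardized internally) and emits `n_new` generated rows. Each epoch
#' samples a batch, runs `critic_steps` critic updates then one generator
#' update. Deterministic under a fixed seed (single-threaded base-R linear
#' algebra).
#'
#' @param class_rows numeric matrix of the class's PC scores (n >= 20).
#' @param n_new number of rows to generate.
#' @param seed integer seed.
#' @param epochs number of generator update steps.
#' @param lambda_gp gradient-penalty weight; `0` trains an unpenalized
#'   Wasserstein loss (a message flags this).
#' @param critic_steps critic updates per generator update.
#' @param hidden widths of the two hidden layers.
#' @param lr Adam learning rate.
#' @param batch mini-batch size (clamped to n; the default is effectively
#'   full-batch at the class sizes this pipeline produces, which stabilises
#'   training at desk scale).
#' @return `n_new x k` matrix with attribute `critic_loss` (per-epoch log).
#' @export
wgan_gp_augment <- function(class_rows, n_new, seed = 1L, epochs = 1000L,
                            lambda_gp = 10, critic_steps = 5L,
                            hidden = c(32L, 32L), lr = 1e-3, batch = 512L) {
  X <- as.matrix(class_rows)
  if (nrow(X) < 20L) stop("WGAN-GP needs class n >= 20")
  if (lambda_gp == 0) message("lambda_gp = 0: unpenalized Wasserstein loss")
  d <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  batch <- min(batch, nrow(Z))
  gen <- mlp_init(c(d, hidden, d))
  crit <- mlp_init(c(d, hidden, 1L))
  opt_g <- adam_init(gen)
  opt_c <- adam_init(crit)
  closs <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    for (cs in seq_len(critic_steps)) {
      real <- Z[sample.int(nrow(Z), batch, replace = TRUE), , drop = FALSE]
      noise <- matrix(stats::rnorm(batch * d), batch, d)
      fake <- mlp_forward(gen, noise)$out
      fw_r <- mlp_forward(crit, real)
      fw_f <- mlp_forward(crit, fake)
      w_loss <- mean(fw_f$out) - mean(fw_r$out)
      g_r <- mlp_backward(crit, fw_r, matrix(-1 / batch, batch, 1L))
      g_f <- mlp_backward(crit, fw_f, matrix(1 / batch, batch, 1L))
      grads <- add_grads(g_r, g_f)
      if (lambda_gp > 0) {
        eps_mix <- stats::runif(batch)
        xhat <- eps_mix * real + (1 - eps_mix) * fake
        gp <- critic_gradient_penalty(crit, xhat, lambda_gp)
        grads <- add_grads(grads, gp)
        w_loss <- w_loss + gp$penalty
      }
      if (!is.finite(w_loss)) {
        stop("WGAN-GP diverged (non-finite critic loss); lower the ",
             "learning rate")
      }
      upd <- adam_step(crit, grads, opt_c, lr)
      crit <- upd$net
      opt_c <- upd$state
    }
    closs[ep] <- w_loss
    noise <- matrix(stats::rnorm(batch * d), batch, d)
    fw_g <- mlp_forward(gen, noise)
    fw_c <- mlp_forward(crit, fw_g$out)
    dfake <- mlp_backward(crit, fw_c, matrix(-1 / batch, batch, 1L))$dX
    g_gen <- mlp_backward(gen, fw_g, dfake)
    upd <- adam_step(gen, g_gen, opt_g, lr)
    gen <- upd$net
    opt_g <- upd$state
  }
  noise <- matrix(stats::rnorm(n_new * d), n_new, d)
  out <- mlp_forward(gen, noise)$out
  out <- sweep(sweep(out, 2L, sdv, `*`), 2L, mu, `+`)
  colnames(out) <- colnames(X)
  attr(out, "critic_loss") <- closs
  out
}
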