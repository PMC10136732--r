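# Compact convolutional network for pathway-grid images.
#
# Architecture (10 layers, 8 hidden): conv 4 filters 3x3 -> conv 4 filters
# 3x3 -> flatten -> dense 256 -> dropout -> dense 64 -> dropout ->
# dense 16 -> dense 1 (sigmoid). Rectified-linear hidden activations,
# class-weighted binary cross-entropy, adadelta optimization. Implemented
# directly in vectorized R (im2col convolutions with explicit
# backpropagation): fully deterministic under one seed and free of
# external runtime dependencies.

# im2col linear indices for an (H, W, C) array and a 3x3 valid kernel:
# K = (H-2)(W-2) patch rows, 9C columns (di, dj, then channel-major).
conv_indices <- function(H, W, C) {
  H2 <- H - 2L; W2 <- W - 2L
  stopifnot(H2 >= 1L, W2 >= 1L)
  k_i <- rep(seq_len(H2), W2)
  k_j <- rep(seq_len(W2), each = H2)
  idx <- matrix(0L, H2 * W2, 9L * C)
  col <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    col <- col + 1L
    idx[, col] <- (k_i + di) + (k_j + dj - 1L) * H + (c - 1L) * H * W
  }
  idx
}

# im2col over a batch: x is an (H, W, C, N) array; returns (K*N) x 9C
# matrix with sample-major row blocks.
im2col_batch <- function(x, idx) {
  d <- dim(x)
  N <- d[4]
  K <- nrow(idx)
  off <- (seq_len(N) - 1L) * prod(d[1:3])
  out <- matrix(0, K * N, ncol(idx))
  xf <- as.vector(x)
  for (j in seq_len(ncol(idx)))
    out[, j] <- xf[rep.int(idx[, j], N) + rep(off, each = K)]
  out
}

# Scatter-add of patch gradients back onto the input batch.
col2im_batch <- function(dP, idx, dims, N) {
  K <- nrow(idx)
  off <- (seq_len(N) - 1L) * prod(dims)
  dx <- numeric(prod(dims) * N)
  for (j in seq_len(ncol(idx))) {
    pos <- rep.int(idx[, j], N) + rep(off, each = K)
    dx[pos] <- dx[pos] + dP[, j]
  }
  array(dx, dim = c(dims, N))
}

relu <- function(z) z * (z > 0)

cnn_init <- function(H, W, seed) {
  if (H < 5L || W < 5L)
    stop("images must be at least 5 x 5 for two 3x3 convolutions",
         call. = FALSE)
  with_seed(seed, {
    he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
    Fdim <- (H - 4L) * (W - 4L) * 4L
    list(Wc1 = he(9L, 4L), bc1 = numeric(4),
         Wc2 = he(36L, 4L), bc2 = numeric(4),
         W1 = he(Fdim, 256L), b1 = numeric(256),
         W2 = he(256L, 64L), b2 = numeric(64),
         W3 = he(64L, 16L), b3 = numeric(16),
         W4 = he(16L, 1L), b4 = numeric(1))
  })
}

# Forward pass. x: (H, W, 1, N). Returns activations needed for backprop
# when keep_cache = TRUE; drop_masks NULL disables dropout (inference).
cnn_forward <- function(par, x, idx1, idx2, drop_masks = NULL,
                        keep_cache = FALSE) {
  d <- dim(x); N <- d[4]
  H2 <- d[1] - 2L; W2 <- d[2] - 2L
  H4 <- d[1] - 4L; W4 <- d[2] - 4L
  P1 <- im2col_batch(x, idx1)
  Z1 <- sweep(P1 %*% par$Wc1, 2L, par$bc1, "+")
  A1 <- relu(Z1)
  a1 <- array(A1, c(H2 * W2, N, 4L))
  a1 <- aperm(a1, c(1L, 3L, 2L))
  dim(a1) <- c(H2, W2, 4L, N)
  P2 <- im2col_batch(a1, idx2)
  Z2 <- sweep(P2 %*% par$Wc2, 2L, par$bc2, "+")
  A2 <- relu(Z2)
  a2 <- array(A2, c(H4 * W4, N, 4L))
  a2 <- aperm(a2, c(1L, 3L, 2L))
  Fdim <- H4 * W4 * 4L
  Xf <- t(`dim<-`(a2, c(Fdim, N)))
  D1 <- relu(sweep(Xf %*% par$W1, 2L, par$b1, "+"))
  if (!is.null(drop_masks)) D1 <- D1 * drop_masks$m1
  D2 <- relu(sweep(D1 %*% par$W2, 2L, par$b2, "+"))
  if (!is.null(drop_masks)) D2 <- D2 * drop_masks$m2
  D3 <- relu(sweep(D2 %*% par$W3, 2L, par$b3, "+"))
  logit <- drop(D3 %*% par$W4) + par$b4
  p <- 1 / (1 + exp(-logit))
  out <- list(p = p)
  if (keep_cache)
    out <- c(out, list(P1 = P1, Z1 = Z1, a1dim = c(H2, W2, 4L),
                       P2 = P2, Z2 = Z2, Xf = Xf,
                       D1 = D1, D2 = D2, D3 = D3, N = N))
  out
}

cnn_backward <- function(par, cache, x, idx1, idx2, dlogit, drop_masks) {
  N <- cache$N
  g <- list()
  g$W4 <- crossprod(cache$D3, dlogit)
  g$b4 <- sum(dlogit)
  dD3 <- (dlogit %*% t(par$W4)) * (cache$D3 > 0)
  g$W3 <- crossprod(cache$D2, dD3)
  g$b3 <- colSums(dD3)
  dD2 <- (dD3 %*% t(par$W3)) * (cache$D2 > 0)
  if (!is.null(drop_masks)) dD2 <- dD2 * drop_masks$m2
  g$W2 <- crossprod(cache$D1, dD2)
  g$b2 <- colSums(dD2)
  dD1 <- (dD2 %*% t(par$W2)) * (cache$D1 > 0)
  if (!is.null(drop_masks)) dD1 <- dD1 * drop_masks$m1
  g$W1 <- crossprod(cache$Xf, dD1)
  g$b1 <- colSums(dD1)
  dXf <- dD1 %*% t(par$W1)                       # N x Fdim
  H4W4 <- nrow(idx2) ; # patches of conv2 = (H-4)(W-4)
  # back to sample-major (K*N) x 4 layout of A2
  da2 <- array(t(dXf), c(H4W4, 4L, N))
  dA2 <- `dim<-`(aperm(da2, c(1L, 3L, 2L)), c(H4W4 * N, 4L))
  dZ2 <- dA2 * (cache$Z2 > 0)
  g$Wc2 <- crossprod(cache$P2, dZ2)
  g$bc2 <- colSums(dZ2)
  dP2 <- dZ2 %*% t(par$Wc2)
  a1dim <- cache$a1dim
  da1 <- col2im_batch(dP2, idx2, a1dim, N)       # (H2, W2, 4, N)
  K1 <- a1dim[1] * a1dim[2]
  da1 <- aperm(`dim<-`(da1, c(K1, 4L, N)), c(1L, 3L, 2L))
  dA1 <- `dim<-`(da1, c(K1 * N, 4L))
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$Wc1 <- crossprod(cache$P1, dZ1)
  g$bc1 <- colSums(dZ1)
  g
}

# Weighted binary cross-entropy; p clipped away from 0/1.
wbce <- function(p, y, w) {
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

adadelta_step <- function(par, grads, state, rho = 0.95, eps = 1e-6) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$Eg2[[nm]] <- rho * state$Eg2[[nm]] + (1 - rho) * g^2
    dx <- -sqrt(state$Edx2[[nm]] + eps) / sqrt(state$Eg2[[nm]] + eps) * g
    state$Edx2[[nm]] <- rho * state$Edx2[[nm]] + (1 - rho) * dx^2
    par[[nm]] <- par[[nm]] + dx
  }
  list(par = par, state = state)
}

#' Train the imPlatelet-style convolutional network
#'
#' Fits the compact CNN (two 3x3 convolutions with four filters each,
#' four dense layers of 256/64/16/1 units with two dropout layers) on
#' pathway-grid images using class-weighted binary cross-entropy and
#' adadelta, returning the parameters of the epoch with the best
#' validation loss. Deterministic for a fixed seed in single-threaded
#' mode.
#'
#' @param images a `tep_images` object from [build_images()] (all samples
#'   share one shape by construction).
#' @param y named label vector (`cancer` / `control`).
#' @param val_ids validation sample ids; remaining samples train.
#' @param epochs maximum epochs (default 100).
#' @param seed seed for initialization, shuffling and dropout.
#' @param batch_size minibatch size.
#' @param dropout dropout rate of the two dropout layers.
#' @return object of class `tep_model` with `kind = "implatelet_cnn"`.
#' @export
train_implatelet <- function(images, y, val_ids, epochs = 100L, seed = 1L,
                             batch_size = 32L, dropout = 0.3) {
  stopifnot(inherits(images, "tep_images"))
  d <- dim(images$values)
  H <- d[1]; W <- d[2]
  if (H < 5L || W < 5L)
    stop("images must be at least 5 x 5 for two 3x3 convolutions",
         call. = FALSE)
  ids <- images$sample_ids
  y <- y[ids]
  if (anyNA(y)) stop("labels missing for some samples", call. = FALSE)
  if (!all(val_ids %in% ids)) stop("val_ids must be image samples", call. = FALSE)
  tr_ids <- setdiff(ids, val_ids)
  x <- array(images$values, c(H, W, 1L, d[3]))
  dimnames(x) <- NULL
  tr_idx <- match(tr_ids, ids); va_idx <- match(val_ids, ids)
  yb <- as.integer(y == "cancer")
  w_class <- class_weights(y[tr_ids])
  wb <- w_class[ifelse(yb == 1, "cancer", "control")]
  idx1 <- conv_indices(H, W, 1L)
  idx2 <- conv_indices(H - 2L, W - 2L, 4L)
  par <- cnn_init(H, W, seed)
  zero_like <- lapply(par, function(p) p * 0)
  state <- list(Eg2 = zero_like, Edx2 = zero_like)
  xv <- x[, , , va_idx, drop = FALSE]
  best <- list(loss = Inf, par = par, epoch = 0L)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        xb <- x[, , , b, drop = FALSE]
        n_b <- length(b)
        masks <- list(
          m1 = matrix(rbinom(n_b * 256L, 1L, 1 - dropout), n_b) / (1 - dropout),
          m2 = matrix(rbinom(n_b * 64L, 1L, 1 - dropout), n_b) / (1 - dropout))
        fw <- cnn_forward(par, xb, idx1, idx2, masks, keep_cache = TRUE)
        wi <- wb[b]
        dlogit <- matrix(wi * (fw$p - yb[b]) / sum(wi), ncol = 1L)
        grads <- cnn_backward(par, fw, xb, idx1, idx2, dlogit, masks)
        upd <- adadelta_step(par, grads, state)
        par <- upd$par; state <- upd$state
      }
      pv <- cnn_forward(par, xv, idx1, idx2)$p
      vloss <- wbce(pv, yb[va_idx],
                    w_class[ifelse(yb[va_idx] == 1, "cancer", "control")])
      if (vloss < best$loss) best <- list(loss = vloss, par = par, epoch = ep)
    }
  })
  pv <- cnn_forward(best$par, xv, idx1, idx2)$p
  structure(list(kind = "implatelet_cnn", par = best$par,
                 shape = c(H, W), epochs = epochs, best_epoch = best$epoch,
                 class_weights = w_class, seed = seed, dropout = dropout,
                 val_loss = best$loss,
                 val_auc = roc_auc(setNames(yb[va_idx], val_ids),
                                   setNames(pv, val_ids))$auc),
            class = "tep_model")
}

# Inference on a tep_images object (or raw H x W x N array).
cnn_predict <- function(model, images) {
  vals <- if (inherits(images, "tep_images")) images$values else images
  d <- dim(vals)
  if (length(d) != 3L || d[1] != model$shape[1] || d[2] != model$shape[2])
    stop(sprintf("image shape %s does not match training shape %d x %d",
                 paste(d[1:2], collapse = " x "),
                 model$shape[1], model$shape[2]), call. = FALSE)
  x <- array(vals, c(d[1], d[2], 1L, d[3]))
  idx1 <- conv_indices(d[1], d[2], 1L)
  idx2 <- conv_indices(d[1] - 2L, d[2] - 2L, 4L)
  p <- cnn_forward(model$par, x, idx1, idx2)$p
  setNames(as.numeric(p),
           if (inherits(images, "tep_images")) images$sample_ids else NULL)
}
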