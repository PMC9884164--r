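# 13-layer 1-D CNN abstract-feature extractor, implemented natively: valid
# (no-padding) convolutions via im2col matrix products, width-2/stride-2 max
# pooling, ReLU, a terminal fully-connected layer producing the abstract
# features, and a detachable softmax head used only during training.

#' The 13-layer 1-D CNN architecture
#'
#' Six (convolution, max-pool) pairs with kernel sizes 5,5,7,7,9,11 and
#' channel counts 4,8,16,16,32,32 (stride 1, no padding; pool stride 2),
#' followed by a fully-connected layer to `n_features` units. A length-3000
#' input traverses temporal lengths 2996, 1498, 1494, 747, 741, 370, 364,
#' 182, 174, 87, 77, 38 before the fully-connected output.
#'
#' @param input_len input length in samples.
#' @param n_features dimension of the abstract-feature output.
#' @param kernel_sizes,channels per-conv-layer kernel sizes and output
#'   channel counts (equal length).
#' @return list of class `cnn_arch`.
#' @export
cnn_architecture <- function(input_len = 3000, n_features = 38,
                             kernel_sizes = c(5, 5, 7, 7, 9, 11),
                             channels = c(4, 8, 16, 16, 32, 32)) {
  stopifnot(length(kernel_sizes) == length(channels))
  kernel_sizes <- as.integer(kernel_sizes)
  channels <- as.integer(channels)
  layers <- list()
  c_in <- 1L
  for (i in seq_along(kernel_sizes)) {
    layers[[length(layers) + 1]] <- list(type = "conv", k = kernel_sizes[i],
                                         c_in = c_in, c_out = channels[i],
                                         name = paste0("Convolution-", i))
    layers[[length(layers) + 1]] <- list(type = "pool",
                                         name = paste0("Pooling-", i))
    c_in <- channels[i]
  }
  structure(list(input_len = as.integer(input_len),
                 n_features = as.integer(n_features),
                 layers = layers),
            class = "cnn_arch")
}

#' Forward shape chain of the architecture
#'
#' Valid convolution maps length L to L - k + 1; pooling to floor(L / 2).
#'
#' @param arch a `cnn_arch`.
#' @param input_len input length (defaults to the architecture's).
#' @return data.frame with `layer`, `channels`, `length` rows for every conv
#'   and pool layer, ending with the fully-connected output row.
#' @export
forward_shapes <- function(arch, input_len = arch$input_len) {
  L <- as.integer(input_len)
  ch <- 1L
  rows <- list(data.frame(layer = "Input", channels = 1L, length = L))
  for (ly in arch$layers) {
    if (ly$type == "conv") {
      if (L < ly$k) stop("input too short at layer ", ly$name,
                         ": length ", L, " < kernel ", ly$k)
      L <- L - ly$k + 1L
      ch <- ly$c_out
    } else {
      L <- L %/% 2L
      if (L < 1) stop("input too short at layer ", ly$name)
    }
    rows[[length(rows) + 1]] <- data.frame(layer = ly$name, channels = ch,
                                           length = L)
  }
  rows[[length(rows) + 1]] <- data.frame(layer = "FC", channels = 1L,
                                         length = arch$n_features)
  do.call(rbind, rows)
}

#' Prepare a segment for the CNN input layer
#'
#' Decimates the unified 30-s segment to the network's input length
#' (anti-aliasing low-pass plus subsampling for an integer factor, polyphase
#' resampling with a warning otherwise) and z-normalizes it (a constant
#' segment becomes all zeros).
#'
#' @param x numeric segment samples.
#' @param fs sampling frequency in Hz.
#' @param input_len target length.
#' @return numeric vector of exactly `input_len` samples, mean ~0, sd ~1.
#' @export
prepare_cnn_input <- function(x, fs = 300, input_len = 3000) {
  n <- length(x)
  if (sd_pop(x) == 0) return(rep(0, input_len))
  if (n != input_len) {
    if (n %% input_len == 0) {
      q <- n %/% input_len
      y <- as.numeric(signal::decimate(x, q))
      y <- y[seq_len(input_len)]
    } else {
      warning("segment length ", n, " is not an integer multiple of ",
              input_len, "; polyphase resampling")
      y <- as.numeric(signal::resample(x, input_len, n))
      y <- y[seq_len(input_len)]
    }
  } else {
    y <- x
  }
  s <- sd_pop(y)
  if (s == 0) return(rep(0, input_len))
  (y - mean(y)) / s
}

# ---- native layer primitives (batch-first arrays: dim (B, L, C)) ----------

im2col <- function(X, k) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Lo <- L - k + 1L
  M <- matrix(0, B * Lo, k * C)
  for (j in seq_len(k)) {
    M[, ((j - 1) * C + 1):(j * C)] <- matrix(X[, j:(j + Lo - 1), , drop = FALSE],
                                             B * Lo, C)
  }
  M
}

conv_fwd <- function(X, W, b, k) {
  d <- dim(X); B <- d[1]; Lo <- d[2] - k + 1L
  M <- im2col(X, k)
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = array(Y, c(B, Lo, ncol(W))), M = M)
}

conv_bwd <- function(dY, M, W, k, in_dim) {
  B <- in_dim[1]; L <- in_dim[2]; C <- in_dim[3]
  Lo <- L - k + 1L
  dYm <- matrix(dY, B * Lo, dim(dY)[3])
  dW <- crossprod(M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  dX <- array(0, in_dim)
  for (j in seq_len(k)) {
    dX[, j:(j + Lo - 1), ] <- dX[, j:(j + Lo - 1), , drop = FALSE] +
      array(dM[, ((j - 1) * C + 1):(j * C)], c(B, Lo, C))
  }
  list(dX = dX, dW = dW, db = db)
}

pool_fwd <- function(X) {
  d <- dim(X); Lo <- d[2] %/% 2L
  A <- X[, seq(1, by = 2, length.out = Lo), , drop = FALSE]
  Bb <- X[, seq(2, by = 2, length.out = Lo), , drop = FALSE]
  mask <- A >= Bb  # tie -> earlier sample
  list(Y = pmax(A, Bb), mask = mask)
}

pool_bwd <- function(dY, mask, in_dim) {
  Lo <- dim(dY)[2]
  dX <- array(0, in_dim)
  dX[, seq(1, by = 2, length.out = Lo), ] <- dY * mask
  dX[, seq(2, by = 2, length.out = Lo), ] <- dY * !mask
  dX
}

# ---- parameter init / forward / backward ----------------------------------

cnn_init <- function(arch, n_classes = 4, seed = 1L) {
  set.seed(seed)
  params <- list()
  shapes <- forward_shapes(arch)
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      fan_in <- ly$k * ly$c_in
      params[[paste0("W", i)]] <- matrix(stats::rnorm(fan_in * ly$c_out,
                                                      0, sqrt(2 / fan_in)),
                                         fan_in, ly$c_out)
      params[[paste0("b", i)]] <- rep(0, ly$c_out)
    }
  }
  last <- shapes[nrow(shapes) - 1, ]
  flat <- last$channels * last$length
  params$W_fc <- matrix(stats::rnorm(flat * arch$n_features, 0, sqrt(2 / flat)),
                        flat, arch$n_features)
  params$b_fc <- rep(0, arch$n_features)
  params$W_head <- matrix(stats::rnorm(arch$n_features * n_classes,
                                       0, sqrt(2 / arch$n_features)),
                          arch$n_features, n_classes)
  params$b_head <- rep(0, n_classes)
  params
}

# forward through conv/pool stack + FC; returns features and caches
cnn_forward <- function(arch, params, Xmat, keep_cache = FALSE) {
  B <- nrow(Xmat)
  X <- array(Xmat, c(B, ncol(Xmat), 1))
  caches <- list()
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_fwd(X, params[[paste0("W", i)]], params[[paste0("b", i)]], ly$k)
      relu_mask <- cf$Y > 0
      Y <- cf$Y * relu_mask
      if (keep_cache) caches[[i]] <- list(M = cf$M, relu = relu_mask,
                                          in_dim = dim(X))
      X <- Y
    } else {
      pf <- pool_fwd(X)
      if (keep_cache) caches[[i]] <- list(mask = pf$mask, in_dim = dim(X))
      X <- pf$Y
    }
  }
  flat <- matrix(X, B, prod(dim(X)[-1]))
  feats <- flat %*% params$W_fc + rep(params$b_fc, each = B)
  list(features = feats, flat = flat, conv_out_dim = dim(X), caches = caches)
}

softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# loss + full gradient for a batch (labels: integer 1..n_classes)
cnn_loss_grad <- function(arch, params, Xmat, y) {
  B <- nrow(Xmat)
  fw <- cnn_forward(arch, params, Xmat, keep_cache = TRUE)
  Z <- fw$features %*% params$W_head + rep(params$b_head, each = B)
  P <- softmax(Z)
  loss <- -mean(log(pmax(P[cbind(seq_len(B), y)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ / B
  grads <- list()
  grads$W_head <- crossprod(fw$features, dZ)
  grads$b_head <- colSums(dZ)
  dF <- tcrossprod(dZ, params$W_head)
  grads$W_fc <- crossprod(fw$flat, dF)
  grads$b_fc <- colSums(dF)
  dFlat <- tcrossprod(dF, params$W_fc)
  dX <- array(dFlat, fw$conv_out_dim)
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    cache <- fw$caches[[i]]
    if (ly$type == "conv") {
      dX <- dX * cache$relu
      bw <- conv_bwd(dX, cache$M, params[[paste0("W", i)]], ly$k, cache$in_dim)
      grads[[paste0("W", i)]] <- bw$dW
      grads[[paste0("b", i)]] <- bw$db
      dX <- bw$dX
    } else {
      dX <- pool_bwd(dX, cache$mask, cache$in_dim)
    }
  }
  list(loss = loss, grads = grads)
}

#' Train the CNN feature extractor
#'
#' Minimizes 4-class cross-entropy through a detachable softmax head with
#' Adam. Fully deterministic given the seed.
#'
#' @param Xmat numeric matrix, one prepared input (see [prepare_cnn_input()])
#'   per row.
#' @param labels character/factor labels over the four rhythm classes.
#' @param arch a `cnn_arch` (default: the 13-layer architecture).
#' @param epochs,batch_size,lr training hyperparameters.
#' @param seed RNG seed for initialization and batch shuffling.
#' @param verbose print per-epoch loss.
#' @return list of class `cnn_model`: `arch`, `params`, `history` (mean
#'   training loss per epoch), `classes`.
#' @export
train_cnn <- function(Xmat, labels, arch = cnn_architecture(),
                      epochs = 30, batch_size = 32, lr = 1e-3,
                      seed = 1L, verbose = FALSE) {
  classes <- AF_CLASSES[AF_CLASSES %in% unique(as.character(labels))]
  if (length(classes) < 2) stop("training set must contain at least 2 classes")
  y <- match(as.character(labels), classes)
  if (anyNA(y)) stop("unknown label in training set")
  stopifnot(ncol(Xmat) == arch$input_len, epochs >= 1)
  params <- cnn_init(arch, n_classes = length(classes), seed = seed)
  # Adam state
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  history <- numeric(epochs)
  n <- nrow(Xmat)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)     # RNG continues from cnn_init's seed
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      lg <- cnn_loss_grad(arch, params, Xmat[idx, , drop = FALSE], y[idx])
      losses <- c(losses, lg$loss)
      step <- step + 1
      for (nm in names(params)) {
        g <- lg$grads[[nm]]
        if (is.null(g)) next
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, history[ep]))
  }
  structure(list(arch = arch, params = params, history = history,
                 classes = classes),
            class = "cnn_model")
}

#' Extract abstract features from prepared inputs
#'
#' Returns the activations of the terminal fully-connected layer (the
#' softmax head is not applied).
#'
#' @param model a `cnn_model` from [train_cnn()].
#' @param Xmat numeric matrix of prepared inputs (rows) or a single vector.
#' @return numeric matrix, one `n_features`-dimensional row per input.
#' @export
extract_abstract <- function(model, Xmat) {
  if (is.null(dim(Xmat))) Xmat <- matrix(Xmat, nrow = 1)
  stopifnot(ncol(Xmat) == model$arch$input_len)
  out <- cnn_forward(model$arch, model$params, Xmat)$features
  colnames(out) <- paste0("S", seq_len(ncol(out)))
  out
}
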