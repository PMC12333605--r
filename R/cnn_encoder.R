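# One-dimensional convolutional encoder for pair feature vectors.
#
# Architecture (single trainable conv layer + two trainable dense layers):
#   conv1d (16 filters, width 16, stride 1, valid padding) + ReLU
#   -> max-pool (width 2, stride 2)
#   -> dropout
#   -> dense to floor(input_dim / 2) units + ReLU   <- the encoding layer
#   -> dropout
#   -> dense to 1 unit + sigmoid                    <- training head
# Trained with Adam on binary cross-entropy against the pair labels; the
# penultimate (dense + ReLU) activations are the low-dimensional pair
# embedding. Dropout is inactive at inference, so encoding is deterministic.
#
# All linear algebra is plain matrix arithmetic; the convolution is applied
# through an im2col expansion so each batch is two matrix products.

#' Encoder configuration
#'
#' @param input_dim Length of the pair feature vectors (`nm + nd`).
#' @param n_filters Convolution filters (default 16).
#' @param kernel_width Convolution kernel width (default 16).
#' @param pool_width Max-pool width and stride (default 2).
#' @param dropout_rate Dropout probability at both dropout sites
#'   (default 0.5).
#' @param epochs Training epochs (default 20).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An `encoder_config` list; `output_dim` is fixed at
#'   `floor(input_dim / 2)`.
#' @export
encoder_config <- function(input_dim, n_filters = 16L, kernel_width = 16L,
                           pool_width = 2L, dropout_rate = 0.5, epochs = 20L,
                           batch_size = 32L, learning_rate = 1e-3, seed = 1L) {
  input_dim <- as.integer(input_dim)
  if (input_dim < kernel_width) {
    stop_mda("input_dim (%d) must be at least kernel_width (%d)",
             input_dim, kernel_width, class = "mda_config_error")
  }
  if (epochs < 1L) {
    stop_mda("epochs must be >= 1", class = "mda_config_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_mda("dropout_rate must be in [0, 1)", class = "mda_config_error")
  }
  conv_len <- input_dim - as.integer(kernel_width) + 1L
  pooled_len <- conv_len %/% as.integer(pool_width)
  if (pooled_len < 1L) {
    stop_mda("input too short to pool", class = "mda_config_error")
  }
  structure(list(
    input_dim = input_dim,
    n_filters = as.integer(n_filters),
    kernel_width = as.integer(kernel_width),
    pool_width = as.integer(pool_width),
    dropout_rate = dropout_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    seed = as.integer(seed),
    conv_len = conv_len,
    pooled_len = pooled_len,
    flat_dim = pooled_len * as.integer(n_filters),
    output_dim = input_dim %/% 2L
  ), class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat(sprintf(
    "<encoder_config: %d -> conv(%dx%d) -> pool(%d) -> %d -> 1, epochs=%d>\n",
    x$input_dim, x$n_filters, x$kernel_width, x$pool_width, x$output_dim,
    x$epochs))
  invisible(x)
}

#' Build an untrained encoder
#'
#' Allocates seeded He-normal weights for the layer stack described in
#' [encoder_config()].
#'
#' @param input_dim Length of the pair feature vectors.
#' @param config An `encoder_config`; defaults to
#'   `encoder_config(input_dim)`.
#' @return A `cnn_encoder` object (untrained).
#' @export
build_encoder <- function(input_dim, config = encoder_config(input_dim)) {
  if (config$input_dim != input_dim) {
    stop_mda("config input_dim (%d) != input_dim (%d)", config$input_dim,
             input_dim, class = "mda_config_error")
  }
  K <- config$kernel_width
  F_ <- config$n_filters
  H <- config$output_dim
  flat <- config$flat_dim
  weights <- with_seed(config$seed, list(
    Wc = matrix(stats::rnorm(K * F_, sd = sqrt(2 / K)), K, F_),
    bc = numeric(F_),
    W1 = matrix(stats::rnorm(flat * H, sd = sqrt(2 / flat)), flat, H),
    b1 = numeric(H),
    w2 = matrix(stats::rnorm(H, sd = sqrt(2 / H)), H, 1L),
    b2 = 0
  ))
  structure(list(config = config, weights = weights, trained = FALSE,
                 loss_curve = numeric(0)),
            class = "cnn_encoder")
}

#' @export
print.cnn_encoder <- function(x, ...) {
  cat(sprintf("<cnn_encoder: input %d -> embedding %d, %s, %d parameters>\n",
              x$config$input_dim, x$config$output_dim,
              if (x$trained) "trained" else "untrained", n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Closed form: `K*F + F` (conv) `+ flat*H + H` (dense 1) `+ H + 1`
#' (dense 2), with `flat = floor((input_dim - K + 1) / pool) * F`.
#'
#' @param encoder A `cnn_encoder` or `encoder_config`.
#' @return Integer parameter count.
#' @export
n_params <- function(encoder) {
  cfg <- if (inherits(encoder, "cnn_encoder")) encoder$config else encoder
  K <- cfg$kernel_width; F_ <- cfg$n_filters
  H <- cfg$output_dim; flat <- cfg$flat_dim
  K * F_ + F_ + flat * H + H + H + 1L
}

# im2col: rows of X expand to sliding windows; output is (n * conv_len) x K
# with row (i, p) at index i + n * (p - 1).
im2col <- function(X, K, P) {
  n <- nrow(X)
  C <- matrix(0, n * P, K)
  for (k in seq_len(K)) {
    C[, k] <- as.vector(X[, k:(P + k - 1), drop = FALSE])
  }
  C
}

# Forward pass. Returns all intermediates needed for backprop when
# keep = TRUE. Dropout masks must be pre-drawn by the caller (NULL = off).
cnn_forward <- function(w, cfg, X, mask1 = NULL, mask2 = NULL, keep = FALSE) {
  n <- nrow(X)
  P <- cfg$conv_len
  P2 <- cfg$pooled_len
  F_ <- cfg$n_filters
  C <- im2col(X, cfg$kernel_width, P)
  Zc <- sweep(C %*% w$Wc, 2L, w$bc, `+`)
  Ac <- pmax(Zc, 0)
  idx1 <- rep(seq_len(n), P2) + n * rep(2L * seq_len(P2) - 2L, each = n)
  idx2 <- idx1 + n
  A1 <- Ac[idx1, , drop = FALSE]
  A2 <- Ac[idx2, , drop = FALSE]
  take1 <- A1 >= A2
  Pm <- pmax(A1, A2)
  Fl <- Pm
  dim(Fl) <- c(n, P2 * F_)
  Fl_d <- if (is.null(mask1)) Fl else Fl * mask1
  H1pre <- sweep(Fl_d %*% w$W1, 2L, w$b1, `+`)
  H1 <- pmax(H1pre, 0)
  H1_d <- if (is.null(mask2)) H1 else H1 * mask2
  z <- H1_d %*% w$w2 + w$b2
  p <- 1 / (1 + exp(-z))
  if (!keep) return(list(H1 = H1, p = p))
  list(C = C, Zc = Zc, idx1 = idx1, idx2 = idx2, take1 = take1,
       Fl = Fl, Fl_d = Fl_d, H1pre = H1pre, H1 = H1, H1_d = H1_d, p = p)
}

cnn_backward <- function(w, cfg, fw, y, mask1, mask2) {
  n <- length(y)
  dz <- (fw$p - y) / n
  dw2 <- crossprod(fw$H1_d, dz)
  db2 <- sum(dz)
  dH1 <- dz %*% t(w$w2)
  if (!is.null(mask2)) dH1 <- dH1 * mask2
  dH1pre <- dH1 * (fw$H1pre > 0)
  dW1 <- crossprod(fw$Fl_d, dH1pre)
  db1 <- colSums(dH1pre)
  dFl <- dH1pre %*% t(w$W1)
  if (!is.null(mask1)) dFl <- dFl * mask1
  dPm <- dFl
  dim(dPm) <- c(n * cfg$pooled_len, cfg$n_filters)
  dAc <- matrix(0, n * cfg$conv_len, cfg$n_filters)
  dAc[fw$idx1, ] <- dPm * fw$take1
  dAc[fw$idx2, ] <- dPm * (!fw$take1)
  dZc <- dAc * (fw$Zc > 0)
  dWc <- crossprod(fw$C, dZc)
  dbc <- colSums(dZc)
  list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1, w2 = dw2, b2 = db2)
}

#' Train the encoder
#'
#' Runs exactly `config$epochs` passes of minibatch Adam on binary
#' cross-entropy. Shuffling, dropout and initialization all derive from
#' `config$seed`, so the same seed and data reproduce the same weights.
#'
#' @param encoder A `cnn_encoder` from [build_encoder()].
#' @param X Feature matrix (`n x input_dim`), typically `training_set$X`.
#' @param y Binary labels (0/1).
#' @param config Optional `encoder_config` override (defaults to the
#'   encoder's own).
#' @return The trained `cnn_encoder`, with `$loss_curve` holding the mean
#'   training loss per epoch. Warns (does not error) if the final-epoch
#'   loss exceeds the first-epoch loss.
#' @export
train_encoder <- function(encoder, X, y, config = encoder$config) {
  stopifnot(inherits(encoder, "cnn_encoder"))
  if (ncol(X) != config$input_dim) {
    stop_mda("X has %d columns, encoder expects %d", ncol(X), config$input_dim,
             class = "mda_shape_error")
  }
  if (!all(y %in% c(0, 1))) {
    stop_mda("labels must be 0/1", class = "mda_config_error")
  }
  w <- encoder$weights
  rate <- config$dropout_rate
  lr <- config$learning_rate
  n <- nrow(X)
  mstate <- lapply(w, function(p) p * 0)
  vstate <- lapply(w, function(p) p * 0)
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(config$epochs)

  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        if (rate > 0) {
          mask1 <- matrix((stats::runif(nb * config$flat_dim) >= rate) / (1 - rate),
                          nb, config$flat_dim)
          mask2 <- matrix((stats::runif(nb * config$output_dim) >= rate) / (1 - rate),
                          nb, config$output_dim)
        } else {
          mask1 <- NULL; mask2 <- NULL
        }
        fw <- cnn_forward(w, config, Xb, mask1, mask2, keep = TRUE)
        pc <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(pc) + (1 - yb) * log(1 - pc))
        if (!is.finite(loss)) {
          stop_mda("training diverged (non-finite loss); lower learning_rate",
                   class = "mda_divergence_error")
        }
        epoch_loss <- epoch_loss + loss * nb
        grads <- cnn_backward(w, config, fw, yb, mask1, mask2)
        step <- step + 1L
        bc1 <- 1 - beta1^step
        bc2 <- 1 - beta2^step
        for (nm in names(w)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
          w[[nm]] <- w[[nm]] - lr * (mstate[[nm]] / bc1) /
            (sqrt(vstate[[nm]] / bc2) + eps)
        }
      }
      losses[epoch] <- epoch_loss / n
    }
  })
  if (losses[config$epochs] > losses[1L]) {
    warning("final training loss exceeds first-epoch loss; encoder may be undertrained")
  }
  encoder$weights <- w
  encoder$config <- config
  encoder$trained <- TRUE
  encoder$loss_curve <- losses
  encoder
}

#' Encode pair features
#'
#' Deterministic inference pass returning the penultimate-layer (embedding)
#' activations; dropout and the sigmoid head are inactive.
#'
#' @param encoder A trained `cnn_encoder`.
#' @param X Feature matrix with `input_dim` columns.
#' @param chunk Rows per forward chunk (memory control).
#' @return Matrix `nrow(X) x output_dim`.
#' @export
encode <- function(encoder, X, chunk = 4096L) {
  stopifnot(inherits(encoder, "cnn_encoder"))
  cfg <- encoder$config
  if (ncol(X) != cfg$input_dim) {
    stop_mda("X has %d columns, encoder expects %d", ncol(X), cfg$input_dim,
             class = "mda_shape_error")
  }
  n <- nrow(X)
  out <- matrix(0, n, cfg$output_dim)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- cnn_forward(encoder$weights, cfg, X[idx, , drop = FALSE])$H1
  }
  out
}

#' Classification-head probabilities
#'
#' Emits the sigmoid head's probability for each row; used by the CNN-only
#' baseline.
#'
#' @inheritParams encode
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
encoder_predict <- function(encoder, X, chunk = 4096L) {
  stopifnot(inherits(encoder, "cnn_encoder"))
  cfg <- encoder$config
  if (ncol(X) != cfg$input_dim) {
    stop_mda("X has %d columns, encoder expects %d", ncol(X), cfg$input_dim,
             class = "mda_shape_error")
  }
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- cnn_forward(encoder$weights, cfg, X[idx, , drop = FALSE])$p
  }
  out
}
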