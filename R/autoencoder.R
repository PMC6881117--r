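#' Autoencoder architecture and training specification
#'
#' Describes the feedforward autoencoder used for latent-space gene-set
#' benchmarking: a mirrored encoder/decoder with four ReLU hidden layers per
#' side, a linear latent layer of dimension `latent_dim` followed by batch
#' normalization (the latent representation), optional input dropout for
#' regularization, and Adam optimization on the mean squared reconstruction
#' error. The full-scale reference uses hidden width 100 with input dropout
#' 0.8; the linked small-gene-set network uses width 50 and no dropout.
#'
#' @param input_dim Number of input genes.
#' @param hidden_widths Encoder hidden widths, mirrored in the decoder
#'   (must be length 4).
#' @param latent_dim Latent dimension `d` (>= 2; 5 for quantitative runs,
#'   2 for visualization).
#' @param input_dropout_rate Dropout probability on the input layer.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (default 956).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(input_dim, hidden_widths = rep(100, 4),
                             latent_dim = 5, input_dropout_rate = 0.8,
                             epochs = 500, batch_size = 956,
                             learning_rate = 1e-3, seed = 1L) {
  stopifnot(length(hidden_widths) == 4, latent_dim >= 2,
            input_dropout_rate >= 0, input_dropout_rate < 1,
            epochs >= 1, batch_size >= 2, input_dim >= 1)
  structure(as.list(environment()), class = "autoencoder_spec")
}

#' Preprocess expression input for the autoencoder
#'
#' Raw CPM spans around five decades and would let a handful of abundant
#' genes dominate the squared-error loss, so the default transform is
#' `log10(CPM + 1)` followed by per-gene standardization (genes with zero
#' variance are left at zero).
#'
#' @param m An `np_expression` (CPM).
#' @param genes Gene subset to keep.
#' @param transform `"log1p_standardize"` (default), `"log1p"` or `"raw"`.
#' @return Numeric cells x genes matrix.
#' @export
preprocess_expression <- function(m, genes = gene_ids(m),
                                  transform = c("log1p_standardize",
                                                "log1p", "raw")) {
  transform <- match.arg(transform)
  x <- expression_values(m, genes)
  if (transform == "raw") return(x)
  x <- log10(x + 1)
  if (transform == "log1p") return(x)
  mu <- colMeans(x)
  sd <- sqrt(colMeans(x^2) - mu^2)
  sd[sd < 1e-12] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

# ---- internal MLP machinery -------------------------------------------

relu <- function(x) (x > 0) * x

# column-wise ops via recycling, faster than sweep() in the training loop
col_add <- function(X, v) X + rep(v, rep.int(nrow(X), length(v)))
col_mul <- function(X, v) X * rep(v, rep.int(nrow(X), length(v)))

ae_init <- function(spec) {
  widths_enc <- c(spec$input_dim, spec$hidden_widths, spec$latent_dim)
  widths_dec <- c(spec$latent_dim, rev(spec$hidden_widths), spec$input_dim)
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  }
  layer <- function(widths) {
    lapply(seq_len(length(widths) - 1), function(i) {
      list(W = he(widths[i], widths[i + 1]), b = rep(0, widths[i + 1]))
    })
  }
  list(enc = layer(widths_enc), dec = layer(widths_dec),
       bn_mean = rep(0, spec$latent_dim), bn_var = rep(1, spec$latent_dim),
       spec = spec)
}

ae_forward <- function(model, X, training = FALSE, bn_momentum = 0.99) {
  spec <- model$spec
  cache <- list(input = X)
  A <- X
  if (training && spec$input_dropout_rate > 0) {
    keep <- 1 - spec$input_dropout_rate
    mask <- matrix(stats::rbinom(length(A), 1, keep) / keep,
                   nrow(A), ncol(A))
    A <- A * mask
  }
  cache$dropped <- A
  n_enc <- length(model$enc)
  cache$enc_pre <- cache$enc_act <- vector("list", n_enc)
  for (i in seq_len(n_enc)) {
    pre <- col_add(A %*% model$enc[[i]]$W, model$enc[[i]]$b)
    A <- if (i < n_enc) relu(pre) else pre  # latent layer is linear
    cache$enc_pre[[i]] <- pre
    cache$enc_act[[i]] <- A
  }
  zpre <- A
  eps <- 1e-5
  if (training) {
    mu <- colMeans(zpre)
    v <- colMeans(zpre^2) - mu^2
    model$bn_mean <- bn_momentum * model$bn_mean + (1 - bn_momentum) * mu
    model$bn_var <- bn_momentum * model$bn_var + (1 - bn_momentum) * v
  } else {
    mu <- model$bn_mean
    v <- model$bn_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  z <- col_mul(col_add(zpre, -mu), inv_sd)
  cache$bn <- list(mu = mu, inv_sd = inv_sd, zpre = zpre, z = z)
  A <- z
  n_dec <- length(model$dec)
  cache$dec_pre <- cache$dec_act <- vector("list", n_dec)
  for (i in seq_len(n_dec)) {
    pre <- col_add(A %*% model$dec[[i]]$W, model$dec[[i]]$b)
    A <- if (i < n_dec) relu(pre) else pre  # linear reconstruction output
    cache$dec_pre[[i]] <- pre
    cache$dec_act[[i]] <- A
  }
  list(model = model, z = z, out = A, cache = cache)
}

# gradient of the narrowest-direction variance penalty (sigma_min - 1)^2
# with respect to the latent batch z (n x d)
sigma_min_penalty <- function(z) {
  n <- nrow(z)
  zc <- sweep(z, 2, colMeans(z), "-")
  cv <- crossprod(zc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- max(eg$values[length(eg$values)], 1e-12)
  v <- eg$vectors[, length(eg$values)]
  s <- sqrt(lam)
  grad <- ((s - 1) / s) * (2 / (n - 1)) * (zc %*% v) %*% t(v)
  list(value = (s - 1)^2, grad = grad)
}

ae_backward <- function(model, fw, target, z_target = NULL, lambda = 0) {
  cache <- fw$cache
  n <- nrow(target)
  p <- ncol(target)
  grads <- list(enc = vector("list", length(model$enc)),
                dec = vector("list", length(model$dec)))
  losses <- list()
  dA <- 2 * (fw$out - target) / (n * p)
  losses$R <- mean((fw$out - target)^2)
  n_dec <- length(model$dec)
  for (i in rev(seq_len(n_dec))) {
    dpre <- if (i < n_dec) dA * (cache$dec_pre[[i]] > 0) else dA
    below <- if (i == 1) cache$bn$z else cache$dec_act[[i - 1]]
    grads$dec[[i]] <- list(W = crossprod(below, dpre), b = colSums(dpre))
    dA <- tcrossprod(dpre, model$dec[[i]]$W)
  }
  dZ <- dA
  C <- 0
  if (!is.null(z_target) && lambda > 0) {
    d <- ncol(fw$z)
    mismatch <- fw$z - z_target
    C_mse <- mean(mismatch^2)
    pen <- sigma_min_penalty(fw$z)
    C <- C_mse + pen$value
    dZ <- dZ + lambda * (2 * mismatch / (n * d) + pen$grad)
  }
  losses$C <- C
  # batch-normalization backward (no affine parameters)
  zhat <- cache$bn$z
  dzp <- col_add(dZ, -colMeans(dZ)) - col_mul(zhat, colMeans(dZ * zhat))
  dA <- col_mul(dzp, cache$bn$inv_sd)
  n_enc <- length(model$enc)
  for (i in rev(seq_len(n_enc))) {
    dpre <- if (i < n_enc) dA * (cache$enc_pre[[i]] > 0) else dA
    below <- if (i == 1) cache$dropped else cache$enc_act[[i - 1]]
    grads$enc[[i]] <- list(W = crossprod(below, dpre), b = colSums(dpre))
    dA <- tcrossprod(dpre, model$enc[[i]]$W)
  }
  list(grads = grads, losses = losses)
}

adam_init <- function(model) {
  zero_like <- function(l) lapply(l, function(x)
    list(W = list(m = x$W * 0, v = x$W * 0),
         b = list(m = x$b * 0, v = x$b * 0)))
  list(enc = zero_like(model$enc), dec = zero_like(model$dec), t = 0)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(param, grad, st) {
    for (nm in c("W", "b")) {
      st[[nm]]$m <- beta1 * st[[nm]]$m + (1 - beta1) * grad[[nm]]
      st[[nm]]$v <- beta2 * st[[nm]]$v + (1 - beta2) * grad[[nm]]^2
      param[[nm]] <- param[[nm]] -
        lr * (st[[nm]]$m / corr1) / (sqrt(st[[nm]]$v / corr2) + eps)
    }
    list(param = param, state = st)
  }
  for (side in c("enc", "dec")) {
    for (i in seq_along(model[[side]])) {
      r <- upd(model[[side]][[i]], grads[[side]][[i]], state[[side]][[i]])
      model[[side]][[i]] <- r$param
      state[[side]][[i]] <- r$state
    }
  }
  list(model = model, state = state)
}

ae_train <- function(X, spec, z_target = NULL, lambda = 0) {
  withr::with_seed(spec$seed, {
    model <- ae_init(spec)
    state <- adam_init(model)
    n <- nrow(X)
    bs <- min(spec$batch_size, n)
    report <- vector("list", spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = bs)
      Rs <- Cs <- numeric(length(starts))
      used <- logical(length(starts))
      for (k in seq_along(starts)) {
        rows <- idx[starts[k]:min(starts[k] + bs - 1, n)]
        if (length(rows) < 2) next
        used[k] <- TRUE
        xb <- X[rows, , drop = FALSE]
        zb <- if (!is.null(z_target)) z_target[rows, , drop = FALSE]
        fw <- ae_forward(model, xb, training = TRUE)
        model <- fw$model  # running BN statistics
        bw <- ae_backward(model, fw, xb, z_target = zb, lambda = lambda)
        st <- adam_step(model, bw$grads, state, spec$learning_rate)
        model <- st$model
        state <- st$state
        Rs[k] <- bw$losses$R
        Cs[k] <- bw$losses$C
        if (!is.finite(Rs[k])) {
          stop("autoencoder training diverged (non-finite loss) at epoch ",
               ep, call. = FALSE)
        }
      }
      mR <- mean(Rs[used])
      mC <- mean(Cs[used])
      report[[ep]] <- tibble::tibble(epoch = ep, R = mR, C = mC,
                                     lambda = lambda, L = mR + lambda * mC)
    }
    list(model = model, loss = dplyr::bind_rows(report))
  })
}

#' Train the reference autoencoder
#'
#' Trains on a preprocessed cells x genes matrix (typically the highly
#' expressed gene set) and returns the latent embedding `z1` of every cell,
#' computed in inference mode with the running batch-normalization
#' statistics.
#'
#' @param X Numeric cells x genes matrix (see [preprocess_expression()]).
#' @param spec An [autoencoder_spec()] with `input_dim == ncol(X)`.
#' @return List of class `np_autoencoder`: `model`, `embedding` (cells x d,
#'   role `"reference z1"`), `loss` (per-epoch tibble with columns
#'   `epoch`, `R`, `C`, `lambda`, `L`).
#' @export
train_reference_autoencoder <- function(X, spec) {
  stopifnot(inherits(spec, "autoencoder_spec"), ncol(X) == spec$input_dim,
            all(is.finite(X)))
  fit <- ae_train(X, spec)
  emb <- ae_embed(fit$model, X)
  structure(list(model = fit$model, embedding = emb, loss = fit$loss,
                 role = "reference z1"), class = "np_autoencoder")
}

#' Train a linked autoencoder on a small gene set
#'
#' With the reference network frozen, trains a second autoencoder on the
#' small gene set's expression, with loss `L = R + lambda * C` where `R` is
#' the mean squared reconstruction error and `C` penalizes mismatch between
#' this network's latent representation `z2` and the reference `z1`
#' (`C = MSE(z2, z1) + (sigma_min(z2) - 1)^2`; the second term normalizes
#' variance along the narrowest principal direction of the `z2` batch,
#' preventing latent collapse). With `lambda = 0` the loss reduces to plain
#' reconstruction.
#'
#' @param X_small Numeric cells x genes matrix over the small gene set.
#' @param z1 Reference embedding (cells x d), row-aligned with `X_small`.
#' @param spec An [autoencoder_spec()]; the linked defaults are hidden width
#'   50 and no input dropout.
#' @param lambda Latent-mismatch weight (default 100).
#' @return List of class `np_autoencoder` with `embedding` of role
#'   `"linked z2"`.
#' @export
train_linked_autoencoder <- function(X_small, z1, spec, lambda = 100) {
  stopifnot(inherits(spec, "autoencoder_spec"),
            ncol(X_small) == spec$input_dim,
            nrow(X_small) == nrow(z1), all(is.finite(X_small)))
  if (spec$latent_dim != ncol(z1)) {
    stop("latent dimension of spec (", spec$latent_dim,
         ") does not match z1 (", ncol(z1), ")", call. = FALSE)
  }
  fit <- ae_train(X_small, spec, z_target = z1, lambda = lambda)
  emb <- ae_embed(fit$model, X_small)
  structure(list(model = fit$model, embedding = emb, loss = fit$loss,
                 role = "linked z2"), class = "np_autoencoder")
}

#' Embed data with a trained autoencoder (inference mode)
#'
#' @param model A trained model (the `model` element of an
#'   `np_autoencoder`).
#' @param X Cells x genes matrix preprocessed the same way as the training
#'   input.
#' @return Cells x d latent coordinate matrix.
#' @export
ae_embed <- function(model, X) {
  fw <- ae_forward(model, X, training = FALSE)
  z <- fw$z
  rownames(z) <- rownames(X)
  z
}

#' @export
print.np_autoencoder <- function(x, ...) {
  last <- x$loss[nrow(x$loss), ]
  cat(sprintf("<np_autoencoder> role %s, %d epochs, final L = %.4g\n",
              x$role, nrow(x$loss), last$L))
  invisible(x)
}

#' @rdname train_reference_autoencoder
#' @param x An `np_autoencoder`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble with the final epoch's losses.
#' @export
glance.np_autoencoder <- function(x, ...) {
  out <- x$loss[nrow(x$loss), ]
  out$role <- x$role
  out
}
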