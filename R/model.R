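#' Configuration for the circular autoencoder
#'
#' The model embeds each cell onto one circular dimension (an angle) plus an
#' optional set of linear dimensions. The encoder is a multilayer perceptron
#' with `tanh` activations ending in a single unbounded circular coordinate;
#' the decoder maps `(cos x, sin x)` and the linear coordinates back to
#' expression space with a single linear layer, so each gene's reconstruction
#' along the circle is `A_g * cos(x - phi_g)`.
#'
#' @param encoder_widths Integer sizes of the hidden `tanh` layers.
#' @param n_linear Number of additional linear embedding dimensions
#'   (the `k - 1` non-periodic components); 0 keeps the model purely circular.
#' @param alpha L2 penalty coefficient(s) for the encoder weight matrices;
#'   recycled across matrices in order (hidden layers, circular output,
#'   linear map).
#' @param beta L2 penalty coefficient for the decoder matrix.
#' @param gene_weights Optional non-negative per-gene weights applied inside
#'   the squared reconstruction error, to encode prior knowledge about which
#'   genes should drive the embedding. `NULL` weights all genes equally.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size; `NULL` means `min(N, 128)`.
#' @param learning_rate Adam step size.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param circular Set `FALSE` to clamp the circular pathway to zero and
#'   train a purely linear autoencoder (useful as a PCA-equivalent baseline).
#' @param early_stop_tol,early_stop_window Stop early when the relative
#'   change of the training loss over `early_stop_window` epochs falls below
#'   `early_stop_tol`.
#' @param verbose Print the loss every 50 epochs.
#' @return A list of class `ca_config`.
#' @export
model_config <- function(encoder_widths = c(30L, 20L), n_linear = 0L,
                         alpha = 1e-3, beta = 1e-4, gene_weights = NULL,
                         epochs = 500L, batch_size = NULL,
                         learning_rate = 0.01, seed = 0L, circular = TRUE,
                         early_stop_tol = 1e-6, early_stop_window = 50L,
                         verbose = FALSE) {
  stopifnot(length(encoder_widths) >= 1, all(encoder_widths >= 1),
            n_linear >= 0, all(alpha >= 0), beta >= 0,
            epochs >= 1, learning_rate > 0)
  if (!is.null(gene_weights)) {
    if (any(gene_weights < 0) || !any(gene_weights > 0))
      stop("gene_weights must be non-negative with at least one positive entry")
  }
  structure(list(
    encoder_widths = as.integer(encoder_widths), n_linear = as.integer(n_linear),
    alpha = alpha, beta = beta, gene_weights = gene_weights,
    epochs = as.integer(epochs), batch_size = batch_size,
    learning_rate = learning_rate, seed = as.integer(seed),
    circular = isTRUE(circular),
    early_stop_tol = early_stop_tol,
    early_stop_window = as.integer(early_stop_window),
    verbose = isTRUE(verbose)), class = "ca_config")
}

# internal: per-encoder-matrix alpha vector (W1..Wh, W3_circular, W_linear)
expand_alpha <- function(config) {
  n_mats <- (if (config$circular) length(config$encoder_widths) + 1L else 0L) +
    (if (config$n_linear > 0) 1L else 0L)
  rep_len(config$alpha, max(n_mats, 1L))
}

#' Encode standardized expression into the circular/linear embedding
#'
#' Computes `x_circular = W3 tanh(W2 tanh(W1 y + b1) + b2)` and
#' `x_linear = W_linear y`, vectorized over cells. The circular coordinate is
#' returned un-wrapped (any real value); see [pseudotime()] for the modulus.
#'
#' @param y A cells-by-genes numeric matrix (or a single row vector) on the
#'   standardized scale.
#' @param enc Encoder parameter list (`W` matrices and `b` vectors) from a
#'   fitted model.
#' @return List with `circular` (N-vector) and `linear` (N x n_linear matrix).
#' @export
encode_cells <- function(y, enc) {
  y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  G <- if (!is.null(enc$G)) enc$G else
    (if (length(enc$W)) nrow(enc$W[[1]]) else nrow(enc$W_linear))
  if (ncol(y) != G)
    stop("expected ", G, " genes (columns); got ", ncol(y))
  n <- nrow(y)
  if (length(enc$W)) {
    h <- y
    for (i in seq_along(enc$W))
      h <- tanh(sweep(h %*% enc$W[[i]], 2, enc$b[[i]], "+"))
    circ <- as.vector(h %*% enc$W3_circular)
  } else {
    circ <- rep(0, n)
  }
  lin <- if (!is.null(enc$W_linear)) y %*% enc$W_linear
         else matrix(0, n, 0)
  list(circular = circ, linear = lin)
}

#' Decode an embedding back to expression space
#'
#' `yhat = V_circular [cos x; sin x] + V_linear x_linear`. With
#' `parts = TRUE` the circular and linear addends are returned separately;
#' the circular addend is the estimated periodic (e.g. cell-cycle) effect.
#'
#' @param circular N-vector of circular coordinates (radians, any real).
#' @param linear N x n_linear matrix of linear coordinates (or NULL).
#' @param dec Decoder parameters: `V_circular` (G x 2) and `V_linear`
#'   (G x n_linear).
#' @param parts Return the two addends separately?
#' @return A cells-by-genes matrix, or a list with `circular`, `linear`,
#'   `total` when `parts = TRUE`.
#' @export
decode_embedding <- function(circular, linear = NULL, dec, parts = FALSE) {
  circular <- as.numeric(circular)
  n <- length(circular)
  yc <- cbind(cos(circular), sin(circular)) %*% t(dec$V_circular)
  if (!is.null(dec$V_linear) && ncol(dec$V_linear) > 0) {
    if (is.null(linear) || ncol(as.matrix(linear)) != ncol(dec$V_linear))
      stop("linear embedding must have ", ncol(dec$V_linear), " columns")
    yl <- as.matrix(linear) %*% t(dec$V_linear)
  } else {
    yl <- matrix(0, n, nrow(dec$V_circular))
  }
  if (parts) list(circular = yc, linear = yl, total = yc + yl) else yc + yl
}

#' Training objective of the circular autoencoder
#'
#' `sum_n w (y_n - yhat_n)^2 + sum_i alpha_i ||W_i||^2 + beta ||V||^2` where
#' `w` are the optional per-gene weights (all ones when absent) and the norms
#' are Frobenius norms.
#'
#' @param y Cells-by-genes matrix of standardized expression (batch).
#' @param model A fitted (or freshly initialized) model.
#' @return Single non-negative number.
#' @export
model_loss <- function(y, model) {
  y <- as_values(y)
  stopifnot(nrow(y) >= 1)
  emb <- encode_cells(y, model$encoder)
  yhat <- decode_embedding(emb$circular, emb$linear, model$decoder)
  w <- model$config$gene_weights
  if (is.null(w)) w <- rep(1, ncol(y))
  resid <- sum(sweep((y - yhat)^2, 2, w, "*"))
  a <- expand_alpha(model$config)
  pen <- 0; i <- 1L
  if (length(model$encoder$W)) {
    for (Wi in model$encoder$W) { pen <- pen + a[i] * sum(Wi^2); i <- i + 1L }
    pen <- pen + a[i] * sum(model$encoder$W3_circular^2); i <- i + 1L
  }
  if (!is.null(model$encoder$W_linear) && ncol(model$encoder$W_linear) > 0)
    pen <- pen + a[i] * sum(model$encoder$W_linear^2)
  pen <- pen + model$config$beta *
    (sum(model$decoder$V_circular^2) + sum(model$decoder$V_linear^2))
  resid + pen
}

# internal: Glorot-style uniform init, seeded by the caller
init_mat <- function(nr, nc, gain = 1) {
  lim <- gain * sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# internal: Adam update; st holds m, v, t
adam_step <- function(par, grad, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mh <- st$m / (1 - b1^st$t)
  vh <- st$v / (1 - b2^st$t)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Fit the circular autoencoder
#'
#' Trains encoder and decoder by minibatch gradient descent (Adam) on the
#' regularized least-squares objective. Training is deterministic for a
#' given seed: two runs with the same input and config return identical
#' parameters.
#'
#' @param m A standardized `expr_matrix` (see [standardize_genes()]).
#' @param config A [model_config()].
#' @return An object of class `fitted_ca` with elements `config`, `encoder`,
#'   `decoder`, `loss_history` (full-data objective per epoch),
#'   `mse_history` (per-entry reconstruction MSE per epoch), `gene_ids`.
#' @export
fit_circular_ae <- function(m, config = model_config()) {
  assert_standardized(m)
  Y <- m$values
  N <- nrow(Y); G <- ncol(Y)
  if (N < 2) stop("need at least 2 cells to fit")
  if (!is.null(config$gene_weights) && length(config$gene_weights) != G)
    stop("gene_weights must have length ", G)
  w <- config$gene_weights
  if (is.null(w)) w <- rep(1, G)
  bs <- if (is.null(config$batch_size)) min(N, 128L) else
    min(N, as.integer(config$batch_size))
  a <- expand_alpha(config)
  lr <- config$learning_rate
  beta <- config$beta
  widths <- config$encoder_widths
  k <- config$n_linear
  circ_on <- config$circular

  set.seed(config$seed)
  par <- list()
  if (circ_on) {
    dims <- c(G, widths)
    par$W <- vector("list", length(widths))
    par$b <- vector("list", length(widths))
    for (i in seq_along(widths)) {
      par$W[[i]] <- init_mat(dims[i], dims[i + 1])
      par$b[[i]] <- rep(0, dims[i + 1])
    }
    # wider init on the output row so initial angles spread over the circle
    d_last <- widths[length(widths)]
    par$W3 <- matrix(stats::runif(d_last, -1, 1) * pi / sqrt(d_last), d_last, 1)
    par$Vc <- init_mat(G, 2)
  } else {
    par$Vc <- matrix(0, G, 2)
  }
  if (k > 0) {
    par$Wl <- init_mat(G, k)
    par$Vl <- init_mat(G, k)
  }

  flat <- function(p) p[!vapply(p, is.null, TRUE)]
  st <- lapply(flat(par), function(x) {
    if (is.list(x)) lapply(x, function(xx) list(m = xx * 0, v = xx * 0, t = 0))
    else list(m = x * 0, v = x * 0, t = 0)
  })

  forward <- function(Yb) {
    out <- list()
    if (circ_on) {
      H <- vector("list", length(widths))
      h <- Yb
      for (i in seq_along(widths)) {
        h <- tanh(sweep(h %*% par$W[[i]], 2, par$b[[i]], "+"))
        H[[i]] <- h
      }
      out$H <- H
      out$x <- as.vector(h %*% par$W3)
      out$cx <- cos(out$x); out$sx <- sin(out$x)
      out$Yc <- cbind(out$cx, out$sx) %*% t(par$Vc)
    } else {
      out$x <- rep(0, nrow(Yb))
      out$Yc <- matrix(0, nrow(Yb), G)
    }
    if (k > 0) {
      out$XL <- Yb %*% par$Wl
      out$Yl <- out$XL %*% t(par$Vl)
    } else out$Yl <- 0
    out$Yhat <- out$Yc + out$Yl
    out
  }

  loss_full <- function() {
    fw <- forward(Y)
    resid <- sum(sweep((Y - fw$Yhat)^2, 2, w, "*"))
    pen <- 0; i <- 1L
    if (circ_on) {
      for (Wi in par$W) { pen <- pen + a[i] * sum(Wi^2); i <- i + 1L }
      pen <- pen + a[i] * sum(par$W3^2); i <- i + 1L
    }
    if (k > 0) pen <- pen + a[i] * sum(par$Wl^2)
    pen <- pen + beta * (sum(par$Vc^2) + if (k > 0) sum(par$Vl^2) else 0)
    list(loss = resid + pen, mse = mean((Y - fw$Yhat)^2))
  }

  upd <- function(name, grad) {
    res <- adam_step(par[[name]], grad,
                     within(st[[name]], t <- t + 1), lr)
    par[[name]] <<- res$par
    st[[name]] <<- res$st
  }

  loss_history <- numeric(0)
  mse_history <- numeric(0)
  n_enc <- if (circ_on) length(widths) else 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(N)
    starts <- seq(1, N, by = bs)
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1, N)]
      Yb <- Y[idx, , drop = FALSE]
      nb <- length(idx)
      fw <- forward(Yb)
      R2 <- sweep((fw$Yhat - Yb), 2, (2 / nb) * w, "*")
      if (circ_on) {
        C <- cbind(fw$cx, fw$sx)
        gVc <- crossprod(R2, C) + 2 * beta * par$Vc
        gx <- -fw$sx * as.vector(R2 %*% par$Vc[, 1]) +
               fw$cx * as.vector(R2 %*% par$Vc[, 2])
        Hlast <- fw$H[[n_enc]]
        gW3 <- crossprod(Hlast, gx) + 2 * a[n_enc + 1L] * par$W3
        dH <- outer(gx, as.vector(par$W3))
        gW <- vector("list", n_enc); gb <- vector("list", n_enc)
        for (i in rev(seq_len(n_enc))) {
          dA <- dH * (1 - fw$H[[i]]^2)
          inp <- if (i == 1) Yb else fw$H[[i - 1]]
          gW[[i]] <- crossprod(inp, dA) + 2 * a[i] * par$W[[i]]
          gb[[i]] <- colSums(dA)
          if (i > 1) dH <- dA %*% t(par$W[[i]])
        }
        for (i in seq_len(n_enc)) {
          resW <- adam_step(par$W[[i]], gW[[i]],
                            within(st$W[[i]], t <- t + 1), lr)
          par$W[[i]] <- resW$par; st$W[[i]] <- resW$st
          resb <- adam_step(par$b[[i]], gb[[i]],
                            within(st$b[[i]], t <- t + 1), lr)
          par$b[[i]] <- resb$par; st$b[[i]] <- resb$st
        }
        upd("W3", gW3)
        upd("Vc", gVc)
      }
      if (k > 0) {
        gXL <- R2 %*% par$Vl
        gVl <- crossprod(R2, fw$XL) + 2 * beta * par$Vl
        gWl <- crossprod(Yb, gXL) +
          2 * a[if (circ_on) n_enc + 2L else 1L] * par$Wl
        upd("Wl", gWl)
        upd("Vl", gVl)
      }
    }
    lf <- loss_full()
    if (!is.finite(lf$loss))
      stop("training loss became non-finite at epoch ", epoch,
           "; try a lower learning_rate")
    loss_history <- c(loss_history, lf$loss)
    mse_history <- c(mse_history, lf$mse)
    if (config$verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d  loss %.5g  mse %.5g", epoch, lf$loss, lf$mse))
    win <- config$early_stop_window
    if (epoch > win) {
      rel <- abs(loss_history[epoch - win] - lf$loss) / max(lf$loss, 1e-12)
      if (rel < config$early_stop_tol) break
    }
  }

  encoder <- list(
    W = if (circ_on) par$W else list(),
    b = if (circ_on) par$b else list(),
    W3_circular = if (circ_on) par$W3 else NULL,
    W_linear = if (k > 0) par$Wl else NULL,
    G = G)
  decoder <- list(V_circular = par$Vc,
                  V_linear = if (k > 0) par$Vl else matrix(0, G, 0))
  structure(list(config = config, encoder = encoder, decoder = decoder,
                 loss_history = loss_history, mse_history = mse_history,
                 gene_ids = m$gene_ids),
            class = "fitted_ca")
}

#' @export
print.fitted_ca <- function(x, ...) {
  cat(sprintf(
    "<fitted_ca> %d genes, widths [%s], n_linear %d, %d epochs, final loss %.5g\n",
    length(x$gene_ids), paste(x$config$encoder_widths, collapse = ","),
    x$config$n_linear, length(x$loss_history),
    x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Circular pseudo-time of cells under a fitted model
#'
#' Encodes the cells and wraps the circular coordinate into `[0, 2*pi)`.
#'
#' @param model A `fitted_ca`.
#' @param m A standardized `expr_matrix` with the same genes, in the same
#'   order, as the model was trained on.
#' @return An object of class `pseudotime_result`: list with `circular`
#'   (named N-vector in `[0, 2*pi)`), `linear` (N x n_linear matrix) and
#'   `cell_ids`.
#' @export
pseudotime <- function(model, m) {
  assert_standardized(m)
  assert_same_genes(model$gene_ids, m$gene_ids)
  emb <- encode_cells(m$values, model$encoder)
  circ <- emb$circular %% (2 * pi)
  circ[circ >= 2 * pi] <- 0  # guard against rounding at the boundary
  names(circ) <- m$cell_ids
  structure(list(circular = circ, linear = emb$linear,
                 cell_ids = m$cell_ids),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("<pseudotime_result> %d cells, %d linear component(s)\n",
              length(x$circular), ncol(x$linear)))
  invisible(x)
}

#' Rotate (and optionally reflect) the circular part of a decoder
#'
#' The model is identifiable only up to a global rotation and reflection of
#' the circle: shifting all pseudo-times by `delta` while advancing every
#' gene's peak phase by `delta` leaves the reconstruction unchanged. This
#' helper applies the compensating rotation to `V_circular`, so that
#' `decode(x + delta, rotate_decoder(dec, delta))` equals `decode(x, dec)`.
#'
#' @param dec Decoder parameter list.
#' @param delta Rotation angle in radians.
#' @param reflect Also reflect the circle (`x -> -x`)?
#' @return Decoder list with rotated `V_circular`.
#' @export
rotate_decoder <- function(dec, delta, reflect = FALSE) {
  a <- dec$V_circular[, 1]; b <- dec$V_circular[, 2]
  if (reflect) b <- -b
  dec$V_circular <- cbind(a * cos(delta) - b * sin(delta),
                          a * sin(delta) + b * cos(delta))
  dec
}
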