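# straight transcription of the encoder/decoder formulas, evaluated one
# cell at a time with plain loops; independent of the vectorized code paths
oracle_encode <- function(y, enc) {
  h <- as.numeric(y)
  for (i in seq_along(enc$W))
    h <- tanh(as.numeric(t(enc$W[[i]]) %*% h) + enc$b[[i]])
  circ <- sum(h * enc$W3_circular)
  lin <- if (!is.null(enc$W_linear)) as.numeric(t(enc$W_linear) %*% y)
         else numeric(0)
  list(circular = circ, linear = lin)
}

random_encoder <- function(G, widths, k, seed) {
  set.seed(seed)
  dims <- c(G, widths)
  W <- lapply(seq_along(widths), function(i)
    matrix(rnorm(dims[i] * dims[i + 1]), dims[i], dims[i + 1]))
  b <- lapply(widths, function(d) rnorm(d))
  list(W = W, b = b, W3_circular = matrix(rnorm(widths[length(widths)])),
       W_linear = if (k > 0) matrix(rnorm(G * k), G, k) else NULL, G = G)
}

test_that("encode matches a direct transcription of the formula", {
  expect_equal(encode_cells(matrix(rnorm(4), 1, 4),
                            list(W = list(matrix(0, 4, 3)),
                                 b = list(rep(0, 3)),
                                 W3_circular = matrix(0, 3, 1),
                                 W_linear = matrix(0, 4, 2), G = 4))$circular,
               0)
  enc <- random_encoder(4, c(3, 2), 2, seed = 21)
  expect_equal(encode_cells(matrix(0, 1, 4), list(
    W = enc$W, b = list(rep(0, 3), rep(0, 2)),
    W3_circular = enc$W3_circular, W_linear = enc$W_linear,
    G = 4))$circular, 0)
  set.seed(22)
  Y <- matrix(rnorm(3 * 4), 3, 4)
  got <- encode_cells(Y, enc)
  for (n in 1:3) {
    want <- oracle_encode(Y[n, ], enc)
    expect_equal(got$circular[n], want$circular, tolerance = 1e-12)
    expect_equal(as.numeric(got$linear[n, ]), want$linear, tolerance = 1e-12)
  }
  expect_error(encode_cells(matrix(0, 1, 5), enc), "4")
})

test_that("decode matches the amplitude/phase oracle", {
  dec1 <- list(V_circular = matrix(c(2, 0), 1, 2),
               V_linear = matrix(0, 1, 0))
  expect_equal(as.numeric(decode_embedding(0, dec = dec1)), 2)
  expect_equal(as.numeric(decode_embedding(pi / 2, dec = dec1)), 0,
               tolerance = 1e-12)
  set.seed(31)
  G <- 6
  dec <- list(V_circular = matrix(rnorm(2 * G), G, 2),
              V_linear = matrix(0, G, 0))
  A <- sqrt(rowSums(dec$V_circular^2))
  phi <- atan2(dec$V_circular[, 2], dec$V_circular[, 1])
  x <- runif(5, 0, 2 * pi)
  got <- decode_embedding(x, dec = dec)
  want <- outer(x, phi, function(xx, pp) cos(xx - pp)) %*% diag(A)
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("loss equals independently summed residual and penalty terms", {
  tf <- tiny_fit()
  model <- tf$fit
  Y <- tf$std$values
  # zero parameters, zero data
  z <- model
  z$encoder$W <- lapply(z$encoder$W, function(w) w * 0)
  z$encoder$b <- lapply(z$encoder$b, function(b) b * 0)
  z$encoder$W3_circular <- z$encoder$W3_circular * 0
  z$encoder$W_linear <- z$encoder$W_linear * 0
  z$decoder$V_circular <- z$decoder$V_circular * 0
  z$decoder$V_linear <- z$decoder$V_linear * 0
  expect_equal(model_loss(Y * 0, z), 0)
  # term-by-term oracle on the trained model
  emb <- encode_cells(Y, model$encoder)
  yhat <- decode_embedding(emb$circular, emb$linear, model$decoder)
  resid <- 0
  for (n in seq_len(nrow(Y))) resid <- resid + sum((Y[n, ] - yhat[n, ])^2)
  a <- rep_len(model$config$alpha, 4)
  pen <- a[1] * sum(model$encoder$W[[1]]^2) +
    a[2] * sum(model$encoder$W[[2]]^2) +
    a[3] * sum(model$encoder$W3_circular^2) +
    a[4] * sum(model$encoder$W_linear^2) +
    model$config$beta * (sum(model$decoder$V_circular^2) +
                         sum(model$decoder$V_linear^2))
  expect_equal(model_loss(Y, model), resid + pen, tolerance = 1e-10)
})

test_that("gene weights scale the per-gene residual inside the loss", {
  tf <- tiny_fit()
  model <- tf$fit
  Y <- tf$std$values
  w <- runif(ncol(Y), 0.5, 2)
  mw <- model
  mw$config$gene_weights <- w
  emb <- encode_cells(Y, model$encoder)
  yhat <- decode_embedding(emb$circular, emb$linear, model$decoder)
  expected_resid <- sum(t((Y - yhat)^2) * w)
  expect_equal(model_loss(Y, mw) - (model_loss(Y, model) -
                 sum((Y - yhat)^2)),
               expected_resid, tolerance = 1e-8)
})

test_that("training is bit-reproducible given the seed and descends", {
  std <- std_gaussian(30, 8, seed = 4)
  cfg <- model_config(encoder_widths = c(5, 3), n_linear = 1, epochs = 25,
                      seed = 7)
  f1 <- fit_circular_ae(std, cfg)
  f2 <- fit_circular_ae(std, cfg)
  expect_identical(f1$encoder, f2$encoder)
  expect_identical(f1$decoder, f2$decoder)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_lt(f1$loss_history[length(f1$loss_history)], f1$loss_history[1])
})

test_that("pseudotime wraps the circular coordinate into [0, 2*pi)", {
  G <- 3
  std <- std_gaussian(3, G, seed = 6)
  for (raw in c(7.0, -0.5, 0)) {
    enc <- list(W = list(matrix(0, G, 2), matrix(0, 2, 2)),
                b = list(rep(0, 2), c(atanh(0.5), 0)),
                W3_circular = matrix(c(raw / 0.5, 0), 2, 1),
                W_linear = NULL, G = G)
    model <- structure(list(config = model_config(), encoder = enc,
                            decoder = list(V_circular = matrix(0, G, 2),
                                           V_linear = matrix(0, G, 0)),
                            loss_history = 1, gene_ids = std$gene_ids),
                       class = "fitted_ca")
    pt <- pseudotime(model, std)
    expect_equal(unname(pt$circular), rep(raw %% (2 * pi), 3),
                 tolerance = 1e-12)
    expect_true(all(pt$circular >= 0 & pt$circular < 2 * pi))
  }
  expect_equal(7 %% (2 * pi), 0.7168147, tolerance = 1e-6)
  expect_equal(-0.5 %% (2 * pi), 5.7831853, tolerance = 1e-6)
})

test_that("pseudotime refuses a mismatched gene universe", {
  tf <- tiny_fit()
  std2 <- tf$std
  std2$gene_ids[3] <- "other_gene"
  colnames(std2$values)[3] <- "other_gene"
  expect_error(pseudotime(tf$fit, std2), "position 3")
})

test_that("decode is invariant under compensated phase shift and reflection", {
  tf <- tiny_fit()
  dec <- tf$fit$decoder
  x <- runif(20, 0, 2 * pi)
  lin <- matrix(rnorm(20), 20, 1)
  base <- decode_embedding(x, lin, dec)
  for (delta in c(0.3, 1.9, -2.5)) {
    shifted <- decode_embedding(x + delta, lin, rotate_decoder(dec, delta))
    expect_equal(shifted, base, tolerance = 1e-10)
    reflected <- decode_embedding(-x + delta, lin,
                                  rotate_decoder(dec, delta, reflect = TRUE))
    expect_equal(reflected, base, tolerance = 1e-10)
  }
})

test_that("the model recovers a noiseless circular trajectory almost exactly", {
  nf <- noiseless_fit()
  pt <- pseudotime(nf$fit, nf$std)
  al <- circular_alignment_score(pt$circular, nf$sim$truth$pseudotime)
  expect_gte(al$score, 0.99)
  expect_lte(tail(nf$fit$loss_history, 1), nf$fit$loss_history[1])
})

test_that("reconstruction of an equispaced noiseless circle is tight everywhere", {
  fx <- equispaced_circle()
  fit <- fit_circular_ae(fx$std, model_config(seed = 0, epochs = 8000,
                                              early_stop_tol = 0))
  emb <- encode_cells(fx$std$values, fit$encoder)
  rec <- decode_embedding(emb$circular, emb$linear, fit$decoder)
  expect_lte(max(abs(fx$std$values - rec)), 0.05)
})

test_that("a linear-only model matches the PCA optimum on Gaussian data", {
  std <- std_gaussian(120, 30, seed = 13)
  fit <- fit_circular_ae(std, model_config(circular = FALSE, n_linear = 2,
                                           epochs = 400, seed = 0,
                                           early_stop_tol = 0))
  mse <- fit$mse_history[length(fit$mse_history)]
  expect_lte(mse / pca_reconstruction_mse(std, 2), 1.02)
})

test_that("model archive round-trips exactly", {
  tf <- tiny_fit()
  path <- tempfile(fileext = ".rds")
  save_model(tf$fit, path)
  expect_identical(load_model(path), tf$fit)
})
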