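#' PCA reconstruction error at a given rank
#'
#' Per-entry mean squared error of the best rank-`k` approximation, computed
#' by truncated SVD. The input is expected to be standardized, i.e. already
#' column-centered, so no additional centering is applied and the rank-k
#' approximation is the usual PCA reconstruction.
#'
#' @param m Standardized `expr_matrix` (or bare matrix).
#' @param k Number of components, `1 <= k <= min(N, G)`.
#' @return Non-negative number: `mean((Y - Y_k)^2)` over all entries.
#' @export
pca_reconstruction_mse <- function(m, k) {
  Y <- as_values(m)
  r <- min(dim(Y))
  if (k < 1 || k > r) stop("k must be in [1, ", r, "]")
  d <- svd(Y, nu = 0, nv = 0)$d
  sum(d[seq_len(r) > k]^2) / length(Y)
}

#' Scan embedding dimensionality against the PCA baseline
#'
#' Fits the model with one circular plus `k - 1` linear components for each
#' `k` in `1..k_max` and records the reconstruction MSE next to the PCA MSE
#' at the same `k`. The chosen `k*` is the largest `k` whose relative MSE
#' drop from `k - 1` exceeds `drop_threshold`; when no drop qualifies,
#' `k* = 1`. An extra linear dimension is only worth keeping when it buys a
#' large decrease in reconstruction error.
#'
#' @param m Standardized `expr_matrix`.
#' @param k_max Largest total dimensionality to try.
#' @param config Base [model_config()]; `n_linear` is overridden per `k`.
#' @param drop_threshold Relative MSE decrease counting as "large"
#'   (default 0.05).
#' @return A list of class `dim_scan`: `k_values`, `model_mse`, `pca_mse`,
#'   `k_star`.
#' @export
scan_dimensionality <- function(m, k_max, config = model_config(),
                                drop_threshold = 0.05) {
  assert_standardized(m)
  stopifnot(k_max >= 1)
  model_mse <- numeric(k_max)
  pca_mse <- numeric(k_max)
  for (k in seq_len(k_max)) {
    cfg <- config
    cfg$n_linear <- k - 1L
    fitk <- fit_circular_ae(m, cfg)
    model_mse[k] <- fitk$mse_history[length(fitk$mse_history)]
    pca_mse[k] <- pca_reconstruction_mse(m, k)
  }
  k_star <- 1L
  if (k_max >= 2) {
    drops <- (model_mse[-k_max] - model_mse[-1]) / pmax(model_mse[-k_max], 1e-12)
    ok <- which(drops > drop_threshold)
    if (length(ok)) k_star <- max(ok) + 1L
  }
  structure(list(k_values = seq_len(k_max), model_mse = model_mse,
                 pca_mse = pca_mse, k_star = k_star),
            class = "dim_scan")
}

#' @export
print.dim_scan <- function(x, ...) {
  cat("<dim_scan>\n")
  print(data.frame(k = x$k_values, model_mse = x$model_mse,
                   pca_mse = x$pca_mse))
  cat("k* =", x$k_star, "\n")
  invisible(x)
}
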