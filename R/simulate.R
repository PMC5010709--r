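#' Population covariance matrix of the simulated covariates
#'
#' Builds the P x P covariance implied by the block map: unit variances,
#' equicorrelation `rho` between every pair of variables inside a block
#' (generating and relevant covariates alike), zero elsewhere. Covariates
#' outside all blocks are independent of everything.
#'
#' @param config a [sim_config()].
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @examples
#' cfg <- sim_config(n = 30, P = 40, n_true = 4, n_relevant = 8,
#'   block_spec = tibble::tibble(block = 1, true_vars = list(1:4),
#'                               relevant_vars = list(5:8), rho = 0.5))
#' Sigma <- build_covariance(cfg)
#' Sigma[1, 5] # 0.5
#' @export
build_covariance <- function(config) {
  validate_sim_config(config)
  P <- config$P
  Sigma <- diag(1, P)
  bs <- config$block_spec
  for (b in seq_len(nrow(bs))) {
    idx <- c(bs$true_vars[[b]], bs$relevant_vars[[b]])
    Sigma[idx, idx] <- bs$rho[[b]]
    diag(Sigma)[idx] <- 1
  }
  Sigma
}

#' Noise variance achieving a target signal-to-noise ratio
#'
#' With SNR defined as the ratio of the variance of the linear signal to the
#' noise variance, `sigma^2 = beta' Sigma beta / snr`.
#'
#' @param beta coefficient vector (length P).
#' @param cov covariance matrix of the covariates (P x P).
#' @param snr target signal-to-noise ratio, > 0.
#' @return The noise variance `sigma^2`.
#' @examples
#' noise_variance_for_snr(c(rep(0.1, 20), rep(0, 10)), diag(30), snr = 0.5)
#' @export
noise_variance_for_snr <- function(beta, cov, snr) {
  if (snr <= 0) stop("`snr` must be positive.", call. = FALSE)
  if (all(beta == 0)) {
    stop("zero coefficient vector: SNR undefined.", call. = FALSE)
  }
  stopifnot(length(beta) == nrow(cov))
  signal <- as.numeric(t(beta) %*% cov %*% beta)
  signal / snr
}

#' Simulate one dataset from the block-correlated Gaussian design
#'
#' Covariates are drawn multivariate normal with the covariance of
#' [build_covariance()] (sampled block-by-block via the Cholesky factor of
#' each equicorrelation block, which is exact and avoids factorizing the full
#' P x P matrix). The response is `y = X beta + eps` with
#' `eps ~ N(0, sigma^2)`, `beta_j = beta_value` for the generating
#' covariates and 0 otherwise, and `sigma^2` set from the configured SNR.
#' Covariate columns are then standardized and the response centered.
#'
#' The relevance oracle flags the first `n_relevant` variables (generating
#' covariates plus correlated extras) as biologically relevant.
#'
#' @param config a [sim_config()].
#' @param sigma2 optional override of the noise variance (e.g. 0 for a
#'   noiseless check); default derives it from `config$snr`.
#' @return A list of class `sim_data` with elements `data` (a
#'   [bag_dataset()]), `true_beta` (named vector), `relevance` (named logical
#'   vector over all variables), and `sigma2`.
#' @export
simulate_dataset <- function(config, sigma2 = NULL) {
  validate_sim_config(config)
  n <- config$n; P <- config$P
  bs <- config$block_spec
  beta <- c(rep(config$beta_value, config$n_true), rep(0, P - config$n_true))
  if (is.null(sigma2)) {
    sigma2 <- noise_variance_for_snr(beta, build_covariance(config), config$snr)
  }
  set.seed(config$seed)
  X <- matrix(rnorm(n * P), n, P)
  for (b in seq_len(nrow(bs))) {
    idx <- c(bs$true_vars[[b]], bs$relevant_vars[[b]])
    k <- length(idx)
    C <- matrix(bs$rho[[b]], k, k); diag(C) <- 1
    X[, idx] <- matrix(rnorm(n * k), n, k) %*% chol(C)
  }
  y <- as.numeric(X %*% beta) + rnorm(n, sd = sqrt(sigma2))
  var_ids <- paste0("x", seq_len(P))
  relevance <- setNames(seq_len(P) <= config$n_relevant, var_ids)
  structure(list(
    data = bag_dataset(X, y, var_ids = var_ids),
    true_beta = setNames(beta, var_ids),
    relevance = relevance,
    sigma2 = sigma2
  ), class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d x %d, %d relevant, sigma^2 = %.4g\n",
              nrow(x$data$X), ncol(x$data$X), sum(x$relevance), x$sigma2))
  invisible(x)
}
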