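## shared fixtures: small configurations and crafted datasets

tiny_block_spec <- function(rho = 0.5) {
  tibble::tibble(block = 1L, true_vars = list(1:4),
                 relevant_vars = list(5:8), rho = rho)
}

tiny_config <- function(n = 60L, P = 12L, beta_value = 0.5, snr = 2,
                        seed = 1L, rho = 0.5) {
  sim_config(n = n, P = P, n_true = 4L, n_relevant = 8L,
             beta_value = beta_value, snr = snr,
             block_spec = tiny_block_spec(rho), seed = seed)
}

tiny_experiment_config <- function(..., n_runs = 5L, bootstrap_B = 0L,
                                   master_seed = 42L, q = 3L,
                                   threshold = 0.25, sim = tiny_config()) {
  experiment_config(sim = sim, n_runs = n_runs, bootstrap_B = bootstrap_B,
                    master_seed = master_seed, q = q, threshold = threshold,
                    m = 20L, ...)
}

## deterministic gaussian dataset, no structure
random_dataset <- function(n, P, seed = 1, beta = NULL, sigma = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * P), n, P)
  y <- if (is.null(beta)) rnorm(n, sd = sigma)
       else as.numeric(X %*% beta) + rnorm(n, sd = sigma)
  bag_dataset(X, y)
}

## independent coordinate-descent lasso solver (oracle), glmnet objective:
## (1/(2n)) ||y - a - X b||^2 + lambda * sum(w |b|)
cd_lasso <- function(X, y, lambda, w = rep(1, ncol(X)), iters = 5000,
                     tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p); a <- mean(y)
  xm <- colMeans(X); xv <- colMeans(scale(X, center = xm, scale = FALSE)^2)
  r <- y - a - as.numeric(X %*% b)
  for (it in seq_len(iters)) {
    b_old <- b
    for (j in seq_len(p)) {
      xj <- X[, j] - xm[j]
      rho_j <- mean(xj * (r + xj * b[j]))
      bj_new <- sign(rho_j) * max(abs(rho_j) - lambda * w[j], 0) / xv[j]
      r <- r + xj * (b[j] - bj_new)
      b[j] <- bj_new
    }
    a_new <- mean(y - X %*% b)
    r <- r + (a - a_new); a <- a_new
    if (max(abs(b - b_old)) < tol) break
  }
  list(intercept = a, beta = b)
}

## glmnet-scale lasso objective value
lasso_objective <- function(X, y, a, b, lambda, w = rep(1, ncol(X))) {
  mean((y - a - as.numeric(X %*% b))^2) / 2 + lambda * sum(w * abs(b))
}
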