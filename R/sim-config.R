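#' Default block-correlation map for the simulation design
#'
#' Four disjoint blocks, each pairing 5 generating ("true") covariates with
#' 10 additional biologically relevant covariates under a common
#' equicorrelation: x1-x5 with x21-x30 at rho 0.55, x6-x10 with x31-x40 at
#' 0.60, x11-x15 with x41-x50 at 0.65, and x16-x20 with x51-x60 at 0.70.
#' All remaining covariates are independent.
#'
#' @return A tibble with list-columns `true_vars` and `relevant_vars`
#'   (integer indices) and column `rho`.
#' @export
default_block_spec <- function() {
  tibble::tibble(
    block = 1:4,
    true_vars = lapply(0:3, function(g) 5L * g + 1:5),
    relevant_vars = lapply(0:3, function(g) 20L + 10L * g + 1:10),
    rho = c(0.55, 0.60, 0.65, 0.70)
  )
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: problem size, the
#' block-correlation map, the common coefficient magnitude of the generating
#' covariates, and the signal-to-noise ratio that fixes the noise variance.
#' Defaults reproduce the reference simulation design: n = 300 samples,
#' P = 1000 covariates, 20 generating covariates with beta = 0.1, 60
#' biologically relevant covariates, SNR = 0.5.
#'
#' @param n sample count.
#' @param P covariate count.
#' @param n_true number of generating covariates (nonzero coefficients).
#' @param n_relevant number of covariates flagged biologically relevant
#'   (the generating covariates plus the correlated extras).
#' @param beta_value common coefficient magnitude of the generating
#'   covariates (reference settings: 0.1, 0.2 or 0.8).
#' @param snr signal-to-noise ratio, defined as Var(x'beta) / sigma^2 =
#'   beta' Sigma beta / sigma^2 (reference settings: 0.5 or 2).
#' @param block_spec block map as produced by [default_block_spec()]: a data
#'   frame with list-columns `true_vars`, `relevant_vars` and column `rho`.
#' @param seed integer seed for dataset generation.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_dataset()], [build_covariance()]
#' @export
sim_config <- function(n = 300L, P = 1000L, n_true = 20L, n_relevant = 60L,
                       beta_value = 0.1, snr = 0.5,
                       block_spec = default_block_spec(), seed = 1L) {
  cfg <- structure(list(
    n = as.integer(n), P = as.integer(P), n_true = as.integer(n_true),
    n_relevant = as.integer(n_relevant), beta_value = as.numeric(beta_value),
    snr = as.numeric(snr), block_spec = block_spec, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n < 3) stop("`n` must be at least 3.", call. = FALSE)
    if (!(n_true <= n_relevant && n_relevant <= P)) {
      stop("need n_true <= n_relevant <= P.", call. = FALSE)
    }
    if (snr <= 0) stop("`snr` must be positive.", call. = FALSE)
  })
  bs <- cfg$block_spec
  if (!is.data.frame(bs) ||
      !all(c("true_vars", "relevant_vars", "rho") %in% names(bs))) {
    stop("`block_spec` needs columns true_vars, relevant_vars, rho.",
         call. = FALSE)
  }
  all_idx <- unlist(c(bs$true_vars, bs$relevant_vars))
  if (anyDuplicated(all_idx)) {
    stop("blocks must be disjoint over variables.", call. = FALSE)
  }
  if (length(all_idx) && max(all_idx) > cfg$P) {
    stop("block variable index exceeds P.", call. = FALSE)
  }
  for (b in seq_len(nrow(bs))) {
    size <- length(bs$true_vars[[b]]) + length(bs$relevant_vars[[b]])
    rho <- bs$rho[[b]]
    if (size >= 2 && (rho <= -1 / (size - 1) || rho >= 1)) {
      stop(sprintf(
        "block %d: rho = %g outside (-1/%d, 1); equicorrelation not positive-definite.",
        b, rho, size - 1), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> n=%d P=%d | %d generating (beta=%g) of %d relevant | SNR=%g seed=%d\n",
    x$n, x$P, x$n_true, x$beta_value, x$n_relevant, x$snr, x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  bs <- config$block_spec
  out <- list(
    n = config$n, P = config$P, n_true = config$n_true,
    n_relevant = config$n_relevant, beta_value = config$beta_value,
    snr = config$snr, seed = config$seed,
    blocks = lapply(seq_len(nrow(bs)), function(b) list(
      true_vars = as.integer(bs$true_vars[[b]]),
      relevant_vars = as.integer(bs$relevant_vars[[b]]),
      rho = bs$rho[[b]]))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bs <- tibble::tibble(
    block = seq_along(raw$blocks),
    true_vars = lapply(raw$blocks, function(b) as.integer(b$true_vars)),
    relevant_vars = lapply(raw$blocks, function(b) as.integer(b$relevant_vars)),
    rho = vapply(raw$blocks, function(b) as.numeric(b$rho), numeric(1))
  )
  sim_config(n = raw$n, P = raw$P, n_true = raw$n_true,
             n_relevant = raw$n_relevant, beta_value = raw$beta_value,
             snr = raw$snr, block_spec = bs, seed = raw$seed)
}
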