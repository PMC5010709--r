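## Stage-1 penalized fits and stage-2 OLS refits.
##
## All glmnet calls use standardize = FALSE: a bag_dataset is already
## standardized, and the adaptive lasso is solved through the rescaling
## identity (penalize X_j / w_j at a common lambda, then rescale back),
## which must not be re-standardized away.

fold_ids <- function(n, k, seed) {
  set.seed(as.integer(seed))
  sample(rep(seq_len(k), length.out = n))
}

## lambda grid: geometric, nlambda points from lambda_max down to
## ratio * lambda_max. CV picks the minimum-mean-error lambda; exact ties
## resolve to the smallest lambda.
pick_lambda_min <- function(cv) {
  min(cv$lambda[cv$cvm <= min(cv$cvm)])
}

new_selection <- function(selected, coefficients, intercept, lambda, weights,
                          method, cvm = NULL, lambda_grid = NULL) {
  structure(list(
    selected = selected, coefficients = coefficients, intercept = intercept,
    lambda = lambda, weights = weights, method = method,
    cvm = cvm, lambda_grid = lambda_grid
  ), class = "bag_selection")
}

#' @export
print.bag_selection <- function(x, ...) {
  cat(sprintf("<bag_selection> %s: %d variables at lambda = %.4g\n",
              x$method, length(x$selected), x$lambda))
  invisible(x)
}

#' Lasso with k-fold cross-validated penalty
#'
#' Solves the L1-penalized least-squares problem on a standardized dataset
#' over a geometric grid of 100 penalties from `lambda_max` (the smallest
#' penalty giving the empty model) down to `0.001 * lambda_max`, choosing
#' the penalty that minimizes the mean k-fold cross-validation squared
#' prediction error (exact ties resolve to the smallest penalty). Fold
#' assignment is drawn once from `seed`, so the cross-validation curve is
#' reproducible and shared between a plain-lasso and an adaptive fit given
#' the same seed.
#'
#' @param data a [bag_dataset()].
#' @param k number of cross-validation folds (>= 2).
#' @param seed integer seed controlling fold assignment.
#' @param lambda optional fixed penalty: skips cross-validation and fits at
#'   the given value (useful for the unpenalized `lambda = 0` limit on
#'   low-dimensional problems, or a forced full-shrinkage fit).
#' @param lambda_min_ratio,nlambda grid geometry.
#' @return A `bag_selection`: the ordered selected variables, their
#'   coefficients, the intercept, the chosen `lambda`, the penalty weights
#'   (all 1 for the plain lasso) and the method label.
#' @export
fit_lasso_cv <- function(data, k = 5L, seed = 1L, lambda = NULL,
                         lambda_min_ratio = 0.001, nlambda = 100L) {
  stopifnot(inherits(data, "bag_dataset"), k >= 2)
  w <- setNames(rep(1, length(data$var_ids)), data$var_ids)
  fit_weighted_lasso(data, weights = w, k = k, seed = seed, lambda = lambda,
                     lambda_min_ratio = lambda_min_ratio, nlambda = nlambda,
                     method = "lasso")
}

## shared solver: plain lasso is the unit-weight case
fit_weighted_lasso <- function(data, weights, k, seed, lambda,
                               lambda_min_ratio, nlambda, method) {
  X <- data$X; y <- data$y
  n <- nrow(X)
  if (sd(y) == 0) {
    warning("constant response: returning empty selection.", call. = FALSE)
    return(new_selection(character(0), numeric(0), mean(y), Inf, weights, method))
  }
  keep <- is.finite(weights) & weights > 0
  if (!any(keep)) {
    warning("all weights infinite: returning empty model.", call. = FALSE)
    return(new_selection(character(0), numeric(0), mean(y), Inf, weights, method))
  }
  Xw <- sweep(X[, keep, drop = FALSE], 2, weights[keep], "/")
  if (ncol(Xw) == 1L && is.null(lambda)) {
    ## glmnet needs >= 2 columns; solve the univariate path directly
    return(fit_univariate_lasso_cv(Xw, y, X, weights, keep, k, seed,
                                   lambda_min_ratio, nlambda, method))
  }
  if (is.null(lambda)) {
    if (n < k) stop("need at least k rows for k-fold CV.", call. = FALSE)
    foldid <- fold_ids(n, k, seed)
    cv <- glmnet::cv.glmnet(Xw, y, foldid = foldid, standardize = FALSE,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            thresh = 1e-12)
    lam <- pick_lambda_min(cv)
    fit <- cv$glmnet.fit
    cvm <- cv$cvm; grid <- cv$lambda
  } else {
    ## glmnet is unreliable for a single small lambda without a path;
    ## fit a path down to the requested value and extract it exactly.
    lam <- lambda
    fit <- glmnet::glmnet(Xw, y, standardize = FALSE, thresh = 1e-12,
                          lambda = lambda_path_to(Xw, y, lambda, nlambda))
    cvm <- NULL; grid <- fit$lambda
  }
  b_scaled <- as.numeric(coef(fit, s = lam, exact = TRUE, x = Xw, y = y))
  intercept <- b_scaled[1]
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  beta[keep] <- b_scaled[-1] / weights[keep]
  sel <- names(beta)[beta != 0]
  new_selection(sel, beta[sel], intercept, lam, weights, method,
                cvm = cvm, lambda_grid = grid)
}

## closed-form soft-threshold path for a single candidate column, with the
## same CV-minimum / smallest-tied-lambda rule as the multivariate solver
fit_univariate_lasso_cv <- function(Xw, y, X, weights, keep, k, seed,
                                    lambda_min_ratio, nlambda, method) {
  n <- nrow(Xw)
  x <- Xw[, 1]
  soft <- function(z, lam) sign(z) * pmax(abs(z) - lam, 0)
  bhat <- function(rows, lam) {
    xc <- x[rows] - mean(x[rows]); yc <- y[rows] - mean(y[rows])
    soft(mean(xc * yc), lam) / mean(xc^2)
  }
  lam_max <- abs(mean((x - mean(x)) * (y - mean(y))))
  grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = nlambda))
  foldid <- fold_ids(n, k, seed)
  cvm <- vapply(grid, function(lam) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- foldid != f
      b <- bhat(tr, lam)
      a <- mean(y[tr]) - b * mean(x[tr])
      mean((y[!tr] - a - b * x[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lam <- min(grid[cvm <= min(cvm)])
  b <- bhat(seq_len(n), lam)
  intercept <- mean(y) - b * mean(x)
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  beta[keep] <- b / weights[keep]
  sel <- names(beta)[beta != 0]
  new_selection(sel, beta[sel], intercept, lam, weights, method,
                cvm = cvm, lambda_grid = grid)
}

lambda_path_to <- function(X, y, lambda, nlambda) {
  n <- nrow(X)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  lam_max <- max(lam_max, lambda, 1e-8)
  floor_lam <- max(lambda, 1e-8 * lam_max)
  path <- exp(seq(log(lam_max * 1.00001), log(floor_lam), length.out = nlambda))
  unique(sort(c(path, lambda), decreasing = TRUE))
}

#' Initial coefficient estimates for adaptive-lasso weights
#'
#' The adaptive lasso penalizes each coefficient by the reciprocal absolute
#' value of an initial estimate, `w_j = 1 / |beta_init_j|`. With more
#' covariates than samples the full ordinary-least-squares estimate does not
#' exist, so several initial estimators are offered:
#'
#' * `"lasso_ols"` (default): a cross-validated lasso on the same data
#'   selects a support, and the initial estimate is the OLS refit on that
#'   support -- variables outside the support get weight infinity and are
#'   excluded from the adaptive fit. This is the reading of
#'   "OLS coefficients" that remains computable when the selected set is
#'   smaller than the sample, and it nests the adaptive fit inside the
#'   lasso support.
#' * `"ols"`: the full OLS estimate; only valid when P < n.
#' * `"marginal_ols"`: per-column univariate OLS slopes.
#' * `"ridge"`: a lightly penalized ridge fit on all columns.
#'
#' @param data a [bag_dataset()].
#' @param scheme initial estimator, see Details.
#' @param k,seed fold count and seed for the internal lasso when
#'   `scheme = "lasso_ols"`.
#' @param ridge_lambda penalty for `scheme = "ridge"`.
#' @return Named weight vector `w` over all variables; entries may be `Inf`
#'   (the variable is excluded from the penalized fit).
#' @export
initial_weights <- function(data, scheme = c("lasso_ols", "ols",
                                             "marginal_ols", "ridge"),
                            k = 5L, seed = 1L, ridge_lambda = 0.01) {
  stopifnot(inherits(data, "bag_dataset"))
  scheme <- match.arg(scheme)
  X <- data$X; y <- data$y
  n <- nrow(X); P <- ncol(X)
  b_init <- switch(scheme,
    lasso_ols = {
      s1 <- fit_lasso_cv(data, k = k, seed = seed)
      b <- setNames(rep(0, P), colnames(X))
      if (length(s1$selected)) {
        ols <- refit_ols(s1$selected, data)
        b[ols$variables] <- ols$coefficients
      }
      b
    },
    ols = {
      if (P >= n) {
        stop("full OLS weights need P < n; use scheme = \"ridge\" or ",
             "\"marginal_ols\".", call. = FALSE)
      }
      qr.coef(qr(cbind(1, X)), y)[-1]
    },
    marginal_ols = as.numeric(crossprod(X, y)) / colSums(X^2),
    ridge = {
      fit <- glmnet::glmnet(X, y, alpha = 0, lambda = ridge_lambda,
                            standardize = FALSE, thresh = 1e-10)
      as.numeric(coef(fit))[-1]
    })
  w <- 1 / abs(as.numeric(b_init))
  setNames(w, colnames(X))
}

#' Adaptive lasso with k-fold cross-validated penalty
#'
#' Solves the weighted-L1 problem by the rescaling identity: each column is
#' divided by its weight, a plain lasso path is fit at a common penalty, and
#' the coefficients are rescaled back. Infinite weights exclude the column
#' from the fit entirely. With unit weights this reduces exactly to
#' [fit_lasso_cv()] on the same folds.
#'
#' @inheritParams fit_lasso_cv
#' @param weights named weight vector from [initial_weights()].
#' @return A `bag_selection` with `method = "adaptive_lasso"`.
#' @export
fit_adaptive_lasso_cv <- function(data, k = 5L, weights, seed = 1L,
                                  lambda = NULL, lambda_min_ratio = 0.001,
                                  nlambda = 100L) {
  stopifnot(inherits(data, "bag_dataset"), k >= 2)
  if (length(weights) != length(data$var_ids)) {
    stop("`weights` must cover every variable.", call. = FALSE)
  }
  if (is.null(names(weights))) names(weights) <- data$var_ids
  if (any(weights <= 0, na.rm = TRUE)) {
    stop("weights must be positive (Inf allowed).", call. = FALSE)
  }
  fit_weighted_lasso(data, weights = weights, k = k, seed = seed,
                     lambda = lambda, lambda_min_ratio = lambda_min_ratio,
                     nlambda = nlambda, method = "adaptive_lasso")
}

#' One-call stage-1 selection
#'
#' Convenience wrapper running the configured stage-1 method on a data
#' portion: plain lasso, or adaptive lasso with weights from
#' [initial_weights()].
#'
#' @param data stage-1 portion.
#' @param method `"adaptive_lasso"` or `"lasso"`.
#' @param k,seed CV folds and seed.
#' @param weight_scheme passed to [initial_weights()] for the adaptive fit.
#' @return A `bag_selection`.
#' @export
stage1_select <- function(data, method = c("adaptive_lasso", "lasso"),
                          k = 5L, seed = 1L, weight_scheme = "lasso_ols") {
  method <- match.arg(method)
  if (method == "lasso") return(fit_lasso_cv(data, k = k, seed = seed))
  w <- initial_weights(data, scheme = weight_scheme, k = k, seed = seed)
  fit_adaptive_lasso_cv(data, k = k, weights = w, seed = seed)
}

#' Use a penalized selection directly as a prediction model
#'
#' Wraps the stage-1 penalized coefficients as a model, so prediction error
#' can be measured without a stage-2 OLS refit (the "no-refit" comparison
#' mode).
#'
#' @param selection a `bag_selection`.
#' @return A `bag_model` carrying the penalized coefficients.
#' @export
as_model <- function(selection) {
  stopifnot(inherits(selection, "bag_selection"))
  structure(list(variables = selection$selected,
                 coefficients = selection$coefficients,
                 intercept = selection$intercept,
                 dropped = character(0)),
            class = "bag_model")
}

#' Ordinary-least-squares refit of a variable set
#'
#' Stage two refits the chosen variables by plain OLS on a fresh data
#' portion, so the final coefficients are not shrunk by the stage-1 penalty.
#' A rank-deficient design drops later-listed collinear columns with a
#' warning; the dropped identifiers are recorded on the result.
#'
#' @param variables character vector of variable identifiers (may be empty:
#'   intercept-only model).
#' @param data a [bag_dataset()] containing those variables.
#' @return An object of class `bag_model`: `variables`, named
#'   `coefficients`, `intercept`, and `dropped` (collinear columns removed).
#' @export
refit_ols <- function(variables, data) {
  stopifnot(inherits(data, "bag_dataset"))
  variables <- as.character(variables)
  miss <- setdiff(variables, data$var_ids)
  if (length(miss)) {
    stop("variables not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data$X)
  if (length(variables) >= n) {
    stop("OLS refit needs fewer variables than rows.", call. = FALSE)
  }
  if (!length(variables)) {
    return(structure(list(variables = character(0), coefficients = numeric(0),
                          intercept = mean(data$y), dropped = character(0)),
                     class = "bag_model"))
  }
  Xs <- cbind(`(Intercept)` = 1, data$X[, variables, drop = FALSE])
  qx <- qr(Xs)
  dropped <- character(0)
  if (qx$rank < ncol(Xs)) {
    keep_cols <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(colnames(Xs), colnames(Xs)[keep_cols])
    dropped <- setdiff(dropped, "(Intercept)")
    warning("rank-deficient refit; dropping: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    variables <- setdiff(variables, dropped)
    Xs <- cbind(`(Intercept)` = 1, data$X[, variables, drop = FALSE])
    qx <- qr(Xs)
  }
  b <- qr.coef(qx, data$y)
  structure(list(variables = variables,
                 coefficients = setNames(b[-1], variables),
                 intercept = b[1], dropped = dropped),
            class = "bag_model")
}

#' @export
print.bag_model <- function(x, ...) {
  cat(sprintf("<bag_model> %d variables (OLS refit)\n", length(x$variables)))
  invisible(x)
}

#' Predict from a refit model
#'
#' @param object a `bag_model`.
#' @param data a [bag_dataset()] containing the model's variables.
#' @param ... unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.bag_model <- function(object, data, ...) {
  stopifnot(inherits(data, "bag_dataset"))
  miss <- setdiff(object$variables, data$var_ids)
  if (length(miss)) {
    stop("variables missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!length(object$variables)) {
    return(rep(object$intercept, nrow(data$X)))
  }
  as.numeric(object$intercept +
               data$X[, object$variables, drop = FALSE] %*% object$coefficients)
}

## penalized-fit serialization -------------------------------------------

#' Write or read a selection / model as JSON
#'
#' @param x a `bag_selection` or `bag_model`.
#' @param path file path.
#' @return `read_selection()` returns a `bag_selection`; `read_model()` a
#'   `bag_model`.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "bag_selection"))
  out <- list(method = x$method, lambda = x$lambda, intercept = x$intercept,
              selected = as.list(setNames(as.numeric(x$coefficients),
                                          x$selected)),
              weights = as.list(setNames(as.numeric(x$weights),
                                         names(x$weights))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(raw$selected)
  if (is.null(coefs)) coefs <- setNames(numeric(0), character(0))
  new_selection(names(coefs), coefs, raw$intercept, raw$lambda,
                unlist(raw$weights), raw$method)
}

#' @rdname write_selection
#' @export
write_model <- function(x, path) {
  stopifnot(inherits(x, "bag_model"))
  out <- list(intercept = x$intercept,
              coefficients = as.list(setNames(as.numeric(x$coefficients),
                                              x$variables)),
              dropped = x$dropped)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(raw$coefficients)
  if (is.null(coefs)) coefs <- setNames(numeric(0), character(0))
  structure(list(variables = names(coefs), coefficients = coefs,
                 intercept = raw$intercept,
                 dropped = as.character(raw$dropped %||% character(0))),
            class = "bag_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
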