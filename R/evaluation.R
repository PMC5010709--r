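#' Prediction mean squared error on a held-out portion
#'
#' @param model a `bag_model`.
#' @param data a [bag_dataset()] disjoint from the portion the model was
#'   fit on.
#' @return Mean squared prediction error.
#' @export
pmse <- function(model, data) {
  stopifnot(inherits(model, "bag_model"), inherits(data, "bag_dataset"))
  if (nrow(data$X) == 0) stop("empty validation data.", call. = FALSE)
  mean((data$y - predict(model, data))^2)
}

#' Percent ratio of prediction errors (PRPMSE)
#'
#' `100 * pmse(sub) / pmse(base)` on the same validation portion. Values
#' below 100 mean the substituted model predicts better than the stage-1
#' baseline.
#'
#' @param sub,base `bag_model`s fit on the same stage-2 portion.
#' @param data validation portion.
#' @return Percentage.
#' @export
prpmse <- function(sub, base, data) {
  pb <- pmse(base, data)
  if (pb == 0) stop("baseline PMSE is zero; ratio undefined.", call. = FALSE)
  100 * pmse(sub, data) / pb
}

#' Bootstrap confidence interval for the prediction-error ratio
#'
#' Rows of the validation portion are resampled with replacement `B` times
#' (paired: the same rows enter numerator and denominator), the PMSE ratio
#' `pmse(sub)/pmse(base)` is recomputed on each resample, and a percentile
#' interval is formed. A substitution is "favorable" when the interval
#' contains 1 or lies entirely below it (its lower endpoint is at most 1):
#' the swap does not significantly worsen prediction.
#'
#' Degenerate resamples with zero baseline error are redrawn (and counted
#' in the `redrawn` attribute).
#'
#' @param sub,base `bag_model`s.
#' @param data validation portion.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level, default 0.95.
#' @param seed integer seed.
#' @return A list with `ci` (length-2 vector), `favorable` (logical) and
#'   the resampled `ratios`.
#' @export
bootstrap_ratio_ci <- function(sub, base, data, B = 1000L, level = 0.95,
                               seed = 1L) {
  stopifnot(B >= 100)
  e_sub <- (data$y - predict(sub, data))^2
  e_base <- (data$y - predict(base, data))^2
  n <- length(e_base)
  set.seed(as.integer(seed))
  ratios <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      ii <- sample.int(n, replace = TRUE)
      den <- mean(e_base[ii])
      if (den > 0) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L) stop("baseline errors identically zero.", call. = FALSE)
    }
    ratios[b] <- mean(e_sub[ii]) / den
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(ratios, c(alpha, 1 - alpha), type = 7))
  structure(list(ci = ci, favorable = ci[1] <= 1, ratios = ratios),
            redrawn = redrawn)
}

#' Integrated squared error of the fitted regression function
#'
#' Estimation accuracy of a final model against the generating coefficients:
#' the model's coefficients are embedded in the full coefficient space
#' (zero for unselected variables) and the error is integrated over the
#' covariate law, `(bhat - beta)' Sigma (bhat - beta)`. With an identity
#' covariance this is the plain coefficient sum of squared errors. Averaged
#' over replicates it is reported as the MISE. The intercept is ignored: the
#' generating model and the standardized data are both mean-centered.
#'
#' @param model a `bag_model`.
#' @param true_beta named generating coefficient vector over all variables.
#' @param cov covariance matrix of the covariates, in `true_beta` order.
#' @return A single numeric value.
#' @export
mise <- function(model, true_beta, cov) {
  stopifnot(inherits(model, "bag_model"))
  if (length(true_beta) != nrow(cov) || nrow(cov) != ncol(cov)) {
    stop("`true_beta` and `cov` dimensions disagree.", call. = FALSE)
  }
  if (is.null(names(true_beta))) {
    stop("`true_beta` must be named by variable id.", call. = FALSE)
  }
  miss <- setdiff(model$variables, names(true_beta))
  if (length(miss)) {
    stop("model variables not in `true_beta`: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bhat <- setNames(rep(0, length(true_beta)), names(true_beta))
  bhat[model$variables] <- model$coefficients
  d <- bhat - true_beta
  as.numeric(t(d) %*% cov %*% d)
}

#' Composition of a variable set with respect to the relevance map
#'
#' @param variables character vector of variable ids.
#' @param relevance named logical relevance map covering them.
#' @return A tibble with `n_selected`, `n_relevant` and `pct_relevant`
#'   (100 * ratio; `NaN` for an empty set).
#' @export
selection_composition <- function(variables, relevance) {
  miss <- setdiff(variables, names(relevance))
  if (length(miss)) {
    stop("relevance missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_sel <- length(variables)
  n_rel <- sum(as.logical(relevance[variables]))
  tibble::tibble(n_selected = n_sel, n_relevant = n_rel,
                 pct_relevant = 100 * n_rel / n_sel)
}
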