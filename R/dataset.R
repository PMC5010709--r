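#' Assemble a standardized modelling dataset
#'
#' A `bag_dataset` bundles a numeric covariate matrix and a response vector
#' in the form every downstream step of the workflow expects: covariate
#' columns centered to mean zero and scaled to unit sample variance, and the
#' response centered to mean zero. Variable identifiers are kept alongside so
#' that selections, bags and substitution records can always refer to
#' variables by name.
#'
#' @param X numeric matrix (samples in rows, covariates in columns) or a
#'   data frame of numeric columns.
#' @param y numeric response, one value per row of `X`.
#' @param var_ids character vector of variable identifiers; defaults to the
#'   column names of `X`, or `x1..xP` when absent.
#' @param standardize center/scale the columns and center `y`. Set to
#'   `FALSE` only if the inputs are already standardized.
#'
#' @return An object of class `bag_dataset`: a list with elements `X`
#'   (standardized matrix), `y` (centered response) and `var_ids`.
#'
#' @examples
#' d <- bag_dataset(matrix(rnorm(60), 20, 3), rnorm(20))
#' colMeans(d$X) # ~ 0
#' @export
bag_dataset <- function(X, y, var_ids = NULL, standardize = TRUE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric matrix or data frame.", call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("`y` must have one value per row of `X`.", call. = FALSE)
  }
  if (is.null(var_ids)) {
    var_ids <- colnames(X)
    if (is.null(var_ids)) var_ids <- paste0("x", seq_len(ncol(X)))
  }
  if (length(var_ids) != ncol(X) || anyDuplicated(var_ids)) {
    stop("`var_ids` must be unique and match the number of columns.", call. = FALSE)
  }
  if (standardize) {
    sds <- apply(X, 2, sd)
    if (any(sds == 0)) {
      stop("constant covariate column(s): ",
           paste(var_ids[sds == 0], collapse = ", "), call. = FALSE)
    }
    X <- scale(X, center = TRUE, scale = sds)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    y <- y - mean(y)
  }
  colnames(X) <- var_ids
  structure(list(X = X, y = y, var_ids = var_ids), class = "bag_dataset")
}

#' Build a dataset from a data frame holding response and covariates
#'
#' Convenience wrapper for tabular input: one column is the response, the
#' remaining numeric columns are covariates.
#'
#' @param data a data frame.
#' @param response name of the response column.
#' @param standardize passed to [bag_dataset()].
#' @return A `bag_dataset`.
#' @export
as_bag_dataset <- function(data, response, standardize = TRUE) {
  stopifnot(is.data.frame(data))
  if (!response %in% names(data)) {
    stop("response column `", response, "` not found.", call. = FALSE)
  }
  y <- data[[response]]
  X <- data[setdiff(names(data), response)]
  keep <- vapply(X, is.numeric, logical(1))
  bag_dataset(as.matrix(X[keep]), y, standardize = standardize)
}

#' @export
print.bag_dataset <- function(x, ...) {
  cat(sprintf("<bag_dataset> %d samples x %d covariates\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' @export
dim.bag_dataset <- function(x) dim(x$X)

#' @method as_tibble bag_dataset
#' @export
as_tibble.bag_dataset <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$X))
  out$y <- x$y
  dplyr::relocate(out, "y")
}

#' Subset the rows of a dataset
#'
#' @param data a `bag_dataset`.
#' @param rows integer row indices.
#' @param restandardize re-center/scale the covariates and re-center the
#'   response within the subset (the default, so each analysis portion sees
#'   standardized inputs).
#' @return A `bag_dataset` on the selected rows.
#' @export
dataset_subset <- function(data, rows, restandardize = TRUE) {
  stopifnot(inherits(data, "bag_dataset"))
  bag_dataset(data$X[rows, , drop = FALSE], data$y[rows],
              var_ids = data$var_ids, standardize = restandardize)
}

#' Split a dataset into three disjoint portions
#'
#' The workflow uses one portion for penalized variable selection and bag
#' construction, a second to refit the final sparse model, and a third to
#' validate prediction error. Rows are assigned by simple random partition
#' without replacement: the first two portions receive `m` rows each and the
#' third receives the remaining `n - 2m`. Each portion is restandardized by
#' default so every stage models mean-zero, unit-variance inputs.
#'
#' @param data a `bag_dataset`.
#' @param m portion size for the first two portions; the default `n %/% 3`
#'   splits a sample of 300 into 100/100/100.
#' @param seed integer seed making the partition reproducible.
#' @param restandardize restandardize within each portion (default `TRUE`).
#'
#' @return An object of class `three_way_split`: list with `d1`, `d2`, `d3`
#'   (`bag_dataset`s) and `index_map`, a list of the original row indices of
#'   each portion.
#' @export
split_three_way <- function(data, m = NULL, seed = 1L, restandardize = TRUE) {
  stopifnot(inherits(data, "bag_dataset"))
  n <- nrow(data$X)
  if (is.null(m)) m <- n %/% 3L
  if (m <= 0 || 2 * m > n) {
    stop("`m` must satisfy 0 < 2m <= n.", call. = FALSE)
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  idx <- list(d1 = sort(perm[seq_len(m)]),
              d2 = sort(perm[m + seq_len(m)]),
              d3 = sort(perm[(2 * m + 1):n]))
  structure(list(
    d1 = dataset_subset(data, idx$d1, restandardize),
    d2 = dataset_subset(data, idx$d2, restandardize),
    d3 = dataset_subset(data, idx$d3, restandardize),
    index_map = idx
  ), class = "three_way_split")
}

#' @export
print.three_way_split <- function(x, ...) {
  cat(sprintf("<three_way_split> sizes %d / %d / %d\n",
              nrow(x$d1$X), nrow(x$d2$X), nrow(x$d3$X)))
  invisible(x)
}

#' Split a dataset into two portions
#'
#' In applied analyses with no held-out validation requirement the data are
#' divided into a selection/elicitation portion and a refit portion only.
#'
#' @inheritParams split_three_way
#' @param m size of the first portion (default `n %/% 2`).
#' @return List with `d1`, `d2` and `index_map`.
#' @export
split_two_way <- function(data, m = NULL, seed = 1L, restandardize = TRUE) {
  stopifnot(inherits(data, "bag_dataset"))
  n <- nrow(data$X)
  if (is.null(m)) m <- n %/% 2L
  if (m <= 0 || m >= n) stop("`m` must satisfy 0 < m < n.", call. = FALSE)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  idx <- list(d1 = sort(perm[seq_len(m)]), d2 = sort(perm[(m + 1):n]))
  structure(list(
    d1 = dataset_subset(data, idx$d1, restandardize),
    d2 = dataset_subset(data, idx$d2, restandardize),
    index_map = idx
  ), class = "two_way_split")
}

#' Keep the K highest-variance covariates
#'
#' Generic pre-screening step for expression matrices: retains the `k`
#' columns with the largest empirical variance (computed before
#' standardization this is only meaningful on unstandardized input, so the
#' filter accepts a plain matrix).
#'
#' @param X numeric matrix.
#' @param k number of columns to keep.
#' @return The filtered matrix.
#' @export
top_variance_filter <- function(X, k) {
  stopifnot(is.matrix(X), k >= 1)
  k <- min(k, ncol(X))
  keep <- order(apply(X, 2, var), decreasing = TRUE)[seq_len(k)]
  X[, sort(keep), drop = FALSE]
}
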