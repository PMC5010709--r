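## broom-style tidiers

#' Tidy a stage-1 selection
#'
#' @param x a `bag_selection`.
#' @param ... unused.
#' @return A tibble with one row per selected variable: `variable`,
#'   `coefficient`, `weight`.
#' @method tidy bag_selection
#' @export
tidy.bag_selection <- function(x, ...) {
  tibble::tibble(variable = x$selected,
                 coefficient = unname(x$coefficients),
                 weight = unname(x$weights[x$selected]))
}

#' @rdname tidy.bag_selection
#' @return `glance()` gives a one-row tibble: method, lambda, selection size.
#' @method glance bag_selection
#' @export
glance.bag_selection <- function(x, ...) {
  tibble::tibble(method = x$method, lambda = x$lambda,
                 n_selected = length(x$selected), intercept = x$intercept)
}

#' Tidy an OLS refit
#'
#' @param x a `bag_model`.
#' @param ... unused.
#' @method tidy bag_model
#' @export
tidy.bag_model <- function(x, ...) {
  tibble::tibble(variable = c("(Intercept)", x$variables),
                 coefficient = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.bag_model
#' @method glance bag_model
#' @export
glance.bag_model <- function(x, ...) {
  tibble::tibble(n_variables = length(x$variables),
                 n_dropped = length(x$dropped))
}

#' Tidy a bag collection
#'
#' @param x a `bag_collection`.
#' @param ... unused.
#' @return The members tibble (`owner`, `rule`, `rank`, `candidate`,
#'   `score`).
#' @method tidy bag_collection
#' @export
tidy.bag_collection <- function(x, ...) x$members

#' @rdname tidy.bag_collection
#' @method glance bag_collection
#' @export
glance.bag_collection <- function(x, ...) {
  tibble::tibble(rule = x$rule, n_owners = length(x$owners),
                 n_members = nrow(x$members),
                 shortlist_size = length(x$shortlist),
                 q = x$q, threshold = x$threshold)
}

#' Tidy a substitution result
#'
#' @param x a `bag_substitution`.
#' @param ... unused.
#' @return The per-owner records tibble.
#' @method tidy bag_substitution
#' @export
tidy.bag_substitution <- function(x, ...) x$records

#' @rdname tidy.bag_substitution
#' @method glance bag_substitution
#' @export
glance.bag_substitution <- function(x, ...) {
  tab <- table(factor(x$records$outcome,
                      levels = c("kept_relevant", "switched",
                                 "kept_no_candidate", "collapsed_duplicate")))
  tibble::tibble(rule = x$rule, n_owners = nrow(x$records),
                 n_final = length(x$final_variables),
                 kept_relevant = as.integer(tab[["kept_relevant"]]),
                 switched = as.integer(tab[["switched"]]),
                 kept_no_candidate = as.integer(tab[["kept_no_candidate"]]),
                 collapsed_duplicate = as.integer(tab[["collapsed_duplicate"]]))
}

#' Tidy an experiment
#'
#' @param x a `bag_experiment`.
#' @param ... unused.
#' @return `tidy()` returns the per-replicate rows; `glance()` the
#'   per-method summary.
#' @method tidy bag_experiment
#' @export
tidy.bag_experiment <- function(x, ...) x$replicates

#' @rdname tidy.bag_experiment
#' @method glance bag_experiment
#' @export
glance.bag_experiment <- function(x, ...) x$summary
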