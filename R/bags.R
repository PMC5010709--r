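## Bags of candidate substitutes around each stage-1 selected covariate.
##
## All three rules are computed on the stage-1 portion only. Ranking ties
## break towards the lower variable index (the order of var_ids).

new_bag_collection <- function(members, rule, selection, q = NA,
                               threshold = NA, ranking = NA,
                               skipped = character(0)) {
  shortlist <- unique(c(selection$selected, members$candidate))
  structure(list(
    members = members, rule = rule, owners = selection$selected,
    q = q, threshold = threshold, ranking = ranking,
    shortlist = shortlist, skipped = skipped
  ), class = "bag_collection")
}

#' @export
print.bag_collection <- function(x, ...) {
  cat(sprintf("<bag_collection> rule %s: %d owners, %d member rows, shortlist %d\n",
              x$rule, length(x$owners), nrow(x$members), length(x$shortlist)))
  invisible(x)
}

rank_order <- function(score_key, idx) order(-score_key, idx)

owner_correlations <- function(owner, data) {
  ## correlation of the owner column with every other column
  r <- as.numeric(cor(data$X[, owner], data$X))
  setNames(r, data$var_ids)
}

#' Bag rule B1: top-q correlated covariates per selected covariate
#'
#' For each stage-1 selected covariate, the bag contains the `q` other
#' covariates with the largest correlation to it on the stage-1 portion.
#' `ranking = "signed"` (default) ranks by the correlation itself, matching
#' a design where substitutes are positively correlated proxies;
#' `"absolute"` ranks by magnitude.
#'
#' @param selection a `bag_selection` from stage 1.
#' @param data the stage-1 portion the selection was fit on.
#' @param q bag size (0 gives empty bags); values >= P are capped at P - 1
#'   with a warning.
#' @param ranking `"signed"` or `"absolute"`.
#' @return A `bag_collection` whose `members` tibble has columns
#'   `owner`, `rule`, `rank`, `candidate`, `score` (the signed correlation).
#' @export
bag_correlation_topq <- function(selection, data, q = 20L,
                                 ranking = c("signed", "absolute")) {
  stopifnot(inherits(selection, "bag_selection"), inherits(data, "bag_dataset"))
  ranking <- match.arg(ranking)
  if (q < 0) stop("`q` must be non-negative.", call. = FALSE)
  P <- length(data$var_ids)
  if (q >= P) {
    warning("q >= P; capping bag size at P - 1.", call. = FALSE)
    q <- P - 1L
  }
  members <- purrr::map_dfr(selection$selected, function(j) {
    if (q == 0) return(tibble::tibble())
    r <- owner_correlations(j, data)
    r <- r[names(r) != j]
    key <- if (ranking == "signed") r else abs(r)
    ord <- rank_order(key, match(names(r), data$var_ids))[seq_len(q)]
    tibble::tibble(owner = j, rule = "B1", rank = seq_len(q),
                   candidate = names(r)[ord], score = unname(r[ord]))
  })
  if (!nrow(members)) {
    members <- tibble::tibble(owner = character(0), rule = character(0),
                              rank = integer(0), candidate = character(0),
                              score = numeric(0))
  }
  new_bag_collection(members, "B1", selection, q = q, ranking = ranking)
}

#' Bag rule B2: all covariates above a correlation threshold
#'
#' Instead of a fixed bag size, every covariate whose correlation with the
#' selected covariate reaches `threshold` on the stage-1 portion joins the
#' bag, so bag sizes vary per owner. The reference threshold is 0.25.
#'
#' @inheritParams bag_correlation_topq
#' @param threshold correlation cutoff in (0, 1].
#' @return A `bag_collection` (rule `"B2"`).
#' @export
bag_correlation_threshold <- function(selection, data, threshold = 0.25,
                                      ranking = c("signed", "absolute")) {
  stopifnot(inherits(selection, "bag_selection"), inherits(data, "bag_dataset"))
  ranking <- match.arg(ranking)
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1].", call. = FALSE)
  }
  members <- purrr::map_dfr(selection$selected, function(j) {
    r <- owner_correlations(j, data)
    r <- r[names(r) != j]
    key <- if (ranking == "signed") r else abs(r)
    hit <- which(key >= threshold)
    if (!length(hit)) return(tibble::tibble())
    ord <- hit[rank_order(key[hit], match(names(r)[hit], data$var_ids))]
    tibble::tibble(owner = j, rule = "B2", rank = seq_along(ord),
                   candidate = names(r)[ord], score = unname(r[ord]))
  })
  if (!nrow(members)) {
    members <- tibble::tibble(owner = character(0), rule = character(0),
                              rank = integer(0), candidate = character(0),
                              score = numeric(0))
  }
  new_bag_collection(members, "B2", selection, threshold = threshold,
                     ranking = ranking)
}

## residual mean squared error of OLS fits where column `owner` of the
## selected design is replaced, in turn, by each candidate column.
## Returns RSS/n. Collinear replacements (no residual variance left in the
## candidate after projecting on the retained columns) come back NA.
replacement_mse <- function(owner, candidates, selection, data) {
  S <- selection$selected
  others <- setdiff(S, owner)
  n <- nrow(data$X)
  Z <- cbind(1, data$X[, others, drop = FALSE])
  qz <- qr(Z)
  Q <- qr.Q(qz)[, seq_len(qz$rank), drop = FALSE]
  ry <- data$y - Q %*% crossprod(Q, data$y)
  CK <- data$X[, candidates, drop = FALSE]
  RK <- CK - Q %*% crossprod(Q, CK)
  den <- colSums(RK^2)
  num <- as.numeric(crossprod(RK, ry))^2
  rss0 <- sum(ry^2)
  rss <- rss0 - ifelse(den > 1e-8 * n, num / den, NA_real_)
  setNames(rss / n, candidates)
}

## residual mean squared error (RSS/n) of the OLS fit on the full selected set
model_mse <- function(selection, data) {
  fit <- refit_ols(selection$selected, data)
  mean((data$y - predict(fit, data))^2)
}

#' Bag rule B3: top-q candidates by replacement regression error
#'
#' For each selected covariate j, every non-selected covariate k is swapped
#' into j's place in the OLS regression of the response on the full selected
#' set (stage-1 portion), and scored by the residual mean squared error of
#' that replacement fit. The bag keeps the `q` candidates with the smallest
#' replacement MSE. Candidates whose replacement design is rank-deficient
#' are skipped and recorded in the collection's `skipped` field.
#'
#' @inheritParams bag_correlation_topq
#' @return A `bag_collection` (rule `"B3"`) whose `score` column holds the
#'   replacement MSE (ascending).
#' @export
bag_mse_topq <- function(selection, data, q = 20L) {
  stopifnot(inherits(selection, "bag_selection"), inherits(data, "bag_dataset"))
  if (q < 0) stop("`q` must be non-negative.", call. = FALSE)
  S <- selection$selected
  if (length(S) >= nrow(data$X)) {
    stop("replacement OLS needs |S| < n on the stage-1 portion.", call. = FALSE)
  }
  pool <- setdiff(data$var_ids, S)
  q <- min(q, length(pool))
  skipped <- character(0)
  members <- purrr::map_dfr(S, function(j) {
    if (q == 0) return(tibble::tibble())
    mse <- replacement_mse(j, pool, selection, data)
    bad <- names(mse)[is.na(mse)]
    if (length(bad)) skipped <<- union(skipped, bad)
    mse <- mse[!is.na(mse)]
    ord <- order(mse, match(names(mse), data$var_ids))[seq_len(min(q, length(mse)))]
    tibble::tibble(owner = j, rule = "B3", rank = seq_along(ord),
                   candidate = names(mse)[ord], score = unname(mse[ord]))
  })
  if (!nrow(members)) {
    members <- tibble::tibble(owner = character(0), rule = character(0),
                              rank = integer(0), candidate = character(0),
                              score = numeric(0))
  }
  new_bag_collection(members, "B3", selection, q = q, skipped = skipped)
}

#' Replacement-to-original MSE ratio
#'
#' Ratio of the residual MSE when `bag_member` takes `owner`'s place in the
#' selected-set OLS regression to the residual MSE of the original selected
#' set. Ratios below one flag particularly appealing substitutes: the swap
#' reduces the in-sample error of the model.
#'
#' @param bag_member candidate variable id.
#' @param owner selected variable id being replaced.
#' @param selection the stage-1 `bag_selection`.
#' @param data the stage-1 portion.
#' @return A single numeric ratio.
#' @export
mse_ratio <- function(bag_member, owner, selection, data) {
  stopifnot(owner %in% selection$selected)
  num <- if (identical(bag_member, owner)) {
    model_mse(selection, data)
  } else {
    replacement_mse(owner, bag_member, selection, data)[[1]]
  }
  num / model_mse(selection, data)
}

#' Elicitation shortlist: union of owners and all bag members
#'
#' The deduplicated union of the selected covariates and every bag member,
#' owners first, then members in order of first appearance. This is the set
#' of variables a domain expert has to label, which is far smaller than the
#' full covariate list.
#'
#' @param bags a `bag_collection`.
#' @return Character vector of variable ids.
#' @export
shortlist_union <- function(bags) {
  stopifnot(inherits(bags, "bag_collection"))
  unique(c(bags$owners, bags$members$candidate))
}

## Elicitation worksheet I/O ---------------------------------------------

#' Write and re-read the expert elicitation worksheet
#'
#' The worksheet is a CSV with one row per owner (rank 0, the owner itself
#' as candidate) and one row per bag member, with columns
#' `owner,rule,rank,candidate,score,relevant`. The `relevant` column is left
#' blank for the expert to fill with 0/1. `read_worksheet()` returns the
#' relevance map and fails if any shortlist variable is left unlabeled or is
#' labeled inconsistently across rows.
#'
#' @param bags a `bag_collection`.
#' @param path CSV path.
#' @return `write_worksheet()` the path, invisibly; `read_worksheet()` a
#'   named logical vector (the relevance map over the shortlist).
#' @export
write_worksheet <- function(bags, path) {
  stopifnot(inherits(bags, "bag_collection"))
  self <- tibble::tibble(owner = bags$owners, rule = bags$rule, rank = 0L,
                         candidate = bags$owners, score = NA_real_)
  ws <- dplyr::bind_rows(self, bags$members)
  ws$relevant <- NA_integer_
  readr::write_csv(ws, path, na = "")
  invisible(path)
}

#' @rdname write_worksheet
#' @export
read_worksheet <- function(path) {
  ws <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          owner = "c", rule = "c", rank = "i",
                          candidate = "c", score = "d", relevant = "i"))
  blank <- unique(ws$candidate[is.na(ws$relevant)])
  if (length(blank)) {
    stop("unlabeled worksheet entries (incomplete elicitation): ",
         paste(blank, collapse = ", "), call. = FALSE)
  }
  lab <- tapply(ws$relevant, ws$candidate, function(v) unique(v))
  bad <- names(lab)[lengths(lab) > 1]
  if (length(bad)) {
    stop("inconsistent relevance labels for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  setNames(unlist(lab) > 0, names(lab))
}

#' Write / read a relevance map as CSV
#'
#' Two-column CSV `variable_id,relevant` with 0/1 flags.
#'
#' @param relevance named logical vector.
#' @param path CSV path.
#' @return `read_relevance()` returns a named logical vector.
#' @export
write_relevance <- function(relevance, path) {
  readr::write_csv(tibble::tibble(variable_id = names(relevance),
                                  relevant = as.integer(relevance)), path)
  invisible(path)
}

#' @rdname write_relevance
#' @export
read_relevance <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(variable_id = "c",
                                                relevant = "i"))
  setNames(df$relevant > 0, df$variable_id)
}
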