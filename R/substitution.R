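#' Apply the knowledge-based substitution rules
#'
#' Each stage-1 selected covariate (the bag "owner") is resolved in
#' selection order by fixed rules:
#'
#' 1. an owner that is itself biologically relevant is kept (`kept_relevant`);
#' 2. otherwise, if exactly one bag member is relevant, the owner is
#'    switched to it (`switched`, decided by `only_candidate`);
#' 3. with several relevant members, correlation bags (B1/B2) switch to the
#'    member most correlated with the owner and MSE bags (B3) to the member
#'    with the smallest replacement error (`switched`, decided by
#'    `max_correlation` / `min_mse`; ties resolve to the lower variable
#'    index, i.e. the stored bag order);
#' 4. with no relevant member the owner is retained (`kept_no_candidate`).
#'
#' A variable pulled in from two or more bags (or coinciding with a kept
#' owner) appears only once in the final model: later occurrences are marked
#' `collapsed_duplicate`, so the final model can be sparser than the
#' stage-1 selection.
#'
#' @param selection the stage-1 `bag_selection`.
#' @param bags a `bag_collection` built from the same selection.
#' @param relevance named logical vector covering the shortlist (owners and
#'   all bag members); missing labels are an error naming the variable.
#' @param data unused by the rules themselves (all scores are stored in the
#'   bags); accepted for interface symmetry with the bag constructors.
#'
#' @return An object of class `bag_substitution`: `records`, a tibble with
#'   one row per owner (`owner`, `outcome`, `replacement`, `decided_by`),
#'   and `final_variables`, the deduplicated final id list.
#' @export
apply_substitutions <- function(selection, bags, relevance, data = NULL) {
  stopifnot(inherits(selection, "bag_selection"),
            inherits(bags, "bag_collection"))
  if (!setequal(bags$owners, selection$selected)) {
    stop("`bags` were not built from this selection.", call. = FALSE)
  }
  short <- shortlist_union(bags)
  missing_lab <- setdiff(short, names(relevance))
  if (length(missing_lab)) {
    stop("relevance label missing for: ",
         paste(missing_lab, collapse = ", "),
         " (incomplete elicitation).", call. = FALSE)
  }
  best_first <- if (bags$rule == "B3") {
    function(df) df[order(df$score, df$rank), ]
  } else {
    function(df) df[order(-df$score, df$rank), ]
  }
  records <- purrr::map_dfr(selection$selected, function(j) {
    if (isTRUE(relevance[[j]])) {
      return(tibble::tibble(owner = j, outcome = "kept_relevant",
                            replacement = NA_character_, decided_by = "n/a"))
    }
    bag <- bags$members[bags$members$owner == j, , drop = FALSE]
    rel <- bag[as.logical(relevance[bag$candidate]), , drop = FALSE]
    if (!nrow(rel)) {
      return(tibble::tibble(owner = j, outcome = "kept_no_candidate",
                            replacement = NA_character_, decided_by = "n/a"))
    }
    if (nrow(rel) == 1L) {
      return(tibble::tibble(owner = j, outcome = "switched",
                            replacement = rel$candidate[1],
                            decided_by = "only_candidate"))
    }
    pick <- best_first(rel)$candidate[1]
    tibble::tibble(owner = j, outcome = "switched", replacement = pick,
                   decided_by = if (bags$rule == "B3") "min_mse"
                                else "max_correlation")
  })
  ## collapse duplicates in selection order
  final <- character(0)
  for (i in seq_len(nrow(records))) {
    target <- if (records$outcome[i] == "switched") {
      records$replacement[i]
    } else {
      records$owner[i]
    }
    if (target %in% final) {
      records$outcome[i] <- "collapsed_duplicate"
      records$replacement[i] <- target
      records$decided_by[i] <- "n/a"
    } else {
      final <- c(final, target)
    }
  }
  structure(list(records = records, final_variables = final,
                 rule = bags$rule), class = "bag_substitution")
}

#' @export
print.bag_substitution <- function(x, ...) {
  tab <- table(x$records$outcome)
  cat(sprintf("<bag_substitution> rule %s: %d owners -> %d final variables\n",
              x$rule, nrow(x$records), length(x$final_variables)))
  cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Write the substitution audit log as JSON
#'
#' @param x a `bag_substitution`.
#' @param path file path.
#' @export
write_substitution <- function(x, path) {
  stopifnot(inherits(x, "bag_substitution"))
  out <- list(rule = x$rule,
              final_variables = x$final_variables,
              records = x$records)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
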