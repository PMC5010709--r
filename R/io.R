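## Delimited-text interchange for datasets.

#' Write / read a dataset as TSV
#'
#' The covariate table is TSV with a `sample_id` first column and one header
#' column per variable id; the response is a separate one-column file.
#' Reading re-assembles a [bag_dataset()] (re-standardizing by default).
#'
#' @param data a `bag_dataset`.
#' @param x_path covariate TSV path.
#' @param y_path response file path.
#' @param standardize passed to [bag_dataset()] on read.
#' @return `read_dataset()` returns a `bag_dataset`.
#' @export
write_dataset <- function(data, x_path, y_path) {
  stopifnot(inherits(data, "bag_dataset"))
  df <- tibble::as_tibble(as.data.frame(data$X))
  df <- dplyr::mutate(df, sample_id = paste0("s", dplyr::row_number()),
                      .before = 1)
  readr::write_tsv(df, x_path)
  readr::write_tsv(tibble::tibble(y = data$y), y_path)
  invisible(x_path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(x_path, y_path, standardize = TRUE) {
  df <- readr::read_tsv(x_path, show_col_types = FALSE)
  y <- readr::read_tsv(y_path, show_col_types = FALSE)[[1]]
  X <- as.matrix(df[setdiff(names(df), "sample_id")])
  bag_dataset(X, y, standardize = standardize)
}
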