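# Reaction table I/O and train/test splitting.
#
# The CSV dialect matches the public high-throughput yield benchmarks:
# comma-separated, UTF-8, a header row, reactant SMILES in columns sharing a
# name prefix (blank cells allowed so the reactant count may vary by row),
# one product column, one yield column in percent. Any other column (e.g. an
# additive annotation) is carried through untouched and can key an
# out-of-sample split.

#' Read a reaction table from CSV
#'
#' Malformed rows (unparseable or out-of-range yield, no reactant SMILES) are
#' rejected with a message naming the row numbers, never a crash; row order
#' of the kept rows is preserved and a per-file summary is reported.
#'
#' @param path Path to a CSV file.
#' @param reactant_prefix Name prefix identifying reactant columns.
#' @param product_col,yield_col Product SMILES and yield column names.
#' @return A tibble of valid reactions (all original columns kept).
#' @export
read_reaction_csv <- function(path, reactant_prefix = "reactant",
                              product_col = "product", yield_col = "yield") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  cols <- reaction_columns(data, reactant_prefix, product_col, yield_col)
  y <- suppressWarnings(as.numeric(data[[cols$yield]]))
  n_react <- rowSums(!is.na(data[cols$reactants]) &
                       data[cols$reactants] != "")
  ok <- !is.na(y) & y >= 0 & y <= 100 & n_react >= 1 &
    !is.na(data[[cols$product]]) & data[[cols$product]] != ""
  if (any(!ok)) {
    message(sprintf("rejected %d malformed row(s): %s", sum(!ok),
                    paste(utils::head(which(!ok), 10), collapse = ", ")))
  }
  out <- data[ok, , drop = FALSE]
  out[[cols$yield]] <- y[ok]
  message(sprintf("read %d rows, kept %d", nrow(data), nrow(out)))
  out
}

#' Write a reaction table to CSV
#'
#' Columns whose names start with `"true_"` (the synthetic generator's hidden
#' ground-truth annotations) are never written to the main file; if
#' `truth_path` is given they go to that sibling file together with the row
#' index, so the training CSV stays free of oracle information.
#'
#' @param data A reaction tibble.
#' @param path Output CSV path.
#' @param truth_path Optional path for the ground-truth annotations.
#' @return `data`, invisibly.
#' @export
write_reaction_csv <- function(data, path, truth_path = NULL) {
  truth_cols <- grep("^true_", names(data), value = TRUE)
  readr::write_csv(data[setdiff(names(data), truth_cols)], path)
  if (!is.null(truth_path) && length(truth_cols)) {
    readr::write_csv(
      dplyr::bind_cols(tibble::tibble(row = seq_len(nrow(data))),
                       data[truth_cols]),
      truth_path
    )
  }
  invisible(data)
}

#' Random train/test split of a reaction table
#'
#' Disjoint, exhaustive partition with `round(train_fraction * n)` training
#' rows; identical inputs and seed reproduce the split exactly.
#'
#' @param data A data frame (`n >= 2` rows).
#' @param train_fraction Fraction of rows assigned to training, in `(0, 1)`.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_random <- function(data, train_fraction, seed = 1) {
  n <- nrow(data)
  if (n < 2L) stopf("need at least two records to split")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stopf("train_fraction must lie in (0, 1)")
  }
  n_train <- round(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Out-of-sample split by a component annotation
#'
#' Every record whose key column takes one of the holdout values goes to the
#' test set; the rest train. No key value occurs on both sides, emulating the
#' setting where certain components (e.g. additives) are only seen at test
#' time.
#'
#' @param data A data frame.
#' @param holdout_key Name of the annotation column.
#' @param holdout_values Character vector of key values to hold out.
#' @return A list with tibbles `train` and `test`.
#' @export
split_out_of_sample <- function(data, holdout_key, holdout_values) {
  if (!holdout_key %in% names(data)) {
    stopf("holdout key column '%s' not found", holdout_key)
  }
  key <- as.character(data[[holdout_key]])
  unseen <- setdiff(holdout_values, key)
  if (length(unseen)) {
    warnf("holdout value(s) matching no records: %s",
          paste(unseen, collapse = ", "))
  }
  in_test <- key %in% holdout_values
  if (all(in_test)) stopf("holdout leaves an empty training set")
  if (!any(in_test)) stopf("holdout selects no test records")
  list(train = data[!in_test, , drop = FALSE],
       test = data[in_test, , drop = FALSE])
}
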