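# Response-matrix container and the CSV dialects for item parameters and
# responses. Values are integer categories coded 1..K_i; NA marks missing.

#' Person-by-item response matrix
#'
#' @param values Integer matrix, persons in rows, items in columns; `NA` for
#'   missing. Observed values must lie in `1..K` for their item.
#' @param items Data frame with one row per column of `values`: columns
#'   `item_id`, `instrument` (`"anchor"` or `"linked"`), `K` (number of
#'   categories).
#' @param person_ids Character vector of person identifiers (defaults to
#'   rownames of `values` or `P0001...`).
#'
#' @return An object of class `response_matrix`: list with `values`
#'   (dimnamed matrix), `items`, `person_ids`.
#' @export
response_matrix <- function(values, items, person_ids = NULL) {
  values <- as.matrix(values)
  if (!is.data.frame(items) ||
      !all(c("item_id", "instrument", "K") %in% names(items)))
    stop("items must be a data frame with item_id, instrument, K",
         call. = FALSE)
  if (ncol(values) != nrow(items))
    stop("values must have one column per items row", call. = FALSE)
  if (!all(items$instrument %in% c("anchor", "linked")))
    stop("instrument labels must be 'anchor' or 'linked'", call. = FALSE)
  if (is.null(person_ids)) {
    person_ids <- rownames(values)
    if (is.null(person_ids))
      person_ids <- sprintf("P%04d", seq_len(nrow(values)))
  }
  if (length(person_ids) != nrow(values) || anyDuplicated(person_ids))
    stop("person_ids must be unique, one per row", call. = FALSE)
  storage.mode(values) <- "integer"
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    bad <- !is.na(x) & (x < 1L | x > items$K[j])
    if (any(bad))
      stop(sprintf("item '%s': observed categories outside 1..%d",
                   items$item_id[j], items$K[j]), call. = FALSE)
  }
  dimnames(values) <- list(person_ids, items$item_id)
  structure(list(values = values, items = items,
                 person_ids = as.character(person_ids)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response matrix: %d persons x %d items (%d anchor, %d linked), %.1f%% missing>\n",
    nrow(x$values), ncol(x$values), sum(x$items$instrument == "anchor"),
    sum(x$items$instrument == "linked"),
    100 * mean(is.na(x$values))))
  invisible(x)
}

# Columns of one instrument, aligned to a parameter bank by item_id.
instrument_values <- function(rm, bank) {
  ids <- bank_ids(bank)
  missing_cols <- setdiff(ids, colnames(rm$values))
  if (length(missing_cols))
    stop(sprintf("response matrix lacks items: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  rm$values[, ids, drop = FALSE]
}

#' Read / write an item-parameter bank CSV
#'
#' CSV dialect: columns `item_id, instrument, n_categories, a, b1, b2, ...`
#' with unused threshold cells empty.
#'
#' @param path File path.
#' @return `read_item_bank()` returns a list of [item_parameters];
#'   `write_item_bank()` returns `path` invisibly.
#' @export
read_item_bank <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "instrument", "n_categories", "a")
  if (!all(need %in% names(d)))
    stop("item-parameter CSV must have item_id, instrument, n_categories, a",
         call. = FALSE)
  bcols <- grep("^b[0-9]+$", names(d), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  lapply(seq_len(nrow(d)), function(i) {
    K <- as.integer(d$n_categories[i])
    b <- as.numeric(d[i, bcols[seq_len(K - 1L)]])
    item_parameters(d$item_id[i], d$a[i], b, d$instrument[i])
  })
}

#' @rdname read_item_bank
#' @param bank List of [item_parameters].
#' @export
write_item_bank <- function(bank, path) {
  validate_bank(bank)
  Kmax <- max(bank_K(bank))
  rows <- lapply(bank, function(it) {
    b <- c(it$b, rep(NA_real_, Kmax - it$K))
    c(list(item_id = it$item_id, instrument = it$instrument,
           n_categories = it$K, a = it$a),
      stats::setNames(as.list(b), paste0("b", seq_len(Kmax - 1L))))
  })
  d <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a response CSV
#'
#' Dialect: header row of item ids, first column `person_id`, one row per
#' person, missing cells empty.
#'
#' @param path File path.
#' @param items Item description data frame (as in [response_matrix]); when
#'   `NULL`, instruments and K are inferred from a `bank` argument.
#' @param bank Optional list of [item_parameters] used to derive `items`.
#' @return A [response_matrix].
#' @export
read_responses <- function(path, items = NULL, bank = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "person_id")
    stop("first column of a response CSV must be person_id", call. = FALSE)
  if (is.null(items)) {
    if (is.null(bank))
      stop("supply items or bank to describe the columns", call. = FALSE)
    validate_bank(bank)
    items <- data.frame(item_id = bank_ids(bank),
                        instrument = vapply(bank, `[[`, character(1),
                                            "instrument"),
                        K = bank_K(bank), stringsAsFactors = FALSE)
  }
  vals <- as.matrix(d[, items$item_id, drop = FALSE])
  response_matrix(vals, items, person_ids = as.character(d$person_id))
}

#' @rdname read_responses
#' @param rm A [response_matrix].
#' @export
write_responses <- function(rm, path) {
  d <- data.frame(person_id = rm$person_ids, rm$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
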