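#' Read and write elicitation experiment tables
#'
#' Tables are plain CSV with the fixed header `ce_conc, cf_conc, adding_day,
#' harvest_day, replicate, dw, intra, extra, total, portion`. Reading
#' validates the input columns, coerces cells to numeric (a non-numeric cell
#' is a format error naming the row), and permits missing response cells:
#' rows with any missing response are flagged in the `"incomplete_rows"`
#' attribute of the returned data frame.
#'
#' @param path file path.
#' @param table data frame with the table columns.
#' @param digits decimal places written.
#' @return `read_experiment()` a data frame; `write_experiment()` the path,
#'   invisibly.
#' @export
read_experiment <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(TABLE_INPUTS, "replicate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stopf("format error: missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  for (col in intersect(TABLE_COLUMNS, names(raw))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stopf("format error: non-numeric value in column '%s', row %d",
              col, bad[1])
      conv[!is.na(v) & v == ""] <- NA_real_
      raw[[col]] <- conv
    }
  }
  for (resp in setdiff(TABLE_RESPONSES, names(raw))) raw[[resp]] <- NA_real_
  if (anyNA(raw[required]))
    stopf("format error: missing values in input columns")
  raw <- raw[TABLE_COLUMNS]
  incomplete <- which(apply(is.na(raw[TABLE_RESPONSES]), 1, any))
  attr(raw, "incomplete_rows") <- incomplete
  raw
}

#' @rdname read_experiment
#' @export
write_experiment <- function(table, path, digits = 6) {
  missing_cols <- setdiff(TABLE_COLUMNS, names(table))
  if (length(missing_cols))
    stopf("table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  out <- table[TABLE_COLUMNS]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, digits))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random train/test partition of observation rows
#'
#' Uniform random partition without replacement, one shared split for all
#' responses. The training count is `floor(fraction * n + 0.5)` (round half
#' up). Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param n number of rows, or a data frame whose rows are split.
#' @param fraction proportion of rows assigned to training, in (0, 1).
#' @param seed RNG seed.
#' @return object of class `split_index`: list with integer vectors `train`
#'   and `test`, plus `fraction` and `seed`.
#' @examples
#' s <- split_train_test(720, 0.7, seed = 1)
#' length(s$train)  # 504
#' @export
split_train_test <- function(n, fraction = 0.7, seed = NULL) {
  if (is.data.frame(n)) n <- nrow(n)
  check_number(n, "n", lower = 2)
  check_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) stopf("'fraction' must be in (0, 1)")
  n <- as.integer(n)
  n_train <- as.integer(floor(fraction * n + 0.5))
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  s <- structure(list(train = train, test = setdiff(seq_len(n), train),
                      fraction = fraction, seed = seed),
                 class = "split_index")
  stopifnot(length(intersect(s$train, s$test)) == 0L,
            length(union(s$train, s$test)) == n)
  s
}

#' @export
print.split_index <- function(x, ...) {
  cat(sprintf("train/test split: %d train, %d test (fraction %.2f, seed %s)\n",
              length(x$train), length(x$test), x$fraction,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
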