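#' Construct a cohort from a data frame
#'
#' Validates every column against the dictionary: all columns must be
#' declared, and every non-missing value must be one of its variable's
#' declared levels. The variable's missing code is converted to `NA`.
#'
#' @param data A data frame of character (or factor) columns, one row per
#'   record (here: one emergency-department presentation).
#' @param dictionary A [variable_dictionary()] declaring every column.
#' @return An object of class `"cohort"`: a list with elements `data`
#'   (character data frame, `NA` for missing), `dictionary`, and `n`.
#' @export
cohort <- function(data, dictionary) {
  stopifnot(is.data.frame(data), inherits(dictionary, "variable_dictionary"))
  undeclared <- setdiff(names(data), variable_names(dictionary))
  if (length(undeclared))
    stop("undeclared column(s) in data: ", paste(undeclared, collapse = ", "),
         call. = FALSE)
  out <- data
  for (nm in names(data)) {
    spec <- get_spec(dictionary, nm)
    v <- as.character(data[[nm]])
    v[!is.na(v) & v == spec$missing_code] <- NA_character_
    bad <- !is.na(v) & !(v %in% spec$levels)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "value '%s' in row %d, column '%s' is not a declared level (%s)",
        v[i], i, nm, paste(spec$levels, collapse = ", ")), call. = FALSE)
    }
    out[[nm]] <- v
  }
  structure(list(data = out, dictionary = dictionary, n = nrow(out)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort:", x$n, "records,", ncol(x$data), "variables\n")
  miss <- vapply(x$data, function(v) sum(is.na(v)), integer(1))
  if (any(miss > 0))
    cat("  missing values in:",
        paste(sprintf("%s (%d)", names(miss)[miss > 0], miss[miss > 0]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from CSV
#'
#' The CSV must carry a header row; every column must be declared in the
#' dictionary. Values equal to a variable's missing code become `NA`.
#'
#' @param path Path to an RFC 4180 CSV file (UTF-8, comma-separated).
#' @param dictionary A [variable_dictionary()].
#' @return A [cohort()].
#' @export
read_cohort <- function(path, dictionary) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  cohort(df, dictionary)
}

#' Write a cohort to CSV
#'
#' Missing values are written as each variable's missing code, so that a
#' read/write/read round trip preserves values and missingness exactly.
#'
#' @param x A [cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- x$data
  for (nm in names(df)) {
    mc <- get_spec(x$dictionary, nm)$missing_code
    v <- df[[nm]]
    v[is.na(v)] <- mc
    df[[nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Collapse attendance counts to a binary indicator
#'
#' Attendance frequency is analysed as a 0/1 indicator: zero previous
#' attendances stay 0, one or more become 1.
#'
#' @param counts Vector of non-negative integers (`NA` allowed, preserved).
#' @return Integer vector of 0/1 (with `NA` where input was `NA`).
#' @export
#' @examples
#' recode_attendance(c(0, 1, 5, 0))
recode_attendance <- function(counts) {
  if (!is.numeric(counts))
    stop("`counts` must be numeric", call. = FALSE)
  if (any(!is.na(counts) & (counts < 0 | counts != floor(counts))))
    stop("attendance counts must be non-negative integers", call. = FALSE)
  as.integer(counts >= 1)
}

#' Descriptive summary table
#'
#' Per-variable level counts and percentages of the total sample, in the
#' style of a clinical descriptive table. When `stratum` is given (a binary
#' variable), a second pair of columns counts records with `stratum` at its
#' second declared level ("positive"), with percentages still computed over
#' the full sample, matching the convention of reporting subgroup counts as
#' percent of total.
#'
#' @param x A [cohort()].
#' @param stratum Optional name of a declared binary variable.
#' @param variables Optional character vector restricting which variables to
#'   summarise (default: all except `stratum`).
#' @return A data frame of class `"summary_table"` with columns `variable`,
#'   `level`, `count`, `percent` and, when stratified, `count_stratum`,
#'   `percent_stratum`. Percentages are rounded to 1 decimal place. For an
#'   empty cohort all counts are 0, percentages are reported as 0 and the
#'   attribute `zero_n` is set.
#' @export
summarise_cohort <- function(x, stratum = NULL, variables = NULL) {
  stopifnot(inherits(x, "cohort"))
  dict <- x$dictionary
  in_stratum <- NULL
  if (!is.null(stratum)) {
    spec <- get_spec(dict, stratum)
    if (spec$kind != "binary")
      stop("stratum variable '", stratum, "' must be binary", call. = FALSE)
    if (!stratum %in% names(x$data))
      stop("stratum variable '", stratum, "' not present in data",
           call. = FALSE)
    in_stratum <- !is.na(x$data[[stratum]]) &
      x$data[[stratum]] == spec$levels[2L]
  }
  if (is.null(variables))
    variables <- setdiff(names(x$data), stratum)
  n <- x$n
  ## half-up rounding to 1 dp (the convention of printed clinical tables;
  ## base round() is half-even: 21.25 would print 21.2)
  pct <- function(k) if (n == 0L) 0 else floor(1000 * k / n + 0.5) / 10

  rows <- lapply(variables, function(nm) {
    spec <- get_spec(dict, nm)
    v <- x$data[[nm]]
    cnt <- vapply(spec$levels, function(l) sum(!is.na(v) & v == l),
                  integer(1))
    out <- data.frame(variable = nm, level = spec$levels,
                      count = unname(cnt), percent = pct(unname(cnt)),
                      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(in_stratum)) {
      cs <- vapply(spec$levels, function(l)
        sum(!is.na(v) & v == l & in_stratum), integer(1))
      out$count_stratum <- unname(cs)
      out$percent_stratum <- pct(unname(cs))
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  attr(out, "stratum") <- stratum
  attr(out, "zero_n") <- n == 0L
  class(out) <- c("summary_table", "data.frame")
  out
}

#' @export
print.summary_table <- function(x, ...) {
  n <- attr(x, "n")
  st <- attr(x, "stratum")
  cat(sprintf("Summary of %d records%s\n", n,
              if (is.null(st)) "" else paste0(" (stratified by ", st, ")")))
  if (isTRUE(attr(x, "zero_n")))
    cat("  [empty cohort: percentages undefined, reported as 0]\n")
  hdr <- sprintf("  %-24s %-22s %6s %7s", "variable", "level", "n", "%")
  if (!is.null(st)) hdr <- paste0(hdr, sprintf(" %8s %7s", "n[s=1]", "%"))
  cat(hdr, "\n")
  for (i in seq_len(nrow(x))) {
    line <- sprintf("  %-24s %-22s %6d %7.1f", x$variable[i], x$level[i],
                    x$count[i], x$percent[i])
    if (!is.null(st))
      line <- paste0(line, sprintf(" %8d %7.1f", x$count_stratum[i],
                                   x$percent_stratum[i]))
    cat(line, "\n")
  }
  invisible(x)
}

#' Export a summary table
#'
#' @param x A `"summary_table"` from [summarise_cohort()].
#' @param path Output path; `.csv` writes CSV, anything else aligned text.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "summary_table"))
  if (tolower(tools::file_ext(path)) == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con)
    print(x)
    sink()
  }
  invisible(path)
}
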