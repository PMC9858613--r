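#' Cross-tabulate two cohort variables
#'
#' Counts records over the level combinations of `x` and `y`, optionally
#' within every level combination of `strata`. Pairwise-complete records are
#' used: any record missing `x`, `y` or a stratifying variable is excluded
#' and the exclusion count is reported.
#'
#' @param cohort A [cohort()].
#' @param x,y Names of declared variables; must differ.
#' @param strata Optional character vector of conditioning variable names.
#' @return An object of class `"contingency_table"`: counts as an
#'   `r x c` matrix (or `r x c x s` array over stratum combinations), with
#'   attributes `x`, `y`, `strata`, `N` (records used) and `n_excluded`.
#' @export
crosstab <- function(cohort, x, y, strata = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (identical(x, y)) stop("x and y must be different variables",
                            call. = FALSE)
  vars <- c(x, y, strata)
  specs <- lapply(vars, get_spec, dictionary = cohort$dictionary)
  cols <- lapply(vars, function(v) cohort$data[[v]])
  keep <- !Reduce(`|`, lapply(cols, is.na), rep(FALSE, cohort$n))
  n_excluded <- cohort$n - sum(keep)
  if (sum(keep) == 0L)
    stop(structure(class = c("cimap_empty_table", "error", "condition"),
                   list(message = sprintf(
                     "no complete records for %s x %s: table is empty",
                     x, y), call = NULL)))
  fx <- factor(cols[[1L]][keep], levels = specs[[1L]]$levels)
  fy <- factor(cols[[2L]][keep], levels = specs[[2L]]$levels)
  if (is.null(strata)) {
    counts <- table(fx, fy, dnn = NULL)
    counts <- matrix(as.integer(counts), nrow = nlevels(fx),
                     dimnames = list(specs[[1L]]$levels, specs[[2L]]$levels))
  } else {
    fs <- lapply(seq_along(strata), function(i)
      factor(cols[[i + 2L]][keep], levels = specs[[i + 2L]]$levels))
    z <- interaction(fs, drop = FALSE, lex.order = FALSE)
    tab <- table(fx, fy, z, dnn = NULL)
    counts <- array(as.integer(tab),
                    dim = c(nlevels(fx), nlevels(fy), nlevels(z)),
                    dimnames = list(specs[[1L]]$levels, specs[[2L]]$levels,
                                    levels(z)))
  }
  structure(counts, class = "contingency_table",
            x = x, y = y, strata = strata,
            N = sum(keep), n_excluded = n_excluded)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table %s x %s%s (N = %d, %d excluded)\n",
              attr(x, "x"), attr(x, "y"),
              if (is.null(attr(x, "strata"))) "" else
                paste0(" | ", paste(attr(x, "strata"), collapse = ", ")),
              attr(x, "N"), attr(x, "n_excluded")))
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(y)
  invisible(x)
}

as_count_matrix <- function(table) {
  if (inherits(table, "contingency_table") || is.array(table)) {
    m <- unclass(table)
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
    storage.mode(m) <- "double"
    return(m)
  }
  stop("expected a contingency table or count matrix", call. = FALSE)
}

#' Read or write a contingency table as a CSV matrix
#'
#' The CSV carries column levels in the header row and row levels in the
#' first column.
#'
#' @param path File path.
#' @return `read_contingency_csv()` returns an integer count matrix.
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_contingency_csv
#' @param table A count matrix or unstratified `contingency_table`.
#' @export
write_contingency_csv <- function(table, path) {
  m <- as_count_matrix(table)
  if (length(dim(m)) != 2L)
    stop("only unstratified tables can be written as a CSV matrix",
         call. = FALSE)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
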