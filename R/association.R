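#' @keywords internal
"_PACKAGE"

## Shannon entropy of a probability vector, in bits; 0 log 0 = 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Plug-in MI in bits from a count matrix; 0 log 0 = 0.
mi_from_counts <- function(m) {
  N <- sum(m)
  p <- m / N
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' Mutual information of a two-way table
#'
#' Plug-in mutual information, in bits:
#' `MI = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`, with `0 log 0 = 0`.
#' MI measures the strength of association between two discrete variables;
#' it is 0 exactly when the empirical table factorises, and bounded above
#' by the smaller marginal entropy.
#'
#' @param table An unstratified [crosstab()] result or a count matrix.
#' @return Mutual information in bits (non-negative scalar).
#' @export
#' @examples
#' mutual_information(matrix(c(40, 10, 10, 40), 2))
mutual_information <- function(table) {
  m <- as_count_matrix(table)
  if (length(dim(m)) != 2L)
    stop("mutual_information() expects a two-way table; see conditional_mi()",
         call. = FALSE)
  if (sum(m) == 0) stop("table has N = 0: mutual information undefined",
                        call. = FALSE)
  mi_from_counts(m)
}

## CMI in bits from a stratified count array (r x c x s):
## sum over strata of (N_z / N) * MI_z.
cmi_from_array <- function(a) {
  if (length(dim(a)) == 2L) return(mi_from_counts(a))
  Nz <- unname(apply(a, 3L, sum))
  N <- sum(Nz)
  cmi <- 0
  for (k in which(Nz > 0))
    cmi <- cmi + (Nz[k] / N) * mi_from_counts(a[, , k])
  cmi
}

#' Conditional mutual information
#'
#' Stratum-weighted mutual information
#' `CMI(x, y | Z) = sum_z phat(z) MI(x, y | Z = z)`, in bits. Strata with no
#' records contribute 0. With an empty conditioning set this is the ordinary
#' mutual information. CMI is zero exactly when `x` and `y` are empirically
#' independent within every stratum.
#'
#' @param cohort A [cohort()].
#' @param x,y Variable names.
#' @param given Character vector of conditioning variable names (may be
#'   empty or `NULL`).
#' @return Conditional mutual information in bits.
#' @export
conditional_mi <- function(cohort, x, y, given = NULL) {
  if (length(given) == 0L)
    return(mutual_information(crosstab(cohort, x, y)))
  cmi_from_array(as_count_matrix(crosstab(cohort, x, y, strata = given)))
}

association_result <- function(mi, g, df, p, n_effective, method,
                               degenerate = FALSE) {
  structure(list(mi = mi, g = g, df = df, p = p, n_effective = n_effective,
                 method = method, degenerate = degenerate),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "Association (%s): MI = %.4f bits, G = %.3f, df = %s, p = %.4g, N = %d\n",
    x$method, x$mi, x$g, format(x$df), x$p, x$n_effective))
  invisible(x)
}

## Relaxed Cochran rule: asymptotic G-test only when, pooling expected
## counts over non-empty strata, >= 80% are >= 1 and all are >= 0.2.
expected_counts_ok <- function(a) {
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  e <- numeric(0)
  for (k in seq_len(dim(a)[3L])) {
    m <- a[, , k]
    Nk <- sum(m)
    if (Nk == 0) next
    e <- c(e, as.vector(outer(rowSums(m), colSums(m)) / Nk))
  }
  length(e) > 0 && min(e) >= 0.2 && mean(e >= 1) >= 0.8
}

#' Likelihood-ratio (G) test of independence
#'
#' Computes `G = 2 sum O ln(O/E)` (zero-observed cells contribute 0) via the
#' identity `G = 2 N ln(2) MI` with plug-in (conditional) mutual information
#' in bits, and refers it to a chi-square tail. Degrees of freedom are
#' `(r-1)(c-1)` for a plain table and `(r-1)(c-1)` summed over non-empty
#' strata for a stratified one.
#'
#' If the expected counts are too sparse for the asymptotic reference
#' (less than 80% of expected cells at least 1, or any below 0.2), the
#' result is flagged `degenerate = TRUE`; callers such as [ci_test()] then
#' fall back to a permutation test.
#'
#' @param table A [crosstab()] result (optionally stratified) or count
#'   matrix.
#' @param df_override Optional degrees of freedom overriding the closed
#'   form.
#' @return An `"association_result"` with fields `mi` (bits), `g`, `df`,
#'   `p`, `n_effective`, `method = "g-test"`, `degenerate`.
#' @export
g_test <- function(table, df_override = NULL) {
  a <- as_count_matrix(table)
  N <- sum(a)
  if (N == 0) stop("table has N = 0: G-test undefined", call. = FALSE)
  d <- dim(a)
  mi <- cmi_from_array(a)
  g <- 2 * N * log(2) * mi
  if (!is.null(df_override)) {
    df <- df_override
  } else if (length(d) == 2L) {
    df <- (d[1L] - 1L) * (d[2L] - 1L)
  } else {
    nonempty <- sum(apply(a, 3L, sum) > 0)
    df <- (d[1L] - 1L) * (d[2L] - 1L) * nonempty
  }
  p <- if (df >= 1) stats::pchisq(g, df, lower.tail = FALSE) else 1
  association_result(mi, g, df, p, as.integer(N), "g-test",
                     degenerate = !expected_counts_ok(a))
}

#' Stratified permutation test of (conditional) independence
#'
#' Permutation null distribution of the plug-in (conditional) mutual
#' information, shuffling `y` within every conditioning stratum so the
#' conditional margins are preserved. The p-value uses the add-one
#' estimator `p = (1 + #[MI* >= MI]) / (1 + n_perm)`.
#'
#' @param cohort A [cohort()].
#' @param x,y Variable names.
#' @param given Optional conditioning variable names.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; fixed seed gives an identical p-value on
#'   re-run.
#' @return An `"association_result"` with `method = "permutation"` (`g` is
#'   the G statistic implied by the observed MI; `df` is `NA`).
#' @export
permutation_test <- function(cohort, x, y, given = NULL, n_perm = 9999,
                             seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  vars <- c(x, y, given)
  specs <- lapply(vars, get_spec, dictionary = cohort$dictionary)
  cols <- lapply(vars, function(v) cohort$data[[v]])
  keep <- !Reduce(`|`, lapply(cols, is.na), rep(FALSE, cohort$n))
  if (!any(keep))
    stop("no complete records for the permutation test", call. = FALSE)
  xc <- match(cols[[1L]][keep], specs[[1L]]$levels)
  yc <- match(cols[[2L]][keep], specs[[2L]]$levels)
  nx <- length(specs[[1L]]$levels)
  ny <- length(specs[[2L]]$levels)
  if (length(given)) {
    zc <- rep(1L, sum(keep))
    mult <- 1L
    for (i in seq_along(given)) {
      lev <- specs[[i + 2L]]$levels
      zc <- zc + (match(cols[[i + 2L]][keep], lev) - 1L) * mult
      mult <- mult * length(lev)
    }
    nz <- mult
  } else {
    zc <- rep(1L, sum(keep))
    nz <- 1L
  }
  N <- length(xc)
  idx_of <- function(yy) (zc - 1L) * (nx * ny) + (xc - 1L) * ny + yy
  cmi_of <- function(yy) {
    cnt <- tabulate(idx_of(yy), nbins = nx * ny * nz)
    cmi_from_array(array(cnt, dim = c(ny, nx, nz)))
  }
  obs <- cmi_of(yc)
  blocks <- split(seq_len(N), zc)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  exceed <- 0L
  yp <- yc
  for (b in seq_len(n_perm)) {
    for (blk in blocks) {
      if (length(blk) > 1L)
        yp[blk] <- yc[blk][sample.int(length(blk))]
    }
    if (cmi_of(yp) >= obs - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)
  association_result(obs, 2 * N * log(2) * obs, NA_integer_, p, N,
                     "permutation")
}

#' Test (conditional) independence of two cohort variables
#'
#' The default pipeline test: an asymptotic G-test when the expected counts
#' support it (at least 80% of expected cells >= 1 and all >= 0.2, a relaxed
#' Cochran rule), otherwise a stratified permutation test with `n_perm`
#' permutations.
#'
#' @inheritParams permutation_test
#' @param method `"auto"` (sparse-aware fallback, default), `"g"`, or
#'   `"permutation"`.
#' @return An `"association_result"`.
#' @export
ci_test <- function(cohort, x, y, given = NULL, n_perm = 9999, seed = 1L,
                    method = c("auto", "g", "permutation")) {
  method <- match.arg(method)
  if (method != "permutation") {
    tab <- crosstab(cohort, x, y, strata = if (length(given)) given)
    res <- g_test(tab)
    if (method == "g" || !res$degenerate) return(res)
  }
  permutation_test(cohort, x, y, given = given, n_perm = n_perm, seed = seed)
}

#' Pearson chi-square with phi / Cramer's V effect size
#'
#' Pearson chi-square without continuity correction;
#' `phi = sqrt(chi2 / N)` for 2x2 tables and
#' `V = sqrt(chi2 / (N (min(r, c) - 1)))` otherwise (phi and V coincide on
#' 2x2 tables).
#'
#' @param table An unstratified [crosstab()] result or count matrix with no
#'   zero row/column margins.
#' @return A list of class `"effect_size_result"` with `chi2`, `df`, `p`,
#'   `phi` (2x2 only, else `NA`), `cramers_v`, `n`.
#' @export
chi_square_effect <- function(table) {
  m <- as_count_matrix(table)
  if (length(dim(m)) != 2L)
    stop("chi_square_effect() expects an unstratified two-way table",
         call. = FALSE)
  N <- sum(m)
  if (N == 0) stop("table has N = 0", call. = FALSE)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    lvl <- c(rownames(m)[rs == 0], colnames(m)[cs == 0])
    stop("zero margin for level(s): ",
         paste(if (length(lvl)) lvl else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  e <- outer(rs, cs) / N
  chi2 <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  v <- sqrt(chi2 / (N * (min(dim(m)) - 1L)))
  phi <- if (all(dim(m) == 2L)) sqrt(chi2 / N) else NA_real_
  structure(list(chi2 = chi2, df = df, p = p, phi = phi, cramers_v = v,
                 n = as.integer(N)),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  es <- if (!is.na(x$phi)) sprintf("phi = %.2f", x$phi) else
    sprintf("V = %.2f", x$cramers_v)
  cat(sprintf("X2(%d) = %.2f, p = %.4g, %s (N = %d)\n",
              x$df, x$chi2, x$p, es, x$n))
  invisible(x)
}
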