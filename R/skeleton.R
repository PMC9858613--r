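## Integer encoding of a cohort for the structure-learning inner loops:
## codes[i, v] is the 1-based level index of variable v in record i (NA for
## missing); variables are kept in sorted name order so every downstream
## step is invariant to the column order of the input data.
encode_cohort <- function(cohort, variables = NULL) {
  if (is.null(variables)) variables <- names(cohort$data)
  variables <- sort(variables)
  specs <- lapply(variables, get_spec, dictionary = cohort$dictionary)
  nlev <- vapply(specs, function(s) length(s$levels), integer(1))
  codes <- matrix(NA_integer_, nrow = cohort$n, ncol = length(variables),
                  dimnames = list(NULL, variables))
  for (k in seq_along(variables))
    codes[, k] <- match(cohort$data[[variables[k]]], specs[[k]]$levels)
  list(codes = codes, nlev = nlev, variables = variables)
}

## G or permutation CI test on encoded columns. zidx may be empty.
## `alpha_stop`: the permutation fallback may stop early once the add-one
## p-value lower bound (1 + exceed)/(1 + n_perm) exceeds it — the bound is
## monotone in the exceedance count, so the reject/non-reject decision at
## alpha_stop is exact; only the reported p is then conservative.
ci_test_codes <- function(enc, xi, yi, zidx, n_perm, seed,
                          alpha_stop = NULL) {
  cols <- c(xi, yi, zidx)
  sub <- enc$codes[, cols, drop = FALSE]
  keep <- !rowSums(is.na(sub))
  sub <- sub[keep, , drop = FALSE]
  N <- nrow(sub)
  if (N == 0L) return(association_result(0, 0, NA, 1, 0L, "empty",
                                         degenerate = TRUE))
  nx <- enc$nlev[xi]
  ny <- enc$nlev[yi]
  if (length(zidx)) {
    zc <- rep(1L, N)
    mult <- 1L
    for (k in seq_along(zidx)) {
      zc <- zc + (sub[, 2L + k] - 1L) * mult
      mult <- mult * enc$nlev[zidx[k]]
    }
    nz <- mult
  } else {
    zc <- rep(1L, N)
    nz <- 1L
  }
  xc <- sub[, 1L]
  yc <- sub[, 2L]
  counts <- tabulate((zc - 1L) * (nx * ny) + (xc - 1L) * ny + yc,
                     nbins = nx * ny * nz)
  a <- array(counts, dim = c(ny, nx, nz))
  if (expected_counts_ok(a)) {
    mi <- cmi_from_array(a)
    nonempty <- if (nz == 1L) 1L else sum(apply(a, 3L, sum) > 0)
    df <- (nx - 1L) * (ny - 1L) * nonempty
    g <- 2 * N * log(2) * mi
    p <- if (df >= 1) stats::pchisq(g, df, lower.tail = FALSE) else 1
    return(association_result(mi, g, df, p, N, "g-test"))
  }
  ## permutation fallback, shuffling y within conditioning strata
  obs <- cmi_from_array(a)
  blocks <- split(seq_len(N), zc)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  exceed <- 0L
  yp <- yc
  stop_at <- if (is.null(alpha_stop)) n_perm + 1L else
    ceiling(alpha_stop * (1 + n_perm))
  for (b in seq_len(n_perm)) {
    for (blk in blocks)
      if (length(blk) > 1L) yp[blk] <- yc[blk][sample.int(length(blk))]
    cnt <- tabulate((zc - 1L) * (nx * ny) + (xc - 1L) * ny + yp,
                    nbins = nx * ny * nz)
    if (cmi_from_array(array(cnt, dim = c(ny, nx, nz))) >= obs - 1e-12) {
      exceed <- exceed + 1L
      if (exceed >= stop_at) break
    }
  }
  association_result(obs, 2 * N * log(2) * obs, NA_integer_,
                     (1 + exceed) / (1 + n_perm), N, "permutation")
}

## Deterministic, order-invariant per-test seed.
test_seed <- function(seed, xname, yname, znames) {
  key <- paste(xname, yname, paste(sort(znames), collapse = ","),
               sep = "|")
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Significance-pruned skeleton of the conditional independence map
#'
#' Stable-order constraint-based pruning. Starting from the complete
#' undirected graph, for conditioning-set sizes `0 .. max_cond` every
#' surviving pair is tested for independence given each subset (of that
#' size) of the pair's common neighbourhood, with neighbourhoods frozen at
#' the start of each size level (so the result does not depend on the order
#' variables are stored in). An edge is removed on the first non-rejection;
#' retained edges carry their marginal mutual information and the maximum
#' p-value observed across their tests.
#'
#' Tests are [ci_test()]-style: asymptotic G-test with a stratified
#' permutation fallback when expected counts are sparse.
#'
#' @param cohort A [cohort()].
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param max_cond Largest conditioning-set size (default 2); clamped with
#'   a warning if it exceeds `#variables - 2`.
#' @param seed Integer seed (used only by permutation fallbacks; seeds are
#'   derived per test so results are order-invariant).
#' @param correction `"none"` (default) or `"bonferroni"` (alpha divided by
#'   the number of variable pairs — appropriate when scanning many pairs).
#' @param n_perm Permutations for the sparse fallback.
#' @param variables Optional subset of variables to analyse.
#' @return An object of class `"ci_skeleton"`: list with `variables`
#'   (sorted), `edges` (data frame `x`, `y`, `mi`, `p_max`), `alpha`,
#'   `alpha_effective`, `n_tests`, `removed` (data frame with separating
#'   sets).
#' @export
learn_skeleton <- function(cohort, alpha = 0.05, max_cond = 2, seed = 1L,
                           correction = c("none", "bonferroni"),
                           n_perm = 9999, variables = NULL) {
  stopifnot(inherits(cohort, "cohort"), alpha > 0, alpha < 1, max_cond >= 0)
  correction <- match.arg(correction)
  enc <- encode_cohort(cohort, variables)
  vars <- enc$variables
  p <- length(vars)
  if (p < 2L) stop("at least two variables are required", call. = FALSE)
  if (max_cond > p - 2L) {
    warning("max_cond clamped to ", p - 2L)
    max_cond <- p - 2L
  }
  npairs <- p * (p - 1L) / 2L
  alpha_eff <- if (correction == "bonferroni") alpha / npairs else alpha
  ## permutation resolution scaled to the decision threshold: beyond
  ## ~50/alpha_eff permutations the accept/reject decision at alpha_eff
  ## gains no further resolution
  n_perm_use <- max(199, min(n_perm, ceiling(50 / alpha_eff)))
  adj <- matrix(TRUE, p, p, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  mi0 <- matrix(NA_real_, p, p)
  pmax_ <- matrix(-Inf, p, p)
  removed <- list()
  n_tests <- 0L
  for (s in 0:max_cond) {
    adj_frozen <- adj
    for (i in seq_len(p - 1L)) {
      for (j in seq.int(i + 1L, p)) {
        if (!adj[i, j]) next
        common <- setdiff(which(adj_frozen[i, ] & adj_frozen[j, ]),
                          c(i, j))
        if (s == 0L) {
          subsets <- list(integer(0))
        } else {
          if (length(common) < s) next
          ## combn(n, k) on a scalar n would enumerate seq_len(n)
          subsets <- if (length(common) == s) list(common) else
            utils::combn(common, s, simplify = FALSE)
        }
        for (S in subsets) {
          res <- ci_test_codes(enc, i, j, S, n_perm_use,
                               test_seed(seed, vars[i], vars[j], vars[S]),
                               alpha_stop = alpha_eff)
          n_tests <- n_tests + 1L
          if (s == 0L) mi0[i, j] <- res$mi
          pmax_[i, j] <- max(pmax_[i, j], res$p)
          if (res$p > alpha_eff) {
            adj[i, j] <- adj[j, i] <- FALSE
            removed[[length(removed) + 1L]] <- data.frame(
              x = vars[i], y = vars[j], size = s,
              sepset = paste(vars[S], collapse = ","),
              p = res$p, stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
  }
  keep <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(
    x = vars[keep[, 1L]], y = vars[keep[, 2L]],
    mi = mi0[keep], p_max = pmax_[keep],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$x, edges$y), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(variables = vars, edges = edges, alpha = alpha,
                 alpha_effective = alpha_eff, correction = correction,
                 max_cond = max_cond, n_tests = n_tests,
                 removed = if (length(removed)) do.call(rbind, removed)
                           else NULL),
            class = "ci_skeleton")
}

#' @export
print.ci_skeleton <- function(x, ...) {
  cat(sprintf(
    "CI skeleton: %d variables, %d edges (alpha = %g%s, %d tests)\n",
    length(x$variables), nrow(x$edges), x$alpha,
    if (x$correction != "none") paste0(", ", x$correction), x$n_tests))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -- %s (MI %.3f, max p %.3g)\n",
                  x$edges$x[i], x$edges$y[i], x$edges$mi[i],
                  x$edges$p_max[i]))
  invisible(x)
}
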