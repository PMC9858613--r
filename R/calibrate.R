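## Analytic MI (bits) of a 2x2 joint with cells p11, p10, p01, p00.
mi_of_joint <- function(p11, px, py) {
  p10 <- px - p11
  p01 <- py - p11
  p00 <- 1 - px - py + p11
  cells <- c(p11, p10, p01, p00)
  marg <- c(px * py, px * (1 - py), (1 - px) * py, (1 - px) * (1 - py))
  nz <- cells > 0
  sum(cells[nz] * log2(cells[nz] / marg[nz]))
}

#' Calibrate a 2x2 joint distribution to a target mutual information
#'
#' A 2x2 joint with fixed margins has a single free parameter, `p11`, which
#' runs from `max(0, px + py - 1)` to `min(px, py)`; MI is zero at
#' independence (`p11 = px * py`) and increases monotonically towards each
#' boundary. The joint attaining the target MI is found by monotone
#' root-finding in `p11` on the requested side of independence.
#'
#' @param target_mi Target mutual information in bits (non-negative).
#' @param marginal_x,marginal_y Marginal success probabilities, in (0, 1).
#' @param association `"positive"` (default) or `"negative"`: the side of
#'   independence on which to solve.
#' @param tol Absolute tolerance on the achieved MI (default `1e-9` bits).
#' @return A list of class `"pairwise_joint"` with cells `p11`, `p10`,
#'   `p01`, `p00` (non-negative, summing to 1), the margins, and
#'   `achieved_mi`. The achieved MI is within `tol` of the target.
#'   If the target exceeds the marginal-constrained maximum an error states
#'   that maximum.
#' @export
#' @examples
#' calibrate_pairwise_joint(0.12, 0.3, 0.15)
calibrate_pairwise_joint <- function(target_mi, marginal_x, marginal_y,
                                     association = c("positive", "negative"),
                                     tol = 1e-9) {
  association <- match.arg(association)
  px <- marginal_x
  py <- marginal_y
  if (!(px > 0 && px < 1 && py > 0 && py < 1))
    stop("marginals must lie strictly in (0, 1)", call. = FALSE)
  if (target_mi < 0) stop("target_mi must be non-negative", call. = FALSE)
  lo <- max(0, px + py - 1)
  hi <- min(px, py)
  p0 <- px * py
  bound <- if (association == "positive") hi else lo
  max_mi <- mi_of_joint(bound, px, py)
  if (target_mi > max_mi + 1e-12)
    stop(sprintf(
      "target MI %.6f bits exceeds the maximum %.6f attainable with margins (%.4g, %.4g)",
      target_mi, max_mi, px, py), call. = FALSE)
  if (target_mi == 0) {
    p11 <- p0
  } else if (abs(target_mi - max_mi) <= 1e-12) {
    p11 <- bound
  } else {
    f <- function(p) mi_of_joint(p, px, py) - target_mi
    iv <- if (association == "positive") c(p0, bound) else c(bound, p0)
    p11 <- stats::uniroot(f, interval = iv, tol = 1e-14)$root
  }
  out <- list(p11 = p11, p10 = px - p11, p01 = py - p11,
              p00 = 1 - px - py + p11,
              marginal_x = px, marginal_y = py,
              achieved_mi = mi_of_joint(p11, px, py))
  if (abs(out$achieved_mi - target_mi) > max(tol, 1e-6))
    stop("root-finding failed to reach the target MI", call. = FALSE)
  class(out) <- "pairwise_joint"
  out
}

#' @export
print.pairwise_joint <- function(x, ...) {
  cat(sprintf(
    "2x2 joint: p11 = %.5f, p10 = %.5f, p01 = %.5f, p00 = %.5f (MI = %.5f bits)\n",
    x$p11, x$p10, x$p01, x$p00, x$achieved_mi))
  invisible(x)
}

## Conditional table P(child | parent) implied by a calibrated 2x2 joint,
## rows = parent level (0 then 1), cols = child level (0 then 1).
joint_to_conditional <- function(j) {
  rbind(
    c(j$p00, j$p01) / (1 - j$marginal_x),
    c(j$p10, j$p11) / j$marginal_x
  )
}

## MI (bits) between parent and child for parent marginal w (vector) and
## conditional stochastic matrix M (rows = parent levels).
mi_parent_child <- function(w, M) {
  joint <- M * w
  mi_from_counts(joint)  # scale-invariant: works on probabilities too
}

#' Calibrate a conditional stochastic matrix to a target mutual information
#'
#' For a categorical child given a categorical parent, the 2x2 root-finding
#' shortcut does not apply. Instead the conditional table is moved along a
#' fixed direction away from independence: `P_t(child | parent = k) =
#' m + t * D_k`, where `m` is the child marginal and the direction matrix
#' `D` has zero row sums and zero parent-weighted column sums, so every
#' `P_t` is a proper stochastic matrix with the child marginal preserved
#' exactly for all `t`. MI is continuous and increasing in `t` on the
#' feasible range, and the target is met by root-finding in `t`.
#'
#' @param target_mi Target MI in bits.
#' @param parent_marginal Probability vector over parent levels.
#' @param child_marginal Probability vector over child levels.
#' @param direction Numeric matrix (parent levels x child levels) giving the
#'   tilt applied to each parent level's conditional; it is projected to
#'   have zero row sums and zero parent-weighted column means before use.
#' @return A list with `matrix` (rows = parent levels: `P(child | parent)`),
#'   `t` (the scale used), and `achieved_mi` (within `1e-9` bits of target).
#' @export
calibrate_conditional_matrix <- function(target_mi, parent_marginal,
                                         child_marginal, direction) {
  w <- parent_marginal
  m <- child_marginal
  D <- as.matrix(direction)
  stopifnot(length(w) == nrow(D), length(m) == ncol(D),
            abs(sum(w) - 1) < 1e-9, abs(sum(m) - 1) < 1e-9)
  D <- D - rowMeans(D)                      # zero row sums
  D <- sweep(D, 2L, colSums(D * w))         # zero weighted column means
  if (max(abs(D)) < 1e-12)
    stop("direction matrix is degenerate after projection", call. = FALSE)
  base <- matrix(m, nrow = length(w), ncol = length(m), byrow = TRUE)
  ## largest t keeping all probabilities non-negative
  neg <- D < 0
  t_max <- min(base[neg] / -D[neg])
  f <- function(t) mi_parent_child(w, base + t * D) - target_mi
  max_mi <- f(t_max) + target_mi
  if (target_mi > max_mi + 1e-12)
    stop(sprintf(
      "target MI %.4f bits exceeds the maximum %.4f reachable along this direction",
      target_mi, max_mi), call. = FALSE)
  t <- if (target_mi == 0) 0 else
    stats::uniroot(f, interval = c(0, t_max), tol = 1e-14)$root
  M <- base + t * D
  achieved <- mi_parent_child(w, M)
  if (abs(achieved - target_mi) > 1e-9)
    stop("root-finding failed to reach the target MI", call. = FALSE)
  rownames(M) <- names(w)
  list(matrix = M, t = t, achieved_mi = achieved)
}

#' Fit a binary CPT with several parents to pairwise MI targets
#'
#' For a binary child with two or more (binary) parents, the conditional
#' probability table is fitted so the child's marginal and its pairwise MI
#' with every parent hit given targets simultaneously. The parents' exact
#' joint distribution must be supplied; fitting is deterministic BFGS on the
#' logits of `P(child = 1 | parent configuration)`, and the fit is rejected
#' unless all residuals are below `tol`.
#'
#' @param parent_configs Integer/0-1 matrix, one row per parent
#'   configuration, one column per parent (columns named).
#' @param parent_probs Probability of each configuration (sums to 1).
#' @param mi_targets Named numeric vector: target MI (bits) with each
#'   parent.
#' @param child_marginal Target `P(child = 1)`.
#' @param tol Maximum absolute residual accepted (default `1e-6`).
#' @return Numeric vector `P(child = 1 | configuration)`, one per row of
#'   `parent_configs`.
#' @export
fit_binary_cpt <- function(parent_configs, parent_probs, mi_targets,
                           child_marginal, tol = 1e-6) {
  parent_configs <- as.matrix(parent_configs)
  stopifnot(nrow(parent_configs) == length(parent_probs),
            all(names(mi_targets) %in% colnames(parent_configs)))
  q <- parent_probs / sum(parent_probs)
  resid <- function(theta) {
    pc <- stats::plogis(theta)
    marg <- sum(q * pc)
    r <- marg - child_marginal
    for (pa in names(mi_targets)) {
      on <- parent_configs[, pa] == 1
      joint <- rbind(
        c(sum(q[!on] * (1 - pc[!on])), sum(q[!on] * pc[!on])),
        c(sum(q[on] * (1 - pc[on])), sum(q[on] * pc[on]))
      )
      r <- c(r, mi_from_counts(joint) - mi_targets[[pa]])
    }
    r
  }
  obj <- function(theta) sum(resid(theta)^2)
  ## positive-association start: child raised with each parent present
  theta0 <- stats::qlogis(child_marginal) +
    1.5 * (rowSums(parent_configs) - mean(rowSums(parent_configs)))
  fit <- stats::optim(theta0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  if (max(abs(resid(fit$par))) > tol)
    stop("CPT fit did not reach the MI/marginal targets (max residual ",
         signif(max(abs(resid(fit$par))), 3), ")", call. = FALSE)
  stats::plogis(fit$par)
}
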