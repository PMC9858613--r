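#' Orientation asymmetry scores for a skeleton edge
#'
#' For each direction, the score is the largest total-variation distance
#' between the conditional distributions of the putative child across any
#' two observed levels of the putative parent:
#' `score(x -> y) = max_{a,b} TV( P(y | x = a), P(y | x = b) )`.
#' The edge points towards the variable whose distribution is more strongly
#' shifted, i.e. `x -> y` when `score(x -> y) > score(y -> x)`. Parent
#' levels with zero counts are skipped; if fewer than two levels remain in
#' either direction the corresponding score is `NA` and the edge is left
#' unoriented.
#'
#' @param cohort A [cohort()].
#' @param x,y Variable names of a skeleton edge.
#' @return Named numeric vector `c(forward =, reverse = )` for
#'   `x -> y` and `y -> x`.
#' @export
orientation_scores <- function(cohort, x, y) {
  m <- as_count_matrix(crosstab(cohort, x, y))
  tv_score <- function(cnt) {
    ## rows = putative parent levels, cols = child levels
    keep <- rowSums(cnt) > 0
    if (sum(keep) < 2L) return(NA_real_)
    pr <- cnt[keep, , drop = FALSE] / rowSums(cnt[keep, , drop = FALSE])
    best <- 0
    for (a in seq_len(nrow(pr) - 1L))
      for (b in seq.int(a + 1L, nrow(pr)))
        best <- max(best, 0.5 * sum(abs(pr[a, ] - pr[b, ])))
    best
  }
  c(forward = tv_score(m), reverse = tv_score(t(m)))
}

would_close_cycle <- function(adj, src, tgt) {
  ## is src reachable from tgt along oriented edges?
  stack <- tgt
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == src) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, adj[[v]])
  }
  FALSE
}

#' Orient a skeleton and enforce acyclicity
#'
#' Edges are processed in decreasing mutual information (ties broken
#' lexicographically by endpoint names). Each edge takes its preferred
#' direction from the asymmetry scores (ties: lexicographically smaller
#' endpoint becomes the source). An edge whose preferred direction would
#' close a directed cycle is reversed; if both directions close cycles it
#' is retained unoriented and flagged. The oriented subgraph of the result
#' is always acyclic.
#'
#' @param skeleton A `"ci_skeleton"` from [learn_skeleton()].
#' @param scores Data frame aligned with `skeleton$edges`, columns
#'   `forward` and `reverse` (from [orientation_scores()]).
#' @param provenance Optional list stored on the map (parameters, seed).
#' @return An object of class `"cimap"`: list with `variables`, `edges`
#'   (data frame `source`, `target`, `mi`, `p`, `oriented`,
#'   `score_forward`, `score_reverse`), `alpha`, `provenance`.
#' @export
orient_and_acyclify <- function(skeleton, scores, provenance = list()) {
  stopifnot(inherits(skeleton, "ci_skeleton"))
  ed <- skeleton$edges
  stopifnot(nrow(ed) == nrow(scores))
  ord <- order(-ed$mi, ed$x, ed$y)
  adj <- stats::setNames(vector("list", length(skeleton$variables)),
                         skeleton$variables)
  out <- vector("list", nrow(ed))
  for (k in ord) {
    x <- ed$x[k]; y <- ed$y[k]
    sf <- scores$forward[k]; sr <- scores$reverse[k]
    if (is.na(sf) || is.na(sr)) {
      out[[k]] <- data.frame(source = x, target = y, mi = ed$mi[k],
                             p = ed$p_max[k], oriented = FALSE,
                             score_forward = sf, score_reverse = sr,
                             stringsAsFactors = FALSE)
      next
    }
    prefer_forward <- if (sf == sr) TRUE else sf > sr  # tie: lexicographic
    src <- if (prefer_forward) x else y
    tgt <- if (prefer_forward) y else x
    if (would_close_cycle(adj, src, tgt)) {
      if (would_close_cycle(adj, tgt, src)) {
        out[[k]] <- data.frame(source = x, target = y, mi = ed$mi[k],
                               p = ed$p_max[k], oriented = FALSE,
                               score_forward = sf, score_reverse = sr,
                               stringsAsFactors = FALSE)
        next
      }
      tmp <- src; src <- tgt; tgt <- tmp
    }
    adj[[src]] <- c(adj[[src]], tgt)
    out[[k]] <- data.frame(source = src, target = tgt, mi = ed$mi[k],
                           p = ed$p_max[k], oriented = TRUE,
                           score_forward = sf, score_reverse = sr,
                           stringsAsFactors = FALSE)
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(source = character(0), target = character(0),
               mi = numeric(0), p = numeric(0), oriented = logical(0),
               score_forward = numeric(0), score_reverse = numeric(0))
  rownames(edges) <- NULL
  structure(list(variables = skeleton$variables, edges = edges,
                 alpha = skeleton$alpha, provenance = provenance),
            class = "cimap")
}

#' Build a conditional independence map from a cohort
#'
#' The full pipeline: [learn_skeleton()] (significance-pruned stable
#' skeleton), [orientation_scores()] for every surviving edge, then
#' [orient_and_acyclify()]. The run's parameters and seed are recorded in
#' the map's provenance.
#'
#' @inheritParams learn_skeleton
#' @return A `"cimap"`; see [orient_and_acyclify()].
#' @export
build_cimap <- function(cohort, alpha = 0.05, max_cond = 2, seed = 1L,
                        correction = c("none", "bonferroni"),
                        n_perm = 9999, variables = NULL) {
  correction <- match.arg(correction)
  if (length(if (is.null(variables)) names(cohort$data) else variables)
      < 2L) {
    return(structure(list(
      variables = sort(if (is.null(variables)) names(cohort$data)
                       else variables),
      edges = data.frame(source = character(0), target = character(0),
                         mi = numeric(0), p = numeric(0),
                         oriented = logical(0),
                         score_forward = numeric(0),
                         score_reverse = numeric(0)),
      alpha = alpha,
      provenance = list(alpha = alpha, max_cond = max_cond, seed = seed,
                        correction = correction, n = cohort$n)),
      class = "cimap"))
  }
  sk <- learn_skeleton(cohort, alpha = alpha, max_cond = max_cond,
                       seed = seed, correction = correction,
                       n_perm = n_perm, variables = variables)
  sc <- if (nrow(sk$edges)) {
    do.call(rbind, lapply(seq_len(nrow(sk$edges)), function(i) {
      s <- orientation_scores(cohort, sk$edges$x[i], sk$edges$y[i])
      data.frame(forward = s[["forward"]], reverse = s[["reverse"]])
    }))
  } else {
    data.frame(forward = numeric(0), reverse = numeric(0))
  }
  orient_and_acyclify(sk, sc, provenance = list(
    alpha = alpha, max_cond = max_cond, seed = seed,
    correction = correction, n_perm = n_perm, n = cohort$n,
    rng = "Mersenne-Twister",
    package_version = as.character(utils::packageVersion("cimap"))))
}

#' @export
print.cimap <- function(x, ...) {
  cat(sprintf("CI-Map: %d variables, %d edges (alpha = %g)\n",
              length(x$variables), nrow(x$edges), x$alpha))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s %s %s (MI %.3f)\n", x$edges$source[i],
                  if (x$edges$oriented[i]) "->" else "--",
                  x$edges$target[i], x$edges$mi[i]))
  invisible(x)
}

cimap_igraph <- function(map, directed = TRUE) {
  ed <- map$edges
  igraph::graph_from_data_frame(
    data.frame(from = ed$source, to = ed$target, mi = ed$mi, p = ed$p,
               oriented = as.integer(ed$oriented), stringsAsFactors = FALSE),
    directed = directed, vertices = map$variables)
}

#' Connected components (variable clusters) of a CI-Map
#'
#' Components of the undirected view of the map, ordered by size
#' (descending, ties by first variable name). In the emulated analysis
#' these correspond to the person-centred, household-risk, parental-risk
#' and sex/means/risk clusters.
#'
#' @param map A `"cimap"`.
#' @return List of character vectors of variable names.
#' @export
cimap_components <- function(map) {
  stopifnot(inherits(map, "cimap"))
  g <- cimap_igraph(map, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  groups[order(-vapply(groups, length, integer(1)),
               vapply(groups, `[`, character(1), 1L))]
}

#' Is the oriented part of a CI-Map acyclic?
#' @param map A `"cimap"`.
#' @return `TRUE`/`FALSE`.
#' @export
is_acyclic <- function(map) {
  stopifnot(inherits(map, "cimap"))
  ed <- map$edges[map$edges$oriented, , drop = FALSE]
  if (nrow(ed) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = map$variables)
  igraph::is_dag(g)
}

#' Export a CI-Map
#'
#' GraphML and DOT exports carry `mi`, `p` and `oriented` edge attributes;
#' the CSV export is the flat edge list.
#'
#' @param map A `"cimap"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cimap_graphml <- function(map, path) {
  igraph::write_graph(cimap_igraph(map), path, format = "graphml")
  invisible(path)
}

#' @rdname write_cimap_graphml
#' @export
write_cimap_dot <- function(map, path) {
  igraph::write_graph(cimap_igraph(map), path, format = "dot")
  invisible(path)
}

#' @rdname write_cimap_graphml
#' @export
write_cimap_edges <- function(map, path) {
  utils::write.csv(map$edges, path, row.names = FALSE)
  invisible(path)
}
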