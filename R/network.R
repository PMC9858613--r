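#' Conditional probability table
#'
#' A CPT gives the distribution of a child variable for every combination of
#' its parents' levels. Parent configurations are enumerated in
#' [expand.grid()] order (first parent varying fastest).
#'
#' @param child Child variable name.
#' @param child_levels Character vector of the child's levels.
#' @param parents Character vector of parent names (may be empty).
#' @param parent_levels Named list of level vectors, one per parent.
#' @param table Numeric matrix: one row per parent configuration, one column
#'   per child level; every row must sum to 1 (within 1e-12) with entries in
#'   [0, 1]. For a root variable, a single row (the marginal).
#' @return An object of class `"cpt"`.
#' @export
cpt <- function(child, child_levels, parents = character(0),
                parent_levels = list(), table) {
  table <- as.matrix(table)
  n_cfg <- prod(vapply(parent_levels, length, integer(1)))
  if (length(parents) == 0L) n_cfg <- 1L
  if (nrow(table) != n_cfg)
    stop("CPT for '", child, "' must have ", n_cfg,
         " rows (one per parent configuration)", call. = FALSE)
  if (ncol(table) != length(child_levels))
    stop("CPT for '", child, "' must have one column per child level",
         call. = FALSE)
  if (any(table < -1e-12) || any(table > 1 + 1e-12) ||
      any(abs(rowSums(table) - 1) > 1e-12))
    stop("CPT rows for '", child,
         "' must be probability vectors summing to 1", call. = FALSE)
  table[table < 0] <- 0
  structure(list(child = child, child_levels = child_levels,
                 parents = parents, parent_levels = parent_levels,
                 table = table),
            class = "cpt")
}

#' Ground-truth network for ancestral sampling
#'
#' A directed acyclic graph over the dictionary's variables together with
#' one CPT per variable (whose parents must equal the variable's in-edges),
#' used to simulate synthetic cohorts. Edges carry the target mutual
#' information they were calibrated to and a flag saying whether that value
#' was published or is a fixture invention.
#'
#' @param dictionary A [variable_dictionary()].
#' @param edges Data frame with columns `source`, `target`, `target_mi`,
#'   `published` (logical).
#' @param cpts Named list of [cpt()] objects, one per variable.
#' @return An object of class `"ground_truth_network"`.
#' @export
ground_truth_network <- function(dictionary, edges, cpts) {
  vars <- variable_names(dictionary)
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "target_mi") %in% names(edges)))
  if (!"published" %in% names(edges)) edges$published <- NA
  if (!all(c(edges$source, edges$target) %in% vars))
    stop("edge endpoints must be declared variables", call. = FALSE)
  if (!setequal(names(cpts), vars))
    stop("exactly one CPT per variable is required", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE, vertices = vars)
  if (!igraph::is_dag(g))
    stop("the edge set must be acyclic", call. = FALSE)
  for (v in vars) {
    expect <- sort(edges$source[edges$target == v])
    got <- sort(cpts[[v]]$parents)
    if (!identical(expect, got))
      stop("CPT parents for '", v, "' must equal its in-edges",
           call. = FALSE)
  }
  structure(list(dictionary = dictionary, edges = edges, cpts = cpts,
                 graph = g),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("Ground-truth network:", length(x$cpts), "variables,",
      nrow(x$edges), "edges\n")
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s (target MI %.2f bits%s)\n",
                x$edges$source[i], x$edges$target[i], x$edges$target_mi[i],
                if (isTRUE(x$edges$published[i])) "" else ", unpublished"))
  invisible(x)
}

#' Simulate a cohort by ancestral sampling
#'
#' Draws `n` records from the network: variables are sampled in a
#' topological order, each from its CPT row selected by its already-sampled
#' parents. Identical `(network, n, seed)` gives identical output
#' (Mersenne-Twister; the sampler draws one uniform per record per
#' variable, in topological order).
#'
#' @param network A [ground_truth_network()].
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @return A [cohort()] with the network's dictionary.
#' @export
simulate_cohort <- function(network, n, seed = 1L) {
  stopifnot(inherits(network, "ground_truth_network"), n >= 0)
  vars <- variable_names(network$dictionary)
  ord <- names(igraph::topo_sort(network$graph, mode = "out"))
  codes <- matrix(NA_integer_, nrow = n, ncol = length(vars),
                  dimnames = list(NULL, vars))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  for (v in ord) {
    ct <- network$cpts[[v]]
    L <- length(ct$child_levels)
    if (length(ct$parents) == 0L) {
      idx <- rep(1L, n)
    } else {
      idx <- rep(1L, n)
      mult <- 1L
      for (pa in ct$parents) {
        np <- length(ct$parent_levels[[pa]])
        idx <- idx + (codes[, pa] - 1L) * mult
        mult <- mult * np
      }
    }
    u <- stats::runif(n)
    cum <- t(apply(ct$table, 1L, cumsum))
    if (L == 1L) cum <- matrix(cum, ncol = 1L)
    code <- rep(1L, n)
    if (L > 1L && n > 0L)
      for (l in seq_len(L - 1L))
        code <- code + as.integer(u > cum[idx, l])
    codes[, v] <- code
  }
  df <- as.data.frame(lapply(vars, function(v)
    network$cpts[[v]]$child_levels[codes[, v]]),
    col.names = vars, stringsAsFactors = FALSE)
  if (n == 0L) {
    df <- as.data.frame(matrix(character(0), nrow = 0,
                               ncol = length(vars),
                               dimnames = list(NULL, vars)),
                        stringsAsFactors = FALSE)
  }
  cohort(df, network$dictionary)
}

#' Serialise / load a ground-truth network (YAML or JSON)
#'
#' The on-disk form lists the dictionary, the edges with target MI and
#' published flag, and every CPT's rows.
#'
#' @param network A [ground_truth_network()].
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_network()` returns a [ground_truth_network()].
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "ground_truth_network"))
  obj <- list(
    dictionary = dict_to_list(network$dictionary),
    edges = lapply(seq_len(nrow(network$edges)), function(i) list(
      source = network$edges$source[i],
      target = network$edges$target[i],
      target_mi = network$edges$target_mi[i],
      published = network$edges$published[i])),
    cpts = lapply(network$cpts, function(ct) list(
      child = ct$child,
      child_levels = as.list(ct$child_levels),
      parents = as.list(ct$parents),
      parent_levels = lapply(ct$parent_levels, as.list),
      table = apply(ct$table, 1L, as.list, simplify = FALSE)))
  )
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(obj, path),
    json = jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported network format: .", ext, call. = FALSE))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported network format: .", ext, call. = FALSE))
  dict <- list_to_dict(obj$dictionary)
  edges <- do.call(rbind, lapply(obj$edges, function(e)
    data.frame(source = e$source, target = e$target,
               target_mi = e$target_mi,
               published = isTRUE(e$published),
               stringsAsFactors = FALSE)))
  cpts <- lapply(obj$cpts, function(ct) {
    tab <- do.call(rbind, lapply(ct$table, function(r) unlist(r)))
    cpt(ct$child, as.character(unlist(ct$child_levels)),
        parents = as.character(unlist(ct$parents)),
        parent_levels = lapply(ct$parent_levels,
                               function(l) as.character(unlist(l))),
        table = tab)
  })
  names(cpts) <- vapply(cpts, `[[`, character(1), "child")
  ground_truth_network(dict, edges, cpts)
}
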