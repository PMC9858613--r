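test_that("a pairwise-independent cohort yields an (almost always) empty skeleton", {
  net <- independent_network(10)
  empty <- 0L
  for (s in 1:60) {
    co <- simulate_cohort(net, 2000, seed = s)
    sk <- learn_skeleton(co, alpha = 0.05, max_cond = 1, seed = s,
                         correction = "bonferroni")
    if (nrow(sk$edges) == 0L) empty <- empty + 1L
  }
  expect_gte(empty / 60, 0.90)
})

test_that("the skeleton recovers a three-variable chain exactly", {
  net <- chain_network(eps = 0.1)
  exact <- 0L
  for (s in 1:40) {
    co <- simulate_cohort(net, 5000, seed = s)
    sk <- learn_skeleton(co, alpha = 0.05, max_cond = 1, seed = s)
    key <- paste(sk$edges$x, sk$edges$y)
    if (identical(sort(key), c("x z", "y z"))) exact <- exact + 1L
  }
  expect_gte(exact / 40, 0.95)
})

test_that("conditioning on the mediator is accepted as independence", {
  # chain x -> z -> y: CMI(x, y | z) should not be rejected at alpha 0.05
  net <- chain_network(eps = 0.15)
  not_rejected <- 0L
  for (s in 1:200) {
    co <- simulate_cohort(net, 10000, seed = s)
    if (ci_test(co, "x", "y", given = "z")$p > 0.05)
      not_rejected <- not_rejected + 1L
  }
  expect_gte(not_rejected / 200, 0.92)
})

test_that("the skeleton is invariant under variable reordering", {
  net <- chain_network(eps = 0.1)
  co <- simulate_cohort(net, 3000, seed = 17)
  sk1 <- learn_skeleton(co, max_cond = 1, seed = 1)
  co_perm <- co
  co_perm$data <- co_perm$data[, c("z", "y", "x")]
  sk2 <- learn_skeleton(co_perm, max_cond = 1, seed = 1)
  expect_identical(sk1$edges, sk2$edges)
})

test_that("max_cond beyond the variable count is clamped with a warning", {
  co <- as_binary_cohort(x = rbinom(50, 1, 0.5), y = rbinom(50, 1, 0.5),
                         z = rbinom(50, 1, 0.5))
  expect_warning(learn_skeleton(co, max_cond = 10), "clamped")
})

test_that("orientation scores recover conditional-probability asymmetry", {
  # ground truth x -> y, P(y=1|x=0)=0.1, P(y=1|x=1)=0.9, P(x=1)=0.3
  lev <- c("0", "1")
  dict <- binary_dict(c("x", "y"))
  net <- ground_truth_network(
    dict,
    data.frame(source = "x", target = "y", target_mi = NA_real_,
               published = FALSE),
    list(x = cpt("x", lev, table = matrix(c(0.7, 0.3), 1)),
         y = cpt("y", lev, parents = "x", parent_levels = list(x = lev),
                 table = rbind(c(0.9, 0.1), c(0.1, 0.9)))))
  co <- simulate_cohort(net, 20000, seed = 2)
  sc <- orientation_scores(co, "x", "y")
  # forward TV = |0.9 - 0.1| = 0.8; reverse from Bayes inversion:
  # P(x=1|y=1) = 0.27/0.34, P(x=1|y=0) = 0.03/0.66
  rev_oracle <- abs(0.27 / 0.34 - 0.03 / 0.66)
  expect_lt(abs(sc[["forward"]] - 0.8), 0.03)
  expect_lt(abs(sc[["reverse"]] - rev_oracle), 0.03)
  expect_gt(sc[["forward"]], sc[["reverse"]])
})

test_that("deterministic copies tie and independent pairs score near zero", {
  x <- rbinom(5000, 1, 0.3)
  co <- as_binary_cohort(x = x, y = x)
  sc <- orientation_scores(co, "x", "y")
  expect_identical(sc[["forward"]], 1)
  expect_identical(sc[["reverse"]], 1)
  set.seed(12)
  co2 <- as_binary_cohort(x = rbinom(20000, 1, 0.5),
                          y = rbinom(20000, 1, 0.5))
  sc2 <- orientation_scores(co2, "x", "y")
  expect_lt(max(sc2), 0.05)
})

test_that("cycle resolution reverses the weakest conflicting edge", {
  sk <- structure(list(
    variables = c("A", "B", "C"),
    edges = data.frame(x = c("A", "A", "B"), y = c("B", "C", "C"),
                       mi = c(0.5, 0.1, 0.3),
                       p_max = c(1e-5, 1e-4, 1e-5),
                       stringsAsFactors = FALSE),
    alpha = 0.05), class = "ci_skeleton")
  # preferred directions A->B, B->C, C->A (a directed 3-cycle)
  scores <- data.frame(forward = c(0.9, 0.1, 0.9),
                       reverse = c(0.1, 0.9, 0.1))
  map <- orient_and_acyclify(sk, scores)
  expect_true(is_acyclic(map))
  weakest <- map$edges[map$edges$mi == 0.1, ]
  expect_identical(c(weakest$source, weakest$target), c("A", "C"))
  expect_true(all(map$edges$oriented))
  # single edge: oriented, trivially acyclic
  sk1 <- structure(list(variables = c("A", "B"),
                        edges = data.frame(x = "A", y = "B", mi = 0.2,
                                           p_max = 1e-4,
                                           stringsAsFactors = FALSE),
                        alpha = 0.05), class = "ci_skeleton")
  m1 <- orient_and_acyclify(sk1, data.frame(forward = 0.3, reverse = 0.1))
  expect_identical(nrow(m1$edges), 1L)
  expect_true(is_acyclic(m1))
})

test_that("every emitted map is acyclic over random cohorts", {
  for (s in 1:8) {
    set.seed(s)
    n <- 400
    x <- rbinom(n, 1, 0.5)
    df <- data.frame(a = x, b = rbinom(n, 1, 0.2 + 0.6 * x),
                     c = rbinom(n, 1, 0.5), d = rbinom(n, 1, 0.5))
    df$e <- rbinom(n, 1, 0.2 + 0.6 * df$b)
    co <- as_binary_cohort(a = df$a, b = df$b, c = df$c, d = df$d,
                           e = df$e)
    map <- build_cimap(co, seed = s)
    expect_true(is_acyclic(map))
  }
})

test_that("single-variable cohorts give an empty map; toy maps cluster", {
  co <- as_binary_cohort(x = c(0, 1, 0))
  map <- build_cimap(co)
  expect_identical(nrow(map$edges), 0L)
  expect_identical(cimap_components(map), list(`1` = "x"),
                   ignore_attr = TRUE)
  # fully connected toy map: one component; empty map: all singletons
  sk <- structure(list(variables = c("a", "b", "c"),
                       edges = data.frame(x = c("a", "a", "b"),
                                          y = c("b", "c", "c"),
                                          mi = c(0.3, 0.2, 0.1),
                                          p_max = rep(1e-4, 3),
                                          stringsAsFactors = FALSE),
                       alpha = 0.05), class = "ci_skeleton")
  full <- orient_and_acyclify(sk, data.frame(forward = rep(0.5, 3),
                                             reverse = rep(0.1, 3)))
  expect_identical(length(cimap_components(full)), 1L)
})

test_that("retained edges dominate size-0-pruned pairs in marginal MI", {
  net <- study_network()
  co <- simulate_cohort(net, 10000, seed = 3)
  sk <- learn_skeleton(co, correction = "bonferroni")
  enc_binary <- function(v) length(get_spec(co$dictionary, v)$levels) == 2
  ret <- sk$edges[vapply(sk$edges$x, enc_binary, TRUE) &
                    vapply(sk$edges$y, enc_binary, TRUE), ]
  pruned0 <- sk$removed[sk$removed$size == 0 &
                          vapply(sk$removed$x, enc_binary, TRUE) &
                          vapply(sk$removed$y, enc_binary, TRUE), ]
  mi_pruned <- mapply(function(a, b)
    mutual_information(crosstab(co, a, b)), pruned0$x, pruned0$y)
  expect_gt(min(ret$mi), max(mi_pruned))
})

test_that("the full pipeline recovers the study network from samples", {
  net <- study_network()
  truth <- net$edges
  tkey <- paste(pmin(truth$source, truth$target),
                pmax(truth$source, truth$target))
  co <- simulate_cohort(net, 10000, seed = 1)
  map <- build_cimap(co, alpha = 0.05, max_cond = 2, seed = 1,
                     correction = "bonferroni")
  expect_true(is_acyclic(map))
  mkey <- paste(pmin(map$edges$source, map$edges$target),
                pmax(map$edges$source, map$edges$target))
  expect_setequal(mkey, tkey)
  # recovered MI close to the calibrated targets
  m <- merge(data.frame(k = tkey, target = truth$target_mi),
             data.frame(k = mkey, mi = map$edges$mi))
  expect_lt(max(abs(m$mi - m$target)), 0.03)
  # the four thematic clusters emerge as separate components
  comp <- cimap_components(map)
  sizes <- vapply(comp, length, integer(1))
  expect_identical(unname(sizes[1:4]), c(8L, 7L, 3L, 3L))
  person <- comp[[2]]
  expect_true(all(c("known_camhs", "asd_traits", "anxiety", "low_mood",
                    "previous_attendance", "history_dsh") %in% person))
  expect_true(any(vapply(comp, function(g) identical(g, "sen"), TRUE)))
})

test_that("map exports carry the edge attributes", {
  net <- chain_network(eps = 0.1)
  co <- simulate_cohort(net, 3000, seed = 21)
  map <- build_cimap(co, max_cond = 1, seed = 21)
  fg <- withr::local_tempfile(fileext = ".graphml")
  fd <- withr::local_tempfile(fileext = ".dot")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_cimap_graphml(map, fg)
  write_cimap_dot(map, fd)
  write_cimap_edges(map, fc)
  expect_true(any(grepl("mi", readLines(fg))))
  expect_true(file.size(fd) > 0)
  back <- utils::read.csv(fc)
  expect_identical(nrow(back), nrow(map$edges))
  g <- igraph::read_graph(fg, format = "graphml")
  expect_identical(sort(igraph::V(g)$name), map$variables)
})
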