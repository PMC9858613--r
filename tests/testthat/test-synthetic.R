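test_that("pairwise calibration hits trivial and boundary targets", {
  j0 <- calibrate_pairwise_joint(0, 0.5, 0.5)
  expect_equal(j0$p11, 0.25, tolerance = 1e-12)
  j1 <- calibrate_pairwise_joint(1.0, 0.5, 0.5)
  expect_equal(c(j1$p11, j1$p00), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(c(j1$p10, j1$p01), c(0, 0), tolerance = 1e-9)
  expect_error(calibrate_pairwise_joint(0.9, 0.15, 0.15), "maximum")
})

test_that("calibrated 2x2 joints agree with the grid-scan oracle", {
  j <- calibrate_pairwise_joint(0.80, 0.3, 0.3)
  expect_equal(j$achieved_mi, 0.80, tolerance = 1e-6)
  expect_equal(oracle_mi_bits(rbind(c(j$p00, j$p01), c(j$p10, j$p11))),
               0.80, tolerance = 1e-6)
  p11_oracle <- oracle_calibrated_p11(0.80, 0.3, 0.3)
  expect_equal(j$p11, p11_oracle, tolerance = 2e-6)
})

test_that("calibration round trip is the identity across a grid", {
  for (px in c(0.2, 0.5, 0.64)) {
    for (py in c(0.15, 0.3, 0.67)) {
      max_mi <- oracle_mi_bits(rbind(c(1 - max(px, py), max(px, py) - min(px, py)),
                                     c(0, min(px, py))))
      for (f in c(0.1, 0.5, 0.9)) {
        target <- f * max_mi
        j <- calibrate_pairwise_joint(target, px, py)
        expect_equal(j$achieved_mi, target, tolerance = 1e-6)
        expect_equal(j$p11 + j$p10, px, tolerance = 1e-12)
        expect_equal(j$p11 + j$p01, py, tolerance = 1e-12)
        expect_gte(min(j$p11, j$p10, j$p01, j$p00), 0)
      }
    }
  }
})

test_that("categorical calibration preserves both marginals exactly", {
  w <- c(1 / 3, 2 / 3)
  m <- c(0.65, 0.17, 0.10, 0.03, 0.05)
  D <- rbind(c(0.1, -0.06, -0.03, -0.005, -0.005),
             c(-0.1, 0.06, 0.03, 0.005, 0.005))
  cal <- calibrate_conditional_matrix(0.05, w, m, D)
  expect_equal(cal$achieved_mi, 0.05, tolerance = 1e-9)
  expect_equal(rowSums(cal$matrix), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colSums(cal$matrix * w), m, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_gte(min(cal$matrix), 0)
})

test_that("multi-parent CPT fitting matches all pairwise MI targets", {
  cfg <- as.matrix(expand.grid(a = 0:1, b = 0:1))
  # independent parents, p = 0.3 each
  q <- c(0.49, 0.21, 0.21, 0.09)
  pc <- fit_binary_cpt(cfg, q, c(a = 0.06, b = 0.04), 0.25)
  marg <- sum(q * pc)
  expect_equal(marg, 0.25, tolerance = 1e-6)
  for (pa in c("a", "b")) {
    on <- cfg[, pa] == 1
    joint <- rbind(c(sum(q[!on] * (1 - pc[!on])), sum(q[!on] * pc[!on])),
                   c(sum(q[on] * (1 - pc[on])), sum(q[on] * pc[on])))
    expect_equal(oracle_mi_bits(joint), c(a = 0.06, b = 0.04)[[pa]],
                 tolerance = 1e-6)
  }
})

test_that("ancestral sampling is deterministic and honours degenerate CPTs", {
  net <- chain_network(eps = 0)   # deterministic copy down the chain
  co <- simulate_cohort(net, 1000, seed = 3)
  expect_identical(co$data$x, co$data$z)
  expect_identical(co$data$z, co$data$y)
  expect_identical(simulate_cohort(net, 50, seed = 9)$data,
                   simulate_cohort(net, 50, seed = 9)$data)
  expect_false(identical(simulate_cohort(net, 50, seed = 9)$data,
                         simulate_cohort(net, 50, seed = 10)$data))
  expect_identical(simulate_cohort(net, 0, seed = 1)$n, 0L)
})

test_that("fixed seed gives byte-identical emitted CSV", {
  net <- study_network()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(net, 500, seed = 11), f1)
  write_cohort(simulate_cohort(net, 500, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the study network encodes the published structure", {
  net <- study_network()
  key <- paste(net$edges$source, net$edges$target)
  expect_true("neglect domestic_violence" %in% key)
  expect_identical(
    net$edges$target_mi[net$edges$source == "neglect" &
                          net$edges$target == "domestic_violence"], 0.80)
  # no SEN / mental-health edges: SEN is isolated
  expect_false(any(net$edges$source == "sen" | net$edges$target == "sen"))
  expect_true(igraph::is_dag(net$graph))
  # one CPT per variable, rows normalised
  for (ct in net$cpts)
    expect_equal(rowSums(ct$table), rep(1, nrow(ct$table)),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simulated marginals match their CPT values (binomial oracle)", {
  net <- study_network()
  co <- simulate_cohort(net, 50000, seed = 1)
  p <- 160 / 240
  se <- sqrt(p * (1 - p) / co$n)
  expect_lt(abs(mean(co$data$sex == "female") - p), 3 * se)
  p2 <- 154 / 240
  se2 <- sqrt(p2 * (1 - p2) / co$n)
  expect_lt(abs(mean(co$data$known_camhs == "1") - p2), 3 * se2)
})

test_that("plug-in MI on calibrated edges converges to the targets", {
  net <- study_network()
  co <- simulate_cohort(net, 100000, seed = 2)
  for (i in seq_len(nrow(net$edges))) {
    mi <- mutual_information(
      crosstab(co, net$edges$source[i], net$edges$target[i]))
    expect_lt(abs(mi - net$edges$target_mi[i]), 0.02)
  }
})

test_that("network YAML serialisation round-trips and resimulates identically", {
  net <- chain_network(eps = 0.2, p_root = 0.3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, f)
  back <- read_network(f)
  expect_identical(back$edges$source, net$edges$source)
  expect_equal(back$cpts$z$table, net$cpts$z$table, tolerance = 1e-12)
  expect_identical(simulate_cohort(back, 200, seed = 5)$data,
                   simulate_cohort(net, 200, seed = 5)$data)
})
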