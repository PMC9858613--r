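test_that("crosstab counts by direct enumeration and reports exclusions", {
  co <- as_binary_cohort(x = c(0, 0, 1, 1), y = c(0, 1, 1, 1))
  ct <- crosstab(co, "x", "y")
  expect_identical(as.integer(unclass(ct)), c(1L, 0L, 1L, 2L))
  expect_identical(attr(ct, "N"), 4L)
  co$data$y[1] <- NA
  ct2 <- crosstab(co, "x", "y")
  expect_identical(attr(ct2, "n_excluded"), 1L)
  expect_identical(attr(ct2, "N"), 3L)
  expect_error(crosstab(co, "x", "x"), "different")
  co$data$y <- NA_character_
  expect_error(crosstab(co, "x", "y"), class = "cimap_empty_table")
})

test_that("mutual information matches hand values and the summation oracle", {
  expect_equal(mutual_information(matrix(c(50, 50, 50, 50), 2)), 0)
  expect_equal(mutual_information(matrix(c(60, 0, 0, 60), 2)), 1.0)
  m <- matrix(c(40, 10, 10, 40), 2)
  expect_equal(mutual_information(m), oracle_mi_bits(m), tolerance = 1e-12)
  expect_equal(mutual_information(m), 0.278, tolerance = 1e-3)
  expect_error(mutual_information(matrix(0, 2, 2)), "N = 0")
})

test_that("MI is symmetric and bounded by the marginal entropies", {
  set.seed(42)
  for (i in 1:50) {
    r <- sample(2:4, 1)
    s <- sample(2:4, 1)
    m <- matrix(rpois(r * s, 5), r, s)
    if (sum(m) == 0) next
    mi <- mutual_information(m)
    expect_identical(mi, mutual_information(t(m)))
    p <- m / sum(m)
    hx <- -sum(ifelse(rowSums(p) > 0, rowSums(p) * log2(rowSums(p)), 0))
    hy <- -sum(ifelse(colSums(p) > 0, colSums(p) * log2(colSums(p)), 0))
    expect_lte(mi, min(hx, hy) + 1e-12)
    expect_gte(mi, 0)
  }
})

test_that("G equals 2 N ln2 MI and the direct O ln(O/E) sum", {
  m <- matrix(c(40, 10, 10, 40), 2)
  res <- g_test(m)
  expect_equal(res$g, 2 * 100 * log(2) * res$mi, tolerance = 1e-12)
  expect_equal(res$g, oracle_g_stat(m), tolerance = 1e-9)
  expect_equal(res$g, 38.5, tolerance = 0.1)
  expect_identical(res$df, 2L * 1L - 1L)  # (2-1)(2-1)
  expect_lt(res$p, 0.001)
  # independence: G = 0, p = 1
  ind <- outer(c(30, 70), c(40, 60)) / 100
  res0 <- g_test(ind)
  expect_equal(res0$g, 0, tolerance = 1e-6)
  expect_equal(res0$p, 1, tolerance = 1e-6)
  # closed-form df for wider tables
  expect_identical(g_test(matrix(5, 2, 3))$df, 2L)
  set.seed(99)
  for (i in 1:25) {
    m <- matrix(rpois(6, 20) + 1, 2, 3)
    res <- g_test(m)
    expect_equal(res$g, oracle_g_stat(m), tolerance = 1e-9 * max(1, res$g))
  }
})

test_that("conditional MI handles copies, self-conditioning and delegation", {
  set.seed(5)
  x <- rbinom(400, 1, 0.3)
  z <- rbinom(400, 1, 0.5)
  co <- as_binary_cohort(x = x, y = x, z = z)
  hx <- {
    p <- mean(x)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  # y a deterministic copy of x: CMI given unrelated z equals H(X) (plug-in,
  # up to stratum-wise estimation of the marginal entropy)
  expect_equal(conditional_mi(co, "x", "y", "z"),
               cmi <- sum(sapply(split(seq_along(x), z), function(i) {
                 length(i) / 400 * oracle_mi_bits(table(x[i], x[i]))
               })), tolerance = 1e-12)
  expect_equal(conditional_mi(co, "x", "y"), hx, tolerance = 1e-12)
  # conditioning on x itself annihilates the association
  expect_equal(conditional_mi(co, "x", "y", "x"), 0, tolerance = 1e-12)
  # empty conditioning set delegates to plain MI
  expect_identical(conditional_mi(co, "x", "y", character(0)),
                   mutual_information(crosstab(co, "x", "y")))
})

test_that("chi-square effect sizes match the textbook oracle", {
  d <- matrix(c(60, 0, 0, 60), 2, dimnames = list(c("0", "1"), c("0", "1")))
  expect_equal(chi_square_effect(d)$phi, 1)
  # sex x previous attendance from the descriptive fixture
  ct <- crosstab(reference_cohort(), "sex", "previous_attendance")
  res <- chi_square_effect(ct)
  m <- as.integer(unclass(ct))
  m <- matrix(m, 2)
  expect_equal(res$chi2, oracle_chi2(m), tolerance = 1e-9)
  expect_equal(res$phi, oracle_phi(m), tolerance = 1e-9)
  expect_identical(res$df, 1L)
  # cross-check against the standard uncorrected test
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  # product table: no association
  prod_tab <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(chi_square_effect(prod_tab)$chi2, 0, tolerance = 1e-9)
  # zero margin names the degenerate level
  z <- matrix(c(10, 0, 20, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(chi_square_effect(z), "b")
  # phi equals Cramer's V on 2x2; V used beyond
  r23 <- matrix(c(20, 5, 10, 30, 5, 20), 2, 3)
  expect_true(is.na(chi_square_effect(r23)$phi))
  expect_equal(chi_square_effect(r23)$cramers_v,
               sqrt(oracle_chi2(r23) / sum(r23)), tolerance = 1e-9)
})

test_that("oracle equivalence holds over random tables", {
  set.seed(2024)
  for (i in 1:200) {
    r <- sample(2:4, 1)
    s <- sample(2:4, 1)
    m <- matrix(rpois(r * s, 30) + 1, r, s)
    mi <- mutual_information(m)
    expect_equal(mi, oracle_mi_bits(m), tolerance = 1e-9 * max(1, mi))
    g <- g_test(m)$g
    expect_equal(g, oracle_g_stat(m), tolerance = 1e-9 * max(1, g))
    chi <- chi_square_effect(m)$chi2
    expect_equal(chi, oracle_chi2(m), tolerance = 1e-9 * max(1, chi))
  }
})

test_that("permutation p-values are deterministic and exact at the extreme", {
  x <- rep(c(0, 1), each = 30)
  co <- as_binary_cohort(x = x, y = x)
  res <- permutation_test(co, "x", "y", n_perm = 999, seed = 4)
  expect_equal(res$p, 1 / 1000)
  res2 <- permutation_test(co, "x", "y", n_perm = 999, seed = 4)
  expect_identical(res$p, res2$p)
  expect_error(permutation_test(co, "x", "y", n_perm = 10), "at least 99")
})

test_that("permutation and G-test p-values agree on dense 2x2 tables", {
  set.seed(31)
  for (i in 1:4) {
    x <- rbinom(500, 1, 0.5)
    y <- rbinom(500, 1, 0.35 + 0.2 * x)
    co <- as_binary_cohort(x = x, y = y)
    pg <- g_test(crosstab(co, "x", "y"))$p
    pp <- permutation_test(co, "x", "y", n_perm = 9999, seed = i)$p
    expect_lt(abs(pg - pp), 0.02)
  }
})

test_that("the permutation test is calibrated under independence", {
  rejections <- 0L
  for (s in 1:400) {
    set.seed(s)
    co <- as_binary_cohort(x = rbinom(100, 1, 0.5),
                           y = rbinom(100, 1, 0.5))
    p <- permutation_test(co, "x", "y", n_perm = 199, seed = s)$p
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 400, 0.03)
  expect_lte(rejections / 400, 0.07)
})

test_that("ci_test falls back to permutation only on sparse tables", {
  set.seed(8)
  co <- as_binary_cohort(x = rbinom(300, 1, 0.5), y = rbinom(300, 1, 0.5))
  expect_identical(ci_test(co, "x", "y")$method, "g-test")
  # sparse: tiny n with a rare level forces the fallback
  co2 <- as_binary_cohort(x = c(0, 0, 0, 0, 0, 0, 0, 1),
                          y = c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_identical(ci_test(co2, "x", "y", n_perm = 199)$method,
                   "permutation")
})
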