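# Independent brute-force oracles: direct term-by-term summation and grid
# scans, deliberately written without reusing any package internals.

oracle_mi_bits <- function(m) {
  N <- sum(m)
  mi <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        pxy <- m[i, j] / N
        px <- sum(m[i, ]) / N
        py <- sum(m[, j]) / N
        mi <- mi + pxy * log2(pxy / (px * py))
      }
    }
  }
  mi
}

oracle_g_stat <- function(m) {
  N <- sum(m)
  g <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        e <- sum(m[i, ]) * sum(m[, j]) / N
        g <- g + 2 * m[i, j] * log(m[i, j] / e)
      }
    }
  }
  g
}

oracle_chi2 <- function(m) {
  N <- sum(m)
  chi2 <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / N
      chi2 <- chi2 + (m[i, j] - e)^2 / e
    }
  }
  chi2
}

oracle_phi <- function(m) sqrt(oracle_chi2(m) / sum(m))

# Half-up percentage to 1 dp, the printed-table convention.
pct_half_up <- function(k, n) floor(1000 * k / n + 0.5) / 10

# Grid-scan oracle for the 2x2 calibration: best p11 at `step` resolution.
oracle_calibrated_p11 <- function(target_mi, px, py, step = 1e-6) {
  grid <- seq(px * py, min(px, py), by = step)
  mi <- vapply(grid, function(p11) {
    cells <- c(p11, px - p11, py - p11, 1 - px - py + p11)
    marg <- c(px * py, px * (1 - py), (1 - px) * py, (1 - px) * (1 - py))
    nz <- cells > 0
    sum(cells[nz] * log2(cells[nz] / marg[nz]))
  }, numeric(1))
  grid[which.min(abs(mi - target_mi))]
}

# Small binary helper dictionary / cohort builders used across tests.
binary_dict <- function(names) {
  variable_dictionary(lapply(names, function(nm)
    variable_spec(nm, "binary", c("0", "1"))))
}

as_binary_cohort <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df[] <- lapply(df, as.character)
  cohort(df, binary_dict(names(df)))
}

# Chain network x -> z -> y with symmetric flip noise; eps = P(child
# differs from parent).
chain_network <- function(eps = 0.1, p_root = 0.5) {
  dict <- binary_dict(c("x", "y", "z"))
  lev <- c("0", "1")
  flip <- rbind(c(1 - eps, eps), c(eps, 1 - eps))
  ground_truth_network(
    dict,
    data.frame(source = c("x", "z"), target = c("z", "y"),
               target_mi = NA_real_, published = FALSE),
    list(
      x = cpt("x", lev, table = matrix(c(1 - p_root, p_root), 1)),
      z = cpt("z", lev, parents = "x", parent_levels = list(x = lev),
              table = flip),
      y = cpt("y", lev, parents = "z", parent_levels = list(z = lev),
              table = flip)
    )
  )
}

# Fully independent binary network over k variables.
independent_network <- function(k, p = 0.4) {
  nms <- sprintf("v%02d", seq_len(k))
  dict <- binary_dict(nms)
  cpts <- lapply(nms, function(nm)
    cpt(nm, c("0", "1"), table = matrix(c(1 - p, p), 1)))
  names(cpts) <- nms
  ground_truth_network(
    dict,
    data.frame(source = character(0), target = character(0),
               target_mi = numeric(0), published = logical(0)),
    cpts)
}

# Printed descriptive-table cells asserted in tests: counts per level for
# the overall column and the previous-attender column.
printed_table1 <- function() {
  list(
    sex = list(levels = c("female", "male"),
               overall = c(160, 80), attended = c(45, 12)),
    ethnicity = list(levels = c("white_british", "other", "unknown"),
                     overall = c(222, 16, 2), attended = c(51, 5, 1)),
    mental_health = list(
      levels = c("anxiety", "anxiety_comorbidities", "anxiety_low_mood",
                 "low_mood", "low_mood_comorbidity", "other", "none"),
      overall = c(43, 10, 9, 40, 5, 35, 98),
      attended = c(10, 3, 4, 20, 3, 10, 7)),
    sen = list(
      levels = c("adhd", "adhd_other_ld", "asc", "asc_adhd", "asc_adhd_ld",
                 "asc_ld", "ld", "none"),
      overall = c(12, 3, 21, 12, 1, 3, 6, 182),
      attended = c(7, 0, 8, 5, 0, 0, 1, 36)),
    asc_traits = list(levels = c("yes", "no"),
                      overall = c(51, 189), attended = c(16, 41)),
    known_camhs = list(levels = c("yes", "no"),
                       overall = c(154, 86), attended = c(55, 2)),
    open_camhs = list(levels = c("yes", "no"),
                      overall = c(54, 186), attended = c(25, 32)),
    history_dsh = list(levels = c("yes", "no"),
                       overall = c(162, 78), attended = c(55, 2))
  )
}
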