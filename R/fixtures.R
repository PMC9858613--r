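## Prevalences used by the generator. Values with published = TRUE come from
## the printed descriptive table / results prose of the source cohort
## (n = 240); the rest are fixture defaults (0.15 unless noted, see the
## methods vignette).
study_marginals <- function() {
  list(
    known_camhs = 154 / 240,
    previous_attendance = 58 / 240,
    history_dsh = 162 / 240,
    asd_traits = 51 / 240,
    anxiety = 43 / 240,
    low_mood = 40 / 240,
    diagnosis_other = 35 / 240,
    sen = 58 / 240,
    female = 160 / 240,
    ## unprinted marginals: 0.15 default, except the household-abuse trio,
    ## which needs prevalence 0.30 so the strong published edge weights
    ## (0.80 and 0.72 bits) are attainable (max MI = H(prevalence))
    neglect = 0.30, abuse = 0.30, domestic_violence = 0.30,
    social_worker = 0.15, single_parent = 0.15, step_parent = 0.15,
    sep_loss_parent = 0.15, siblings = 0.15,
    parental_mental_health = 0.15, parent_drug_misuse = 0.15,
    parental_crime = 0.15,
    ## 83 / 240 presented with self-harm in addition to ideation; the
    ## means split across methods is a fixture choice (overdose commonest)
    means = c(none = 157, overdose = 41, cutting = 24, suffocation = 7,
              other = 11) / 240,
    risk = c(low = 0.5, medium = 0.3, high = 0.2)
  )
}

b01 <- c("0", "1")

#' Variable dictionary of the synthetic study network
#'
#' Binary ACE, demographic and clinical flags plus categorical
#' means-of-self-harm (5 levels), clinician risk band (3 levels) and
#' integer age 8-16, matching the variable set of the emulated
#' emergency-department cohort.
#'
#' @return A [variable_dictionary()].
#' @export
study_dictionary <- function() {
  vs <- variable_spec
  variable_dictionary(list(
    vs("sex", "binary", c("male", "female"), role = "demographic"),
    vs("age", "integer_bounded", as.character(8:16), role = "demographic"),
    vs("sen", "binary", b01, role = "demographic"),
    vs("asd_traits", "binary", b01, role = "clinical"),
    vs("anxiety", "binary", b01, role = "clinical"),
    vs("low_mood", "binary", b01, role = "clinical"),
    vs("diagnosis_other", "binary", b01, role = "clinical"),
    vs("known_camhs", "binary", b01, role = "clinical"),
    vs("previous_attendance", "binary", b01, role = "outcome"),
    vs("history_dsh", "binary", b01, role = "clinical"),
    vs("neglect", "binary", b01, role = "ACE"),
    vs("abuse", "binary", b01, role = "ACE"),
    vs("domestic_violence", "binary", b01, role = "ACE"),
    vs("social_worker", "binary", b01, role = "clinical"),
    vs("single_parent", "binary", b01, role = "demographic"),
    vs("step_parent", "binary", b01, role = "demographic"),
    vs("siblings", "binary", b01, role = "demographic"),
    vs("sep_loss_parent", "binary", b01, role = "ACE"),
    vs("parental_mental_health", "binary", b01, role = "ACE"),
    vs("parent_drug_misuse", "binary", b01, role = "ACE"),
    vs("parental_crime", "binary", b01, role = "ACE"),
    vs("means", "categorical",
       c("none", "overdose", "cutting", "suffocation", "other"),
       role = "clinical"),
    vs("risk", "categorical", c("low", "medium", "high"), role = "clinical")
  ))
}

## Single-parent binary CPT calibrated so MI(parent, child) = target_mi.
edge_cpt <- function(child, parent, target_mi, parent_marginal,
                     child_marginal) {
  j <- calibrate_pairwise_joint(target_mi, parent_marginal, child_marginal)
  cpt(child, b01, parents = parent,
      parent_levels = stats::setNames(list(b01), parent),
      table = joint_to_conditional(j))
}

root_cpt <- function(name, p1, levels = b01) {
  cpt(name, levels, table = matrix(c(1 - p1, p1), nrow = 1L))
}

#' Ground-truth network calibrated to the published CI-Map
#'
#' Encodes the four clusters reported for the emulated cohort of
#' emergency-department presentations in suicidal crisis:
#' (i) person-centred — a CAMHS hub linked to autistic traits (MI 0.03
#' bits), anxiety (0.10), low mood (0.09) and other diagnoses (0.06), with
#' previous ED attendance linked to history of deliberate self-harm (0.11),
#' CAMHS (0.13) and low mood (0.07); (ii) household risk — neglect linked
#' to social worker involvement (0.12), domestic violence (0.80) and abuse
#' (0.72), joined to family-structure variables; (iii) parental risk — a
#' triangle of parental mental ill health, drug misuse and criminality;
#' (iv) sex linked to means of self-harm (0.05) and means to clinician risk
#' band (0.24). Edge weights without a published value default to 0.15 bits
#' and are flagged `published = FALSE`. CPTs are solved with
#' [calibrate_pairwise_joint()], [calibrate_conditional_matrix()] and
#' [fit_binary_cpt()] so each listed edge attains its target MI exactly in
#' the generating distribution, with marginals matching published
#' prevalences where printed. SEN is included but isolated: the emulated
#' analysis found no association between SEN and the mental-health
#' variables.
#'
#' @return A [ground_truth_network()].
#' @export
study_network <- function() {
  m <- study_marginals()
  dict <- study_dictionary()
  edges <- function(src, tgt, mi, pub) {
    data.frame(source = src, target = tgt, target_mi = mi, published = pub,
               stringsAsFactors = FALSE)
  }
  ed <- rbind(
    edges("known_camhs", "asd_traits", 0.03, TRUE),
    edges("known_camhs", "anxiety", 0.10, TRUE),
    edges("known_camhs", "diagnosis_other", 0.06, TRUE),
    edges("known_camhs", "previous_attendance", 0.13, TRUE),
    edges("known_camhs", "low_mood", 0.09, TRUE),
    edges("previous_attendance", "low_mood", 0.07, TRUE),
    edges("previous_attendance", "history_dsh", 0.11, TRUE),
    edges("neglect", "domestic_violence", 0.80, TRUE),
    edges("neglect", "abuse", 0.72, TRUE),
    edges("neglect", "social_worker", 0.12, TRUE),
    edges("social_worker", "single_parent", 0.15, FALSE),
    edges("social_worker", "step_parent", 0.15, FALSE),
    edges("single_parent", "siblings", 0.15, FALSE),
    edges("single_parent", "sep_loss_parent", 0.15, FALSE),
    edges("parental_mental_health", "parent_drug_misuse", 0.15, FALSE),
    edges("parental_mental_health", "parental_crime", 0.15, FALSE),
    edges("parent_drug_misuse", "parental_crime", 0.15, FALSE),
    edges("sex", "means", 0.05, TRUE),
    edges("means", "risk", 0.24, TRUE)
  )

  cpts <- list()
  cpts$known_camhs <- root_cpt("known_camhs", m$known_camhs)
  cpts$neglect <- root_cpt("neglect", m$neglect)
  cpts$parental_mental_health <- root_cpt("parental_mental_health",
                                          m$parental_mental_health)
  cpts$sen <- root_cpt("sen", m$sen)
  cpts$sex <- cpt("sex", c("male", "female"),
                  table = matrix(c(1 - m$female, m$female), nrow = 1L))
  ## age: discretised truncated normal on 8..16, mean 13.5, sd 1.42
  aw <- stats::dnorm(8:16, mean = 13.5, sd = 1.42)
  cpts$age <- cpt("age", as.character(8:16),
                  table = matrix(aw / sum(aw), nrow = 1L))

  cpts$asd_traits <- edge_cpt("asd_traits", "known_camhs", 0.03,
                              m$known_camhs, m$asd_traits)
  cpts$anxiety <- edge_cpt("anxiety", "known_camhs", 0.10,
                           m$known_camhs, m$anxiety)
  cpts$diagnosis_other <- edge_cpt("diagnosis_other", "known_camhs", 0.06,
                                   m$known_camhs, m$diagnosis_other)
  cpts$previous_attendance <- edge_cpt("previous_attendance", "known_camhs",
                                       0.13, m$known_camhs,
                                       m$previous_attendance)
  cpts$history_dsh <- edge_cpt("history_dsh", "previous_attendance", 0.11,
                               m$previous_attendance, m$history_dsh)
  cpts$domestic_violence <- edge_cpt("domestic_violence", "neglect", 0.80,
                                     m$neglect, m$domestic_violence)
  cpts$abuse <- edge_cpt("abuse", "neglect", 0.72, m$neglect, m$abuse)
  cpts$social_worker <- edge_cpt("social_worker", "neglect", 0.12,
                                 m$neglect, m$social_worker)
  cpts$single_parent <- edge_cpt("single_parent", "social_worker", 0.15,
                                 m$social_worker, m$single_parent)
  cpts$step_parent <- edge_cpt("step_parent", "social_worker", 0.15,
                               m$social_worker, m$step_parent)
  cpts$siblings <- edge_cpt("siblings", "single_parent", 0.15,
                            m$single_parent, m$siblings)
  cpts$sep_loss_parent <- edge_cpt("sep_loss_parent", "single_parent", 0.15,
                                   m$single_parent, m$sep_loss_parent)
  cpts$parent_drug_misuse <- edge_cpt("parent_drug_misuse",
                                      "parental_mental_health", 0.15,
                                      m$parental_mental_health,
                                      m$parent_drug_misuse)

  ## shared children: fit the CPT to both pairwise MI targets at once
  cfg2 <- cbind(expand.grid(0:1, 0:1)[, 1L], expand.grid(0:1, 0:1)[, 2L])
  ## low_mood | known_camhs, previous_attendance
  pk <- m$known_camhs
  cond_prev <- joint_to_conditional(
    calibrate_pairwise_joint(0.13, pk, m$previous_attendance))
  colnames(cfg2) <- c("known_camhs", "previous_attendance")
  qlm <- c((1 - pk) * cond_prev[1L, 1L], pk * cond_prev[2L, 1L],
           (1 - pk) * cond_prev[1L, 2L], pk * cond_prev[2L, 2L])
  p_lm <- fit_binary_cpt(cfg2, qlm,
                         c(known_camhs = 0.09, previous_attendance = 0.07),
                         m$low_mood)
  cpts$low_mood <- cpt("low_mood", b01,
                       parents = c("known_camhs", "previous_attendance"),
                       parent_levels = list(known_camhs = b01,
                                            previous_attendance = b01),
                       table = cbind(1 - p_lm, p_lm))
  ## parental_crime | parental_mental_health, parent_drug_misuse
  pmh <- m$parental_mental_health
  cond_pdm <- joint_to_conditional(
    calibrate_pairwise_joint(0.15, pmh, m$parent_drug_misuse))
  cfgp <- cfg2
  colnames(cfgp) <- c("parental_mental_health", "parent_drug_misuse")
  qpc <- c((1 - pmh) * cond_pdm[1L, 1L], pmh * cond_pdm[2L, 1L],
           (1 - pmh) * cond_pdm[1L, 2L], pmh * cond_pdm[2L, 2L])
  p_pc <- fit_binary_cpt(cfgp, qpc,
                         c(parental_mental_health = 0.15,
                           parent_drug_misuse = 0.15),
                         m$parental_crime)
  cpts$parental_crime <- cpt("parental_crime", b01,
                             parents = c("parental_mental_health",
                                         "parent_drug_misuse"),
                             parent_levels = list(
                               parental_mental_health = b01,
                               parent_drug_misuse = b01),
                             table = cbind(1 - p_pc, p_pc))

  ## categorical edges: tilt a stochastic matrix away from independence
  sexw <- c(male = 1 - m$female, female = m$female)
  d_means <- rbind(
    male = c(0.10, -0.06, -0.03, -0.005, -0.005),
    female = c(-0.10, 0.06, 0.03, 0.005, 0.005))
  cal_means <- calibrate_conditional_matrix(0.05, sexw, m$means, d_means)
  cpts$means <- cpt("means", names(m$means), parents = "sex",
                    parent_levels = list(sex = c("male", "female")),
                    table = cal_means$matrix)
  d_risk <- rbind(
    none = c(1, -0.4, -0.6),
    overdose = c(-1, 0.1, 0.9),
    cutting = c(0, 0.3, -0.3),
    suffocation = c(-1, 0, 1),
    other = c(0, 0, 0))
  cal_risk <- calibrate_conditional_matrix(0.24, m$means, m$risk, d_risk)
  cpts$risk <- cpt("risk", names(m$risk), parents = "means",
                   parent_levels = list(means = names(m$means)),
                   table = cal_risk$matrix)

  ground_truth_network(dict, ed, cpts[variable_names(dict)])
}

#' Variable dictionary of the deterministic descriptive cohort
#'
#' Covers the variables of the published descriptive table: sex, age,
#' ethnicity, prior mental-health category, SEN category, autistic traits,
#' CAMHS status, history of self-harm and previous ED attendance.
#'
#' @return A [variable_dictionary()].
#' @export
reference_dictionary <- function() {
  vs <- variable_spec
  yn <- c("no", "yes")
  variable_dictionary(list(
    vs("previous_attendance", "binary", yn, role = "outcome"),
    vs("sex", "binary", c("female", "male"), role = "demographic"),
    vs("age", "integer_bounded", as.character(8:16), role = "demographic"),
    vs("ethnicity", "categorical", c("white_british", "other", "unknown"),
       role = "demographic"),
    vs("mental_health", "categorical",
       c("anxiety", "anxiety_comorbidities", "anxiety_low_mood", "low_mood",
         "low_mood_comorbidity", "other", "none"), role = "clinical"),
    vs("sen", "categorical",
       c("adhd", "adhd_other_ld", "asc", "asc_adhd", "asc_adhd_ld",
         "asc_ld", "ld", "none"), role = "demographic"),
    vs("asc_traits", "binary", rev(yn), role = "clinical"),
    vs("known_camhs", "binary", rev(yn), role = "clinical"),
    vs("open_camhs", "binary", rev(yn), role = "clinical"),
    vs("history_dsh", "binary", rev(yn), role = "clinical")
  ))
}

## Printed per-level counts: overall column and previous-attender column.
reference_counts <- function() {
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

#' Deterministic cohort reproducing the published descriptive table
#'
#' A 240-record cohort whose per-variable level counts reproduce the
#' published descriptive table cell-for-cell, in both the overall column
#' and the previous-attender column. Records are filled deterministically
#' in blocks: the previous attenders come first, each variable assigned its
#' attended-column counts in level order, then the remaining records take
#' the overall-minus-attended counts in level order.
#'
#' The printed sub-columns for previous attenders each sum to 57 although
#' the printed attender total is 58; no 240-record table can satisfy both.
#' This fixture follows the sub-columns (57 previous attenders), which
#' reproduces every per-variable cell exactly and leaves only the printed
#' attender total one higher than the fixture's.
#'
#' Ages are filled deterministically so the overall mean is exactly 13.5
#' (range 8-16) and the attenders' mean is 13.70.
#'
#' @return A [cohort()] with [reference_dictionary()], n = 240.
#' @export
reference_cohort <- function() {
  n <- 240L
  n_att <- 57L
  cc <- reference_counts()
  fill <- function(spec) {
    att <- rep(spec$levels, spec$attended)
    rest <- rep(spec$levels, spec$overall - spec$attended)
    c(att, rest)
  }
  df <- data.frame(
    previous_attendance = c(rep("yes", n_att), rep("no", n - n_att)),
    stringsAsFactors = FALSE)
  for (nm in names(cc)) df[[nm]] <- fill(cc[[nm]])
  df$age <- as.character(c(
    8, 16, rep(13, 13), rep(14, 42),       # attenders: mean 13.70
    rep(13, 103), rep(14, 80)))            # others: overall mean 13.5
  cohort(df[, variable_names(reference_dictionary())],
         reference_dictionary())
}
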