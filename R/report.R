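#' Run configuration for a scripted report
#'
#' A fully serialisable description of one analysis run; a run is
#' reproducible from its configuration and inputs alone.
#'
#' @param input Path to the cohort CSV (or `NULL` when `cohort` is passed
#'   to [run_report()] directly).
#' @param dictionary Path to the variable dictionary (YAML/JSON), or `NULL`.
#' @param alpha Significance level (default 0.05).
#' @param max_cond Largest conditioning-set size (default 2).
#' @param n_perm Permutations for sparse fallbacks (default 9999).
#' @param seed Integer seed (default 1).
#' @param out_dir Output directory.
#' @param correction Skeleton multiple-testing correction (`"none"` or
#'   `"bonferroni"`).
#' @param p_adjust Adjustment applied to the follow-up test table
#'   (`"none"` or `"BH"`).
#' @param stratify Optional binary variable for the stratified summary
#'   (default `"previous_attendance"` when present).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input = NULL, dictionary = NULL, alpha = 0.05,
                       max_cond = 2, n_perm = 9999, seed = 1L,
                       out_dir = "cimap-report",
                       correction = c("none", "bonferroni"),
                       p_adjust = c("none", "BH"),
                       stratify = "previous_attendance") {
  structure(list(input = input, dictionary = dictionary, alpha = alpha,
                 max_cond = max_cond, n_perm = n_perm, seed = seed,
                 out_dir = out_dir, correction = match.arg(correction),
                 p_adjust = match.arg(p_adjust), stratify = stratify),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

## The named follow-up analyses: each derives the binary/categorical
## variables it needs from `means` and crosses them with sex or risk.
followup_specs <- function() {
  list(
    list(name = "sex_x_self_harm",
         needs = c("sex", "means"),
         what = "sex x presented-with-self-harm (means != none)"),
    list(name = "sex_x_overdose",
         needs = c("sex", "means"),
         what = "sex x overdose"),
    list(name = "means_x_risk",
         needs = c("means", "risk"),
         what = "means x clinician risk band"),
    list(name = "ideation_only_x_risk",
         needs = c("means", "risk"),
         what = "ideation-only (means == none) x risk"),
    list(name = "overdose_x_risk",
         needs = c("means", "risk"),
         what = "overdose x risk")
  )
}

derive_followup_table <- function(cohort, name) {
  d <- cohort$data
  two <- function(v, yes) factor(ifelse(v == yes, "yes", "no"),
                                 levels = c("no", "yes"))
  sh <- function() two(ifelse(d$means == "none", "none", "sh"), "sh")
  tab <- switch(name,
    sex_x_self_harm = table(d$sex, sh()),
    sex_x_overdose = table(d$sex, two(d$means, "overdose")),
    means_x_risk = table(d$means, d$risk),
    ideation_only_x_risk = table(two(d$means, "none"),
                                 factor(d$risk,
                                        levels = get_spec(
                                          cohort$dictionary,
                                          "risk")$levels)),
    overdose_x_risk = table(two(d$means, "overdose"),
                            factor(d$risk,
                                   levels = get_spec(cohort$dictionary,
                                                     "risk")$levels)),
    stop("unknown follow-up: ", name, call. = FALSE))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Run the scripted analysis report
#'
#' Produces, under `config$out_dir`: the descriptive summary
#' (`summary.csv`, `summary.txt`), the CI-Map (`map.graphml`, `map.dot`,
#' `edges.csv`), the component listing (`components.json`), the named
#' follow-up effect-size tests (`followups.csv`: sex x self-harm, sex x
#' overdose, means x risk with ideation-only and overdose risk sub-tests),
#' a structured log with one record per statistical operation
#' (`log.csv`), and the configuration used (`config.json`). Follow-ups
#' whose variables are absent from the cohort are skipped with a logged
#' reason. Re-running with the same configuration and inputs reproduces
#' the outputs byte for byte.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param cohort Optionally, an in-memory [cohort()] overriding
#'   `config$input`.
#' @return Invisibly, a list with `summary`, `map`, `components`,
#'   `followups`, `log`, `out_dir`.
#' @export
run_report <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    if (is.null(config$input) || is.null(config$dictionary))
      stop("config must give input and dictionary paths when no cohort ",
           "is passed", call. = FALSE)
    cohort <- read_cohort(config$input, read_dictionary(config$dictionary))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  log_op <- function(op, vars, n_used, n_excluded, df = NA, method = NA,
                     statistic = NA, p = NA, note = "") {
    log[[length(log) + 1L]] <<- data.frame(
      op = op, variables = paste(vars, collapse = "|"),
      n_used = n_used, n_excluded = n_excluded, df = df, method = method,
      statistic = statistic, p = p, seed = config$seed, note = note,
      stringsAsFactors = FALSE)
  }

  stratum <- if (!is.null(config$stratify) &&
                 config$stratify %in% names(cohort$data))
    config$stratify else NULL
  summ <- summarise_cohort(cohort, stratum = stratum)
  write_summary(summ, file.path(config$out_dir, "summary.csv"))
  write_summary(summ, file.path(config$out_dir, "summary.txt"))
  log_op("summarise", names(cohort$data), cohort$n, 0,
         note = if (is.null(stratum)) "" else paste0("stratum=", stratum))

  map <- build_cimap(cohort, alpha = config$alpha,
                     max_cond = config$max_cond, seed = config$seed,
                     correction = config$correction,
                     n_perm = config$n_perm)
  write_cimap_graphml(map, file.path(config$out_dir, "map.graphml"))
  write_cimap_dot(map, file.path(config$out_dir, "map.dot"))
  write_cimap_edges(map, file.path(config$out_dir, "edges.csv"))
  log_op("build_cimap", map$variables, cohort$n, 0,
         note = sprintf("edges=%d alpha=%g max_cond=%d correction=%s",
                        nrow(map$edges), config$alpha, config$max_cond,
                        config$correction))

  comps <- cimap_components(map)
  jsonlite::write_json(comps, file.path(config$out_dir, "components.json"),
                       pretty = TRUE)

  fu_rows <- list()
  for (fu in followup_specs()) {
    missing_vars <- setdiff(fu$needs, names(cohort$data))
    if (length(missing_vars)) {
      log_op("followup_skipped", fu$needs, 0, cohort$n,
             note = paste("missing:", paste(missing_vars, collapse = ",")))
      next
    }
    cc <- stats::complete.cases(cohort$data[, fu$needs, drop = FALSE])
    tab <- derive_followup_table(
      cohort(cohort$data[cc, , drop = FALSE], cohort$dictionary), fu$name)
    res <- tryCatch(chi_square_effect(tab), error = function(e) e)
    if (inherits(res, "error")) {
      log_op("followup_skipped", fu$needs, sum(cc), sum(!cc),
             note = conditionMessage(res))
      next
    }
    fu_rows[[length(fu_rows) + 1L]] <- data.frame(
      test = fu$name, description = fu$what, chi2 = res$chi2, df = res$df,
      p = res$p, phi = res$phi, cramers_v = res$cramers_v, n = res$n,
      n_excluded = sum(!cc), stringsAsFactors = FALSE)
    log_op("followup", fu$needs, res$n, sum(!cc), df = res$df,
           method = "chi-square", statistic = res$chi2, p = res$p)
  }
  followups <- if (length(fu_rows)) do.call(rbind, fu_rows) else NULL
  if (!is.null(followups) && config$p_adjust == "BH")
    followups$p_adjusted <- stats::p.adjust(followups$p, method = "BH")
  if (!is.null(followups))
    utils::write.csv(followups, file.path(config$out_dir, "followups.csv"),
                     row.names = FALSE)

  log_df <- do.call(rbind, log)
  utils::write.csv(log_df, file.path(config$out_dir, "log.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(summary = summ, map = map, components = comps,
                 followups = followups, log = log_df,
                 out_dir = config$out_dir))
}
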