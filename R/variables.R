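#' Declare a study variable
#'
#' A variable specification records the name, measurement kind, ordered level
#' labels, analytic role and missing-value code of one column of a cohort
#' table. Most variables in an emergency-department ACE cohort are binary
#' flags extracted from clinical notes; a few are categorical (means of
#' self-harm, clinician risk band) or bounded integers (age).
#'
#' @param name Variable name (non-empty string, unique within a dictionary).
#' @param kind One of `"binary"`, `"categorical"`, `"count"`,
#'   `"integer_bounded"`. Binary variables must declare exactly two levels.
#' @param levels Character vector of ordered level labels. Defaults to
#'   `c("0", "1")` for binary variables.
#' @param role One of `"ACE"`, `"demographic"`, `"clinical"`, `"outcome"`,
#'   `"derived"`.
#' @param missing_code Label treated as missing on input (default `""`).
#'
#' @return An object of class `"variable_spec"`.
#' @export
#' @examples
#' variable_spec("neglect", "binary", role = "ACE")
#' variable_spec("risk", "categorical", c("low", "medium", "high"))
variable_spec <- function(name,
                          kind = c("binary", "categorical", "count",
                                   "integer_bounded"),
                          levels = NULL,
                          role = c("clinical", "ACE", "demographic",
                                   "outcome", "derived"),
                          missing_code = "") {
  kind <- match.arg(kind)
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a single non-empty string", call. = FALSE)
  if (is.null(levels))
    levels <- if (kind == "binary") c("0", "1") else
      stop("`levels` must be given for non-binary variables", call. = FALSE)
  levels <- as.character(levels)
  if (length(levels) == 0L || anyDuplicated(levels))
    stop("levels must be non-empty and unique for variable '", name, "'",
         call. = FALSE)
  if (kind == "binary" && length(levels) != 2L)
    stop("binary variable '", name, "' must have exactly 2 levels",
         call. = FALSE)
  if (missing_code %in% levels)
    stop("missing code may not be a declared level of '", name, "'",
         call. = FALSE)
  structure(
    list(name = name, kind = kind, levels = levels, role = role,
         missing_code = missing_code),
    class = "variable_spec"
  )
}

#' Assemble a variable dictionary
#'
#' A dictionary is an ordered collection of [variable_spec()] objects with
#' unique names; it defines the schema every cohort table is validated
#' against. Undeclared columns in data are an error.
#'
#' @param ... `variable_spec` objects, or a single list of them.
#' @return An object of class `"variable_dictionary"`.
#' @export
variable_dictionary <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "variable_spec"))
    specs <- specs[[1L]]
  ok <- vapply(specs, inherits, logical(1), "variable_spec")
  if (length(specs) == 0L || !all(ok))
    stop("a dictionary is built from variable_spec objects", call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(specs) <- nms
  structure(list(specs = specs), class = "variable_dictionary")
}

#' @export
print.variable_dictionary <- function(x, ...) {
  cat("Variable dictionary:", length(x$specs), "variables\n")
  for (s in x$specs)
    cat(sprintf("  %-24s %-15s [%s] (%s)\n", s$name, s$kind,
                paste(s$levels, collapse = ", "), s$role))
  invisible(x)
}

#' Names of the variables declared in a dictionary
#' @param dictionary A [variable_dictionary()].
#' @return Character vector of variable names, in declaration order.
#' @export
variable_names <- function(dictionary) {
  stopifnot(inherits(dictionary, "variable_dictionary"))
  names(dictionary$specs)
}

#' Look up one variable's specification
#' @param dictionary A [variable_dictionary()].
#' @param name Variable name; must be declared.
#' @return The `variable_spec`.
#' @export
get_spec <- function(dictionary, name) {
  stopifnot(inherits(dictionary, "variable_dictionary"))
  s <- dictionary$specs[[name]]
  if (is.null(s))
    stop("variable '", name, "' is not declared in the dictionary",
         call. = FALSE)
  s
}

dict_to_list <- function(dictionary) {
  lapply(unname(dictionary$specs), function(s)
    list(name = s$name, kind = s$kind, levels = as.list(s$levels),
         role = s$role, missing_code = s$missing_code))
}

list_to_dict <- function(lst) {
  specs <- lapply(lst, function(e) {
    variable_spec(
      name = e$name,
      kind = e$kind,
      levels = as.character(unlist(e$levels)),
      role = if (is.null(e$role)) "clinical" else e$role,
      missing_code = if (is.null(e$missing_code)) "" else e$missing_code
    )
  })
  variable_dictionary(specs)
}

#' Read or write a variable dictionary (YAML or JSON)
#'
#' The on-disk form is a list of records with fields
#' `name`, `kind`, `levels`, `role`, `missing_code`. Format is chosen by
#' file extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path File path.
#' @return `read_dictionary()` returns a [variable_dictionary()].
#' @export
read_dictionary <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    stop("unsupported dictionary format: .", ext, call. = FALSE))
  list_to_dict(lst)
}

#' @rdname read_dictionary
#' @param dictionary A [variable_dictionary()] to serialise.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "variable_dictionary"))
  ext <- tolower(tools::file_ext(path))
  lst <- dict_to_list(dictionary)
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE),
    stop("unsupported dictionary format: .", ext, call. = FALSE))
  invisible(path)
}
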