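#' Declare the analysis design of a cohort table
#'
#' A study design assigns a role to every analysis variable: the continuous
#' outcome, single predictors that enter the final regression on their own,
#' and category members that are combined into one weighted risk score per
#' category. Variable types control preprocessing: `"continuous"` and
#' `"binary"` variables are standardized before weight learning, `"snp"`
#' variables (minor-allele counts coded 0/1/2) are exempt.
#'
#' @param outcome name of the outcome column (exactly one).
#' @param singles character vector of single-predictor column names.
#' @param categories named list; each element is a character vector of member
#'   column names for one risk-factor category.
#' @param var_types optional named character vector mapping variable names to
#'   one of `"continuous"`, `"binary"`, `"snp"`. Unnamed variables default to
#'   `"continuous"`.
#' @param single_groups optional named list grouping single predictors that
#'   are treated as one unit in the importance decomposition (e.g. the two
#'   dummy variables of a three-level socio-economic status factor).
#' @param standardize optional named logical vector overriding the default
#'   standardization flag (default `TRUE` for every predictor except
#'   `var_type = "snp"`). The outcome is never standardized here.
#'
#' @return an object of class `study_design`.
#' @seealso [validate_design()], [read_design()]
#' @export
study_design <- function(outcome, singles = character(), categories = list(),
                         var_types = NULL, single_groups = list(),
                         standardize = NULL) {
  stopifnot(is.character(outcome), length(outcome) == 1L)
  singles <- as.character(singles)
  if (length(categories) && is.null(names(categories)))
    stop("'categories' must be a named list of member-name vectors")
  categories <- lapply(categories, as.character)
  members <- unlist(categories, use.names = FALSE)

  vars <- c(outcome, singles, members)
  dup <- unique(vars[duplicated(vars)])
  if (length(dup))
    stop("variable(s) declared in more than one role: ",
         paste(dup, collapse = ", "))

  types <- stats::setNames(rep("continuous", length(vars)), vars)
  if (!is.null(var_types)) {
    bad <- setdiff(var_types, c("continuous", "binary", "snp"))
    if (length(bad)) stop("unknown var_type(s): ", paste(bad, collapse = ", "))
    unknown <- setdiff(names(var_types), vars)
    if (length(unknown))
      stop("var_types given for undeclared variable(s): ",
           paste(unknown, collapse = ", "))
    types[names(var_types)] <- var_types
  }

  std <- stats::setNames(types != "snp", vars)
  std[outcome] <- FALSE
  if (!is.null(standardize)) {
    unknown <- setdiff(names(standardize), vars)
    if (length(unknown))
      stop("standardize flags for undeclared variable(s): ",
           paste(unknown, collapse = ", "))
    std[names(standardize)] <- standardize
    std[outcome] <- FALSE
  }

  if (length(single_groups)) {
    if (is.null(names(single_groups)))
      stop("'single_groups' must be a named list")
    single_groups <- lapply(single_groups, as.character)
    grouped <- unlist(single_groups, use.names = FALSE)
    if (anyDuplicated(grouped))
      stop("a single predictor belongs to more than one single_group")
    missing <- setdiff(grouped, singles)
    if (length(missing))
      stop("single_groups refer to non-single variable(s): ",
           paste(missing, collapse = ", "))
  }

  structure(
    list(outcome = outcome, singles = singles, categories = categories,
         var_types = types, single_groups = single_groups,
         standardize = std,
         m = vapply(categories, length, integer(1))),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design\n")
  cat("  outcome:   ", x$outcome, "\n")
  cat("  singles:   ", length(x$singles),
      if (length(x$single_groups))
        sprintf("(%d grouped)", length(unlist(x$single_groups))) else "", "\n")
  for (k in names(x$categories))
    cat(sprintf("  category %-12s m = %d\n", k, length(x$categories[[k]])))
  invisible(x)
}

# all analysis variables in canonical order: outcome, singles, members
design_vars <- function(design) {
  c(design$outcome, design$singles,
    unlist(design$categories, use.names = FALSE))
}

# member columns of all categories, in declared order
design_members <- function(design) {
  unlist(design$categories, use.names = FALSE)
}

#' Validate a study design against a cohort table
#'
#' Checks that every declared variable has a column, that roles partition the
#' analysis variables, that SNP-typed columns only contain values in
#' \{0, 1, 2\}, and records the member count of each category. Validation is
#' idempotent: validating a validated design changes nothing.
#'
#' @param design a [study_design()].
#' @param table a data frame holding the cohort.
#' @return the validated design (class `study_design`), with member counts in
#'   `$m` and attribute `validated = TRUE`.
#' @export
validate_design <- function(design, table) {
  stopifnot(inherits(design, "study_design"), is.data.frame(table))
  vars <- design_vars(design)
  missing <- setdiff(vars, names(table))
  if (length(missing))
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  for (v in vars) {
    if (!is.numeric(table[[v]]))
      stop("column '", v, "' is not numeric")
    if (design$var_types[[v]] == "snp") {
      vals <- table[[v]]
      vals <- vals[!is.na(vals)]
      if (!all(vals %in% c(0, 1, 2)))
        stop("snp column '", v, "' contains values outside {0,1,2}")
    }
    if (design$var_types[[v]] == "binary") {
      vals <- table[[v]]
      vals <- vals[!is.na(vals)]
      if (!all(vals %in% c(0, 1)))
        stop("binary column '", v, "' contains values outside {0,1}")
    }
  }
  if (any(design$m < 1L))
    stop("every category needs at least one member")
  design$m <- vapply(design$categories, length, integer(1))
  attr(design, "validated") <- TRUE
  design
}

#' Drop participants with missing analysis variables
#'
#' Complete-case analysis: any row with a missing value in an analysis
#' variable (outcome, single predictor or category member) is removed. The
#' number of dropped rows is reported via `message()`.
#'
#' @inheritParams validate_design
#' @return the table restricted to complete cases.
#' @export
drop_incomplete <- function(table, design) {
  vars <- design_vars(design)
  keep <- stats::complete.cases(table[, vars, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " row(s) dropped with missing analysis variables")
  table[keep, , drop = FALSE]
}

#' Read / write a study design as a YAML config
#'
#' The config schema mirrors the constructor:
#' ```yaml
#' outcome: fev1_z
#' singles: [age, height, ses_med, ses_high]
#' single_groups:
#'   SES: [ses_med, ses_high]
#' categories:
#'   genetic: [snp1, snp2, snp3]
#'   obesity: [bmi_fu1, bmi_fu2, low_activity]
#' var_types:
#'   snp1: snp
#'   low_activity: binary
#' ```
#'
#' A complete example mirroring a lung-function analysis design ships at
#' `system.file("extdata", "lung_design.yaml", package = "rscontrib")`.
#'
#' @param path file path of the YAML design.
#' @return [read_design()] returns a `study_design`; [write_design()] returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$outcome)) stop("design config lacks an 'outcome' entry")
  vt <- if (!is.null(cfg$var_types)) unlist(cfg$var_types) else NULL
  std <- if (!is.null(cfg$standardize))
    vapply(cfg$standardize, isTRUE, logical(1)) else NULL
  study_design(outcome = cfg$outcome,
               singles = cfg$singles %||% character(),
               categories = lapply(cfg$categories %||% list(), unlist),
               var_types = vt,
               single_groups = lapply(cfg$single_groups %||% list(), unlist),
               standardize = std)
}

#' @rdname read_design
#' @param design a [study_design()] to serialize.
#' @export
write_design <- function(design, path) {
  out <- list(outcome = design$outcome,
              singles = as.list(design$singles),
              categories = lapply(design$categories, as.list),
              var_types = as.list(design$var_types[design$var_types != "continuous"]),
              single_groups = lapply(design$single_groups, as.list))
  out <- out[vapply(out, length, integer(1)) > 0]
  yaml::write_yaml(out, path)
  invisible(path)
}
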