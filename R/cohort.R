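#' Construct a cohort of reproductive histories
#'
#' A cohort is the atomic data structure of the package: one row per
#' ever-married woman, holding her full birth history on a months-since-
#' marriage clock together with time-fixed socio-demographic covariates.
#' Birth times and child sexes are stored as list columns so that a woman of
#' any parity (0 to 7) occupies exactly one row.
#'
#' @param woman_id Character vector of unique identifiers.
#' @param interview_time Months from marriage to interview (> 0).
#' @param birth_times List of numeric vectors; each element holds one woman's
#'   birth times in months since marriage, strictly increasing and in
#'   `(0, interview_time]`. Length 0 for childless women.
#' @param child_sexes List of character vectors (`"male"`/`"female"`), each the
#'   same length as the matching element of `birth_times`.
#' @param covariates Data frame with one row per woman and columns
#'   `woman_age_at_marriage`, `woman_education`, `woman_employment`,
#'   `husband_age`, `husband_education`, `husband_employment`, `stillbirth`,
#'   `age_first_pregnancy`, `income`. Categorical columns are coerced to
#'   factors with the package's fixed level sets; the first level of each is
#'   the reference used in model output.
#' @return An object of class `cohort` (a data frame).
#' @seealso [read_cohort()], [write_cohort()], [expand_gaps()],
#'   [simulate_cohort()]
#' @examples
#' coh <- cohort(
#'   woman_id = c("w1", "w2"),
#'   interview_time = c(300, 280),
#'   birth_times = list(c(30, 84), numeric(0)),
#'   child_sexes = list(c("male", "female"), character(0)),
#'   covariates = data.frame(
#'     woman_age_at_marriage = c(19, 23), woman_education = "secondary",
#'     woman_employment = "unemployed", husband_age = c(24, 30),
#'     husband_education = "secondary", husband_employment = "employed",
#'     stillbirth = "no", age_first_pregnancy = ">18", income = "135-270"
#'   )
#' )
#' parity(coh)
#' @export
cohort <- function(woman_id, interview_time, birth_times, child_sexes,
                   covariates) {
  n <- length(woman_id)
  if (!is.list(birth_times) || !is.list(child_sexes))
    stop_input("'birth_times' and 'child_sexes' must be lists")
  if (length(interview_time) != n || length(birth_times) != n ||
      length(child_sexes) != n || nrow(covariates) != n)
    stop_input("all cohort components must describe the same number of women")
  missing_cov <- setdiff(.covariate_columns, names(covariates))
  if (length(missing_cov))
    stop_input("missing covariate column(s): %s",
               paste(missing_cov, collapse = ", "))

  out <- data.frame(woman_id = as.character(woman_id),
                    interview_time = as.numeric(interview_time),
                    stringsAsFactors = FALSE)
  out$birth_times <- lapply(birth_times, as.numeric)
  out$child_sexes <- lapply(child_sexes, as.character)
  for (nm in .covariate_columns) {
    v <- covariates[[nm]]
    out[[nm]] <- if (nm %in% names(.factor_levels))
      factor(as.character(v), levels = .factor_levels[[nm]]) else as.numeric(v)
  }
  class(out) <- c("cohort", "data.frame")
  validate_cohort(out)
}

#' Validate a cohort
#'
#' Checks every invariant of the data model and fails with a message naming
#' the offending woman and field: unique ids, positive interview times,
#' strictly increasing birth times inside `(0, interview_time]`, matching sex
#' vectors with valid codes, parity at most 7, positive ages, and categorical
#' covariates restricted to their level sets.
#'
#' @param x A `cohort`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_cohort <- function(x) {
  if (!inherits(x, "cohort")) stop_input("not a cohort object")
  if (anyDuplicated(x$woman_id))
    stop_input("duplicated woman_id: %s",
               x$woman_id[duplicated(x$woman_id)][1])
  for (i in seq_len(nrow(x))) {
    id <- x$woman_id[i]
    it <- x$interview_time[i]
    bt <- x$birth_times[[i]]
    cs <- x$child_sexes[[i]]
    if (!is.finite(it) || it <= 0)
      stop_input("woman %s: interview_time must be a positive number", id)
    if (anyNA(bt))
      stop_input("woman %s: birth_times contains missing values", id)
    if (length(bt) > .max_parity)
      stop_input("woman %s: parity %d exceeds the maximum of %d", id,
                 length(bt), .max_parity)
    if (length(bt) && (any(diff(bt) <= 0)))
      stop_input("woman %s: birth_times must be strictly increasing", id)
    if (length(bt) && (bt[1] <= 0 || bt[length(bt)] > it))
      stop_input("woman %s: birth_times must lie in (0, interview_time]", id)
    if (length(cs) != length(bt))
      stop_input("woman %s: child_sexes length differs from birth_times", id)
    if (length(cs) && !all(cs %in% .sex_levels))
      stop_input("woman %s: child_sexes must be 'male' or 'female'", id)
  }
  for (nm in names(.factor_levels)) {
    bad <- is.na(x[[nm]])
    if (any(bad))
      stop_input("woman %s: %s is missing or not one of: %s",
                 x$woman_id[which(bad)[1]], nm,
                 paste(.factor_levels[[nm]], collapse = ", "))
  }
  for (nm in c("woman_age_at_marriage", "husband_age")) {
    bad <- !is.finite(x[[nm]]) | x[[nm]] <= 0
    if (any(bad))
      stop_input("woman %s: %s must be a positive number",
                 x$woman_id[which(bad)[1]], nm)
  }
  invisible(x)
}

#' Number of live births per woman
#'
#' @param x A `cohort`.
#' @return Integer vector of parities (lengths of the birth histories).
#' @export
parity <- function(x) {
  stopifnot(inherits(x, "cohort"))
  vapply(x$birth_times, length, integer(1))
}

#' @export
print.cohort <- function(x, ...) {
  p <- parity(x)
  cat(sprintf("<cohort> %d women, parity 0-%d (mean %.2f)\n",
              nrow(x), if (nrow(x)) max(p) else 0, mean(p)))
  cat(sprintf("  interview at %.0f-%.0f months since marriage\n",
              min(x$interview_time), max(x$interview_time)))
  tab <- table(factor(p, levels = 0:.max_parity))
  cat("  parity distribution:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) {
  p <- parity(object)
  structure(list(
    n = nrow(object),
    parity_table = table(factor(p, levels = 0:max(c(p, 4L)))),
    interview_range = range(object$interview_time),
    total_births = sum(p)
  ), class = "summary.cohort")
}

#' @export
print.summary.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d women, %d births\n", x$n, x$total_births))
  print(x$parity_table)
  invisible(x)
}

# CSV dialect ------------------------------------------------------------
# Comma-separated, UTF-8, header mandatory. Birth times and child sexes are
# semicolon-joined inside a single cell; an empty cell is parity 0.

.fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a cohort to CSV
#'
#' Serialises a cohort in the package's CSV dialect: one row per woman,
#' birth times and child sexes semicolon-joined inside one cell, numeric
#' fields written with full double precision so that
#' `read_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  df <- data.frame(
    woman_id = x$woman_id,
    interview_time = .fmt_num(x$interview_time),
    birth_times = vapply(x$birth_times, function(b)
      paste(.fmt_num(b), collapse = ";"), character(1)),
    child_sexes = vapply(x$child_sexes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  for (nm in .covariate_columns) {
    df[[nm]] <- if (nm %in% names(.factor_levels))
      as.character(x[[nm]]) else .fmt_num(x[[nm]])
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses and validates a cohort file written in the package's CSV dialect
#' (see [write_cohort()]). Every row is checked against the data-model
#' invariants; a malformed row fails with a message naming the woman and the
#' field. Birth histories longer than 7 births are truncated to the first 7
#' with a warning.
#'
#' @param path Input file path.
#' @param schema_version Schema tag; only `"1"` exists.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1"))
    stop_input("unknown cohort schema version: %s", schema_version)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (!identical(names(df), .cohort_columns))
    stop_input("header does not match cohort schema; expected: %s",
               paste(.cohort_columns, collapse = ","))
  split_cell <- function(cell, convert) {
    if (is.na(cell) || !nzchar(cell)) return(convert(character(0)))
    convert(strsplit(cell, ";", fixed = TRUE)[[1]])
  }
  bt <- lapply(df$birth_times, split_cell, convert = as.numeric)
  cs <- lapply(df$child_sexes, split_cell, convert = as.character)
  long <- vapply(bt, length, integer(1)) > .max_parity
  if (any(long)) {
    warning(sprintf("%d row(s) exceed parity %d; birth histories truncated",
                    sum(long), .max_parity), call. = FALSE)
    bt[long] <- lapply(bt[long], head, .max_parity)
    cs[long] <- lapply(cs[long], head, .max_parity)
  }
  cov <- df[.covariate_columns]
  for (nm in setdiff(.covariate_columns, names(.factor_levels))) {
    v <- suppressWarnings(as.numeric(cov[[nm]]))
    if (anyNA(v))
      stop_input("woman %s: field %s is not numeric",
                 df$woman_id[which(is.na(v))[1]], nm)
    cov[[nm]] <- v
  }
  cohort(df$woman_id, as.numeric(df$interview_time), bt, cs, cov)
}
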