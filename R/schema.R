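# Cohort data model: schema, validation, CSV round-trip, and descriptive
# between-group comparison tables.

#' Default cohort schema
#'
#' Declares the column set, category level sets (with the first level as the
#' treatment-coding reference) and numeric ranges of a cohort table. The
#' participant record mirrors a web questionnaire: demographics, seventeen
#' health/lifestyle answers, current-smoker status, and the paired-associate
#' learning (PAL) total score, an integer 0--36 (12 word pairs x 3 trials).
#'
#' @param education_levels,race_levels,ethnicity_levels,marital_levels,handedness_levels
#'   Character vectors of category levels; the first entry is the reference.
#' @return An object of class `cohort_schema`: a list with `levels` (named
#'   list of category level sets), `booleans` (names of yes/no columns),
#'   `integers` (named list of `c(min, max)` ranges) and `columns` (the
#'   canonical column order).
#' @export
cohort_schema <- function(education_levels = c("high_school_or_less",
                                               "some_college", "college",
                                               "masters", "doctoral"),
                          race_levels = c("white", "black", "asian",
                                          "native_american", "other"),
                          ethnicity_levels = c("not_hispanic", "hispanic"),
                          marital_levels = c("single", "married", "divorced",
                                             "widowed", "separated"),
                          handedness_levels = c("right", "left",
                                                "ambidextrous")) {
  lv <- list(sex = c("woman", "man"),
             education = education_levels,
             race = race_levels,
             ethnicity = ethnicity_levels,
             marital_status = marital_levels,
             handedness = handedness_levels)
  booleans <- c("smoker", "diabetes", "seizures", "cancer", "stroke",
                "hypertension", "heart_disease", "family_history_ad",
                "drug_abuse", "loss_of_consciousness", "dizziness")
  integers <- list(age = c(18L, 85L),
                   daily_medications = c(0L, Inf),
                   pal_total = c(0L, 36L))
  columns <- c("age", "sex", "smoker", "education", "race", "ethnicity",
               "marital_status", "handedness", "daily_medications",
               "diabetes", "seizures", "cancer", "stroke", "hypertension",
               "heart_disease", "family_history_ad", "drug_abuse",
               "loss_of_consciousness", "dizziness", "pal_total")
  structure(list(levels = lv, booleans = booleans, integers = integers,
                 columns = columns),
            class = "cohort_schema")
}

#' Names of the model covariates in the default schema
#'
#' The sixteen adjustment covariates of the full linear model (everything in
#' the schema except the outcome and the focal smoker/sex terms).
#' @return Character vector of covariate names.
#' @export
covariate_names <- function() {
  c("age", "race", "ethnicity", "marital_status", "handedness", "education",
    "daily_medications", "diabetes", "seizures", "cancer", "stroke",
    "hypertension", "heart_disease", "family_history_ad", "drug_abuse",
    "loss_of_consciousness", "dizziness")
}

#' Validate a cohort data frame against a schema
#'
#' Checks column presence, category membership, boolean coding and integer
#' ranges. Rows with missing values are rejected: the analyses are
#' complete-case only (use [drop_incomplete()] first to filter and count).
#'
#' @param data A data frame of participant records.
#' @param schema A [cohort_schema()].
#' @return The validated cohort: a data frame with canonical column order,
#'   factor columns carrying the declared levels, and class `cohort`.
#' @export
as_cohort <- function(data, schema = cohort_schema()) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  missing_cols <- setdiff(schema$columns, names(data))
  if (length(missing_cols))
    abort_check("cohort is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[schema$columns]
  if (nrow(data)) {
    na_rows <- which(!stats::complete.cases(data))
    if (length(na_rows))
      abort_check("missing values in row(s) ",
                  paste(utils::head(na_rows, 5L), collapse = ", "),
                  if (length(na_rows) > 5L) " ..." else "",
                  " (complete cases only; see drop_incomplete())")
  }
  for (nm in names(schema$levels)) {
    x <- as.character(data[[nm]])
    bad <- which(!(x %in% schema$levels[[nm]]))
    if (length(bad))
      abort_check("column '", nm, "', row ", bad[1L],
                  ": value '", x[bad[1L]], "' not in declared levels")
    data[[nm]] <- factor(x, levels = schema$levels[[nm]])
  }
  for (nm in schema$booleans) {
    x <- data[[nm]]
    if (is.character(x) || is.factor(x)) {
      x <- as.character(x)
      if (!all(x %in% c("yes", "no")))
        abort_check("column '", nm, "': booleans must be yes/no or logical")
      x <- x == "yes"
    }
    if (!is.logical(x)) {
      if (is.numeric(x) && all(x %in% c(0, 1))) x <- x == 1
      else abort_check("column '", nm, "': booleans must be yes/no or logical")
    }
    data[[nm]] <- x
  }
  for (nm in names(schema$integers)) {
    rng <- schema$integers[[nm]]
    x <- data[[nm]]
    if (!is.numeric(x) || any(x != floor(x)))
      abort_check("column '", nm, "' must be integer-valued")
    bad <- which(x < rng[1L] | x > rng[2L])
    if (length(bad))
      abort_check("column '", nm, "', row ", bad[1L], ": value ", x[bad[1L]],
                  " outside [", rng[1L], ", ", rng[2L], "]")
    data[[nm]] <- as.integer(x)
  }
  rownames(data) <- NULL
  attr(data, "schema") <- schema
  class(data) <- c("cohort", "data.frame")
  data
}

#' @method print cohort
#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d columns\n", nrow(x), ncol(x)))
  if (nrow(x)) {
    cat(sprintf("  women: %.1f%%  smokers: %.1f%%  PAL mean: %.2f\n",
                100 * mean(x$sex == "woman"), 100 * mean(x$smoker),
                mean(x$pal_total)))
  }
  invisible(x)
}

#' Drop incomplete rows before validation
#'
#' Complete-case pre-filter: removes rows with any missing value and reports
#' how many were dropped (via a message and the `n_dropped` attribute).
#'
#' @param data A raw data frame.
#' @return The complete-case subset, with attribute `n_dropped`.
#' @export
drop_incomplete <- function(data) {
  keep <- stats::complete.cases(data)
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " incomplete row(s) dropped")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a cohort CSV
#'
#' Plain UTF-8 CSV with a header row, one participant per row, booleans coded
#' yes/no. The file is validated against the schema on read; row order is
#' preserved.
#'
#' @param path Path to the CSV file.
#' @param schema A [cohort_schema()].
#' @return A validated `cohort`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) abort_check("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (nm in intersect(names(raw), names(schema$integers)))
    raw[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
  as_cohort(raw, schema)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: deterministic column order, booleans as
#' yes/no. Byte-stable for a given cohort.
#'
#' @param cohort A validated `cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  schema <- attr(cohort, "schema")
  if (is.null(schema)) schema <- cohort_schema()
  out <- as.data.frame(cohort)
  for (nm in schema$booleans) out[[nm]] <- ifelse(out[[nm]], "yes", "no")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) abort_check("cannot write '", path, "': ",
                                     conditionMessage(e)))
  invisible(path)
}

#' Chi-square comparison of covariates between two groups
#'
#' For every covariate other than the grouping variable, a Pearson chi-square
#' test of independence between the two groups, with no continuity
#' correction. `daily_medications` is binned 0/1/2/3/4+ for the table (it
#' enters models as a raw count); `age` is binned by decade; `pal_total` is
#' excluded (it is the outcome, not a covariate).
#'
#' @param cohort A validated `cohort`.
#' @param grouping Name of a binary covariate (logical column or two-level
#'   factor), default `"smoker"`.
#' @return A `group_comparison` data frame with columns covariate,
#'   statistic, df, p, and the contingency tables in attribute `tables`.
#' @export
covariate_group_tests <- function(cohort, grouping = "smoker") {
  stopifnot(inherits(cohort, "cohort"))
  g <- cohort[[grouping]]
  if (is.null(g)) abort_check("grouping covariate '", grouping, "' not found")
  if (is.logical(g)) g <- factor(ifelse(g, "yes", "no"), c("no", "yes"))
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2L)
    abort_check("grouping covariate '", grouping,
                "' is constant: cannot form two groups")
  if (nlevels(g) > 2L)
    abort_check("grouping covariate '", grouping, "' is not binary")
  vars <- setdiff(covariate_names(), grouping)
  rows <- vector("list", length(vars))
  tables <- vector("list", length(vars))
  names(tables) <- vars
  for (i in seq_along(vars)) {
    nm <- vars[i]
    x <- cohort[[nm]]
    if (nm == "daily_medications") {
      x <- cut(pmin(x, 4L), breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5),
               labels = c("0", "1", "2", "3", "4+"))
    } else if (nm == "age") {
      x <- cut(x, breaks = c(17, 29, 39, 49, 59, 69, 85),
               labels = c("18-29", "30-39", "40-49", "50-59", "60-69", "70-85"))
    } else if (is.logical(x)) {
      x <- factor(ifelse(x, "yes", "no"), c("no", "yes"))
    }
    tab <- table(x, g)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) {
      rows[[i]] <- data.frame(covariate = nm, statistic = 0, df = 0L, p = 1)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[i]] <- data.frame(covariate = nm,
                              statistic = unname(ct$statistic),
                              df = unname(ct$parameter),
                              p = unname(ct$p.value))
    }
    tables[[i]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tables") <- tables
  attr(out, "n") <- nrow(cohort)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @method print group_comparison
#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Between-group chi-square tests (N = %d)\n", attr(x, "n")))
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 4)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a group-comparison table as TSV
#'
#' @param x A `group_comparison` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_comparison <- function(x, path) {
  stopifnot(inherits(x, "group_comparison"))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
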