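# Registry table I/O and validation.
#
# All tables are plain data frames with a class tag; tract_id is always an
# opaque string (11-digit FIPS-style IDs pass through unmodified), and
# age_group is a 1-based index into an age_scheme.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
      paste(missing, collapse = ", ")), call. = FALSE)
  }
  d
}

# Coerce a character column to numeric, reporting offending CSV line numbers
# (header is line 1, so data row i is line i + 1).
numeric_column <- function(d, col, path, integer = FALSE,
                           nonneg = TRUE) {
  x <- suppressWarnings(as.numeric(d[[col]]))
  bad <- which(!is.finite(x))
  if (integer) bad <- union(bad, which(is.finite(x) & x != floor(x)))
  if (nonneg) bad <- union(bad, which(is.finite(x) & x < 0))
  if (length(bad)) {
    bad <- sort(bad)
    stop(sprintf("%s: invalid value(s) in column '%s' at line(s) %s",
      basename(path), col,
      paste(utils::head(bad + 1L, 5), collapse = ", ")), call. = FALSE)
  }
  if (integer) x <- as.integer(x)
  x
}

validate_cell_table <- function(d, what) {
  key <- paste(d$tract_id, d$year, d$age_group, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicate (tract_id, year, age_group) keys", what),
      call. = FALSE)
  }
  yrs <- sort(unique(d$year))
  if (length(yrs) > 1 && !identical(yrs, seq(min(yrs), max(yrs)))) {
    stop(sprintf("%s: years must form a contiguous study period", what),
      call. = FALSE)
  }
  invisible(d)
}

#' Read a case-count table from CSV
#'
#' Reads case records aggregated to (tract, year, age-group) cells. The file
#' must have a header row with columns `tract_id`, `year`, `age_group` and
#' `cases`; `age_group` is a 1-based index into `scheme`. Malformed rows are
#' reported with their CSV line numbers, and any violation (negative count,
#' out-of-range age group, duplicate key, gap in the study period) is a hard
#' failure naming the offending field.
#'
#' @param path CSV file path.
#' @param scheme The [age_scheme()] the `age_group` indices refer to.
#' @return A `case_table`: data frame with columns `tract_id` (character),
#'   `year`, `age_group` (integer) and `cases` (integer), carrying the
#'   scheme as attribute `"scheme"`.
#' @seealso [read_population_table()], [apply_exclusions()]
#' @export
read_case_table <- function(path, scheme = age_scheme()) {
  d <- read_checked_csv(path, c("tract_id", "year", "age_group", "cases"))
  out <- data.frame(
    tract_id = as.character(d$tract_id),
    year = numeric_column(d, "year", path, integer = TRUE, nonneg = FALSE),
    age_group = numeric_column(d, "age_group", path, integer = TRUE),
    cases = numeric_column(d, "cases", path, integer = TRUE),
    stringsAsFactors = FALSE)
  bad <- which(out$age_group < 1 | out$age_group > n_age_groups(scheme))
  if (length(bad)) {
    stop(sprintf("%s: 'age_group' outside scheme (1..%d) at line(s) %s",
      basename(path), n_age_groups(scheme),
      paste(utils::head(bad + 1L, 5), collapse = ", ")), call. = FALSE)
  }
  validate_cell_table(out, "case table")
  as_case_table(out, scheme)
}

as_case_table <- function(d, scheme) {
  attr(d, "scheme") <- scheme
  class(d) <- c("case_table", "data.frame")
  d
}

#' Read a population denominator table from CSV
#'
#' Same layout as [read_case_table()] with a `population` column
#' (non-negative, possibly fractional: intercensal estimates are real
#' numbers).
#'
#' @inheritParams read_case_table
#' @return A `pop_table` data frame with columns `tract_id`, `year`,
#'   `age_group`, `population`.
#' @export
read_population_table <- function(path, scheme = age_scheme()) {
  d <- read_checked_csv(path,
    c("tract_id", "year", "age_group", "population"))
  out <- data.frame(
    tract_id = as.character(d$tract_id),
    year = numeric_column(d, "year", path, integer = TRUE, nonneg = FALSE),
    age_group = numeric_column(d, "age_group", path, integer = TRUE),
    population = numeric_column(d, "population", path),
    stringsAsFactors = FALSE)
  validate_cell_table(out, "population table")
  attr(out, "scheme") <- scheme
  class(out) <- c("pop_table", "data.frame")
  out
}

#' Read a tract-level covariate table from CSV
#'
#' First column must be `tract_id`; every other column is treated as a
#' numeric covariate. Columns whose names contain `"percent"` (case
#' insensitive) are checked to lie in \[0, 100\].
#'
#' @param path CSV file path.
#' @return A data frame, one row per tract, `tract_id` first.
#' @export
read_covariate_table <- function(path) {
  d <- read_checked_csv(path, "tract_id")
  out <- data.frame(tract_id = as.character(d$tract_id),
    stringsAsFactors = FALSE)
  for (col in setdiff(names(d), "tract_id")) {
    x <- numeric_column(d, col, path, nonneg = FALSE)
    if (grepl("percent", col, ignore.case = TRUE) &&
        any(x < 0 | x > 100, na.rm = TRUE)) {
      stop(sprintf("%s: column '%s' must lie in [0, 100]",
        basename(path), col), call. = FALSE)
    }
    out[[col]] <- x
  }
  if (anyDuplicated(out$tract_id)) {
    stop("covariate table: duplicate tract_id", call. = FALSE)
  }
  out
}

#' Read an adjacency edge list from CSV
#'
#' Two columns `tract_a`, `tract_b`, one undirected edge per row.
#'
#' @param path CSV file path.
#' @param tract_ids Optional character vector of all tract ids (so that
#'   isolated tracts are represented).
#' @return An `adjacency` object (see [queen_adjacency()]).
#' @export
read_adjacency <- function(path, tract_ids = NULL) {
  d <- read_checked_csv(path, c("tract_a", "tract_b"))
  make_adjacency(as.character(d$tract_a), as.character(d$tract_b),
    tract_ids)
}

make_adjacency <- function(a, b, tract_ids = NULL) {
  if (any(a == b)) stop("adjacency: self-loops are not allowed",
    call. = FALSE)
  ids <- if (is.null(tract_ids)) sort(unique(c(a, b))) else
    as.character(tract_ids)
  unknown <- setdiff(c(a, b), ids)
  if (length(unknown)) {
    stop("adjacency: unknown tract id(s): ",
      paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  # canonical undirected edges, deduplicated
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  edges <- data.frame(tract_a = lo[keep], tract_b = hi[keep],
    stringsAsFactors = FALSE)
  nbr <- split(c(edges$tract_b, edges$tract_a),
    factor(c(edges$tract_a, edges$tract_b), levels = ids))
  nbr <- lapply(nbr, function(v) sort(unique(v)))
  structure(list(ids = ids, edges = edges, neighbors = nbr),
    class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  iso <- sum(lengths(x$neighbors) == 0)
  cat(sprintf("Adjacency graph: %d tracts, %d undirected edges%s\n",
    length(x$ids), nrow(x$edges),
    if (iso) sprintf(" (%d isolated)", iso) else ""))
  invisible(x)
}

#' Write an adjacency edge list to CSV
#' @param adj An `adjacency` object.
#' @param path Output CSV path.
#' @export
write_adjacency <- function(adj, path) {
  utils::write.csv(adj$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop case records falling in zero-population cells
#'
#' Registry QA filter: a case whose age at diagnosis falls in an age group
#' with zero estimated population for its tract and year indicates a likely
#' geocoding or coding error, and the cell would make rate denominators
#' undefined. Such records are removed and counted. Record-level filters
#' that act upstream of aggregation (non-invasive histology; cases not
#' uniquely matched to a tract) cannot be applied to aggregated counts; the
#' report carries slots for their counts so a complete exclusion accounting
#' can be assembled by the caller.
#'
#' The operation is idempotent: applying it twice changes nothing.
#'
#' @param cases A `case_table`.
#' @param pop A `pop_table` covering the same scheme and study period.
#' @param upstream Optional named list or vector with counts of cases
#'   already excluded upstream (e.g. `c(histology = 10, unmatched = 3)`).
#' @return A list with `cases` (the filtered `case_table`) and `report`
#'   (a data frame of exclusion criteria and case counts removed).
#' @export
apply_exclusions <- function(cases, pop, upstream = NULL) {
  key <- function(d) paste(d$tract_id, d$year, d$age_group, sep = "\r")
  popmap <- stats::setNames(pop$population, key(pop))
  p <- popmap[key(cases)]
  p[is.na(p)] <- 0
  drop <- p == 0 & cases$cases > 0
  # zero-case rows in zero-population cells are vacuous; drop them too so
  # downstream denominators never see an empty cell
  drop_empty <- p == 0 & cases$cases == 0
  out <- cases[!(drop | drop_empty), , drop = FALSE]
  rownames(out) <- NULL
  out <- as_case_table(out, attr(cases, "scheme"))
  report <- data.frame(
    criterion = c("histology", "unmatched_tract", "zero_population_cell"),
    cases_excluded = c(
      as.numeric(upstream[["histology"]] %||% 0),
      as.numeric(upstream[["unmatched"]] %||% 0),
      sum(cases$cases[drop])),
    stringsAsFactors = FALSE)
  list(cases = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
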