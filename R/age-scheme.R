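#' Age-group schemes for standardization
#'
#' An age scheme is an ordered set of contiguous, non-overlapping age bins
#' starting at age 0, with the last bin open-ended. Registry case and
#' population tables are indexed by position in such a scheme, and every
#' standardization routine takes the scheme (or a weight table keyed by it)
#' as an explicit argument: the scheme is data, not code.
#'
#' The default scheme has 16 bins (0-4, 5-9, ..., 60-64, 65-74, 75-84, 85+),
#' the grouping typically used when elderly strata are pooled to stabilise
#' rates in small areas. Classic 18-bin (5-year bins through 80-84) and
#' 19-bin (0, 1-4, then 5-year bins) schemes are also available by name.
#'
#' @param breaks Integer vector of lower bin bounds, starting at 0 and
#'   strictly increasing. The last bin is open-ended. Alternatively a
#'   single string naming a built-in scheme: `"16"`, `"18"` or `"19"`.
#' @return An object of class `age_scheme`: a data frame with columns
#'   `lower` (inclusive), `upper` (inclusive; `Inf` for the open last bin)
#'   and `label`.
#' @examples
#' age_scheme()           # the 16-bin default
#' age_scheme("19")       # 0, 1-4, 5-9, ... 85+
#' age_scheme(c(0, 18, 45, 65))
#' @export
age_scheme <- function(breaks = "16") {
  if (is.character(breaks)) {
    breaks <- switch(match.arg(breaks, c("16", "18", "19")),
      "16" = c(seq(0, 60, by = 5), 65, 75, 85),
      "18" = seq(0, 85, by = 5),
      "19" = c(0, 1, seq(5, 85, by = 5))
    )
  }
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1 || breaks[1] != 0) {
    stop("age scheme must start at age 0", call. = FALSE)
  }
  if (any(diff(breaks) <= 0)) {
    stop("age scheme breaks must be strictly increasing", call. = FALSE)
  }
  n <- length(breaks)
  upper <- c(breaks[-1] - 1, Inf)
  label <- ifelse(is.finite(upper),
    ifelse(breaks == upper, sprintf("%.0f", breaks),
      sprintf("%.0f-%.0f", breaks, upper)),
    sprintf("%.0f+", breaks))
  out <- data.frame(lower = breaks, upper = upper, label = label,
    stringsAsFactors = FALSE)
  class(out) <- c("age_scheme", "data.frame")
  out
}

#' @export
print.age_scheme <- function(x, ...) {
  cat(sprintf("Age scheme with %d bins: %s\n", nrow(x),
    paste(x$label, collapse = ", ")))
  invisible(x)
}

n_age_groups <- function(scheme) nrow(scheme)

#' Standard population weights for direct age standardization
#'
#' Returns the 2000 U.S. Standard Million Population aggregated to a named
#' age scheme: the notional count of persons, out of 1,000,000, in each age
#' bin. These are the fixed weights used by [direct_adjusted_rate()].
#'
#' @param scheme An [age_scheme()] built from one of the named schemes
#'   (`"16"`, `"18"` or `"19"`), or the name itself.
#' @return An object of class `standard_pop`: a data frame with columns
#'   `age_group` (bin index), `label` and `weight`; weights sum to
#'   1,000,000.
#' @examples
#' std <- standard_million()
#' sum(std$weight)   # 1e6
#' @export
standard_million <- function(scheme = "16") {
  # 2000 U.S. Standard Million (Census projected population), 19 age groups
  w19 <- c(13818, 55317, 72533, 73032, 72169, 66478, 64529, 71044, 80762,
           81851, 72118, 62716, 48454, 38793, 34264, 31773, 26999, 17842,
           15508)
  if (inherits(scheme, "age_scheme")) {
    scheme <- as.character(nrow(scheme))
  }
  scheme <- match.arg(as.character(scheme), c("16", "18", "19"))
  w <- switch(scheme,
    "19" = w19,
    # merge 0 and 1-4
    "18" = c(w19[1] + w19[2], w19[-(1:2)]),
    # additionally pool 65-69/70-74 and 75-79/80-84
    "16" = {
      w18 <- c(w19[1] + w19[2], w19[-(1:2)])
      c(w18[1:13], w18[14] + w18[15], w18[16] + w18[17], w18[18])
    }
  )
  sch <- age_scheme(scheme)
  out <- data.frame(age_group = seq_along(w), label = sch$label,
    weight = w, stringsAsFactors = FALSE)
  class(out) <- c("standard_pop", "data.frame")
  out
}

#' Read a standard population weight table from CSV
#'
#' Expects columns `age_group` (1-based bin index) and `weight`. Weights
#' must be non-negative and sum to 1,000,000 within a small relative
#' tolerance; arbitrary positive rescalings are accepted by
#' [direct_adjusted_rate()] itself, but a stored standard population is
#' validated against the standard-million convention.
#'
#' @param path CSV file path.
#' @param tol Relative tolerance on the sum (default `1e-6`).
#' @return A `standard_pop` data frame.
#' @export
read_standard_population <- function(path, tol = 1e-6) {
  d <- read_checked_csv(path, c("age_group", "weight"))
  d$age_group <- as.integer(d$age_group)
  d$weight <- as.numeric(d$weight)
  if (any(!is.finite(d$weight)) || any(d$weight < 0)) {
    stop("standard population: 'weight' must be finite and non-negative",
      call. = FALSE)
  }
  if (abs(sum(d$weight) - 1e6) > tol * 1e6) {
    stop("standard population weights must sum to 1,000,000", call. = FALSE)
  }
  d <- d[order(d$age_group), , drop = FALSE]
  if (!identical(d$age_group, seq_len(nrow(d)))) {
    stop("standard population: 'age_group' must be 1..K with no gaps",
      call. = FALSE)
  }
  rownames(d) <- NULL
  class(d) <- c("standard_pop", "data.frame")
  d
}
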