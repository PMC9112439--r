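# Direct and indirect (internal) age standardization, SIRs, and
# descriptive quantile trends of tract-level adjusted rates.

#' Directly age-standardized incidence rate
#'
#' Weighted average of age-specific rates using a fixed standard
#' population's age weights, expressed per 100,000:
#' \deqn{100{,}000 \times \sum_a w_a (c_a / p_a) / \sum_a w_a}
#' The convention \eqn{c_a/p_a = 0} applies when both the count and the
#' denominator are zero; a positive count over a zero denominator is an
#' error (the zero-population exclusion filter should have removed it).
#' The result is invariant to rescaling all weights by a positive
#' constant.
#'
#' @param cases_by_age,pop_by_age Numeric vectors over the age scheme.
#' @param std A `standard_pop` (see [standard_million()]) or a bare
#'   numeric weight vector of the same length.
#' @return The age-adjusted rate per 100,000 (scalar).
#' @examples
#' # two age groups, weights 60:40, rates 100 and 200 per 100,000
#' direct_adjusted_rate(c(1, 2), c(1000, 1000), c(600000, 400000))  # 140
#' @export
direct_adjusted_rate <- function(cases_by_age, pop_by_age,
                                 std = standard_million()) {
  w <- if (is.data.frame(std)) std$weight else as.numeric(std)
  k <- length(w)
  if (length(cases_by_age) != k || length(pop_by_age) != k) {
    stop("cases, population and standard weights must have equal length",
      call. = FALSE)
  }
  if (any(cases_by_age > 0 & pop_by_age == 0)) {
    stop("cases observed in an age group with zero population; ",
      "apply_exclusions() first", call. = FALSE)
  }
  r <- ifelse(pop_by_age > 0, cases_by_age / pop_by_age, 0)
  1e5 * sum(w * r) / sum(w)
}

#' Age-adjusted rates for every tract
#'
#' Convenience wrapper applying [direct_adjusted_rate()] tract by tract,
#' either pooled over the whole study period (`by_year = FALSE`, the map
#' product) or separately per calendar year (`by_year = TRUE`, the trend
#' product).
#'
#' @param cases A `case_table`.
#' @param pop A `pop_table`.
#' @param std Standard population weights.
#' @param by_year Compute per-year rates instead of pooled rates.
#' @return A data frame with `tract_id`, `rate` (per 100,000) and, when
#'   `by_year`, `year`.
#' @export
adjusted_rate_table <- function(cases, pop, std = standard_million(),
                                by_year = FALSE) {
  scheme <- attr(cases, "scheme") %||% age_scheme()
  K <- n_age_groups(scheme)
  w <- if (is.data.frame(std)) std$weight else as.numeric(std)
  if (length(w) != K) {
    stop("standard population does not match the age scheme",
      call. = FALSE)
  }
  grp <- function(d, count_col) {
    g <- if (by_year) paste(d$tract_id, d$year, sep = "\r") else d$tract_id
    rowsum(matrix_by_age(d, count_col, K), g)
  }
  C <- grp(cases, "cases")
  P <- grp(pop, "population")
  keys <- rownames(P)
  Cfull <- matrix(0, length(keys), K, dimnames = list(keys, NULL))
  Cfull[rownames(C), ] <- C
  rate <- vapply(keys, function(k) {
    direct_adjusted_rate(Cfull[k, ], P[k, ], w)
  }, numeric(1))
  if (by_year) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(
      tract_id = vapply(parts, `[`, "", 1),
      year = as.integer(vapply(parts, `[`, "", 2)),
      rate = unname(rate), stringsAsFactors = FALSE)
    out[order(out$tract_id, out$year), , drop = FALSE]
  } else {
    data.frame(tract_id = keys, rate = unname(rate),
      stringsAsFactors = FALSE)
  }
}

# spread a long (tract,year,age) table into rows x age-group columns
matrix_by_age <- function(d, col, K) {
  m <- matrix(0, nrow(d), K)
  m[cbind(seq_len(nrow(d)), d$age_group)] <- d[[col]]
  m
}

#' Internally standardized expected counts
#'
#' Indirect standardization against the study population itself: the
#' expected count for tract \eqn{i} in year \eqn{j} applies that year's
#' study-wide age-specific crude rates to the tract's own age structure,
#' \deqn{E_{ij} = \sum_a r_{aj}\, p_{ija}, \qquad
#'       r_{aj} = \frac{\sum_i O_{ija}}{\sum_i p_{ija}},}
#' computed separately per year. By construction the expected counts
#' conserve the observed total within every year
#' (\eqn{\sum_i E_{ij} = \sum_i O_{ij}}), which makes downstream scan
#' statistics scale-free and centers SIRs at 1.
#'
#' @param cases A `case_table` (exclusions applied).
#' @param pop A `pop_table` covering every case cell.
#' @return A data frame with `tract_id`, `year`, `expected`, covering
#'   every (tract, year) present in `pop`.
#' @export
internal_expected <- function(cases, pop) {
  scheme <- attr(cases, "scheme") %||% age_scheme()
  K <- n_age_groups(scheme)
  years <- sort(unique(pop$year))
  out <- NULL
  ckey <- paste(cases$tract_id, cases$year, cases$age_group, sep = "\r")
  cmap <- stats::setNames(cases$cases, ckey)
  for (yr in years) {
    p <- pop[pop$year == yr, , drop = FALSE]
    O_cell <- cmap[paste(p$tract_id, p$year, p$age_group, sep = "\r")]
    O_cell[is.na(O_cell)] <- 0
    O_a <- rowsum(O_cell, p$age_group)          # study-wide cases by age
    P_a <- rowsum(p$population, p$age_group)    # study-wide pop by age
    bad <- O_a > 0 & P_a == 0
    if (any(bad)) {
      stop(sprintf(
        "year %d: age group(s) %s have cases but zero total population",
        yr, paste(rownames(O_a)[bad], collapse = ", ")), call. = FALSE)
    }
    r_a <- ifelse(P_a > 0, O_a / P_a, 0)
    e_cell <- r_a[as.character(p$age_group), 1] * p$population
    E <- rowsum(e_cell, p$tract_id)
    out <- rbind(out, data.frame(tract_id = rownames(E), year = yr,
      expected = E[, 1], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Standardized incidence ratios
#'
#' SIR for each tract: total observed cases divided by total expected
#' cases, pooled over all study years. SIR > 1 indicates more cases than
#' the tract's age structure predicts. Tracts with zero expected count get
#' `SIR = NA` and are flagged.
#'
#' @param cases A `case_table`.
#' @param expected An expected-count table from [internal_expected()].
#' @return A data frame with `tract_id`, `observed`, `expected`, `sir`
#'   and logical `undefined`.
#' @examples
#' # a tract observing 30 cases where 6 were expected has SIR 5
#' @export
sir <- function(cases, expected) {
  O <- rowsum(cases$cases, cases$tract_id)
  E <- rowsum(expected$expected, expected$tract_id)
  ids <- rownames(E)
  Ofull <- stats::setNames(rep(0, length(ids)), ids)
  Ofull[rownames(O)] <- O[, 1]
  stray <- setdiff(rownames(O), ids)
  if (length(stray)) {
    stop("cases for tract(s) absent from the expected-count table: ",
      paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(tract_id = ids, observed = unname(Ofull),
    expected = unname(E[, 1]), stringsAsFactors = FALSE)
  out$undefined <- out$expected == 0
  out$sir <- ifelse(out$undefined, NA_real_, out$observed / out$expected)
  out[order(out$tract_id), c("tract_id", "observed", "expected", "sir",
    "undefined")]
}

#' Descriptive quantile trends in tract-level adjusted rates
#'
#' For each requested quantile level, computes the empirical quantile of
#' the per-tract age-adjusted rates within each calendar year (linear
#' interpolation between order statistics, `stats::quantile` type 7) and
#' fits an ordinary least-squares line to the (year, quantile) pairs. This
#' is a descriptive summary of the rate distribution's drift over time; it
#' deliberately carries no tract-level random effects, so the slopes are
#' population-level quantile trends, not subject-specific ones.
#'
#' @param rates A per-tract-per-year rate table
#'   ([adjusted_rate_table()] with `by_year = TRUE`).
#' @param taus Quantile levels (default the 50th, 75th, 80th and 90th
#'   percentiles).
#' @return A `quantile_trend` object: list with `by_year` (data frame of
#'   `year`, `tau`, `value`) and `trend` (data frame of `tau`,
#'   `intercept`, `slope` — rate units per calendar year).
#' @export
quantile_trend <- function(rates, taus = c(0.5, 0.75, 0.8, 0.9)) {
  if (length(unique(rates$year)) < 2) {
    stop("quantile_trend needs at least 2 distinct years", call. = FALSE)
  }
  years <- sort(unique(rates$year))
  by_year <- do.call(rbind, lapply(years, function(yr) {
    q <- stats::quantile(rates$rate[rates$year == yr], probs = taus,
      type = 7, names = FALSE)
    data.frame(year = yr, tau = taus, value = q)
  }))
  trend <- do.call(rbind, lapply(taus, function(tl) {
    d <- by_year[by_year$tau == tl, ]
    f <- stats::lm(value ~ year, data = d)
    data.frame(tau = tl, intercept = unname(stats::coef(f)[1]),
      slope = unname(stats::coef(f)[2]))
  }))
  structure(list(by_year = by_year, trend = trend, taus = taus),
    class = "quantile_trend")
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat("Quantile trends of age-adjusted rates (per 100,000 per year):\n")
  for (i in seq_len(nrow(x$trend))) {
    cat(sprintf("  tau = %.2f: slope %+.3f\n", x$trend$tau[i],
      x$trend$slope[i]))
  }
  invisible(x)
}

#' @export
plot.quantile_trend <- function(x, ...) {
  yl <- range(x$by_year$value)
  plot(NA, xlim = range(x$by_year$year), ylim = yl, xlab = "year",
    ylab = "rate per 100,000", main = "Quantile trends", ...)
  cols <- grDevices::hcl.colors(length(x$taus), "Dark 3")
  for (i in seq_along(x$taus)) {
    d <- x$by_year[x$by_year$tau == x$taus[i], ]
    graphics::lines(d$year, d$value, col = cols[i], lwd = 2)
    graphics::points(d$year, d$value, col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = sprintf("tau %.2f", x$taus),
    col = cols, lwd = 2, bty = "n")
  invisible(x)
}
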