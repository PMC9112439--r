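# Cylindrical space-time scan statistic: candidate enumeration, Poisson
# log-likelihood-ratio scoring, Monte Carlo inference, and non-overlapping
# secondary-cluster extraction.
#
# The candidate structure (circle orderings, deduplicated tract sets, the
# sparse set-by-tract aggregation matrix) depends only on geometry and the
# expected counts, so it is built once and reused across the hundreds of
# Monte Carlo replicates; each replicate costs one sparse matrix product
# plus vectorized scoring.

#' Poisson scan log-likelihood ratio
#'
#' The high-rate scan statistic for a window observing `O` of the study's
#' `N` cases where `E` were expected:
#' \deqn{LLR = O \ln(O/E) + (N-O) \ln\{(N-O)/(N-E)\}}
#' when `O > E`, and 0 otherwise (a deficit is no evidence of a
#' high-incidence cluster). `O = N` drops the second term (its limit is
#' zero). Because the expected counts are internally standardized
#' (\eqn{\sum E = N}), the statistic is scale-free.
#'
#' @param O Observed cases in the window (vectorized).
#' @param E Expected cases in the window; must satisfy `0 < E < N`.
#' @param N Total study cases.
#' @return The log-likelihood ratio (same length as `O`).
#' @examples
#' poisson_llr(4601, 3823, 73937)  # 78.6
#' poisson_llr(10, 5, 100)         # 2.0654
#' @export
poisson_llr <- function(O, E, N) {
  if (any(E <= 0) || any(E >= N)) {
    stop("poisson_llr requires 0 < E < N", call. = FALSE)
  }
  if (any(O < 0) || any(O > N)) {
    stop("poisson_llr requires 0 <= O <= N", call. = FALSE)
  }
  llr_vec(O, E, N)
}

# scoring kernel: permissive about degenerate windows (E >= N -> 0)
llr_vec <- function(O, E, N) {
  k <- max(length(O), length(E))
  O <- rep_len(O, k); E <- rep_len(E, k)
  out <- numeric(length(O))
  ok <- O > E & E > 0 & E < N
  if (any(ok)) {
    o <- O[ok]; e <- E[ok]
    second <- ifelse(o < N, (N - o) * log((N - o) / (N - e)), 0)
    out[ok] <- o * log(o / e) + second
  }
  out
}

#' Inside-versus-outside relative risk of a scan window
#'
#' The rate inside the window relative to the rate outside,
#' \eqn{(O/E) / \{(N-O)/(N-E)\}}. This exceeds the simple ratio `O/E`
#' whenever `O/E > 1`, because the window's excess depresses the outside
#' rate. Cluster reports carry both measures.
#'
#' @inheritParams poisson_llr
#' @return The adjusted relative risk.
#' @examples
#' adjusted_rr(3557, 2676, 73937)  # 1.35
#' adjusted_rr(4601, 3823, 73937)  # 1.22
#' @export
adjusted_rr <- function(O, E, N) {
  if (any(E <= 0) || any(E >= N)) {
    stop("adjusted_rr requires 0 < E < N", call. = FALSE)
  }
  if (any(O >= N)) {
    stop("adjusted_rr requires O < N", call. = FALSE)
  }
  (O / E) / ((N - O) / (N - E))
}

# aggregate a case table (or tract-year data) to a tracts x years matrix
# aligned with ids/years
tract_year_matrix <- function(tract_id, year, value, ids, years) {
  m <- matrix(0, length(ids), length(years),
    dimnames = list(ids, as.character(years)))
  i <- match(tract_id, ids)
  j <- match(year, years)
  if (anyNA(i) || anyNA(j)) {
    stop("tract or year outside the scan frame", call. = FALSE)
  }
  # accumulate (there may be several age groups per cell)
  for (k in seq_along(value)) m[i[k], j[k]] <- m[i[k], j[k]] + value[k]
  m
}

#' Enumerate candidate space-time cylinders
#'
#' For every tract, circles grow by adding the next-nearest centroid
#' (Euclidean distance; ties broken lexicographically by tract id) while
#' the circle's pooled expected count over the full study period stays
#' within `max_spatial_fraction` of the study total; the bare center is
#' always a candidate. Distinct tract sets arising from different centers
#' are kept once (first center in id order wins). Each retained set is
#' crossed with every contiguous year interval of length at most
#' `ceiling(max_temporal_fraction * T)`.
#'
#' @param geometry A `tract_geometry` (planar centroids).
#' @param expected Expected-count table from [internal_expected()].
#' @param max_spatial_fraction Cap on a circle's share of total expected
#'   cases (default 0.5).
#' @param max_temporal_fraction Cap on a cylinder's share of the study
#'   period (default 0.5).
#' @return A data frame with one row per cylinder: `set` (integer id of
#'   the tract set), `center`, `radius`, `n_tracts`, `year_start`,
#'   `year_end`, plus attribute `"sets"` — a list mapping set id to the
#'   member tract ids.
#' @export
enumerate_cylinders <- function(geometry, expected,
                                max_spatial_fraction = 0.5,
                                max_temporal_fraction = 0.5) {
  fr <- scan_frame(geometry, expected, max_spatial_fraction,
    max_temporal_fraction)
  base <- fr$sets_df[fr$cyl$set, c("center", "radius", "n_tracts")]
  out <- data.frame(
    set = fr$cyl$set,
    center = base$center,
    radius = base$radius,
    n_tracts = base$n_tracts,
    year_start = fr$years[fr$cyl$j1],
    year_end = fr$years[fr$cyl$j2],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sets") <- lapply(fr$members, function(ix) fr$ids[ix])
  out
}

# Precompute everything reusable across Monte Carlo replicates.
scan_frame <- function(geometry, expected, max_spatial_fraction = 0.5,
                       max_temporal_fraction = 0.5) {
  if (looks_geographic(geometry)) {
    stop("scan needs planar coordinates; see project_local()",
      call. = FALSE)
  }
  ids <- sort(geometry$ids)
  ord0 <- match(ids, geometry$ids)
  x <- geometry$x[ord0]; y <- geometry$y[ord0]
  years <- sort(unique(expected$year))
  Tn <- length(years)
  E <- tract_year_matrix(expected$tract_id, expected$year,
    expected$expected, ids, years)
  Etot <- rowSums(E)
  cap <- max_spatial_fraction * sum(Etot)
  n <- length(ids)

  members <- vector("list", 0)   # set id -> integer tract indices (sorted)
  set_center <- character(0); set_radius <- numeric(0)
  set_size <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (c0 in seq_len(n)) {
    d <- sqrt((x - x[c0])^2 + (y - y[c0])^2)
    # nearest first; ties by tract id (ids are already sorted)
    ordn <- order(d, seq_len(n))
    cumE <- cumsum(Etot[ordn])
    kmax <- max(1L, sum(cumE <= cap))
    for (k in seq_len(kmax)) {
      ix <- sort(ordn[seq_len(k)])
      key <- paste(ix, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      members[[length(members) + 1]] <- ix
      set_center <- c(set_center, ids[c0])
      set_radius <- c(set_radius, d[ordn[k]])
      set_size <- c(set_size, k)
    }
  }
  S <- length(members)
  sets_df <- data.frame(center = set_center, radius = set_radius,
    n_tracts = set_size, stringsAsFactors = FALSE)
  # sparse set-by-tract incidence matrix for fast aggregation
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(S), lengths(members)),
    j = unlist(members), x = 1, dims = c(S, n))

  Lmax <- max(1L, ceiling(max_temporal_fraction * Tn))
  j1 <- integer(0); j2 <- integer(0)
  for (l in seq_len(Lmax)) {
    if (l > Tn) break
    j1 <- c(j1, seq_len(Tn - l + 1))
    j2 <- c(j2, seq_len(Tn - l + 1) + l - 1)
  }
  cyl <- data.frame(
    set = rep(seq_len(S), times = length(j1)),
    j1 = rep(j1, each = S), j2 = rep(j2, each = S))

  # per-set expected counts, pooled per interval
  SE <- as.matrix(A %*% E)
  CE <- cbind(0, row_cumsum(SE))
  Ecyl <- CE[cbind(cyl$set, cyl$j2 + 1)] - CE[cbind(cyl$set, cyl$j1)]

  list(ids = ids, years = years, E = E, A = A, members = members,
    sets_df = sets_df, cyl = cyl, Ecyl = Ecyl,
    max_spatial_fraction = max_spatial_fraction,
    max_temporal_fraction = max_temporal_fraction)
}

# score every cylinder against a tracts x years observed matrix;
# returns llr vector (and pooled O if wanted)
row_cumsum <- function(m) {
  for (j in seq_len(ncol(m))[-1]) m[, j] <- m[, j - 1] + m[, j]
  m
}

score_frame <- function(fr, O, N, want_O = FALSE) {
  SO <- as.matrix(fr$A %*% O)
  CO <- cbind(0, row_cumsum(SO))
  Ocyl <- CO[cbind(fr$cyl$set, fr$cyl$j2 + 1)] -
    CO[cbind(fr$cyl$set, fr$cyl$j1)]
  llr <- llr_vec(Ocyl, fr$Ecyl, N)
  if (want_O) list(llr = llr, O = Ocyl) else llr
}

#' Score every candidate cylinder
#'
#' Enumerates the candidate cylinders ([enumerate_cylinders()]) and
#' returns each with its pooled observed and expected counts and Poisson
#' LLR — the full scored field underlying [st_scan()], sorted by
#' decreasing LLR with the scan's deterministic tie-breaks (fewer
#' tracts, then lexicographic center id, then earlier start year).
#'
#' @inheritParams st_scan
#' @return A data frame: `center`, `radius`, `n_tracts`, `year_start`,
#'   `year_end`, `observed`, `expected`, `llr`, with attribute `"sets"`
#'   mapping set ids to tract ids and column `set` joining to it.
#' @export
score_cylinders <- function(cases, expected, geometry,
                            max_spatial_fraction = 0.5,
                            max_temporal_fraction = 0.5) {
  fr <- scan_frame(geometry, expected, max_spatial_fraction,
    max_temporal_fraction)
  Oc <- rowsum(cases$cases, paste(cases$tract_id, cases$year,
    sep = "\r"))
  parts <- strsplit(rownames(Oc), "\r", fixed = TRUE)
  O <- tract_year_matrix(vapply(parts, `[`, "", 1),
    as.integer(vapply(parts, `[`, "", 2)), Oc[, 1], fr$ids, fr$years)
  sc <- score_frame(fr, O, sum(O), want_O = TRUE)
  out <- data.frame(
    set = fr$cyl$set,
    center = fr$sets_df$center[fr$cyl$set],
    radius = fr$sets_df$radius[fr$cyl$set],
    n_tracts = fr$sets_df$n_tracts[fr$cyl$set],
    year_start = fr$years[fr$cyl$j1],
    year_end = fr$years[fr$cyl$j2],
    observed = sc$O, expected = fr$Ecyl, llr = sc$llr,
    stringsAsFactors = FALSE)
  out <- out[order(-out$llr, out$n_tracts, out$center,
    out$year_start), ]
  rownames(out) <- NULL
  attr(out, "sets") <- lapply(fr$members, function(ix) fr$ids[ix])
  out
}

#' Space-time scan for high-incidence clusters
#'
#' Runs the full cylindrical scan: enumerates candidate cylinders
#' ([enumerate_cylinders()]), scores each with the Poisson
#' log-likelihood ratio using its pooled observed and expected counts,
#' identifies the most likely cluster (maximum LLR; ties broken toward
#' fewer tracts, then lexicographic center id), attaches Monte Carlo
#' p-values by redistributing the `N` observed cases multinomially over
#' all (tract, year) cells with probabilities proportional to the expected
#' counts, and greedily retains non-overlapping significant secondary
#' clusters in decreasing LLR order.
#'
#' @param cases A `case_table` (exclusions applied).
#' @param expected Expected counts from [internal_expected()]; must
#'   conserve the observed total.
#' @param geometry A `tract_geometry` with planar centroids.
#' @param pop Optional `pop_table` used to report each cluster's averaged
#'   annual population size.
#' @param max_spatial_fraction,max_temporal_fraction Window caps; see
#'   [enumerate_cylinders()].
#' @param replications Monte Carlo replicates `R` (default 999; p-values
#'   are multiples of `1/(R+1)`).
#' @param alpha Significance level for retaining clusters (default 0.05).
#' @param seed Integer seed governing the Monte Carlo replicates
#'   (mandatory for reproducibility).
#' @return An object of class `st_scan`: list with `clusters` (retained
#'   clusters, rank 1 the most likely), `best` (the most likely cluster
#'   regardless of significance), `N`, `replications`, `alpha`, `seed`,
#'   and `config`. Use `as.data.frame()` for the cluster report table.
#' @examples
#' sc <- sim_registry(sim_scenario_preset("small_test"))
#' res <- st_scan(sc$cases, sc$expected, sc$geometry, pop = sc$pop,
#'   replications = 99, seed = 1)
#' print(res)
#' @export
st_scan <- function(cases, expected, geometry, pop = NULL,
                    max_spatial_fraction = 0.5,
                    max_temporal_fraction = 0.5,
                    replications = 999, alpha = 0.05, seed) {
  if (missing(seed)) stop("st_scan requires an explicit seed",
    call. = FALSE)
  if (replications < 1) stop("replications must be >= 1", call. = FALSE)
  fr <- scan_frame(geometry, expected, max_spatial_fraction,
    max_temporal_fraction)
  Ocase <- rowsum(cases$cases, paste(cases$tract_id, cases$year,
    sep = "\r"))
  parts <- strsplit(rownames(Ocase), "\r", fixed = TRUE)
  O <- tract_year_matrix(
    vapply(parts, `[`, "", 1),
    as.integer(vapply(parts, `[`, "", 2)),
    Ocase[, 1], fr$ids, fr$years)
  N <- sum(O)
  if (N == 0) stop("scan requires at least one observed case",
    call. = FALSE)

  sc <- score_frame(fr, O, N, want_O = TRUE)
  maxima <- monte_carlo_maxima(fr, N, replications, seed)

  # Monte Carlo p per cylinder: rank of its LLR among replicate maxima
  p_of <- function(llr) (1 + sum(maxima >= llr)) / (replications + 1)

  # greedy non-overlapping extraction in decreasing LLR order
  nt <- fr$sets_df$n_tracts[fr$cyl$set]
  ctr <- fr$sets_df$center[fr$cyl$set]
  ord <- order(-sc$llr, nt, ctr, fr$cyl$j1)
  used <- logical(length(fr$ids))
  clusters <- list()
  best <- NULL
  for (k in ord) {
    if (sc$llr[k] <= 0 && length(clusters)) break
    ix <- fr$members[[fr$cyl$set[k]]]
    if (any(used[ix])) next
    p <- p_of(sc$llr[k])
    cl <- cluster_record(fr, sc, k, N, p, pop,
      rank = length(clusters) + 1L)
    if (is.null(best)) best <- cl
    if (p <= alpha) {
      clusters[[length(clusters) + 1]] <- cl
      used[ix] <- TRUE
    } else if (length(clusters) == 0) {
      break  # the most likely cluster itself is not significant
    } else {
      next
    }
    if (sc$llr[k] <= 0) break
  }
  structure(list(clusters = clusters, best = best, N = N,
    replications = replications, alpha = alpha, seed = seed,
    maxima = maxima,
    config = list(max_spatial_fraction = max_spatial_fraction,
      max_temporal_fraction = max_temporal_fraction)),
    class = "st_scan")
}

cluster_record <- function(fr, sc, k, N, p, pop, rank) {
  ix <- fr$members[[fr$cyl$set[k]]]
  tracts <- fr$ids[ix]
  ys <- fr$years[fr$cyl$j1[k]]; ye <- fr$years[fr$cyl$j2[k]]
  O <- sc$O[k]; E <- fr$Ecyl[k]
  avg_pop <- NA_real_
  if (!is.null(pop)) {
    pp <- pop[pop$tract_id %in% tracts & pop$year >= ys & pop$year <= ye, ]
    if (nrow(pp)) {
      avg_pop <- sum(pp$population) / length(unique(pp$year))
    }
  }
  list(rank = rank, tracts = tracts, center = fr$sets_df$center[fr$cyl$set[k]],
    radius = fr$sets_df$radius[fr$cyl$set[k]],
    year_start = ys, year_end = ye, observed = O, expected = E,
    rr = O / E,
    rr_adjusted = if (O < N && E > 0 && E < N) adjusted_rr(O, E, N)
      else NA_real_,
    llr = sc$llr[k], p_value = p, avg_population = avg_pop)
}

#' Monte Carlo null distribution of the maximum scan statistic
#'
#' Redistributes the `N` total cases across all (tract, year) cells by a
#' multinomial draw with probabilities proportional to the expected
#' counts (conditioning on `N`), re-scores every cylinder, and records the
#' maximum LLR per replicate.
#'
#' @keywords internal
monte_carlo_maxima <- function(fr, N, replications, seed) {
  set.seed(as.integer(seed))
  pr <- as.vector(fr$E) / sum(fr$E)
  dims <- dim(fr$E)
  vapply(seq_len(replications), function(r) {
    Orep <- matrix(stats::rmultinom(1, N, pr), dims[1], dims[2])
    max(score_frame(fr, Orep, N))
  }, numeric(1))
}

#' @export
print.st_scan <- function(x, ...) {
  cat(sprintf(
    "Space-time scan: N = %d cases, %d Monte Carlo replicates, alpha = %g\n",
    x$N, x$replications, x$alpha))
  if (!length(x$clusters)) {
    cat("No significant clusters.")
    if (!is.null(x$best)) {
      cat(sprintf(" Most likely cluster: LLR %.2f, p = %.3g\n",
        x$best$llr, x$best$p_value))
    } else cat("\n")
    return(invisible(x))
  }
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.st_scan <- function(object, ...) {
  print(object)
  invisible(as.data.frame(object))
}

#' Cluster report table
#'
#' One row per retained cluster: rank, detected years, tract count,
#' averaged population, observed and expected cases, simple and adjusted
#' relative risk, LLR, Monte Carlo p-value.
#'
#' @param x An `st_scan` object.
#' @param ... Unused.
#' @export
as.data.frame.st_scan <- function(x, ...) {
  if (!length(x$clusters)) {
    return(data.frame(rank = integer(0), years = character(0),
      n_tracts = integer(0), avg_population = numeric(0),
      observed = numeric(0), expected = numeric(0), rr = numeric(0),
      rr_adjusted = numeric(0), llr = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(rank = cl$rank,
      years = sprintf("%d-%d", cl$year_start, cl$year_end),
      n_tracts = length(cl$tracts), avg_population = cl$avg_population,
      observed = cl$observed, expected = cl$expected, rr = cl$rr,
      rr_adjusted = cl$rr_adjusted, llr = cl$llr, p_value = cl$p_value,
      stringsAsFactors = FALSE)
  }))
}

#' Write the cluster report to CSV
#' @param x An `st_scan` object.
#' @param path Output CSV path.
#' @export
write_cluster_report <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
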