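# Independent oracle implementations: deliberately simple, loop-based
# code paths used only to validate the package's vectorized ones.

# O(n^2) pairwise queen contiguity by explicit vertex comparison
queen_oracle <- function(geometry, snap = 1e-6) {
  ids <- geometry$ids
  n <- length(ids)
  snapv <- function(ring) {
    unique(round(ring / snap))
  }
  verts <- lapply(geometry$polygons[ids], snapv)
  hits <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vi <- verts[[i]]; vj <- verts[[j]]
    shared <- FALSE
    for (k in seq_len(nrow(vi))) {
      if (any(vj[, 1] == vi[k, 1] & vj[, 2] == vi[k, 2])) {
        shared <- TRUE; break
      }
    }
    if (shared) hits[[length(hits) + 1]] <- sort(c(ids[i], ids[j]))
  }
  if (!length(hits)) return(data.frame(tract_a = character(0),
    tract_b = character(0)))
  m <- do.call(rbind, hits)
  d <- data.frame(tract_a = m[, 1], tract_b = m[, 2],
    stringsAsFactors = FALSE)
  d[order(d$tract_a, d$tract_b), ]
}

# term-by-term Poisson log-likelihood for the space-time model
poisson_loglik_oracle <- function(O, E, logRR) {
  total <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    mu <- E[i, j] * exp(logRR[i, j])
    total <- total + dpois(O[i, j], mu, log = TRUE)
  }
  total
}

# scan LLR written as an explicit likelihood ratio of two Poisson fits
llr_oracle <- function(O, E, N) {
  if (O <= E) return(0)
  inside <- O * log(O / E)
  outside <- if (O < N) (N - O) * log((N - O) / (N - E)) else 0
  inside + outside
}

# brute-force space-time scan: exhaustive loops, no shared code with the
# package's scan path
brute_scan <- function(cases, expected, geometry,
                       max_spatial_fraction = 0.5,
                       max_temporal_fraction = 0.5) {
  ids <- sort(geometry$ids)
  x <- geometry$x[match(ids, geometry$ids)]
  y <- geometry$y[match(ids, geometry$ids)]
  years <- sort(unique(expected$year))
  Tn <- length(years)
  Ecell <- matrix(0, length(ids), Tn, dimnames = list(ids, years))
  for (r in seq_len(nrow(expected))) {
    Ecell[expected$tract_id[r], as.character(expected$year[r])] <-
      Ecell[expected$tract_id[r], as.character(expected$year[r])] +
      expected$expected[r]
  }
  Ocell <- matrix(0, length(ids), Tn, dimnames = list(ids, years))
  cd <- as.data.frame(cases)
  for (r in seq_len(nrow(cd))) {
    Ocell[cd$tract_id[r], as.character(cd$year[r])] <-
      Ocell[cd$tract_id[r], as.character(cd$year[r])] + cd$cases[r]
  }
  N <- sum(Ocell)
  cap <- max_spatial_fraction * sum(Ecell)
  Lmax <- max(1, ceiling(max_temporal_fraction * Tn))
  seen <- character(0)
  rows <- list()
  for (c0 in seq_along(ids)) {
    d <- sqrt((x - x[c0])^2 + (y - y[c0])^2)
    ordn <- order(d, seq_along(ids))
    for (k in seq_along(ids)) {
      members <- sort(ordn[seq_len(k)])
      Eset <- sum(Ecell[members, , drop = FALSE])
      if (k > 1 && Eset > cap) break
      key <- paste(members, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      for (l in seq_len(min(Lmax, Tn))) {
        for (j1 in seq_len(Tn - l + 1)) {
          j2 <- j1 + l - 1
          Oin <- sum(Ocell[members, j1:j2, drop = FALSE])
          Ein <- sum(Ecell[members, j1:j2, drop = FALSE])
          llr <- if (Ein > 0 && Ein < N) llr_oracle(Oin, Ein, N) else 0
          rows[[length(rows) + 1]] <- list(
            key = key, center = ids[c0], n_tracts = k,
            year_start = years[j1], year_end = years[j2],
            O = Oin, E = Ein, llr = llr)
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame,
    stringsAsFactors = FALSE))
  out[order(-out$llr, out$n_tracts, out$center, out$year_start), ]
}

# two-pass summation SIR oracle
sir_oracle <- function(cases, expected) {
  ids <- sort(unique(expected$tract_id))
  sapply(ids, function(id) {
    O <- sum(cases$cases[cases$tract_id == id])
    E <- sum(expected$expected[expected$tract_id == id])
    if (E == 0) NA_real_ else O / E
  })
}
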