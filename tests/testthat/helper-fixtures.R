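# Small fixtures built in code.

# a case/population pair on a tiny lattice, one age group, handy for
# exercising standardization identities by hand
tiny_tables <- function(tracts = c("A", "B"), years = 2010,
                        pops = c(100, 300), cases = c(2, 6)) {
  scheme <- age_scheme(c(0))
  cs <- data.frame(tract_id = rep(tracts, times = length(years)),
    year = rep(years, each = length(tracts)),
    age_group = 1L,
    cases = rep_len(cases, length(tracts) * length(years)),
    stringsAsFactors = FALSE)
  pp <- cs
  pp$cases <- NULL
  pp$population <- rep_len(pops, nrow(pp))
  attr(cs, "scheme") <- scheme
  class(cs) <- c("case_table", "data.frame")
  attr(pp, "scheme") <- scheme
  class(pp) <- c("pop_table", "data.frame")
  list(cases = cs, pop = pp, scheme = scheme)
}

# write a data frame to a temp CSV and return the path
tmp_csv <- function(d) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(d, f, row.names = FALSE, quote = FALSE)
  f
}

# a deterministic multi-age fixture with known structure
demo_registry <- function(seed = 42, nrow = 3, ncol = 3,
                          years = 2010:2012) {
  sim_registry(sim_scenario(nrow = nrow, ncol = ncol, years = years,
    seed = seed))
}
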