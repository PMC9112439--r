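test_that("model spec collapses degenerate dimensions and echoes priors", {
  t1 <- tiny_tables(tracts = "solo", pops = 500, cases = 9)
  E1 <- internal_expected(t1$cases, t1$pop)
  adj <- scanmap:::make_adjacency(character(0), character(0), "solo")
  spec <- stpois_spec(t1$cases, E1, adj,
    priors = list(alpha_sd = 3, sigma_u_scale = 0.7))
  expect_false(spec$has_u)
  expect_false(spec$has_beta)
  expect_false(spec$has_delta)
  expect_equal(spec$priors$alpha_sd, 3)
  expect_equal(spec$priors$sigma_u_scale, 0.7)
  expect_equal(spec$priors$beta_sd, 10)  # default retained

  # observed cases with zero expected count refuse to build
  E1$expected <- 0
  expect_error(stpois_spec(t1$cases, E1, adj), "zero expected")
})

test_that("CAR structure follows the queen graph Laplacian", {
  sc <- demo_registry(seed = 12)
  spec <- stpois_spec(sc$cases, sc$expected, sc$adjacency)
  # neighbor lists in the spec match an independent edge-count oracle
  or <- queen_oracle(sc$geometry)
  deg_oracle <- table(factor(c(or$tract_a, or$tract_b),
    levels = spec$ids))
  expect_equal(lengths(spec$nbr), as.vector(deg_oracle),
    ignore_attr = TRUE)
  # colouring is proper: no edge within a colour class
  for (i in seq_along(spec$ids)) {
    for (j in spec$nbr[[i]]) {
      expect_true(spec$colors[i] != spec$colors[j])
    }
  }
})

test_that("Poisson likelihood matches a term-by-term oracle", {
  set.seed(33)
  n <- 4; Tn <- 3
  O <- matrix(rpois(n * Tn, 5), n, Tn)
  E <- matrix(runif(n * Tn, 1, 10), n, Tn)
  logRR <- matrix(rnorm(n * Tn, 0, 0.3), n, Tn)
  mine <- sum(stats::dpois(O, E * exp(logRR), log = TRUE))
  expect_equal(mine, poisson_loglik_oracle(O, E, logRR),
    tolerance = 1e-10)
})

test_that("the sampler is deterministic given a seed", {
  sc <- demo_registry(seed = 13)
  f1 <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    iterations = 400, burn_in = 100, seed = 7)
  f2 <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    iterations = 400, burn_in = 100, seed = 7)
  expect_identical(f1$scalars, f2$scalars)
  expect_identical(f1$rr, f2$rr)
})

test_that("near-null data yield posterior RR close to 1 and no drift", {
  # large expected counts per cell, flat risk
  scn <- sim_scenario(nrow = 4, ncol = 4, years = 2010:2013,
    pop_scale = 4e5, pop_sdlog = 0.05, seed = 44)
  sc <- sim_registry(scn)
  expect_true(all(sc$expected$expected >= 100))
  fit <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    iterations = 2500, burn_in = 500, seed = 10)
  rr <- fit$rr$rr
  expect_true(mean(rr > 0.8 & rr < 1.25) >= 0.95)
  # identifiability: the spatial field stays centered
  expect_lt(abs(mean(fit$u$mean)), 0.05)
  # quantile ordering in every reported summary
  expect_true(all(fit$rr$q2.5 <= fit$rr$q97.5))
  expect_true(all(fit$rr$rr > 0))
})

test_that("no-interaction fits give exactly parallel log-RR profiles", {
  sc <- demo_registry(seed = 14)
  fit <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    interaction = FALSE, iterations = 600, burn_in = 200, seed = 3)
  prof <- rr_decile_profiles(fit)
  # pairwise log-differences between deciles constant across years
  wide <- stats::reshape(prof, idvar = "decile", timevar = "year",
    direction = "wide")
  lw <- log(as.matrix(wide[, -1]))
  for (i in 2:nrow(lw)) {
    d <- lw[i, ] - lw[1, ]
    expect_lt(max(d) - min(d), 1e-9)
  }

  # cell-level surfaces parallel too
  rr <- fit$rr
  m <- matrix(rr$log_rr, nrow = length(unique(rr$tract_id)))
  centered <- sweep(m, 2, m[1, ])
  expect_lt(max(apply(centered, 1, function(z) diff(range(z)))), 1e-9)
})

test_that("decile profiles match an independent groupby-median oracle", {
  sc <- sim_registry(sim_scenario(nrow = 4, ncol = 5, seed = 15))
  fit <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    iterations = 600, burn_in = 200, seed = 5)
  prof <- rr_decile_profiles(fit)
  rr <- fit$rr
  rr$est <- exp(rr$log_rr)
  yr1 <- min(rr$year)
  first <- rr[rr$year == yr1, ]
  br <- stats::quantile(first$est, probs = seq(0, 1, 0.1), type = 7)
  br[1] <- -Inf; br[length(br)] <- Inf
  dec <- cut(first$est, breaks = br, labels = FALSE)
  for (d in unique(dec)) for (yr in unique(rr$year)) {
    ids <- first$tract_id[dec == d]
    expect_equal(
      prof$median_rr[prof$decile == d & prof$year == yr],
      stats::median(rr$est[rr$tract_id %in% ids & rr$year == yr]))
  }
})

test_that("prior-only sampling recovers prior moments", {
  sc <- demo_registry(seed = 16)
  spec <- stpois_spec(sc$cases, sc$expected, sc$adjacency,
    priors = list(alpha_sd = 2, beta_sd = 1))
  fit <- fit_mcmc(spec, iterations = 20000, burn_in = 2000, seed = 11,
    likelihood = FALSE)
  # diffuse normal priors on alpha, beta
  expect_equal(mean(fit$samples$alpha), 0, tolerance = 0.35)
  expect_equal(stats::sd(fit$samples$alpha), 2, tolerance = 0.3)
  expect_equal(stats::sd(fit$samples$beta), 1, tolerance = 0.2)
  # half-normal(1) on sigma_delta: mean sqrt(2/pi)
  expect_equal(mean(fit$samples$sigma_delta), sqrt(2 / pi),
    tolerance = 0.25)
})

test_that("interaction assessment separates null and alternative", {
  run <- function(sigma_delta, seed) {
    scn <- sim_scenario(nrow = 5, ncol = 5, pop_scale = 8000,
      sigma_delta = sigma_delta, seed = seed)
    sc <- sim_registry(scn)
    f1 <- st_poisson(sc$cases, sc$expected, sc$adjacency,
      iterations = 1500, burn_in = 500, seed = seed)
    f0 <- st_poisson(sc$cases, sc$expected, sc$adjacency,
      interaction = FALSE, iterations = 1500, burn_in = 500,
      seed = seed)
    interaction_assessment(f1, f0)
  }
  null_calls <- vapply(1:5, function(s) run(0, 100 + s)$interaction,
    logical(1))
  alt_calls <- vapply(1:5, function(s) run(0.5, 200 + s)$interaction,
    logical(1))
  expect_true(sum(!null_calls) >= 4)
  expect_true(sum(alt_calls) >= 4)

  # same fit twice: zero DIC difference, no interaction claimed
  sc <- demo_registry(seed = 17)
  f1 <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    iterations = 600, burn_in = 200, seed = 2)
  ia <- interaction_assessment(f1, f1)
  expect_equal(ia$dic_diff, 0)

  # mismatched data fingerprints error
  sc2 <- demo_registry(seed = 18)
  f2 <- st_poisson(sc2$cases, sc2$expected, sc2$adjacency,
    iterations = 600, burn_in = 200, seed = 2)
  expect_error(interaction_assessment(f1, f2), "identical data")
})

test_that("fit methods expose coefficients, fits, residuals, simulations", {
  sc <- demo_registry(seed = 19)
  fit <- st_poisson(sc$cases, sc$expected, sc$adjacency,
    iterations = 600, burn_in = 200, seed = 4)
  cf <- coef(fit)
  expect_true(all(c("alpha", "beta", "sigma_u", "sigma_delta") %in%
    names(cf)))
  f <- fitted(fit)
  expect_equal(nrow(f), 9 * 3)
  r <- residuals(fit)
  expect_equal(nrow(r), nrow(f))
  s <- simulate(fit, nsim = 2, seed = 1)
  expect_true(all(s$sim_1 >= 0))
  expect_equal(names(s), c("tract_id", "year", "sim_1", "sim_2"))
})
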