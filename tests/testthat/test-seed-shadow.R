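test_that("basal area and fecundity follow the size model", {
  expect_equal(basal_area(10), pi * 25)
  expect_equal(basal_area(2), pi)
  d <- seq(1, 50, by = 0.5)
  expect_true(all(diff(basal_area(d)) > 0))
  expect_equal(fecundity(0.1, 10), 0.1 * pi * 25)
  expect_equal(fecundity(0, 10), 0)
  expect_equal(fecundity(0.4, 7), 2 * fecundity(0.2, 7))
  expect_error(basal_area(-3), "positive")
})

test_that("expected trap count sums per-tree seed shadows", {
  k <- dispersal_kernel("negative_exponential", b1 = 10)
  tree <- tibble::tibble(x = 0, y = 0, dbh = 10)
  trap <- list(x = 10, y = 0, area = 0.5)
  lam <- expected_trap_count(tree, trap, beta = 0.1, kernel = k,
                             years = 10, dbh_r = 5)
  expect_equal(lam, 10 * 0.5 * 0.1 * basal_area(10) * exp(-1) /
                 (2 * pi * 100), tolerance = 1e-12)
  # below the reproductive threshold nothing contributes
  expect_equal(expected_trap_count(tibble::tibble(x = 0, y = 0, dbh = 4),
                                   trap, 0.1, k, 10, dbh_r = 5), 0)
  # linearity: duplicated tree doubles the expectation
  two <- dplyr::bind_rows(tree, tree)
  expect_equal(expected_trap_count(two, trap, 0.1, k, 10, 5), 2 * lam)
  expect_warning(
    expected_trap_count(tree, trap, 0.1, k, 10, 5, plot = c(5, 5)),
    "outside")
})

test_that("the Poisson likelihood matches a brute-force double loop", {
  ds <- toy_dataset()
  k <- dispersal_kernel("lognormal", b1 = 14, b2 = 0.6)
  for (beta in c(0.05, 1, 20)) {
    got <- seed_nll(c(log(beta), log(14), log(0.6)), ds, "AA", "lognormal")
    want <- oracle_seed_nll(beta, k, ds$trees, ds$traps,
                            c(3, 0, 7), ds$years, dbh_r = 5)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # single-trap closed form: lambda = 2, n = 3
  expect_equal(2 - 3 * log(2) + log(6),
               cctradeoff:::poisson_nll_terms(2, 3))
  # all-zero counts reduce to the total intensity
  ds0 <- toy_dataset(counts = c(0L, 0L, 0L))
  lam <- sapply(seq_len(3), function(i) {
    expected_trap_count(ds0$trees, as.list(ds0$traps[i, ]), 0.5, k, 10, 5)
  })
  expect_equal(seed_nll(c(log(0.5), log(14), log(0.6)), ds0, "AA",
                        "lognormal"),
               sum(lam), tolerance = 1e-10)
})

test_that("expected counts scale exactly with years, area and beta", {
  ds <- toy_dataset()
  k <- dispersal_kernel("weibull", b1 = 12, b2 = 1.4)
  trap <- as.list(ds$traps[1, ])
  base <- expected_trap_count(ds$trees, trap, 0.2, k, 10, 5)
  expect_equal(expected_trap_count(ds$trees, trap, 0.2, k, 20, 5), 2 * base)
  expect_equal(expected_trap_count(ds$trees, trap, 0.4, k, 10, 5), 2 * base)
  trap2 <- trap; trap2$area <- 1.5
  expect_equal(expected_trap_count(ds$trees, trap2, 0.2, k, 10, 5), 3 * base)
})

test_that("the MLE recovers generating parameters on simulated seed rain", {
  set.seed(31)
  n <- 300
  trees <- tibble::tibble(id = paste0("t", 1:n), species = "SP",
                          x = runif(n, 0, 500), y = runif(n, 0, 400),
                          dbh = pmin(exp(rnorm(n, log(10), 0.6)) + 1, 80))
  traps <- tibble::tibble(id = paste0("k", 1:149),
                          x = runif(149, 0, 500), y = runif(149, 0, 400),
                          area = 0.5)
  k_true <- dispersal_kernel("negative_exponential", b1 = 15)
  counts <- simulate_seed_rain(trees, traps, beta = 20, kernel = k_true,
                               years = 10, dbh_r = 5, seed = 5,
                               species = "SP")
  ds <- seed_dataset(trees, traps, counts,
                     tibble::tibble(species = "SP", dbh_r = 5, dbh_m = 80),
                     years = 10)
  fit <- fit_seed_shadow(ds, "SP", "negative_exponential")
  expect_true(fit$converged)
  expect_equal(fit$beta, 20, tolerance = 0.15)
  expect_equal(unname(fit$kernel$params["b1"]), 15, tolerance = 0.15)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$logLik)
  # the optimum beats every grid start
  for (s in cctradeoff:::kernel_start_grid("negative_exponential")) {
    nll_start <- cctradeoff:::profile_fit(
      cctradeoff:::shadow_prep(ds, "SP"), "negative_exponential",
      starts = list(s), fast = TRUE)$nll
    expect_lte(-fit$logLik, nll_start + 1e-6)
  }
})

test_that("a more flexible family never fits worse at the optimum", {
  set.seed(77)
  n <- 400
  trees <- tibble::tibble(id = paste0("t", 1:n), species = "SP",
                          x = runif(n, 0, 500), y = runif(n, 0, 400),
                          dbh = pmin(exp(rnorm(n, log(12), 0.5)) + 1, 80))
  traps <- tibble::tibble(id = paste0("k", 1:149),
                          x = runif(149, 0, 500), y = runif(149, 0, 400),
                          area = 0.5)
  k_true <- dispersal_kernel("two_dim_t", b1 = 200, b2 = 1)
  counts <- simulate_seed_rain(trees, traps, beta = 30, kernel = k_true,
                               years = 10, dbh_r = 5, seed = 9,
                               species = "SP")
  ds <- seed_dataset(trees, traps, counts,
                     tibble::tibble(species = "SP", dbh_r = 5, dbh_m = 80),
                     years = 10)
  f2dt <- fit_seed_shadow(ds, "SP", "two_dim_t")
  fexp <- fit_seed_shadow(ds, "SP", "negative_exponential")
  expect_gte(f2dt$logLik, fexp$logLik - 1e-6)
})

test_that("AIC selection takes the minimum with documented tie-breaks", {
  mk <- function(fam, aic, npar) {
    structure(list(species = "SP", family = fam, aic = aic,
                   n_params = npar),
              class = "seed_shadow_fit")
  }
  fits <- list(mk("negative_exponential", 210, 2L), mk("two_dim_t", 205.3, 3L),
               mk("lognormal", 206, 3L), mk("weibull", 209.1, 3L))
  expect_equal(select_best_kernel(fits)$family, "two_dim_t")
  # exact tie: fewer parameters wins
  tie <- list(mk("lognormal", 200, 3L), mk("negative_exponential", 200, 2L))
  expect_equal(select_best_kernel(tie)$family, "negative_exponential")
  # tie at equal parameter count: fixed family order
  tie2 <- list(mk("weibull", 200, 3L), mk("two_dim_t", 200, 3L))
  expect_equal(select_best_kernel(tie2)$family, "two_dim_t")
  expect_error(select_best_kernel(list()), "no converged fits")
})

test_that("datasets are validated and species screened by the seed rule", {
  ds <- toy_dataset()
  expect_error(seed_dataset(ds$trees[, -1], ds$traps, ds$counts,
                            ds$species_meta),
               "missing column")
  bad_trees <- ds$trees; bad_trees$dbh[1] <- 0.5
  expect_error(seed_dataset(bad_trees, ds$traps, ds$counts,
                            ds$species_meta, plot = c(100, 100)),
               "DBH >= 1")
  bad_counts <- ds$counts; bad_counts$count[1] <- -2L
  expect_error(seed_dataset(ds$trees, ds$traps, bad_counts,
                            ds$species_meta, plot = c(100, 100)),
               "non-negative")
  scr <- include_species(ds, min_seeds = 10, min_traps = 2)
  expect_true(scr$included[1])    # 10 seeds in 2 traps meets both bars
  expect_identical(scr$total_seeds[1], 10L)
  expect_identical(scr$n_traps_present[1], 2L)
  expect_false(include_species(ds, 11, 2)$included[1])
  expect_false(include_species(ds, 10, 3)$included[1])
  expect_error(fit_seed_shadow(toy_dataset(c(0L, 0L, 0L)), "AA",
                               "weibull"),
               "no seeds")
})
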