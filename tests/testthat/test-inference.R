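# one small community reused across the bootstrap tests
local_sim <- local({
  cfg <- community_config(n_species = 4, stem_scale = 0.6, seed = 73)
  generate_community(cfg, n_gap_placements = 50)
})

test_that("bootstrap CIs honor the 2.5/97.5 percentile convention", {
  reps <- tibble::tibble(replicate = 1:100, quantity = "q",
                         value = as.numeric(1:100))
  ci <- boot_ci(reps)
  expect_equal(ci$lower, unname(quantile(1:100, 0.025, type = 7)))
  expect_equal(ci$upper, unname(quantile(1:100, 0.975, type = 7)))
  expect_equal(ci$mean, 50.5)
})

test_that("the trap bootstrap is reproducible and brackets the estimate", {
  ds <- local_sim$dataset
  sp <- local_sim$ground_truth$species[1]
  fam <- local_sim$ground_truth$family[1]
  b1 <- bootstrap_seed_traps(ds, sp, fam, n_boot = 60, seed = 42)
  b2 <- bootstrap_seed_traps(ds, sp, fam, n_boot = 60, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  ci <- boot_ci(b1)
  expect_true(all(ci$lower <= ci$upper))
  # the full-data MLE sits inside its own bootstrap CI for beta
  beta_ci <- ci[ci$quantity == "beta", ]
  expect_gte(b1$baseline$beta, beta_ci$lower * 0.8)
  expect_lte(b1$baseline$beta, beta_ci$upper * 1.2)
  # derived quantities present at every requested diameter
  expect_setequal(unique(b1$replicates$quantity),
                  c("beta", "b1", "b2", "ldd", "p_g",
                    "inv_t_dbh5", "inv_t_dbh10", "inv_t_dbh20"))
})

test_that("more traps give tighter fecundity intervals", {
  make_ds <- function(n_traps, seed) {
    set.seed(seed)
    n <- 250
    trees <- tibble::tibble(id = paste0("t", 1:n), species = "SP",
                            x = runif(n, 0, 500), y = runif(n, 0, 400),
                            dbh = pmin(exp(rnorm(n, log(10), 0.6)) + 1, 80))
    traps <- tibble::tibble(id = paste0("k", seq_len(n_traps)),
                            x = runif(n_traps, 0, 500),
                            y = runif(n_traps, 0, 400), area = 0.5)
    k <- dispersal_kernel("negative_exponential", b1 = 15)
    counts <- simulate_seed_rain(trees, traps, 20, k, 10, 5, seed = seed,
                                 species = "SP")
    seed_dataset(trees, traps, counts,
                 tibble::tibble(species = "SP", dbh_r = 5, dbh_m = 80),
                 years = 10)
  }
  w <- vapply(c(40, 160), function(nt) {
    b <- bootstrap_seed_traps(make_ds(nt, seed = 3), "SP",
                              "negative_exponential", n_boot = 120,
                              seed = 5)
    ci <- boot_ci(b)
    diff(unlist(ci[ci$quantity == "beta", c("lower", "upper")]))
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("the quadrat bootstrap preserves spatial structure", {
  # plant strong quadrat-level survival heterogeneity; resampling quadrats
  # must acknowledge it with wider coefficient CIs than a per-tree bootstrap
  set.seed(55)
  n <- 2500
  d <- tibble::tibble(x = runif(n, 0, 500), y = runif(n, 0, 400),
                      dbh = exp(rnorm(n, log(8), 0.5)) + 1,
                      nc = rnorm(n, 4, 1), edge_ok = TRUE,
                      quadrat = paste(floor(x / 20), floor(y / 20)))
  re <- rnorm(length(unique(d$quadrat)), 0, 1.5)
  names(re) <- unique(d$quadrat)
  eta <- 1.5 + 0.05 * d$dbh - 0.4 * d$nc + re[d$quadrat]
  d$survived <- runif(n) < 1 / (1 + exp(-eta))
  qb <- bootstrap_quadrats(d, nc_high = 6, n_boot = 150, seed = 8,
                           species = "SP")
  ci_q <- boot_ci(qb)
  # naive per-tree bootstrap for comparison
  set.seed(9)
  naive <- replicate(150, {
    idx <- sample.int(n, n, replace = TRUE)
    fit_survival(d[idx, ], min_obs = 20)$coef[["nc"]]
  })
  w_naive <- diff(unname(quantile(naive, c(0.025, 0.975), type = 7)))
  w_quad <- diff(unlist(ci_q[ci_q$quantity == "coef_nc",
                             c("lower", "upper")]))
  expect_gt(w_quad, w_naive)
})

test_that("quadrat bootstrap needs at least two occupied quadrats", {
  d <- tibble::tibble(x = runif(30, 0, 10), y = runif(30, 0, 10),
                      dbh = runif(30, 2, 20), nc = rnorm(30, 4),
                      edge_ok = TRUE,
                      survived = rep(c(TRUE, FALSE), 15))
  expect_error(bootstrap_quadrats(d, nc_high = 5, n_boot = 10, seed = 1),
               "fewer than 2 quadrats")
})

test_that("SOR replicates are refused above the species maximum size", {
  set.seed(14)
  n <- 800
  d <- tibble::tibble(x = runif(n, 0, 500), y = runif(n, 0, 400),
                      dbh = runif(n, 2, 30), nc = rnorm(n, 4, 1),
                      edge_ok = TRUE)
  d$survived <- runif(n) < 0.8
  qb <- bootstrap_quadrats(d, nc_high = 5, n_boot = 30, seed = 2,
                           dbh = c(5, 10, 20), dbh_m = 15)
  # dbh 20 exceeds dbh_m = 15: no sor_dbh20 quantity
  expect_false("sor_dbh20" %in% qb$replicates$quantity)
  expect_true(all(c("sor_dbh5", "sor_dbh10") %in% qb$replicates$quantity))
})

test_that("paired draws from point masses collapse to the plain correlation", {
  a <- tibble::tibble(species = rep(c("A", "B", "C", "D"), each = 5),
                      value = rep(c(1, 2, 3, 4), each = 5))
  b <- tibble::tibble(species = rep(c("A", "B", "C", "D"), each = 5),
                      value = rep(c(8, 6, 4, 2), each = 5))
  cr <- paired_bootstrap_correlation(a, b, n_draw = 200, seed = 1)
  expect_equal(cr$r, -1)
  expect_equal(cr$ci_lower, -1)
  expect_equal(cr$ci_upper, -1)
  expect_true(cr$significant)
  expect_true(cr$negative_significant)
})

test_that("correlation significance mirrors the CI-excludes-zero rule", {
  set.seed(100)
  mk <- function(truth, noise) {
    purrr::map_dfr(seq_along(truth), function(i) {
      tibble::tibble(species = LETTERS[i],
                     value = truth[i] + rnorm(200, 0, noise))
    })
  }
  # strong planted association across 10 species, small uncertainty
  x <- rnorm(10)
  boot_a <- mk(x, 0.05)
  boot_b <- mk(-2 * x, 0.05)
  cr <- paired_bootstrap_correlation(boot_a, boot_b, n_draw = 400, seed = 3)
  expect_true(cr$negative_significant)
  expect_identical(cr$significant, cr$ci_lower > 0 || cr$ci_upper < 0)
  expect_true(all(abs(cr$r_draws) <= 1, na.rm = TRUE))
  # identical seeds reproduce the draws exactly
  cr2 <- paired_bootstrap_correlation(boot_a, boot_b, n_draw = 400, seed = 3)
  expect_identical(cr$r_draws, cr2$r_draws)
  expect_error(paired_bootstrap_correlation(mk(x[1:2], 0.1), mk(x[1:2], 0.1)),
               "fewer than 3")
})

test_that("spearman draws are supported and bounded", {
  set.seed(6)
  a <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(species = LETTERS[i], value = rlnorm(50, i / 2, 0.2))
  })
  b <- purrr::map_dfr(1:6, function(i) {
    tibble::tibble(species = LETTERS[i], value = rlnorm(50, -i / 3, 0.2))
  })
  cr <- paired_bootstrap_correlation(a, b, n_draw = 300, seed = 4,
                                     method = "spearman")
  expect_equal(cr$method, "spearman")
  expect_lt(cr$r, 0)
  expect_true(all(cr$r_draws >= -1 & cr$r_draws <= 1, na.rm = TRUE))
})
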