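test_that("plot generation honors counts, bounds and the seed", {
  cfg <- community_config(n_species = 3, stem_scale = 0.3, seed = 19)
  pg <- generate_plot(cfg)
  expect_identical(nrow(pg$trees), as.integer(sum(cfg$species$n_stems)))
  expect_true(all(pg$trees$x >= 0 & pg$trees$x <= 500 &
                    pg$trees$y >= 0 & pg$trees$y <= 400))
  expect_true(all(pg$trees$dbh >= 1))
  expect_identical(nrow(pg$traps), 149L)
  expect_true(all(pg$traps$area == 0.5))
  pg2 <- generate_plot(cfg)
  expect_identical(pg, pg2)
  expect_false(identical(pg, generate_plot(cfg, seed = 20)))
})

test_that("clustered placement aggregates stems (Clark-Evans < 1)", {
  cfg <- community_config(n_species = 1, stem_scale = 1, seed = 3,
                          placement = "clustered")
  pg <- generate_plot(cfg)
  xy <- as.matrix(pg$trees[, c("x", "y")])
  nn <- vapply(seq_len(nrow(xy)), function(i) {
    sqrt(min(colSums((t(xy[-i, ]) - xy[i, ])^2)))
  }, numeric(1))
  dens <- nrow(xy) / (500 * 400)
  ce <- mean(nn) / (0.5 / sqrt(dens))
  expect_lt(ce, 0.9)
})

test_that("simulated seed rain is Poisson around the kernel expectation", {
  set.seed(4)
  trees <- tibble::tibble(x = runif(60, 0, 100), y = runif(60, 0, 100),
                          dbh = runif(60, 6, 30))
  traps <- tibble::tibble(id = paste0("k", 1:5),
                          x = c(10, 30, 50, 70, 90), y = rep(50, 5),
                          area = 0.5)
  k <- dispersal_kernel("negative_exponential", b1 = 12)
  lam <- vapply(seq_len(5), function(i) {
    expected_trap_count(trees, as.list(traps[i, ]), 5, k, 10, 6)
  }, numeric(1))
  sims <- vapply(1:400, function(s) {
    simulate_seed_rain(trees, traps, 5, k, 10, 6, seed = s)$count
  }, numeric(5))
  expect_true(all(abs(rowMeans(sims) - lam) <= 3 * sqrt(lam / 400) + 1e-9))
  # beta = 0 silences every trap; years double the totals in expectation
  expect_true(all(simulate_seed_rain(trees, traps, 0, k, 10, 6,
                                     seed = 1)$count == 0))
  t10 <- sum(vapply(1:150, function(s)
    sum(simulate_seed_rain(trees, traps, 5, k, 10, 6, seed = s)$count),
    numeric(1)))
  t20 <- sum(vapply(1:150, function(s)
    sum(simulate_seed_rain(trees, traps, 5, k, 20, 6, seed = s)$count),
    numeric(1)))
  expect_equal(t20 / t10, 2, tolerance = 0.1)
})

test_that("simulated survival follows the logistic model", {
  set.seed(8)
  n <- 3000
  trees <- tibble::tibble(dbh = runif(n, 2, 30), nc = rnorm(n, 4, 1),
                          quadrat = sample(paste0("q", 1:40), n, TRUE))
  cf <- c(intercept = 1.5, dbh = 0.04, nc = -0.4)
  out <- simulate_survival(trees, cf, seed = 2)
  p <- 1 / (1 + exp(-(1.5 + 0.04 * trees$dbh - 0.4 * trees$nc)))
  se <- sqrt(sum(p * (1 - p))) / n
  expect_lt(abs(mean(out$survived) - mean(p)), 3 * se)
  # overwhelming crowding penalty kills crowded trees
  cf_hard <- c(intercept = 1.5, dbh = 0, nc = -50)
  out2 <- simulate_survival(trees, cf_hard, seed = 2)
  expect_lt(mean(out2$survived[trees$nc > 1]), 0.01)
  # undefined crowding falls back to intercept + dbh and is flagged
  trees_na <- trees; trees_na$nc[1:100] <- NA
  out3 <- simulate_survival(trees_na, cf_hard, seed = 3)
  expect_false(any(out3$nc_defined[1:100]))
  expect_gt(mean(out3$survived[1:100]), 0.5)
})

test_that("quadrat random effects induce intra-quadrat correlation", {
  set.seed(12)
  n <- 6000
  trees <- tibble::tibble(dbh = runif(n, 2, 30), nc = rnorm(n, 4, 1),
                          quadrat = sample(paste0("q", 1:30), n, TRUE))
  cf <- c(intercept = 0.5, dbh = 0, nc = 0)
  out <- simulate_survival(trees, cf, quadrat_sd = 2, seed = 5)
  # between-quadrat variance of survival fractions far exceeds binomial
  frac <- tapply(out$survived, out$quadrat, mean)
  nq <- tapply(out$survived, out$quadrat, length)
  expect_gt(var(frac), 3 * mean(frac * (1 - frac) / nq))
  out0 <- simulate_survival(trees, cf, quadrat_sd = 0, seed = 5)
  frac0 <- tapply(out0$survived, out0$quadrat, mean)
  expect_lt(var(frac0), 3 * mean(frac0 * (1 - frac0) / nq))
})

test_that("the ground-truth ledger is self-consistent", {
  cfg <- community_config(n_species = 5, stem_scale = 0.4, seed = 31)
  sim <- generate_community(cfg, n_gap_placements = 50)
  gt <- sim$ground_truth
  # abilities recomputed from the stored parameters match stored values
  expect_equal(gt$inv_t_dbh5, gt$p_g * gt$beta * basal_area(5),
               tolerance = 1e-10)
  expect_equal(gt$inv_t_dbh20, gt$p_g * gt$beta * basal_area(20),
               tolerance = 1e-10)
  expect_equal(gt$sor_dbh10,
               exp(gt$intercept + gt$coef_dbh * 10 + gt$coef_nc * gt$nc_high),
               tolerance = 1e-10)
  # stored p_g agrees with an independent engine rebuilt from the seed
  eng <- gap_engine(plot = cfg$plot, n_placements = 50,
                    seed = sim$gap_engine_seed)
  k1 <- dispersal_kernel(gt$family[1], b1 = gt$b1[1],
                         b2 = if (is.na(gt$b2[1])) NULL else gt$b2[1])
  expect_equal(gt$p_g[1], mean_gap_probability(eng, k1), tolerance = 1e-12)
  # the dataset carries outcomes and passes its own validation
  expect_s3_class(sim$dataset, "seed_dataset")
  expect_true(all(c("survived", "nc_defined") %in%
                    names(sim$dataset$trees)))
})

test_that("the planted ability correlation is realized exactly", {
  for (target in c(0, -0.8)) {
    cfg <- community_config(n_species = 13, stem_scale = 0.15, seed = 47,
                            target_correlation = target)
    sim <- generate_community(cfg, n_gap_placements = 30)
    gt <- sim$ground_truth
    realized <- cor(log(gt$inv_t_dbh10), log(gt$sor_dbh10))
    expect_equal(realized, target, tolerance = 0.05)
  }
  expect_error(community_config(target_correlation = 1.5), "\\[-1, 1\\]")
})

test_that("simulated data are most likely at the generating parameters", {
  cfg <- community_config(n_species = 1, stem_scale = 0.4, seed = 61)
  sp <- cfg$species
  pg <- generate_plot(cfg)
  k <- dispersal_kernel(sp$family[1], b1 = sp$b1[1],
                        b2 = if (is.na(sp$b2[1])) NULL else sp$b2[1])
  meta <- tibble::tibble(species = sp$species, dbh_r = sp$dbh_r,
                         dbh_m = sp$dbh_m)
  theta_true <- c(log(sp$beta[1]), log(sp$b1[1]),
                  if (!is.na(sp$b2[1])) log(sp$b2[1]))
  delta <- rowMeans(vapply(1:50, function(s) {
    counts <- simulate_seed_rain(pg$trees, pg$traps, sp$beta[1], k,
                                 cfg$years, sp$dbh_r[1], seed = s,
                                 species = sp$species[1])
    ds <- seed_dataset(pg$trees, pg$traps, counts, meta, cfg$years)
    at_truth <- seed_nll(theta_true, ds, sp$species[1], sp$family[1])
    perturbed <- seed_nll(theta_true + c(0.4, -0.4, 0.3)[seq_along(theta_true)],
                          ds, sp$species[1], sp$family[1])
    c(truth = at_truth, pert = perturbed)
  }, numeric(2)))
  expect_lt(delta["truth"], delta["pert"])
})
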