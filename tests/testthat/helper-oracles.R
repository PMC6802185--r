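# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (double loops, direct formula transcription) so they
# cannot share bugs with the vectorized implementations they check.

# Poisson trap NLL by an explicit per-tree-per-trap double loop
oracle_seed_nll <- function(beta, kernel, trees, traps, counts, years,
                            dbh_r) {
  nll <- 0
  for (k in seq_len(nrow(traps))) {
    lam <- 0
    for (i in seq_len(nrow(trees))) {
      if (trees$dbh[i] >= dbh_r) {
        d <- sqrt((trees$x[i] - traps$x[k])^2 + (trees$y[i] - traps$y[k])^2)
        lam <- lam + beta * pi * (trees$dbh[i] / 2)^2 *
          kernel_density(kernel, d)
      }
    }
    lam <- lam * years * traps$area[k]
    n <- counts[k]
    nll <- nll + lam - ifelse(n > 0, n * log(lam), 0) + lgamma(n + 1)
  }
  nll
}

# neighborhood crowding by an O(n^2) double loop, straight from the formula
oracle_nc <- function(trees, radius = 15, decay = 0.2) {
  n <- nrow(trees)
  nc <- rep(NA_real_, n)
  n_neigh <- integer(n)
  for (i in seq_len(n)) {
    s <- 0
    cnt <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt((trees$x[i] - trees$x[j])^2 + (trees$y[i] - trees$y[j])^2)
      if (d > 0 && d <= radius && trees$dbh[j] > trees$dbh[i]) {
        s <- s + pi * (trees$dbh[j] / 2)^2 * exp(-decay * d)
        cnt <- cnt + 1L
      }
    }
    n_neigh[i] <- cnt
    if (s > 0) nc[i] <- log(s)
  }
  list(nc = nc, n_neighbors = n_neigh)
}

# a 5-tree, 3-trap toy dataset on a 100 x 100 plot
toy_dataset <- function(counts = c(3L, 0L, 7L), years = 10) {
  trees <- tibble::tibble(
    id = paste0("t", 1:5), species = "AA",
    x = c(20, 35, 50, 70, 85), y = c(30, 60, 45, 20, 75),
    dbh = c(4, 12, 25, 8, 16))
  traps <- tibble::tibble(id = paste0("k", 1:3),
                          x = c(25, 55, 80), y = c(35, 50, 70), area = 0.5)
  cnt <- tibble::tibble(trap_id = traps$id, species = "AA", count = counts)
  meta <- tibble::tibble(species = "AA", dbh_r = 5, dbh_m = 40,
                         growth_form = "canopy")
  seed_dataset(trees, traps, cnt, meta, years = years, plot = c(100, 100))
}

# random plot of n trees for the NC oracle comparisons
random_plot <- function(n, plot = c(100, 80), seed = 1) {
  set.seed(seed)
  tibble::tibble(id = paste0("t", seq_len(n)), species = "SP",
                 x = runif(n, 0, plot[1]), y = runif(n, 0, plot[2]),
                 dbh = exp(rnorm(n, log(5), 0.7)) + 1)
}

# a fake seed_shadow_fit for functions that only need kernel + beta
fake_fit <- function(kernel, beta, species = "SP", n_trees = 1L) {
  structure(list(species = species, family = kernel$family, kernel = kernel,
                 beta = beta, logLik = 0, n_params = 2L, aic = 0,
                 converged = TRUE, n_trees = n_trees, n_traps = 0L,
                 total_seeds = 0L, dbh_m = Inf),
            class = "seed_shadow_fit")
}

example_kernels <- function() {
  list(
    negative_exponential = dispersal_kernel("negative_exponential", b1 = 10),
    two_dim_t = dispersal_kernel("two_dim_t", b1 = 100, b2 = 1),
    lognormal = dispersal_kernel("lognormal", b1 = 12, b2 = 0.7),
    weibull = dispersal_kernel("weibull", b1 = 15, b2 = 1.3))
}

# random valid parameters per family for property sweeps
random_kernel <- function(family) {
  switch(family,
    negative_exponential = dispersal_kernel(family,
                                            b1 = runif(1, 0.5, 80)),
    two_dim_t = dispersal_kernel(family, b1 = runif(1, 5, 3000),
                                 b2 = runif(1, 0.2, 4)),
    lognormal = dispersal_kernel(family, b1 = runif(1, 1, 60),
                                 b2 = runif(1, 0.2, 1.5)),
    weibull = dispersal_kernel(family, b1 = runif(1, 2, 60),
                               b2 = runif(1, 0.5, 3)))
}

# numerical radial normalization integral of a kernel
radial_mass <- function(kernel, upper = Inf) {
  stats::integrate(function(r) 2 * pi * r * kernel_density(kernel, r),
                   0, upper, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}
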