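#' Configuration of a synthetic mapped community
#'
#' Describes a virtual census emulating the study design the pipeline
#' expects: a rectangular 20-ha plot of mapped stems, 149 point seed traps
#' of 0.5 m^2, a 10-year seed-rain window, and a 13-species community
#' spanning understory, midstory and canopy growth forms. Per-species
#' generating parameters (stem counts, DBH distributions, reproductive
#' thresholds, fecundity, dispersal kernels, survival coefficients) are
#' drawn reproducibly from `seed` unless a full `species` table is supplied.
#' Default stem counts are in the hundreds per species — enough spatial
#' signal for the estimators at desk-scale runtime; `stem_scale` multiplies
#' them (e.g. `stem_scale = 5` approaches census densities).
#'
#' @param n_species Number of species (default 13).
#' @param plot Plot rectangle `c(width, height)` m (default 500 x 400).
#' @param n_traps Number of seed traps (default 149).
#' @param trap_area Trap area m^2 (default 0.5).
#' @param trap_layout `"transect"` (along trails, the field design) or
#'   `"uniform"`.
#' @param years Seed-rain window, years (default 10).
#' @param quadrat_size Bootstrap quadrat side, m (default 20).
#' @param placement Stem placement: `"uniform"` (homogeneous Poisson) or
#'   `"clustered"` (parent-offspring Thomas process).
#' @param quadrat_sd SD of a quadrat-level random effect on the survival
#'   logit (default 0 = none).
#' @param target_correlation Optional target cross-species Pearson
#'   correlation (on the log scale, at the 10 cm reference size) between
#'   true colonization ability and true SOR; species survival intercepts are
#'   adjusted to realize it exactly in-sample. `NULL` leaves intercepts as
#'   drawn.
#' @param stem_scale Multiplier on per-species stem counts (default 1).
#' @param seed Master seed; every downstream draw derives from it.
#' @param species Optional full species tibble overriding the generated one
#'   (columns as in the returned config).
#' @return An object of class `community_config`.
#' @export
community_config <- function(n_species = 13, plot = c(500, 400),
                             n_traps = 149, trap_area = 0.5,
                             trap_layout = c("transect", "uniform"),
                             years = 10, quadrat_size = 20,
                             placement = c("uniform", "clustered"),
                             quadrat_sd = 0, target_correlation = NULL,
                             stem_scale = 1, seed = 1L, species = NULL) {
  trap_layout <- match.arg(trap_layout)
  placement <- match.arg(placement)
  if (!is.null(target_correlation) &&
      (abs(target_correlation) > 1 || !is.finite(target_correlation))) {
    stop("`target_correlation` must lie in [-1, 1]", call. = FALSE)
  }
  if (is.null(species)) {
    set.seed(child_seed(seed, stream = "species-params"))
    forms <- rep(c("understory", "midstory", "canopy"),
                 c(3, 3, 7))[
                   ((seq_len(n_species) - 1) %% 13) + 1]
    base_n <- c(understory = 700, midstory = 350, canopy = 300)
    meanlog <- c(understory = log(2.5), midstory = log(4), canopy = log(6))
    sdlog <- c(understory = 0.45, midstory = 0.55, canopy = 0.75)
    dbh_r_rng <- list(understory = c(1.5, 3), midstory = c(2.5, 5),
                      canopy = c(4, 8))
    dbh_m_rng <- list(understory = c(16, 35), midstory = c(24, 40),
                      canopy = c(48, 95))
    fam <- kernel_families()[((seq_len(n_species) - 1) %% 4) + 1]
    b1 <- b2 <- numeric(n_species)
    for (i in seq_len(n_species)) {
      b1[i] <- switch(fam[i],
        negative_exponential = stats::runif(1, 6, 25),
        two_dim_t = stats::runif(1, 80, 1200),
        lognormal = stats::runif(1, 6, 22),
        weibull = stats::runif(1, 8, 30))
      b2[i] <- switch(fam[i],
        negative_exponential = NA_real_,
        two_dim_t = stats::runif(1, 0.7, 2),
        lognormal = stats::runif(1, 0.4, 0.9),
        weibull = stats::runif(1, 0.9, 1.8))
    }
    species <- tibble::tibble(
      species = sprintf("SP%02d", seq_len(n_species)),
      growth_form = forms,
      n_stems = round(stem_scale * base_n[forms] *
                        exp(stats::runif(n_species, -0.4, 0.6))),
      dbh_meanlog = meanlog[forms],
      dbh_sdlog = sdlog[forms],
      dbh_r = purrr::map_dbl(forms, ~ stats::runif(1, dbh_r_rng[[.x]][1],
                                                   dbh_r_rng[[.x]][2])),
      dbh_m = purrr::map_dbl(forms, ~ stats::runif(1, dbh_m_rng[[.x]][1],
                                                   dbh_m_rng[[.x]][2])),
      beta = exp(stats::runif(n_species, log(5), log(80))),
      family = fam, b1 = b1, b2 = b2,
      intercept = stats::runif(n_species, 1.2, 2.5),
      coef_dbh = stats::runif(n_species, 0.02, 0.08),
      coef_nc = stats::runif(n_species, -0.55, -0.15))
  } else {
    species <- tibble::as_tibble(species)
  }
  if (any(species$n_stems <= 0)) {
    stop("all species stem counts must be positive", call. = FALSE)
  }
  structure(list(species = species, plot = plot, n_traps = n_traps,
                 trap_area = trap_area, trap_layout = trap_layout,
                 years = years, quadrat_size = quadrat_size,
                 placement = placement, quadrat_sd = quadrat_sd,
                 target_correlation = target_correlation, seed = seed),
            class = "community_config")
}

#' @export
print.community_config <- function(x, ...) {
  cat("<community_config> ", nrow(x$species), " species, ",
      sum(x$species$n_stems), " stems, ", x$n_traps, " traps (",
      x$trap_layout, "), ", x$years, " yr, plot ", x$plot[1], " x ",
      x$plot[2], " m, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# lognormal DBH truncated to [1, dbh_m] by inverse-CDF
rtrunc_lnorm <- function(n, meanlog, sdlog, lo = 1, hi = Inf) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate the mapped stems and seed traps
#'
#' Stems are placed by a homogeneous Poisson process or a clustered
#' parent-offspring (Thomas) process per species, with DBH drawn from the
#' species' truncated lognormal. Traps follow the configured layout:
#' `"transect"` spaces them along three trails crossing the plot (the field
#' design placed traps along trails), `"uniform"` scatters them.
#'
#' @param config A [community_config()].
#' @param seed Seed (defaults to the config's master seed).
#' @return A list with tibbles `trees` (`id`, `species`, `x`, `y`, `dbh`,
#'   `quadrat`) and `traps` (`id`, `x`, `y`, `area`).
#' @export
generate_plot <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "community_config"))
  W <- config$plot[1]; H <- config$plot[2]
  set.seed(child_seed(seed, stream = "plot"))
  trees <- purrr::pmap_dfr(
    list(config$species$species, config$species$n_stems,
         config$species$dbh_meanlog, config$species$dbh_sdlog,
         config$species$dbh_m),
    function(sp, n, ml, sl, dm) {
      if (config$placement == "uniform") {
        x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
      } else {
        np <- max(5L, ceiling(n / 50))
        px <- stats::runif(np, 0, W); py <- stats::runif(np, 0, H)
        pick <- sample.int(np, n, replace = TRUE)
        x <- pmin(pmax(px[pick] + stats::rnorm(n, 0, 15), 0), W)
        y <- pmin(pmax(py[pick] + stats::rnorm(n, 0, 15), 0), H)
      }
      tibble::tibble(species = sp, x = x, y = y,
                     dbh = rtrunc_lnorm(n, ml, sl, 1, dm))
    })
  trees <- trees |>
    dplyr::mutate(id = sprintf("t%06d", dplyr::row_number()),
                  quadrat = paste(floor(.data$x / config$quadrat_size),
                                  floor(.data$y / config$quadrat_size)),
                  .before = 1)
  set.seed(child_seed(seed, stream = "traps"))
  nt <- config$n_traps
  if (config$trap_layout == "uniform") {
    tx <- stats::runif(nt, 0, W); ty <- stats::runif(nt, 0, H)
  } else {
    trail_y <- H * c(0.25, 0.5, 0.75)
    trail <- rep_len(1:3, nt)
    tx <- stats::runif(nt, 0, W)
    ty <- pmin(pmax(trail_y[trail] + stats::rnorm(nt, 0, 8), 0), H)
  }
  traps <- tibble::tibble(id = sprintf("trap%03d", seq_len(nt)),
                          x = tx, y = ty, area = config$trap_area)
  list(trees = trees, traps = traps)
}

#' Simulate seed rain into traps
#'
#' The generative twin of the trap likelihood: each trap's pooled count over
#' the window is one Poisson draw with mean [expected_trap_count()].
#'
#' @param trees Conspecific stems (`x`, `y`, `dbh`).
#' @param traps Trap table (`id`, `x`, `y`, `area`).
#' @param beta Fecundity parameter.
#' @param kernel A [dispersal_kernel()].
#' @param years Window length (yr).
#' @param dbh_r Reproductive threshold (cm).
#' @param seed Integer seed.
#' @param species Optional species label column in the output.
#' @return Tibble `trap_id` (, `species`), `count`.
#' @export
simulate_seed_rain <- function(trees, traps, beta, kernel, years, dbh_r,
                               seed = 1L, species = NULL) {
  rep_trees <- trees[trees$dbh >= dbh_r, , drop = FALSE]
  lam <- if (nrow(rep_trees) == 0L) rep(0, nrow(traps)) else {
    D <- sqrt(outer(traps$x, rep_trees$x, "-")^2 +
                outer(traps$y, rep_trees$y, "-")^2)
    as.vector(kernel_density(kernel, D) %*%
                (beta * basal_area(rep_trees$dbh))) * years * traps$area
  }
  set.seed(child_seed(seed, species %||% "", stream = "seed-rain"))
  out <- tibble::tibble(trap_id = traps$id, count = stats::rpois(nrow(traps),
                                                                 lam))
  if (!is.null(species)) out <- dplyr::mutate(out, species = species,
                                              .after = "trap_id")
  out
}

#' Simulate census-interval survival
#'
#' Bernoulli survival with
#' \eqn{\mathrm{logit}(s) = \beta_0 + \beta_D dbh + \beta_{NC} NC}
#' (+ a quadrat-level normal random effect when `quadrat_sd > 0`). Trees
#' with undefined NC draw their outcome from the intercept + DBH terms only
#' and are flagged `nc_defined = FALSE`.
#'
#' @param trees Tibble with `dbh`, `nc`, and `quadrat` (required when
#'   `quadrat_sd > 0`).
#' @param coefficients Named vector `c(intercept, dbh, nc)` on the logit
#'   scale.
#' @param quadrat_sd SD of the quadrat random effect (default 0).
#' @param seed Integer seed.
#' @return The input tibble with `survived` (logical) and `nc_defined`
#'   appended.
#' @export
simulate_survival <- function(trees, coefficients, quadrat_sd = 0,
                              seed = 1L) {
  trees <- tibble::as_tibble(trees)
  stopifnot(all(c("dbh", "nc") %in% names(trees)))
  set.seed(child_seed(seed, stream = "survival"))
  eta <- coefficients[["intercept"]] + coefficients[["dbh"]] * trees$dbh
  nc_def <- is.finite(trees$nc)
  eta[nc_def] <- eta[nc_def] + coefficients[["nc"]] * trees$nc[nc_def]
  if (quadrat_sd > 0) {
    stopifnot("quadrat" %in% names(trees))
    qs <- unique(trees$quadrat)
    re <- stats::setNames(stats::rnorm(length(qs), 0, quadrat_sd), qs)
    eta <- eta + re[trees$quadrat]
  }
  trees |>
    dplyr::mutate(survived = stats::runif(dplyr::n()) < inv_logit(eta),
                  nc_defined = nc_def)
}

#' Generate a complete synthetic community with ground truth
#'
#' Runs the whole generative model: mapped stems and traps, community-wide
#' crowding, survival outcomes, and pooled seed-trap counts, and writes the
#' generating parameters plus the true derived abilities (colonization rate
#' 1/t, LDD, SOR at the realized community 97.5th crowding percentile, each
#' at 5/10/20 cm) into a ground-truth ledger for recovery scoring. When the
#' config carries a `target_correlation`, species survival intercepts are
#' adjusted so the in-sample Pearson correlation between log 1/t and log SOR
#' (10 cm reference) equals the target exactly. A synthetic species trait
#' table (eight traits with planted ability associations) is attached.
#'
#' @param config A [community_config()].
#' @param dbh Evaluation diameters for the true abilities.
#' @param n_gap_placements Gap placements used for the true \eqn{p_G}.
#' @return An object of class `community_sim`: `dataset` (a
#'   [seed_dataset()] whose trees carry survival outcomes), `crowding` (the
#'   full NC table), `nc_high`, `ground_truth` (per-species tibble),
#'   `traits`, and the `config`.
#' @export
generate_community <- function(config, dbh = c(5, 10, 20),
                               n_gap_placements = 200) {
  stopifnot(inherits(config, "community_config"))
  sp <- config$species
  pg <- generate_plot(config)
  crowding <- neighborhood_crowding(pg$trees, plot = config$plot)
  nc_high <- crowding_percentile(crowding$nc, 97.5)
  engine <- gap_engine(plot = config$plot,
                       n_placements = n_gap_placements,
                       seed = child_seed(config$seed, stream = "truth-gaps"))
  kernels <- purrr::pmap(list(sp$family, sp$b1, sp$b2), function(f, a, b) {
    dispersal_kernel(f, b1 = a, b2 = if (is.na(b)) NULL else b)
  })
  p_g <- purrr::map_dbl(kernels, ~ mean_gap_probability(engine, .x))
  ldd <- purrr::map_dbl(kernels, long_distance_dispersal)
  ref_dbh <- 10
  inv_t_ref <- p_g * sp$beta * basal_area(ref_dbh)
  if (!is.null(config$target_correlation)) {
    rho <- config$target_correlation
    if (nrow(sp) < 3L) {
      stop("target correlation needs at least 3 species", call. = FALSE)
    }
    z <- log(inv_t_ref)
    if (stats::sd(z) == 0) {
      stop("degenerate colonization abilities; correlation target ",
           "unattainable", call. = FALSE)
    }
    z <- as.vector(scale(z))
    set.seed(child_seed(config$seed, stream = "target-corr"))
    e <- stats::rnorm(nrow(sp))
    e <- e - mean(e) - z * sum(e * z) / sum(z^2)     # orthogonal to z and 1
    if (sum(e^2) == 0) {
      stop("correlation target unattainable for this species set",
           call. = FALSE)
    }
    e <- e / stats::sd(e)
    y <- rho * z + sqrt(1 - rho^2) * e
    log_sor <- 1.2 + 0.6 * y
    sp$intercept <- log_sor - sp$coef_dbh * ref_dbh - sp$coef_nc * nc_high
  }
  # survival outcomes per species from its generating coefficients
  trees <- dplyr::left_join(pg$trees,
                            dplyr::select(crowding, "id", "nc",
                                          "n_neighbors", "edge_ok"),
                            by = "id")
  surv <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    d <- trees[trees$species == sp$species[i], , drop = FALSE]
    simulate_survival(d, c(intercept = sp$intercept[i],
                           dbh = sp$coef_dbh[i], nc = sp$coef_nc[i]),
                      quadrat_sd = config$quadrat_sd,
                      seed = child_seed(config$seed, sp$species[i],
                                        stream = "surv"))
  })
  counts <- purrr::map_dfr(seq_len(nrow(sp)), function(i) {
    simulate_seed_rain(surv[surv$species == sp$species[i], ],
                       pg$traps, sp$beta[i], kernels[[i]],
                       config$years, sp$dbh_r[i],
                       seed = child_seed(config$seed, sp$species[i],
                                         stream = "rain"),
                       species = sp$species[i])
  })
  meta <- dplyr::select(sp, "species", "dbh_r", "dbh_m", "growth_form")
  dataset <- seed_dataset(surv, pg$traps, counts, meta,
                          years = config$years, plot = config$plot)
  sor_true <- function(i, d) {
    exp(sp$intercept[i] + sp$coef_dbh[i] * d + sp$coef_nc[i] * nc_high)
  }
  gt <- sp |>
    dplyr::mutate(p_g = p_g, ldd = ldd, nc_high = nc_high)
  for (d in dbh) {
    gt[[paste0("inv_t_dbh", d)]] <- p_g * sp$beta * basal_area(d)
    gt[[paste0("sor_dbh", d)]] <-
      purrr::map_dbl(seq_len(nrow(sp)), sor_true, d = d)
  }
  traits <- synthesize_traits(gt, seed = child_seed(config$seed,
                                                    stream = "traits"))
  structure(list(dataset = dataset, crowding = crowding, nc_high = nc_high,
                 ground_truth = gt, traits = traits, config = config,
                 gap_engine_seed = child_seed(config$seed,
                                              stream = "truth-gaps")),
            class = "community_sim")
}

# eight positive traits per species; wood density tracks competitive
# ability, leaf area tracks colonization, seed mass runs against LDD --
# the planted associations the trait-correlation machinery should find
synthesize_traits <- function(gt, seed) {
  set.seed(seed)
  n <- nrow(gt)
  zc <- as.vector(scale(log(gt$sor_dbh10)))
  zt <- as.vector(scale(log(gt$inv_t_dbh10)))
  zl <- as.vector(scale(log(gt$ldd + 1e-12)))
  sla <- exp(log(150) - 0.3 * zc + stats::rnorm(n, 0, 0.25))
  thickness <- exp(log(0.025) + 0.15 * zc + stats::rnorm(n, 0, 0.2))
  tibble::tibble(
    species = gt$species,
    wood_density = exp(log(0.55) + 0.2 * zc + stats::rnorm(n, 0, 0.1)),
    seed_mass = exp(log(0.1) - 0.8 * zl + stats::rnorm(n, 0, 0.4)),
    sla = sla,
    ldmc = exp(log(0.4) + 0.1 * zc + stats::rnorm(n, 0, 0.15)),
    leaf_area = exp(log(30) + 0.5 * zt + stats::rnorm(n, 0, 0.3)),
    lamina_thickness = thickness,
    lamina_density = leaf_lamina_density(sla, thickness),
    chlorophyll = exp(log(45) + stats::rnorm(n, 0, 0.2)))
}

#' @export
print.community_sim <- function(x, ...) {
  cat("<community_sim> ", nrow(x$ground_truth), " species, ",
      nrow(x$dataset$trees), " stems, ", nrow(x$dataset$traps),
      " traps; NC 97.5th pct = ", round(x$nc_high, 3), "\n", sep = "")
  invisible(x)
}
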