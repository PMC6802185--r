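#' Percentile confidence intervals of a bootstrap table
#'
#' Both bootstrap schemes return a long tibble of replicate values; this
#' summarises each quantity by its mean and 2.5th / 97.5th percentile bounds
#' (the 95% CI convention used throughout).
#'
#' @param boot A `trap_bootstrap` or `quadrat_bootstrap` object, or any
#'   tibble with columns `quantity` and `value`.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `quantity`, `mean`, `lower`, `upper`.
#' @export
boot_ci <- function(boot, level = 0.95) {
  reps <- if (is.data.frame(boot)) boot else boot$replicates
  a <- (1 - level) / 2 * 100
  reps |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(mean = mean(.data$value),
                     lower = percentile(.data$value, a),
                     upper = percentile(.data$value, 100 - a),
                     .groups = "drop")
}

#' Seed-trap bootstrap of the dispersal fit and derived abilities
#'
#' Resamples the seed traps (with their counts) with replacement `n_boot`
#' times, refits the seed shadow for the given kernel family on each
#' resample, and recomputes the derived quantities: the fecundity parameter,
#' the kernel parameters, the long-distance dispersal probability, the
#' placement-averaged gap probability and the colonization ability
#' \eqn{1/t} at each requested diameter. Replicates whose refit fails are
#' dropped and counted; more than 20% failures is an error.
#'
#' @param dataset A [seed_dataset()].
#' @param species Species code.
#' @param family Kernel family (typically the AIC-selected one).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param dbh Diameters (cm) at which \eqn{1/t} is evaluated.
#' @param engine Optional [gap_engine()]; defaults to one built on the
#'   dataset's plot with its own fixed placement seed.
#' @param ldd_threshold Long-distance threshold (m).
#' @param derived Recompute the derived abilities (p_G, LDD, 1/t) per
#'   replicate (default `TRUE`); `FALSE` bootstraps the fitted parameters
#'   only, which is cheaper for pure parameter-calibration experiments.
#' @return An object of class `trap_bootstrap`: a list with `species`,
#'   `family`, `baseline` (the full-data `seed_shadow_fit`), `replicates`
#'   (long tibble `replicate`, `quantity`, `value`), `n_failed`.
#' @export
bootstrap_seed_traps <- function(dataset, species, family, n_boot = 1000,
                                 seed = 1L, dbh = c(5, 10, 20),
                                 engine = NULL, ldd_threshold = 50,
                                 derived = TRUE) {
  stopifnot(inherits(dataset, "seed_dataset"))
  prep <- shadow_prep(dataset, species)
  baseline <- fit_seed_shadow(dataset, species, family)
  if (derived && is.null(engine)) {
    engine <- gap_engine(plot = dataset$plot,
                         seed = child_seed(seed, species,
                                           stream = "trap-boot-gaps"))
  }
  k <- kernel_n_params(family)
  base_start <- baseline$kernel$params
  alt_start <- kernel_start_grid(family)[[2]]
  set.seed(child_seed(seed, species, stream = "trap-boot"))
  n_traps <- prep$n_traps
  ba_dbh <- basal_area(dbh)
  rows <- vector("list", n_boot)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n_traps, n_traps, replace = TRUE)
    prep_b <- prep
    prep_b$D <- prep$D[idx, , drop = FALSE]
    prep_b$area <- prep$area[idx]
    prep_b$n <- prep$n[idx]
    res <- if (sum(prep_b$n) == 0) NULL else
      profile_fit(prep_b, family, starts = list(base_start, alt_start),
                  fast = TRUE)
    if (is.null(res) || !is.finite(res$nll)) {
      n_failed <- n_failed + 1L
      next
    }
    vals <- c(beta = res$beta,
              b1 = unname(res$kernel$params["b1"]),
              b2 = if (k == 2L) unname(res$kernel$params["b2"]) else NA_real_)
    if (derived) {
      p_g <- mean_gap_probability(engine, res$kernel)
      vals <- c(vals,
                ldd = long_distance_dispersal(res$kernel, ldd_threshold),
                p_g = p_g,
                stats::setNames(p_g * res$beta * ba_dbh,
                                paste0("inv_t_dbh", dbh)))
    }
    rows[[b]] <- tibble::tibble(replicate = b, quantity = names(vals),
                                value = unname(vals))
  }
  if (n_failed > 0.2 * n_boot) {
    stop("more than 20% of trap-bootstrap replicates failed (", n_failed,
         "/", n_boot, "); inspect the model or data", call. = FALSE)
  }
  structure(list(species = species, family = family, baseline = baseline,
                 replicates = dplyr::bind_rows(rows),
                 n_failed = n_failed, n_boot = n_boot),
            class = "trap_bootstrap")
}

#' @export
print.trap_bootstrap <- function(x, ...) {
  cat("<trap_bootstrap> ", x$species, " (", x$family, "), ",
      x$n_boot - x$n_failed, "/", x$n_boot, " replicates\n", sep = "")
  invisible(x)
}

#' Spatial quadrat bootstrap of the survival model
#'
#' Resamples the 20 x 20 m quadrats a species occupies (with replacement,
#' the same number as occupied) `n_boot` times; each replicate pools the
#' focal trees of the sampled quadrats (duplicated quadrats contribute
#' duplicate trees), refits the logistic survival model, and recomputes the
#' survival odds ratio at each diameter at the fixed high-crowding level
#' `nc_high` (held at its full-data value, since the percentile describes
#' the community, not the resample). Sampling whole quadrats preserves the
#' spatial correlation of survival.
#'
#' @param data Per-tree tibble with `survived`, `dbh`, `nc`, `edge_ok`,
#'   `x`, `y` for one species.
#' @param nc_high The fixed NC value at which SOR is evaluated (typically
#'   [crowding_percentile()] of the whole community).
#' @param quadrat_size Quadrat side length in meters (default 20).
#' @param n_boot Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param dbh Diameters (cm) at which SOR is evaluated.
#' @param dbh_m Maximum observed DBH; larger diameters are not predicted.
#' @param species Optional label.
#' @param min_obs Minimum usable focals per replicate fit.
#' @return An object of class `quadrat_bootstrap` with the same shape as
#'   [bootstrap_seed_traps()] (quantities: `intercept`, `coef_dbh`,
#'   `coef_nc`, `sor_dbh*`).
#' @export
bootstrap_quadrats <- function(data, nc_high, quadrat_size = 20,
                               n_boot = 1000, seed = 1L, dbh = c(5, 10, 20),
                               dbh_m = Inf, species = NULL, min_obs = 20) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("survived", "dbh", "nc", "x", "y") %in% names(data)))
  if (!"edge_ok" %in% names(data)) data$edge_ok <- TRUE
  usable <- dplyr::filter(data, .data$edge_ok, is.finite(.data$nc))
  usable$quadrat <- paste(floor(usable$x / quadrat_size),
                          floor(usable$y / quadrat_size))
  quads <- split(seq_len(nrow(usable)), usable$quadrat)
  if (length(quads) < 2L) {
    stop("species occupies fewer than 2 quadrats; cannot resample",
         call. = FALSE)
  }
  baseline <- fit_survival(usable, species = species, min_obs = min_obs)
  dbh_ok <- dbh[dbh <= dbh_m]
  set.seed(child_seed(seed, species %||% "", stream = "quadrat-boot"))
  rows <- vector("list", n_boot)
  n_failed <- 0L
  nq <- length(quads)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(nq, nq, replace = TRUE)
    idx <- unlist(quads[pick], use.names = FALSE)
    fit_b <- tryCatch(
      fit_survival(usable[idx, ], species = species, min_obs = min_obs),
      error = function(e) NULL)
    if (is.null(fit_b)) {
      n_failed <- n_failed + 1L
      next
    }
    vals <- c(intercept = unname(fit_b$coef["intercept"]),
              coef_dbh = unname(fit_b$coef["dbh"]),
              coef_nc = unname(fit_b$coef["nc"]))
    if (length(dbh_ok)) {
      vals <- c(vals, stats::setNames(
        survival_odds_ratio(fit_b, dbh_ok, nc_high),
        paste0("sor_dbh", dbh_ok)))
    }
    rows[[b]] <- tibble::tibble(replicate = b, quantity = names(vals),
                                value = unname(vals))
  }
  if (n_failed > 0.2 * n_boot) {
    stop("more than 20% of quadrat-bootstrap replicates failed (", n_failed,
         "/", n_boot, ")", call. = FALSE)
  }
  structure(list(species = species, baseline = baseline, nc_high = nc_high,
                 replicates = dplyr::bind_rows(rows),
                 n_failed = n_failed, n_boot = n_boot,
                 n_quadrats = nq),
            class = "quadrat_bootstrap")
}

#' @export
print.quadrat_bootstrap <- function(x, ...) {
  cat("<quadrat_bootstrap> ", x$species %||% "", " ", x$n_quadrats,
      " quadrats, ", x$n_boot - x$n_failed, "/", x$n_boot,
      " replicates\n", sep = "")
  invisible(x)
}

# columnwise correlation of two matrices with matched columns
col_cor <- function(A, B, method = "pearson") {
  if (method == "spearman") {
    A <- apply(A, 2, rank)
    B <- apply(B, 2, rank)
  }
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Paired-bootstrap correlation across species
#'
#' Tests whether two per-species quantities covary across the community
#' while honoring each species' estimation uncertainty. On each of `n_draw`
#' draws, one replicate value per species is sampled independently from each
#' quantity's bootstrap distribution and the cross-species correlation is
#' computed; the 2.5th and 97.5th percentiles of the `n_draw` correlations
#' form the CI. The point estimate `r` is the correlation of the per-species
#' bootstrap means. A CI that excludes zero is flagged `significant`; a CI
#' entirely below zero (`negative_significant`) is the evidence criterion
#' for a competition-colonization trade-off when the pair is 1/t vs SOR
#' under high crowding.
#'
#' @param boot_a,boot_b Tibbles with columns `species` and `value`
#'   (bootstrap replicate values stacked per species). At least 3 shared
#'   species are required.
#' @param n_draw Number of paired draws (default 1000).
#' @param seed Integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param label Optional pair label carried into the result.
#' @return An object of class `correlation_result`: `label`, `r`,
#'   `ci_lower`, `ci_upper`, `significant`, `negative_significant`,
#'   `n_species`, `n_draw`, `method`, and the draw vector `r_draws`.
#' @export
paired_bootstrap_correlation <- function(boot_a, boot_b, n_draw = 1000,
                                         seed = 1L,
                                         method = c("pearson", "spearman"),
                                         label = NULL) {
  method <- match.arg(method)
  boot_a <- tibble::as_tibble(boot_a)
  boot_b <- tibble::as_tibble(boot_b)
  stopifnot(all(c("species", "value") %in% names(boot_a)),
            all(c("species", "value") %in% names(boot_b)))
  boot_a <- dplyr::filter(boot_a, is.finite(.data$value))
  boot_b <- dplyr::filter(boot_b, is.finite(.data$value))
  shared <- intersect(unique(boot_a$species), unique(boot_b$species))
  if (length(shared) < 3L) {
    stop("fewer than 3 species shared between the two distributions",
         call. = FALSE)
  }
  shared <- sort(shared)
  va <- split(boot_a$value, boot_a$species)[shared]
  vb <- split(boot_b$value, boot_b$species)[shared]
  means_a <- purrr::map_dbl(va, mean)
  means_b <- purrr::map_dbl(vb, mean)
  r_point <- stats::cor(means_a, means_b, method = method)
  set.seed(child_seed(seed, label %||% "", stream = "paired-corr"))
  draw <- function(v) {
    t(vapply(v, function(x) x[sample.int(length(x), n_draw, replace = TRUE)],
             numeric(n_draw)))
  }
  A <- draw(va)   # n_species x n_draw
  B <- draw(vb)
  r_draws <- col_cor(A, B, method = method)
  ci <- c(percentile(r_draws[is.finite(r_draws)], 2.5),
          percentile(r_draws[is.finite(r_draws)], 97.5))
  structure(list(label = label, r = r_point,
                 ci_lower = ci[1], ci_upper = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 negative_significant = ci[2] < 0,
                 n_species = length(shared), n_draw = n_draw,
                 method = method, r_draws = r_draws),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result>", x$label %||% "",
      sprintf("r = %.3f, 95%% CI [%.3f, %.3f]%s (%s, %d species, %d draws)",
              x$r, x$ci_lower, x$ci_upper,
              if (x$significant) " *" else "", x$method, x$n_species,
              x$n_draw), "\n")
  invisible(x)
}

#' Extract per-species bootstrap values of one quantity
#'
#' Convenience for feeding [paired_bootstrap_correlation()]: stacks the
#' replicate values of a single quantity from a list of bootstrap objects
#' into a `(species, value)` tibble.
#'
#' @param boots A list of `trap_bootstrap` or `quadrat_bootstrap` objects.
#' @param quantity Quantity name, e.g. `"inv_t_dbh5"` or `"sor_dbh5"`.
#' @return A tibble with columns `species`, `value`.
#' @export
boot_quantity <- function(boots, quantity) {
  purrr::map_dfr(boots, function(b) {
    tibble::tibble(species = b$species,
                   value = b$replicates$value[
                     b$replicates$quantity == quantity])
  })
}
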