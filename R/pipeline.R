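#' Run the full competition-colonization trade-off analysis
#'
#' The end-to-end pipeline on one dataset: screen species by the seed-rain
#' inclusion rule, fit all four dispersal kernels per species and select by
#' AIC, bootstrap the seed traps for colonization ability and its
#' components, compute community-wide crowding and fit the per-species
#' survival models, bootstrap the quadrats for competitive ability, and run
#' the paired-bootstrap correlations of 1/t, LDD and fecundity against SOR
#' at each evaluation diameter. The trade-off verdict per diameter is a
#' significantly negative 1/t-SOR correlation.
#'
#' @param dataset A [seed_dataset()] whose trees carry `survived`.
#' @param dbh Evaluation diameters (cm), default `c(5, 10, 20)`.
#' @param n_boot Bootstrap replicates for both schemes (default 1000).
#' @param n_draw Paired-correlation draws (default 1000).
#' @param seed Master seed for all resampling.
#' @param min_seeds,min_traps Species inclusion thresholds.
#' @param n_gap_placements Gap placements for the p_G average.
#' @param families Kernel families to compare.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return An object of class `tradeoff_analysis`: `included` (screen
#'   table), `fits` (AIC-selected fit per species), `trap_boots`,
#'   `quadrat_boots` (per-species bootstrap objects), `abilities` (baseline
#'   ability tibble), `nc_high`, `correlations` (tibble with one row per
#'   pair x diameter), `verdict` (per-diameter trade-off flag).
#' @export
tradeoff_analysis <- function(dataset, dbh = c(5, 10, 20), n_boot = 1000,
                              n_draw = 1000, seed = 1L, min_seeds = 250,
                              min_traps = 20, n_gap_placements = 1000,
                              families = kernel_families(),
                              method = "pearson") {
  stopifnot(inherits(dataset, "seed_dataset"))
  if (!"survived" %in% names(dataset$trees)) {
    stop("dataset trees need a `survived` column for the survival models",
         call. = FALSE)
  }
  screen <- include_species(dataset, min_seeds, min_traps)
  keep <- screen$species[screen$included]
  keep <- keep[keep %in% dataset$species_meta$species]
  if (length(keep) < 3L) {
    stop("fewer than 3 species pass the inclusion rule", call. = FALSE)
  }
  engine <- gap_engine(plot = dataset$plot,
                       n_placements = n_gap_placements,
                       seed = child_seed(seed, stream = "pipeline-gaps"))
  # dispersal side: AIC-selected fit + trap bootstrap per species
  fits <- purrr::map(keep, function(sp) {
    select_best_kernel(fit_all_kernels(dataset, sp, families))
  })
  names(fits) <- keep
  trap_boots <- purrr::map(keep, function(sp) {
    bootstrap_seed_traps(dataset, sp, fits[[sp]]$family, n_boot = n_boot,
                         seed = child_seed(seed, sp, stream = "traps"),
                         dbh = dbh, engine = engine)
  })
  names(trap_boots) <- keep
  abilities <- purrr::map_dfr(fits, colonization_ability, dbh = dbh,
                              engine = engine)
  # competition side: community-wide crowding, survival fits, quadrat boots
  crowding <- neighborhood_crowding(dataset$trees, plot = dataset$plot)
  nc_high <- crowding_percentile(crowding$nc, 97.5)
  surv_data <- crowding |>
    dplyr::left_join(dplyr::select(dataset$trees, "id", "survived"),
                     by = "id")
  quadrat_boots <- purrr::map(keep, function(sp) {
    meta <- dataset$species_meta[dataset$species_meta$species == sp, ]
    bootstrap_quadrats(surv_data[surv_data$species == sp, ],
                       nc_high = nc_high, n_boot = n_boot,
                       seed = child_seed(seed, sp, stream = "quads"),
                       dbh = dbh, dbh_m = meta$dbh_m, species = sp)
  })
  names(quadrat_boots) <- keep
  # cross-species correlations at each diameter
  pairs <- list(colonization_vs_sor = "inv_t_dbh",
                ldd_vs_sor = "ldd", fecundity_vs_sor = "beta")
  corr_rows <- purrr::map_dfr(dbh, function(d) {
    sor_b <- boot_quantity(quadrat_boots, paste0("sor_dbh", d))
    purrr::imap_dfr(pairs, function(prefix, nm) {
      qty <- if (prefix == "inv_t_dbh") paste0(prefix, d) else prefix
      cr <- paired_bootstrap_correlation(
        boot_quantity(trap_boots, qty), sor_b, n_draw = n_draw,
        seed = child_seed(seed, nm, d, stream = "corr"),
        method = method, label = paste0(nm, "_dbh", d))
      tibble::tibble(pair = nm, dbh = d, r = cr$r, ci_lower = cr$ci_lower,
                     ci_upper = cr$ci_upper, significant = cr$significant,
                     negative_significant = cr$negative_significant)
    })
  })
  verdict <- corr_rows |>
    dplyr::filter(.data$pair == "colonization_vs_sor") |>
    dplyr::transmute(dbh = .data$dbh, tradeoff = .data$negative_significant)
  structure(list(included = screen, fits = fits, trap_boots = trap_boots,
                 quadrat_boots = quadrat_boots, abilities = abilities,
                 crowding = crowding, nc_high = nc_high,
                 correlations = corr_rows, verdict = verdict,
                 method = method, dbh = dbh, seed = seed),
            class = "tradeoff_analysis")
}

#' @export
print.tradeoff_analysis <- function(x, ...) {
  cat("<tradeoff_analysis> ", length(x$fits), " species, NC 97.5th pct = ",
      round(x$nc_high, 3), ", ", x$method, " correlations\n", sep = "")
  print(x$correlations, n = Inf)
  invisible(x)
}
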