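#' Tidy a seed-shadow fit
#'
#' @param x A `seed_shadow_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.seed_shadow_fit <- function(x, ...) {
  tibble::tibble(
    species = x$species,
    term = c("beta", names(x$kernel$params)),
    estimate = c(x$beta, unname(x$kernel$params)))
}

#' @rdname tidy.seed_shadow_fit
#' @export
glance.seed_shadow_fit <- function(x, ...) {
  tibble::tibble(species = x$species, family = x$family,
                 logLik = x$logLik, AIC = x$aic, n_params = x$n_params,
                 n_traps = x$n_traps, n_trees = x$n_trees,
                 total_seeds = x$total_seeds, converged = x$converged)
}

#' Tidy a survival fit
#'
#' @param x A `survival_fit`.
#' @param ... Unused.
#' @export
tidy.survival_fit <- function(x, ...) {
  tibble::tibble(species = x$species %||% NA_character_,
                 term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname tidy.survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble::tibble(species = x$species %||% NA_character_,
                 logLik = x$logLik, n_obs = x$n_obs,
                 converged = x$converged, method = x$method)
}

#' Tidy bootstrap distributions
#'
#' Summarises a trap or quadrat bootstrap as one row per quantity with its
#' mean and 95% percentile CI.
#'
#' @param x A `trap_bootstrap` or `quadrat_bootstrap`.
#' @param ... Unused.
#' @export
tidy.trap_bootstrap <- function(x, ...) {
  dplyr::mutate(boot_ci(x), species = x$species, .before = 1)
}

#' @rdname tidy.trap_bootstrap
#' @export
tidy.quadrat_bootstrap <- function(x, ...) {
  dplyr::mutate(boot_ci(x), species = x$species %||% NA_character_,
                .before = 1)
}

#' Tidy a paired-bootstrap correlation
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(label = x$label %||% NA_character_, r = x$r,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 significant = x$significant,
                 negative_significant = x$negative_significant,
                 n_species = x$n_species, n_draw = x$n_draw,
                 method = x$method)
}

#' Tidy a trait PCA
#'
#' @param x A `trait_pca`.
#' @param ... Unused.
#' @return Loadings in long form with per-component variance fractions.
#' @export
tidy.trait_pca <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    trait = rep(rownames(L), ncol(L)),
    component = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L)) |>
    dplyr::left_join(
      tibble::tibble(component = colnames(L),
                     variance_fraction = x$variance_fraction),
      by = "component")
}

#' @rdname tidy.trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  k <- x$n_components
  tibble::tibble(n_species = nrow(x$scores),
                 n_traits = nrow(x$loadings),
                 n_components = k,
                 variance_explained = sum(x$variance_fraction[seq_len(k)]))
}

#' Tidy a full trade-off analysis
#'
#' @param x A `tradeoff_analysis`.
#' @param ... Unused.
#' @return The correlation table (one row per pair x diameter).
#' @export
tidy.tradeoff_analysis <- function(x, ...) x$correlations

#' @rdname tidy.tradeoff_analysis
#' @export
glance.tradeoff_analysis <- function(x, ...) {
  tibble::tibble(n_species = length(x$fits), nc_high = x$nc_high,
                 method = x$method,
                 any_tradeoff = any(x$verdict$tradeoff))
}
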