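#' Leaf lamina density
#'
#' Derived trait \eqn{1/(SLA \times thickness)}: the dry-mass density of the
#' leaf lamina (g cm\eqn{^{-3}}), given specific leaf area in
#' cm\eqn{^2} g\eqn{^{-1}} and lamina thickness in cm.
#'
#' @param sla Specific leaf area (cm\eqn{^2} g\eqn{^{-1}}); positive.
#' @param thickness Lamina thickness (cm); positive.
#' @return Lamina density (g cm\eqn{^{-3}}).
#' @examples
#' leaf_lamina_density(200, 0.02) # 0.25
#' @export
leaf_lamina_density <- function(sla, thickness) {
  if (any(!is.finite(sla)) || any(sla <= 0) ||
      any(!is.finite(thickness)) || any(thickness <= 0)) {
    stop("`sla` and `thickness` must be strictly positive", call. = FALSE)
  }
  1 / (sla * thickness)
}

#' PCA of the species trait table
#'
#' Principal components analysis of the standardized (zero-mean,
#' unit-variance) trait matrix, one row per species. Component signs follow
#' the convention that the largest-magnitude loading of each component is
#' positive. Missing trait values are an error (no imputation), as is a
#' constant trait column.
#'
#' @param traits Data frame with a `species` column and numeric trait
#'   columns.
#' @param n_components Number of components to retain in the summary
#'   (scores and loadings for all components are returned regardless).
#' @return An object of class `trait_pca`: `scores` (tibble, species x PC),
#'   `loadings` (matrix, trait x PC, orthonormal), `variance_fraction`
#'   (per component), `n_components`.
#' @export
trait_pca <- function(traits, n_components = 3) {
  traits <- tibble::as_tibble(traits)
  stopifnot("species" %in% names(traits))
  mat <- as.matrix(dplyr::select(traits, -"species"))
  rownames(mat) <- traits$species
  if (nrow(mat) < 3L) {
    stop("need at least 3 species for a PCA", call. = FALSE)
  }
  if (anyNA(mat)) {
    bad <- colnames(mat)[colSums(is.na(mat)) > 0]
    stop("missing trait values in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = tibble::as_tibble(pc$x) |>
      dplyr::mutate(species = traits$species, .before = 1),
    loadings = pc$rotation,
    variance_fraction = varfrac,
    n_components = min(n_components, ncol(pc$rotation))),
    class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- x$n_components
  cat("<trait_pca> ", nrow(x$scores), " species, ", nrow(x$loadings),
      " traits; first ", k, " PCs explain ",
      round(100 * sum(x$variance_fraction[seq_len(k)]), 1), "% of variance\n",
      sep = "")
  invisible(x)
}

#' Correlation of a fixed trait with a bootstrapped ability
#'
#' Like [paired_bootstrap_correlation()], but one side is a fixed
#' per-species scalar (a trait value or PC score): each draw samples one
#' replicate per species from the ability's bootstrap distribution and
#' correlates it against the fixed values.
#'
#' @param trait_values Data frame with columns `species` and `value`
#'   (fixed trait or PC score per species).
#' @param ability_boot Tibble with columns `species`, `value` (bootstrap
#'   replicates; see [boot_quantity()]).
#' @param n_draw Number of draws (default 1000).
#' @param seed Integer seed.
#' @param method `"pearson"` or `"spearman"`.
#' @param label Optional label.
#' @return A `correlation_result`; the point `r` correlates the trait with
#'   the per-species bootstrap means.
#' @export
trait_ability_correlation <- function(trait_values, ability_boot,
                                      n_draw = 1000, seed = 1L,
                                      method = c("pearson", "spearman"),
                                      label = NULL) {
  trait_values <- tibble::as_tibble(trait_values)
  stopifnot(all(c("species", "value") %in% names(trait_values)))
  # a point-mass "distribution" per species reuses the paired machinery
  paired_bootstrap_correlation(trait_values, ability_boot,
                               n_draw = n_draw, seed = seed,
                               method = method, label = label)
}
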