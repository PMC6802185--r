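#' Assemble a seed-rain dataset
#'
#' Bundles the mapped stems, seed traps, pooled per-trap seed counts and
#' species metadata that the inverse model consumes. Counts are totals over
#' the observation window (`years`), one row per trap x species.
#'
#' @param trees Data frame with columns `id`, `species`, `x`, `y` (m),
#'   `dbh` (cm) and optionally `survived` (logical, used by the survival
#'   models).
#' @param traps Data frame with columns `id`, `x`, `y` (m), `area` (m^2).
#' @param counts Data frame with columns `trap_id`, `species`, `count`
#'   (non-negative integers, pooled over the window).
#' @param species_meta Data frame with columns `species`, `dbh_r`
#'   (reproductive threshold, cm), `dbh_m` (maximum observed DBH, cm) and
#'   optionally `growth_form`.
#' @param years Length of the observation window in years (default 10).
#' @param plot Plot dimensions `c(width, height)` in meters
#'   (default `c(500, 400)`, a 20-ha rectangle).
#' @return An object of class `seed_dataset`.
#' @export
seed_dataset <- function(trees, traps, counts, species_meta, years = 10,
                         plot = c(500, 400)) {
  trees <- tibble::as_tibble(trees)
  traps <- tibble::as_tibble(traps)
  counts <- tibble::as_tibble(counts)
  species_meta <- tibble::as_tibble(species_meta)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  need(trees, c("id", "species", "x", "y", "dbh"), "`trees`")
  need(traps, c("id", "x", "y", "area"), "`traps`")
  need(counts, c("trap_id", "species", "count"), "`counts`")
  need(species_meta, c("species", "dbh_r", "dbh_m"), "`species_meta`")
  if (!is.numeric(years) || length(years) != 1L || years <= 0) {
    stop("`years` must be a single positive number", call. = FALSE)
  }
  if (any(trees$dbh < 1)) {
    stop("census convention: all mapped stems have DBH >= 1 cm", call. = FALSE)
  }
  if (any(trees$x < 0 | trees$x > plot[1] | trees$y < 0 | trees$y > plot[2])) {
    stop("tree coordinates fall outside the plot rectangle", call. = FALSE)
  }
  if (any(traps$area <= 0)) stop("trap areas must be positive", call. = FALSE)
  if (any(counts$count < 0) || any(counts$count != floor(counts$count))) {
    stop("seed counts must be non-negative integers", call. = FALSE)
  }
  if (any(species_meta$dbh_r <= 0)) {
    stop("reproductive thresholds `dbh_r` must be positive", call. = FALSE)
  }
  bad <- setdiff(counts$trap_id, traps$id)
  if (length(bad)) {
    stop("counts refer to unknown trap id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(trees = trees, traps = traps, counts = counts,
                 species_meta = species_meta, years = years, plot = plot),
            class = "seed_dataset")
}

#' @export
print.seed_dataset <- function(x, ...) {
  cat("<seed_dataset> ", nrow(x$trees), " stems, ", nrow(x$traps),
      " traps, ", length(unique(x$counts$species)), " species with counts, ",
      x$years, " yr window, plot ", x$plot[1], " x ", x$plot[2], " m\n",
      sep = "")
  invisible(x)
}

#' Species meeting the seed-rain inclusion rule
#'
#' A species enters the dispersal analysis only with enough signal in the
#' traps: at least `min_seeds` seeds collected in total and present in at
#' least `min_traps` distinct traps (defaults 250 and 20).
#'
#' @param dataset A [seed_dataset()].
#' @param min_seeds Minimum total seed count.
#' @param min_traps Minimum number of traps with at least one seed.
#' @return A tibble with columns `species`, `total_seeds`, `n_traps_present`,
#'   `included`.
#' @export
include_species <- function(dataset, min_seeds = 250, min_traps = 20) {
  stopifnot(inherits(dataset, "seed_dataset"))
  dataset$counts |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total_seeds = sum(.data$count),
                     n_traps_present = sum(.data$count > 0),
                     .groups = "drop") |>
    dplyr::mutate(included = .data$total_seeds >= min_seeds &
                    .data$n_traps_present >= min_traps)
}

#' Expected seed count in one trap
#'
#' Sums the seed shadow of every reproductive conspecific over the window:
#' \deqn{\lambda = \mathrm{years} \times \mathrm{area} \times
#'   \sum_{i: dbh_i \ge dbh_r} \beta\,BA(dbh_i)\,P(d_i)}
#' where \eqn{d_i} is the tree-to-trap distance and \eqn{P} the kernel
#' density per m\eqn{^2}.
#'
#' @param trees Data frame of conspecific stems (`x`, `y`, `dbh`).
#' @param trap A single trap: list or one-row data frame with `x`, `y`,
#'   `area`.
#' @param beta Fecundity parameter (seeds cm\eqn{^{-2}} yr\eqn{^{-1}}).
#' @param kernel A [dispersal_kernel()].
#' @param years Observation window (yr).
#' @param dbh_r Reproductive DBH threshold (cm).
#' @param plot Optional plot rectangle `c(width, height)`; a trap outside it
#'   triggers a warning but is still computed.
#' @return Expected seed count (dimensionless).
#' @export
expected_trap_count <- function(trees, trap, beta, kernel, years, dbh_r,
                                plot = NULL) {
  trap <- as.list(trap)
  if (!is.null(plot) &&
      (trap$x < 0 || trap$x > plot[1] || trap$y < 0 || trap$y > plot[2])) {
    warning("trap lies outside the plot rectangle; computing anyway")
  }
  rep_trees <- trees[trees$dbh >= dbh_r, , drop = FALSE]
  if (nrow(rep_trees) == 0L) return(0)
  d <- sqrt((rep_trees$x - trap$x)^2 + (rep_trees$y - trap$y)^2)
  years * trap$area *
    sum(fecundity(beta, rep_trees$dbh) * kernel_density(kernel, d))
}

# precompute the trap x tree geometry for one species once; everything the
# likelihood needs is then two vectorized operations per evaluation
shadow_prep <- function(dataset, species) {
  meta <- dataset$species_meta[dataset$species_meta$species == species, ]
  if (nrow(meta) != 1L) {
    stop("species '", species, "' not found in species metadata",
         call. = FALSE)
  }
  tr <- dataset$trees[dataset$trees$species == species &
                        dataset$trees$dbh >= meta$dbh_r, , drop = FALSE]
  if (nrow(tr) == 0L) {
    stop("no reproductive trees (DBH >= ", meta$dbh_r, " cm) for species '",
         species, "': fit impossible", call. = FALSE)
  }
  traps <- dataset$traps
  cnt <- dataset$counts[dataset$counts$species == species, , drop = FALSE]
  n <- cnt$count[match(traps$id, cnt$trap_id)]
  n[is.na(n)] <- 0L
  D <- outer(traps$x, tr$x, "-")^2 + outer(traps$y, tr$y, "-")^2
  list(D = sqrt(D),                      # ntraps x ntrees distances (m)
       ba = basal_area(tr$dbh),          # cm^2
       area = traps$area, n = as.numeric(n),
       years = dataset$years, dbh_r = meta$dbh_r, dbh_m = meta$dbh_m,
       n_trees = nrow(tr), n_traps = nrow(traps))
}

# lambda per trap for given beta/kernel on a prepared geometry
prep_lambda <- function(prep, beta, kernel, idx = NULL) {
  P <- kdens(kernel, prep$D)
  contrib <- as.vector(P %*% prep$ba) * prep$years * prep$area
  lam <- beta * contrib
  if (is.null(idx)) lam else lam[idx]
}

poisson_nll_terms <- function(lambda, n) {
  out <- lambda + lgamma(n + 1)
  pos <- n > 0
  if (any(pos)) {
    bad <- pos & lambda <= 0
    if (any(bad)) return(1e12)   # sentinel: positive count, zero intensity
    out[pos] <- out[pos] - n[pos] * log(lambda[pos])
  }
  sum(out)
}

#' Poisson negative log-likelihood of the seed shadow
#'
#' The inverse model assumes each trap's pooled count is Poisson with mean
#' \eqn{\lambda_k} from [expected_trap_count()]. This evaluates
#' \eqn{\sum_k [\lambda_k - n_k \ln \lambda_k + \ln(n_k!)]} at parameters
#' supplied on the log scale.
#'
#' @param theta Numeric vector `log(beta)` followed by the log kernel
#'   parameters (1 or 2 depending on `family`).
#' @param dataset A [seed_dataset()].
#' @param species Species code to fit.
#' @param family Kernel family name.
#' @return The negative log-likelihood (finite unless a trap with a positive
#'   count receives zero intensity, which returns a large sentinel).
#' @export
seed_nll <- function(theta, dataset, species, family) {
  stopifnot(inherits(dataset, "seed_dataset"))
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  k <- kernel_n_params(family)
  if (length(theta) != 1L + k) {
    stop("`theta` must have length ", 1L + k, " for family '", family, "'",
         call. = FALSE)
  }
  prep <- shadow_prep(dataset, species)
  kern <- dispersal_kernel(family, b1 = exp(theta[2]),
                           b2 = if (k == 2L) exp(theta[3]) else NULL)
  lam <- prep_lambda(prep, exp(theta[1]), kern)
  poisson_nll_terms(lam, prep$n)
}

# documented multi-start grids on the natural scale of each family
kernel_start_grid <- function(family) {
  switch(family,
    negative_exponential = lapply(c(3, 8, 15, 30, 60), function(b) c(b1 = b)),
    two_dim_t = {
      g <- expand.grid(u = c(25, 225, 1600), p = c(0.5, 1.5))
      lapply(seq_len(nrow(g)), function(i) c(b1 = g$u[i], b2 = g$p[i]))
    },
    lognormal = {
      g <- expand.grid(a = c(5, 15, 40), b = c(0.5, 1))
      lapply(seq_len(nrow(g)), function(i) c(b1 = g$a[i], b2 = g$b[i]))
    },
    weibull = {
      g <- expand.grid(a = c(5, 15, 40), cshape = c(0.7, 1.5))
      lapply(seq_len(nrow(g)), function(i) c(b1 = g$a[i], b2 = g$cshape[i]))
    }
  )
}

# profile NLL over kernel parameters: for fixed kernel the Poisson MLE of
# beta is closed-form (sum n / sum c), so the optimizer works in 1-2
# dimensions on the log scale
profile_fit <- function(prep, family, starts = NULL, reltol = 1e-8,
                        fast = FALSE) {
  k <- kernel_n_params(family)
  total_n <- sum(prep$n)
  obj <- function(log_kpar) {
    kern <- dispersal_kernel(family, b1 = exp(log_kpar[1]),
                             b2 = if (k == 2L) exp(log_kpar[2]) else NULL)
    P <- kdens(kern, prep$D)
    contrib <- as.vector(P %*% prep$ba) * prep$years * prep$area
    sc <- sum(contrib)
    if (!is.finite(sc) || sc <= 0) return(1e12)
    beta_hat <- total_n / sc
    poisson_nll_terms(beta_hat * contrib, prep$n)
  }
  if (is.null(starts)) starts <- kernel_start_grid(family)
  lower <- rep(log(1e-3), k); upper <- rep(log(1e7), k)
  if (k == 2L) { lower[2] <- log(0.02); upper[2] <- log(60) }
  if (fast && k == 1L) {
    # warm bootstrap refits: the 1-D profile is smooth, Brent needs no
    # gradient and an order of magnitude fewer evaluations
    res <- stats::optimize(function(lp) obj(lp), lower = log(0.3),
                           upper = log(2000), tol = 1e-9)
    kern <- dispersal_kernel(family, b1 = exp(res$minimum))
    P <- kdens(kern, prep$D)
    contrib <- as.vector(P %*% prep$ba) * prep$years * prep$area
    return(list(kernel = kern, beta = total_n / sum(contrib),
                nll = res$objective, converged = TRUE, n_starts_ok = 1L))
  }
  if (fast) starts <- starts[1]
  # bootstrap refits tolerate the standard L-BFGS-B factor; the full fit
  # polishes to ~1e-8 relative on the objective
  factr <- if (fast) 1e7 else reltol / .Machine$double.eps
  best <- NULL
  n_ok <- 0L
  for (s in starts) {
    res <- tryCatch(
      stats::optim(log(unname(s)), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = factr, maxit = 300)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) return(NULL)
  kern <- dispersal_kernel(family, b1 = exp(best$par[1]),
                           b2 = if (k == 2L) exp(best$par[2]) else NULL)
  P <- kdens(kern, prep$D)
  contrib <- as.vector(P %*% prep$ba) * prep$years * prep$area
  beta_hat <- total_n / sum(contrib)
  list(kernel = kern, beta = beta_hat, nll = best$value,
       converged = best$convergence == 0, n_starts_ok = n_ok)
}

#' Fit the seed shadow of one species
#'
#' Jointly estimates the size-independent fecundity parameter \eqn{\beta} and
#' the kernel parameters by maximum likelihood (Poisson trap counts), using a
#' documented multi-start grid with parameters on the log scale. For fixed
#' kernel parameters \eqn{\beta} has a closed-form Poisson MLE, so the
#' numerical search runs over the kernel parameters only; the result is the
#' joint MLE.
#'
#' @param dataset A [seed_dataset()].
#' @param species Species code.
#' @param family Kernel family name (see [dispersal_kernel()]).
#' @param starts Optional list of named start vectors on the natural scale;
#'   defaults to the family's grid.
#' @return An object of class `seed_shadow_fit` with elements `species`,
#'   `family`, `kernel`, `beta`, `logLik`, `n_params`, `aic`, `converged`,
#'   `n_trees`, `n_traps`, `total_seeds`.
#' @export
fit_seed_shadow <- function(dataset, species, family, starts = NULL) {
  stopifnot(inherits(dataset, "seed_dataset"))
  family <- match.arg(family, kernel_families())
  prep <- shadow_prep(dataset, species)
  if (sum(prep$n) == 0) {
    stop("species '", species,
         "' has no seeds in any trap: fit impossible", call. = FALSE)
  }
  res <- profile_fit(prep, family, starts = starts)
  if (is.null(res)) {
    stop("all optimizer starts failed for species '", species,
         "', family '", family, "'", call. = FALSE)
  }
  n_params <- 1L + kernel_n_params(family)
  ll <- -res$nll
  structure(list(species = species, family = family, kernel = res$kernel,
                 beta = res$beta, logLik = ll, n_params = n_params,
                 aic = 2 * n_params - 2 * ll, converged = res$converged,
                 n_trees = prep$n_trees, n_traps = prep$n_traps,
                 total_seeds = sum(prep$n), dbh_m = prep$dbh_m),
            class = "seed_shadow_fit")
}

#' @export
print.seed_shadow_fit <- function(x, ...) {
  cat("<seed_shadow_fit> ", x$species, " | ", x$family,
      " | beta = ", signif(x$beta, 4),
      " | ", paste(names(x$kernel$params), signif(x$kernel$params, 4),
                   sep = " = ", collapse = ", "),
      " | AIC = ", round(x$aic, 2),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Fit all four kernel families for one species
#'
#' @inheritParams fit_seed_shadow
#' @param families Character vector of families (default all four).
#' @return A named list of `seed_shadow_fit` objects; families whose fit
#'   failed are dropped with a warning.
#' @export
fit_all_kernels <- function(dataset, species, families = kernel_families()) {
  fits <- purrr::map(families, function(fam) {
    tryCatch(fit_seed_shadow(dataset, species, fam),
             error = function(e) {
               warning("family '", fam, "' failed for '", species, "': ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  names(fits) <- families
  purrr::compact(fits)
}

#' Select the best kernel by AIC
#'
#' Returns the fit with the lowest AIC. Exact ties are broken first by fewer
#' parameters, then by the fixed family order (negative_exponential,
#' two_dim_t, lognormal, weibull).
#'
#' @param fits A list of `seed_shadow_fit` objects for one species.
#' @return The selected `seed_shadow_fit`.
#' @export
select_best_kernel <- function(fits) {
  fits <- purrr::compact(fits)
  fits <- purrr::keep(fits, ~ inherits(.x, "seed_shadow_fit"))
  if (length(fits) == 0L) {
    stop("no converged fits to select from", call. = FALSE)
  }
  ord <- order(purrr::map_dbl(fits, "aic"),
               purrr::map_int(fits, "n_params"),
               match(purrr::map_chr(fits, "family"), kernel_families()))
  fits[[ord[1]]]
}
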