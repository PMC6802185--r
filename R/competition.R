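#' Neighborhood crowding index
#'
#' For each focal stem, the crowding index is the log of the
#' distance-decayed basal area of all larger neighbors within `radius`:
#' \deqn{NC_i = \ln\!\Big(\sum_j \pi (D_j/2)^2 \exp(-0.2\,d_{ij})\Big)}
#' where the sum runs over stems of any species with DBH strictly greater
#' than the focal's and \eqn{0 < d_{ij} \le} `radius`. Focals with no such
#' neighbor have an undefined index (`NA`). `edge_ok` flags focals more than
#' `edge_buffer` m from every plot edge, whose neighborhoods are fully
#' observed.
#'
#' Neighbor search uses a grid-cell spatial index (cells of size `radius`),
#' so the cost is near-linear in the number of stems.
#'
#' @param trees Data frame with `id`, `species`, `x`, `y` (m), `dbh` (cm).
#' @param radius Neighborhood radius in meters (default 15).
#' @param decay Distance decay rate per meter (default 0.2).
#' @param plot Plot rectangle `c(width, height)` (m).
#' @param edge_buffer Distance from the edge within which neighborhoods are
#'   incomplete (default = `radius`).
#' @return A tibble: `id`, `species`, `x`, `y`, `dbh`, `nc`, `n_neighbors`,
#'   `edge_ok`, in the input row order.
#' @export
neighborhood_crowding <- function(trees, radius = 15, decay = 0.2,
                                  plot = c(500, 400), edge_buffer = radius) {
  trees <- tibble::as_tibble(trees)
  stopifnot(all(c("id", "species", "x", "y", "dbh") %in% names(trees)))
  n <- nrow(trees)
  x <- trees$x; y <- trees$y; dbh <- trees$dbh
  ba <- basal_area(dbh)
  cx <- floor(x / radius); cy <- floor(y / radius)
  ncx <- max(cx) - min(cx) + 1L
  key <- (cx - min(cx)) + (cy - min(cy)) * ncx
  by_cell <- split(seq_len(n), key)
  cell_of <- match(as.character(key), names(by_cell))
  nc <- rep(NA_real_, n)
  n_neigh <- integer(n)
  for (cell in names(by_cell)) {
    focals <- by_cell[[cell]]
    k <- as.integer(cell)
    kx <- k %% ncx; ky <- k %/% ncx
    cand <- integer(0)
    for (dxc in -1:1) for (dyc in -1:1) {
      nb <- as.character((kx + dxc) + (ky + dyc) * ncx)
      if (dxc == 0 && dyc == 0) next
      if (kx + dxc < 0 || kx + dxc >= ncx) next
      if (!is.null(by_cell[[nb]])) cand <- c(cand, by_cell[[nb]])
    }
    cand <- c(cand, focals)
    d2 <- outer(x[focals], x[cand], "-")^2 + outer(y[focals], y[cand], "-")^2
    keep <- d2 <= radius^2 & d2 > 0
    larger <- outer(dbh[focals], dbh[cand], "<")
    contrib <- matrix(rep(ba[cand], each = length(focals)),
                      nrow = length(focals)) * exp(-decay * sqrt(d2))
    contrib[!(keep & larger)] <- 0
    s <- rowSums(contrib)
    n_neigh[focals] <- as.integer(rowSums(keep & larger))
    nc[focals] <- ifelse(s > 0, log(s), NA_real_)
  }
  tibble::tibble(id = trees$id, species = trees$species,
                 x = x, y = y, dbh = dbh, nc = nc, n_neighbors = n_neigh,
                 edge_ok = x > edge_buffer & x < plot[1] - edge_buffer &
                   y > edge_buffer & y < plot[2] - edge_buffer)
}

# Jeffreys-prior (Firth) penalized logistic regression, used when ordinary
# ML separates; returns finite estimates for any data configuration
firth_logit <- function(X, y, maxit = 200, tol = 1e-10) {
  b <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- inv_logit(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X * w, X)
    XtWXinv <- solve(XtWX)
    h <- rowSums((X %*% XtWXinv) * X) * w
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(XtWXinv %*% U)
    step <- 1
    while (max(abs(step * delta)) > 5) step <- step / 2
    b <- b + step * delta
    if (max(abs(step * delta)) < tol) break
  }
  eta <- drop(X %*% b)
  p <- inv_logit(eta)
  w <- pmax(p * (1 - p), 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p)) +
    0.5 * determinant(crossprod(X * w, X), logarithm = TRUE)$modulus
  list(coef = b, logLik = as.numeric(ll), iter = it)
}

#' Fit a species-level logistic survival model
#'
#' Survival over one census interval is modeled on the logit scale as a
#' linear function of initial diameter and the neighborhood crowding index:
#' \eqn{\mathrm{logit}(s) = \beta_0 + \beta_D\,dbh + \beta_{NC}\,NC}. Only
#' focals with a defined NC and complete neighborhoods (`edge_ok`) enter the
#' fit. When ordinary maximum likelihood separates (or fails to converge), a
#' Jeffreys-prior penalized fit is used instead and flagged in `method`.
#'
#' @param data Data frame with columns `survived` (logical or 0/1), `dbh`,
#'   `nc`, and optionally `edge_ok` (assumed `TRUE` if absent).
#' @param species Optional species label carried into the result.
#' @param min_obs Minimum number of usable focals (default 20).
#' @return An object of class `survival_fit` with coefficients `intercept`,
#'   `dbh`, `nc` on the logit scale, `logLik`, `n_obs`, `converged`,
#'   `method` (`"ml"` or `"firth"`).
#' @export
fit_survival <- function(data, species = NULL, min_obs = 20) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("survived", "dbh", "nc") %in% names(data)))
  if (!"edge_ok" %in% names(data)) data$edge_ok <- TRUE
  d <- dplyr::filter(data, .data$edge_ok, is.finite(.data$nc))
  if (nrow(d) < min_obs) {
    stop("too few usable focals (", nrow(d), " < ", min_obs,
         ") to fit a survival model", call. = FALSE)
  }
  y <- as.numeric(d$survived)
  X <- cbind(1, d$dbh, d$nc)
  colnames(X) <- c("intercept", "dbh", "nc")
  method <- "ml"
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  p <- fit$fitted.values
  separated <- !fit$converged || any(abs(fit$coefficients) > 20) ||
    all(y == 1) || all(y == 0) ||
    any(p > 1 - 1e-10 & y == 1) && any(p < 1e-10 & y == 0)
  if (all(y == 1) || all(y == 0) || separated) {
    method <- "firth"
    ff <- firth_logit(X, y)
    coefs <- ff$coef
    ll <- ff$logLik
    converged <- TRUE
  } else {
    coefs <- fit$coefficients
    ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    converged <- fit$converged
  }
  names(coefs) <- c("intercept", "dbh", "nc")
  structure(list(species = species, coef = coefs, logLik = ll,
                 n_obs = nrow(d), converged = converged, method = method),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit>", if (!is.null(x$species)) x$species else "",
      sprintf("logit(s) = %.3f %+.4f dbh %+.4f nc", x$coef[1], x$coef[2],
              x$coef[3]),
      paste0("(n = ", x$n_obs, ", ", x$method, ")"), "\n")
  invisible(x)
}

#' Community-wide crowding percentile
#'
#' The high-crowding reference level at which competitive ability is read
#' off: the `q`-th percentile (linear interpolation) of all defined NC
#' values pooled across species.
#'
#' @param nc_values Numeric vector of defined NC values (NAs dropped).
#' @param q Percentile in \[0, 100\] (default 97.5).
#' @return The NC value at that percentile.
#' @export
crowding_percentile <- function(nc_values, q = 97.5) {
  nc_values <- nc_values[is.finite(nc_values)]
  if (length(nc_values) == 0L) {
    stop("no defined NC values to take a percentile of", call. = FALSE)
  }
  percentile(nc_values, q)
}

#' Predicted survival probability
#'
#' @param fit A [fit_survival()] result.
#' @param dbh Diameter(s) in cm.
#' @param nc Crowding index value.
#' @return Survival probabilities in (0, 1).
#' @export
predict_survival <- function(fit, dbh, nc) {
  stopifnot(inherits(fit, "survival_fit"))
  inv_logit(fit$coef[["intercept"]] + fit$coef[["dbh"]] * dbh +
              fit$coef[["nc"]] * nc)
}

#' Survival odds ratio
#'
#' Competitive ability metric: the odds \eqn{s/(1-s)} of surviving the
#' census interval at a given diameter and crowding level, typically at the
#' community-wide 97.5th crowding percentile. Diameters above the species'
#' maximum observed DBH are not predicted and return `NA` with a warning.
#'
#' @inheritParams predict_survival
#' @param dbh_m Maximum observed DBH for the species (cm); predictions are
#'   refused above it (default `Inf`).
#' @return Odds ratios in \eqn{(0, \infty)}; `NA` where `dbh > dbh_m`.
#' @export
survival_odds_ratio <- function(fit, dbh, nc, dbh_m = Inf) {
  stopifnot(inherits(fit, "survival_fit"))
  # s/(1-s) computed as exp(linear predictor): algebraically identical and
  # immune to s rounding to 1 in floating point at high survival
  out <- exp(fit$coef[["intercept"]] + fit$coef[["dbh"]] * dbh +
               fit$coef[["nc"]] * nc)
  if (any(dbh > dbh_m)) {
    warning("dbh exceeds the species' maximum observed DBH; not predicted")
    out[dbh > dbh_m] <- NA_real_
  }
  out
}
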