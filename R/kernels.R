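#' Dispersal kernel specification
#'
#' Construct a radially symmetric two-dimensional seed dispersal kernel.
#' The kernel density \eqn{P(r)} is the probability per unit area (m\eqn{^{-2}})
#' that a seed lands at distance \eqn{r} (m) from its source, so that
#' \eqn{\int_0^\infty 2\pi r P(r)\,dr = 1}.
#'
#' Supported families and their densities:
#' \describe{
#'   \item{`negative_exponential`}{\eqn{P(r) = e^{-r/b_1} / (2\pi b_1^2)};
#'     `b1` is the scale in meters. The dispersal distance is Gamma(2, b1)
#'     distributed with mean \eqn{2 b_1}.}
#'   \item{`two_dim_t`}{\eqn{P(r) = (b_2/(\pi b_1)) (1 + r^2/b_1)^{-(b_2+1)}};
#'     `b1` is the scale \eqn{u} (m\eqn{^2}) and `b2` the shape \eqn{p}. Heavy
#'     tailed for small \eqn{p}.}
#'   \item{`lognormal`}{\eqn{P(r) = \exp(-(\ln(r/b_1))^2/(2 b_2^2)) /
#'     ((2\pi)^{3/2} b_2 r^2)}; the dispersal distance is lognormal with
#'     median `b1` (m) and log-scale SD `b2`. The pointwise density diverges as
#'     \eqn{r \to 0} when `b2` is large, but the radial integrand
#'     \eqn{2\pi r P(r)} is always finite; `kernel_density()` returns 0 at
#'     exactly \eqn{r = 0}.}
#'   \item{`weibull`}{\eqn{P(r) = (b_2/(2\pi b_1^{b_2})) r^{b_2-2}
#'     e^{-(r/b_1)^{b_2}}}; the distance is Weibull with scale `b1` (m) and
#'     shape `b2`. For `b2 < 2` the raw density diverges at the origin and is
#'     likewise handled through the radial integrand.}
#' }
#'
#' @param family One of `"negative_exponential"`, `"two_dim_t"`,
#'   `"lognormal"`, `"weibull"`.
#' @param b1 First (scale-like) parameter; strictly positive.
#' @param b2 Second (shape-like) parameter where the family has one;
#'   strictly positive. Must be omitted for `negative_exponential`.
#' @return An object of class `dispersal_kernel`.
#' @examples
#' k <- dispersal_kernel("negative_exponential", b1 = 10)
#' kernel_density(k, 0)              # 1 / (2 pi 100)
#' radial_cdf(k, 10)                 # 1 - 2/e
#' long_distance_dispersal(k)        # mass beyond 50 m
#' @export
dispersal_kernel <- function(family = c("negative_exponential", "two_dim_t",
                                        "lognormal", "weibull"),
                             b1, b2 = NULL) {
  family <- match.arg(family)
  n_expected <- kernel_n_params(family)
  if (!is.numeric(b1) || length(b1) != 1L || !is.finite(b1) || b1 <= 0) {
    stop("kernel parameter `b1` must be a single strictly positive number",
         call. = FALSE)
  }
  if (n_expected == 2L) {
    if (is.null(b2) || !is.numeric(b2) || length(b2) != 1L ||
        !is.finite(b2) || b2 <= 0) {
      stop("family '", family,
           "' needs a strictly positive second parameter `b2`", call. = FALSE)
    }
    params <- c(b1 = unname(b1), b2 = unname(b2))
  } else {
    if (!is.null(b2)) {
      stop("family 'negative_exponential' takes a single parameter",
           call. = FALSE)
    }
    params <- c(b1 = unname(b1))
  }
  structure(list(family = family, params = params),
            class = "dispersal_kernel")
}

kernel_families <- function() {
  c("negative_exponential", "two_dim_t", "lognormal", "weibull")
}

kernel_n_params <- function(family) {
  if (family == "negative_exponential") 1L else 2L
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("<dispersal_kernel> ", x$family, ": ",
      paste(names(x$params), signif(x$params, 5), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_kernel <- function(spec) {
  if (!inherits(spec, "dispersal_kernel")) {
    stop("expected a `dispersal_kernel` object", call. = FALSE)
  }
  if (any(!is.finite(spec$params)) || any(spec$params <= 0)) {
    stop("invalid kernel spec: parameters must be strictly positive",
         call. = FALSE)
  }
  invisible(spec)
}

check_distance <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  invisible(r)
}

#' Kernel density P(r)
#'
#' Seed deposition probability per unit area at distance `r` from the source.
#'
#' @param spec A [dispersal_kernel()].
#' @param r Distance(s) from the source, in meters; non-negative.
#' @return Numeric vector of densities (m\eqn{^{-2}}).
#' @export
kernel_density <- function(spec, r) {
  check_kernel(spec)
  check_distance(r)
  kdens(spec, r)
}

# validation-free density kernel shared by the likelihood and quadrature
# hot loops; callers guarantee r >= 0 and a checked spec
kdens <- function(spec, r) {
  p <- spec$params
  dims <- dim(r)
  out <- switch(spec$family,
    negative_exponential = exp(-r / p[["b1"]]) / (2 * pi * p[["b1"]]^2),
    two_dim_t = {
      u <- p[["b1"]]; sh <- p[["b2"]]
      sh / (pi * u) * (1 + r^2 / u)^(-(sh + 1))
    },
    lognormal = {
      a <- p[["b1"]]; b <- p[["b2"]]
      out <- numeric(length(r))
      pos <- r > 0
      out[pos] <- exp(-(log(r[pos] / a))^2 / (2 * b^2)) /
        ((2 * pi)^1.5 * b * r[pos]^2)
      out
    },
    weibull = {
      a <- p[["b1"]]; cc <- p[["b2"]]
      out <- numeric(length(r))
      pos <- r > 0
      out[pos] <- cc / (2 * pi * a^cc) * r[pos]^(cc - 2) *
        exp(-(r[pos] / a)^cc)
      # r = 0: finite only for shape >= 2 (0 for > 2, 1/(pi a^2) at exactly 2)
      if (any(!pos)) {
        out[!pos] <- if (cc > 2) 0 else if (cc == 2) 1 / (pi * a^2) else 0
      }
      out
    }
  )
  dim(out) <- dims
  out
}

#' Radial cumulative distribution of dispersal distance
#'
#' \eqn{\Pr(\text{distance} \le r) = \int_0^r 2\pi s P(s)\,ds}, in closed form
#' for every family.
#'
#' @inheritParams kernel_density
#' @return Probabilities in \[0, 1\].
#' @export
radial_cdf <- function(spec, r) {
  check_kernel(spec)
  check_distance(r)
  p <- spec$params
  switch(spec$family,
    negative_exponential = {
      b <- p[["b1"]]
      1 - (1 + r / b) * exp(-r / b)
    },
    two_dim_t = 1 - (1 + r^2 / p[["b1"]])^(-p[["b2"]]),
    lognormal = stats::plnorm(r, meanlog = log(p[["b1"]]), sdlog = p[["b2"]]),
    weibull = stats::pweibull(r, shape = p[["b2"]], scale = p[["b1"]])
  )
}

#' Probability of long-distance dispersal
#'
#' Kernel mass beyond a threshold distance:
#' \eqn{LDD = 1 - \int_0^{thr} 2\pi r P(r)\,dr}. The conventional threshold
#' is 50 m.
#'
#' @inheritParams kernel_density
#' @param threshold Distance threshold in meters (default 50).
#' @return A probability in \[0, 1\].
#' @export
long_distance_dispersal <- function(spec, threshold = 50) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive distance", call. = FALSE)
  }
  1 - radial_cdf(spec, threshold)
}

#' Sample seed destinations around a source
#'
#' Draws `n` points whose distances from `origin` follow the kernel's radial
#' distribution (by inversion or the matching base-R sampler) and whose angles
#' are uniform.
#'
#' @inheritParams kernel_density
#' @param origin Numeric length-2 source location `c(x, y)` in meters.
#' @param n Number of seeds to drop.
#' @param seed Integer seed; the same seed reproduces the same points.
#' @return A tibble with columns `x`, `y` (m).
#' @export
sample_positions <- function(spec, origin = c(0, 0), n, seed = NULL) {
  check_kernel(spec)
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("`origin` must be a finite (x, y) pair", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- sample_distances(spec, n)
  theta <- stats::runif(n, 0, 2 * pi)
  tibble::tibble(x = origin[1] + r * cos(theta),
                 y = origin[2] + r * sin(theta))
}

# radial distance sampler shared by sample_positions and the MC fallbacks
sample_distances <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    negative_exponential = stats::rgamma(n, shape = 2, scale = p[["b1"]]),
    two_dim_t = {
      u <- stats::runif(n)
      sqrt(p[["b1"]] * (u^(-1 / p[["b2"]]) - 1))
    },
    lognormal = stats::rlnorm(n, meanlog = log(p[["b1"]]), sdlog = p[["b2"]]),
    weibull = stats::rweibull(n, shape = p[["b2"]], scale = p[["b1"]])
  )
}

#' Serialize / deserialize kernel specs
#'
#' Kernels serialize to JSON objects `{"family": ..., "params": [b1, b2]}`.
#'
#' @param spec A [dispersal_kernel()].
#' @return `kernel_to_json()` a JSON string; `kernel_from_json()` a
#'   `dispersal_kernel`.
#' @export
kernel_to_json <- function(spec) {
  check_kernel(spec)
  jsonlite::toJSON(list(family = spec$family,
                        params = unname(spec$params)),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname kernel_to_json
#' @param json A JSON string as produced by `kernel_to_json()`.
#' @export
kernel_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  params <- as.numeric(x$params)
  dispersal_kernel(x$family, b1 = params[1],
                   b2 = if (length(params) > 1) params[2] else NULL)
}
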