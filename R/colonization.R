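#' A rectangular canopy gap
#'
#' @param x,y Lower-left corner (m).
#' @param width,height Gap dimensions (m); default 10 x 10, roughly the crown
#'   projection of a canopy tree.
#' @param plot Optional plot rectangle `c(width, height)`; if given the gap
#'   must lie fully inside it.
#' @return An object of class `gap_rect`.
#' @export
gap_rect <- function(x, y, width = 10, height = 10, plot = NULL) {
  if (width <= 0 || height <= 0) {
    stop("gap dimensions must be positive", call. = FALSE)
  }
  if (!is.null(plot) &&
      (x < 0 || y < 0 || x + width > plot[1] || y + height > plot[2])) {
    stop("gap does not lie fully within the plot", call. = FALSE)
  }
  structure(list(x = x, y = y, width = width, height = height),
            class = "gap_rect")
}

#' Probability that a seed lands in a gap
#'
#' Integrates the dispersal kernel over the gap rectangle:
#' \eqn{p_G = \int\!\!\int_{gap} P(\|(x,y) - mother\|)\,dx\,dy}, by adaptive
#' 2D quadrature. The domain is first split at the mother's coordinates if
#' she lies inside the gap (the density may be sharply peaked around her),
#' and each panel is refined recursively until 2 x 2 subdivision changes its
#' value by less than `abstol`. If the quadrature fails, a Monte Carlo
#' estimate from sampled seed positions is returned with its standard error
#' attached as attribute `"mc_se"`.
#'
#' @param kernel A [dispersal_kernel()].
#' @param mother Source location `c(x, y)` (m).
#' @param gap A [gap_rect()].
#' @param reltol Relative tolerance of the adaptive rule on each panel.
#' @param abstol Absolute subdivision-convergence tolerance.
#' @param mc_n Monte Carlo sample size for the fallback.
#' @param mc_seed Seed for the fallback sampler.
#' @return A probability in \[0, 1\].
#' @export
gap_arrival_probability <- function(kernel, mother, gap, reltol = 1e-10,
                                    abstol = 1e-9, mc_n = 1e6,
                                    mc_seed = 1L) {
  check_kernel(kernel)
  stopifnot(inherits(gap, "gap_rect"))
  f <- function(x, y) {
    kernel_density(kernel, sqrt((x - mother[1])^2 + (y - mother[2])^2))
  }
  quad <- function(x0, x1, y0, y1) {
    tryCatch(pracma::integral2(f, x0, x1, y0, y1, reltol = reltol)$Q,
             error = function(e) NA_real_)
  }
  refine <- function(x0, x1, y0, y1, tol, depth) {
    q <- quad(x0, x1, y0, y1)
    if (!is.finite(q)) return(NA_real_)
    if (depth >= 7) return(q)
    xm <- (x0 + x1) / 2; ym <- (y0 + y1) / 2
    qs <- c(quad(x0, xm, y0, ym), quad(xm, x1, y0, ym),
            quad(x0, xm, ym, y1), quad(xm, x1, ym, y1))
    if (any(!is.finite(qs))) return(q)
    if (abs(q - sum(qs)) < tol) return(sum(qs))
    refine(x0, xm, y0, ym, tol / 4, depth + 1) +
      refine(xm, x1, y0, ym, tol / 4, depth + 1) +
      refine(x0, xm, ym, y1, tol / 4, depth + 1) +
      refine(xm, x1, ym, y1, tol / 4, depth + 1)
  }
  # panel edges: split at the mother when she falls strictly inside
  xe <- c(gap$x, gap$x + gap$width)
  ye <- c(gap$y, gap$y + gap$height)
  if (mother[1] > xe[1] && mother[1] < xe[2]) xe <- sort(c(xe, mother[1]))
  if (mother[2] > ye[1] && ye[2] > mother[2]) ye <- sort(c(ye, mother[2]))
  total <- 0
  for (i in seq_len(length(xe) - 1)) {
    for (j in seq_len(length(ye) - 1)) {
      total <- total + refine(xe[i], xe[i + 1], ye[j], ye[j + 1],
                              abstol, 0)
    }
  }
  if (is.finite(total)) return(min(max(total, 0), 1))
  set.seed(mc_seed)
  pts <- sample_positions(kernel, origin = mother, n = mc_n)
  inside <- pts$x >= gap$x & pts$x <= gap$x + gap$width &
    pts$y >= gap$y & pts$y <= gap$y + gap$height
  est <- mean(inside)
  warning("adaptive quadrature failed; Monte Carlo estimate returned ",
          "(se = ", signif(sqrt(est * (1 - est) / mc_n), 3), ")")
  structure(est, mc_se = sqrt(est * (1 - est) / mc_n))
}

#' Placement-averaged gap probability engine
#'
#' Draws `n_placements` uniformly random gap rectangles fully inside the plot
#' (fixed seed, so the estimand is deterministic) and precomputes a tensor
#' Gauss-Legendre rule over each. `mean_gap_probability()` then evaluates the
#' placement-averaged \eqn{p_G} for any kernel with a single vectorized pass,
#' which makes bootstrap re-evaluation cheap. Placements whose rectangle
#' comes within `near` meters of the mother use a much finer node grid
#' (`n_nodes_near` per axis), since the kernel may be sharply peaked there;
#' elsewhere the kernel is smooth and a coarse rule is already accurate to
#' quadrature precision.
#'
#' @param plot Plot rectangle `c(width, height)` (m).
#' @param gap Gap dimensions `c(width, height)` (m).
#' @param mother Mother location `c(x, y)`; defaults to the plot center.
#' @param n_placements Number of random placements to average over.
#' @param seed Integer seed fixing the placements.
#' @param n_nodes Gauss-Legendre nodes per axis for far placements.
#' @param n_nodes_near Nodes per axis for near-mother placements.
#' @param near Distance (m) below which a placement counts as near.
#' @return An object of class `gap_engine`.
#' @export
gap_engine <- function(plot = c(500, 400), gap = c(10, 10), mother = NULL,
                       n_placements = 1000, seed = 1L, n_nodes = 12L,
                       n_nodes_near = 48L, near = 15) {
  if (is.null(mother)) mother <- plot / 2
  if (gap[1] > plot[1] || gap[2] > plot[2]) {
    stop("gap larger than the plot", call. = FALSE)
  }
  set.seed(child_seed(seed, stream = "gap-placements"))
  x0 <- stats::runif(n_placements, 0, plot[1] - gap[1])
  y0 <- stats::runif(n_placements, 0, plot[2] - gap[2])
  # distance from mother to each placement rectangle
  dx <- pmax(x0 - mother[1], mother[1] - (x0 + gap[1]), 0)
  dy <- pmax(y0 - mother[2], mother[2] - (y0 + gap[2]), 0)
  is_near <- sqrt(dx^2 + dy^2) < near
  tensor_nodes <- function(x0s, y0s, nn) {
    gl <- pracma::gaussLegendre(nn, 0, 1)
    nx <- outer(gl$x * gap[1], x0s, "+")     # nn x n_placements
    ny <- outer(gl$x * gap[2], y0s, "+")
    xs <- nx[rep(seq_len(nn), times = nn), , drop = FALSE]
    ys <- ny[rep(seq_len(nn), each = nn), , drop = FALSE]
    list(dist = as.vector(sqrt((xs - mother[1])^2 + (ys - mother[2])^2)),
         w = rep(as.vector(outer(gl$w, gl$w)) * gap[1] * gap[2],
                 times = length(x0s)))
  }
  dist <- numeric(0); w <- numeric(0)
  if (any(!is_near)) {
    far <- tensor_nodes(x0[!is_near], y0[!is_near], n_nodes)
    dist <- far$dist; w <- far$w
  }
  if (any(is_near)) {
    nr <- tensor_nodes(x0[is_near], y0[is_near], n_nodes_near)
    dist <- c(dist, nr$dist); w <- c(w, nr$w)
  }
  structure(list(plot = plot, gap = gap, mother = mother,
                 n_placements = n_placements, seed = seed,
                 dist = dist, w = w, n_near = sum(is_near),
                 placements = tibble::tibble(x = x0, y = y0)),
            class = "gap_engine")
}

#' Placement-averaged gap arrival probability
#'
#' @param engine A [gap_engine()].
#' @param kernel A [dispersal_kernel()].
#' @return Mean of \eqn{p_G} over the engine's gap placements.
#' @export
mean_gap_probability <- function(engine, kernel) {
  stopifnot(inherits(engine, "gap_engine"))
  check_kernel(kernel)
  total <- sum(engine$w * kdens(kernel, engine$dist))
  min(max(total / engine$n_placements, 0), 1)
}

#' Colonization ability of a species
#'
#' Converts a fitted seed shadow into the colonization-rate metric. A single
#' mother tree of diameter `dbh` stands at the plot center; its annual seed
#' output is \eqn{F = \beta BA(dbh)} and each seed lands in a randomly
#' located 10 x 10 m gap with probability \eqn{p_G} (averaged over
#' `n_gap_placements` uniform placements under a fixed seed). First arrival
#' is geometric in the number of seeds, so the expected waiting time is
#' \eqn{t = 1/(p_G F)} years and colonization ability is \eqn{1/t = p_G F}.
#' The long-distance dispersal probability (kernel mass beyond 50 m) is
#' reported alongside.
#'
#' @param fit A `seed_shadow_fit` (or a list with elements `kernel`, `beta`,
#'   `species`).
#' @param dbh Diameter(s) of the hypothetical mother (cm); the conventional
#'   evaluation sizes are 5, 10 and 20 cm.
#' @param plot Plot rectangle (m); default 500 x 400 (20 ha).
#' @param gap Gap dimensions (m).
#' @param n_gap_placements Placements averaged over (default 1000). Set to 1
#'   for the single-random-gap variant.
#' @param seed Seed fixing the gap placements.
#' @param engine Optional pre-built [gap_engine()] (overrides `plot`, `gap`,
#'   `n_gap_placements`, `seed`).
#' @param ldd_threshold Long-distance threshold (m).
#' @return A tibble with one row per `dbh`: `species`, `dbh`, `fecundity`,
#'   `p_g`, `t`, `inv_t`, `ldd`.
#' @export
colonization_ability <- function(fit, dbh = c(5, 10, 20), plot = c(500, 400),
                                 gap = c(10, 10), n_gap_placements = 1000,
                                 seed = 1L, engine = NULL,
                                 ldd_threshold = 50) {
  if (any(dbh <= 0)) stop("`dbh` must be positive", call. = FALSE)
  if (is.null(engine)) {
    engine <- gap_engine(plot = plot, gap = gap,
                         n_placements = n_gap_placements, seed = seed)
  }
  p_g <- mean_gap_probability(engine, fit$kernel)
  ldd <- long_distance_dispersal(fit$kernel, ldd_threshold)
  f <- fecundity(fit$beta, dbh)
  if (p_g <= 0) {
    warning("p_G is numerically zero; colonization time is infinite")
  }
  tibble::tibble(species = fit$species %||% NA_character_,
                 dbh = dbh, fecundity = f, p_g = p_g,
                 t = ifelse(p_g > 0, 1 / (p_g * f), Inf),
                 inv_t = p_g * f, ldd = ldd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
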