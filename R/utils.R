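#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

inv_logit <- function(x) 1 / (1 + exp(-x))

# derive a reproducible child seed from a master seed and a stream label;
# stays below 2^31 so it is a valid R integer seed
child_seed <- function(seed, ..., stream = "") {
  key <- paste(c(stream, ...), collapse = "/")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) %% 7919)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# percentile with the documented linear-interpolation convention (type 7)
percentile <- function(x, q) {
  if (length(x) == 0L) stop("empty input to percentile", call. = FALSE)
  unname(stats::quantile(x, probs = q / 100, type = 7, names = FALSE))
}

#' Basal area of a stem
#'
#' \eqn{BA = \pi (DBH/2)^2}, the size measure used throughout: fecundity is
#' proportional to basal area and the crowding index sums the basal area of
#' larger neighbors.
#'
#' @param dbh Diameter at breast height in cm; strictly positive.
#' @return Basal area in cm\eqn{^2}.
#' @examples
#' basal_area(10) # ~78.54 cm^2
#' @export
basal_area <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("`dbh` must be strictly positive", call. = FALSE)
  }
  pi * (dbh / 2)^2
}

#' Size-specific fecundity
#'
#' Annual seed production of a reproductive tree:
#' \eqn{F = \beta \times BA(dbh)}, where \eqn{\beta} is the size-independent
#' fecundity parameter (seeds per cm\eqn{^2} basal area per year).
#'
#' @param beta Fecundity parameter (seeds cm\eqn{^{-2}} yr\eqn{^{-1}});
#'   non-negative.
#' @param dbh Diameter at breast height in cm.
#' @return Seeds per year.
#' @export
fecundity <- function(beta, dbh) {
  if (any(!is.finite(beta)) || any(beta < 0)) {
    stop("`beta` must be non-negative", call. = FALSE)
  }
  beta * basal_area(dbh)
}
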