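#' Read the pipeline's CSV inputs
#'
#' Column-validated readers for the four tabular inputs: the stem census
#' (`id, species, x, y, dbh[, survived]`), the trap table
#' (`id, x, y, area`), the pooled seed counts (`trap_id, species, count`)
#' and the species metadata (`species, dbh_r, dbh_m[, growth_form]`).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_census <- function(path) {
  df <- read_checked(path, c("id", "species", "x", "y", "dbh"))
  if ("survived" %in% names(df)) df$survived <- as.logical(df$survived)
  df
}

#' @rdname read_census
#' @export
read_traps <- function(path) {
  read_checked(path, c("id", "x", "y", "area"))
}

#' @rdname read_census
#' @export
read_seed_counts <- function(path) {
  read_checked(path, c("trap_id", "species", "count"))
}

#' @rdname read_census
#' @export
read_species_meta <- function(path) {
  read_checked(path, c("species", "dbh_r", "dbh_m"))
}

read_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write / read seed-shadow fits as JSON
#'
#' Fits serialize per species as
#' `{"family", "params": [b1, b2], "beta", "logLik", "aic"}`.
#'
#' @param fits A list of `seed_shadow_fit` objects (e.g. one AIC-selected
#'   fit per species).
#' @param path Output path.
#' @export
write_fits_json <- function(fits, path) {
  obj <- purrr::map(fits, function(f) {
    list(family = f$family, params = unname(f$kernel$params),
         beta = f$beta, logLik = f$logLik, aic = f$aic)
  })
  names(obj) <- purrr::map_chr(fits, "species")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fits_json
#' @return `read_fits_json()`: a named list of lists with elements
#'   `species`, `kernel`, `beta`, `logLik`, `aic`.
#' @export
read_fits_json <- function(path) {
  obj <- jsonlite::read_json(path)
  purrr::imap(obj, function(f, sp) {
    params <- as.numeric(unlist(f$params))
    list(species = sp,
         kernel = dispersal_kernel(f$family, b1 = params[1],
                                   b2 = if (length(params) > 1)
                                     params[2] else NULL),
         beta = f$beta, logLik = f$logLik, aic = f$aic)
  })
}
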