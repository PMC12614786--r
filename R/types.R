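#' Species trait table
#'
#' Bundles the per-species uptake preferences and maintenance requirements of
#' a consumer-resource community. Each row of `uptake` is one species'
#' allocation of its fixed preference budget across the M resource types;
#' `maintenance` is the minimum energy uptake a species needs for zero growth.
#'
#' @param uptake numeric S x M matrix of uptake rates c (volume/time), all
#'   entries >= 0.
#' @param maintenance numeric vector of length S, minimum energy uptake m
#'   (energy), all entries > 0. Recycled if length 1.
#' @param species_ids character vector of stable identifiers (default
#'   `"sp1"`, `"sp2"`, ...).
#' @param budget optional preference budget mu_c; when supplied, every uptake
#'   row must sum to it within 1e-9.
#' @param max_pref optional cap on the number of nonzero preferences per row.
#' @return An object of class `cr_traits`.
#' @export
cr_traits <- function(uptake, maintenance, species_ids = NULL,
                      budget = NULL, max_pref = NULL) {
  uptake <- as.matrix(uptake)
  storage.mode(uptake) <- "double"
  S <- nrow(uptake)
  maintenance <- rep_len(as.numeric(maintenance), S)
  if (is.null(species_ids))
    species_ids <- if (S == 0) character(0) else paste0("sp", seq_len(S))
  if (length(species_ids) != S)
    stop("`species_ids` must have one entry per uptake row", call. = FALSE)
  x <- structure(
    list(uptake = uptake, maintenance = maintenance,
         species_ids = as.character(species_ids)),
    budget = budget, max_pref = max_pref, class = "cr_traits")
  validate_traits(x)
  x
}

validate_traits <- function(x) {
  if (any(x$uptake < 0)) stop("uptake entries must be >= 0", call. = FALSE)
  if (any(x$maintenance <= 0)) stop("maintenance must be > 0", call. = FALSE)
  if (anyDuplicated(x$species_ids))
    stop("species ids must be unique", call. = FALSE)
  budget <- attr(x, "budget")
  if (!is.null(budget) && nrow(x$uptake) > 0) {
    rs <- rowSums(x$uptake)
    if (any(abs(rs - budget) > 1e-9))
      stop("each uptake row must sum to the preference budget", call. = FALSE)
  }
  mp <- attr(x, "max_pref")
  if (!is.null(mp)) {
    nz <- rowSums(x$uptake > 0)
    if (nrow(x$uptake) > 0 && any(nz < 1 | nz > mp))
      stop("each species must use between 1 and max_pref resources",
           call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cr_traits <- function(x, ...) {
  cat(sprintf("<cr_traits> %d species x %d resource types\n",
              nrow(x$uptake), ncol(x$uptake)))
  invisible(x)
}

#' Number of species in a trait table
#' @param traits a [cr_traits] object.
#' @return Integer species count.
#' @export
n_species <- function(traits) nrow(traits$uptake)

#' Subset a trait table by species
#' @param traits a [cr_traits] object.
#' @param keep logical or integer index of species to retain.
#' @return A `cr_traits` object with the selected rows.
#' @export
subset_traits <- function(traits, keep) {
  cr_traits(traits$uptake[keep, , drop = FALSE], traits$maintenance[keep],
            traits$species_ids[keep],
            budget = attr(traits, "budget"), max_pref = attr(traits, "max_pref"))
}

#' Concatenate two trait tables
#' @param a,b [cr_traits] objects over the same resource set.
#' @return A combined `cr_traits` object.
#' @export
bind_traits <- function(a, b) {
  stopifnot(ncol(a$uptake) == ncol(b$uptake))
  cr_traits(rbind(a$uptake, b$uptake), c(a$maintenance, b$maintenance),
            c(a$species_ids, b$species_ids),
            budget = attr(a, "budget"), max_pref = attr(a, "max_pref"))
}

#' Abiotic environment
#'
#' The resource side of the model: a supply vector K (energy
#' concentration/time) over M resource types, a dissipation rate gamma
#' (1/time), the byproduct leakage proportion l, and a column-stochastic
#' conversion matrix D where `D[a, b]` is the proportion of consumed resource
#' b leaked as resource a.
#'
#' @param supply numeric vector K of length M, entries >= 0.
#' @param conversion numeric M x M matrix D with every column summing to 1.
#' @param leakage leakage proportion l in `[0, 1]`.
#' @param dissipation dissipation rate gamma (> 0, default 1).
#' @param meta optional list of generating parameters (U, E, sigma_D, ...).
#' @return An object of class `cr_env`.
#' @export
cr_env <- function(supply, conversion, leakage, dissipation = 1,
                   meta = list()) {
  supply <- as.numeric(supply)
  conversion <- as.matrix(conversion)
  M <- length(supply)
  if (!all(dim(conversion) == c(M, M)))
    stop("`conversion` must be M x M for M = length(supply)", call. = FALSE)
  if (any(supply < 0)) stop("supply entries must be >= 0", call. = FALSE)
  if (leakage < 0 || leakage > 1)
    stop("`leakage` must lie in [0, 1]", call. = FALSE)
  if (dissipation <= 0) stop("`dissipation` must be > 0", call. = FALSE)
  cs <- colSums(conversion)
  if (any(abs(cs - 1) > 1e-9))
    stop("every column of `conversion` must sum to 1", call. = FALSE)
  structure(list(supply = supply, conversion = conversion,
                 leakage = leakage, dissipation = dissipation, meta = meta),
            class = "cr_env")
}

#' @export
print.cr_env <- function(x, ...) {
  cat(sprintf(
    "<cr_env> M=%d, supplied=%d, U=%.4g, l=%.3g, gamma=%.3g\n",
    length(x$supply), sum(x$supply > 0), sum(x$supply), x$leakage,
    x$dissipation))
  invisible(x)
}

#' Community state
#'
#' A snapshot of the dynamical variables: species population densities N
#' (1/volume) and resource concentrations R (energy/volume).
#'
#' @param populations numeric vector N of length S, entries >= 0.
#' @param resources numeric vector R of length M, entries >= 0.
#' @param time model time of the snapshot (default 0).
#' @return An object of class `cr_state`.
#' @export
cr_state <- function(populations, resources, time = 0) {
  populations <- as.numeric(populations)
  resources <- as.numeric(resources)
  if (any(populations < 0) || any(resources < 0))
    stop("state entries must be >= 0", call. = FALSE)
  structure(list(populations = populations, resources = resources,
                 time = time), class = "cr_state")
}

#' @export
print.cr_state <- function(x, ...) {
  cat(sprintf("<cr_state> S=%d (%d extant), M=%d, t=%.4g\n",
              length(x$populations), sum(x$populations > 0),
              length(x$resources), x$time))
  invisible(x)
}

#' Steady-state solver settings
#'
#' The integrator runs an adaptive Dormand-Prince RK5(4) pair in repeated
#' windows of length `horizon`; a steady state is declared when the maximum
#' relative change of every population and resource across one window drops
#' below `ss_rel_change`. Populations below the consumer extinction threshold
#' are zeroed when a steady state is returned.
#'
#' @param abs_tol solver absolute tolerance (default 1e-20, effectively
#'   pure relative error control).
#' @param rel_tol solver relative tolerance (default 1e-8).
#' @param horizon window length in model time units (default 500).
#' @param ss_rel_change steady-state relative-change tolerance (default 1e-6).
#' @param max_windows cap on repeated windows before flagging
#'   non-convergence (default 20).
#' @param extinction_threshold consumer extinction threshold L_ext
#'   (default 0.001).
#' @param extinction_mode `"relative"` (default) zeroes populations below
#'   L_ext times the total population density at the moment of
#'   thresholding; `"absolute"` applies L_ext as a density directly. The
#'   relative reading keeps serial dilution from mass-extinguishing
#'   low-supply communities whose absolute densities scale with the
#'   energy supplied.
#' @return An object of class `cr_solver_config`.
#' @export
solver_config <- function(abs_tol = 1e-20, rel_tol = 1e-8, horizon = 500,
                          ss_rel_change = 1e-6, max_windows = 20,
                          extinction_threshold = 0.001,
                          extinction_mode = c("relative", "absolute")) {
  extinction_mode <- match.arg(extinction_mode)
  stopifnot(abs_tol > 0, rel_tol > 0, horizon > 0, ss_rel_change > 0,
            ss_rel_change < 1, max_windows >= 1, extinction_threshold > 0)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol, horizon = horizon,
                 ss_rel_change = ss_rel_change, max_windows = max_windows,
                 extinction_threshold = extinction_threshold,
                 extinction_mode = extinction_mode),
            class = "cr_solver_config")
}

check_dims <- function(state, traits, env) {
  S <- length(state$populations)
  M <- length(state$resources)
  if (nrow(traits$uptake) != S || ncol(traits$uptake) != M ||
      length(env$supply) != M)
    stop("dimensions of state, traits and environment disagree",
         call. = FALSE)
  invisible(TRUE)
}
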