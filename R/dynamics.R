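#' Consumer-resource time derivatives
#'
#' Evaluates the right-hand side of the consumer-resource system with
#' byproduct leakage:
#' \deqn{dN_i/dt = N_i[(1-l)\sum_a c_{ia} R_a - m_i]}
#' \deqn{dR_a/dt = K_a - R_a(\gamma + \sum_i c_{ia} N_i) +
#'   l\sum_b R_b D_{ab} \sum_i c_{ib} N_i}
#' Consumption is linear in the resource concentration; the leakage term
#' reroutes a proportion l of all consumption through the conversion matrix,
#' so with a column-stochastic D the energy removed from resource b equals
#' the energy either converted to growth or leaked as byproducts.
#'
#' @param state a [cr_state].
#' @param traits a [cr_traits].
#' @param env a [cr_env].
#' @return A list with components `dN` (length S) and `dR` (length M).
#' @export
cr_rhs <- function(state, traits, env) {
  check_dims(state, traits, env)
  N <- state$populations
  R <- state$resources
  C <- traits$uptake
  growth <- (1 - env$leakage) * drop(C %*% R) - traits$maintenance
  cons <- drop(crossprod(C, N))   # per-resource consumption pressure
  dR <- env$supply - R * (env$dissipation + cons) +
    env$leakage * drop(env$conversion %*% (R * cons))
  list(dN = N * growth, dR = dR)
}

#' Per-capita invasion growth rate
#'
#' The instantaneous per-capita growth rate \eqn{(1-l)\sum_a c_a R_a - m} of
#' a (rare) species at the given resource concentrations. A positive value
#' predicts initial invasion success at those resource levels.
#'
#' @param traits a [cr_traits] (one rate is returned per species).
#' @param resources numeric vector of resource concentrations R.
#' @param leakage leakage proportion l.
#' @return Numeric vector of per-capita growth rates, one per species.
#' @export
invasion_growth_rate <- function(traits, resources, leakage) {
  if (ncol(traits$uptake) != length(resources))
    stop("resource vector length must match the trait matrix", call. = FALSE)
  drop((1 - leakage) * traits$uptake %*% resources) - traits$maintenance
}

#' Apply the consumer extinction threshold
#'
#' Zeroes every population strictly below the threshold. Idempotent.
#'
#' @param state a [cr_state].
#' @param threshold extinction threshold L_ext.
#' @return The thresholded `cr_state`.
#' @export
threshold_extinct <- function(state, threshold) {
  N <- state$populations
  N[N < threshold] <- 0
  cr_state(N, state$resources, state$time)
}

effective_threshold <- function(cfg, populations) {
  if (cfg$extinction_mode == "relative")
    cfg$extinction_threshold * sum(populations)
  else cfg$extinction_threshold
}

cr_integration_error <- function(msg, state) {
  structure(class = c("cr_integration_error", "error", "condition"),
            list(message = msg, call = NULL, state = state))
}

pack_parms <- function(traits, env) {
  c(n_species(traits), length(env$supply), env$leakage, env$dissipation,
    traits$maintenance, env$supply, as.double(traits$uptake),
    as.double(env$conversion))
}

# Integrate the compiled model over `n_windows` windows of `horizon` time
# units with lsoda (the dynamics are stiff: resource turnover is much
# faster than population change). Returns the state matrix at window
# boundaries, one row per boundary including t = 0.
solve_windows <- function(y0, traits, env, horizon, n_windows, cfg) {
  .Call(cr_set_parms, pack_parms(traits, env))
  times <- seq(0, horizon * n_windows, length.out = n_windows + 1)
  out <- NULL
  # BDF throughout (vode mf = 22): an Adams/functional-iteration phase can
  # diverge catastrophically on these stiff systems. On a rare failed
  # window, retry with a capped maximum step, then fall back to lsoda
  # (whose corrector survives some states vode's does not), all
  # deterministic with no RNG involved.
  attempts <- list(list("vode", NULL), list("vode", horizon / 100),
                   list("lsoda", NULL), list("lsoda", horizon / 100),
                   list("vode", horizon / 1000))
  for (att in attempts) {
    withCallingHandlers(
      out <- if (att[[1]] == "vode")
        deSolve::vode(
          y = y0, times = times, func = "cr_derivs", parms = NULL,
          dllname = "crinvade", mf = 22, hmax = att[[2]],
          atol = cfg$abs_tol, rtol = cfg$rel_tol, maxsteps = 1000000)
      else
        deSolve::lsoda(
          y = y0, times = times, func = "cr_derivs", parms = NULL,
          dllname = "crinvade", hmax = att[[2]],
          atol = cfg$abs_tol, rtol = cfg$rel_tol, maxsteps = 1000000),
      warning = function(w) invokeRestart("muffleWarning"))
    istate <- attr(out, "istate")
    ok <- !is.null(out) && (is.null(istate) || istate[1] >= 0) &&
      nrow(out) == n_windows + 1 && !anyNA(out)
    if (ok) return(out)
  }
  stop(cr_integration_error(
    "stiff solver failed to complete the integration window",
    restore_state(out, y0, traits)))
}

restore_state <- function(out, y0, traits) {
  y <- if (is.null(out) || nrow(out) == 0) y0 else out[nrow(out), -1]
  y[is.na(y)] <- 0
  S <- n_species(traits)
  M <- ncol(traits$uptake)
  cr_state(pmax(y[seq_len(S)], 0), pmax(y[S + seq_len(M)], 0))
}

#' Integrate a community to numerical steady state
#'
#' Integrates the consumer-resource system in windows of `cfg$horizon` time
#' units until the maximum relative change of every population and resource
#' across one window is below `cfg$ss_rel_change`, or until
#' `cfg$max_windows` windows have elapsed (flagged via the `converged`
#' attribute). Populations below the extinction threshold are set to 0
#' before returning; tiny solver undershoots below zero are clipped.
#'
#' @param state a [cr_state] (at least one species or resource present).
#' @param traits a [cr_traits].
#' @param env a [cr_env].
#' @param cfg a [solver_config].
#' @return A `cr_state` at (numerical) steady state, with attributes
#'   `converged` (logical) and `windows` (windows used). On step-size
#'   collapse a condition of class `cr_integration_error` is signalled,
#'   carrying the last valid state in its `state` field.
#' @export
integrate_to_steady_state <- function(state, traits, env,
                                      cfg = solver_config()) {
  check_dims(state, traits, env)
  S <- length(state$populations)
  y <- c(state$populations, state$resources)
  # relative change of a variable below the extinction threshold is
  # measured against the threshold itself, so species decaying toward
  # extinction (zeroed on return anyway) cannot stall convergence
  floor_ <- cfg$extinction_threshold
  converged <- FALSE
  windows <- 0L
  # one solver call per window; between windows, populations more than six
  # decades below the extinction threshold are flushed to zero. They are
  # ecologically extinct, and carrying them at roundoff scale makes the
  # error-weighted BDF corrector fragile (absolute tolerances far below
  # the accuracy of their own derivatives). Resources are flushed only
  # near the denormal floating-point floor.
  nflush <- 1e-6 * cfg$extinction_threshold
  flush <- function(v) {
    v[seq_len(S)][abs(v[seq_len(S)]) < nflush] <- 0
    v[abs(v) < 1e-30] <- 0
    v
  }
  y <- flush(y)
  rescues <- 0L
  while (windows < cfg$max_windows) {
    # a multi-window first call amortizes solver start-up over the usual
    # transient; later calls go window-by-window so the flush and the
    # convergence check stay fine-grained
    chunk <- if (windows == 0L) min(3L, cfg$max_windows) else 1L
    out <- tryCatch(
      solve_windows(y, traits, env, cfg$horizon, chunk, cfg),
      cr_integration_error = function(e) e)
    if (inherits(out, "cr_integration_error")) {
      # a marginal population at roundoff scale can wedge the BDF
      # corrector mid-window; apply the extinction threshold to the last
      # valid state (as the assay does after every step) and resume
      rescues <- rescues + 1L
      if (rescues > 2L) stop(out)
      st <- out$state
      Np <- st$populations
      Np[Np < effective_threshold(cfg, Np)] <- 0
      y <- flush(c(Np, st$resources))
      windows <- windows + 1L
      next
    }
    for (k in seq_len(nrow(out) - 1L)) {
      ynew <- flush(out[k + 1L, -1])
      windows <- windows + 1L
      rel <- max(abs(ynew - y) / pmax(abs(ynew), floor_))
      y <- ynew
      if (rel < cfg$ss_rel_change) {
        converged <- TRUE
        break
      }
    }
    if (converged) {
      # the converged state only counts once it is also threshold-stable:
      # removing a marginal species perturbs the balance, so integration
      # resumes after any removal (removals are monotone, so this ends)
      Nv <- pmax(y[seq_len(S)], 0)
      drop_ <- Nv > 0 & Nv < effective_threshold(cfg, Nv)
      if (any(drop_)) {
        y[seq_len(S)][drop_] <- 0
        converged <- FALSE
      } else break
    }
  }
  N <- pmax(y[seq_len(S)], 0)        # clip solver undershoot
  R <- pmax(y[S + seq_len(length(state$resources))], 0)
  N[N < effective_threshold(cfg, N)] <- 0
  out <- cr_state(N, R, state$time + windows * cfg$horizon)
  attr(out, "converged") <- converged
  attr(out, "windows") <- windows
  out
}

#' Serial dilution-propagation
#'
#' Repeats `[dilute all populations, threshold, re-equilibrate]` for the
#' given number of passages, emulating serial transfer of a community into
#' fresh medium. Species whose diluted density falls below the extinction
#' threshold and cannot regrow are removed along the way.
#'
#' @inheritParams integrate_to_steady_state
#' @param passages number of dilution-propagation steps (>= 0).
#' @param dilution_factor factor by which populations are divided (> 1).
#' @return The final `cr_state`.
#' @export
dilution_propagation <- function(state, traits, env, cfg = solver_config(),
                                 passages = 5, dilution_factor = 100) {
  stopifnot(passages >= 0, dilution_factor > 1)
  for (p in seq_len(passages)) {
    diluted <- cr_state(state$populations / dilution_factor,
                        state$resources, state$time)
    diluted <- threshold_extinct(diluted,
                                 effective_threshold(cfg, diluted$populations))
    state <- integrate_to_steady_state(diluted, traits, env, cfg)
  }
  state
}

#' Perturbation filtering of marginally stable species
#'
#' Repeatedly multiplies each population by an independent uniform factor in
#' `[1 - magnitude, 1 + magnitude]` and re-equilibrates, filtering out
#' species that only persist on a knife's edge. Uses the current R RNG
#' stream; seed via [set.seed()].
#'
#' @inheritParams integrate_to_steady_state
#' @param rounds number of perturbation rounds (>= 0).
#' @param magnitude perturbation magnitude in (0, 1).
#' @return The final `cr_state`, which has survived all rounds.
#' @export
perturbation_filter <- function(state, traits, env, cfg = solver_config(),
                                rounds = 3, magnitude = 0.5) {
  stopifnot(rounds >= 0, magnitude > 0, magnitude < 1)
  for (r in seq_len(rounds)) {
    fac <- stats::runif(length(state$populations),
                        1 - magnitude, 1 + magnitude)
    kicked <- cr_state(state$populations * fac, state$resources, state$time)
    state <- integrate_to_steady_state(kicked, traits, env, cfg)
  }
  state
}
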