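# small deterministic systems used across test files

# single species on a single resource, no cross-feeding
monoculture_system <- function(c = 10, m = 1, K = 3, gamma = 1, l = 0) {
  list(traits = cr_traits(matrix(c, 1, 1), m, "a"),
       env = cr_env(K, matrix(1, 1, 1), leakage = l, dissipation = gamma))
}

# S species over M resources with explicit uptake matrix, identity conversion
toy_system <- function(uptake, supply, l = 0, maintenance = 1) {
  M <- ncol(uptake)
  list(traits = cr_traits(uptake, maintenance),
       env = cr_env(supply, diag(M), leakage = l))
}

# closed-form monoculture steady state for l = 0
mono_closed_form <- function(c, m, K, gamma) {
  Rstar <- m / c
  list(R = Rstar, N = (K - gamma * Rstar) / (c * Rstar))
}

quiet_solver <- function(...) solver_config(...)

# independent steady-state oracle: deSolve integration of the R-level rhs,
# entirely separate from the compiled-model path used by the package
oracle_steady_state <- function(state, traits, env, t_end = 5000) {
  rhs_fun <- function(t, y, p) {
    S <- n_species(traits)
    st <- cr_state(pmax(y[seq_len(S)], 0),
                   pmax(y[S + seq_along(env$supply)], 0))
    d <- cr_rhs(st, traits, env)
    list(c(d$dN, d$dR))
  }
  out <- deSolve::ode(c(state$populations, state$resources),
                      times = c(0, t_end), func = rhs_fun, parms = NULL,
                      method = "lsoda", atol = 1e-12, rtol = 1e-10)
  y <- out[nrow(out), -1]
  S <- n_species(traits)
  cr_state(pmax(y[seq_len(S)], 0), pmax(y[S + seq_along(env$supply)], 0))
}
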