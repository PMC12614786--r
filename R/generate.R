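#' Ensemble generation settings
#'
#' Parameters for random environments, metabolic conversion matrices and
#' species pools. Defaults follow the community-generation setup of the
#' invasion assay: M = 18 resource types, preference budget mu_c = 10 spread
#' over at most 5 resource types, maintenance 1, 5% minimum conversion
#' proportion, leakage 0.8, and a 1% invader propagule.
#'
#' @param M total number of resource types (default 18).
#' @param U total resource supply (concentration/time), default 12.
#' @param E number of environmentally supplied resource types (default 5).
#' @param S0 initial species pool size. `NULL` (default) draws a random
#'   integer in `s0_range` per trial; a scalar fixes it.
#' @param s0_range range for random pool sizes (default `c(5, 50)`).
#' @param mu_c preference budget, total uptake per species (default 10).
#' @param max_pref maximum number of preferred resource types (default 5).
#' @param sigma_D metabolic spread of the conversion matrix (default 1,
#'   about 2.8 byproducts per consumed resource).
#' @param L_D minimum conversion proportion; Dirichlet entries below it are
#'   zeroed before column renormalization (default 0.05).
#' @param l byproduct leakage proportion (default 0.8).
#' @param P_inv invader propagule proportion of total resident density
#'   (default 0.01).
#' @param dirichlet_convention concentration parameter of the symmetric
#'   Dirichlet: `"ratio"` uses sigma_D / M (the calibrated default,
#'   reproducing the 1.13 / 2.83 / 5.41 mean-byproduct benchmarks at
#'   sigma_D = 0.05 / 1 / 5), `"raw"` uses sigma_D itself.
#' @param supply_mode `"simplex"` (default) allots U continuously over the E
#'   chosen resources via a uniform simplex draw; `"integer"` allots U in
#'   whole concentration units by a multinomial draw.
#' @param support_mode `"uniform"` (default) draws each species' support
#'   size uniformly from 1..max_pref; `"fixed"` uses exactly max_pref.
#' @param zero_diagonal forbid self-conversion D\[a, a\] > 0 (default FALSE).
#' @param redraw_cap attempts allowed for viability and collision redraws
#'   (default 1000).
#' @return An object of class `cr_gen_config`.
#' @export
generation_config <- function(M = 18, U = 12, E = 5, S0 = NULL,
                              s0_range = c(5, 50), mu_c = 10, max_pref = 5,
                              sigma_D = 1, L_D = 0.05, l = 0.8, P_inv = 0.01,
                              dirichlet_convention = c("ratio", "raw"),
                              supply_mode = c("simplex", "integer"),
                              support_mode = c("uniform", "fixed"),
                              zero_diagonal = FALSE, redraw_cap = 1000) {
  dirichlet_convention <- match.arg(dirichlet_convention)
  supply_mode <- match.arg(supply_mode)
  support_mode <- match.arg(support_mode)
  stopifnot(M >= 1, E >= 1, E <= M, U > 0, mu_c > 0,
            max_pref >= 1, max_pref <= M, L_D > 0, L_D < 1,
            l >= 0, l <= 1, P_inv > 0, P_inv <= 1, redraw_cap >= 1)
  if (!is.null(S0)) stopifnot(S0 >= 1)
  structure(list(M = M, U = U, E = E, S0 = S0, s0_range = s0_range,
                 mu_c = mu_c, max_pref = max_pref, sigma_D = sigma_D,
                 L_D = L_D, l = l, P_inv = P_inv,
                 dirichlet_convention = dirichlet_convention,
                 supply_mode = supply_mode, support_mode = support_mode,
                 zero_diagonal = zero_diagonal, redraw_cap = redraw_cap),
            class = "cr_gen_config")
}

# uniform draw from the (n-1)-simplex, scaled to `total`
rsimplex <- function(n, total = 1) {
  g <- stats::rgamma(n, shape = 1)
  total * g / sum(g)
}

#' Sample a random environment
#'
#' Chooses E of the M resource types uniformly without replacement and
#' randomly allots the total supply U among them (continuous uniform-simplex
#' allocation by default, so every chosen resource receives a strictly
#' positive share). Dissipation is 1; leakage and the conversion matrix come
#' from `cfg`. A fresh conversion matrix is drawn unless one is passed in.
#'
#' @param cfg a [generation_config].
#' @param conversion optional M x M conversion matrix to reuse.
#' @return A [cr_env] whose `meta` records U, E and sigma_D.
#' @export
sample_environment <- function(cfg, conversion = NULL) {
  idx <- sample.int(cfg$M, cfg$E)
  supply <- numeric(cfg$M)
  supply[idx] <- if (cfg$supply_mode == "simplex") {
    rsimplex(cfg$E, cfg$U)
  } else {
    u <- round(cfg$U)
    drop(stats::rmultinom(1, u, rep(1 / cfg$E, cfg$E)))
  }
  if (is.null(conversion)) conversion <- sample_metabolic_matrix(cfg)
  cr_env(supply, conversion, leakage = cfg$l, dissipation = 1,
         meta = list(U = cfg$U, E = cfg$E, sigma_D = cfg$sigma_D))
}

dirichlet_alpha <- function(cfg) {
  switch(cfg$dirichlet_convention,
         ratio = cfg$sigma_D / cfg$M,
         raw = cfg$sigma_D)
}

sample_conversion_column <- function(M, alpha, L_D, zero_row = 0L,
                                     redraw_cap = 1000) {
  for (attempt in seq_len(redraw_cap)) {
    g <- stats::rgamma(M, shape = alpha)
    if (zero_row > 0L) g[zero_row] <- 0
    s <- sum(g)
    if (s == 0) next      # all-zero gamma draw at tiny alpha; redraw
    col <- g / s
    col[col < L_D] <- 0
    s <- sum(col)
    if (s > 0) return(col / s)
  }
  stop("could not draw a conversion column with any entry >= L_D",
       call. = FALSE)
}

#' Sample a metabolic conversion matrix
#'
#' Each column b is a symmetric Dirichlet draw giving the proportions in
#' which consumed resource b is leaked as each resource type. Entries below
#' the minimum conversion proportion L_D are zeroed and the column is
#' rescaled to sum 1. Smaller `sigma_D` concentrates leakage into fewer
#' byproducts; at M = 18 and L_D = 5%, sigma_D of 0.05, 1 and 5 give on
#' average about 1.13, 2.83 and 5.41 byproducts per consumed resource.
#'
#' @param cfg a [generation_config].
#' @param n_columns number of columns (default `cfg$M`, a full matrix).
#' @return An M x `n_columns` column-stochastic matrix.
#' @export
sample_metabolic_matrix <- function(cfg, n_columns = cfg$M) {
  alpha <- dirichlet_alpha(cfg)
  D <- matrix(0, cfg$M, n_columns)
  for (b in seq_len(n_columns)) {
    zr <- if (cfg$zero_diagonal && b <= cfg$M) b else 0L
    D[, b] <- sample_conversion_column(cfg$M, alpha, cfg$L_D, zr,
                                       cfg$redraw_cap)
  }
  D
}

sample_one_species <- function(cfg) {
  k <- if (cfg$support_mode == "uniform") sample.int(cfg$max_pref, 1)
       else cfg$max_pref
  support <- sample.int(cfg$M, k)
  row <- numeric(cfg$M)
  row[support] <- rsimplex(k, cfg$mu_c)
  row
}

#' Sample a random species pool
#'
#' Draws `S0` species. Each species prefers k distinct resource types (k
#' uniform on 1..max_pref by default) with uptake weights drawn from a
#' uniform simplex and scaled to the preference budget mu_c; maintenance is
#' 1 energy unit for all species. Pool members are pairwise distinct in
#' their trait vectors.
#'
#' @param cfg a [generation_config].
#' @param S0 pool size; defaults to `cfg$S0`, or a random integer in
#'   `cfg$s0_range` when that is `NULL`.
#' @param id_prefix prefix for species identifiers.
#' @return A [cr_traits] of S0 species.
#' @export
sample_species_pool <- function(cfg, S0 = NULL, id_prefix = "sp") {
  if (is.null(S0)) {
    S0 <- if (is.null(cfg$S0)) {
      sample.int(cfg$s0_range[2] - cfg$s0_range[1] + 1L, 1L) +
        cfg$s0_range[1] - 1L
    } else cfg$S0
  }
  uptake <- matrix(0, S0, cfg$M)
  for (i in seq_len(S0)) {
    for (attempt in seq_len(cfg$redraw_cap)) {
      row <- sample_one_species(cfg)
      dup <- i > 1 && any(apply(uptake[seq_len(i - 1), , drop = FALSE], 1,
                                function(r) all(r == row)))
      if (!dup) break
    }
    uptake[i, ] <- row
  }
  cr_traits(uptake, maintenance = 1,
            species_ids = paste0(id_prefix, seq_len(S0)),
            budget = cfg$mu_c, max_pref = cfg$max_pref)
}

#' Sample an invader
#'
#' Draws one species exactly as in [sample_species_pool()], redrawing until
#' its trait vector differs from every resident's.
#'
#' @param cfg a [generation_config].
#' @param residents a nonempty [cr_traits] of resident species.
#' @return A single-species [cr_traits] with id `"inv"`.
#' @export
sample_invader <- function(cfg, residents) {
  if (n_species(residents) == 0)
    stop("resident community is empty", call. = FALSE)
  for (attempt in seq_len(cfg$redraw_cap)) {
    row <- sample_one_species(cfg)
    clash <- any(apply(residents$uptake, 1, function(r) all(r == row)))
    if (!clash)
      return(cr_traits(matrix(row, 1), maintenance = 1, species_ids = "inv",
                       budget = cfg$mu_c, max_pref = cfg$max_pref))
  }
  stop("could not draw an invader distinct from all residents",
       call. = FALSE)
}

#' Check that a pool can seed a community
#'
#' TRUE iff at least one pool species has a positive invasion growth rate at
#' the empty-community resource levels R = K / gamma, i.e.
#' `(1 - l) * sum_a c_ia K_a / gamma > m_i` for some i. Used as a guard so
#' that assembly always starts from at least one viable species.
#'
#' @param pool a [cr_traits].
#' @param env a [cr_env].
#' @return Logical scalar.
#' @export
viability_guard <- function(pool, env) {
  if (n_species(pool) == 0) return(FALSE)
  r0 <- env$supply / env$dissipation
  any(invasion_growth_rate(pool, r0, env$leakage) > 0)
}

#' Check that an environment can support an ideal species
#'
#' TRUE iff a hypothetical species spending its whole preference budget on
#' the best-supplied resource would grow at the empty-community resource
#' levels: `(1 - l) * mu_c * max(K) / gamma > m`. Environments failing this
#' cannot host any community and are redrawn during generation.
#'
#' @param env a [cr_env].
#' @param cfg a [generation_config] (supplies mu_c).
#' @param maintenance the maintenance requirement of the ideal species
#'   (default 1).
#' @return Logical scalar.
#' @export
supports_ideal_species <- function(env, cfg, maintenance = 1) {
  (1 - env$leakage) * cfg$mu_c * max(env$supply) / env$dissipation >
    maintenance
}

#' Sample an environment and pool passing the viability guards
#'
#' Draws environments until one can support an ideal species
#' ([supports_ideal_species()]), then draws species pools until at least
#' one member is viable in it ([viability_guard()]). If the pool guard is
#' not met within `cfg$redraw_cap` attempts the environment is redrawn as
#' well; generation fails only when both caps are exhausted.
#'
#' @param cfg a [generation_config].
#' @param S0 pool size passed to [sample_species_pool()].
#' @return A list with `env`, `pool` and `redraws` (failed pool draws).
#' @export
sample_viable_system <- function(cfg, S0 = NULL) {
  if (is.null(S0)) {
    S0 <- if (is.null(cfg$S0)) {
      sample.int(cfg$s0_range[2] - cfg$s0_range[1] + 1L, 1L) +
        cfg$s0_range[1] - 1L
    } else cfg$S0
  }
  redraws <- 0L
  for (round in seq_len(cfg$redraw_cap)) {
    env <- sample_environment(cfg)
    if (!supports_ideal_species(env, cfg)) next
    for (attempt in seq_len(cfg$redraw_cap)) {
      pool <- sample_species_pool(cfg, S0 = S0)
      if (viability_guard(pool, env))
        return(list(env = env, pool = pool, redraws = redraws))
      redraws <- redraws + 1L
    }
  }
  stop("viability guard not satisfied within the redraw cap", call. = FALSE)
}
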