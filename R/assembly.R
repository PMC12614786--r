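#' Assembly and invasion protocol settings
#'
#' Controls the assembly / post-invasion protocol: initial seeding density,
#' number and strength of dilution-propagation passages, and perturbation
#' filtering. The same protocol is applied during community assembly and
#' after invader introduction.
#'
#' @param passages dilution-propagation passages (default 5).
#' @param dilution_factor dilution per passage (default 100).
#' @param perturbation_rounds perturbation-filter rounds (default 3).
#' @param perturbation_magnitude multiplicative perturbation half-width in
#'   (0, 1) (default 0.5, i.e. factors uniform in \[0.5, 1.5\]).
#' @param init_density initial density of every pool species at assembly
#'   (default 0.01).
#' @param solver a [solver_config].
#' @return An object of class `cr_assembly_config`.
#' @export
assembly_config <- function(passages = 5, dilution_factor = 100,
                            perturbation_rounds = 3,
                            perturbation_magnitude = 0.5,
                            init_density = 0.01,
                            solver = solver_config()) {
  stopifnot(passages >= 0, dilution_factor > 1, perturbation_rounds >= 0,
            perturbation_magnitude > 0, perturbation_magnitude < 1,
            init_density > 0)
  structure(list(passages = passages, dilution_factor = dilution_factor,
                 perturbation_rounds = perturbation_rounds,
                 perturbation_magnitude = perturbation_magnitude,
                 init_density = init_density, solver = solver),
            class = "cr_assembly_config")
}

cr_assembly_error <- function(msg) {
  structure(class = c("cr_assembly_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# drop species with zero density from a (state, traits) pair
prune_extinct <- function(state, traits) {
  keep <- state$populations > 0
  list(state = cr_state(state$populations[keep], state$resources,
                        state$time),
       traits = subset_traits(traits, keep))
}

# The three protocol stages, pruning extinct species between stages: a
# species at exactly zero density can never re-grow (dN/dt = 0), so
# dropping it is dynamically neutral and keeps the stiff system small.
run_protocol <- function(state, traits, env, acfg) {
  state <- integrate_to_steady_state(state, traits, env, acfg$solver)
  pr <- prune_extinct(state, traits)
  state <- dilution_propagation(pr$state, pr$traits, env, acfg$solver,
                                passages = acfg$passages,
                                dilution_factor = acfg$dilution_factor)
  pr <- prune_extinct(state, pr$traits)
  state <- perturbation_filter(pr$state, pr$traits, env, acfg$solver,
                               rounds = acfg$perturbation_rounds,
                               magnitude = acfg$perturbation_magnitude)
  prune_extinct(state, pr$traits)
}

#' Assemble a resident community from a species pool
#'
#' Seeds every pool species at a small equal density, integrates to steady
#' state, then applies dilution-propagation and perturbation filtering. The
#' surviving subset of the pool, with its steady-state densities, is the
#' resident community.
#'
#' @param pool a [cr_traits] passing [viability_guard()] for `env`.
#' @param env a [cr_env].
#' @param acfg an [assembly_config].
#' @return A list with `state` (a [cr_state] over the survivors only) and
#'   `traits` (the surviving subset of the pool).
#' @export
assemble_resident_community <- function(pool, env,
                                        acfg = assembly_config()) {
  state <- cr_state(rep(acfg$init_density, n_species(pool)),
                    env$supply / env$dissipation)
  out <- run_protocol(state, pool, env, acfg)
  if (n_species(out$traits) == 0)
    stop(cr_assembly_error("all pool species went extinct during assembly"))
  out
}

#' Introduce an invader into a resident community
#'
#' Appends the invader at a propagule density of `P_inv` times the total
#' resident population density; resident densities and resource
#' concentrations are unchanged at the moment of introduction.
#'
#' @param community a [cr_state] of the residents at steady state.
#' @param residents a [cr_traits] matching `community`.
#' @param invader a single-species [cr_traits] distinct from all residents.
#' @param P_inv propagule proportion in (0, 1].
#' @return A list with the augmented `state` and `traits`.
#' @export
introduce_invader <- function(community, residents, invader, P_inv = 0.01) {
  if (n_species(residents) == 0 || sum(community$populations) == 0)
    stop("resident community is empty", call. = FALSE)
  stopifnot(n_species(invader) == 1, P_inv > 0, P_inv <= 1)
  list(state = cr_state(c(community$populations,
                          P_inv * sum(community$populations)),
                        community$resources, community$time),
       traits = bind_traits(residents, invader))
}

#' Run the post-invasion phase
#'
#' Integrates the invaded community to steady state, then applies the same
#' dilution-propagation and perturbation filtering as assembly. Extinct
#' species (possibly including the invader) are removed from the result.
#'
#' @param state,traits the invaded community from [introduce_invader()].
#' @param env a [cr_env].
#' @param acfg an [assembly_config].
#' @return A list with the final `state` and surviving `traits`.
#' @export
run_invasion <- function(state, traits, env, acfg = assembly_config()) {
  run_protocol(state, traits, env, acfg)
}

#' Classify an invasion outcome
#'
#' The four-way classification by invader persistence and resident
#' retention: `Augment` — invader and every resident persist; `Displace` —
#' invader persists, at least one resident lost; `Resist` — invader fails,
#' every resident persists; `Disrupt` — invader fails and at least one
#' resident is lost. The cases are exhaustive and mutually exclusive.
#' "Residents" are the species present at the pre-invasion steady state.
#'
#' @param residents_pre a [cr_traits] of the pre-invasion residents.
#' @param final a [cr_traits] of the final (post-invasion) community.
#' @param invader_id the invader's species id.
#' @return One of `"Augment"`, `"Displace"`, `"Resist"`, `"Disrupt"`.
#' @export
classify_outcome <- function(residents_pre, final, invader_id = "inv") {
  if (n_species(residents_pre) == 0)
    stop("resident community is empty", call. = FALSE)
  invader_in <- invader_id %in% final$species_ids
  residents_ok <- all(residents_pre$species_ids %in% final$species_ids)
  if (invader_in) {
    if (residents_ok) "Augment" else "Displace"
  } else {
    if (residents_ok) "Resist" else "Disrupt"
  }
}

#' Abundance ranks of a resident community
#'
#' Rank 1 is the most abundant resident; ties are broken by species id
#' (lexicographic), making ranks deterministic.
#'
#' @param state a [cr_state].
#' @param traits the matching [cr_traits].
#' @return Integer ranks named by species id.
#' @export
abundance_ranks <- function(state, traits) {
  ord <- order(-state$populations, traits$species_ids)
  ranks <- integer(length(ord))
  ranks[ord] <- seq_along(ord)
  stats::setNames(ranks, traits$species_ids)
}

#' Run one full invasion trial
#'
#' The complete pipeline for a single replicate: sample an environment and
#' conversion matrix, sample a species pool (redrawing until the viability
#' guard passes), assemble the resident community, sample an invader with
#' traits distinct from all residents, introduce it, run the post-invasion
#' protocol, and classify the outcome. Consumes the current R RNG stream;
#' call [set.seed()] (or pass `seed`) for reproducibility.
#'
#' @param gen_cfg a [generation_config].
#' @param acfg an [assembly_config].
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first and the value is recorded in the output.
#' @param P_inv propagule proportion; defaults to `gen_cfg$P_inv`.
#' @return A one-row `data.frame` (an invasion record) with columns
#'   `U, E, sigma_D, l, seed, initial_pool_size, resident_richness_pre,
#'   resident_richness_post, invader_persisted, outcome,
#'   extinct_resident_ranks` (semicolon-separated, empty when none),
#'   `survival_fraction`, and `failed`. Failed trials (integration or
#'   assembly errors) carry `failed = TRUE` and `NA` outcome fields.
#' @export
run_trial <- function(gen_cfg = generation_config(),
                      acfg = assembly_config(), seed = NULL,
                      P_inv = gen_cfg$P_inv) {
  if (!is.null(seed)) set.seed(seed)
  base <- data.frame(U = gen_cfg$U, E = gen_cfg$E, sigma_D = gen_cfg$sigma_D,
                     l = gen_cfg$l,
                     seed = if (is.null(seed)) NA_integer_ else seed)
  rec <- tryCatch({
    sys <- sample_viable_system(gen_cfg)
    s0 <- n_species(sys$pool)
    res <- assemble_resident_community(sys$pool, sys$env, acfg)
    invader <- sample_invader(gen_cfg, res$traits)
    inv <- introduce_invader(res$state, res$traits, invader, P_inv)
    fin <- run_invasion(inv$state, inv$traits, sys$env, acfg)
    outcome <- classify_outcome(res$traits, fin$traits, "inv")
    ranks <- abundance_ranks(res$state, res$traits)
    lost <- setdiff(res$traits$species_ids, fin$traits$species_ids)
    data.frame(
      initial_pool_size = s0,
      resident_richness_pre = n_species(res$traits),
      resident_richness_post = sum(fin$traits$species_ids != "inv"),
      invader_persisted = "inv" %in% fin$traits$species_ids,
      outcome = outcome,
      extinct_resident_ranks = paste(sort(ranks[lost]), collapse = ";"),
      survival_fraction = n_species(res$traits) / s0,
      failed = FALSE)
  }, cr_integration_error = function(e) NULL,
     cr_assembly_error = function(e) NULL)
  if (is.null(rec))
    rec <- data.frame(initial_pool_size = NA_integer_,
                      resident_richness_pre = NA_integer_,
                      resident_richness_post = NA_integer_,
                      invader_persisted = NA, outcome = NA_character_,
                      extinct_resident_ranks = NA_character_,
                      survival_fraction = NA_real_, failed = TRUE)
  cbind(base, rec)
}
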