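OUTCOMES <- c("Augment", "Displace", "Disrupt", "Resist")

# Deterministic per-trial child seeds from a root seed: a Lehmer-style mix
# over the Mersenne prime 2^31 - 1, so serial and reordered execution give
# identical records and all seeds stay below 2^31.
derive_seed <- function(root, condition_index, replicate_index) {
  p <- 2147483647
  x <- as.double(root %% p)
  x <- (x * 48271 + condition_index) %% p
  x <- (x * 48271 + replicate_index) %% p
  as.integer(x + 1)
}

#' Specify a parameter sweep
#'
#' @param grid a list of conditions; each condition is a named list of
#'   [generation_config()] overrides (e.g. `list(U = 3, E = 5)`).
#' @param replicates trials per condition (>= 1).
#' @param seed root seed; per-trial seeds are derived deterministically.
#' @param base_config the [generation_config] the overrides are applied to.
#' @return An object of class `cr_sweep_spec`.
#' @export
sweep_spec <- function(grid, replicates, seed = 1,
                       base_config = generation_config()) {
  stopifnot(length(grid) >= 1, replicates >= 1)
  structure(list(grid = grid, replicates = replicates, seed = seed,
                 base_config = base_config), class = "cr_sweep_spec")
}

apply_overrides <- function(base, overrides) {
  args <- unclass(base)
  args$s0_range <- base$s0_range
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(generation_config, args)
}

#' Run a parameter sweep of invasion trials
#'
#' Runs `spec$replicates` independently seeded trials per condition and
#' stacks the invasion records. Each record carries its condition index and
#' the generation parameters of its condition.
#'
#' @param spec a [sweep_spec].
#' @param acfg an [assembly_config].
#' @param progress print a line per condition (default FALSE).
#' @return A `data.frame` of invasion records (see [run_trial()]) with an
#'   extra `condition` column.
#' @export
run_sweep <- function(spec, acfg = assembly_config(), progress = FALSE) {
  out <- vector("list", length(spec$grid))
  for (ci in seq_along(spec$grid)) {
    cfg <- apply_overrides(spec$base_config, spec$grid[[ci]])
    recs <- vector("list", spec$replicates)
    for (ri in seq_len(spec$replicates)) {
      recs[[ri]] <- run_trial(cfg, acfg,
                              seed = derive_seed(spec$seed, ci, ri))
    }
    block <- do.call(rbind, recs)
    block$condition <- ci
    out[[ci]] <- block
    if (progress)
      message(sprintf("condition %d/%d done (%d trials, %d failed)",
                      ci, length(spec$grid), nrow(block),
                      sum(block$failed)))
  }
  do.call(rbind, out)
}

classified <- function(records) {
  records[!is.na(records$outcome) & !records$failed, , drop = FALSE]
}

group_index <- function(records, group_keys) {
  if (is.null(group_keys) || length(group_keys) == 0)
    return(rep("all", nrow(records)))
  interaction(records[group_keys], drop = TRUE, lex.order = TRUE)
}

outcome_freq_vec <- function(outcomes) {
  tab <- table(factor(outcomes, levels = OUTCOMES))
  as.numeric(tab) / length(outcomes)
}

#' Relative frequencies of invasion outcomes
#'
#' The relative frequency of each outcome is its count divided by the
#' number of classified (non-failed) trials in the group.
#'
#' @param records invasion records from [run_trial()] / [run_sweep()].
#' @param group_keys character vector of record columns to group by
#'   (default none: one overall summary).
#' @return A `data.frame` with one row per group x outcome, columns
#'   `group`, grouping columns, `outcome`, `n_trials`, `count`, `freq`.
#' @export
outcome_frequencies <- function(records, group_keys = NULL) {
  records <- classified(records)
  if (nrow(records) == 0) stop("no classified records", call. = FALSE)
  g <- group_index(records, group_keys)
  rows <- lapply(levels(factor(g)), function(lv) {
    sub <- records[g == lv, , drop = FALSE]
    out <- data.frame(group = lv, outcome = OUTCOMES, n_trials = nrow(sub),
                      count = as.integer(table(factor(sub$outcome,
                                                      levels = OUTCOMES))),
                      freq = outcome_freq_vec(sub$outcome))
    for (k in rev(group_keys)) out <- cbind(stats::setNames(
      data.frame(rep(sub[[k]][1], nrow(out))), k), out)
    rownames(out) <- NULL
    out
  })
  do.call(rbind, rows)
}

#' Percentile bootstrap confidence intervals for outcome frequencies
#'
#' Resamples trials with replacement within each group and reports
#' percentile confidence bounds for every outcome frequency.
#'
#' @inheritParams outcome_frequencies
#' @param B bootstrap samples (default 1000).
#' @param level confidence level (default 0.95).
#' @return The [outcome_frequencies()] table with `ci_lower` and
#'   `ci_upper` columns added.
#' @export
bootstrap_ci <- function(records, group_keys = NULL, B = 1000,
                         level = 0.95) {
  records <- classified(records)
  summ <- outcome_frequencies(records, group_keys)
  g <- group_index(records, group_keys)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  summ$ci_lower <- NA_real_
  summ$ci_upper <- NA_real_
  for (lv in unique(summ$group)) {
    outc <- records$outcome[g == lv]
    n <- length(outc)
    boot <- matrix(NA_real_, B, length(OUTCOMES))
    for (b in seq_len(B))
      boot[b, ] <- outcome_freq_vec(outc[sample.int(n, n, replace = TRUE)])
    qs <- apply(boot, 2, stats::quantile, probs = probs, names = FALSE)
    sel <- summ$group == lv
    summ$ci_lower[sel] <- qs[1, ]
    summ$ci_upper[sel] <- qs[2, ]
  }
  summ
}

#' Outcome frequencies by resident richness
#'
#' Bins records by pre-invasion resident richness and summarizes outcome
#' frequencies (with bootstrap CIs) per bin. By default unit-width bins
#' over the observed richness range are used and sparse bins are merged
#' upward until each holds at least `min_trials` trials.
#'
#' @param records invasion records.
#' @param bins optional numeric vector of right-closed bin upper edges; by
#'   default unit bins merged to `min_trials`.
#' @param min_trials minimum trials per default bin (default 50).
#' @param B bootstrap samples.
#' @return A summary `data.frame` with `richness_bin` (bin label),
#'   `bin_upper`, outcome frequencies and CIs; an attribute `sparse` lists
#'   bins below `min_trials`.
#' @export
richness_resistance_curve <- function(records, bins = NULL,
                                      min_trials = 50, B = 1000) {
  records <- classified(records)
  r <- records$resident_richness_pre
  if (is.null(bins)) {
    edges <- sort(unique(r))
    bins <- c()
    count <- 0
    for (e in edges) {
      count <- count + sum(r == e)
      if (count >= min_trials) {
        bins <- c(bins, e)
        count <- 0
      }
    }
    if (count > 0 || length(bins) == 0) bins <- c(bins, max(r))
    bins <- unique(bins)
  }
  stopifnot(all(diff(bins) > 0))
  idx <- findInterval(r, bins, left.open = TRUE) + 1L
  idx[idx > length(bins)] <- length(bins)
  records$richness_bin <- bins[idx]
  summ <- bootstrap_ci(records, "richness_bin", B = B)
  names(summ)[names(summ) == "richness_bin"] <- "bin_upper"
  counts <- table(records$richness_bin)
  attr(summ, "sparse") <- as.numeric(names(counts)[counts < min_trials])
  summ
}

parse_ranks <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Extinction frequency by abundance rank
#'
#' Over trials that lost residents (Disrupt and Displace), tallies the
#' abundance ranks (1 = most abundant at the pre-invasion steady state) of
#' the residents that went extinct, alongside the uniform-random
#' expectation in which each of the `richness_pre` residents is equally
#' likely to be lost.
#'
#' @param records invasion records.
#' @param outcomes outcome labels to include (default Disrupt and
#'   Displace).
#' @return A `data.frame` with `rank`, `losses`, `freq` (share of all
#'   losses) and `expected` (uniform-expectation share), or an empty frame
#'   when no extinctions occurred. Also reports `freq_lowest` /
#'   `expected_lowest` attributes: the observed and uniform-expected share
#'   of loss events that hit the lowest-abundance resident.
#' @export
rank_extinction_profile <- function(records,
                                    outcomes = c("Disrupt", "Displace")) {
  records <- classified(records)
  records <- records[records$outcome %in% outcomes, , drop = FALSE]
  all_ranks <- integer(0)
  low_hits <- 0
  low_expect <- 0
  n_loss_events <- 0
  for (i in seq_len(nrow(records))) {
    ranks <- parse_ranks(records$extinct_resident_ranks[i])
    if (length(ranks) == 0) next
    rich <- records$resident_richness_pre[i]
    all_ranks <- c(all_ranks, ranks)
    n_loss_events <- n_loss_events + length(ranks)
    low_hits <- low_hits + sum(ranks == rich)
    low_expect <- low_expect + length(ranks) / rich
  }
  if (n_loss_events == 0) {
    out <- data.frame(rank = integer(0), losses = integer(0),
                      freq = numeric(0), expected = numeric(0))
    return(out)
  }
  tab <- table(all_ranks)
  out <- data.frame(rank = as.integer(names(tab)),
                    losses = as.integer(tab),
                    freq = as.integer(tab) / n_loss_events)
  # expected share of losses landing on each rank under uniform loss
  max_rank <- max(records$resident_richness_pre)
  exp_by_rank <- vapply(seq_len(max_rank), function(k) {
    sub <- records[records$resident_richness_pre >= k, , drop = FALSE]
    sum(vapply(seq_len(nrow(sub)), function(i) {
      length(parse_ranks(sub$extinct_resident_ranks[i])) /
        sub$resident_richness_pre[i]
    }, numeric(1)))
  }, numeric(1)) / n_loss_events
  out$expected <- exp_by_rank[out$rank]
  attr(out, "freq_lowest") <- low_hits / n_loss_events
  attr(out, "expected_lowest") <- low_expect / n_loss_events
  out
}

#' Survival fraction versus invasion success
#'
#' For records generated at a fixed initial pool size S0, bins trials by
#' the survival fraction (pre-invasion richness / S0) and reports the
#' invasion success frequency (Augment or Displace: the invader persists)
#' per bin, for comparison against the identity line.
#'
#' @param records invasion records with constant `initial_pool_size`.
#' @param n_bins number of equal-width survival-fraction bins (default 10).
#' @return A `data.frame` with `bin_mid`, `mean_survival`,
#'   `invasion_success` and `n_trials` per nonempty bin.
#' @export
survival_fraction_vs_invasion <- function(records, n_bins = 10) {
  records <- classified(records)
  if (length(unique(records$initial_pool_size)) != 1)
    stop("records must share a single initial pool size S0", call. = FALSE)
  sf <- records$survival_fraction
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(sf, edges, left.open = TRUE), 1), n_bins)
  success <- records$outcome %in% c("Augment", "Displace")
  rows <- lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    data.frame(bin_mid = (edges[b] + edges[b + 1]) / 2,
               mean_survival = mean(sf[sel]),
               invasion_success = mean(success[sel]),
               n_trials = sum(sel))
  })
  do.call(rbind, rows)
}

#' Calibrate metabolic spread against mean byproduct counts
#'
#' Generates conversion-matrix columns at each metabolic spread value and
#' returns the mean number of nonzero byproducts per consumed resource
#' (nonzero entries per column after thresholding at L_D and
#' renormalization).
#'
#' @param sigma_values metabolic spread values (default 0.05, 1, 5).
#' @param n_columns columns per value (default 1e5).
#' @param cfg base [generation_config] supplying M, L_D and the Dirichlet
#'   convention.
#' @return A `data.frame` with `sigma_D`, `mean_byproducts`, `n_columns`.
#' @export
byproduct_calibration <- function(sigma_values = c(0.05, 1, 5),
                                  n_columns = 1e5,
                                  cfg = generation_config()) {
  stopifnot(n_columns >= 1)
  rows <- lapply(sigma_values, function(s) {
    c2 <- apply_overrides(cfg, list(sigma_D = s))
    alpha <- dirichlet_alpha(c2)
    # vectorized draw: columns of gammas, threshold, count nonzero
    nz_total <- 0
    done <- 0
    chunk <- 20000L
    while (done < n_columns) {
      nb <- min(chunk, n_columns - done)
      g <- matrix(stats::rgamma(nb * c2$M, shape = alpha), nrow = c2$M)
      cs <- colSums(g)
      bad <- cs == 0
      while (any(bad)) {        # redraw degenerate all-zero columns
        g[, bad] <- stats::rgamma(sum(bad) * c2$M, shape = alpha)
        cs <- colSums(g)
        bad <- cs == 0
      }
      frac <- sweep(g, 2, cs, "/")
      nz <- colSums(frac >= c2$L_D)
      if (any(nz == 0))         # column fully below L_D: redraw one by one
        nz[nz == 0] <- vapply(which(nz == 0), function(j)
          sum(sample_conversion_column(c2$M, alpha, c2$L_D,
                                       redraw_cap = c2$redraw_cap) > 0),
          numeric(1))
      nz_total <- nz_total + sum(nz)
      done <- done + nb
    }
    data.frame(sigma_D = s, mean_byproducts = nz_total / n_columns,
               n_columns = n_columns)
  })
  do.call(rbind, rows)
}
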