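---
title: "Consumer-resource invasion assays: model, protocol, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-resource invasion assays: model, protocol, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crinvade)
```

## The model

`crinvade` simulates colonization resistance — the joint ability of an
environment and its resident microbial community to block an invader — in a
MacArthur-style consumer-resource model with metabolic cross-feeding. The
state is a vector of population densities $N_i$ (1/volume) and resource
concentrations $R_\alpha$ (energy/volume) over $M$ resource types:

$$
\frac{dN_i}{dt} = N_i\Big[(1-l)\sum_\alpha c_{i\alpha} R_\alpha - m_i\Big],
\qquad
\frac{dR_\alpha}{dt} = K_\alpha - R_\alpha\Big(\gamma + \sum_i c_{i\alpha}
N_i\Big) + l\sum_\beta D_{\alpha\beta} R_\beta \sum_i c_{i\beta} N_i .
$$

Each species is a row of the uptake matrix $c_{i\alpha}$ (volume/time): a
fixed preference budget $\mu_c$ distributed over at most `max_pref` resource
types, a metabolic trade-off that prevents universal generalists.
Consumption of resource $\beta$ proceeds at rate $R_\beta \sum_i c_{i\beta}
N_i$; a fraction $l$ of the consumed energy leaks back into the environment
as byproducts, partitioned among resource types by the column-stochastic
conversion matrix $D$ ($D_{\alpha\beta}$ is the share of consumed $\beta$
reappearing as $\alpha$), and the remaining $1-l$ fuels growth against the
maintenance requirement $m_i$. With column-stochastic $D$ the model is
energy-balanced: at any steady state, supply equals dissipation plus net
(growth-directed) consumption, a property the test suite asserts to
$10^{-6}$ relative accuracy.

Resources here are substitutable (think alternative carbon sources);
obligate co-requirements (carbon *and* nitrogen), diauxie, and regulated
metabolic switching are outside the model, as are spatial structure and
host feedback. The consumption term is linear in $R_\alpha$; mass balance
with the byproduct term requires this form, since the byproducts of
consuming $\beta$ are generated at exactly the rate $\beta$ is consumed.

## Random ensembles

Environments and species pools are generated, not measured:

* **Environment.** $E$ of the $M = 18$ resource types are chosen uniformly
  without replacement, and the total supply $U$ (concentration/time) is
  allotted among them by a uniform simplex draw, so every chosen resource
  receives a strictly positive share. (An integer-multinomial allotment is
  available via `supply_mode = "integer"`.) Dissipation is $\gamma = 1$.
  $U$ is *resource supply*; $E$ is *resource diversity*.
* **Conversion matrix.** Each column of $D$ is a symmetric Dirichlet draw
  with concentration $\sigma_D / M$; entries below the minimum conversion
  proportion $L_D = 5\%$ are zeroed and the column is renormalized. The
  $\sigma_D/M$ convention is pinned by calibration: at $M = 18$ it yields
  means of about 1.13, 2.83 and 5.41 nonzero byproducts per consumed
  resource at $\sigma_D$ = 0.05, 1 and 5 — the reference values for this
  construction — whereas concentrations $\sigma_D$ or $\sigma_D \cdot M$
  give (2.70, 7.53, 9.71) and (7.37, 11.65, 15.04). `scripts/acceptance.R`
  recomputes this calibration from scratch.
* **Species.** Each species draws a support size $k$ uniformly from
  $1,\dots,5$ (`support_mode = "fixed"` forces $k = 5$), a support of $k$
  distinct resource types, and uniform-simplex weights scaled to the budget
  $\mu_c = 10$; maintenance is $m_i = 1$ throughout. The within-support
  weight distribution is a package choice; only the budget and the support
  cap are structural.
* **Viability guard.** A pool is accepted only if at least one member has
  positive per-capita growth at the empty-environment resource levels
  $R_\alpha = K_\alpha/\gamma$; otherwise the pool (and, every 50 failed
  draws, the environment) is redrawn. Invaders are drawn from the same
  distribution, rejected only if they duplicate a resident's trait vector.

Defaults are $U = 12$, $E = 5$, $l = 0.8$, $\sigma_D = 1$ (the mid-range
spread, about 2.8 byproducts per resource), pool sizes drawn uniformly from
5–50, and a 1% invader propagule.

## Assembly and the invasion assay

A trial proceeds in two phases with identical protocols:

1. **Assembly.** All pool species start at density 0.01 (well above typical
   extinction cutoffs, well below typical steady states — the value is a
   package choice, configurable via `init_density`) with resources at
   $K/\gamma$; the system is integrated to a numerical steady state, run
   through 5 dilution–propagation passages (100× dilution each), and
   filtered by 3 rounds of multiplicative population perturbations drawn
   uniformly from $[0.5, 1.5]$, each followed by re-equilibration. The
   perturbation filter removes species persisting only on a knife's edge.
   Passage count, dilution factor, and perturbation settings are package
   choices behind `assembly_config()`; the protocol *shape* (propagate,
   dilute serially, perturb iteratively) is structural.
2. **Invasion.** The invader enters at 1% of the total resident density,
   resources untouched, and the same propagate–dilute–perturb protocol
   runs again.

Each trial is classified by invader persistence and resident retention:
**Augment** (invader in, all residents persist), **Displace** (invader in,
some resident lost), **Resist** (invader out, all residents persist),
**Disrupt** (invader out, some resident lost). "Residents" means species
present at the pre-invasion steady state. The rare trials whose
integration fails outright or whose pool collapses entirely during
assembly are flagged `failed = TRUE` and excluded from frequency
denominators; their counts are reported in run manifests.

## Extinction threshold semantics

Populations below the consumer extinction threshold $L_{ext} = 10^{-3}$ are
zeroed after every propagation, dilution, and perturbation step. The
package applies the threshold *relative to the total population density at
the moment of thresholding* (`extinction_mode = "relative"`, the default),
zeroing $N_i < L_{ext} \sum_j N_j$. The absolute reading
($N_i < L_{ext}$ directly) is available as a switch but interacts
pathologically with serial dilution at low supply: total density is
energy-bounded by $(1-l)U/\min_i m_i$, so at $U = 3$ and $l = 0.8$ the
whole community holds about 0.6 density units and a 100× dilution drops
almost every species below an absolute $10^{-3}$, collapsing a large
share of low-supply communities outright — not a regime where meaningful
outcome statistics exist. Under the relative reading the assay is
well-behaved across the full supply range.

## Numerical choices

* **Stiffness.** Resource turnover rates ($\gamma + \sum_i c_{i\alpha}
  N_i$, easily $10$–$10^2$) exceed population rates ($\lesssim 1$) by
  orders of magnitude, so the system is stiff and explicit Runge–Kutta
  pairs are stability-limited to steps of $\sim 10^{-2}$ time units. The
  integrator is BDF (`deSolve::vode`, `mf = 22`, internally generated
  Jacobians) over a compiled C right-hand side; the test suite checks its
  steady states against an independent `lsoda` integration of the
  R-level derivative function and against closed forms.
* **Tolerances.** Relative tolerance $10^{-8}$, absolute tolerance
  $10^{-20}$ (effectively pure relative control). Closed-form monoculture
  steady states are recovered to better than $10^{-6}$ relative error.
* **Steady-state detection.** Integration proceeds in windows of 500 time
  units; a steady state is declared when the largest relative change of
  any variable across one window falls below $10^{-6}$, up to 20 windows
  (non-convergence is flagged on the returned state). The relative change
  of a variable below $L_{ext}$ is measured against $L_{ext}$ itself so
  that species in free exponential decay — which thresholding will remove
  anyway — cannot stall the criterion. Re-integrating a returned steady
  state for one further window moves no variable by more than the
  criterion, i.e. no sustained oscillations are observed, consistent with
  the model's behaviour under fixed supply.
* **Numerical hygiene.** Solver undershoots below zero are clipped at
  window boundaries. Populations more than six decades below the
  extinction threshold ($< 10^{-9}$) are flushed to zero between windows:
  they are ecologically extinct, and carrying them at roundoff scale makes
  the BDF corrector fragile. On a failed window the solver retries with a
  capped maximum step, then with a second integrator (`lsoda`), then — as
  a last resort — applies the extinction threshold to the last valid state
  and resumes; all retries are deterministic. Residual failures surface as
  flagged trials, never silent data.
* **Seeding.** A root seed spawns per-trial child seeds through a
  Lehmer-style mix modulo $2^{31}-1$, so records are reproducible
  trial-by-trial and independent of execution order; identical config and
  seed give byte-identical record CSVs.

## Statistics

Outcome frequencies are relative counts over classified trials. Confidence
intervals are percentile bootstrap over trial resampling (B = 1000, 95%).
Richness–resistance curves bin trials by pre-invasion richness into
unit-width bins merged upward until each holds at least 50 trials (the
binning is a package choice). The rank–extinction profile compares the
abundance ranks of lost residents against the uniform expectation
$1/\mathrm{richness}$ per rank; survival-fraction analysis defines invasion
success as Augment or Displace (the invader persists). No multiplicity
correction is applied — intervals are descriptive, matching how the outcome
frequencies are reported.

## What the tests do and do not show

The test suite runs the full pipeline at 2,000 trials per condition
(the published study conditions use $2\times 10^5$–$2\times 10^6$; the
desk-scale runs keep the default suite in the tens of minutes). At this
size the first-order effects — resistance falling with supply, the sign
reversal of the diversity effect between scarce and abundant supply,
declining augmentation and growing disruption with richness, and the
leakage effect in consolidated environments — separate cleanly with
non-overlapping 95% bootstrap intervals. Fine structure (the exact
non-monotonic shape of the richness–resistance curve, narrow-bin
frequencies) needs the full replicate counts and is out of scope here.
Because every input is synthetic, agreement with these checks validates
the machinery and the qualitative resource-competition mechanisms, not any
claim about a particular real microbiome: the generator has no phylogenetic
trait correlation, no family structure in the conversion matrix, and no
temporal variation in supply.

## A worked example

```{r example, eval = FALSE}
library(crinvade)

spec <- sweep_spec(grid = list(list(U = 3, E = 5), list(U = 18, E = 5)),
                   replicates = 500, seed = 42)
records <- run_sweep(spec)
summary <- bootstrap_ci(records, group_keys = c("condition", "U"))
summary[summary$outcome == "Resist",
        c("U", "n_trials", "freq", "ci_lower", "ci_upper")]
plot_resistance(summary, x = "U")
```

The same pipeline is exposed on the command line through
`inst/cli/crinvade` (`calibrate`, `invade`, and `sweep` subcommands); every
run writes a JSON manifest with the config snapshot, seeds, and failure
counts as its final artifact.
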