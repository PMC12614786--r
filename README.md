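# crinvade

Consumer-resource invasion assays for colonization resistance in microbial
communities.

## The problem

Resident microbial communities often block invading species — *colonization
resistance* — and the strength of that protection depends on the
environment as much as on the residents. `crinvade` is a simulation toolkit
for asking how **resource supply** (the total nutrient input rate *U*),
**resource diversity** (the number of supplied resource types *E*), and
**cross-feeding** (byproduct leakage *l* and metabolic spread *σ_D*) shape
the outcome when a random invader meets a randomly assembled resident
community. It is aimed at theoretical and microbial ecologists who want
reproducible, desk-scale ensembles of invasion experiments rather than a
single hand-tuned simulation.

## The model

Species population densities `N_i` and resource concentrations `R_a`
follow a MacArthur-style consumer-resource model with metabolic
conversion:

```
dN_i/dt = N_i [ (1 - l) * sum_a c_ia R_a - m_i ]
dR_a/dt = K_a - R_a (gamma + sum_i c_ia N_i)
          + l * sum_b D_ab R_b sum_i c_ib N_i
```

Each species allocates a fixed uptake budget `mu_c = 10` across at most 5
of `M = 18` resource types; a fraction `l` of all consumption leaks back
as byproducts distributed by a column-stochastic conversion matrix `D`
drawn from a thresholded Dirichlet whose concentration is set by the
metabolic spread `σ_D`. A trial assembles a random species pool to steady
state through serial dilution and perturbation filtering, introduces an
invader at 1% of total resident density, re-runs the protocol, and
classifies the result as **Augment**, **Displace**, **Resist**, or
**Disrupt** according to whether the invader establishes and whether every
resident survives. Outcome frequencies over seeded ensembles come with
percentile bootstrap confidence intervals (B = 1000).

See the methods vignette
(`vignettes/consumer-resource-invasion.Rmd`) for the full account of the
model, the generation distributions, the extinction-threshold semantics,
and the numerical choices.

## A worked example

Resistance falls as resource supply grows (here 500 trials per condition,
diversity fixed at 5 supplied resource types):

```r
library(crinvade)
spec <- sweep_spec(grid = list(list(U = 3, E = 5), list(U = 18, E = 5)),
                   replicates = 500, seed = 42)
records <- run_sweep(spec)
summary <- bootstrap_ci(records, group_keys = c("condition", "U"))
summary[summary$outcome == "Resist",
        c("U", "n_trials", "freq", "ci_lower", "ci_upper")]
#>   U n_trials  freq ci_lower ci_upper
#>   3      500 0.944    0.924    0.962
#>  18      500 0.628    0.586    0.668
```

At a supply of 3 concentration units, 94% of invasions are resisted; at a
supply of 18 the scarce-nutrient filter is gone, open niches abound, and
resistance drops to 63%, with non-overlapping 95% bootstrap intervals.
`plot_resistance(summary, x = "U")` draws the corresponding curve, and
`richness_resistance_curve(records)` bins the same records by resident
richness.

A thin command-line wrapper lives at `inst/cli/crinvade`:

```sh
Rscript inst/cli/crinvade sweep --seed 1 --replicates 200 --out runs/supply
Rscript inst/cli/crinvade calibrate --seed 1 --out runs/calib
```

Every command writes a JSON manifest (config snapshot, seeds, failure
counts) as its final artifact; identical config and seed reproduce
byte-identical record CSVs.

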