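# mir9step

Dynamical models of how a **stepwise** increase of mature miR-9 — built
from the sequential, additive activation of paralogous pri-mir-9 loci —
can drive Her6 out of a perfectly adapting regulatory state during
zebrafish hindbrain neurogenesis.

The package is for systems-biology modellers who want a tested, seeded
implementation of the two circuits and of the synthetic input
generator, rather than a one-off simulation script.

## The models

**Basic circuit (perfect adaptation).** miR-9 (`m`) represses Her6
(`h`) directly and through an intermediate repressor `X`, an incoherent
feed-forward loop with repression function G(x) = 1/x:

    dh/dt = α_h G(m) G(X) − μ_h h
    dX/dt = α_X G(m)      − μ_X X

Its steady state h\* = α_h μ_X / (μ_h α_X) is independent of miR-9, and
with this G the Her6 trajectory is exactly invariant under rescaling of
the input: the circuit detects *fold* changes only and fully absorbs
any sustained input level.

**Extended circuit (bistable switch).** A downstream target `Y`
self-activates (Hill coefficient > 1) and is in mutual repression with
Her6. A sharp miR-9 increase dips Her6 long enough for `Y` to escape
past its unstable branch and lock Her6 into a new low state; gradual
ramps of the same total fold are absorbed by adaptation. Fixed points,
stability (analytic Jacobian), outcome classification
(adapted/switched), switching-threshold search and parameter
feasibility checks are all provided.

**Synthetic inputs.** Constant / linear / stepwise / log-OU-fluctuating
profiles, plus a per-cell locus-activation generator (independent
normal onset times per locus, additive production, first-order decay)
that emulates the early (pri-mir-9-4/-9-5, ~30 hpf) and late
(pri-mir-9-1, ~36.5 hpf) deployment and reports co-expression
fractions of precursor-positive cells.

## Worked example

```r
library(mir9step)
p <- extended_params()          # shipped reference parameter set
steady_state_h(p$basic)
#> [1] 1

# matched inputs: linear ramp vs two-step profile, both 1 -> 12 over 10-40 h
ex <- run_linear_vs_step(p)
ex$summary$classifications
#>     linear       step
#>  "adapted" "switched"
signif(ex$runs$linear$final_h_relative, 4)   # ramp: Her6 back at h*
#> [1] 1
signif(ex$runs$step$final_h_relative, 4)     # steps: Her6 in the low state
#> [1] 5.961e-05

find_switching_threshold(p)     # critical instantaneous fold change
#> [1] 5.858

# locus-activation pipeline: population input, linearised control, knockout
px <- run_additive_locus_pipeline(locus_config(seed = 1), p)
px$summary$classifications
#>          locus linear_control       knockout
#>     "switched"      "adapted"      "adapted"
px$summary$coexpression
#>   time fraction_1 fraction_2 fraction_3 n_positive population_m
#> 1   30      0.677      0.323      0.000        371        0.372
#> 2   37      0.000      0.318      0.682        500        1.141
#> 3   48      0.000      0.000      1.000        500        3.240
```

Reading the output: the linear ramp leaves Her6 adapted at h\* while
the equally sized two-step input switches it to ~6×10⁻⁵ h\*; an
instantaneous fold change above ~5.86 is what it takes. The
locus-driven population input (nine-fold rise, concentrated at the
late onset) switches the circuit, while its least-squares linear
control and the late-locus knockout both leave Her6 adapted — the
in-silico analogue of the pri-mir-9-1 mutant failing to downregulate
Her6. The co-expression table shows the fraction of positive cells
expressing all three loci rising from 0 (30 hpf) to 0.68 (37 hpf) to
1.0 (48 hpf) as late expression is added onto early expression.

A thin command-line wrapper over the same functions is installed at
`inst/cli/mir9step.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mir9step.R",package="mir9step"))')" \
    steady-state --config inst/extdata/reference_config.yaml --out out/
```

## Package layout

- `R/profiles.R` — miR-9 input profiles (constant, linear, steps,
  tabulated, log-OU fluctuations)
- `R/locus_model.R` — per-cell locus activation and co-expression
  summaries
- `R/basic_model.R` — the adaptation loop: closed forms, simulation,
  adaptation metrics
- `R/extended_model.R` — Hill functions, fixed points and stability,
  classification, threshold search, feasibility
- `R/experiments.R` — seeded experiment drivers
- `R/config.R` — YAML configuration, TSV serialisation
- `vignettes/her6-mir9-switch.Rmd` — the methods vignette: model
  assumptions, parameter choices, feasibility theory, generator design,
  numerical details, limitations
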