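# imkfit

Cell-survival modelling for intensity modulated radiation fields with the
integrated microdosimetric-kinetic (IMK) model.

In modulated radiotherapy deliveries (IMRT, VMAT), directly irradiated
("in-field") and shielded ("out-of-field") cell populations coexist, doses
are delivered over minutes rather than seconds, and intercellular signalling
couples the two populations. `imkfit` is aimed at radiobiologists analysing
clonogenic survival from such experiments. It provides:

- **Dose-delivery schedules** — acute, split-dose, constant-rate and pulsed
  multi-fraction timelines as one piecewise-constant dose-rate
  representation.
- **The IMK survival model** — targeted (DNA damage) plus non-targeted
  (bystander signalling) lethal lesions for any schedule and field geometry.
- **Split-dose SLDR estimation** — the sub-lethal damage repair rate
  `(a+c)` and quadratic coefficient `β₀` from recovery curves.
- **Bayesian inference** — random-walk Metropolis MCMC for the remaining
  parameters with 95.4% predictive bands, `R²` and reduced `χ²`.
- **A synthetic-data generator** emulating single-dose, split-dose and
  dose-rate-regimen clonogenic experiments for a fibroblast-like (AGO1522)
  and a prostate-carcinoma-like (DU145) cell line.

## The model

Survival after a delivery with sub-section doses `d_n` separated by `ΔT` is
`S = S_T · S_NT` with

    -ln S_T = Σ_n [(α₀ + γβ₀) d_n + β₀ d_n²]
            + 2 β₀ Σ_{n<m} d_n d_m exp(-(m-n)(a+c)ΔT)

which for a constant dose rate collapses to the familiar
`-ln S_T = (α₀ + γβ₀)D + F β₀ D²` with the Lea-Catcheside protraction factor
`F = 2[(a+c)T + e^{-(a+c)T} - 1] / ((a+c)T)²`. The microdosimetric constant
is `γ = y_D / (ρ π r_d²)` from the dose-mean lineal energy `y_D`. Non-targeted
killing follows Poisson activation of signal-releasing targets:

    -ln S_NT = δ · f_h(D)_IF · f_b(D)_region ,
    f_h(D) = 1 - exp(-[(α_b + γβ_b)D + β_b D²]),  f_b = 1 - f_h

and depends on cumulative dose only. From a split-dose recovery curve `S(τ)`,

    (a+c) = [lim_{τ→0} (1/S) dS/dτ] / ln(S(∞)/S(0)) ,
    β₀ = ln(S(∞)/S(0)) / (2 D₁ D₂).

Given `γ`, `β₀` and `(a+c)`, the remaining parameters
`θ = (α₀, α_b, β_b, δ)` are sampled by component-wise random-walk Metropolis
with truncated-normal priors and Gaussian errors on `-ln S`.

## Worked example

```r
library(imkfit)

p     <- imk_presets("AGO1522")          # shipped literature parameter sets
half  <- field_config(a_if = 0.5)        # 50% of the flask irradiated
sched <- make_acute(4)                   # 4 Gy delivered acutely

imk_survival(p$modulated, p$nte, half, sched, "in_field")       # 0.1772
imk_survival(p$modulated, p$nte, half, sched, "out_of_field")   # 0.5794
imk_survival(p$uniform,  p$nte, field_config(a_if = 1), sched, "uniform")  # 0.0407
```

In-field cells under the half-field exposure survive far better (0.18) than
uniformly exposed cells at the same dose (0.04): the modulated-field
parameter set carries a smaller `β₀` and essentially no SLDR, while
out-of-field survival (0.58) is set entirely by signalling, not dose.

Recovering the repair parameters from a noiseless model-generated recovery
curve (2 Gy + 2 Gy, uniform field):

```r
crv <- generate_recovery_curve(p$uniform, p$nte, field_config(a_if = 1),
                               taus = c(0, 1e-4, 0.25, 0.5, 1, 2, 4, 24, 48))
estimate_a_plus_c(crv, step = 1e-4)
#> <sldr_estimate: a+c = 1.684 /h, beta0 = 0.081 /Gy^2
#>                 (S0 = 0.04071, Sinf = 0.07782, step = 0.0001 h)>
```

both generating values are recovered. Dose-rate effects under the uniform
field (4 Gy via pulsed regimens averaging 0.59 to 0.05 Gy/min):

```r
sapply(dose_rate_regimens(), function(r)
  imk_survival(p$uniform, p$nte, field_config(a_if = 1), r, "uniform"))
#> 0.59: 0.0440   0.2: 0.0511   0.1: 0.0608   0.05: 0.0768
```

survival rises as delivery stretches, and with the modulated-field set
(`a+c ≈ 0`) the same computation returns identical survival for all four
regimens — the schedule-independence the model predicts when repair during
delivery is negligible.

A command-line wrapper over the same functions is installed at
`system.file("cli", "imk.R", package = "imkfit")` with subcommands
`simulate`, `generate`, `estimate-sldr`, `fit`, `predict` and `gof`.

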