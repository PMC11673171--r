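# albudial

Simulation and grid-sweep fitting of protein-bound toxin removal by albumin
(binder) dialysis in counter-current hollow-fiber dialyzers.

Toxins such as bilirubin are ~99% albumin-bound in plasma, so ordinary
dialysis removes almost none of them: only the free fraction crosses the
membrane. Adding albumin to the dialysate captures free toxin as it crosses,
sustaining the free-concentration gradient. `albudial` is for people
designing or analysing such circuits — bench experimenters validating
transport models, and modellers choosing dialyzers and flow prescriptions —
and reproduces the full chain from membrane physics to fitted parameters:

* **Hydraulics** — closed-form axial profiles of blood/dialysate pressure,
  flow and local ultrafiltration flux `Jv = 2nπ·ri·Lp·(Pb − Pd)` under zero
  *net* ultrafiltration (locally nonzero: ultrafiltration proximal,
  backfiltration distal).
* **Binding** — single-site equilibrium; free toxin from the stable root of
  `Cs² + Cs(Ca + 1/KB − Ct) − Ct/KB = 0`.
* **Membrane flux** — convection–diffusion with Peclet weighting
  `f(Pe) = 1/Pe − 1/(e^Pe − 1)`, `Pe = Jv(1−σ)L/KfreeA`, a piecewise pure-
  diffusion branch for `|Jv| < min(Qb,Qd)·10⁻⁵/mm`, linear flow dependence
  `KfreeA(Qd) = KfreeA₅₀₀(1 + β(Qd−500)/300)`, and area rescaling between
  dialyzers.
* **Single pass** — the counter-current boundary-value problem in the
  amount-removed variable `χ`, solved by a numerically stabilized modified
  shooting method (interval classification, breadth-first priority search,
  spurious-root rejection) with a compiled implicit integrator.
* **Sessions** — quasi-steady two-reservoir dynamics
  `Vb·dCb/dt = Qb(Cb,out − Cb,in) = xy₀ = −Vd·dCd/dt`.
* **Fitting & synthetic data** — grid sweeps over `KB`, `KfreeA₅₀₀`, `β`
  scored by whole-trace sum of squares or final percent error, plus a
  seeded generator of replicate bench-style time series.

Five bench configurations (an F6HPS dialyzer at Qb 180/Qd 90 mL/min, and an
F3 dialyzer at Qd = 2, 20, 150, 800 mL/min) ship as YAML fixtures under
`inst/extdata/`.

## Worked example

```r
library(albudial)

setup <- load_setup(system.file("extdata", "f3_qd150.yaml", package = "albudial"))
setup
#> <dialysis_setup>
#>   dialyzer: 2304 fibers, L = 20 cm, nominal area 0.4 m^2
#>   flows: Qb = 150, Qd = 150 mL/min; reservoirs 200 / 200 mL
#>   toxin: 18.81 mg/dL blood start; albumin 1.9 / 1.94 g/dL; 5 h
#>   KfreeA(500) = 769.23 mL/min, beta_Qd = 0.45, KB = 5e+06 1/M

# one quasi-steady pass at the starting composition
sp <- solve_single_pass(single_pass_problem(setup))
sp
#> <single_pass_solution>
#>   xy0 (amount removed): -0.00572922 M mL/min
#>   residual |Delta|: 2.87e-10; shots: 103
#>   Cb_out: 0.000283531 M, Cd_out: 3.81948e-05 M

# a full 5 h session
tr <- simulate_session(setup)
glance(tr)
#> # A tibble: 1 × 4
#>   Cb_final percent_decline conservation_defect t_end
#>      <dbl>           <dbl>               <dbl> <dbl>
#> 1     9.41            50.0            4.31e-16   300
autoplot(tr)
```

`xy0` is the toxin amount transferred from blood to dialysate over one pass
(negative by convention; here ≈ 0.0057 M·mL/min ≈ 3.3 mg/min at the start).
Over five hours the blood reservoir falls from 18.81 to 9.41 mg/dL — a 50%
decline, close to the binding-equilibrium limit for matched reservoirs —
while total toxin mass is conserved to rounding (`conservation_defect`).

Fitting synthetic (or measured) data:

```r
nm <- noise_model(measurement_sd = 0.3, replicates = 3, seed = 1)
cond <- generate_condition(setup, true_params = list(KfreeA_at_500 = 1500),
                           noise = nm)
fit <- sweep_fit(setup, cond[cond$replicate == 1, c("time_min", "concentration_mg_dl")],
                 fit_grid(5e6, c(1000, 1500, 2000), 0.45))
glance(fit)
```

A thin CLI wraps the same functions
(`inst/scripts/albudial simulate|fit|generate|permeability`).

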