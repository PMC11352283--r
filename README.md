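# abasim

Kinetic simulation and calibration of abscisic acid (ABA) signaling and
an ABA-responsive bioluminescent whole-cell biosensor.

Plants perceive the stress hormone ABA through the PYR/PYL/RCAR receptor
family; perception inhibits the phosphatase PP2C, freeing the kinase
SnRK2 to drive downstream stress responses, with cross-talk into MAPK
signaling. Engineered whole-cell biosensors make this pathway
measurable: a stress-responsive promoter drives a luciferase-type
reporter, so intracellular ABA becomes light (relative light units,
RLU). `abasim` is for modelers who want to simulate these systems,
sweep dose-response behavior, quantify parameter sensitivity, and test
whether kinetic parameters can be recovered from (synthetic)
luminescence data before anyone commits to a wet-lab experiment.

## The models

Receptor occupancy follows the Hill equation

$$h(C) = \frac{C^n}{K_{half}^n + C^n},$$

with half-maximal concentration $K_{half}$ (µM) and cooperativity $n$.
Three ODE systems build on it (concentrations in µM, time in s):

* **`signaling_aba`** — ABA, SnRK2, PP2C, MAPK: hormone turnover
  $\dot C = k_{synthesis} - K_1 C$, Hill-driven kinase activation
  $\dot S = K_2\,h(C)$, and linear protein-protein interaction terms.
* **`signaling_noaba`** — the hormone-free reduction, in which PP2C
  deactivates SnRK2.
* **`biosensor`** — free ABA, reporter mRNA, free sensor protein, the
  ABA·protein complex $X$, and cumulative luminescence
  $\dot I = k_{response}\, h(X) \ge 0$. Binding
  ABA + Protein ⇌ Complex is interpreted either by physically
  consistent mass-action fluxes ($k_{on} C P$, $k_{off} X$; the
  default) or by the literal textbook system (a `mode` switch that
  every output records).

Around the models: adaptive LSODA integration with compiled right-hand
sides, an independent fixed-step RK4 oracle, steady-state detection,
dose-response sweeps over initial ABA (default 12 log-spaced levels,
1.5-50 µM), normalized local sensitivity analysis, Hill-curve and
full-model least-squares calibration with seeded multistart, a seeded
synthetic-plate generator, strict YAML run configs, and CSV/JSON outputs
with full provenance sidecars (plus an `inst/cli/abasim.R` command-line
wrapper). The methods vignette
(`vignettes/abasim-methods.Rmd`) documents every modeling and numerical
choice.

## Worked example

```r
library(abasim)

p  <- biosensor_params()        # reference set: kon = 1e5 M^-1 s^-1, koff = 1e-3 s^-1, ...
tr <- integrate_model("biosensor", p,
                      c(C_ABA = 10, mRNA = 0, Protein = 0,
                        Complex = 0, I_biolum = 0),
                      solver_settings(t_end = 3600))
tr
#> <aba_trajectory> model 'biosensor' (mass_action kinetics), 200 time points over [0, 3600] s
#> final state:
#>        C_ABA         mRNA      Protein      Complex     I_biolum
#> 4.568046e-02 8.740052e-02 1.336108e+00 6.558530e+00 3.162729e+03
```

After an hour, nearly all of the 10 µM dose has been captured into the
ABA·protein complex (6.6 µM) or degraded; the complex sits far above
$K_{half} = 1$ µM, so the reporter integrated light at almost the full
rate (3163 RLU out of a possible 3600).

```r
dr <- dose_response(settings = solver_settings(t_end = 3600))
head(as.data.frame(dr), 4)
#>   aba_initial  I_final converged
#> 1    1.500000 1774.354     FALSE
#> 2    2.063169 2094.599     FALSE
#> 3    2.837777 2390.060     FALSE
#> 4    3.903209 2647.823     FALSE

linearity_check(dr)
#> Linear fit: I_final = 2501.25 + 27.389 * ABA (RLU), R² = 0.5535

coef(fit_hill(dr$aba_initial, dr$I_final))
#>        top     K_half          n
#> 3541.73000    1.48591    1.11880
```

The sweep is strictly monotone — more hormone, more light — but
saturating rather than linear at the reference set (the fitted Hill
curve describes it almost perfectly, $R^2 = 0.99996$); the vignette
discusses which parameter regimes behave as linear ABA meters.
Calibration closes the loop: `generate_dose_response_data()` makes a
noisy plate with known ground truth, and `fit_biosensor_params()`
recovers, e.g., `{K_half, k_response}` from it by bounded multistart
least squares.

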