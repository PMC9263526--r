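# granulediff

Solute diffusion analysis for spherical granular biofilms (aerobic granular
sludge and similar hydrogel-like aggregates).

Granular sludge treats wastewater inside dense, roughly spherical biofilm
granules, so whether a substrate molecule can diffuse into a granule — and
how fast — controls which conversions happen where. The standard way to
measure this is the *transient uptake of a non-reactive solute*: granules
are suspended in a stirred, finite liquid volume, a tracer (typically
polyethylene glycol of a chosen molecular weight) is dosed, and the decline
of the bulk concentration is sampled over time. `granulediff` implements the
full analysis chain for such experiments, for researchers in environmental
biotechnology and biofilm mass transfer:

* the analytical finite-bath (limited-volume) forward model,
* effective-diffusivity estimation with multi-start nonlinear least squares
  and Monte-Carlo uncertainty propagation,
* molecular-weight scaling laws and their statistical comparison,
* granule-core penetration assessment, and
* bookkeeping for ultrafiltration COD size fractionation of influent
  wastewater.

A synthetic-data generator with known ground truth and an independent
finite-volume PDE oracle make every stage testable without laboratory data.

## The model

For identical spheres of radius $R$, initially solute-free, taking up a
non-reactive solute from a well-mixed bath with liquid-to-granule volume
ratio $\alpha = V_W/V_G$, the bulk concentration follows

$$\frac{C_B(t)}{C_B(t_0)} = \frac{1}{1+\alpha}\left(\alpha +
\sum_{n=1}^{\infty} \frac{6\alpha(1+\alpha)\,
e^{-D_e q_n^2 t/R^2}}{9+9\alpha+q_n^2\alpha^2}\right),
\qquad \tan q_n = \frac{3q_n}{3+\alpha q_n^2},$$

relaxing to the equilibrium ratio $\alpha/(1+\alpha)$. The effective
diffusivity $D_e$ is the single fitted parameter. When the curve plateaus
*above* $\alpha/(1+\alpha)$, part of the granule volume excludes the solute
and the accessible fraction $f$ follows from the equilibrium mass balance
$C_{eq}(f V_G + V_W) = C_0 V_W$. Diffusivities convert between temperatures
by $D_2 = D_1 (T_2/T_1)(\mu_1/\mu_2)$, scale with molecular weight as
$\log_{10} D = a \log_{10} MW + b$, and the core concentration of a granule
held in a constant bulk follows
$C/C_b = 1 + 2\sum_n (-1)^n e^{-D n^2\pi^2 t/R^2}$.

## Worked example

Generate a synthetic experiment emulating the canonical bench design
(25 samples of 0.5 mL from 300 mL, $\alpha = 4$, 4 °C, 2 % measurement
noise), fit it, and propagate uncertainty:

```r
library(granulediff)

spec <- synthetic_spec(D_true = 3e-10, noise_cv = 0.02, seed = 42)
exp  <- generate_experiment(spec)
exp
#> <uptake_experiment> 25 samples over 21600 s, C_0 = 1e+03 mg/L, alpha = 4

fit <- fit_diffusion(exp, n_starts = 50, seed = 1)
fit$sd_D <- as.numeric(monte_carlo_sd(exp, fit, n_sims = 1000, seed = 2))
fit
#> <diffusion_fit> D_e = 2.288e-10 m^2/s (4.337e-10 at 25 C), sd = 6.25e-11,
#>   rss(ratio) = 9.905e-03, 50/50 starts converged
```

The estimate sits 24 % below the true `3e-10` — within one Monte-Carlo
standard deviation (27 % relative). That spread is a property of the
design, not the optimiser: with only a 20 % total concentration drop at
$\alpha = 4$ and 2 % noise, the information floor for $\ln D$ is about
12–14 % (see the methods vignette), matching the tens-of-percent relative
standard deviations typical of this assay.

Compare a granule scaling law against the PEG-in-water reference law:

```r
granule <- scaling_fit(-0.564, -8.070, 0.044, 0.126, n = 11, label = "granule")
compare_fits(granule, water_reference_law())
#>   t_slope t_intercept    df p_slope p_intercept
#> 1   0.683       0.806    18   0.503       0.431
```

Neither slope nor intercept differs significantly: the granule matrix
barely hinders PEGs of 62–4000 Da. How deep do solutes get during a 60 min
anaerobic feed at 10 °C into 1 mm granules?

```r
assess_penetration(c(62, 1000, 4000), granule)
#>   mw_da D_law_m2_s D_assess_m2_s core_pct
#> 1    62   8.30e-10      5.37e-10    100.0
#> 2  1000   1.73e-10      1.12e-10     96.2
#> 3  4000   7.91e-11      5.12e-11     67.7
```

Molecules of 1 kDa and below reach ≥ 96 % of the bulk concentration in the
core. Combined with influent COD fractionation:

```r
fraction_ranges(summarize_fractions(influent_cod_fractions()))
#>   metric                   min_pct max_pct
#> 1 particulate_pct_of_total      62      77
#> 2 lt1kda_pct_of_total           15      26
#> 3 lt1kda_pct_of_soluble         61      69
#> 4 lt10kda_pct_of_soluble        70      87
#> 5 vfa_pct_of_soluble            15      18
```

so 61–69 % of the soluble COD of the three shipped influents is lighter
than 1 kDa and diffuses essentially unhindered into the granules.

A thin command-line wrapper (`inst/cli/workbench.R`) exposes the same
pipeline as `fit`, `scaling`, `penetrate`, `cod` and `simulate`
subcommands.

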