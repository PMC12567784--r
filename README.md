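# nanopbtk

Physiologically based toxicokinetic (PBTK) simulation of inhaled 20 nm
titanium dioxide nanoparticles (TiO₂-NPs) in the rat.

Inhaled nanoparticles deposit along the respiratory tract, are cleared by the
mucociliary escalator and swallowed, engulfed by macrophages, or translocate
across the air–blood barrier into the systemic circulation, where organs
accumulate them far more persistently than they do dissolved metal ions.
`nanopbtk` implements a mechanistic compartmental model of this process for
toxicokinetic modellers and nanotoxicology risk assessors: it predicts the
TiO₂-NP mass in every organ over time for a given exposure, quantifies how
well those predictions match measured biodistribution data, and identifies
the parameters that control lung retention and systemic distribution.

## The model

The body is represented by 23 mass states M(t) (ng) coupled by blood flow.
Each systemic organ o ∈ {liver, kidney, spleen, rest-of-body} is
permeability-limited and split into capillary blood, tissue and phagocytic
cells (PCs):

    dM_o,cab/dt = Q_o (C_art − C_o,cab) − X_o Q_o (C_o,cab − C_o,tis / P_o)
    dM_o,tis/dt = X_o Q_o (C_o,cab − C_o,tis / P_o) − (K_o,up(t) M_o,tis − K_o,out M_o,PCs)
    dM_o,PCs/dt = K_o,up(t) M_o,tis − K_o,out M_o,PCs

with C = M/V the sub-compartment concentrations, Q_o the organ blood flow,
X_o the permeability coefficient and P_o the tissue–blood partition ratio.
Saturable macrophage endocytosis follows a time-dependent Hill equation

    K_o,up(t) = K_o,max · tⁿ⁰ / (K_o,50ⁿ⁰ + tⁿ⁰),

rising from zero at exposure onset to half its maximum at t = K_o,50. The
respiratory tract comprises upper-airway, tracheobronchial, alveolar (free +
PC), lung-interstitial (free + PC) and lung-capillary states; exposure enters
as `EC × BR × FR_region` during inhalation, or as instantaneous deposited
masses for a bolus. Organs sit in parallel between arterial and venous blood;
the lung capillary sits in series and receives the whole cardiac output.
Excretion drains the upper airway and tracheobronchial region to feces
(mucociliary clearance), liver PCs to feces (biliary) and kidney tissue to
urine. Total mass, including the excretion sinks, is conserved exactly.

Evaluation metrics follow pharmacokinetic convention: the absolute average
fold error AAFE = 10^(mean |log₁₀(sim/meas)|), pointwise relative error,
R² in log₁₀ space, the WHO 0.5–2-fold acceptance band, and elimination
half-lives t½ = ln 2 / k from log-linear regression. Local parameter
influence is the normalized sensitivity S(t) = ∂ln y(t) / ∂ln θ, computed by
central finite differences in log space.

## Worked example

Simulate the calibration exposure — a short intratracheal inhalation that
deposits 40 ng in the tracheobronchial region and 892 ng in the alveolar
region — and summarize the lung burden:

```r
library(nanopbtk)

params <- default_parameters()
preset <- kreyling_preset()
res <- run_simulation(params, preset$scenario, t_end = preset$t_end)
mass_balance_audit(res)   # 1.92e-11 ng: conservation at solver precision

lung <- extract_observable(res, "lung")
peak_analysis(lung)[c("peak_mass", "peak_time")]
#> $peak_mass
#> [1] 624.3328
#> $peak_time
#> [1] 8.594091

alv <- extract_observable(res, "alveolar")
phase_decay_rates(alv, fast_window = c(0, 28), slow_window = c(28, 674))$ratio
#> [1] 0.1582904
```

The lung burden peaks at 624 ng about 8.6 h after exposure, and the slow
alveolar clearance phase proceeds at 15.8 % of the fast redistribution rate —
the signature biphasic decline of poorly soluble inhaled particles. Model
evaluation runs against observed datasets (CSV); synthetic ones with
controlled lognormal noise exercise the same path:

```r
obs <- generate_observed(params, preset, noise_cv = 0.2, replicates = 5,
                         seed = 42)
head(obs, 2)
#>         observable time_h     mean_ng       sd_ng
#> 1 tracheobronchial      4 12.48518015 1.696851932
#> 2 tracheobronchial     24  0.02693613 0.005696741
```

Sensitivity of the liver curve to the lung partition coefficient:

```r
local_sensitivity(params, preset$scenario, "respiratory.P_lu",
                  outputs = "liver", times = c(4, 24, 168, 674))
#> Local sensitivity to respiratory.P_lu (baseline 30359)
#>   aggregation rule: max_abs
#>   liver              2.694
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/nanopbtk.R simulate --preset kreyling --t-end 1500 --out result.csv
Rscript inst/cli/nanopbtk.R fixtures --preset kreyling --noise-cv 0.2 --seed 42 --out observed.csv
Rscript inst/cli/nanopbtk.R evaluate --result result.csv --observed observed.csv
```

Each output is accompanied by a `*.manifest.json` provenance record
(parameter and scenario fingerprints, tolerances, seed, version).

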