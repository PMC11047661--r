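# eyescreen

Probability-based in vitro eye-irritation screening from micropatterned
human corneal epithelial cell (hCEC) assays.

## The problem

Single in vitro endpoints predict eye irritation poorly because irritants
act through several mechanisms at once: surfactants such as sodium lauryl
sulphate (SLS) kill corneal epithelial cells outright, while compounds such
as ethyl methyl acetoacetate (EMA) sting mainly by activating the TRPV1
nociceptor with little cytotoxicity. A way around this is to partition an
hCEC monolayer into hundreds of ~80 µm circular micropatterns (each holding
roughly 4.5 ± 2 cells), expose them to a compound, and read each
micropattern as a *binary* responder/non-responder for two independent
assays:

- **Apoptosis** (caspase-3/7): a cell is positive when its caspase
  intensity exceeds the vehicle-control mean by more than 20%
  ((I − Ī_ctrl)/Ī_ctrl > 0.20); a micropattern is positive when ≥ 50% of
  its cells are.
- **TRPV1 activation** (Fluo-4 Ca²⁺ influx): each cell's trace is
  baseline-subtracted at the first frame, integrated over the 20 frames
  after compound addition, and scored positive when the integrated peak
  area is > 0; the same ≥ 50%-of-cells rule makes the micropattern call.

The many binary micropattern outcomes at each tested concentration C (nM)
support a binary logistic dose-response fit per assay,

    P(C) = 1 / (1 + exp(−(β₀ + β₁·C))),    IC50 = −β₀/β₁,

and the two mechanisms are then folded into one eye-irritation index with
the union rule for non-mutually-exclusive events,

    P_irritation = P_apoptosis + P_TRPV1 − P(apoptosis ∩ TRPV1),

with the intersection modelled as the independence product (other
intersection rules can be plugged in and are checked against the Fréchet
bounds).

The package implements the full analysis chain — ROI-grid registration,
Otsu nuclei segmentation, per-cell intensity and trace measurement,
cell- and pattern-level digitization, logistic fitting with Wald bands,
and probability combination — together with a synthetic-data generator
(chip images, calcium time-lapse stacks, binary dose-response tables) with
known ground truth, so every stage is testable without any microscope data.

## Worked example

Simulate a complete SLS-like experiment (two chips, each with a vehicle
well and three treated wells; pattern-level ground truth drawn from
logit(p) = −1.1057 + 10⁻⁶·C), run the imaging pipeline end to end, and
combine with a constant 0.5 TRPV1 probability:

```r
library(eyescreen)

cfg <- run_config(out_dir = tempfile(), seed = 42, compound = "SLS",
                  concentrations = c(1e4, 1e5, 5e5, 1e6, 3e6, 6e6),
                  true_beta0 = -1.1057, true_beta1 = 1e-6,
                  trpv1 = 0.5, grid_rows = 8, grid_cols = 12)
manifest <- run_pipeline(cfg)

fit <- read_fit_json(file.path(cfg$out_dir, "fit_apoptosis.json"))
fit
#> Binary logistic dose-response fit (linear nM scale)
#>   logit(p) = -1.0218 + 9.49e-07 * C   (n = 144)
#>   converged: TRUE, separation: FALSE
ic50(fit)
#> [1] 1077162

irritation_profile(fit, 0.5, concentrations = c(1e4, 1e5, 1e6, 1e7))
#>   concentration_nM p_apoptosis p_trpv1 p_combined
#> 1            1e+04       0.267     0.5      0.633
#> 2            1e+05       0.284     0.5      0.642
#> 3            1e+06       0.482     0.5      0.741
#> 4            1e+07       1.000     0.5      1.000
```

From 144 simulated micropatterns the fit recovers the generating model
(β₀ = −1.02 vs −1.1057, β₁ = 9.5×10⁻⁷ vs 10⁻⁶ per nM; both within
sampling error), giving an IC50 of ~1.1 × 10⁶ nM ≈ 1 mM. The combined
column shows the characteristic surfactant profile: a sub-cytotoxic
plateau near 0.63 driven by the constant TRPV1 term, rising to ~1 once the
apoptotic mechanism saturates. `autoplot(fit)` and `autoplot()` on an
`irritation_profile` draw the curves with their 95% Wald bands;
`tidy()`/`glance()` expose coefficients and fit summaries in broom
conventions.

Individual stages are ordinary data-frame functions and chain with the
pipe, e.g.:

```r
chip  <- simulate_chip_image(sim_chip_config(grid_rows = 5, grid_cols = 5, seed = 1),
                             apoptotic_fraction = 0.5)
cells <- segment_nuclei(chip$dapi, chip$layout) |>
  measure_cells(chip$caspase)
patterns <- apoptosis_cell_outcomes(cells, control = 54.3) |>
  pattern_outcomes()
```

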