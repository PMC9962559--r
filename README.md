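# oxirelax

Low-field NMR (LF-NMR) relaxometry is becoming a practical, non-destructive
sensor technology for monitoring the oxidation of edible oils: as
polyunsaturated oils oxidize, their proton transverse-relaxation (T₂)
behavior shifts toward shorter relaxation times, their self-diffusion
coefficient D drops, and wet-chemistry oxidation indices (peroxide value PV,
p-anisidine value p-AV, TOTOX = p-AV + 2·PV) rise. `oxirelax` implements the
full software side of such a sensor for R users — instrument-facing data
formats in, oxidation verdict out:

* **Simulation** of class-conditional CPMG echo trains
  S(t_k) = Σᵢ aᵢ·exp(−t_k/T₂ᵢ) + ε_k, pulsed-field-gradient spin-echo
  (PFGSE) attenuation series S/S₀ = exp(−bD) with
  b = γ²G²δ²(Δ−δ/3), and companion chemistry values, with samples labeled
  `Good` / `Fair` / `Bad` (non-, partially, highly oxidized) by construction.
* **Spectrum reconstruction** by regularized inverse Laplace transform:
  min_{f≥0} ‖Kf−s‖₂² + a₁‖f‖₁ + a₂‖f‖₂² on a log-spaced T₂ grid
  (default a₂ = 0.5), solved by an accelerated projected-gradient method
  with active-set certification.
* **Labeling** of samples from (D, PV) via half-open diffusion/peroxide
  bins (D > 0.03×10⁻⁹ m²/s and PV < 20 mmol/kg ⇒ `Good`;
  D ≤ 0.02×10⁻⁹ m²/s and PV ≥ 50 mmol/kg ⇒ `Bad`; between ⇒ `Fair`),
  with explicit conflict policies, plus D estimation from PFGSE series.
* **Classification** of raw relaxation curves by a 1D dilated convolutional
  network (4 dilated conv layers → ReLU → global max pool → dense → 3-way
  softmax), trained with Adam on min-max-normalized curves; the global pool
  lets one model accept curves of any length (1 024 to 16 384 echoes).
* **Evaluation** with per-class precision / recall / F1 and
  median [IQR] aggregation across repeated, independently seeded training
  sessions.

## Worked example

```r
library(oxirelax)

## 60 labeled synthetic samples, 2048-echo CPMG curves
ds <- generate_dataset(60, seed = 7)
print(ds)
#> oxi_dataset: 60 samples (Good=19, Fair=12, Bad=29)

## reconstruct the T2 spectrum of one curve
sp <- ilt(ds$records[[1]]$curve, a2 = 0.5)
print(sp)
#> T2 spectrum on 128 log-spaced points in [0.0008, 16.4] s
#>   penalties a1 = 0, a2 = 0.5; residual norm 0.4624; 200 iter
#>   peaks (T2 s @ amplitude): 0.19 @ 0.0686

## train the dilated CNN (short demo run; default is 210 epochs)
fit <- oxinet(ds, config = model_config(epochs = 60L), seed = 1)
print(fit)
#> 1D dilated CNN oxidation classifier (oxinet)
#>   4 conv layers: filters (16,16,32,32), kernel 9, dilations (1,2,4,8)
#>   global max pool -> dense 64 -> softmax 3; 18675 parameters
#>   trained 60 epochs on 51 curves (input length 512)
#>   final train acc 1.000 / loss 0.0054; validation acc 1.000 / loss 0.0114

## classify a new curve
predict(fit, ds$records[[2]]$curve, type = "both")
#>   class probability
#> 1  Good   0.9989059
```

The spectrum peak near 0.19 s is the jittered slow aliphatic-chain
component of a non-oxidized sample; oxidized samples shift mass toward
shorter T₂. The verdict row gives the predicted class and its softmax
probability (1/3 ≤ p ≤ 1).

`estimate_d()`, `classify_oxidation()` and `totox()` cover the chemistry
route, and `run_experiment()` drives repeated training sessions and writes
the aggregate median [IQR] performance table. A thin command-line front end
(`inst/cli/oxirelax.R`) exposes `simulate`, `label`, `ilt`, `train`,
`classify`, `evaluate`, `report` and `run-experiment` subcommands.

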