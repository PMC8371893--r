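# nitraspec

Hyperspectral estimation of nitrate nitrogen (NO₃⁻–N) in cotton petioles
from canopy reflectance.

Petiole nitrate is the standard in-season tissue diagnostic for cotton
nitrogen management, but the wet-chemistry assay is slow and destructive.
This package estimates it from canopy reflectance spectra (350–1075 nm)
instead. The chain is:

1. **Ingest** reflectance curves (wide or long CSV), average repeated
   scans per sample.
2. **Preprocess**: first-derivative spectra by forward differencing,
   optional Savitzky–Golay smoothing.
3. **Features**: trilateral edge parameters — amplitude `Dx` and area
   `SDx` of the blue (490–530 nm), yellow (560–640 nm), and red
   (680–760 nm) edges of the derivative curve — plus six red-edge
   vegetation indices (RD, CI_red_edge, NDRE, ND705, NIR, RI_1dB) on both
   the original and derivative bases.
4. **Screen** features by Pearson correlation (p < 0.01) and
   linear/quadratic/exponential single-feature regressions.
5. **Estimate** with a wavelet neural network

   ŷ = c + Σⱼ vⱼ ψ((wⱼ·x − bⱼ)/aⱼ),  ψ(t) = cos(1.75 t) · exp(−t²/2),

   trained by online gradient descent (lr 0.01, ≤1000 epochs, error goal
   MSE ≤ 0.001 on min–max-normalized targets), with hidden-layer size
   selected by held-out root-mean-square relative error (MRE).
6. **Compare** against random forest (1070 trees), an
   exact-interpolation Gaussian RBF network, and a back-propagation
   network that shares the WNN trainer with sigmoid activations — scored
   by R², RMSE, MAE, MRE and percent-change arithmetic.

A seeded synthetic generator reproduces the field design (5 nitrogen
rates × 3 replicates × 4 growth stages for modeling; 15 plots × 4 stages
for validation; 3 scans per sample), so everything runs without external
data. See `vignettes/methods.Rmd` for the model and generator details.

## Worked example

```r
library(nitraspec)

# simulate the field campaign (5 N rates x 3 reps x 4 stages, 3 scans each)
cfg <- sim_config(seed = 1)
ft  <- synthetic_feature_tables(cfg)

# blue-edge features: amplitude Db and area SDb of the 490-530 nm derivative
X  <- as.matrix(ft$modeling[c("Db", "SDb")])
Xv <- as.matrix(ft$validation[c("Db", "SDb")])

model <- train_wnn(X, ft$modeling$no3n, cfg = train_config(seed = 1))
model
#> <wavelet network: 2 inputs, 10 hidden (morlet), 1000 epoch(s), final MSE 1.40e-03 (max_iterations)>

str(eval_metrics(predict(model, Xv), ft$validation$no3n))
#> List of 5
#>  $ r_squared: num 0.908
#>  $ rmse     : num 0.792
#>  $ mae      : num 0.615
#>  $ mre      : num 8.24
#>  $ n        : int 60
```

On the same held-out split the baselines reach (from
`analysis/04_model_comparison.R`):

```
 model r_squared      rmse       mae
   WNN 0.9080917 0.7922374 0.6149525
    RF 0.8505336 1.0102983 0.8390078
   RBF 0.5315662 1.7885538 1.0048753
    BP 0.8500696 1.0118654 0.8417043
```

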