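# flakmap

Predicting the post-operative anterior corneal axial-curvature map after
femtosecond laser arcuate keratotomy (FLAK), for researchers working on
astigmatism surgical planning.

Arcuate keratotomy corrects corneal astigmatism by cutting one or two arcs
on an 8.0-mm optical zone; planning today reduces the cornea to a single
cylinder number and a nomogram. `flakmap` treats planning as an
image-to-image problem instead: given the pre-operative curvature map, the
patient's age and the planned arcs, predict the whole post-operative map,
then evaluate the prediction the way the ophthalmic literature does.

The package covers the full pipeline:

* **Raw map I/O** — Pentacam-style CSV grids of anterior radius of curvature
  over a 3.5-mm-radius disk (141x141 at 0.05 mm or 71x71 at 0.1 mm), with
  validity masks, locale-aware dialects and sentinel handling, plus
  pseudo-colour axial-map rendering. Curvature converts to keratometric
  power by `Dpt = (1.3375 - 1) * 1000 / R = 337.5 / R`.
* **Simulated keratometry** — flat/steep K, cylinder and axis from
  area-averaged meridian power profiles in 1/3/5-mm zones, with sub-degree
  axis refinement.
* **Alpins vector analysis** — in double-angle space
  `(M cos 2θ, M sin 2θ)`: TIA (= pre-operative astigmatism),
  DV (= post-operative astigmatism), SIA (= pre ⊖ post, the change
  achieved), CI (= |SIA|/|TIA|), cohort summaries, Pearson r / MAE / paired
  tests between real and synthetic outcomes, polar plots.
* **Image metrics** — zone-masked MSE, `PSNR = 10 log10(MAX²/MSE)` and SSIM
  with `c1 = (0.01 MAX)²`, `c2 = (0.03 MAX)²`.
* **Synthetic cornea + surgery simulator** — paired pre/post-operative maps
  with analytically known ground truth (toric surface plus a coupling-dipole
  surgical response scaled by arc length and age), so everything above is
  testable without patient data.
* **A native pix2pix-style conditional GAN** — U-Net generator, patch
  discriminator, adversarial + λ·L1 objective, buffer-pool alternating
  training — implemented in this package with Rcpp/RcppArmadillo
  convolution kernels (no external deep-learning framework), fully seeded
  and reproducible.

## Worked example

```r
library(flakmap)

# 60 synthetic eyes: toric corneas, nomogram-planned arcs, simulated surgery
cfg <- synth_config(n_eyes = 60, preset = "coarse")
ds  <- generate_dataset(cfg, flak_effect_model(), split = c(0.8, 0.2), seed = 1)

# keratometry of one pre-operative map
zone_keratometry_table(curvature_to_power(ds$preop[[1]]), zones = c(1, 3, 5))
#> # A tibble: 3 × 6
#>    zone k_flat k_steep astig_magnitude steep_axis axis_indeterminate
#>   <dbl>  <dbl>   <dbl>           <dbl>      <dbl> <lgl>
#> 1     1   43.1    44.0           0.922       104. FALSE
#> 2     3   43.0    44.0           1.01        103. FALSE
#> 3     5   43.0    44.0           1.05        103. FALSE

# train the conditional GAN on the paired records and predict held-out maps
model <- train_pix2pix(ds[ds$role == "train", ],
                       train_config(epochs = 20, seed = 1),
                       val_records = ds[ds$role == "test", ])
pred  <- predict(model, ds[ds$role == "test", ])

# Alpins agreement and image quality, per zone
res <- eval_prediction_set(pred)
res$agreement[res$agreement$zone == 3, c("quantity", "pearson_r", "mae", "p_value")]
#> # A tibble: 2 × 4
#>   quantity      pearson_r   mae p_value
#>   <chr>             <dbl> <dbl>   <dbl>
#> 1 sia_magnitude     0.707 0.187   0.129
#> 2 dv_magnitude      0.332 0.116   0.151

res$image_metrics |> dplyr::group_by(zone) |>
  dplyr::summarise(ssim = mean(ssim), psnr = mean(psnr[is.finite(psnr)]))
#> # A tibble: 3 × 3
#>    zone  ssim  psnr
#>   <dbl> <dbl> <dbl>
#> 1     1 0.983  47.9
#> 2     3 0.979  47.3
#> 3     5 0.975  46.9
```

All output above is what the code actually prints. The first table reads a
synthetic cornea with about 1 D of cylinder steep near 103 degrees,
consistent across zones because the surface is globally toric. The agreement
table says that on the 12 held-out eyes of this tiny noisy run the predicted
surgically-induced-astigmatism magnitudes correlate 0.71 with the real ones
(mean absolute error 0.19 D) and the paired test finds no systematic
difference; the residual (DV) magnitudes are small and noise-dominated, so
their correlation is lower. The metrics table shows the predicted maps are
structurally close to the real post-operative maps in every zone (SSIM
about 0.98 on the normalised planes). Larger cohorts, as in
`scripts/acceptance.R`, push the SIA correlation above 0.9.

Trained models serialise to plain JSON (`save_pix2pix()` /
`load_pix2pix()`); datasets write to CSV grids with YAML sidecars and a JSON
manifest (`cmd_simulate()` / `read_dataset()`). A thin command-line wrapper
over the same functions is in `inst/cli/flakmap.R`
(`simulate` / `train` / `evaluate` subcommands).

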