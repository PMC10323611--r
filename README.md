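# msotmix

Spectral mixture analysis for multispectral optoacoustic tomography (MSOT)
of soft tissue, built for studies of peripheral nerves and their vascular
environment.

MSOT records one image per excitation wavelength (by default 28 channels,
700–970 nm in 10 nm steps), so every pixel carries an absorption-weighted
spectrum mixing the local chromophores: oxy-/deoxyhemoglobin, lipid, water,
melanin, collagen. Because fluence correction is unreliable for handheld
probes, the raw spectra are additionally distorted by depth-dependent
spectral coloring. `msotmix` analyses such data with:

* **Regularized NMF unmixing** — the non-negative spectra matrix
  *S* ∈ ℝ^(N×L) is factorized as *S* ≈ *WH* by minimizing

  ½‖S − WH‖²_F + λ₁(‖W‖₁ + ‖H‖₁) + ½λ_F(‖W‖²_F + ‖H‖²_F),  W, H ≥ 0

  with defaults K = 9, λ₁ = 80, λ_F = 20. The strong L1 term yields
  maximally sparse per-pixel decompositions. Comparators: constrained
  linear unmixing against a fixed library (`nnls_unmix()`) and vertex
  component analysis (`vca_endmembers()`).
* **A two-part coefficient model** — per component, presence is Bernoulli
  and the non-zero part is Box-Cox transformed (maximum-likelihood power)
  and studentized; absent entries sit at exactly −3 (the 3σ convention).
* **Co-occurrence statistics** — pairwise Sørensen-Dice coefficients of
  presence patterns and Pearson correlations of the standardized non-zero
  parts, plus nerve-versus-reference difference matrices with reference
  pixels drawn from a bivariate normal location law.
* **Mixture-class clustering** — pixels sharing a presence pattern form a
  class (≤ 2⁹ = 512); classes are clustered by Ward linkage on their mean
  L2-normalized spectra, ROIs get spectral fingerprints (leaf
  distributions) and fingerprint entropies, and per-leaf correlation
  analysis undoes the averaging effects of pooled correlations.
* **A synthetic phantom generator** — layered skin/fat/muscle anatomy with
  a fascicled nerve and vessels, closed-form chromophore analogues,
  Beer–Lambert spectral coloring and seeded noise, providing exact ground
  truth for every stage.

## Worked example

```r
library(msotmix)

scene <- render_phantom(noise_sd = 0.5, seed = 1)   # 200 x 200 px, 28 channels
S <- spectra_matrix(scene)                          # 40000 x 28 pixel spectra

fit <- nmf_unmix(S, nmf_params(k = 9))
fit
#> regularized NMF fit: 40000 x 28 spectra, K = 9, 89 iterations, relative error 2.965%

W_lin <- nnls_unmix(S, scene$endmembers)            # true uncolored library
100 * relative_error(S, W_lin, scene$endmembers)
#> 6.04
```

The data-driven factorization explains the colored scene about twice as
well as exact knowledge of the uncolored endmembers — the free components
absorb the depth-dependent spectral distortion that a fixed library cannot.

```r
presence <- binarize_presence(fit$W)
round(presence$p, 3)
#> comp1 comp2 comp3 comp4 comp5 comp6 comp7 comp8 comp9
#> 0.930 0.434 0.013 0.000 0.000 0.000 0.000 0.000 0.000

classes <- enumerate_classes(presence, S)
classes
#> 4 mixture classes over 9 components (max 512); 0 null-class pixels

tree <- ward_tree(classes)
fp <- fingerprint(which(scene$nerve_mask[attr(S, "backmap")]), classes, tree)
round(fp, 3)
#> 010000000 100000000 110000000 111000000
#>     0.000     0.004     0.996     0.000
fingerprint_entropy(fp)
#> 0.027
```

The sparsity penalty concentrates this simple phantom into a handful of
mixture classes; the nerve's fingerprint is nearly a delta on the class
mixing components 1 and 2 (low entropy). Real pooled datasets with
millions of spectra populate hundreds of classes.

The full chain — including reference sampling, Dice/Pearson contrast
matrices and all persisted artifacts — runs as one call:

```r
report <- run_pipeline(pipeline_config(), "out_dir")
```

or from a shell via the thin wrapper `inst/scripts/msotmix`
(`msotmix run --out out_dir --seed 1`).

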