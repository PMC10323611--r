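---
title: "Spectral mixture analysis of multispectral optoacoustic images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral mixture analysis of multispectral optoacoustic images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multispectral optoacoustic tomography (MSOT) excites tissue with pulsed
laser light at a sequence of near-infrared wavelengths and records the
resulting ultrasonic waves, yielding one image per wavelength. Each pixel
carries an absorption-weighted spectrum that mixes the contributions of the
local chromophores — oxy- and deoxyhemoglobin, lipid, water, melanin,
collagen. Two facts complicate quantitative analysis:

1. **Sparsity of contrast.** Any one tissue is dominated by a handful of
   chromophores, so pixel spectra are sparse mixtures.
2. **Spectral coloring.** Light is attenuated wavelength-dependently on its
   way down, so the same tissue looks spectrally different at different
   depths; in particular, a subcutaneous fat layer carves a dip into the
   900–940 nm (lipid absorption) band of every spectrum beneath it.
   Reliable fluence correction is unsolved for handheld clinical probes,
   so this package deliberately analyses raw (initial-pressure) spectra.

`msotmix` implements a complete analysis chain for such data: data-driven
unmixing, a probabilistic coefficient model, co-occurrence statistics, and
hierarchical clustering of mixture classes — together with a synthetic
phantom generator that provides ground truth for every stage.

## The synthetic phantom

In vivo nerve datasets of this kind are not publicly downloadable, so the
package ships a generator (`phantom_layout()`, `render_phantom()`) whose
scenes have known endmembers, abundances and masks. The phantom emulates
the statistical structure the analysis relies on, not the physics of image
formation:

* **Geometry.** A layered cross-section (epidermis, dermis, subcutaneous
  fat, muscle) with an embedded nerve ellipse containing fascicle
  sub-disks, and blood-vessel disks parameterized by an oxygenation
  fraction. Row 0 is the skin surface; pixels default to 0.1 mm (the
  common 100 µm reconstruction resolution), 200 × 200 pixels.
* **Spectra.** Six closed-form chromophore analogues
  (`endmember_library()`): sums of Gaussians and exponential trends that
  reproduce the qualitative features of the real absorption spectra
  (lipid peak inside 900–940 nm, water peak at 970 nm, the 760 nm
  deoxyhemoglobin bump, the melanin/collagen slope, a weak collagen bump
  near 900 nm). Using parametric stand-ins rather than digitized
  literature spectra keeps the ground truth self-contained and the rows
  provably linearly independent.
* **Coloring.** A one-dimensional Beer–Lambert fluence model
  (`fluence_model()`): a per-wavelength effective attenuation coefficient
  with a bump across the lipid band, accumulated over depth. This is the
  simplest model that produces the observed lipid-band dip under fat;
  full light transport is out of scope.
* **Noise.** Additive Gaussian noise clipped at zero (the unmixing
  requires non-negative data). Reconstructed-image noise levels are not
  something we can calibrate against, so `noise_sd` is a configuration
  knob; the default 0.5 is a few percent of a typical mid-depth signal
  (spectra range up to ≈ 25 in the default scene), which a practitioner
  would call a clean-but-realistic acquisition.

What passing tests on these phantoms does *not* show: robustness to
reconstruction artifacts (streaks, limited-view shadows), motion, probe
coupling, or inter-subject anatomical variability. The phantom's purpose is
to make the algorithmic contracts testable, not to certify clinical
performance.

## Regularized NMF unmixing

`nmf_unmix()` factorizes the non-negative pixel-spectra matrix
\(S \in \mathbb{R}^{N \times L}\) as \(S \approx WH\) with
\(W \in \mathbb{R}^{N \times K}_{\ge 0}\),
\(H \in \mathbb{R}^{K \times L}_{\ge 0}\) by minimizing

\[
\tfrac12\,\lVert S - WH\rVert_F^2
 + \lambda_1\,(\lVert W\rVert_1 + \lVert H\rVert_1)
 + \tfrac12\,\lambda_F\,(\lVert W\rVert_F^2 + \lVert H\rVert_F^2).
\]

Defaults \(K = 9\), \(\lambda_1 = 80\), \(\lambda_F = 20\): the strong
entrywise L1 term promotes maximally sparse coefficient vectors (few
chromophores per pixel), the Frobenius term keeps factors bounded.

Numerical choices:

* **Solver.** Block coordinate descent: each column of \(W\) (row of
  \(H\)) has a closed-form non-negative soft-thresholded ridge update, so
  every step minimizes the *exact* objective over that block and the
  recorded objective trace is non-increasing by construction — the trace,
  not a surrogate, is what tests assert.
* **Initialization.** Deterministic non-negative double SVD (NNDSVD, with
  small-constant backfill of zeros); a seeded random mode is available for
  restarts. Determinism is needed for reproducible runs; the choice of
  initialization is otherwise free.
* **Exact zeros.** After convergence, coefficients at or below
  `eps_zero = 1e-9` times their component's maximum are snapped to exact
  zero. The downstream model dichotomizes zero versus non-zero, so zeros
  must be unambiguous; the relative threshold makes the convention
  scale-free.
* **Ordering.** Components are reordered by descending total coefficient
  mass, giving a canonical output order.
* **Identifiability.** With \(\lambda_1 = \lambda_F = 0\) the
  factorization is only defined up to a non-negative rotation: the solver
  reliably drives the relative error
  \(\lVert S - WH\rVert_F^2 / \lVert S\rVert_F^2\) to numerical zero on
  noiseless scenes, but the individual rows of \(H\) need not equal the
  generating endmembers. Endmember-recovery tests therefore target the
  identifiable cases: rank-1 data (closed form) and pure-pixel scenes via
  VCA, which has an exact-recovery guarantee there.

Two comparators are provided. `nnls_unmix()` is classical constrained
linear unmixing against a fixed library (per-pixel non-negative least
squares via an active-set solver); because its library cannot bend with
depth, it underfits colored scenes — on the default phantom the NMF's
relative error is roughly half the NNLS error, and tests assert this
ordering (not specific percentages, which are dataset properties).
`vca_endmembers()` implements vertex component analysis: SNR-based
subspace selection followed by iterative orthogonal-projection maximization
that picks pixel spectra as endmembers.

## The coefficient model

Sparse coefficients have a spike at zero and a strongly right-skewed
positive part, and the scale of different components varies by orders of
magnitude. `binarize_presence()` and `standardize_coefficients()` model
each component as a two-part mixture:

* presence \(m_j \sim \mathrm{Bernoulli}(p_j)\);
* the non-zero part is Box-Cox transformed,
  \(y = (x^{\beta} - 1)/\beta\) (log at \(\beta = 0\)), with \(\beta\)
  fitted by maximizing the Gaussian profile log-likelihood (Jacobian
  included) over \([-5, 5]\) — a coarse 51-point grid localizes the mode,
  then `optimize()` refines it to 1e-4;
* transformed values are studentized to mean 0, sd 1;
* absent entries are set to exactly −3, just below the 3σ bulk of a
  standard normal, so "absent" stays ordered beneath "barely present".
  The −3 constant is a convention, not a parameter.

Because the Box-Cox family absorbs positive scalings, standardizing the
same underlying signal observed at two depth attenuations yields the same
distribution — the transformation acts as a partial fluence adjustment.
Fitting is done per scope (e.g. per nerve class) so different spectral
environments are standardized independently. Scope × component cells with
fewer than three distinct non-zero values cannot support a Box-Cox fit and
are flagged unusable rather than silently dropped.

## Co-occurrence statistics

On the binary level, `dice_matrix()` computes the pairwise Sørensen-Dice
coefficient \(\mathrm{DSC}_{jk} = 2\,m_j\!\cdot\!m_k /(\lVert m_j\rVert^2 +
\lVert m_k\rVert^2)\): the tendency of two components to mix. On the
continuous level, `pearson_matrix()` computes Pearson correlations of the
standardized non-zero parts: how components mix when they mix (positive =
fixed-ratio, near zero = random, negative = competitive).

The correlation's pixel set is a genuine modelling choice: the non-zero
variables are only defined where a component is present, and correlating a
present value against a −3 placeholder would conflate the model's two
levels. The default pairing therefore uses pixels where *both* components
are present (`"all_pixels"` is available as an option). Pairs with fewer
than 10 co-occurring pixels are flagged undefined rather than reported —
correlation estimates below that are noise. `contrast_difference()` forms
nerve-minus-reference difference matrices; reference pixels are drawn by
`sample_reference_pixels()` from a bivariate normal law fitted to nerve
centroid statistics (`estimate_location_stats()`), with rejection sampling
of draws that leave the analysis mask or hit the nerve mask — the
reference must represent the nerve's surroundings, so nerve pixels are
excluded by construction, and rejection (rather than truncation
renormalization) keeps the law simple. The default reference sample size
equals the nerve ROI's pixel count, balancing the two sides of every
difference statistic.

## Mixture classes, Ward tree, fingerprints

Pixels sharing a presence pattern form a mixture class
(`enumerate_classes()`; at most \(2^K = 512\) classes for \(K = 9\)).
All-zero-pattern pixels go to a flagged null class that is excluded from
the tree — whether such a class should count as a leaf is not decidable
from first principles, so the exclusion is documented rather than claimed
canonical. Each class is summarized by its mean L2-normalized spectrum;
the phrase "mean normalized spectrum" is order-ambiguous, and this package
normalizes first, then averages (the alternative is one flag away in
`class_mean_shape()` users' hands, since the function itself is exposed).

`ward_tree()` builds the agglomerative Ward hierarchy over the class
shapes (Euclidean distance, each class one unweighted observation —
weighting by pixel count is not obviously right and is left to the
caller's aggregation). Heights follow the
\(\sqrt{2\,\Delta\mathrm{SSE}}\) convention, under which two singleton
classes at distance \(d\) merge at height \(d\); tests verify the merges
against a brute-force minimum-variance oracle. Trees serialize to Newick
with pattern strings as leaf names.

`fingerprint()` computes an ROI's distribution over the leaves in
left-to-right dendrogram order; `fingerprint_entropy()` its Shannon
entropy (natural log by default; the base is configurable and recorded in
run reports). Per-leaf correlation analysis (`per_leaf_pcc()`) restricts
the Pearson analysis to the components present in all of the largest
leaves: opposite-sign couplings that cancel in the pooled correlation are
recovered per leaf, which tests reproduce by construction on a two-leaf
design.

## The pipeline

`run_pipeline()` chains simulate (or load) → unmix → model → stats →
cluster → report, persisting every intermediate artifact (component
spectra CSV, coefficient-map TIFFs, metric CSVs, Newick tree, fingerprint
CSV, JSON report with an MD5 config hash and all seeds). Runs are pure
functions of their configuration. A thin command-line wrapper
(`inst/scripts/msotmix`) exposes `simulate`, `run` and `report`
subcommands; the remaining stages are the exported functions themselves.

Problem sizes used in the shipped tests and acceptance script: the default
200 × 200-pixel phantom (40 000 spectra, 28 wavelengths) for end-to-end
comparisons, 80 × 80 scenes for stage-level tests, and tiny enumerable
instances (N ≤ 50) wherever a brute-force oracle is the reference. These
sizes make every oracle comparison exact while keeping a full run in the
order of a minute.

## Known limitations

* The phantom's handful of tissue recipes yields far fewer observed
  mixture classes (typically < 10) than a pooled in vivo dataset with
  millions of spectra (hundreds of classes); quantities that depend on
  that richness — fingerprint entropies, class counts, specific
  correlation values — are scene properties, not reproductions of any
  published dataset's numbers.
* The fluence model is 1D and homogeneous per wavelength; lateral fluence
  structure and tissue-specific attenuation are not modelled.
* VCA endmember quality degrades on data without pure pixels, as expected
  from its simplex assumption; on the regularized-NMF side, nothing
  guarantees a global optimum — only monotone descent to a local one.
* No significance testing is attached to correlation differences; the
  matrices are descriptive.
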