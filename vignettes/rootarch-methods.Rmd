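---
title: "Methods: root system architecture phenotyping and multi-modal clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root system architecture phenotyping and multi-modal clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`rootarch` implements a complete seedling root-system-architecture (RSA)
study pipeline of the kind run on blue-germination-paper imaging
platforms: image segmentation and skeletonization, extraction of the
standard RSA trait set, mixed-model genetics (BLUPs, variance components,
broad-sense heritability), ideotype rank-sum scoring, and three parallel
clusterings of a diversity panel — genotype-based (SNPs), phenotype-based
(trait BLUPs) and shape-based (elliptic Fourier outlines compressed by a
convolutional autoencoder). Because raw study images and genotype calls
are rarely redistributable, the package ships first-class synthetic
generators with known ground truth for every input modality; all tests
and the acceptance script run offline on those generators.

## The phenotype model

Replicated trait observations follow the additive random-effects model

$$y_{ik} = \mu + g_i + b_k + e_{ik},$$

with genotype effects $g_i \sim N(0,\sigma_g^2)$, block (growth-chamber)
effects $b_k \sim N(0,\sigma_b^2)$ and residuals
$e_{ik} \sim N(0,\sigma_e^2)$, all random. `fit_mixed_model()` fits this
by REML through `lme4`; in a balanced design the genotype BLUPs reduce to
the classical shrinkage form
$\hat g_i = \frac{\sigma_g^2}{\sigma_g^2+\sigma_e^2/r}(\bar y_i - \bar y)$,
which the tests verify against the closed form. Entry-mean broad-sense
heritability is

$$H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / r},$$

with $r$ the number of replications (14 by default). The block term is
included only when the data actually contain two or more blocks;
otherwise $\sigma_b^2$ is fixed at zero. Derivative-based convergence
checks in `lme4` are disabled: the fits here are variance-component
extractions on balanced data where those checks produce false alarms at
scale.

Outliers are removed beforehand with Tukey's boxplot rule
(fences at $Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$).
Fences are computed per trait and day across all genotypes jointly:
per-genotype strata of ~14 replicates make quartiles too unstable to
fence on. Genotype-effect significance in the descriptive table uses a
likelihood-ratio test of $\sigma_g^2 = 0$ with the p-value halved for the
boundary null.

## Imaging operators

Segmentation converts RGB to HSV (hue in degrees) and labels pixels with
hue above 175° as blue background, everything else as root. Reds near 0°
remain foreground; the rule is a single threshold with no wrap-around
handling. When the putative foreground exceeds half the frame, the
background is assumed oversaturated and the pipeline falls back to
thresholding the L channel of Lab space with Otsu's method — the manual
threshold such cases would otherwise need is replaced by an automatic
surrogate so batch runs stay unattended. Components under 20 px are
dropped as paper-texture specks and the largest connected component is
retained.

Skeletonization is Zhang–Suen thinning (1-px wide, topology-preserving,
idempotent). Skeleton length uses the standard chain metric: 1 per
orthogonal step, $\sqrt 2$ per diagonal step, with redundant diagonals
(ones short-cutting an existing orthogonal corner) excluded from the
pixel graph so lengths are not double-counted. This chain metric
over-measures oblique digitized segments by up to ~8% (the classical
staircase bias); on near-vertical taproot geometry the bias stays within
a few percent, which is the regime the recovery tests certify.

## Trait extraction

The primary root is traced as the maximal-depth geodesic from the
top-most skeleton node (Dijkstra on the weighted pixel graph), matching
taproot morphology; lateral branches are skeleton edges departing that
path. Depth bands ("upper third" vs "lower two-thirds") are defined on
the root system's own depth extent, not the image frame, so band traits
do not depend on cropping. Lateral root angle is measured between a
lateral's initial direction (20 px along its geodesic) and the vertical
axis: 0° is steep, 90° is horizontal, and the median over laterals is
reported. Convex area expands hull pixels to their corners so that filled
convex shapes have solidity exactly 1; local radii come from the Euclidean
distance transform with a half-pixel correction. Undefined quantities
(lateral statistics with no laterals, length-distribution with an empty
lower band) propagate as missing values, never as zeros.

Growth rate differences total root length between consecutive scheduled
imaging days (6, 9, 12); day 6 is baselined against zero length at
germination, and a missing earlier day leaves the rate missing.

## Ideotype (iRoot) scoring

Each of the five ideotype categories — nutrient foraging, drought
tolerant, umbrella, beard, maximum — is a rank sum over a fixed trait set
with per-trait favorability directions (see `iroot_categories()`).
Genotypes are ranked per trait (1 = best in the favourable direction,
ties averaged, missing values last), constituent ranks are summed, and
genotypes are re-ranked by ascending sum. Scoring uses BLUPs at 9 days
after germination: earlier, slow genotypes lack laterals; later, fast
ones outgrow the pouch. Two direction choices were genuinely open because
prose and the direction markers can be read differently: beard treats
length distribution as lower-favorable, and drought tolerance treats
inverse solidity as lower-favorable; both follow the tabulated markers
and both are overridable by editing the category list. Average ranks for
ties preserve the rank-sum mean, which keeps the mean category rank at
$(n+1)/2$ exactly.

## Genotype-based clusters

SNP preprocessing removes monomorphic markers and markers with minor
allele frequency below 0.05 (frequency computed from non-missing calls;
the boundary value is retained). Genetic distance is allele sharing
between individuals: per marker, shared-allele fraction
$1 - |d_i - d_j|/2$ on the 0/1/2 dosage scale, averaged over markers, and
distance $= 1 -$ similarity. This individual-level measure is the natural
reading for accession panels; it is symmetric with zero diagonal but not
guaranteed metric, which is documented rather than asserted. Ward
minimum-variance clustering (on the distance, `ward.D2`) cut at $k = 8$
gives the genotype-based clusters, labelled A–H in dendrogram order, with
newick export for interoperability.

The number of clusters is selected by the iterative k-means procedure:
k-means on the top 10 principal-component scores for $k = 1..k_{max}$,
scored by a spherical-Gaussian BIC
($n d \log(\mathrm{RSS}/nd) + k(d{+}1)\log n$), returning the inflection
point of the curve (maximum second central difference). A curve where no
$k$ halves the within-cluster variance is flagged flat and weak structure
returns $k = 1$. PCA mean-imputes missing dosages per marker and centres
without unit-variance scaling (the default of the standard PCA routine
class this mirrors).

Differentiation between clusters uses the Hudson estimator

$$F_{ST} = \frac{(\tilde p_1-\tilde p_2)^2 - \frac{\tilde p_1(1-\tilde p_1)}{n_1-1} - \frac{\tilde p_2(1-\tilde p_2)}{n_2-1}}{\tilde p_1(1-\tilde p_2)+\tilde p_2(1-\tilde p_1)},$$

with $n_i$ the number of sampled alleles (twice the diploid count), which
makes the numerator unbiased for binomially sampled dosages. The headline
mean across markers is the ratio of averages (mean numerator over mean
denominator), robust to near-zero denominators; the average of per-marker
ratios is reported alongside.

## Shape-based clusters

Outlines are described by Kuhl–Giardina elliptic Fourier coefficients of
the closed contour parameterized by cumulative chord length, computed
with the exact piecewise-linear formulas (the tests check them against
dense numerical quadrature). Replicate masks are first dilated with a
50 × 50 square kernel so the outline captures the root's overall extent,
then per-replicate descriptors are averaged coefficient-wise and the mean
shape is reconstructed from the first 5 harmonics — truncation is the
smoothing; no separate filter is applied. Reconstructions are aligned
with the top point at vertical coordinate 0 and horizontally centred, and
no rotation normalization is applied: up/down anatomy is meaningful for
roots. One caveat worth stating: harmonic content depends on the
parameterization, so a geometric ellipse traced at uniform *angle* is one
harmonic, while the same ellipse parameterized by arc length carries
small odd higher harmonics; round-trip identities are exact only for
uniform-speed contours and hold approximately (to a few percent)
otherwise.

Mean shapes are rasterized into filled 64 × 64 silhouettes (height
fitted, width padded symmetrically) and compressed to 8 latent dimensions
by a small convolutional autoencoder: three stride-2 3×3 convolution
blocks (8/16/32 filters, ReLU) to a dense bottleneck, mirrored by
nearest-neighbour upsampling blocks, sigmoid output, binary cross-entropy
loss, full-batch Adam. The network is implemented directly on matrix
primitives inside the package, deterministic given its seed, and its
analytic gradients are tested against finite differences. k-means with 25
restarts on the latent vectors yields the shape-based clusters, ordered
A–H by decreasing mean z-scored trait value of members (ties broken by
cluster size).

## Synthetic generators and what they do (not) emulate

All generators are pure functions of (config, seed); substreams are
derived by hashing the operation name so stages never share randomness.

* **Phenotypes** follow the additive model above exactly. The 13-trait
  panel uses day-9 means, SDs and heritabilities typical of a large
  soybean seedling panel, with variance components recovered from
  (SD, $H^2$, $r$). Genotype effects are drawn independently per trait, so
  the generator does not emulate the strong inter-trait correlations of
  real RSA data — tests of correlation structure use it as a null.
* **Root images** draw the taproot as a downward heading random walk
  (mean-reverting, per-step heading noise 0.03 rad by default — a
  realistic near-vertical taproot), laterals as a Poisson process along
  it, and rasterize onto a blue background (hue ≈ 220°) with a
  root-coloured foreground (hue ≈ 42°) so the segmentation rule is
  exercised on both sides. Recorded ground truth (arc lengths, lateral
  counts and angles) is analytic. 2-D geometry only; no occlusion by
  substrate and no root-on-root crossing model, so recovery tests use
  sparse branching.
* **SNPs** follow the Balding–Nichols model: ancestral frequencies
  uniform in the configured window, subpopulation frequencies
  Beta-distributed around them with differentiation $F$, dosages
  binomial. Real allele-frequency spectra are not emulated beyond this.
* **Shape families** ("umbrella", "beard", "drought") are parametric
  width-profiles with smooth low-order jitter, guaranteed simple; they
  provide separable, known-membership inputs for the shape stage.

Passing tests therefore certify the estimators and operators under their
stated models — not robustness to illumination drift, root overlap,
genotyping error or other failure modes of real data.

## Numerical choices and problem sizes

Tolerances: exact formula checks at 1e-6 or tighter; simulation-based
recoveries at the scale their sampling noise warrants (heritability
±0.03 over 20 panels of 292 × 14; Hudson FST ±0.02 at 5,000 markers;
cluster recovery by adjusted Rand index). The test suite and acceptance
script size their simulations to finish in minutes on one CPU: SNP
clustering runs at a few hundred markers and ~300 genotypes (recovery at
$F = 0.3$ is already exact there), and the shape stage trains on 36
silhouettes for 15 epochs, which separates the three families completely;
larger settings change run time, not conclusions. Degenerate inputs error
early with named messages (empty masks, all-missing ranks, $F = 1$,
zero-length contours), and boundary variance estimates of zero are
accepted rather than treated as failures.

## Known limitations

Chain-metric length bias on oblique segments (above); no illumination
correction; no LD pruning or imputation beyond per-marker means; the
likelihood-ratio test for $\sigma_g^2$ uses the simple halved chi-square
approximation; cluster labels beyond the stated ordering rules carry no
meaning. The pipeline intentionally makes no claim about field
performance of any ideotype — it ranks seedling traits in controlled
conditions.
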