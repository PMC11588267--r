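---
title: "Hybrid-zone clines and bioacoustic reinforcement tests: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid-zone clines and bioacoustic reinforcement tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinecall)
```

## The problem

When two incipient species meet along a geographic transect, two families of
questions arise. Genetically: where is the transition, how wide is it, and do
some loci resist introgression (barrier loci, the footprint of hybrid
incompatibilities)? Behaviourally: do the species' mate-recognition signals —
here, anuran advertisement calls — diverge more inside the contact zone than
outside it, as reinforcement predicts? And if so, is that divergence achieved
by shifting call means (reproductive character displacement) or by pruning
within-species variation without moving the means? `clinecall` implements
both analyses plus the synthetic-data generators needed to validate them.

## Genetic models

### Diagnostic SNPs

Species-diagnostic SNPs are loci fixed for alternative alleles in two
unadmixed reference panels. Selection is a between-panel frequency difference
of at least `min_difference` (default 1). Because sampled frequencies are
ratios of integer allele counts, the comparison is done on cross-multiplied
integer counts (`|k_A n_B − k_B n_A| ≥ d·n_A n_B`), so "difference of 1"
never fails by float round-off. Loci with no data in either panel are
excluded rather than treated as maximally different. Presence filtering
mirrors RAD-caller semantics: a group passes at a locus when its within-group
call rate reaches `r`; the locus is kept when at least `p` groups pass. The
two stated rules ("called in all localities" and "in at least half the
samples of each locality") coincide under this reading with `p` equal to the
number of groups, and the filter is idempotent.

### Ancestry

The K = 2 ancestry model is the standard binomial admixture likelihood:
`g_il ~ Binomial(2, Q_i f_Al + (1 − Q_i) f_Bl)`, maximised by EM with the
origin of each allele copy as the latent variable. We use EM rather than an
MCMC clustering program deliberately: it is deterministic given a seed,
desk-scale, and fits the same genotype-frequency model (without linkage or
admixture priors), which is what the downstream cline analysis needs. Both
the `Q` and `f` updates maximise concave per-parameter objectives, so the
log-likelihood is non-decreasing even with cluster frequencies clamped to
`[1e−6, 1 − 1e−6]` (the clamp keeps fixed loci from sending the likelihood to
−∞; the box-constrained maximiser of a concave coordinate objective is the
truncated unconstrained one, preserving monotonicity). Cluster labels are
arbitrary in the likelihood; they are resolved by reference panels when
present, by user anchors otherwise, and as a last resort by forcing the first
individual toward cluster A. An MCMC program with priors would give slightly
different `Q` on the same data; the two agree in the well-differentiated,
many-locus regime this package targets.

### Clines

All cline fitting uses the two-parameter sigmoid
`p(x) = (1 + tanh(2(x − c)/w))/2`, with `pmin = 0`, `pmax = 1` and no
exponential tails — the minimal model one selects when localities are few and
the comparison of interest is between datasets (mitochondrial, mean-ancestry,
per-SNP) rather than between cline shapes. The likelihood is binomial over
per-locality derived-allele counts, with predicted frequencies clamped to
`[1e−6, 1 − 1e−6]`. Fractional "effective" counts arise for mean-ancestry
pseudo-data — per-locality mean Q is treated as a binomial proportion with
effective allele count 2 × individuals, an explicit modelling assumption —
and are handled through the gamma-function form of the binomial coefficient.

Fitting is multi-start (7 × 7 coarse grid over center and log-width, three
best starts refined by L-BFGS-B on `(c, log w)`), bounded by default to
centers within the data range extended by 25% and widths in
`[0.05, 3 × range]` km. Step-like data legitimately drive `w` to the lower
bound. Confidence regions are 2-log-likelihood-unit profile intervals
(asymptotically ~95% per parameter), chosen over MCMC credible intervals for
determinism and speed; they are constructed by outward walk plus bisection on
the profile likelihood, so they always contain the point estimate.

Two numerical conventions matter. First, allele polarity: each locus is
re-oriented so the modelled frequency increases with distance, implemented by
reflecting the distance axis and mapping the fitted center back. A reversed
transect therefore reduces to the *identical* optimisation problem, making
the symmetry `ĉ → L − ĉ` exact up to the ≤1-ulp round-off of the caller's
reversed coordinates. Second, barrier flagging: a locus is flagged when
`ŵ < 2` km by default — "essentially null width" on a 170 km transect with
~9 km locality spacing. At realistic per-locality allele counts (tens of
alleles) a true 20 km cline essentially never fits below 2 km, while a true
0.5 km cline essentially always does; at very small counts (6 alleles per
locality) the distinction genuinely degrades, which is a property of the
data, not the estimator.

With a single fitted locus the width SD is reported as 0 with a warning
rather than NA, so downstream tabulation never silently drops the column.

## Bioacoustic models

Note duration is the only call parameter with a credible temperature
dependence, so ND is replaced by its OLS residuals on recording temperature
(the regression direction is ND-on-temperature: adjusting the trait by the
covariate, which is the biologically sensible reading). DF, RT and PR pass
through unchanged. The PCA is computed on the correlation matrix because the
four variables carry incommensurate units (Hz, s, s, s⁻¹); component signs
are fixed so each loading vector's dominant entry is positive, making score
orientations reproducible.

The three statistics, each weighted by the variance explained `v_k`:

* **Hull overlap**: mean of the two directed fractions
  `(I/A_a + I/A_b)/2` of the species' convex hulls, computed exactly by
  Sutherland–Hodgman clipping, on the PC1/PC2 and PC3/PC4 planes, combined
  with weights `(v1+v2)` and `(v3+v4)`. The mean-directed definition is used
  because the referenced overlap routine reports directed fractions while a
  single number is published; a Jaccard variant is available behind a flag.
* **Centroid distance**: `√Σ_k (v_k (c̄_Ak − c̄_Bk))²`, with coordinates (not
  squared weights) scaled by `v_k` — one of two defensible readings of
  "weighted them by their relative contribution"; the choice only rescales Δ
  and cannot change permutation P-values' meaning.
* **Weighted SD**: `Σ_k v_k sd_k` per group (sum, not mean, over components —
  again a constant factor that Δ signs and P-values are insensitive to).

The five Δ statistics are parapatric − allopatric (so a reinforcement-style
loss of overlap is negative). Significance comes from a permutation null
that reshuffles the full four-level group label across all individuals,
preserving group sizes, with the PCA scores held fixed (the PCA is
label-blind, so refitting it per permutation would change nothing but cost).
`P` is the plain exceedance proportion `#{|Δ_perm| ≥ |Δ_obs|}/B` — no
add-one correction, so 22 exceedances in 1,000 permutations give exactly
0.022. A second pass first down-samples every group larger than the cutoff
(default 10) to that size; with the default group sizes 27/22/9/13 this
coincides with down-sampling "the two largest groups".

### What the permutation test does and does not control

The reshuffled-label null is exact under full exchangeability: if all 71
individuals are draws from one distribution, each test rejects at the nominal
rate (verified: all five rejection rates fall in the 2–9% binomial band over
300 replicates at α = 0.05). When a species effect is present but no context
effect — the biologically interesting "null" — the four-level reshuffle tests
a *stronger* hypothesis than "context has no effect", and the hull-overlap
statistic acquires a group-size bias: convex hulls of the smaller parapatric
groups (9 and 13) cover systematically less of their trait distributions than
the allopatric hulls (27 and 22), giving E[Δ_overlap] ≈ −0.13 under our
generator defaults even with identical context distributions. The centroid
and SD statistics are nearly unbiased in the same world. This is precisely
the asymmetry the down-sampling variant exists to blunt, and it is why the
calibration experiment is run under the exchangeable null while scenario
power is assessed against those calibrated rates. Users comparing contexts
with very unequal group sizes should weight the down-sampled P-values
accordingly.

## The synthetic world

The generators state, once, the conditions the analysis assumes:

* **Transect**: 19 localities evenly spaced over 170 km, 3 samples per
  locality (57 individuals), genome-average cline center 85 km. Per-locus
  widths are log-normal with mean 20.6 km and SD 9.5 km (strictly positive,
  matching the reported dispersion of per-SNP widths); per-locus centers are
  normal around the average with SD 5 km (so ±2 SD spans the ±10 km
  center scatter seen in multi-locus panels). Barrier loci get width 0.5 km.
  The mitochondrial cline is narrower (9.8 km) — mitochondria introgress
  less in this system. Genotypes are independent binomial draws from the
  local cline frequency; there is no linkage, drift or isolation-by-distance
  beyond the cline itself, so a green recovery test establishes estimator
  correctness, not robustness to linked selection.
* **Panels**: 20 + 19 individuals; fixed loci are fixed opposite, shared loci
  draw a common frequency uniform on [0.05, 0.95] in both panels.
* **Calls**: group sizes 27/22/9/13. Baseline species-A trait values are free
  parameters (no per-group means are published): DF 1250 ± 100 Hz,
  ND 0.13 ± 0.018 s, RT 0.05 ± 0.012 s, PR 95 ± 10 s⁻¹ — realistic midwife-
  toad advertisement-call values — with species B offset by ~1 SD upward in
  DF and PR (the two variables that separate the species on PC1) and slightly
  downward in ND and RT. Trait covariance is diagonal by default (no trait
  correlations are published); off-diagonal structure can be supplied.
  Temperature is uniform on 12–22 °C (night-time breeding season) and affects
  ND only, with slope −0.0052 s/°C calibrated so the temperature–ND Pearson
  correlation is ≈ −0.64 at n = 71. Under displacement, parapatric groups
  shift by ±half the species offset; under variance reduction, parapatric SDs
  scale by ρ (default 0.6). Physical constraints (positive DF/ND/PR,
  0 ≤ RT ≤ ND) are enforced by resampling the rare violating draw, a mild
  truncation of the stated multivariate normal.

## Known limitations

* The EM ancestry model ignores linkage and inbreeding; `Q` values from
  prior-based MCMC clustering will differ slightly.
* Profile intervals rely on the asymptotic 2-unit rule; at 19 localities
  their coverage is good (≥85% observed) but not exact.
* Transect distances are great-circle distances from a chosen origin, not
  path distances along a valley; supplied distances are always honoured.
* The hull-overlap statistic is group-size sensitive (see above); the
  package reports both plain and down-sampled P-values for this reason.
* The generators simulate genotypes and trait values, not reads or audio.
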