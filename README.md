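# clinecall

Analysis toolkit for narrow hybrid zones between incipient species, combining
population-genomic cline analysis with a bioacoustic test battery for
reinforcement. It targets the common study design in which two taxa meet along
a geographic transect: reference panels of unadmixed individuals define
species-diagnostic SNPs, a hybrid-zone transect is genotyped at those SNPs,
per-individual ancestry and per-locus allele-frequency clines locate and
measure the transition, and advertisement-call recordings from allopatric and
parapatric populations test whether the species' acoustic repertoires diverge
inside the contact zone — the behavioural signature of reinforcement.

## What it computes

**Diagnostic SNPs.** From two reference panels, loci passing per-group
presence/call-rate filters (the `p`/`r` rules of standard RAD SNP callers,
plus one-SNP-per-RAD-locus thinning) whose between-panel allele-frequency
difference is 1 (fixed differences), compared exactly on integer allele
counts.

**Ancestry (Q).** A K = 2 admixture model fitted by EM on the binomial
likelihood

    g_il ~ Binomial(2, Q_i f_Al + (1 - Q_i) f_Bl)

where `Q_i` is individual i's genome fraction from cluster A and `f_A`, `f_B`
are cluster allele frequencies. Deterministic given a seed, with a provably
non-decreasing log-likelihood.

**Geographic clines.** The two-parameter sigmoid

    p(x) = (1 + tanh(2 (x - c) / w)) / 2

with center `c` (km) and width `w` (km, inverse of the maximum slope), fitted
by maximum binomial likelihood to per-locality allele counts; one code path
serves mitochondrial haplotype frequencies, per-locality mean ancestry and
per-SNP frequencies. Confidence regions are 2-log-likelihood-unit profile
intervals. Multi-locus summaries report the mean/median/SD of `w`, per-locus
center deviations Δc, and flag candidate **barrier loci** (essentially null
width, i.e. loci resisting introgression) as `w` below a threshold (default
2 km).

**Bioacoustics.** Four call parameters per individual — dominant frequency DF
(Hz), note duration ND (s), rising time RT (s), pulse rate PR (s⁻¹) — with ND
replaced by its OLS residuals on recording temperature, then a PCA on the
correlation matrix. Three statistics compare the two species between
allopatric and parapatric contexts, each weighted by the variance explained
per component: convex-hull overlap on the PC1/PC2 and PC3/PC4 planes, centroid
distance, and per-group weighted standard deviations. Their Δ values
(parapatric − allopatric) are tested against a permutation null that
reshuffles the four-level group label (`P = #{|Δ_perm| ≥ |Δ_obs|}/B`), with a
variant that first down-samples large groups to equal size.

**Synthetic data.** Seeded generators state this whole world explicitly —
transect genotypes following per-locus clines with barrier loci, fixed
reference panels, a narrower mitochondrial cline, and call datasets under
three scenarios (null, character displacement, variance reduction) — so the
entire pipeline is exercised end to end without field data.

## Worked example

```r
library(clinecall)

cfg <- run_config(seed = 5,
                  transect = transect_config(n_loci = 30, n_barrier_loci = 2,
                                             samples_per_locality = 10,
                                             missing_rate = 0.05),
                  panels = list(n_a = 10, n_b = 10, n_shared = 40,
                                missing_rate = 0.05),
                  calls = call_scenario("variance_reduction"),
                  B = 1000)
res <- run_pipeline(cfg)

res$fits$ancestry_q
#> <cline_fit:ancestry_q> center 85.02 km (81.77-88.26), width 21.70 km (15.66-30.01), logLik -7.44

res$cline_summary
#> <multilocus_summary> 30 loci | width 18.3 +/- 10.8 km (median 16.3) | mean center 85.8 km | 3 barrier loci (< 2 km)

res$acoustics
#> <delta_test> B = 1000 permutations
#>          statistic allopatric parapatric  delta     P P_downsampled
#>            overlap      0.487      0.255 -0.232 0.132         0.287
#>  centroid_distance      0.632      0.697  0.065 0.622         0.861
#>               sd_A      0.983      0.713 -0.270 0.076         0.020
#>               sd_B      1.014      0.696 -0.318 0.021         0.179
#>       sd_cumulated      1.996      1.409 -0.588 0.006         0.009
```

Reading the output: the mean-ancestry cline is centered at 85.0 km with a
21.7 km width (the simulation's stated truth is c = 85 km, mean w = 20.6 km;
per-locus widths scatter log-normally and its profile interval covers the
truth), and 3 loci are flagged as barrier candidates — the 2 simulated with
near-zero width plus one narrow false positive at this sampling depth. Under
the variance-reduction scenario the cumulated standard-deviation Δ is
negative and significant (P = 0.006, down-sampled P = 0.009) while the
centroid distance is not — the reinforcement-without-displacement pattern
the scenario plants. All CSV outputs and a JSON manifest land in
`cfg$out_dir`.

A command-line wrapper with subcommands (`simulate`, `diagloci`, `ancestry`,
`clines`, `acoustics`, `all`) is installed at
`system.file("scripts", "clinecall.R", package = "clinecall")`.

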