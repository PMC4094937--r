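---
title: "Models and methods behind the twinmeth workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the twinmeth workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

twinmeth analyses monozygotic (MZ) twin DNA-methylation studies measured on
Illumina 450k-style arrays. MZ co-twins share their DNA sequence and, in
childhood, much of their environment, so the correlation of a CpG's
methylation level between co-twins bounds the *familial* contribution
(genetics plus shared environment) to inter-individual variation at that
site; what co-twins do not share is individual environment, stochastic
drift, and measurement error. The package covers the full path from raw
per-probe intensities to context-stratified twin correlations, plus a
generator that simulates the whole study with known truth so every stage is
testable by parameter recovery. This vignette records the models, the
tunable parameters, and the design decisions taken where the methods
literature leaves choices open.

## The generative model

Each CpG `j` in stratum `s` carries a baseline methylation level on the
log-odds scale, drawn from a three-class mixture (hypomethylated,
intermediate, hypermethylated — centred at beta 0.10 / 0.50 / 0.90, i.e.
logits −2.20 / 0 / +2.20, with between-CpG SDs 0.6 / 0.45 / 0.6). For twin
pair `i`, a familial effect `g_ij ~ N(0, sigma_f^2)` is shared by both
co-twins; each twin `t` adds an individual effect
`e_ijt ~ N(0, sigma_e^2)`. The true methylation fraction is the inverse
logit of the sum, so it always lies in (0, 1), and the latent co-twin
Pearson correlation is `rho = sigma_f^2 / (sigma_f^2 + sigma_e^2)`.

Because the data are MZ-only, genetic and shared-environment variance are
not separable; the generator therefore models a single pair-level familial
component. Negative familial correlations have no variance-components
representation and are rejected. `logit_noise_sd` (default 0.35) sets
`sigma_e`; when it is 0 co-twins are identical by construction and
`sigma_f` is fixed at 0.5 so between-pair variation remains.

### Calibrating the rank correlation at a finite number of pairs

Strata are parameterized by a *target Spearman* correlation, matching how
twin similarity is summarized per CpG (Spearman across pairs). For
bivariate-normal latents the population identity is
`rho_S = (6 / pi) asin(rho / 2)`. However, the expected *sample* Spearman
at `n` pairs is

```
E(r_S) = 6 / (pi (n + 1)) * ( asin(rho) + (n - 2) asin(rho / 2) )
```

(the classical finite-sample expectation for bivariate normal samples),
which at `n = 10` pairs sits ~0.05 below the asymptotic value for targets
near 0.66. A generator calibrated with the asymptotic identity would
therefore systematically under-deliver at study scale. By default
(`finite_pair_correction = TRUE`) the generator inverts the finite-`n`
expectation numerically for the configured number of pairs, so the mean
observed per-CpG Spearman matches the target at the study's own `n`; the
inversion converges to `rho = 2 sin(pi rho_S / 6)` as pairs grow, and the
asymptotic form remains available. `latent_rho_for_spearman()` exposes both.

Rank correlations are invariant to monotone transforms, so the same
targets hold for the latent logits, the true beta values, and any M-value
transform — a property the tests assert exactly.

### The intensity layer

The array literature describes processed intensities, not a generative
model, so the technical layer is the package's own: total probe signal is
log-normal (median 6000, log-SD 0.35), split into methylated and
unmethylated channels by the true beta, rounded to integer bead
intensities, with additive background noise drawn from the
negative-control distribution (Normal(150, 40) truncated at zero). Type II
probes are compressed towards 0.5 on the logit scale (factor 0.8) to
emulate the single-bead chemistry's reduced dynamic range — the very
artefact BMIQ exists to undo; the compression is monotone, so rank-based
statistics are unaffected by it. A small fraction of probe-sample cells
fail outright (background-only signal, default 0.2%) or are absent (zero
intensity, 0.1%); both are recorded in the simulation truth. Bead counts
are 1 + Poisson(mean − 1). Control DNA is one extra simulated subject
whose true values are re-measured with fresh technical noise in each of
the (default four) replicates.

Rounding to integer intensities introduces bounded noise and ties;
tolerance budgets in the tests account for both.

### Genomic layout and invertibility

Each stratum occupies its own cassette on one chromosome: a CpG island
(enlarged when the stratum's CpGs sit inside it), shore and shelf flanks,
and a gene placed so that every CpG falls inside the requested gene-centric
window on either strand, with 30 kb of separation between cassettes so no
window leaks across strata. This makes annotation invert the generator
exactly — the round trip is a hard test, not a tendency. Layouts that
cannot be realized (e.g. more shore CpGs than a 2 × 2 kb flank holds) are
rejected as non-invertible rather than silently squeezed.

## Quality control

*Detection p-values.* The background of each channel is summarized per
sample by the mean and SD of the negative-control intensities; a probe's
detection p-value is the upper tail of its total signal under
`Normal(mu_M + mu_U, sqrt(sd_M^2 + sd_U^2))`. This is the simplest model
consistent with assessing background from negative controls; at least 20
control probes per sample are required.

*Probe filters* run in a fixed, documented order: manifest-flagged
ambiguously-mapped probes (defined as a 47-base alignment overlap to a
second locus; the flag is an input) and SNP-at-CpG probes are dropped
globally; then, per sample, zero-intensity cells, cells with detection
p > 0.01, and cells with fewer than 3 beads are set missing; then probes
with cross-sample success below 0.95 are dropped; finally per-sample
success rates are computed over the survivors. The order matters because it
fixes the success-rate denominators, so it is part of the contract and
oracle-tested. Missing cells are excluded pairwise from every downstream
SD and correlation. Bisulfite-conversion controls are reported as not
assessed: the synthetic data carry no conversion chemistry.

*Sample clustering.* Samples are clustered by complete linkage on
`d = sqrt(2 (1 − r))`, where `r` is the pairwise sample correlation over
autosomal, SNP-free probes with beta-SD > 0.10. The phrase "Euclidean
distance calculated from the pairwise correlations" admits a second
reading — Euclidean distance between rows of the correlation matrix — which
is available via `distance = "corvec"`; the transform reading is the
default because `sqrt(2(1−r))` *is* the Euclidean distance between
standardized profiles. The QC flag asks whether each sample's sister
branch at its first merge consists entirely of its own pair (or fellow
control replicates).

## Normalization

Channels are quantile-normalized separately, within probe-chemistry
stratum, across samples (delegated to limma); mixing the two bead
chemistries or the two colour channels would distort both. After
normalization each sample's sorted vector equals the cross-sample mean of
sorted vectors — bit-exactly for complete, tie-free data, which is how the
contract is tested. Integer intensities carry ties, and filtered cells are
missing; there tie-averaging and quantile interpolation leave a sub-0.5%
spread between samples' sorted vectors, which a separate tolerance test
characterizes. Ranks within a sample are never inverted.

Beta is `M / (M + U + 100)`: the 100 offset keeps near-zero-signal probes
near beta 0 instead of undefined, and beta < 1 always. M-values default to
the intensity-ratio form `log2((M + 1) / (U + 1))`; the logit2-of-beta
form is available (`logit2 = TRUE`) since the two differ only in offset
handling and rank-based results are insensitive to the choice.

*BMIQ.* Per sample, three-state beta mixtures are fitted to Type I and
Type II betas separately by EM with moment-matching updates (initialized
by thresholding at 0.25 / 0.75, log-likelihood tolerance 1e-6). The
moment-matching updates converge more slowly than gradient EM near the
optimum, so the iteration cap defaults to 300; all controls are arguments.
Type II states are made contiguous via the responsibility crossover
cutpoints; unmethylated- and methylated-state values are quantile-mapped
onto the corresponding Type I beta fits, and the hemimethylated segment is
rescaled linearly between the two mapped boundaries, which guarantees
global monotonicity within a sample's Type II set. Any degeneracy (empty
state, inverted boundaries, non-convergence) triggers a rank-based
quantile mapping of Type II onto Type I instead, recorded per sample in
the `bmiq_fallback` attribute. Type I values are never altered and output
stays in [0, 1]. Because BMIQ is a per-sample map, it harmonizes
*within-sample* distributions (as needed before classifying CpGs by mean
beta); cross-sample correlation contracts are stated on the
quantile-normalized betas.

## Annotation

Coordinates: manifest positions are 1-based (the C of the CpG); BED files
are 0-based half-open; conversions are centralized and tested. Gene-centric
windows are measured along each gene's strand from the nearest TSS:
proximal promoter [−1.5 kb, +500 bp], distal promoter [−10 kb, −1.5 kb),
gene body (+500 bp, 3' end], downstream (3' end, +5 kb], else intergenic.
Windows are half-open at the boundary nearer the TSS, so every base
belongs to exactly one window per gene. When a CpG satisfies several
genes' windows, precedence is proximal > distal > body > downstream, then
smallest absolute TSS distance, then lexicographic gene id — invented
tie-breaks, frozen and mirrored in the brute-force test oracle. CGI
classes use distance to the nearest merged island: 0 inside (CGI), up to
2 kb (shore), 2–4 kb (shelf), else non-CGI; nearest-island distance makes
CGI > shore > shelf precedence automatic where flanks overlap. DHS, TFBS
and imprinted-DMR membership are point-in-interval overlaps; the imprinted
overlap carries the DMR's gene id.

## Twin statistics

Per CpG, mean and sample SD (n − 1) of beta are computed across twin
subjects only — control replicates are never subjects. Classes follow the
mean: hypo < 0.3, intermediate [0.3, 0.7), hyper ≥ 0.7 (0.3 is
intermediate; 0.7 is hyper); "most variable" means SD ≥ 0.05, boundary
inclusive. CpGs with fewer than 3 non-missing subjects get missing
statistics.

Two Spearman schemes: (1) per pair, across CpGs — the overall profile
similarity of the two co-twins, computed for all CpGs and for the
most-variable subset; and (2) per CpG, across pairs — the similarity of
that CpG's level in MZ twins, requiring at least 3 complete pairs. Ties
take average ranks (Pearson on mid-ranks); at 10 pairs tie policy matters,
so it is frozen and checked against an independent mid-rank oracle. The
unrelated baseline evaluates every subject pairing that is neither a self
pairing nor a co-twin pairing.

Twin-1/twin-2 labels come from the sample sheet. Exchanging the two whole
twin vectors leaves every correlation unchanged (exact symmetry, tested).
Relabelling members within a *subset* of pairs is not an exact symmetry of
the sample Spearman — no correlation statistic with arbitrary within-pair
ordering is — but under the generator's exchangeable construction the
distribution of rho is label-invariant, so the choice does not matter in
expectation.

Summaries follow the standard stratified layout: all CpGs, each
gene-centric class, each island class, each methylation class, and the
island-by-methylation cross, each with count, percentage and
mean/median/min/max rho; the "all" row's mean is the count-weighted mean
of each partition, which the tests assert. The imprinted subset keeps
DMR CpGs at intermediate mean methylation — the level expected when one
parental allele is methylated — and summarizes their rho.

*Cell composition.* The original reference-CpG selection for
contamination checking is not reconstructible, so the package ships a
clearly-labelled reconstruction: given reference CpGs with known mean beta
in buccal and blood tissue, each sample's buccal weight `w` minimizes the
squared deviation of observed beta from `w·buccal + (1−w)·blood`
(closed form, clipped to [0, 1]); samples below `w_min = 0.8` are
flagged, and `sensitivity_excluding_pairs()` re-runs the stratified
summaries without the flagged pairs. At least 10 reference CpGs are
required.

No multiple-testing machinery is included: the statistics are descriptive
correlations, not hypothesis tests.

## Default study conditions and problem sizes

The default design is 10 MZ pairs plus 4 control replicates across nine
strata (~5100 CpGs) whose familial targets follow the island gradient
0.66 (CGI), 0.54 (shore), 0.50 (shelf), 0.49 (non-CGI), with an
intermediate-methylation imprinted cassette at 0.47 — plausible magnitudes
for buccal tissue, used as generator defaults, not as claims of
reproducing any measured dataset. Methylation-class mixtures follow the
usual picture: promoter islands mostly hypomethylated, shores broad,
shelves and open sea mostly hypermethylated.

The recovery experiment uses four island-class strata of 3500 CpGs each
(sized so that over 2000 per stratum pass the SD filter) at 10 pairs; the
per-stratum mean cross-pair Spearman lands within ±0.04 of target with
about ±0.01 Monte-Carlo error, and the island ordering is recovered. The
test suite runs the full pipeline twice to assert bit-identical artifacts
under a fixed seed.

## What passing tests do and do not show

The generator emulates bimodal beta distributions, context-dependent mean
profiles, pair-level familial correlation varying by genomic context,
intensity-level technical noise, sporadic probe failures, and replicated
control DNA. It does not emulate: dizygotic twins (familial variance is
deliberately unsplit), age or longitudinal effects, batch or plate
structure, bisulfite-conversion chemistry, sex chromosomes, cell-type
mixtures in the main design (the composition check uses its own synthetic
reference), probe cross-hybridization beyond a manifest flag, or raw IDAT
files (the signal table is the input contract). Recovery on generated data
therefore validates the statistical machinery and its implementation — not
the biological fidelity of any particular array dataset.
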