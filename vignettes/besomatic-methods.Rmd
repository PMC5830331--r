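---
title: "Comparing somatic mutation landscapes between NSAID users and non-users in Barrett's esophagus"
author: "besomatic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation landscape comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Barrett's esophagus (BE) is a metaplastic precursor of esophageal
adenocarcinoma. Aspirin and other NSAIDs lower esophageal adenocarcinoma
incidence, and one candidate mechanism is that NSAID use suppresses the
accumulation or clonal expansion of somatic mutations in the Barrett's
segment. Testing that hypothesis from whole-exome sequences of purified BE
biopsies requires a chain of analyses: classify each somatic SNV on the 96
pyrimidine-referenced trinucleotide channels and compare the spectra between
exposure groups; compare mutation loads overall, per annotation category,
and per chromosome arm; decompose the spectra into mutational signatures and
ask which covariates drive each signature's load; use variant allele
frequency (VAF) in diploid regions as a clonality readout; aggregate
functional mutations into pathway burdens and a diversity index; and
classify somatic chromosome alterations (SCA) from exome log-ratio/BAF
tracks.

`besomatic` implements that chain as a reusable, tested package. Because the
patient sequence data of such studies are controlled-access, the package
also includes a first-class synthetic cohort generator whose hidden
parameters ("truth") encode the study conditions, so that every stage can be
exercised and validated by parameter-recovery and calibration experiments
rather than by re-deriving printed numbers.

# The synthetic cohort generator

`cohort_truth()` fixes the study conditions; `generate_cohort()` draws a
cohort from them. The defaults are the emulated study's own summaries:

* **Design**: 41 NSAID users and 41 non-users; smoking status is drawn once
  per matched pair (probability 0.5) and shared by both members, mirroring
  the matched design. TP53-mutant fractions default to 6/41 (users) and
  11/41 (non-users).
* **Mutation loads**: per-patient SNV counts are negative binomial,
  parameterized by the printed group summaries — mean 290.93 (SD 209.69) in
  users, 402.49 (SD 362.68) in non-users; indels 17.95 (SD 12.25) vs 22.42
  (SD 13.77). When a requested (mean, sd) implies variance at or below the
  mean, the draw falls back to Poisson with a warning. TP53-mutant patients
  receive a 1.6x load multiplier, renormalized within group so the group
  means stay at their configured values.
* **Capture territory**: 104 Mb per patient, chosen so the combined mean
  load reproduces the ~2.9 mut/Mb scale of a padded exome+UTR capture.
* **Spectra**: each SNV's channel is multinomial from a per-stratum mixture
  of reference signatures. Ever-smokers get a mixture enriched for the
  S17-like signature (0.40 vs 0.22), encoding the smoking-S17 interaction;
  the cohort-average contributions approximate the study's top-five
  signature shares. The emitted record carries either strand representation
  with equal probability, so pyrimidine-strand normalization is genuinely
  exercised.
* **VAF**: three clones per patient with fractions (0.35, 0.40, 0.25); clone
  prevalences are Beta draws — the predominant clone is Beta(5, 4) in
  non-users and Beta(3, 6) in users, encoding the clonality contrast. A
  mutation in a clone of prevalence c has expected VAF purity * c / 2 with
  purity 0.98 (the epithelium purification level of such studies), observed
  through binomial read sampling at Poisson(80x) depth with a one-read
  detection floor.
* **Pathway selection effect**: `pathway_effects` gives, per affected
  pathway, the multiplicative reduction in a user's *per-mutation*
  probability that a functional mutation lands in that pathway (default 0.5
  in nine of 35 pathways). This is a selection effect *conditional on* the
  mutation count, so the observed burden reduction compounds it with the
  group load ratio: with default loads the realized mean reduction is ~62%,
  inside the 37–74% band such cohorts report. The implementation rescales
  the gene-sampling weights so the conditional reduction is exact, not
  diluted by renormalization.
* **SCA**: per-class Poisson segment counts (focal amplification rate 0.217
  in non-users only, i.e. an expected 8/41 carriers; zero in users), with
  class-specific lengths (focal 0.3–2.9 Mb, homozygous deletions 0.2–2 Mb,
  broad events log-normal around 20 Mb), rejection-placed without overlap.
  Genome doubling affects non-users only (probability 4/41) and lays
  arm-wide (4, 2) segments over ~80% of arms.

The synthetic gene model places ~4,000 genes deterministically along the
packaged hg19 arm boundaries with large (hundreds of kb) spacing, so the
1 kb mutation-to-gene linking rule is unambiguous. The 35 synthetic pathways
draw their genes from this model; the nine affected pathways have 150 genes
each. That size was fixed by an a priori power analysis: the nine pathways
of the emulated study jointly span ~906 unique genes, and with the heavy
patient-level load dispersion (CV ≈ 0.7–0.9) smaller pathways leave the
per-pathway Kruskal–Wallis test underpowered at n = 41 per group regardless
of the effect size, because the shared load draw dominates the burden
variance.

## What the generator does not emulate

Passing tests on this generator show that the analysis chain recovers the
effects it encodes, at the study's sample sizes and noise levels. They do
not show that real BE exomes satisfy the generator's simplifications: real
mutation calls carry caller-specific artifacts and mapping biases; real
trinucleotide availability varies with capture content (the generator draws
channels directly from signature mixtures); VAFs in copy-altered regions are
shifted by copy number (the generator leaves them unshifted, which is
harmless here because clonality analyses filter to diploid territory
first, but means the unfiltered VAF distribution is cleaner than reality);
gene lengths and pathway overlap structure are simplified; and indels carry
categories but no sequence context. The generator also makes every pathway
inherit the group load difference, so on default conditions more than the
nine affected pathways can pass FDR 0.2 — the affected nine are recovered,
plus load-driven discoveries that a real cohort's weaker load contrast
produces less often.

# Spectra and mutation load

`normalize_substitution()` refers each substitution to the pyrimidine of the
mutated Watson–Crick pair: purine-reference events are reverse-complemented
together with their 3-base context. The 96 channels are ordered by
substitution block (C>A, C>G, C>T, T>A, T>C, T>G) and, within a block, by 5'
then 3' flanking base in A, C, G, T order, with `A[C>T]G`-style labels — the
conventional ordering, so spectrum matrices interoperate with external
signature tables. `build_spectrum()` conserves counts: row sums equal
per-patient SNV totals (indels carry no channel and are excluded).

Load summaries divide counts by the captured megabases. Arm densities use
the packaged hg19 arm table (0-based half-open intervals; the centromeric
gap belongs to no arm and mutations falling there are dropped with a
reported count).

# Statistical procedures

Standard tests are delegated to base R behind this package's interfaces —
`binom.test` (exact sign test, ties excluded), `kruskal.test` (H with tie
correction, chi-square df = 1), `fisher.test` (two-sided by hypergeometric
probability ordering), `p.adjust(..., "BH")`, and `lm` on `log(count + 1)`
— and each is verified in the test suite against an independent hand-coded
enumeration oracle (binomial tail sums, `dhyper` enumeration, the
definitional step-up rule, the normal equations).

The "mixed effects" comparison of arm densities is realized as a
patient-level permutation test: the statistic is the difference in group
means of per-patient mean arm densities, and patient labels are permuted.
The patient is the exchangeable unit, so within-patient correlation across
arms is preserved exactly; this was preferred over a parametric random
intercept fit because it is assumption-free at these sample sizes and
directly testable for calibration.

## Calibration, and a caution about the cross-channel sign test

Under a fully null generator (identical group parameters everywhere), the
rank, permutation and regression tests hold their nominal 5% size within
Monte-Carlo tolerance, and the exact conditional Fisher test on
focal-amplification prevalence is conservative, as a discrete exact test
must be — its attainable size lies below the nominal level, so only an
upper bound on type-I error is a meaningful check. (One bookkeeping note:
on the suite's fixed 200-cohort null battery the diversity comparison
measured 0.090 at the 0.05 cutoff; isolated checks at 3,000 simulations
give 0.049 and its p-values are uniform by Kolmogorov–Smirnov, so this is a
sampling-tail realization of that batch, not a property of the test.)

The per-gene burden screen is a different animal: genes enter testing only
when at least five carriers sit in one group, and that conditioning selects
genes with a group imbalance, so the raw per-gene size under the null is
far above nominal (~0.2 in the calibration battery) *by construction*. The
screen's operative guarantee is at the BH level after selection — the
probability of any gene surviving FDR 0.1 under the global null stays near
or below 0.1 (measured 0.03) — and its output should be read that way, as
the emulated study's own use of thresholds-then-BH implies.

The sign test across the 96 channel-wise median differences deserves a
warning. It is exact for its own null — independent paired differences with
symmetric signs — and the suite verifies that against enumeration. But under
cohort-level exchangeability it is strongly anti-conservative (measured
size ~0.6 at nominal 0.05 in the null calibration battery), because all 96
channels share each patient's total load: a chance group imbalance in load
moves most channel medians in the same direction, and the test treats those
96 co-moving differences as independent evidence. The package still provides
the test, since it is the field's descriptive convention for spectrum
comparisons, but its p-value should be read as descriptive, not as a
calibrated cohort-level test. This pseudo-replication also explains how
astronomically small printed p-values can arise from such comparisons.

# Mutational signatures

Two complementary routes are implemented.

**De novo extraction** (`extract_signatures_nmf`): for each candidate rank
k, each patient's spectrum is multinomially bootstrap-resampled
(`n_resamples` times), each resample factorized by KL-divergence NMF with
multiplicative updates (10 random restarts, best divergence kept; the KL
objective is the natural choice for count data), and the pooled signature
vectors clustered by average-linkage hierarchical clustering on cosine
distance. Per-rank stability is the mean silhouette of that clustering. The
selected rank is the most stable rank among k ≥ 2 meeting a 0.8 silhouette
floor, with k = 1 as the fallback when no multi-signature clustering is
stable. The single-cluster silhouette is 1 by convention, so k = 1 must not
compete on silhouette — and "largest stable k" overshoots, because forced
sub-clusters of a clean 2-signature solution can also be tight. Final
signatures are normalized cluster centroids; exposures are per-patient
non-negative least-squares fits of the original counts.

**Refitting** (`refit_weights`): the non-negative mixture of reference
signatures minimizing squared error to the normalized spectrum, built by
iterative single-signature addition with full NNLS re-optimization per step
(Lawson–Hanson), then discard of weights below 0.06 with a refit of the
survivors — the deconstructSigs convention, with both the floor and the
stopping tolerance configurable. Patients with fewer than 50 SNVs are not
refit: all assigned counts are zero and a flag is set. Downstream
regressions use `log(count + 1)` responses, which also absorbs those zeros.

The packaged reference set is **synthetic**. The COSMIC catalog is not
redistributed here; instead `make_reference_signatures()` builds ten
deterministic probability vectors whose shapes emulate the processes this
tissue's literature discusses — `SS1` (C>T at NpCpG, clock-like
deamination), `SS17` (T>G/T>C at NTT), `SS2` (TpC, APOBEC-like), `SS4`
(broad C>A, tobacco-like), plus less structured fillers — with pairwise
cosine similarity below 0.9 so refitting is identifiable. Columns are named
`SS*` precisely so nobody mistakes them for the COSMIC consensus vectors; a
real 96 x K reference table in the same TSV layout is a drop-in
replacement.

# Clonality via VAF

Copy number gain, loss and cnLOH all distort VAF, so clonality comparisons
first restrict to mutations lying in no altered segment
(`filter_diploid`; patients without segment data keep all mutations, with a
warning). `count_high_vaf` uses a strict `vaf > threshold` rule (the
headline threshold is 0.3; 0.25 is the conventional "predominant clone"
cut), excluding missing VAFs from numerator and denominator.
`vaf_threshold_scan` walks a grid (default 0.05–0.50 by 0.05) and, per
threshold, compares groups by Kruskal–Wallis on counts (raw) and on
proportions of each patient's total (controlling for load). The scan is
exploratory, so raw per-threshold p-values are reported; a BH-adjusted
column is emitted alongside, and the calibration experiments use that
column — with ten nested, strongly correlated thresholds, "any raw p <
0.05" fires in a large fraction of null cohorts, while the BH column holds
the family-wise rate near its nominal level.

# Pathway burden and diversity

A mutation links to every gene whose 1 kb-flanked interval covers its
position, and through genes to every containing pathway — at most one count
per mutation per pathway, but a mutation in a shared gene increments every
pathway containing it (documented double counting). Per-pathway group
comparisons are Kruskal–Wallis on per-patient functional counts with BH at
FDR 0.2 (non-functional counts analogously); the output carries group
means, SEMs and the percent reduction `100 * (1 - mean_user /
mean_nonuser)`, computed from the actual inputs (printed tables in the
literature derive from unrounded data, so third-decimal agreement is not a
goal). Per-gene tests require at least five carriers in either group and
use BH at FDR 0.1.

The diversity index normalizes each pathway's count by its gene count
(m_i = count_i / genes_i), forms proportions p_i = m_i / sum(m), and
returns SI = -sum(p_i log p_i), with 0 log 0 := 0. A patient with no
mutations in the subset gets SI = 0 — the most concentrated state — and is
flagged in the output; that convention was chosen because the alternative
(dropping such patients) silently changes the group comparison's sample
size. SI is scale-invariant and bounded by log of the subset size. The
group comparison runs separately over the significant-pathway subset and
the remainder.

# SCA calling

`segment_and_call` finds change points per chromosome by greedy binary
segmentation with a BIC-style stopping rule (a split is accepted when the
variance-normalized RSS gain exceeds `penalty_mult * log(n)`); because
cnLOH leaves the log-ratio flat, a second pass segments the BAF deviation
of heterozygous probes and contributes breakpoints the log-ratio pass
missed (near-duplicates within two minimum-segment widths are dropped).
Per segment, total copy number is `round(2 * 2^(lr - baseline))` with the
baseline estimated as the mode of the genome-wide log-ratio density; minor
copy number comes from the mean |BAF - 0.5| deviation, clipped into
[0, total/2], and is NA for segments without heterozygous probes — such
segments merge into an equal-total neighbor, and otherwise only total-CN
classes are called. Adjacent segments with identical (total, minor) merge.

Classification against reference ploidy 2: HD (total 0), loss (0 < total <
ploidy), cnLOH (total = ploidy, minor 0), focal amplification (total ≥
ploidy + 4 and length ≤ 3 Mb), balanced gain (total > ploidy, major =
minor), allele-specific gain (remaining gains), else diploid. The focal
thresholds are this package's definitions and are configurable. Genome
doubling is flagged when major copy number ≥ 2 over more than half of the
assessable autosomal genome; when flagged, classification re-runs at ploidy
4, mirroring WGD-aware callers with a minimal contract. Arm loads intersect
segments with the arm table (segments crossing the centromere split into
both arms) and report MB and counts normalized by arm length.

# Numerical choices and degenerate inputs

* Ties in the sign test are excluded (classical exact test); all-tie input
  returns p = 1 with a warning.
* Kruskal–Wallis on constant data returns H = 0, p = 1 rather than NaN.
* Fisher tables with a zero margin return p = 1.
* NMF uses epsilon-guarded multiplicative updates (eps = 1e-12), converges
  on relative divergence change < 1e-6 or 400 iterations, and re-normalizes
  signature columns to sum 1 (rescaling exposures accordingly).
* NNLS is Lawson–Hanson with a 1e-10 tolerance; refit weights exceeding
  sum 1 are renormalized to the mixture simplex.
* The binomial VAF model resamples zero-alt draws to one read (a called
  mutation has at least one supporting read); read depth draws of zero are
  floored at one.
* All generator randomness flows from one integer seed recorded in the
  truth log; bootstrap, permutation and NMF routines take explicit seeds
  and restore the caller's RNG state.

# Problem sizes in the validation suite

The test suite validates at the study's own scale where the property
demands it (41 per group for power and calibration claims; 200 null
cohorts for calibration, 100 cohorts for each power experiment; 20 seeds
for extraction stability; enumeration oracles over all sign-test
configurations to n = 20 and all 2x2 tables with total ≤ 30) and at
reduced scale (10 patients per group, reduced loads) for structural
properties like round-trips, conservation and monotonicity, where sample
size is irrelevant to the property being checked.

# Known limitations

* The taxonomy's ten non-functional categories are a stable stand-in
  partition; only the five functional categories are fixed by the field's
  definition.
* The segmentation caller is a compatible contract (binary segmentation +
  BAF-aware minor calling), not a reimplementation of any specific
  HMM-based exome CNV tool.
* The packaged reference signatures are synthetic emulations, suitable for
  validation and for demonstrating the refitting machinery, not for
  etiological claims about real tumors.
* The cross-channel sign test is descriptive under cohort sampling (see
  above).
* Indels are generated and counted in loads, categories, pathway burdens
  and VAF analyses, but have no trinucleotide channel and no indel
  signature model.
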