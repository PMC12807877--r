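---
title: "Positional translatome analysis with pausepoint: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional translatome analysis with pausepoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ribosome profiling sequences the ~27-38 nt mRNA fragments protected by
translating ribosomes (RPFs). Aligned to a transcriptome in which each gene
is represented by its most abundant transcript (MAT), every footprint can be
assigned to a single P-site nucleotide, giving a per-nucleotide occupancy
profile per transcript and sample. `pausepoint` implements the positional
analyses that sit on top of such profiles when two conditions (here labeled
WT and KO, four biological replicates each, processed in two batches) are
compared:

1. **Pause-site detection and classification.** Within one condition, a
   pause site is a CDS position whose replicate-pooled count is at least 10
   times the mean of the nonzero CDS counts of the same transcript. Between
   conditions, the change in a site's mRNA-normalized height is compared to
   10 times the transcript's average change, classifying each site as
   *induced*, *resolved*, or *maintained* ("sustained" is accepted as an
   alias).
2. **Metagene delta-occupancy.** Length-scaled per-bin averages of the
   KO-minus-WT normalized occupancy over the 5'UTR, CDS and 3'UTR, with the
   standard deviation across the four replicate pairs.
3. **Differential translation.** Negative-binomial Wald tests (DESeq2, with
   batch as a design covariate) on RPF-CDS and total-RNA count matrices,
   intersected into the joint translational-efficiency (TE) categories:
   both_up/both_down, rpf_up/rpf_down, rna_up/rna_down, ns at padj < 0.1.
4. **Enrichment concordance.** Preranked permutation GSEA (weighted
   Kolmogorov-Smirnov running sum) on the RPF and proteome rankings and the
   set-algebraic comparison of their leading edges.
5. **Cohort contingency analysis.** A two-sided Fisher's exact test for 2x2
   tables, with the row-1 proportion reported.

Every stage is verifiable without deposited data through the synthetic-data
generator, which produces transcript catalogs, RPF read tables, RNA counts
and a proteome with recorded ground truth.

## Coordinate and counting conventions

Coordinates are transcript-space, 0-based, half-open; the CDS occupies
`[utr5_len, utr5_len + cds_len)`. Each read contributes exactly one count at
its P-site (`start + offset(length)`); counts are never spread over the
codon, matching the single-position peak-height language of the pause rule.
P-site offsets are calibrated per read length from the start-codon
metaprofile: the modal 5'-end position relative to the CDS start (within one
read length upstream) determines the offset, and a length is kept only if
its in-frame P-site fraction reaches 0.5 - well above the 1/3 expected from
aperiodic positions, below the periodicity of genuine footprints. Lengths
with fewer than 100 reads are flagged `insufficient`. A user-supplied offset
table bypasses calibration.

## The pause rules and their numerical behavior

Detection uses replicate-pooled per-condition profiles (pooling maximizes
per-position counts for a threshold rule; the per-sample profiles are
divided by median-of-ratios library size factors before pooling so that
condition comparisons reflect occupancy, not sequencing depth). The
candidate set for classification is the union of the two per-condition
calls, so a pause present only in KO can be labeled induced.

Classification computes `delta(i) = h_KO(i)/m_KO - h_WT(i)/m_WT`, where
`m_c` is the size-factor-normalized mean RNA count of the transcript in
condition `c`, and compares it to 10 times the transcript's reference
change. Two choices here were genuinely open:

* **Absolute, not signed, reference.** A signed mean change can be ~0 on a
  transcript with balanced shifts, making the rule degenerate; the reference
  is the mean of |delta|.
* **Reference positions.** The reference is taken over CDS positions with
  nonzero pooled counts in *both* conditions. Positions seen in only one
  condition are dominated by off-frame single-read counts whose |delta| is
  bounded by their own ~1-count heights; including them drags the reference
  scale far below the counting noise of any genuine peak and makes the
  maintained class essentially undetectable. Restricting to positions where
  a height change is measurable keeps the reference commensurate with peak
  noise.

Candidates within the first 3 nt of the CDS (the initiator codon) are
excluded, configurably.

One intrinsic limitation is worth stating precisely. A maintained peak of
amplitude `F x c0` (`F` the pause amplification, `c0` the typical in-frame
position count) fluctuates between conditions with counting sd
`sqrt(2 F c0)`, while the classification threshold is about
`10 x 0.8 x sqrt(2 c0)` (the half-normal mean of the per-position changes).
The probability that a truly maintained site crosses the threshold therefore
depends only on `F`: at `F = 30` roughly 14% of maintained sites are
misclassified by their own noise, independent of depth, frame purity or RNA
precision. The package's recovery tests reflect this ceiling: induced and
resolved sites are recovered essentially perfectly, maintained precision is
high, and maintained recall plateaus near 0.85.

## Metagene methodology

Transcripts enter the metagene when their mean raw CDS count across all
samples exceeds 50 (strictly). Each sample's profile is scaled to
counts-per-million, then divided by the transcript's own mean so every
transcript contributes on a common scale; per-replicate deltas pair KO and
WT replicates by index. Region profiles are averaged into 25/100/25
equal-width scaled bins (5'UTR/CDS/3'UTR); a region of length zero
contributes nothing, and bins not covered by a short region are averaged
over the transcripts that do cover them. Reported are the per-bin mean and
sd across the four replicate pairs, after averaging over transcripts. The
binned values are exported raw; any display normalization is downstream.

## Differential translation

`nb_differential` wraps DESeq2 (`~ batch + condition`, Wald test, BH
adjustment) - the standard engine for this model family - with independent
filtering and Cook's-distance outlier filtering disabled so that the only
transcripts without adjusted p-values are all-zero rows, and no fold-change
shrinkage. The coverage filter excludes transcripts with mean counts across
all samples lower than 10 before testing, separately per assay; the TE
categorization intersects the two surviving sets. Significance is strict
`padj < alpha` (alpha = 0.1), per the category definitions. A transcript
significant on both layers with discordant signs (not observed in practice;
possible in principle) is assigned to the `both_*` category matching its RPF
sign, with a warning, since the categories are RPF-anchored.

## Enrichment and concordance

Rankings: the RPF ranking uses the Wald statistic (log2 fold change is
available as an option); the proteome ranking uses the between-condition
difference of group means of log2 intensities, the Perseus-style "test
difference". Multi-gene protein groups expand to all member symbols tied at
the group score; duplicate symbols collapse to the largest-magnitude score
with a warning. Ties are ordered lexicographically, making every ranking
fully deterministic, so no tie-randomization diagnostic is needed.

The enrichment score is the classic weighted KS running sum (hit increments
`|score|^weight / sum(|score|^weight)`, miss decrements `1/(N - n_hits)`,
weight 1 by default). Because the input is a preranked list, the null is
gene-label permutation: random same-size sets, shared across pathways of
equal size. NES divides ES by the mean |null ES| of matching sign; the
p-value counts same-sign null scores at least as extreme with the standard
`(1+k)/(1+n)` correction, flooring p at `1/(n_perm+1)`; BH is applied across
pathways. The leading edge is the hits at or before (positive ES) or at or
after (negative ES) the extremum. Leading-edge concordance partitions two
results' edges into shared / only-RPF / only-protein and, given abundance
matrices, returns per-gene z-scores (per gene per modality across all
samples) as the substrate for per-condition summaries.

Fisher's exact test is the conditional hypergeometric two-sided rule: the
sum of the probabilities of all tables with the observed margins that are at
most as probable as the observed table (with the customary 1e-7 relative
tolerance for floating-point ties), alongside the sample odds ratio
`ad/bc` and the row-1 proportion.

## What the generator emulates - and what it does not

The generator reproduces the experiment's structure: 2 conditions x 4
replicates with a 2-level batch factor (a multiplicative library-size factor
per batch level, identical across conditions so batch is a pure covariate);
per-codon gamma base rates (shape 2, i.e. codon dwell-time CV ~0.7, capped
at 5x the mean); triplet periodicity (frame weights 0.95/0.03/0.02,
reflecting post-QC footprint quality); an initiation-codon peak (5x) that
anchors offset calibration; low UTR background (5% of the CDS per-nt rate);
reads back-computed from P-sites with a fixed known offset of 12 nt for
lengths 28-32 (written out so calibration can be validated); and per-layer
differential effects defaulting to RPF-only (de_fraction rna = 0,
rpf = 0.15, |log2FC| = 1), mirroring the observation that NPM1 loss changes
RPFs with minimal impact on total RNA.

Injected pauses (one per selected transcript, uniform over the CDS excluding
30 nt at each edge, snapped to frame 0) are amplified to `pause_factor`
times the transcript's mean in-frame peak height - the same scale the
detection rule thresholds on - with `induced` present in KO only, `resolved`
in WT only, `maintained` in both. After applying ramp and pause multipliers,
CDS rates are rescaled so their sum equals the transcript's expected CDS
count: pausing redistributes footprints rather than adding ribosome load,
and the pre-noise rate sums are exactly testable. The 5'-ward shift is a
linear multiplier `1 + ramp_strength (1 - 2x)` over relative CDS position
`x`, KO only, default 0.3.

Replicate noise is gamma-Poisson: a per-transcript, per-sample expression
factor (gamma, shape `nb_dispersion` = 20) shared between the RPF and RNA
layers, mixed with per-position Poisson sampling. Marginally every position
- and exactly the CDS sum - is negative binomial, the distribution the
differential stage assumes; structurally, the shared factor is biological
expression variation, which the pause rule's mRNA normalization is designed
to cancel. The RNA layer is deep (500 expected counts) with near-Poisson
assay-specific noise on top (size 1000), the regime of UMI-deduplicated
counts; this matters because the RNA means act as the normalizer for pause
classification.

Not emulated: raw reads (adapters, UMIs, rRNA contamination), alignment
ambiguity, isoform-level interference, codon-identity effects (dwell times
are random, not sequence-driven), positional autocorrelation of noise, and
proteome missingness. Passing recovery tests therefore demonstrates the
correctness of the analysis logic under the stated stochastic model, not
robustness to upstream artifacts of real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on simulated data at
sizes chosen to make every estimate stable: 400 genes for pause-class
recovery (the pause machinery isolated: ramp and differential effects off,
since a maintained pause on a transcript whose whole translational output
shifts legitimately satisfies the induced/resolved rule); 300 genes under
the full study conditions for the metagene, TE and concordance checks; a
2000-transcript null for Wald-test calibration; 200 random sets with 1000
permutations for enrichment-null calibration; 1000 random profiles against
the brute-force pause oracle; enumeration oracles for Fisher (margins to
~60) and BH. Degenerate inputs are handled explicitly: all-zero profiles
are skipped and recorded, transcripts without positive RNA abundance in
both conditions are skipped and counted, empty pause classes yield empty
histograms, and an empty region contributes nothing to its metagene panel.

## Known limitations

* The maintained-class recall ceiling at high pause amplification described
  above is a property of the 10x classification rule itself.
* MAT selection ties (including all-zero genes) resolve by longer CDS, then
  lexicographically smallest transcript id - a declared convention, not an
  inferred one.
* The GSEA null permutes gene labels, not phenotypes; p-values are exact
  only up to the permutation resolution `1/(n_perm+1)`.
* `classify_te` with `alpha = 1` still reports `ns` for transcripts whose
  BH-adjusted p equals exactly 1, since significance is strict.
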