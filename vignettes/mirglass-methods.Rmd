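---
title: "Methods: cross-species developmental miRNA expression conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species developmental miRNA expression conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements:
the models and conventions behind each analysis step, the parameters
that matter, what the synthetic data generator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The analysis

The pipeline compares microRNA expression across the development of
two species (the built-in defaults describe a *D. melanogaster* /
*D. virilis* style design) in a fixed order: count reads, filter,
normalise, average replicates, pool stages, correlate stages, and
correlate per-ortholog temporal profiles.

**Counting.** Reads are assumed pre-aligned against hairpin reference
sequences whose names equal locus ids (the aligner itself is out of
scope). Only 19–24 nt reads are counted — the mature miRNA length
range; shorter and longer reads are degradation products or unprocessed
species. A read aligning to $k$ distinct loci contributes $1/k$ to
each. Uniform splitting is the minimal-assumption reading of
"corrected for multiple mapping" and conserves read mass, which gives
the suite a sharp invariant: the fractional-count column sums exactly
to the number of retained query names. Within a locus a read is
assigned to the mature arm whose interval contains the read's 5'-most
aligned base, because miRNA 5' ends are defined by Drosha/Dicer
processing and are the least variable end; reads matching no arm go to
a hairpin-other bucket that never enters the mature counts.

**Filtering and normalisation.** Rows with fewer than 10 summed raw
reads over all libraries of a species are removed; the boundary is
strict (a row totalling exactly 10 survives). Filtering precedes
normalisation so that noise rows do not contribute to the library
size; the RPM denominator is therefore reads attributed to mature
arms of retained rows. Each library is then scaled to
$10^6$ (reads per million mapping to microRNAs). Stage pooling — used
to reduce the faster-sampled species B to morphologically comparable
windows (defaults: 0–4, 4–10, 10–16 h) — operates on *raw* counts and
is followed by an explicit re-normalisation, so pooled columns are the
counts a merged library would have produced.

**Sequence divergence.** Hairpins and shared mature arms of each
1-to-1 ortholog pair are aligned globally (Gotoh affine dynamic
programme, compiled in C++). Scoring defaults are (+1, −1) for
match/mismatch and a gap run of length $L$ costs
$\text{open} + L\cdot\text{extend}$ with (−5, −2); the convention and
the traceback tie-break (diagonal, then up, then left) are pinned so
results are bit-reproducible and testable against exhaustive
enumeration. Divergence is the raw proportion of mismatched gap-free
columns (p-distance), with U and T identified; no multiple-hit
correction is applied because the quantity of interest is the rank
ordering of rates, not absolute branch lengths. Mature divergence
pools sites over both arms (substitutions summed over the two arm
alignments divided by summed gap-free sites) rather than averaging
the two per-arm rates; pooling weights each site equally when arms
differ in aligned length. Rate classes are tertiles
($\lceil n/3\rceil$ head and tail; stable tie-break on value then id).

**Clusters.** Genomic miRNA clusters are chains of loci on one
chromosome and strand with inter-locus gaps of at most 10 kb
(inclusive; gap measured end-to-start in 0-based half-open
coordinates, so touching or overlapping loci always chain). Chaining
equals single linkage, which the suite verifies against an all-pairs
oracle.

**Stage correlation.** All stage-versus-stage comparisons use
Spearman's rank correlation on ortholog-matched RPM vectors — robust
to the heavy right tail of expression values and to monotone
distortions between platforms. The alternative metric (Euclidean
distance of per-gene z-scores across that species' stages) is kept for
robustness checks. Within-species matrices are clustered with average
linkage on $1-\rho$; the linkage and the distance are conventions
pinned for determinism, not claims about the uniquely correct tree.
The hourglass profile reads the similarity values along the
homologous-stage diagonal; its score is the mean over designated
mid-developmental pairs minus the mean over the first and last pair,
with the mid window defaulting to the middle third of the diagonal
(positions $\lfloor n/3\rfloor+1$ to $n-\lfloor n/3\rfloor$). The mid
window is configuration, not inference: the analysis reports where the
maximum falls, and the score quantifies how much more similar
mid-development is than the termini.

**Profile conservation.** Temporal profiles are locus-level (arm rows
summed — total mature output of the locus) RPM vectors over the six
comparable stages. Each ortholog pair yields one Pearson $r$;
within-cluster pairs of each species serve as the co-transcription
positive control and uniformly drawn non-ortholog cross-species pairs
(matched in number to the ortholog set) as the negative control.
Group differences use the two-sided Wilcoxon rank-sum test, since the
$r$ distributions are bounded and left-skewed. The rate–conservation
association is the Pearson correlation between divergence and
temporal $r$ with the standard $t$-based p-value, plus per-rate-class
distributions.

Degenerate inputs are rejected rather than patched: correlations of
constant vectors are errors at the scalar level and logged skips at
the pipeline level (an all-zero profile carries no temporal
information); zero-total libraries, non-1-to-1 ortholog or stage
maps, and columns assigned to two pools are errors.

## The synthetic data generator

The generator exists so that every pipeline stage is verifiable
without external data. Its defaults are the study conditions: 118
ortholog families plus 54 and 5 species-specific loci (the scale of
two fly miRNA complements), six species-A stage groups sampled in two
replicates (four embryonic windows, larva, adult), eleven species-B
libraries (eight 2-h embryonic windows to 16 h, a late-embryo 16–30 h
window, larva, adult), a species-B clock stretched 1.5-fold, 90-nt
hairpins with two 22-nt arms, per-family substitution rates uniform on
0–0.2 substitutions/site, 10 genomic clusters, 5% of families with an
identical-hairpin paralog (multi-mapping reads), and libraries of
$10^6$ multinomially drawn reads.

**Temporal profiles.** Each transcription unit draws a profile class:
maternal (exponential decay from fertilisation, time constant 1–8 h,
with a 60% chance of an adult re-deposition bump — ovary loading),
zygotic (sigmoidal onset at a variable time followed by slow
clearance, persistence 5–150 h, reflecting the long half-lives of
mature miRNAs; onsets mostly embryonic, some larval/adult), or
constant; 30% of units add a second expression phase. Species B reads
the same profile on its 1.5x-scaled clock. An earlier, simpler model
(narrow Gaussian pulses, three coarse shapes) was revised because it
made random non-ortholog pairs nearly collinear over six stages —
a degenerate negative control — and was oversensitive to the
imperfect alignment of the two species' sampling windows; persistence
rather than pulses is also the biologically defensible choice.

**Divergence structure.** The hourglass knob is a per-comparable-stage
SD of multiplicative log-normal noise applied to species-B stage
means; the default is U-shaped (0.9, 0.55, 0.25, 0.3, 0.6, 0.9),
minimal at the gastrulation/germband pairs, which embeds an hourglass
whose argmax the analysis must recover. A flat vector embeds no
hourglass and is the null condition for the sign-balance test. The
noise is drawn per transcription unit, so co-transcribed cluster
members diverge together (their shared promoter is what diverges).
Cluster members deviate from their primary transcript profile with
per-stage log-normal noise that is conserved between species
(member-specific deviations are cis-encoded); the default SD (0.4)
and the conserved-profiles test condition (divergence SD 0.2, member
SD 0.2, 15 clusters of 2–4 loci) calibrate the within-cluster scatter
to the cross-species scatter, mirroring the observation that
clustered-miRNA and ortholog $r$ distributions are comparable.
Because one dataset contains only ~15 independent primary
transcripts, the cluster $r$ distribution is lumpy seed to seed, and
the indistinguishability property is asserted across seeds (no
rejection at $\alpha=0.01$ in at least 7 of 10) rather than per seed.

**Reads.** Simulated SAM reads anchor the 5' end at the annotated arm
start (matching the 5'-anchor attribution rule) and jitter the 3' end
by ±1 nt; identical-hairpin paralogs emit one alignment record per
matching locus under one query name; 2% decoy 18-nt reads exercise the
length filter. Counts drawn for a library are reproduced exactly by
the counting module when no paralogs are present, and up to
equivalence classes of identical arms otherwise.

**What is not emulated.** Sequencing error beyond end jitter, adapter
artefacts, 5' isomiR heterogeneity, arm switching between species,
expression-dependent biases of library preparation, ortholog gain and
loss, and inter-platform batch effects. Passing tests therefore show
that the analysis recovers what its own model embeds — counting,
normalisation, divergence and the hourglass geometry — not that real
libraries are free of these complications.

## Problem sizes and tolerances in the test suite

Unit tests run on 15-family datasets with $2\times10^4$-read
libraries; pipeline-level property tests use the full default scale
(118 families, $10^6$ reads, under a second per dataset). The
rate-independence check runs 20 seeded datasets; hourglass recovery
10 (U-shaped) plus 20 (flat, sign test); divergence recovery estimates
each rate from 30 pairs (2700 aligned sites) per trial, 100 trials per
rate, within three binomial SDs — batch estimation keeps the
three-sigma band meaningful, since a single 90-nt hairpin at rate 0.01
misses a 3-SD band over 1% of the time by discreteness alone.
Exact identities (count conservation, RPM column sums, pooling mass
balance, filter boundary) are asserted at $10^{-9}$ or tighter;
correlation oracles at $10^{-12}$.

## Known limitations

* Arm-level profiles are summed to locus level before temporal
  correlation; arm-specific regulatory divergence is invisible to the
  profile analysis (it is visible to the counting and divergence
  modules).
* p-distance saturates for deep divergences; beyond ~0.3
  substitutions/site the rate tertiles compress.
* The hourglass score compares designated mid pairs with the two
  termini only; it is a descriptive contrast, not a fitted model of
  conservation-versus-time, and no formal test of hourglass versus
  early-conservation models is attempted.
* The pipeline takes annotations and the ortholog table as ground
  truth; mis-annotation or hidden paralogy propagates directly.
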