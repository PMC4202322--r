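# mirglass

Cross-species comparison of microRNA expression across *Drosophila*
development, from small-RNA read counts to the hourglass pattern of
stage-wise expression conservation.

## The problem

Protein-coding transcriptomes are most conserved around the
mid-embryonic (phylotypic) period — the developmental *hourglass*.
Whether microRNA expression obeys the same constraint is harder to
test: miRNA complements diverge fast, many loci are species-specific,
and developmental clocks differ between species (*D. virilis* embryos
develop about 1.5x slower than *D. melanogaster*). `mirglass`
implements the complete analysis for a two-species developmental
small-RNA study, for researchers who want to rerun it on their own
species pair or probe its behaviour on simulated data:

* **quantify** — fractional counting of 19–24 nt reads aligned to
  hairpin references (a read hitting *k* loci contributes 1/*k* to
  each; arm attribution by the 5'-anchored read end), a strict
  fewer-than-10-total-reads filter, RPM normalisation
  (reads per million mapping to microRNAs), replicate averaging, and
  pooling of fine stages into morphologically comparable windows
  (0–4 h cleavage, 4–10 h gastrulation + germband elongation, 10–16 h
  germband shortening for the slower species).
* **homology** — ortholog sequence divergence as substitutions per
  site (p-distance) from global affine alignment of hairpins and
  mature arms, rate tertiles (low/medium/high), and genomic miRNA
  clusters (same strand, gap ≤ 10 kb).
* **stagecompare** — all-versus-all Spearman stage correlation
  matrices within and between species (Euclidean distance of z-scores
  as an alternative metric), average-linkage dendrograms, replicate
  SD error bars, and the hourglass profile along the homologous-stage
  diagonal: `score = mean(rho over mid pairs) − mean(rho over the
  first and last pair)`.
* **ortho_profiles** — per-ortholog Pearson *r* between temporal
  profiles on the comparable stages, compared against genomically
  clustered miRNAs (co-transcribed positive control) and random
  cross-species pairs (negative control, Wilcoxon rank-sum), and the
  association between evolutionary rate and temporal conservation.
* **synthetic_data** — a generator of complete two-species datasets
  (GFF3/FASTA annotations, ortholog table, sample sheet, count tables,
  optional SAM) with controllable per-family substitution rates,
  cluster co-expression, multi-mapping paralogs, a 1.5x time-scaled
  second species and a tunable stage-dependent divergence profile
  (U-shaped ⇒ hourglass embedded).

## Worked example

```r
library(mirglass)

ds  <- simulate_mirna_dataset(simulation_config(seed = 1))
res <- analyze_dataset(ds$loci_a, ds$loci_b, ds$orthologs,
                       ds$counts_a, ds$counts_b, ds$samples, seed = 1)
res
#> <mirglass_results>
#>   stages: 6 x 6 cross-species comparable matrix
#>   ortholog pairs: 118 (median r = 0.918) vs random null median r = -0.120, rank-sum p = 4.59e-23
#>   rate vs conservation: r = -0.032, p = 0.728 (n = 118)
#>   hourglass score: 0.0606, argmax pair e6-10 ~ e10-16
res$hourglass
#> <hourglass_profile>
#>   stage_a stage_b   rho
#> 1    e0-1    e0-4 0.920
#> 2    e2-6   e4-10 0.968
#> 3   e6-10  e10-16 0.991
#> 4  e12-24  e16-30 0.969
#> 5   larva   larva 0.955
#> 6   adult   adult 0.919
#> argmax pair: e6-10 ~ e10-16 (position 3)
#> hourglass score: 0.0606 (mid pairs 3,4)
```

Reading the output: orthologous miRNAs keep highly similar temporal
profiles (median Pearson r 0.92, on par with co-transcribed clustered
miRNAs and far above random cross-species pairs); conservation does not
depend on sequence evolutionary rate (r = −0.03, p = 0.73); and the
homologous-stage correlation peaks at the germband stages — the
embedded hourglass, recovered with a positive score and a
mid-developmental argmax.

File-driven runs use a YAML config naming the GFF3/FASTA annotations,
SAM files or count tables, sample sheet and ortholog table:

```r
run_pipeline("run.yaml", outdir = "results/")
```

or, from a shell, the thin wrapper `inst/scripts/mirglass.R`
(`simulate` and `run` subcommands).

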