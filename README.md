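# motifZ

Empirical-null transcription-factor motif enrichment in ChIP-seq peak
summit windows.

## The problem

Given a set of ChIP-seq peaks (e.g. sites bound by a chromatin
remodeller, or sites gained after re-expressing a lost subunit), a
recurring question is whether known transcription-factor binding
motifs occur at those sites more often than chance would allow. motifZ
implements that analysis end to end for R users working with
GenomicRanges/Biostrings objects:

1. **Summit windows.** Each peak is reduced to a fixed window (default
   200 bp) centred on its summit — the narrowPeak point-source when
   available, the peak midpoint otherwise.
2. **PWM scanning.** Each motif, a position frequency matrix from
   JASPAR PFM or MEME minimal files, is converted to a log-odds matrix
   against a background base distribution and scanned over both
   strands of every window. A window offset is a match when its score
   reaches the threshold at which a background-random window would
   match with probability at most α (default 10⁻⁴); the threshold
   comes from the exact score distribution, computed by dynamic
   programming on a 10⁻³-bit score lattice. The observed statistic *x*
   is the total number of matches over all windows.
3. **Empirical null.** The same scan is repeated on `n_reps` (default
   100) sets of random genomic regions, each region length-matched to
   a foreground window, giving null occurrence counts with mean μ and
   sample standard deviation σ.
4. **Significance.** Enrichment is scored as

   z = (x − μ) / σ

   per motif, alongside a distribution-free empirical p-value
   p = (1 + #{replicates ≥ x}) / (n_reps + 1) and Benjamini–Hochberg
   q-values across the motifs of each peak set.

A synthetic-data module (`generateGenome`, `generatePeaks`,
`plantMotifs`) builds toy genomes with motif instances planted into a
known fraction of peaks and a recorded truth table, so the whole
pipeline can be validated on data whose answer is known.

## Worked example

The one-command demonstration generates a 2 × 300 kb genome (GC 0.5),
200 peaks of 200 bp, plants an 8-bp high-information motif into half
of the peaks, adds a column-shuffled decoy with identical base
composition, and runs the full pipeline:

```r
library(motifZ)
res <- runDemo("demo_out", seed = 1)
#> planted motif planted_demo: z = 13.83
#> decoy   motif planted_demo_shuffled: z = -0.83
#> planted instances: 87 of 200 peaks
enrichTable(res)[, c("motif_id", "x", "mu", "sigma", "z", "p_empirical", "q_bh")]
#>                motif_id  x   mu     sigma          z p_empirical       q_bh
#> 1          planted_demo 25 2.46 1.6294016 13.8332995  0.00990099 0.01980198
#> 2 planted_demo_shuffled  0 0.66 0.7941707 -0.8310556  1.00000000 1.00000000
```

Reading the output: the planted motif was found 25 times in the 200
summit windows while length-matched random regions contained it only
2.46 ± 1.63 times, i.e. almost 14 null standard deviations fewer —
strong enrichment, with the smallest empirical p-value 100 replicates
can produce (1/101). The decoy, which has the same base composition
but a scrambled position structure, stays within one standard
deviation of its null: the signal comes from the planted positional
pattern, not from composition.

`demo_out/` then contains the genome FASTA, peaks narrowPeak, motifs
JASPAR file, planting truth table, results TSV, a per-replicate null
count audit TSV, the resolved run configuration YAML, and a log of
every under-specified choice exercised (midpoint fallbacks, clipped or
collapsed windows, degenerate motifs).

For real data, build the run from files instead:

```r
cfg <- enrichConfig(
  genome  = "genome.fa",
  peaks   = list(gained_sites = "peaks.narrowPeak"),
  motifs  = "jaspar_motifs.txt",
  window  = 200, alpha = 1e-4, nReps = 100, seed = 1,
  outputDir = "enrichment_out")
res <- runEnrichment(cfg)
```

A thin CLI with `simulate`, `windows`, `scan`, `enrich` and `demo`
subcommands is installed at `system.file("scripts", "motifz",
package = "motifZ")`.

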