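---
title: "Empirical-null motif enrichment at peak summits: methods and design"
author: "motifZ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical-null motif enrichment at peak summits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The statistical model

motifZ asks whether a transcription-factor motif occurs in a set of
ChIP-seq peak regions more often than in random genomic sequence. The
statistic is deliberately simple and auditable:

* the **observed value** *x* is the total number of motif matches in
  fixed windows around the peak summits;
* the **null** is the distribution of the same count over repeated
  sets of random genomic regions, each drawn length-matched to a
  foreground window (default 100 replicate sets);
* significance is the **Z-score** z = (x − μ)/σ, with μ the mean and
  σ the sample standard deviation of the replicate counts, plus the
  add-one empirical p-value p = (1 + #{replicates ≥ x})/(n_reps + 1)
  and Benjamini–Hochberg q-values across motifs.

The implied assumptions are worth stating. The Z-score treats the null
counts as roughly normal, which holds when the expected match count
per replicate set is not tiny; the empirical p-value is reported
alongside precisely because it makes no such assumption. Matching the
null on region *length only* assumes the genome's composition is
homogeneous enough that position, not composition, is the relevant
difference between foreground and background; GC- or repeat-matched
sampling is out of scope (an `exclude` set for gaps or blacklists is
supported). Matches are counted per (offset, strand) with no merging
of overlapping hits: for direct-repeat or palindromic motifs *x* can
exceed the number of distinct sites, identically in foreground and
null, so z is unaffected in expectation but the raw counts should be
read with that in mind.

# Windows

"A window of *w* bp around the summit" is read as total width *w*:
the half-open interval [summit − w/2, summit + w/2) in 0-based
coordinates. The summit is the narrowPeak point-source offset when
present; for plain BED input the region midpoint (integer division)
is the fallback, and the run log records how often the fallback fired.
Windows overhanging a chromosome edge are clipped, not dropped —
dropping would silently change n_regions — and exact duplicate windows
are collapsed to one, with both counts logged. Null regions are
sampled length-matched to the *windows* (so clipped windows get
shorter null matches) and are scanned as-is, without re-windowing.

# Scanner and score threshold

A motif is held as a position frequency matrix with a background base
distribution and a total pseudocount c (default 0.1, spread across
bases by background frequency, the common scanner convention). The
log-odds score of base b at position i is
log2(((n_bi + c·π_b)/(N_i + c))/π_b) bits; a window's score is the sum
over positions, and the minus strand is scored against the
reverse-complement matrix. Windows containing any N are skipped rather
than scored — scoring masked sequence as "average background" would
fabricate matches where there is no sequence.

A match is an offset whose score reaches the threshold t(α): the
smallest achievable score whose exact background tail probability
P(score ≥ t) is at most α (default 10⁻⁴). The exact distribution is
computed by dynamic programming: log-odds entries are rounded to a
10⁻³-bit lattice and the distribution of the sum is convolved position
by position under the background model, so the cost is linear in motif
width times the score span instead of 4^width. Two numerical details
matter:

* **Achievability.** The lattice sum can exceed the exact maximum
  score (rounding up every column), so a threshold read off the
  lattice alone could be unattainable and silently kill all matches.
  The DP therefore carries, for every lattice bin, the minimum exact
  score of any sequence landing in it — accumulated in the same
  left-to-right order the scanner adds columns, hence bit-for-bit a
  score the scanner can produce — and returns that. The returned
  threshold is always attained by some window.
* **−Inf entries.** With a zero pseudocount a zero count gives a
  −Inf log-odds entry. On the lattice these are clamped to −30 bits
  (below anything a pseudocounted matrix produces, and irrelevant to
  any practical α) so the convolution stays finite; exact scores keep
  the true −Inf.

The lattice groups exact scores that differ by less than the
resolution; near a tail boundary this can move the threshold by up to
one inter-score gap relative to an ungrouped computation. The tests
compare the DP against exhaustive enumeration on the same declared
lattice, which is exact.

The scanner itself concatenates all region sequences with N spacers,
integer-codes the result once, and scores every offset with w
vectorized lattice lookups per strand. Accumulation is left-to-right
per position, which makes the output floating-point identical to
scoring each window independently — the property the test suite's
naive re-scorer checks exactly.

# Null construction and randomness

For each replicate, each foreground window is matched by one random
region of identical length: chromosome chosen with probability
proportional to its number of valid placements (L − len + 1), start
uniform among them — i.e. uniform over all valid genomic positions.
Replicates and regions are independent (positions sampled with
replacement); the foreground itself is *not* excluded by default,
since for sparse peak sets the contamination is negligible, and an
explicit `exclude` set triggers rejection sampling (up to 1000
redraws per region, then an error rather than a silent bias).

σ uses the sample (n − 1) denominator — the unbiased convention for an
estimated null; at n_reps = 100 the population-σ alternative differs
by under 1%. The choice is recorded in the run metadata. When every
replicate count is equal, σ = 0 and z is undefined: the motif is
flagged degenerate and z is NA; no division by zero, and the empirical
p-value is still reported.

All randomness flows from one integer seed. Replicate i of a run uses
a substream seeded deterministically from (seed, i), so raising
n_reps extends the null without perturbing earlier replicates, and
every generator restores the caller's RNG state afterwards. Two runs
with the same resolved configuration are byte-identical on disk.

# The synthetic-data generator

`generateGenome` draws i.i.d. bases at a chosen GC content;
`generatePeaks` places fixed-length peaks uniformly over valid
positions with centred summits; `plantMotifs` gives each peak, with a
chosen probability, at most one motif instance *sampled from the PFM's
column distributions* (not the consensus, so sub-consensus matches
exercise the score threshold), written over the existing bases at a
uniform offset and strand. Overwriting rather than inserting preserves
all coordinates; at most one instance per peak keeps the expected
observed count analytically simple (≈ planted fraction × per-instance
detection probability × n_peaks + background rate). All edits are
returned in a truth table.

What the generator does *not* emulate: composition heterogeneity
(isochores, CpG islands), repeats, chromatin signal, or correlated
peak placement — peaks may overlap, in which case a later planted
instance may overwrite part of an earlier one (the fidelity tests use
non-overlapping peaks for exactly this reason). Passing the synthetic
recovery and calibration checks therefore demonstrates the
statistical machinery is correct under the stated model, not that
length-only null matching is adequate for every real genome.

The standard demonstration scenario (`runDemo`) uses two 300-kb
chromosomes at GC 0.5, 200 peaks of 200 bp, an 8-bp motif with an 85%
majority base per column planted at probability 0.5, a column-shuffled
decoy of identical composition, window 200, α = 10⁻⁴ and 100 null
replicates. At these sizes a full run takes seconds; the calibration
study (planting probability 0, 20 independent datasets) a couple of
minutes. Under this scenario roughly a quarter of sampled instances
are exact consensus — at α = 10⁻⁴ and this information content the
threshold typically admits only the consensus — giving a planted
Z-score far above 5 while the decoy stays within ±2.

# Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `window` | 200 bp | total summit-window width |
| `alpha` | 1e-4 | per-window match p-value defining the score threshold |
| `nReps` | 100 | null replicate sets |
| `bothStrands` | TRUE | scan the reverse complement too |
| `pseudocountTotal` | 0.1 | total pseudocount per PFM column |
| `background` | uniform | base distribution for log-odds and the threshold DP |
| `exclude` | none | intervals barred from null sampling |

# Design choices that were genuinely open

* **Coordinate conventions.** In-memory objects are standard
  Bioconductor containers (GRanges, 1-based closed; DNAStringSet), and
  every file surface is BED-family 0-based half-open, converted at the
  I/O boundary exactly as rtracklayer does. Within-region offsets
  (summits, hit offsets, truth tables) stay 0-based as in narrowPeak
  column 10.
* **Counting rule.** x counts total occurrences, not hit-bearing
  regions; the per-region count is reported as a secondary column but
  never enters z.
* **BH family.** q-values are adjusted across the motifs of one peak
  set; separate peak sets are separate families.
* **Threshold semantics.** The match set is {windows with exact score
  ≥ t(α)}; because t is the minimum exact score of the qualifying
  lattice bins, a window in the boundary bin but below t is not a
  match. The realized per-window match probability can thus differ
  from α by at most the boundary bin's mass.

# Known limitations

Length-only null matching (no GC/repeat matching); single-genome,
single-condition analysis (no differential enrichment between two peak
sets); i.i.d. background in both the threshold DP and the synthetic
genome (no higher-order Markov background); motif widths beyond ~25 bp
make the lattice DP wider but remain exact. For degenerate runs where
every motif has σ = 0 (e.g. a motif absent from a tiny genome), the
CLI signals a dedicated exit code rather than inventing a z.
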