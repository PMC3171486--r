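---
title: "Discovering gapped DNA motifs by stepwise consensus refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering gapped DNA motifs by stepwise consensus refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifstep)
```

## The problem

Transcription factors bind short, partially degenerate DNA sites. Given a
*foreground* set of sequences suspected to share such a site (ChIP-seq peak
regions, promoters of co-regulated genes) and a *background* set that models
chance occurrence (all promoters, matched random regions), de novo motif
discovery asks for sequence patterns over-represented in the foreground.
Two features make this hard in practice: binding sites may be **long**
(beyond the ~12 nt ceiling of many enumeration tools) and they may be
**gapped** — two specified half-sites separated by unspecified positions,
as in the classic GAL4 site `CGG-N11-CCG`.

`motifstep` addresses both by refining *gapped consensuses* stepwise:

1. **Core filtering.** Every consensus of the form `UVW-N^g-XYZ` (two
   specified triplets, gap `g` = 0–14; 4^6 × 15 = 61,440 candidates, spans
   up to 20 nt) is scored for enrichment, filtered at a minimal fold
   enrichment of 1.2, ranked by z-score, and the top 50 are retained.
2. **Degeneration.** Each core's six informative positions are relaxed to
   IUPAC codes *consistent* with the original base (codes whose nucleotide
   set contains it), changing at most 4 of the 6 positions. A candidate
   replaces the core only if both its fold enrichment and its z-score
   strictly improve.
3. **Extension.** The consensus is padded with N to a span of 20 (even
   original gap) or 19 (odd gap), and up to 3 non-informative positions —
   flanks or gap interior — are specialized to any non-N IUPAC code; the
   variant with the best z-score wins if it beats the padded consensus. For
   foregrounds above 100 kb the step runs a second time.
4. **Refinement.** Foreground instances of the extended consensus are
   scanned with one mismatch and pruned under a modified MAP
   (maximum a posteriori) objective against an order-3 Markov background;
   the preserved instances are merged into a position weight matrix (PWM).
5. **Redundancy removal.** PWMs are compared by a CompareACE-style
   correlation and greedily filtered at a similarity cutoff of 0.6,
   keeping higher-MAP motifs.

`run_pipeline()` executes the five stages end to end.

## Enrichment model

For a consensus with `C` foreground instances and `N` background instances
(both strands; self-reverse-complementary patterns scanned once), the
expected foreground count under a uniform instance distribution is

$$E = N \cdot L_{fg} / L_{bg},$$

with `L` the total sequence lengths. Fold enrichment is $F = C/E$ and
significance is scored by a binomial z-approximation

$$Z = \frac{C - E}{\sqrt{E\,(1 - L_{fg}/L_{bg})}},$$

which standardizes a Binomial count with mean $E$ and success probability
$L_{fg}/L_{bg}$: it is 0 exactly when $C = E$ and ranks candidates the same
way a binomial tail test would. Two degenerate cases are pinned down:
$E = 0$ gives $F = \infty$ (pass) for $C > 0$ and $F = 1$, $Z = 0$
otherwise; and when $L_{fg} \ge L_{bg}$ the variance term vanishes, so the
package warns and returns $Z = 0$ — the method presumes a background
substantially larger than the foreground, which is also the realistic
regime (a peak set against all promoters).

Counting conventions: occurrences are counted per site (overlaps included,
pooled across sequences); a sequence `N` never satisfies a specified
consensus position, while consensus `N` positions are free; windows running
past a sequence end are skipped.

## The MAP objective

Refinement scores an instance set of width $w$ and size $x_m$ by the
MDscan-family objective

$$\mathrm{MAP} = \ln(w) \cdot \frac{\ln x_m}{w} \left[ \sum_{i=1}^{w}
\sum_{j \in \{A,C,G,T\}} p_{ij} \ln p_{ij} \;-\; \frac{1}{x_m} \sum_s \ln
p_0(s) \right],$$

where $p_{ij}$ are raw positional frequencies of the instances and
$p_0(s)$ is the probability of site $s$ under the background Markov model,
conditioning each base on its three predecessors (taken from the source
sequence on the instance's strand, backing off to lower orders near
sequence starts). The leading $\ln(w)$ is the length modification that
makes scores of different widths comparable. Natural logarithms are used
throughout; a fixed log base only rescales all scores, so rankings are
unaffected. For $x_m$ identical sites on an exactly uniform background the
score collapses to $\ln(w)\,\ln(x_m)\,\ln 4$, which the test-suite checks
to $10^{-9}$ across $w = 4..20$, $x_m = 2..50$.

Pruning is a single leave-one-out pass: the score with all instances is
compared, for each instance, against the score without it, and the
instance is preserved iff the full score is strictly larger. Each test is
against the full set — there is no iteration to convergence. The MAP of an
empty set is defined as $-\infty$, so a lone instance is always preserved;
if pruning ever discards everything, the scanned set is kept with a
warning. The scoring frequencies carry no pseudocount (so the closed form
above holds exactly); the *reported* PWM adds 0.25 per cell to avoid zero
columns downstream.

## Background model

`fit_markov_background()` estimates conditional probabilities
$p(b \mid \text{context})$ for context lengths 0–3 from k-mer counts over
both strands of the background, with one pseudocount per k-mer and windows
containing N skipped. The lower-order tables exist solely for back-off at
sequence starts. `uniform_background()` provides the exact 1/4 model used
by the synthetic benchmarks and the closed-form tests.

## PWM similarity and accuracy measures

`compare_ace()` computes the maximal Pearson correlation between two PWMs
over all ungapped column offsets with at least 6 overlapping columns and
both orientations of the second matrix. Correlation is taken over the raw
probability entries (not information content); a zero-variance block —
e.g. an exactly uniform PWM — scores 0 rather than NA. Ties between
alignments resolve deterministically: same orientation before reverse
complement, smaller offsets first.

For benchmarking against a known (expected) motif, the best CompareACE
alignment partitions columns into TP (shared), FP (identified only) and FN
(expected only), and

$$\mathrm{mSN} = m \cdot \frac{TP}{TP+FN}, \qquad
\mathrm{mSP} = m \cdot \frac{TP}{TP+FP},$$

with negative $m$ clamped to 0 so both scores stay in $[0,1]$. A
benchmark case is a *success* when the best of a tool's top-3 motifs
reaches a similarity cutoff; `success_rate()` aggregates cases and
averages mSN/mSP over them.

## Synthetic data: what it emulates, what it does not

`generate_dataset()` draws background sequences from a configurable model
(uniform by default; an order-3 Markov model fitted from user sequences
optionally) and plants one motif instance — sampled from a consensus or
PWM, with an optional per-position substitution rate — into a chosen
fraction of foreground sequences at a uniform random position and strand
(ZOOPS-style: zero or one occurrence per sequence, which keeps the planted
truth unambiguous). The default geometry is 200 foreground sequences of
500 bp with a four-fold larger background of the same length: real
backgrounds (all promoters, matched genomic regions) dwarf the target set,
and the z-score variance $E(1 - L_{fg}/L_{bg})$ is only meaningful when
the background dominates. The planted fraction of 0.4 reflects a realistic
ChIP peak set in which under half the regions carry a strong consensus
site.

What passing these benchmarks does *not* show: real regulatory sequence is
not Markovian — repeats, CpG islands and compositional domains create
structured background that uniform or order-3 simulation cannot mimic;
real sites vary in strength and spacing rather than matching a single
consensus; and peak sets carry position biases (sites concentrated at peak
centers) that the uniform planting ignores. Recovery on synthetic data is
a correctness check of the machinery, not a performance claim about any
particular genome.

## Numerical and design choices

* **Exact candidate scoring.** All three consensus-search stages score
  their full candidate spaces exactly. Core counts for all 61,440 gapped
  consensuses come from per-gap 64×64 trimer-pair tables built in one pass
  over the encoded sequences; degeneration contracts those tables with
  per-position code-indicator matrices (Kronecker products) to score all
  8^6 consistent-code combinations at once; extension exploits the fact
  that specializing N positions can only shrink an instance set, tallying
  the base pattern's instances instead of re-scanning (about 1.25 million
  candidates per core at the default limits, well within a desk-scale
  budget — so no greedy approximation is needed). Each shortcut is
  property-tested against a brute-force scanner.
* **Strands and palindromes.** Both strands are always scanned;
  self-reverse-complementary patterns are scanned forward-only so
  palindromic sites are not counted twice. In the tally-based extension
  this surfaces as halving the derived counts of palindromic candidates.
* **Tie-breaks.** Every ranking breaks ties lexicographically on the
  consensus string, making the whole pipeline deterministic for fixed
  inputs and configuration.
* **N handling.** Input letters outside A/C/G/T are folded to N on read;
  N contributes to sequence length but never matches a specified consensus
  position; instances whose site or left context contains N are excluded
  from refinement.
* **Flanking N columns** left over after extension are trimmed before
  refinement, so the refined width counts informative context only.
* **Degeneration count.** The consistent-code rule gives
  $\sum_{k \le 4} \binom{6}{k} 7^k = 43{,}653$ candidates per core (7
  non-identity consistent codes per base); the enumeration is exposed as
  `enumerate_degenerations()`.
* **Non-N IUPAC codes.** The IUPAC nucleotide alphabet has 15 codes
  including N; extension therefore specializes positions over the 14 non-N
  codes.
* **Problem sizes in the test-suite.** Unit fixtures use tens of sequences
  of 100–300 bp; the end-to-end benchmarks use the full default geometry
  (200 × 500 bp foreground, 800 × 500 bp background), where a complete
  pipeline run takes well under a minute on a single core.

## Known limitations

* The gap structure is fixed at enumeration time; degeneration never
  re-estimates the gap length, and extension can specialize gap-interior
  positions but not lengthen the gap.
* Counting is per-site (no ZOOPS/OOPS sequence-level model), so a few
  sequences with many repeats can dominate enrichment.
* Refinement fixes the width given by the extended consensus; there is no
  EM or Gibbs re-optimization of width or alignment.
* Redundancy removal discards motifs rather than merging redundancy
  classes into averaged PWMs.

## A worked example

```{r example, eval = FALSE}
library(motifstep)

ds <- generate_dataset(plant_spec("CGGNNNNNNNNNNNCCG",
                                  planted_fraction = 0.4, seed = 21))
res <- run_pipeline(ds$fg, ds$bg, pipeline_config())
tidy(res)
autoplot(res$motifs[[1]])
```

At seed 21 the gapped plant is recovered among the top motifs with both
`CGG` and `CCG` triplets separated by 11 positions; the summary table, the
per-motif `tidy()`/`glance()` views and the `autoplot()` information
profile expose the result for downstream tooling.
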