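---
title: "Modeling MBD pulldown coverage from fully methylated DNA"
author: "MBDmodel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling MBD pulldown coverage from fully methylated DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MBDmodel)
```

## The model

MBD-seq enriches for methylated DNA by pulling down fragments with a
methyl-CpG binding domain protein (here MBD2, as in the MethylMiner kit).
Absolute methylation callers such as BayMeth are most accurate when, next
to the sample of interest, they see how many reads each window would
attract at *full* methylation — normally measured by an extra pulldown of
SssI-treated DNA.  `MBDmodel` replaces that experiment with a computation.

The expected number of pulldown alignments starting at position $x$ of a
fully methylated genome is modeled as

$$\Lambda_x \propto \sum_{\ell=\ell_{\min}}^{\ell_{\max}}
  P(\ell)\,\bigl[C_{n(x \to x+\ell-1)} + C_{n(x-\ell+1 \to x)}\bigr],$$

with three ingredients:

1. **Fragment lengths** $P(\ell)$: a truncated discrete Gaussian with mean
   $L$ and SD $S$ (defaults $L = 100.7$ bp, $S = 12.98$ bp on
   $[\ell_{\min}, \ell_{\max}] = [3, 200]$, the values estimated for the
   MethylMiner library this model was calibrated on), or a delta at a known
   average length for libraries where only that is available.
2. **Accessible CpGs** $n(a \to b)$: the number of CpGs on the fragment
   $[a, b]$ that can be bound by MBD domains *simultaneously*.  Bound
   proteins exclude each other sterically, so $n$ is the largest subset of
   the fragment's CpGs in which consecutive members obey
   $(c_i + 1) + \mathrm{minSep} < c_j$ (positions are the CpG cytosines;
   default `minSep = 3` bp).  A left-to-right greedy scan — bind the first
   CpG, then every CpG far enough from the last bound one — attains this
   maximum, which the test suite verifies against exhaustive subset search.
   A CpG belongs to a fragment only if both its C and G lie inside; this is
   also what makes the single-CpG profile fit below sensitive to fragment
   length.
3. **Enrichment coefficients** $C_n = E(n)/E(0)$: how much more likely a
   fragment with $n$ accessible methylated CpGs is to be captured,
   sequenced and aligned than a 0-CpG fragment.  The shipped defaults
   (`defaultCnTable()`: 1, 1.489, 5.468, 32.31, 124.7, 207.3, 233.2, 259.7
   for $n = 0..7$) come from a MethylMiner MBD2 experiment; counts above 7
   reuse $C_7$, matching the kit's saturation estimate.  $C_7$ is kept at
   259.7 despite its large subsample SD because fragments with 7+
   well-separated CpGs, although rare, are measurably better captured than
   6-CpG fragments.

The two bracketed terms are forward- and reverse-strand alignments.  The
overall scale ("prefactor", default 1) is arbitrary; window *ranking* is
invariant under it, which the suite checks.  Window coverage is
$y_{\Lambda} = \lfloor \sum_{x \in i} \Lambda_x \rfloor$ over
non-overlapping fixed-width windows (default 100 bp), floored so the
result can stand in for an integer read count.

### Aggregation modes

`windowLambda()` sums $\Lambda_x$ over positions *in* the window — only
fragments starting (on either strand) in the window contribute.
`windowLambdaOverlap()` implements the variant for a fixed fragment length
$\ell_{avg}$ that instead sums the strand-specific terms over every
position whose fragment would *overlap* the window by at least 1 bp,
mirroring how observed window counts are made.  At $\ell_{avg} = 1$ the
two coincide (a tested identity).

### Numerical and boundary choices

- **Chromosome edges.** Fragments running past an end contribute with $n$
  computed on the clipped intersection, keeping $\Lambda$ defined at every
  position; `clipEdges = FALSE` drops those lengths instead.  The
  difference is confined to $\ell_{\max}$ bp at each end.
- **Flooring.** Window sums are accumulated in double precision per window
  (not via a running genome-wide cumulative sum) and rounded to 9 decimals
  before flooring, so values like 5.999999999 do not floor to 5.
- **Scan complexity.** The per-chromosome scan walks, for each position,
  the greedy chain restricted to the $\ell_{\max}$ neighborhood through
  precomputed per-CpG next/previous-accessible pointers, and converts the
  chain's entry lengths into cumulative-probability increments; it is
  $O(G \cdot \text{chain length})$ and is verified position-by-position
  against direct $(\ell, \text{strand})$ enumeration.
- **Coordinates.** Internally everything is 1-based and closed, the native
  convention of `GRanges`/`Biostrings`; BED input/output converts at the
  boundary via `rtracklayer`, and 1-based bisulfite coverage tables load
  unchanged.  The model arithmetic only involves distances, which are
  base-convention invariant.

## Estimating the fragment-length distribution

For single-end data $P(\ell)$ is not directly observable.  Every alignment
is extended to a 250 bp genomic segment from its 5' end in read
orientation; segments containing exactly one CpG, at position $t \ge 11$
from the 5' end (closer CpGs are discarded against alignment edge
effects), are counted by $t$ separately for the pulldown and the input
library.  The ratio of the two positional fractions decays with $t$
because a CpG beyond the real fragment end cannot help capture:

$$\frac{p(1\,\mathrm{CpG}, t)}{q(1\,\mathrm{CpG}, t)}
  = R_0 + (R_1 - R_0)\,P(\ell \ge t + 1),$$

where $R_0, R_1$ are the pulldown efficiencies of 0- and 1-CpG fragments
within this single-CpG pool.  `fitFragLen()` fits $(R_0, R_1, L, S)$ by
least squares (via `minpack.lm`) from the initial guess (1, 1, 200, 50).

One design decision deserves a note: a commonly printed closed form for
the tail, $\mathrm{Erf}((t-L)/(S\sqrt2)) - \mathrm{Erf}((1-L)/(S\sqrt2))$,
*increases* with $t$ and therefore cannot be a survival function; fitted
as printed it cannot follow the decaying ratio.  The package fits the true
tail sum of the truncated discrete Gaussian; the literal expression is
available through `fitFragLen(model = "printed-erf")` for comparison, and
a test asserts its residuals are worse.  On flat (uninformative) profiles
the fit reports $R_0 \approx R_1$ with $(L, S)$ flagged unidentifiable
rather than returning arbitrary numbers.

The discrete pmf uses the Normal density at integer lengths renormalized
over the truncation range (rather than CDF differences); at $S \approx 13$
the two differ by under $10^{-4}$, far below fit uncertainty.

## Estimating enrichment coefficients

`classifyFragmentsByNCpG()` extends each read to a single assumed fragment
length from its 5' end (single-end reads do not reveal their true length;
the fitted $L$, rounded, is the natural choice), counts accessible CpGs,
and tabulates fragments per chromosome.  `cnFromCounts()` forms
$E(n) = \mathrm{frac}_\mathrm{pulldown}(n)/\mathrm{frac}_\mathrm{input}(n)$
on the pooled counts and scales to $C_n = E(n)/E(0)$.  The headline
estimate pools chromosomes; `subsampleSd()` recomputes $C_n$ per
chromosome, averages to $C_n^{*}$, and reports
$\sqrt{\mathrm{mean}_g (C_n(g) - C_n^{*})^2}$ — a population (divide by
the number of groups) fluctuation, as a fraction of the pooled $C_n$.
Both pooled and per-group values are exposed, since either convention may
be wanted for comparison.

## The simulator

`simulate*()` generates the study data all recovery tests run on:

- `randomGenome()` plants CG dinucleotides on an i.i.d. background
  (accidental CGs scrubbed) with geometric inter-CpG gaps of minimum 2 bp,
  at a requested density — human-like 0.01 CpG/bp in most fixtures.
- `simulatePulldownReads()` draws candidate fragments uniformly (5' ends
  uniform, fair strands, lengths from $P(\ell)$), methylates each CpG by
  its methylome probability, and retains the fragment with probability
  $C_{\min(n,7)}/C_7$ — rejection sampling normalized by the cap so
  acceptance probabilities stay in $[0, 1]$.  Since $\Lambda$ is defined
  only up to a prefactor, relative enrichment is all that matters.
- `simulateRrbsCounts()` draws per-CpG totals $r_j \sim$ Poisson and
  methylated counts $m_j \sim$ Binomial$(r_j, \mu_j)$.

What the simulator deliberately does **not** emulate: GC- or PCR-related
sequencing bias (real SssI-control coverage shows a turnover at very high
CpG density that this model attributes to such bias), CpG-island spatial
clustering (planted CpGs have near-geometric gaps), sequencing errors and
quality, and paired-end structure.  Passing recovery tests therefore shows
the estimators invert the model's own generative process at realistic
densities and depths — not that real libraries are free of biases the
model ignores.

Fixture scenarios (`makeFixtureBundle()`) fix the study conditions:
`sssi-recovery` uses a 1 Mb genome, $10^6$ fragments per library and a
*delta* length distribution at 100 bp, so that the estimator's
fixed-length approximation is exact and coefficient recovery is isolated
from length-approximation error; `fraglen-recovery` uses CpG density
0.004/bp — about one CpG per 250 bp segment, which maximizes the fraction
of single-CpG segments the profile can use — with $10^5$ reads per
library; `bimodal-methylome` uses a 200 kb genome, 1 kb blocks at
methylation 0.05/0.95, $2 \times 10^5$ sample reads and mean bisulfite
coverage 20.  All randomness flows from one seed; bundles are
byte-identical across runs.

## Evaluation conventions

Window methylation from bisulfite counts is the read-weighted mean
$\mu_i = \sum_j m_j / \sum_j r_j$; a window is "methylated" iff
$\mu > 0.50$ (exactly 0.50 is unmethylated).  Counts reported on the G
strand of an indexed CpG are merged into the C-strand record — a
convention this package had to choose, since strand handling in coverage
tables varies; unmergeable positions are kept with a warning.  Evaluation
windows require bisulfite coverage $\ge 10$ (33 for WGBS-style filtering)
and $\ge 75\%$ of bases with mappability exactly 1 (after rounding track
scores to 6 decimals).  ROC curves sweep descending score cutoffs with
tied scores grouped into one step; the AUC (trapezoid) equals the
Mann–Whitney statistic with half credit for ties, an identity the suite
checks on random instances.  The Youden point maximizes
$(TPR - FPR)/\sqrt2$ with ties broken toward lower FPR.  Percentile
cutoffs in `lambdaCutoffSweep()` use the nearest-rank convention with
$\ge$ inclusion.  CpG density per window is a plain count of CpGs within
an average fragment length of the window — no positional weighting, by
design, and labeled as such.

## Problem sizes and what the suite computes

The test suite verifies the scan against brute-force enumeration at every
position of a 10 kb random genome (Gaussian and delta lengths, minimum
separation 2 and 3), greedy counting against exhaustive search on 1,000
random instances, coefficient recovery on the 1 Mb / $10^6$-fragment
fixture within propagated binomial error, the distribution and AUC
contracts, and the end-to-end bimodal evaluation.  These sizes were chosen
so the whole suite stays in the minutes range while every estimator is
exercised at its intended operating density.

## Known limitations

- The fragment-length fit's precision is set by the per-bin counts of the
  single-CpG profiles.  At $10^5$ reads per library only a few tens of
  thousands of segments qualify (~100–150 per position bin), and the
  resulting ~12 % per-bin ratio noise propagates to roughly ±2 bp
  uncertainty on $L$ and several bp on $S$; bp-level estimates need on the
  order of $10^6$ or more reads per library.  The estimator is unbiased —
  more depth, not a different model, is what sharpens it.
- The raw ratio score $y_S/(y_\Lambda + 1)$ used in the package's
  end-to-end checks is a deliberately simple stand-in for a full caller.
  Its AUC is insensitive to the model's overall scale (prefactor), but
  reducing the steric minimum separation from 3 to 2 bp perturbs it by
  about 0.01–0.02 on the synthetic fixture at any evaluation size, because
  the score lacks the CpG-density-class normalization an empirical-Bayes
  caller applies on real data.  Conclusions about knob-insensitivity of
  *caller output* should be drawn with the caller in the loop.
- An unexplained efficiency excess at $t \approx 10$–30 observed in real
  profile data is not modeled.
- SssI mode models complete methylation; $\Lambda$ is not a model of
  partial methylomes (the simulator, by contrast, supports arbitrary
  per-CpG levels).
- Genomes are treated as haploid references; allele-aware analysis is out
  of scope.
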