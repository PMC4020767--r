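---
title: "Internal-seed miRNA target analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-seed miRNA target analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodalseed)
```

## The question the package answers

A mature miRNA loaded into Argonaute normally selects targets through its
canonical seed, positions 2–8 from the 5′ end: transcripts whose 3′UTR
contains the reverse complement of that window are repressed.
`bimodalseed` implements the analysis required to detect and
characterise a *non-canonical* mode in which an internal window —
positions 6–12 — plays the same role. The motivating guide is
miR-4728-3p, whose internal-seed target word `GAGGTCA` dominates
enrichment among down-regulated genes after over-expression, while the
canonical word trails it. Because seed position is set by the distance
to the guide 5′ end, 5′-truncated isomiRs shift every window: a guide
shortened by one nucleotide presents windows 3–9 (CS+1) and 7–13 (IS+1)
at canonical register. The package treats seed definitions as data —
`(anchor, length, isomiR shift)` — so canonical, internal and shifted
variants are all instances of one type.

## Coordinates and scanning

miRNA positions are 1-based with position 1 at the 5′ nucleotide,
matching how seeds are conventionally numbered; UTR matches are 0-based
half-open intervals, the convention of interval arithmetic. Scanning is
exact string matching of the target word on the mRNA sense strand only,
all overlapping occurrences counted; `N` never matches. The seed-class
factor used downstream is presence-based (one or more matches), so
overlap counting is visible only in the per-gene counts, not in the
classes.

## Word-enrichment landscapes

For word $w$ contained in $K$ of $N$ genes, and a leading bin of the
$n$ most down-regulated genes containing $x$ carriers, the two one-sided
hypergeometric tails $P(X \ge x)$ and $P(X \le x)$ are exact
(`stats::phyper` in log space). The signed score is
$\pm(-\log_{10} \min(p_\mathrm{over}, p_\mathrm{under}))$, positive for
over-representation; the full-list bin is identically zero. Counting is
presence-based rather than occurrence-based with a Markov composition
correction: presence matches the seed-class factor used everywhere else
and keeps the hypergeometric model exact. The cost is that
composition-driven word biases are not corrected — acceptable for
synthetic i.i.d. backgrounds, a caveat on strongly biased real UTR sets.
The default bin step is $\max(1, \lfloor N/100\rfloor)$; words absent
from every UTR score a flat zero rather than entering the ranking.

## Differential expression and stratification

Per-gene statistics are two-sample Welch $t$ on log2 intensities with
Welch–Satterthwaite degrees of freedom and Benjamini–Hochberg adjustment;
moderated-variance models are deliberately out of scope since the
analysis consumes externally normalised arrays. Ranking is by ascending
$t$ with lexicographic tie-break, so the pipeline is deterministic.
The "down-regulated" stratum for the duplex screen is $t < -4$ (strict);
its complement is the default "unaffected" set. The alternative reading
`t >= 4` is kept behind `unaffected = "t_ge_4"` because the opposite-tail
definition also appears in the literature this analysis style comes
from; the complement is the default since a symmetric-tail definition
would silently drop most genes.

## Seed-class ECDF comparison

Genes are partitioned by seed content (`CS_only`, `IS_only`, `both`,
`neither`, with +1 shifted words included in the word sets when the
isomiR profile supports them) and their log2 fold-change ECDFs compared.
The scalar per-class summary is the mean shift against `neither`
(median optional); the two-sample KS test supplies $D$ and an asymptotic
Kolmogorov p-value, with an exact label-permutation mode for very small
samples. Additivity of canonical and internal repression is tested as
$\mathrm{gap} = \Delta_{both} - (\Delta_{CS} + \Delta_{IS})$ with a
seeded percentile bootstrap (default 1000 resamples, classes resampled
independently); no distributional model is imposed.

## The duplex energy model

`duplex_mfe()` minimises a nearest-neighbour free energy over all
non-crossing antiparallel pairings of guide and target window:
Watson–Crick and GU pairs; stacking energies for adjacent pairs; bulge
and internal-loop penalties by total unpaired size, capped at 10
nucleotides per side; one initiation penalty; no intramolecular
structure, dangling ends or temperature scaling. The parameter table
ships as a plain-text file tagged `bimodalseed-nn-0.1`: Watson–Crick
stacks follow the standard 37 °C duplex set, GU-involving stacks are
approximate wobble values, and the table is exactly symmetric under step
reversal so that swapping the two strands leaves the energy unchanged.
Loop penalties are nonnegative and nondecreasing in size — a model
invariant the package enforces at load time; this intentionally departs
from tables in which a size-1 bulge is costlier than a size-2 bulge,
because the screen's comparisons only need a consistent, monotone
penalty. Numeric agreement with external folding software is a
non-goal; correctness is defined by exact agreement with brute-force
enumeration over all pairings, which the test suite checks on hundreds
of short random pairs.

Tie-breaking in the traceback prefers more pairs, then a fixed candidate
order (stacked predecessor, then loops by increasing size), making
reported structures deterministic.

The screen for extended complementarity asks whether a hybrid contains
an uninterrupted run of ≥ 10 pairs *at* the internal seed. "At" means
the run overlaps the seed window by at least 4 guide positions, not that
it spans the window: a global MFE structure can trade a terminal pair of
a genuinely planted 12-nt helix against chance complementarity elsewhere
in the ±15 nt window (we observed exactly this during development), so a
full-coverage rule misses true extended hybrids, while a one-position
overlap admits chance runs grazing the window edge. Four positions is
robust on both sides: a planted 12-mer loses at most two terminal pairs
to such trades, and a chance run must reach deep into the seed register
to qualify.

## CLIP peak calling

Candidate windows are seed matches extended 10 nt each side, clipped at
transcript bounds, merged within a seed type but never across types.
Reads count toward a window on any-base overlap. A window is positive
when its raw treatment count reaches 5 and its normalised enrichment
$\frac{(n_t + 1)/L_t}{(n_c + 1)/L_c} \ge 2$, with $L$ the library sizes
and pseudocount 1; a one-sided Poisson test is available as an
alternative criterion. These defaults are documented choices, not a
claim to reproduce any particular study's thresholds, which are
typically unstated. Region annotation is by window midpoint against
half-open UTR5/CDS/UTR3 spans, so junction midpoints belong to the
downstream span. Note one property of normalised enrichment with
asymmetric libraries: when the treatment library is dominated by signal
piles, a single control background read in a window can pull a true site
below two-fold — this bounds the caller's sensitivity slightly below 1
at the default depths.

## isomiR profiling

The 5′ offset of a read at the mature locus is
`read 5′ − canonical 5′` in mature orientation (positive = truncated);
on the minus strand the 5′ end is the interval end. Offsets beyond ±5
pool into `other`. Shifts enter the seed set when their locus fraction
reaches `min_fraction`, default 0.10; the study-like spectrum
0.6/0.3/0.1 at offsets 0/1/2 yields shifts {0, 1} at a 0.15 cut, which
is why the default scan set carries CS/CS+1/IS/IS+1. 3′ heterogeneity is
recorded nowhere: it never moves a seed window.

## qPCR normalisation and correlation

CNRQ follows the standard relative-quantification chain:
$RQ = E^{\overline{Cq}_g - Cq}$ per well, a per-sample normalisation
factor equal to the geometric mean of reference-gene RQs, and per-gene
calibration so each gene's geometric mean over samples is 1.
Efficiency defaults to 2.0 (perfect doubling) and may be set per gene.
Spearman correlation drops incomplete pairs, uses average ranks, and
takes the exact permutation null for $n \le 10$ (full enumeration) and
the $t$ approximation above that.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with every stream seeded from one master seed so outputs are
byte-identical across runs. Defaults are the study-like conditions used
throughout testing: 5000 genes; log-normal UTR lengths
(meanlog 6.35, sdlog 0.6, clipped to 100–3000 nt — median ≈ 570 nt,
a realistic human 3′UTR scale); GC 0.45; site classes 10% CS-only,
10% IS-only, 5% both; additive effects $\delta_{CS} = -0.25$,
$\delta_{IS} = -0.40$ log2 units (internal stronger than canonical, the
ordering the analysis is designed to detect) with optional interaction;
noise $\sigma = 0.3$ over 6 replicates per group; CLIP piles of
Poisson(30) reads jittered ±5 nt on every planted site in treatment
only over 0.005 reads/nt background; isomiR proportions 0.6/0.3/0.1;
a 19-sample qPCR panel with planted Spearman $\rho = -0.5$ via a
Gaussian copula (Pearson parameter $2\sin(\pi\rho/6)$).

Three design choices keep the ground truth exact rather than merely
probable:

* **Rejection resampling.** Any UTR whose scan over the full word set
  (including +1 variants) deviates from the planted truth — a chance
  occurrence, or a planted word recreated by background — is redrawn, so
  the class factor is exact, not approximate.
* **Blocker bases.** The two bases flanking each planted site are chosen
  to be unable to pair (WC or GU) with the guide's continuation, so a
  planted 7-mer site cannot extend into a long helix by local chance;
  extended 12-nt complements are planted explicitly (a configurable
  fraction of IS genes) for the long-run screen.
* **A low-self-complementarity guide.** The default synthetic guide
  `UAGAAUCUUGCACUCGGCCUUUCCA` was selected once, by seeded search, so
  that no seed word complements the guide in any off-register window for
  more than 3 consecutive pairs; otherwise planted words can seed chance
  long helices against other parts of the guide and contaminate the
  screen.

What the generator does **not** emulate — real transcriptome
composition, probe-level array noise, crosslink-site biases, multi-site
genes (one site per class per gene by default) — bounds what passing
tests show: they validate the machinery and its statistical behaviour
under the stated model, not performance on any particular organism's
UTR set.

## Problem sizes and numerical choices

The test suite exercises the generator defaults (5000 genes) for the
enrichment, ECDF and pipeline checks, 20 seeded replicates at 250 genes
for peak-calling recovery, 200 random short sequence pairs for the
duplex-vs-enumeration identity, and 200 qPCR panels for correlation
recovery; these sizes give statistical headroom on the assertions while
keeping a full run within a few minutes. Energy ties use a 1e-9
tolerance; ECDF and PFM invariants use 1e-9; hypergeometric exactness is
asserted at 1e-12 against direct enumeration. The Spearman recovery
check compares the mean of the estimates to the exact finite-sample
expectation under the Gaussian copula
($E[r_s] = \tfrac{6}{\pi(n+1)}[\arcsin r + (n-2)\arcsin(r/2)]$, ≈ −0.477
at $n = 19$ for planted −0.5) rather than to the asymptotic value, since
the estimator's small-sample attenuation does not vanish with more
simulation replicates.

## Known limitations

* Enrichment has no composition correction; on real UTR sets with strong
  k-mer biases the landscape ranks words against an exchangeability null
  that may be too liberal for composition-driven words.
* The duplex model is deliberately minimal (no dangles, coaxial terms or
  temperature dependence); energies are comparable within the package,
  not across software.
* The peak caller's defaults are reasonable but not calibrated to any
  specific CLIP protocol; the Poisson mode is provided for depth-skewed
  libraries.
* Transcript-space only: reads must already be mapped to transcript
  coordinates; genome-space lifting and alignment are out of scope.
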