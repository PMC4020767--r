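# bimodalseed

Tools for detecting and characterising **internal-seed** miRNA activity —
target repression guided by an internal window of the mature miRNA
(positions 6–12 from the 5′ end) rather than, or in addition to, the
canonical seed (positions 2–8).

Classical miRNA target prediction assumes perfect complementarity to the
canonical seed. Some miRNAs, however, repress transcripts whose 3′UTRs
match an internally shifted window; miR-4728-3p (encoded in an intron of
*HER2*) is the motivating case, where the internal-seed word `GAGGTCA` —
the reverse complement of miRNA positions 6–12 — dominates the
word-enrichment landscape of down-regulated genes and mediates repression
of *ESR1*. `bimodalseed` packages the full desk analysis needed to make
and test such a claim on any guide:

* **Seed definition and scanning** — arbitrary seed windows `(anchor, k,
  isomiR shift)`, target-word derivation by reverse complement, exact
  overlapping scans of 3′UTR sets, and the four-way seed-class factor
  (`CS_only` / `IS_only` / `both` / `neither`).
* **Word-enrichment landscapes** — for every k-mer *w* with *K* carriers
  among *N* genes, the leading bin of size *n* of a ranked
  differential-expression list containing *x* carriers is scored by the
  exact hypergeometric tails; the signed score is
  `±(−log10 min(P[X ≥ x], P[X ≤ x]))`, positive for over-representation
  (Sylamer-style).
* **Seed-class ECDF comparison** — Grimson-style log2-fold-change ECDFs
  per class, two-sample Kolmogorov–Smirnov tests, per-class location
  shifts and a bootstrap test of whether CS and IS repression combine
  additively (`both ≈ CS + IS`).
* **Duplex energetics** — an intermolecular nearest-neighbour
  minimum-free-energy model (Watson–Crick + GU, stacks, bulges, internal
  loops, initiation) with exact dynamic programming, plus a screen for
  long uninterrupted helices ("is the seed part of a longer motif?").
* **Seed-anchored CLIP peak calling** — windows ±10 nt around seed
  matches, library-size-normalised treatment/control enrichment with
  pseudocounts (or a one-sided Poisson test), transcript-region
  annotation and overlap with down-regulated genes.
* **5′ isomiR profiling** — offset spectra of read 5′ ends at the mature
  locus, used to decide which shifted seed variants (CS+1, IS+1, …) enter
  the scan.
* **qPCR support** — CNRQ normalisation (`RQ = E^(ΔCq)`, geometric-mean
  reference normalisation, per-gene calibration) and Spearman correlation
  with exact permutation p-values for small panels.
* **A deterministic synthetic-data generator** — every input above with a
  ground-truth manifest: planted sites at controlled frequencies,
  additive class effects with Gaussian noise, treatment-only CLIP piles,
  multinomial 5′-offset spectra and Gaussian-copula qPCR panels.

## Worked example

```r
library(bimodalseed)

# the motivating guide: internal seed 6-12 gives the word GAGGTCA
derive_target_word(mir4728_3p(), seed_definition("IS", 6, 7))
#> target word GAGGTCA (IS of hsa-miR-4728-3p)

# synthetic study: 5000 genes, 10% CS / 10% IS / 5% both,
# delta_CS = -0.25, delta_IS = -0.40, sigma = 0.3, 6 replicates/group
cfg <- sim_config(master_seed = 1)
sim <- sim_all(cfg, dir = NULL)
rec <- per_gene_stats(sim$expression$mat, sim$expression$group_labels)
idx <- build_word_index(sim$utrs, 7)
tw  <- top_words(rank_by_downregulation(rec), idx)
head(tw, 3)
#>      word peak_value peak_bin   K
#> 1 TGCAAGA  345.56721      850 750
#> 2 AGATTCT  162.17008     1500 750
#> 3 CTGCAAG   76.89527      850 356
```

`TGCAAGA` is the planted internal-seed word of the synthetic guide and
tops all 16 382 observed 7-mers; the peak value is the largest signed
−log10 hypergeometric score over leading bins (here at the 850 most
down-regulated genes). `AGATTCT` is the canonical-seed word, and third
place `CTGCAAG` is a hitchhiker overlapping the planted IS sites by six
bases. The seed-class ECDF analysis on the same run
recovers the planted effects:

```r
ann <- classify_genes(sim$utrs, cfg$words$cs, cfg$words$is)
d   <- build_class_distributions(rec, ann)
class_shift(d$IS_only$values, d$neither$values)   # -0.394  (planted -0.40)
class_shift(d$both$values,    d$neither$values)   # -0.645  (planted -0.65)
```

`run_all(cfg, out_dir)` executes the whole graph — isomiR profile →
active seed shifts → scan → differential statistics → enrichment → ECDF →
duplex screen → CLIP peaks → CNRQ/correlation — and writes every stage
output plus a JSON manifest; reruns with the same configuration are
byte-identical.

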