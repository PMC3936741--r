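---
title: "Spliced read mapping and splice-junction denoising: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spliced read mapping and splice-junction denoising: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

RNA-seq reads that span splice junctions must be aligned with gaps, and every
gapped alignment nominates an intron. In compact eukaryotic genomes (< 500 Mb,
largely homogeneous GC), a large share of the junctions nominated only by
RNA-seq evidence are not functional: they arise from alignment error and from
noisy splicing — stochastic use of random splice sites that produces many
distinct, individually rare junctions. `splicefinder` maps reads across
junctions and then *scores* every candidate junction with a posterior
probability of being functional, so the final junction set can be cut at any
operating point.

The pipeline has four steps:

1. **Ungapped alignment.** Full reads are placed on the genome by exact k-mer
   seeding plus Hamming verification (at most 2 substitutions, both strands).
   The seed length is lowered to `floor(L / (max_mismatch + 1))` for short
   reads so pigeonhole seeding is exhaustive.
2. **Anchor-and-extend gapped alignment.** Unplaced reads are cut into
   non-overlapping 18–25 nt segments; segments that place ungapped become
   anchors that delimit the genomic region where the intron must lie. The
   unaligned stretch between (or beside) anchors is searched for a single
   intron that begins GT/GC/AT and ends AG/AG/AC (the orientation of the
   dinucleotides defines the junction strand), subject to: at least 8 exonic
   nt on each side of every junction, intron length in `[20, 10000)` nt, and
   at most 2 substitutions in total.
3. **Pseudo-transcript remapping.** Reads spanning exons shorter than a
   segment, or two close junctions, cannot anchor. For every predicted
   junction a spliced reference of length 2L is built (L exonic nt on each
   side); if n other junctions lie within L nt, all 2^n subsets of them are
   spliced in or out. Unmapped reads are placed ungapped on these
   pseudo-transcripts and projected back to genome coordinates. For
   paired-end data, spliced alignments without an opposite-strand mate
   alignment in the expected orientation are then removed.
4. **Classification.** Junction candidates are aggregated from all spliced
   alignments and described by nine features (below). An RBF-kernel SVM is
   trained on a heuristically self-labelled training set, its parameters are
   picked by grid search against an ab initio-labelled development set, and
   decision values are calibrated to posterior probabilities. Junctions with
   score `s > S` (default `S = 0.5`) form the output set.

# Sequence models

Splice sites are modelled by position-specific frequency matrices (PSFMs):
the donor window covers 3 exonic + 6 intronic nt, the acceptor window 20
intronic + 1 exonic nt. Both are first order (each position conditioned on
the previous base; the first position is zero order). Site scores are
log-likelihood ratios in bits against a stationary background model of
genome composition; intron lengths are scored by the log2 mass of a binned
(10 nt) empirical length distribution with a pseudo-mass of 1e-6 for unseen
lengths. These parameters stand in for what an ab initio gene finder would
supply by self-training; the package estimates them from annotation-labelled
introns (add-0.5 pseudocounts), loads them from a sectioned plain-text
parameter file, or takes them from the simulator's generating truth. The
self-training HSMM machinery of an ab initio gene finder itself is out of
scope.

Design points the sources leave open, decided here:

* **Background model.** The denominator of the site log-likelihood ratio is
  an order-0 genome composition model. Nothing in the method requires more;
  order is configurable in the type but only 0 is implemented.
* **N handling.** A window position holding N contributes the background
  probability to numerator and denominator alike — 0 bits — so windows with
  N are scorable but never advantaged. When N is the conditioning base, the
  following position falls back to its marginal.
* **Serialization.** Probabilities are written with 17 significant digits, so
  a save/load cycle is exact.

# The nine junction features

For a candidate junction with supporting spliced alignments
(depth `C`, support *i* at left-anchor offset with count `c_i`):

| feature | definition |
|---|---|
| depth | number of supporting spliced alignments, `C` |
| entropy | depth-weighted Shannon entropy of left-anchor offsets, `-sum c_i log2(c_i / C)` (bits) |
| min_overhang | max over supports of each support's shorter overhang (nt) |
| skew | `log2((1 + C) / (1 + max(u_d, u_a)))`, `u_d`/`u_a` = ungapped reads crossing the donor/acceptor boundary |
| donor_score, acceptor_score | PSFM log-likelihood ratios (bits) |
| gap_loglik | intron-length log-likelihood (bits) |
| frameshift | 1 iff both splice sites fall in predicted CDS exons of one gene and splicing breaks the predicted reading frame |
| strand_discord | 1 iff the intron overlaps a predicted gene on the opposite strand |

The exact entropy and skew formulas used by the method's antecedents are not
public; the definitions above are this package's own, chosen so that the
published selection thresholds remain attainable: a *depth-weighted* entropy
is unbounded in depth (a plain Shannon entropy could never exceed 20 bits at
realistic read lengths), and the skew is negative exactly when a junction is
weakly supported relative to local unspliced coverage, which makes the
negative-label rule "skew < −1" meaningful. The published thresholds (20
bits, −1, 2 nt, 20 nt) are kept as printed; they may merit recalibration
against other entropy/skew definitions.

The phase convention for `frameshift` is `(coding nucleotides preceding the
position) mod 3` along the prediction's own coding strand; splicing preserves
frame iff the downstream flank's phase is one more (mod 3) than the upstream
flank's.

# Classifier

Only six features enter the classifier: donor_score, acceptor_score,
gap_loglik, frameshift, strand_discord and depth. The remaining three
(overhang, entropy, skew) are reserved for self-labelling:

* **positives**: shorter overhang > 20 nt *and* entropy > 20;
* **negatives**: skew < −1 *or* shorter overhang ≤ 2 nt;
* a candidate firing **both** rules carries contradictory evidence (typically
  a deep junction dwarfed by local unspliced coverage) and is excluded from
  both classes — the usual resolution when self-labelling a training set.
  Excluded candidates still appear in the classified pool and may enter the
  development set.

The development set is labelled by exact match (sequence, both boundaries,
strand) to the ab initio intron predictions, and is disjoint from the
training set by junction key. Features are z-scored with training-set
statistics (needed for a shared gamma lattice), and an RBF-SVM (libsvm via
`e1071`) is fitted at every point of the `(ln c, ln gamma)` lattice —
default both in `{-9, ..., 3}`, bracketing the published optimum (−7, −2) —
scoring each fit by `W = TP − FP` on the development set. Ties go to smaller
gamma (smoother boundary), then smaller cost.

Decision values are mapped to posteriors by a Platt sigmoid
`s = k / (1 + exp(A f + B))` fitted by maximum likelihood on out-of-fold
decision values from 5-fold cross-validation (so the sigmoid never sees
overfitted margins); the final SVM for scoring is refitted on the whole
training set. The source text's normalization constant is typographically
unrecoverable; `k = 1` (standard Platt scaling, a proper probability) is
used. The output set keeps candidates with `s > S` strictly, so `S = 1`
yields an empty set and raising `S` can only shrink the set.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every end-to-end property is checked. It emulates:

* a compact genome (default 100 kb) with 200 non-overlapping multi-exon
  genes on both strands; exons 40–120 nt, 2–4 per gene; introns log-normal
  (median 80 nt, truncated to 45–400 nt); i.i.d. background at 42% GC;
* splice sites drawn from generating first-order-representable PSFMs
  (donor consensus (C/A)AG|GTAAGT, acceptor pyrimidine tract + YAG|G), with
  the terminal GT / AG forced during construction;
* log-normal gene expression (sdlog 1);
* **splicing noise**: `noise_per_gene` (default 20) distinct noise
  transcripts per gene, each replacing the donor, the acceptor, or both
  sites of one intron with a random in-gene GT / AG position. Noise events
  are individually rare — they share `noise_fraction` (default 0.2) of the
  read mass, so the mean junction-spanning support per noise junction is
  about 2 reads — but collectively they outnumber functional junctions,
  which is exactly the regime the method targets. Noise junctions are always
  GT–AG, so they cannot be filtered by dinucleotide class alone;
* paired-end 75 nt reads (fragments ~N(160, 20)), i.i.d. substitution
  errors at 0.02 per base; full per-read truth (genomic blocks, transcript,
  functional/noise label);
* an ab initio gene-prediction stand-in: the truth annotation with 10% of
  genes dropped, emulating realistic ab initio sensitivity on compact
  genomes.

What it does **not** emulate: indels and quality-profile errors, intron
retention and other structural alternative splicing, GC-inhomogeneous
genomes, repeat families (multi-mapping is therefore rarer than in real
genomes), and expression-correlated noise depth. Passing tests demonstrate
the machinery is correct under these conditions, not that the published
real-data operating characteristics transfer to any particular genome.

# Numerical and scaling choices

* Coordinates are 0-based half-open internally; GFF3 output is 1-based
  closed, BED 0-based half-open, SAM 1-based; converters are centralized and
  round-trip tested.
* Tie-breaking among equal-mismatch intron placements: higher donor+acceptor
  PSFM score, then smaller intron, then leftmost. An unspliced fill of an
  anchor gap is preferred over a spliced fill at equal mismatch count
  (parsimony).
* A segment that spans a junction can acquire a spurious near-match
  placement; chain resolution therefore also tries variants with one or two
  edge anchors dropped and keeps the minimum-mismatch result.
* The 2^n pseudo-transcript blow-up is capped at the n = 8 nearest
  neighbors (configurable); identical (sequence, blocks) transcripts are
  collapsed before remapping.
* Platt fitting uses BFGS with an analytic gradient; if it fails to
  converge it restarts from Platt's standard initialization.
* The standard benchmark (100 kb, 200 genes, 50k pairs, seed 1) yields
  roughly 2–3k junction candidates; the published training/development sizes
  (10000 / 5000+5000) assume millions of reads and would swallow the whole
  candidate pool, leaving an empty development set. The benchmark therefore
  uses train_size = 600 and dev_size = 600 per class as its scaled study
  conditions; function defaults keep the published sizes. Test problem sizes
  (45 kb genomes for the aligner-oracle comparison, 1.1 Mb / 2100 genes for
  the 5000-intron model-recovery check, 40 kb for the double reproducibility
  run) are the package's own choices for a compact, convincing suite.

# Known limitations

* One intron per anchor gap: reads spanning two junctions with no anchorable
  segment between them are recovered only via pseudo-transcript remapping.
* No indel handling within blocks; quality strings are ignored.
* The heuristic positive rule can be contaminated by *deep* noise junctions
  (high expression × noisy splicing); with the generator's noise regime a
  few percent of positive-eligible candidates are noise, which bounds the
  attainable self-labelling purity.
* Only order-0 background models are implemented.
* Multi-mapping reads keep up to `max_hits` placements with no per-hit
  penalty; pervasive repeats would need a mapping-quality notion this
  package deliberately omits.
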