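---
title: "Modeling promoter architecture from positional motif patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling promoter architecture from positional motif patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

`promarch` asks a structural question about transcriptional regulation in
plants: do genes co-expressed in one plant structure (PS) — flower, seed,
root, shoot, or constitutively across the whole plant — share a promoter
*architecture*, i.e. the same motifs at characteristic distances from the
translation start site (TLS) and on characteristic strands? The package
turns that question into a testable pipeline and ships a synthetic-data
generator whose ground truth exercises every stage. This vignette explains
the model, its assumptions, the parameters that matter, and the choices made
where the design was genuinely open.

## Why the TLS, and what a promoter is here

Transcription start sites are poorly annotated in *A. thaliana*-like
settings, and plant 5' UTRs are short, so all coordinates anchor to the
**TLS** (the start codon). A promoter of declared length `L` ∈ {50, 100,
150, 200} bp is the `L` bases immediately upstream of the annotated gene
start on the gene's own strand, written 5'→3' with the TLS-adjacent base
last. Distance `x ∈ [0, L)` counts bp upstream: `x = 0` is the base
touching the TLS. All model stages operate on `L = 200`.

## The assignment rule and its degeneracies

Genes join structure sets by a gap rule on their per-structure average
expression: gene `g` with sorted averages `a(1) ≥ a(2) ≥ …` is assigned to
its argmax structure `s*` iff

`a(1) − a(2) > t(s*) · sd(averages)`,

with `sd` the population (divide-by-k) standard deviation — the source
design does not specify the divisor; a switch (`sd_type = "sample"`) gives
the n−1 form. The comparison is strict, and a tie for the argmax leaves the
gene unassigned.

Two properties of this rule are worth knowing. With exactly **two**
structures the ratio `gap / sd` is identically 2, so assignment is
all-or-nothing in `t`; with three it discriminates only weakly. The rule is
designed for several structures (five in the defaults), where the planted
recovery property holds comfortably: on synthetic data with effect size 3
and unit noise, the largest threshold retaining ≥ 80% of planted genes
assigns ≥ 90% of them correctly while picking up ~2–3% of background genes.
The per-structure default thresholds (2.05, 2.35, 2.36, 0.80, 0.75 for
flower, seed, root, shoot, whole plant) are the values the modeled design
chose to obtain sets of over a hundred genes.

Each structure set is split 60/40 (model-build / motif-prediction) with
half-up rounding on `0.6 n`, which reproduces the published set sizes
exactly (138 → 83/55, 147 → 88/59). Unassigned genes are eligible as
background promoters: background sets are drawn from genes outside both
subsets.

## Scanning and the distance features

A PFM is scanned as log-odds against a background composition (by default
the positive set's own base frequencies; pseudocount 0.25 per cell). An
offset is a hit when its score reaches `θ ·` (the maximum achievable score),
with `θ = 0.8` by default. The hit-calling scheme is a design choice — the
modeled study never states one — and `θ` is recorded in every output's
provenance. Hits on the minus strand are reported at the same promoter
coordinate; overlapping hits all count. Distance is measured to the hit's
TLS-proximal edge.

Each promoter is then a `2M`-component vector over the fixed motif order
`[m1+, m1−, …, mM+, mM−]`: the mean hit distance per motif and strand,
divided by `L = 200`, and **0 when the motif is absent on that strand**.
Six motifs give the 12-component vector of the flower model.

Two numerical consequences of this representation matter in practice:

* **Threshold sharpness.** Because the threshold is a fraction of the
  maximum score, a single mismatch in a sharp (near-consensus) motif costs
  several log-units and usually rejects the site. Sites sampled from a PFM
  with consensus probability `p` per column are detected with probability
  close to `p^w`. The simulator's "strong signal" settings use
  `strength = 0.99–0.995` for this reason.
* **The `x ≈ 0` blind spot.** A site touching the TLS produces a feature
  value near 0 — the same value as an absent motif. Discriminative signal
  must therefore sit away from the TLS; the bundled benchmarks plant sites
  in bins 2 and 3. This is a known limitation of the mean-distance
  representation, not of the implementation.

## Motif handling

**Discovery** is a deliberately simple stand-in for external tools: words of
length 6 and 8 are counted on both strands and scored by the z-score of
their count against 50 dinucleotide-shuffled copies of the promoter set
(Euler-path shuffle, exact dinucleotide counts preserved). Top seeds —
skipping words within one mismatch of a chosen seed or its reverse
complement — are expanded to PFMs from all occurrences within one mismatch.
Matrices can equally be supplied in MEME-minimal or JASPAR format.

**Redundancy removal** converts each PFM to a strand-symmetrized k-mer
frequency vector (`k = 4` by default, chosen ≤ the shortest motif width 6;
the components are expected k-mer counts under the independent-column model
for the PFM plus its reverse complement, summing to `2(w − k + 1)`),
builds a Pearson-correlation distance matrix, and clusters by average
linkage. When the number of clusters is "auto" it maximizes the mean
silhouette width over `2..min(10, M−1)`, ties to the smallest k — the
source design reports optimal cluster counts without stating a criterion,
so the criterion here is the package's own choice. Per cluster, the motif
with the smallest **group-specificity score** — the hypergeometric upper
tail `P(X ≥ k)` for `k` of the group's `n` promoters containing the motif
when `K` of all `N` promoters contain it — is retained ("contains" = at
least one hit at the default `θ` on the 200 bp promoter).

**Known/novel calls** align a query to every library motif without gaps
(both orientations, overlap ≥ 4 columns). The column score is the Pearson
correlation of probability columns; the alignment score is the *sum* of
column scores divided by the wider motif's width. The sum (rather than the
mean over the overlap) is deliberate: with mean scoring, a perfect
four-column sub-alignment ties a full-length identity match, and the
empirical null — best score against column-shuffled library motifs,
add-one p-value `(1 + #null ≥ obs) / (1 + n_null)`, `n_null = 1000` —
then cannot certify even a self-match at `p < 0.001`. Two related
safeguards: null permutations that merely swap identical columns (common in
sharp motifs with repeated bases) are redrawn, and the default decoys in
simulated libraries are sharp random-consensus PFMs rather than column
shuffles of planted motifs, because a shuffled anagram in the library lets
the null reassemble the query. Strictly `p < 0.001` means "known";
otherwise the motif is called novel.

## Classifier and patterns

The SVM uses an RBF kernel with `C = 1` and width `γ = 1/(d · var)` over
all feature entries — none of these are stated in the modeled design; all
are configurable and logged. Leave-one-out cross-validation holds out
**every** row, positives and background alike: the published accuracies
exceed the true-positive/positive ratios, which implies both classes
entered the accuracy. True positives (positive promoters predicted
positive) are the material for patterns.

Presence is tabulated over four bins of upstream distance — [0,50),
[50,100), [100,150), [150,200], bin of a hit = bin of its TLS-proximal
edge, last bin closed — on both strands. Cells strictly above the presence
threshold (0.60; 0.50 for the whole-plant set) become the pattern's
required cells, and a promoter satisfies a pattern iff every required cell
has at least one hit (a conjunction; the star/triangle table semantics of
the source are read as required/not-required). Genome-wide prediction first
removes promoters more than 60% identical (ungapped identity over the equal
length; greedy in gene-id order, first kept wins) and then applies the
pattern to every retained 200 bp promoter. An empty pattern is refused in
the genome scan — it would vacuously match every gene.

## The synthetic generator

The generator defines the study conditions rather than adapting to them:

* five structures named flower/seed/root/shoot/whole_plant profiled by
  81/27/21/27/9 samples, structure sets of 138/147/159/154/145 genes
  (all overridable);
* continuous expression, baseline 0, Gaussian noise `sd = 1`, structure
  effect `delta = 3` — the modeled input is normalized microarray
  intensity, so no count model;
* A/T-rich intergenic background (0.33/0.17/0.17/0.33), a realistic null
  for plant promoter scans;
* tandem gene layout with ≥ 500 bp intergenic stretches so every promoter
  window exists and neighbouring windows never overlap;
* one implant per (gene, motif spec), sampled column-wise from the PFM's
  raw count frequencies, placed wholly inside a chosen bin, reverse
  complemented for minus-strand sites; all implants recorded in a truth
  table.

All randomness flows from one master seed through named substreams, so
identical configurations give byte-identical output, and adding a stage
never perturbs another stage's draws.

What the generator does **not** emulate: microarray platform effects,
probe-to-gene mapping, real genome composition (repeats, CpG/CHH context,
actual intergenic length distributions), or correlated expression noise.
Passing the planted-recovery benchmarks therefore demonstrates the
machinery is correct and calibrated on clean signal; it does not promise
comparable accuracy on real plant data, where motif signal is weaker and
background structure richer.

## Problem sizes used by the bundled benchmarks

`recover_planted_pattern()` runs 2 structures × 60 genes plus background
(260 genes total), implant fraction 0.9, 2 decoy motifs, and recovers the
planted cell set with precision and recall 1.0 on typical seeds;
`genome_scan_recovery()` uses 1,000 genes with 50 implanted positives and
reaches sensitivity ≈ 0.92 at zero observed false positives. The test
suite runs the same sizes across five seeds. These sizes are the package's
chosen desk-scale study conditions; the published genome-scale numbers
(tens of thousands of genes, external discovery tools, ontology-based
validation) are outside what synthetic ground truth can reproduce and are
not targets here.

## Known limitations

* The mean-distance feature conflates TLS-adjacent sites with absence
  (`x ≈ 0` blind spot) and discards hit multiplicity beyond the mean.
* Score-fraction hit calling has no p-value calibration; `θ` trades recall
  against precision globally, not per motif.
* The discovery stand-in finds compact over-represented words; it will not
  recover long, soft, or gapped motifs.
* The two-structure degeneracy of the assignment rule (above).
* Patterns are conjunctions; a single absent cell vetoes a promoter, which
  makes patterns brittle when presence fractions sit near the threshold.
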