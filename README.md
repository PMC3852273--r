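# promarch

Modeling the promoter architecture of co-expressed plant genes from the
**position and orientation of transcription-factor binding sites (TFBSs)**
relative to the translation start site (TLS).

## The problem

Genes co-expressed in the same plant structure (flower, seed, root, shoot, or
constitutively in the whole plant) are hypothesized to share a common
promoter organization: the same regulatory motifs, sitting in the same
stretch of the promoter, on the same strand. `promarch` implements a complete
pipeline that turns a normalized expression matrix plus a genome into
testable *motif patterns* — sets of required (motif, bin, strand) cells over
the 200 bp upstream of the TLS — and uses them to predict co-expressed genes
genome-wide:

1. **Structure assignment.** For each gene, average expression per structure;
   assign the gene to its top structure when the gap between the two greatest
   averages exceeds `t · sd(averages)` (per-structure threshold `t`).
2. **60/40 split** of each structure set into a model-build and a
   motif-prediction subset; promoters (50–200 bp upstream of the TLS) are
   extracted strand-aware from the genome.
3. **Motif selection.** De-novo over-represented words (z-score against
   dinucleotide-shuffled promoters) or a supplied motif file; redundancy
   removed by clustering k-mer frequency vectors of the PFMs
   (Pearson-correlation distance, average linkage), keeping per cluster the
   motif with the smallest hypergeometric **group-specificity score**;
   known/novel calls against a reference library at `p < 0.001` under an
   empirical column-shuffle null.
4. **Distance features.** Each promoter is represented by the per-motif,
   per-strand normalized average TFBS distance

   `AVG = (Σ x / n) / L`,

   where `x` is the distance of a hit from the TLS, `n` the number of hits on
   that strand, and `L = 200` bp; an absent motif contributes 0. Six motifs
   give a 12-component vector.
5. **Classification.** An SVM (RBF kernel) separates structure promoters
   from background genomic promoters, evaluated by leave-one-out
   cross-validation.
6. **Pattern building.** True-positive promoters are scanned in four 50 bp
   bins on both strands; cells present in more than 60% of promoters (50%
   for the whole-plant set) form the structure's motif pattern.
7. **Genome-wide prediction.** After removing promoters that are more than
   60% identical, every gene whose 200 bp promoter satisfies all pattern
   cells is predicted as co-expressed in that structure.

A fully deterministic synthetic-data generator (`sim_config()`,
`simulate_study()`) provides ground truth — planted expression groups,
implanted motif sites at chosen bins/strands, decoy motifs — for every stage.

## Worked example

```r
library(promarch)

# a synthetic study: 2 structures, one with two motifs implanted
# mid-promoter (bin 2 on +, bin 3 on -) in 90% of its genes
mA <- consensus_pfm("TGACGT",   id = "pmA", strength = 0.99)
mB <- consensus_pfm("GGATCAGG", id = "pmB", strength = 0.99)
cfg <- sim_config(
  n_genes = 260, ps_names = c("ps1", "ps2"), samples_per_ps = 8,
  genes_per_ps = 60,
  motif_specs = list(
    motif_spec(mA, "ps1", bins = 2, strands = "+", implant_fraction = 0.9),
    motif_spec(mB, "ps1", bins = 3, strands = "-", implant_fraction = 0.9)),
  master_seed = 1)
sim <- simulate_study(cfg, n_decoys = 2)

# features -> LOOCV -> true positives -> pattern, in one call
rec <- recover_planted_pattern(1)
rec$loocv_accuracy
#> [1] 98.61111
rec$pattern
#> <motif_pattern> 2 required cell(s), presence > 0.6
#> # A tibble: 2 × 3
#>   motif   bin strand
#>   <chr> <int> <chr>
#> 1 pmA       2 +
#> 2 pmB       3 -
c(rec$precision, rec$recall)
#> [1] 1 1
```

The leave-one-out accuracy (98.6% of the 72 model-build plus background
promoters classified correctly) mirrors the quality of the planted signal;
the recovered pattern is exactly the implanted cell set, so precision and
recall against the ground truth are both 1.

Genome-wide, with 50 implanted genes among 1,000:

```r
genome_scan_recovery(1)
#> # A tibble: 1 × 8
#>      tp    fp    fn    tn sensitivity precision specificity   fpr
#>   <int> <int> <int> <int>       <dbl>     <dbl>       <dbl> <dbl>
#> 1    46     0     4   950        0.92         1           1     0
```

46 of the 50 implanted genes are rediscovered by the pattern scan (the four
misses carry a sampled site one mismatch away from consensus, which the
log-odds threshold rejects) with no false positives.

For real data, `run_pipeline(pipeline_config(...), out_dir)` chains every
stage from files (genome FASTA, BED6 annotation, expression TSV, sample map,
optional MEME/JASPAR motif libraries) and writes every intermediate plus a
reproducibility manifest; re-running the same configuration reproduces all
outputs byte-identically.

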