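test_that("genome generation is deterministic and respects the configuration", {
  cfg <- sim_config(n_genes = 10, n_chromosomes = 2, ps_names = "ps1",
                    samples_per_ps = 4, genes_per_ps = 5, master_seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$annotations, g2$annotations)
  expect_equal(nrow(g1$annotations), 10)
  expect_setequal(unique(g1$annotations$strand), c("+", "-"))
  # every gene has >= 200 bp upstream on its own strand
  lens <- setNames(Biostrings::width(g1$genome), names(g1$genome))
  up <- ifelse(g1$annotations$strand == "+", g1$annotations$start,
               lens[g1$annotations$chrom] - g1$annotations$end)
  expect_true(all(up >= 200))
})

test_that("degenerate base composition gives an all-A intergenic genome", {
  cfg <- sim_config(n_genes = 4, n_chromosomes = 1,
                    base_composition = c(A = 1, C = 0, G = 0, T = 0),
                    ps_names = "ps1", samples_per_ps = 2, genes_per_ps = 2,
                    master_seed = 3)
  g <- generate_genome(cfg)
  expect_equal(unname(Biostrings::letterFrequency(g$genome, "A")[1, 1]),
               Biostrings::width(g$genome)[1])
})

test_that("generated base frequencies track the configured composition", {
  cfg <- sim_config(n_genes = 12, n_chromosomes = 1, master_seed = 7,
                    ps_names = "ps1", samples_per_ps = 2, genes_per_ps = 4)
  g <- generate_genome(cfg)
  freqs <- Biostrings::letterFrequency(g$genome, c("A", "C", "G", "T"))[1, ] /
    Biostrings::width(g$genome)[1]
  expect_true(all(abs(freqs - cfg$base_composition) < 0.03))
})

test_that("expression matrix has planted group structure and the right shape", {
  cfg <- sim_config(n_genes = 300, n_chromosomes = 1,
                    ps_names = c("flower", "seed", "root", "shoot", "whole_plant"),
                    samples_per_ps = c(81, 27, 21, 27, 9),
                    genes_per_ps = 40, master_seed = 11)
  g <- generate_genome(cfg)
  ex <- generate_expression(g$annotations, cfg)
  expect_equal(ncol(ex$expression) - 1L, 81 + 27 + 21 + 27 + 9)
  expect_equal(nrow(ex$expression), 300)

  # delta = 3, noise 1: every labeled gene's own-structure mean is the largest
  pa <- ps_average(ex$expression, ex$sample_map)
  m <- as.matrix(pa[setdiff(names(pa), "gene")])
  labs <- ex$labels$structure[match(pa$gene, ex$labels$gene)]
  planted <- labs != "background"
  argmax <- colnames(m)[max.col(m)]
  expect_true(all(argmax[planted] == labs[planted]))
})

test_that("null expression (delta = 0) shows no group separation", {
  cfg <- sim_config(n_genes = 200, n_chromosomes = 1, ps_names = c("a", "b"),
                    samples_per_ps = c(10, 10), genes_per_ps = 50,
                    effect_size_delta = 0, master_seed = 5)
  g <- generate_genome(cfg)
  ex <- generate_expression(g$annotations, cfg)
  m <- as.matrix(ex$expression[-1])
  in_a <- ex$sample_map$structure == "a"
  p <- apply(m, 1, function(r) stats::t.test(r[in_a], r[!in_a])$p.value)
  expect_lt(mean(p < 0.01), 0.04)
})

test_that("implants are recorded, rescannable, and only touch promoter windows", {
  # strength 1 makes every sampled site the exact consensus, so the rescan
  # check is about implant bookkeeping, not scan-threshold softness
  cfg <- small_planted_config(master_seed = 2, implant_fraction = 1.0,
                              n_genes = 60, genes_per_ps = 15, strength = 1)
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)

  impl <- imp$truth$implants
  expect_true(all(impl$gene %in% ex$labels$gene[ex$labels$structure != "background"]))
  w <- nchar(impl$site)
  expect_true(all(impl$offset >= 0 & impl$offset + w <= 200))

  # every plus-strand implanted promoter has a hit inside its recorded bin
  m1 <- cfg$motif_specs[[1]]$pfm
  b1 <- impl[impl$motif == "pm1", ]
  prom <- extract_promoters(gen$annotations, imp$genome, genes = b1$gene)
  params <- scan_params(theta = 0.6)  # permissive rescan
  bins <- bin_scheme()
  ok <- vapply(seq_len(nrow(b1)), function(r) {
    h <- scan_promoter(m1, prom$seq[prom$gene == b1$gene[r]], params)
    lo <- bins$lo[b1$bin[r]]; hi <- bins$hi[b1$bin[r]]
    any(h$strand == "+" & h$x >= lo & h$x < hi)
  }, TRUE)
  expect_true(all(ok))

  # conservation: bases outside promoter windows are unchanged
  ann <- gen$annotations
  changed <- which(strsplit(as.character(imp$genome[["chr1"]]), "")[[1]] !=
                   strsplit(as.character(gen$genome[["chr1"]]), "")[[1]])
  wins <- ann[ann$chrom == "chr1", ]
  in_window <- function(pos0) {
    any((wins$strand == "+" & pos0 >= wins$start - 200 & pos0 < wins$start) |
        (wins$strand == "-" & pos0 >= wins$end & pos0 < wins$end + 200))
  }
  expect_true(all(vapply(changed - 1L, in_window, TRUE)))
})

test_that("minus-strand implants appear reverse-complemented on the promoter", {
  m <- consensus_pfm("ACGGT", id = "m", strength = 1)
  expect_error(pfm(matrix(1, 4, 3)), "width")
  cfg <- sim_config(n_genes = 20, n_chromosomes = 1, ps_names = "ps1",
                    samples_per_ps = 3, genes_per_ps = 5,
                    motif_specs = list(motif_spec(consensus_pfm("ACGGT", "m", 1),
                                                  "ps1", bins = 2, strands = "-")),
                    master_seed = 9)
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)
  impl <- imp$truth$implants
  prom <- extract_promoters(gen$annotations, imp$genome, genes = impl$gene)
  for (r in seq_len(nrow(impl))) {
    s <- prom$seq[prom$gene == impl$gene[r]]
    x <- impl$offset[r]; w <- nchar(impl$site[r])
    window <- substr(s, 200 - x - w + 1, 200 - x)
    expect_equal(window, revcomp(impl$site[r]))
  }
})

test_that("implant_fraction = 0 leaves the genome untouched", {
  cfg <- small_planted_config(master_seed = 4, implant_fraction = 0,
                              n_genes = 40, genes_per_ps = 10)
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)
  expect_identical(as.character(imp$genome), as.character(gen$genome))
  expect_equal(nrow(imp$truth$implants), 0)
})

test_that("motif library combines planted and decoy matrices deterministically", {
  planted <- list(consensus_pfm("TACGTA", "a"), consensus_pfm("GGATCC", "b"),
                  consensus_pfm("CCCGGG", "c"))
  lib1 <- make_motif_library(planted, n_decoys = 7, seed = 5, method = "shuffle")
  lib2 <- make_motif_library(planted, n_decoys = 7, seed = 5, method = "shuffle")
  expect_length(lib1, 10)
  expect_identical(lib1, lib2)
  # decoys are column permutations: same column multiset as their source
  d1 <- lib1[[4]]
  src <- planted[[1]]
  cols <- function(m) sort(apply(m$counts, 2, paste, collapse = ","))
  expect_identical(cols(d1), cols(src))
  expect_error(make_motif_library(list(), 0), "empty")
})

test_that("label/expression consistency holds across seeds at delta = 3 sd", {
  hit_rates <- vapply(1:5, function(sd) {
    cfg <- sim_config(n_genes = 120, n_chromosomes = 1,
                      ps_names = c("a", "b", "c"), samples_per_ps = 8,
                      genes_per_ps = 25, master_seed = sd)
    gen <- generate_genome(cfg)
    ex <- generate_expression(gen$annotations, cfg)
    pa <- ps_average(ex$expression, ex$sample_map)
    m <- as.matrix(pa[c("a", "b", "c")])
    labs <- ex$labels$structure[match(pa$gene, ex$labels$gene)]
    planted <- labs != "background"
    mean(colnames(m)[max.col(m)][planted] == labs[planted])
  }, 0)
  expect_true(all(hit_rates >= 0.95))
})
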