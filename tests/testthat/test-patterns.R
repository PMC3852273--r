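test_that("presence fractions equal a manual count on hand-built promoters", {
  m <- consensus_pfm("ACGTAC", "m", strength = 1, pseudocount = 0)
  params <- scan_params(theta = 1)
  base <- strrep("T", 200)
  put <- function(s, x, site = "ACGTAC") {
    # place the site so its TLS-proximal edge sits at distance x
    w <- nchar(site)
    substr(s, 200 - x - w + 1, 200 - x) <- site
    s
  }
  seqs <- c(
    put(base, 10),                     # bin 1, +
    put(base, 60),                     # bin 2, +
    put(put(base, 10), 70),            # bins 1 and 2, +
    put(base, 120, revcomp("ACGTAC")), # bin 3, -
    base                               # nothing
  )
  prom <- tibble::tibble(gene = paste0("g", 1:5), seq = seqs, L = 200L,
                         width = 200L, strand = "+", truncated = FALSE)
  pres <- bin_presence(prom, list(m), params)
  get <- function(b, s) pres$fraction[pres$bin == b & pres$strand == s]
  expect_equal(get(1, "+"), 2 / 5)
  expect_equal(get(2, "+"), 2 / 5)
  expect_equal(get(3, "-"), 1 / 5)
  expect_equal(get(4, "+"), 0)
  expect_equal(sum(pres$n_with_hit), 5)

  # a saturated cell: implant for every promoter
  prom_sat <- prom
  prom_sat$seq <- vapply(prom$seq, put, "", x = 30, USE.NAMES = FALSE)
  pres_sat <- bin_presence(prom_sat, list(m), params)
  expect_equal(pres_sat$fraction[pres_sat$bin == 1 & pres_sat$strand == "+"], 1)

  # no hits anywhere
  prom_null <- prom
  prom_null$seq <- rep(strrep("G", 200), 5)
  pres_null <- bin_presence(prom_null, list(m), params)
  expect_true(all(pres_null$fraction == 0))
})

test_that("patterns keep cells strictly above the threshold", {
  pres <- tibble::tibble(
    motif = "m", bin = c(1L, 2L, 3L, 4L), strand = "+",
    n_with_hit = c(6L, 7L, 3L, 5L), fraction = c(0.60, 0.70, 0.30, 0.55)
  )
  attr(pres, "n_promoters") <- 10L
  p60 <- build_pattern(pres, 0.6)
  expect_equal(nrow(p60$cells), 1)     # exactly 0.60 is excluded
  expect_equal(p60$cells$bin, 2L)
  p50 <- build_pattern(pres, 0.5)
  expect_setequal(p50$cells$bin, c(1L, 2L, 4L))  # 0.55 included at 0.50
  expect_warning(build_pattern(pres, 0.95), "empty")
})

test_that("pattern matching is a conjunction over required cells", {
  # m2 must not be palindromic or the wrong-strand case would still match
  m1 <- consensus_pfm("ACGTAC", "m1", strength = 1, pseudocount = 0)
  m2 <- consensus_pfm("GGATCA", "m2", strength = 1, pseudocount = 0)
  params <- scan_params(theta = 1)
  cells <- tibble::tibble(motif = c("m1", "m2"), bin = c(1L, 3L),
                          strand = c("+", "-"))
  pattern <- promarch:::new_motif_pattern(cells, 0.6, list(m1, m2), 10L,
                                          params = params)
  base <- strrep("T", 200)
  withsite <- function(s, x, site) {
    substr(s, 200 - x - nchar(site) + 1, 200 - x) <- site
    s
  }
  good <- withsite(withsite(base, 20, "ACGTAC"), 120, revcomp("GGATCA"))
  expect_true(match_pattern(good, pattern))
  # missing one required cell
  partial <- withsite(base, 20, "ACGTAC")
  expect_false(match_pattern(partial, pattern))
  # right motifs, wrong bin
  wrongbin <- withsite(withsite(base, 80, "ACGTAC"), 120, revcomp("GGATCA"))
  expect_false(match_pattern(wrongbin, pattern))
  # wrong strand
  wrongstrand <- withsite(withsite(base, 20, "ACGTAC"), 120, "GGATCA")
  expect_false(match_pattern(wrongstrand, pattern))
  # short promoters never match; empty patterns match vacuously
  expect_false(match_pattern(strrep("A", 100), pattern))
  empty <- promarch:::new_motif_pattern(cells[0, ], 0.6, list(), 0L)
  expect_true(match_pattern(base, empty))
})

test_that("the similarity filter drops promoters above the identity cutoff", {
  a <- strrep("ACGT", 50)
  prom <- tibble::tibble(gene = c("g1", "g2"), seq = c(a, a), L = 200L,
                         width = 200L, strand = "+", truncated = FALSE)
  kept <- similarity_filter(prom)
  expect_equal(kept$gene, "g1")
  expect_equal(attr(kept, "dropped"), "g2")

  # constructed boundary: 122/200 = 0.61 dropped, 118/200 = 0.59 kept
  aa <- strrep("A", 200)
  b61 <- paste0(strrep("A", 122), strrep("C", 78))
  b59 <- paste0(strrep("A", 118), strrep("C", 82))
  mean_id <- function(x, y) mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  expect_equal(mean_id(aa, b61), 0.61)
  expect_equal(mean_id(aa, b59), 0.59)
  prom2 <- tibble::tibble(gene = c("g1", "g2", "g3"), seq = c(aa, b61, b59),
                          L = 200L, width = 200L, strand = "+", truncated = FALSE)
  kept2 <- similarity_filter(prom2, cutoff = 0.60)
  expect_setequal(kept2$gene, c("g1", "g3"))

  # independent random promoters under the default composition survive
  for (sd in 1:5) {
    pr <- random_promoters(30, L = 200, seed = 700 + sd)
    expect_equal(nrow(similarity_filter(pr)), 30)
  }
})

test_that("confusion-matrix rates follow the standard definitions", {
  truth <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                          structure = rep(c("ps1", "background"), c(10, 90)))
  pos <- truth$gene[1:10]
  perfect <- evaluate_predictions(pos, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$specificity, 1)
  none <- evaluate_predictions(character(0), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  mixed <- evaluate_predictions(c(pos[1:8], truth$gene[11:12]), truth)
  expect_equal(mixed$tp, 8); expect_equal(mixed$fp, 2)
  expect_equal(mixed$fn, 2); expect_equal(mixed$tn, 88)
  expect_equal(mixed$sensitivity, 0.8)
  expect_equal(mixed$precision, 0.8)
  expect_error(evaluate_predictions("nope", truth), "missing")
})

test_that("pattern monotonicity: higher thresholds shrink, more cells match less", {
  cfg <- small_planted_config(master_seed = 3, implant_fraction = 1,
                              n_genes = 80, genes_per_ps = 20)
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)
  pos <- extract_promoters(gen$annotations, imp$genome,
                           genes = sort(ex$labels$gene[ex$labels$structure == "ps1"]))
  motifs <- imp$truth$planted_pfms
  params <- scan_params(theta = 0.8)
  pres <- bin_presence(pos, motifs, params)
  thresholds <- c(0.3, 0.5, 0.7, 0.9)
  sizes <- vapply(thresholds, function(t)
    nrow(suppressWarnings(build_pattern(pres, t, motifs))$cells), 0L)
  expect_true(all(diff(sizes) <= 0))

  # adding required cells never increases genome-scan matches
  p1 <- build_pattern(pres, 0.6, motifs)
  expect_gte(nrow(p1$cells), 1)
  scan1 <- genome_scan(imp$genome, gen$annotations, p1, params)
  extra <- tibble::tibble(motif = motifs[[1]]$id, bin = 4L, strand = "-")
  p2 <- promarch:::new_motif_pattern(dplyr::bind_rows(p1$cells, extra),
                                     p1$threshold, motifs, p1$n_promoters,
                                     params = params)
  scan2 <- genome_scan(imp$genome, gen$annotations, p2, params)
  expect_lte(sum(scan2$matched), sum(scan1$matched))
  expect_error(genome_scan(imp$genome, gen$annotations,
                           promarch:::new_motif_pattern(p1$cells[0, ], 0.6,
                                                        list(), 0L), params),
               "empty pattern")
})

test_that("pattern soundness: the source set matches at a rate above the threshold", {
  cfg <- small_planted_config(master_seed = 11, implant_fraction = 0.95,
                              n_genes = 80, genes_per_ps = 25)
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)
  pos <- extract_promoters(gen$annotations, imp$genome,
                           genes = sort(ex$labels$gene[ex$labels$structure == "ps1"]))
  motifs <- imp$truth$planted_pfms
  params <- scan_params(theta = 0.8)
  pres <- bin_presence(pos, motifs, params)
  pattern <- build_pattern(pres, 0.6, motifs)
  rate <- mean(vapply(pos$seq, match_pattern, TRUE, pattern = pattern,
                      params = params))
  expect_gte(rate, 0.6)
})

test_that("pattern files round-trip with provenance", {
  cells <- tibble::tibble(motif = c("m1", "m2"), bin = c(1L, 3L),
                          strand = c("+", "-"))
  motifs <- list(consensus_pfm("ACGTAC", "m1"), consensus_pfm("GGATCC", "m2"))
  pat <- promarch:::new_motif_pattern(cells, 0.6, motifs, 42L,
                                      structure = "flower")
  f <- withr::local_tempfile(fileext = ".txt")
  write_pattern(pat, f)
  back <- read_pattern(f, motifs)
  expect_equal(back$cells, pat$cells)
  expect_equal(back$threshold, 0.6)
  expect_equal(back$n_promoters, 42L)
  expect_equal(back$structure, "flower")
})
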