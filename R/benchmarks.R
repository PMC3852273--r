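#' Planted-pattern recovery benchmark
#'
#' Runs the pattern-building chain end to end on a synthetic study with known
#' ground truth: two structure gene groups plus background, two motifs
#' implanted in the first structure's promoters at fixed (bin, strand) cells,
#' and decoy motifs in the scanned motif set. The chain is: 60/40 split of
#' the structure's genes, promoter extraction, distance features over planted
#' plus decoy motifs, SVM leave-one-out cross-validation, presence table over
#' the true-positive promoters, pattern at the presence threshold. Recovery
#' is scored against the planted (motif, bin, strand) cells.
#'
#' @param master_seed integer seed driving the whole run
#' @param n_genes genome size (genes)
#' @param genes_per_ps genes per planted structure
#' @param implant_fraction fraction of the structure's genes implanted
#' @param n_decoys decoy motifs added to the scanned motif set
#' @param threshold presence threshold for the pattern
#' @param theta scan threshold fraction
#' @param strength consensus sharpness of the planted PFMs
#' @return list: `pattern`, `planted_cells`, `precision`, `recall`,
#'   `loocv_accuracy`, `n_true_positives`
#' @export
recover_planted_pattern <- function(master_seed, n_genes = 260L,
                                    genes_per_ps = 60L,
                                    implant_fraction = 0.9, n_decoys = 2L,
                                    threshold = 0.6, theta = 0.8,
                                    strength = 0.99) {
  mA <- consensus_pfm("TGACGT", id = "pmA", strength = strength)
  mB <- consensus_pfm("GGATCAGG", id = "pmB", strength = strength)
  planted_cells <- tibble::tibble(motif = c("pmA", "pmB"), bin = c(2L, 3L),
                                  strand = c("+", "-"))
  cfg <- sim_config(
    n_genes = n_genes, n_chromosomes = 2L,
    ps_names = c("ps1", "ps2"), samples_per_ps = 8L,
    genes_per_ps = genes_per_ps,
    motif_specs = list(
      motif_spec(mA, "ps1", bins = 2L, strands = "+",
                 implant_fraction = implant_fraction),
      motif_spec(mB, "ps1", bins = 3L, strands = "-",
                 implant_fraction = implant_fraction)
    ),
    master_seed = master_seed
  )
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)

  split <- split_sets(dplyr::filter(ex$labels, .data$structure == "ps1"),
                      seed = substream_seed(master_seed, "split"))
  mb <- sort(split$gene[split$role == "model_build"])
  pos <- extract_promoters(gen$annotations, imp$genome, genes = mb)
  bg <- sample_background(gen$annotations, imp$genome,
                          exclude = ex$labels$gene[ex$labels$structure != "background"],
                          m = length(mb),
                          seed = substream_seed(master_seed, "background"))
  motifs <- c(list(mA, mB),
              make_motif_library(list(), n_decoys,
                                 seed = substream_seed(master_seed, "decoys")))
  params <- scan_params(bg = base_composition(pos$seq), theta = theta)
  tm <- build_training_matrix(pos, bg, motifs, params)
  cv <- svm_loocv(tm)
  tp <- true_positives(cv)
  prom_tp <- pos[pos$gene %in% tp, ]
  presence <- bin_presence(prom_tp, motifs, params)
  pattern <- suppressWarnings(build_pattern(presence, threshold, motifs))

  key <- function(d) paste(d$motif, d$bin, d$strand)
  hit <- key(pattern$cells) %in% key(planted_cells)
  precision <- if (nrow(pattern$cells) == 0) 0 else mean(hit)
  recall <- mean(key(planted_cells) %in% key(pattern$cells))
  list(pattern = pattern, planted_cells = planted_cells,
       precision = precision, recall = recall,
       loocv_accuracy = cv$accuracy, n_true_positives = length(tp))
}

#' Genome-wide pattern-scan recovery benchmark
#'
#' Builds a synthetic genome in which a subset of genes carries two motifs
#' implanted at fixed (bin, strand) promoter cells, then scans the whole
#' genome with the planted pattern (after the promoter similarity filter) and
#' scores the predictions against the planted labels.
#'
#' @param master_seed integer seed driving the whole run
#' @param n_genes genome size (genes)
#' @param n_pos implanted (positive) genes
#' @param theta scan threshold fraction
#' @param strength consensus sharpness of the planted PFMs; the default is a
#'   strong, near-consensus signal
#' @return one-row tibble: sensitivity, precision, specificity, fpr, plus
#'   counts
#' @export
genome_scan_recovery <- function(master_seed, n_genes = 1000L, n_pos = 50L,
                                 theta = 0.8, strength = 0.995) {
  mA <- consensus_pfm("TGACGT", id = "pmA", strength = strength)
  mB <- consensus_pfm("GGATCAGG", id = "pmB", strength = strength)
  cfg <- sim_config(
    n_genes = n_genes, n_chromosomes = 2L, ps_names = "ps1",
    samples_per_ps = 2L, genes_per_ps = n_pos,
    motif_specs = list(
      motif_spec(mA, "ps1", bins = 2L, strands = "+", implant_fraction = 1),
      motif_spec(mB, "ps1", bins = 3L, strands = "-", implant_fraction = 1)
    ),
    master_seed = master_seed
  )
  gen <- generate_genome(cfg)
  ex <- generate_expression(gen$annotations, cfg)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, cfg)
  cells <- tibble::tibble(motif = c("pmA", "pmB"), bin = c(2L, 3L),
                          strand = c("+", "-"))
  params <- scan_params(bg = cfg$base_composition, theta = theta)
  pattern <- new_motif_pattern(cells, threshold = 0.6, motifs = list(mA, mB),
                               n_promoters = n_pos, params = params)
  scan <- genome_scan(imp$genome, gen$annotations, pattern, params)
  predicted <- scan$gene[scan$matched]
  ev <- evaluate_predictions(predicted, ex$labels)
  dplyr::mutate(ev, fpr = 1 - .data$specificity)
}
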