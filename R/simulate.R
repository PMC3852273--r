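#' Simulation configuration
#'
#' Defines the conditions under which synthetic genomes, expression matrices
#' and implanted motif sites are generated. Defaults mirror the study design
#' the package models: five plant structures (flower, seed, root, shoot,
#' whole plant) profiled by 81/27/21/27/9 arrays, structure sets of
#' 138/147/159/154/145 genes, continuous normalized expression (baseline 0)
#' with Gaussian noise, and A/T-rich intergenic sequence typical of plant
#' promoters.
#'
#' @param n_genes number of genes in the genome
#' @param n_chromosomes number of chromosomes genes are spread over
#' @param intergenic_len bp of intergenic sequence before every gene and at
#'   each chromosome end; must be >= 200 so that every gene has a full
#'   200 bp promoter (>= 400 keeps neighbouring promoters disjoint)
#' @param gene_len bp of gene body
#' @param base_composition named probabilities for A, C, G, T; must sum to 1
#' @param ps_names plant-structure names
#' @param samples_per_ps number of expression samples per structure
#' @param genes_per_ps number of genes whose expression is elevated in each
#'   structure; the remainder are background genes
#' @param effect_size_delta expression elevation of a structure gene in its
#'   own structure's samples
#' @param noise_sd Gaussian noise standard deviation
#' @param motif_specs list of [motif_spec()] describing sites to implant
#' @param master_seed integer; every random draw flows from this through
#'   named substreams (see [substream_seed()])
#' @return a `sim_config` list
#' @export
sim_config <- function(n_genes = 2000,
                       n_chromosomes = 2,
                       intergenic_len = 500,
                       gene_len = 300,
                       base_composition = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33),
                       ps_names = c("flower", "seed", "root", "shoot", "whole_plant"),
                       samples_per_ps = c(81, 27, 21, 27, 9),
                       genes_per_ps = c(138, 147, 159, 154, 145),
                       effect_size_delta = 3,
                       noise_sd = 1,
                       motif_specs = list(),
                       master_seed = 1L) {
  stopifnot(n_genes >= 1, n_chromosomes >= 1, gene_len >= 1)
  if (intergenic_len < 200)
    stop("intergenic_len must be >= 200 so every gene has a 200 bp promoter")
  if (abs(sum(base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1")
  if (length(base_composition) != 4) stop("base_composition needs 4 entries")
  if (length(samples_per_ps) == 1)
    samples_per_ps <- rep(samples_per_ps, length(ps_names))
  if (length(genes_per_ps) == 1)
    genes_per_ps <- rep(genes_per_ps, length(ps_names))
  stopifnot(length(samples_per_ps) == length(ps_names),
            length(genes_per_ps) == length(ps_names))
  if (any(samples_per_ps < 1)) stop("every structure needs at least 1 sample")
  if (sum(genes_per_ps) > n_genes)
    stop("sum(genes_per_ps) exceeds n_genes")
  if (n_chromosomes > n_genes)
    stop("more chromosomes than genes: reduce n_chromosomes")
  for (sp in motif_specs) {
    if (!inherits(sp, "motif_spec")) stop("motif_specs must be motif_spec() objects")
    if (!sp$target_ps %in% ps_names)
      stop("motif_spec targets unknown structure '", sp$target_ps, "'")
  }
  names(base_composition) <- BASES
  structure(list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    intergenic_len = as.integer(intergenic_len), gene_len = as.integer(gene_len),
    base_composition = base_composition, ps_names = ps_names,
    samples_per_ps = as.integer(samples_per_ps),
    genes_per_ps = as.integer(genes_per_ps),
    effect_size_delta = effect_size_delta, noise_sd = noise_sd,
    motif_specs = motif_specs, master_seed = as.integer(master_seed)
  ), class = "sim_config")
}

#' Motif implantation specification
#'
#' One planted motif: which structure's genes receive a site, in which
#' positional bins and on which strands, and for what fraction of the
#' structure's genes.
#'
#' @param pfm a [pfm()]; sites are sampled column-wise from its probabilities
#' @param target_ps structure whose genes receive sites
#' @param bins subset of 1:4 (50 bp promoter bins, bin 1 = TLS-proximal)
#' @param strands subset of c("+", "-")
#' @param implant_fraction fraction of the structure's genes implanted
#' @export
motif_spec <- function(pfm, target_ps, bins = 1L, strands = "+",
                       implant_fraction = 1) {
  stopifnot(inherits(pfm, "pfm"))
  if (!all(bins %in% 1:4)) stop("bins must be a subset of 1:4")
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' and/or '-'")
  if (implant_fraction < 0 || implant_fraction > 1)
    stop("implant_fraction must lie in [0, 1]")
  structure(list(pfm = pfm, target_ps = target_ps, bins = as.integer(bins),
                 strands = strands, implant_fraction = implant_fraction),
            class = "motif_spec")
}

#' Generate a synthetic genome and gene annotation
#'
#' Genes are laid out in tandem (`intergenic_len` bp before each gene body,
#' plus a trailing intergenic stretch), so every gene — on either strand —
#' has at least `intergenic_len` bp of upstream sequence. Strands are drawn
#' at random. Fully deterministic for a fixed `master_seed`.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotations` (tibble: chrom, start, end, gene, score, strand; BED-style
#'   0-based half-open coordinates)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  per_chrom <- rep(n %/% config$n_chromosomes, config$n_chromosomes)
  extra <- n %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  unit <- config$intergenic_len + config$gene_len

  strands <- withr::with_seed(
    substream_seed(config$master_seed, "strand"),
    sample(c("+", "-"), n, replace = TRUE))

  seqs <- character(config$n_chromosomes)
  ann <- vector("list", config$n_chromosomes)
  gi <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    nc <- per_chrom[ci]
    clen <- nc * unit + config$intergenic_len
    seqs[ci] <- withr::with_seed(
      substream_seed(config$master_seed, paste0("chrom", ci)),
      paste(sample(BASES, clen, replace = TRUE,
                   prob = config$base_composition), collapse = ""))
    starts <- config$intergenic_len + (seq_len(nc) - 1L) * unit
    ann[[ci]] <- tibble::tibble(
      chrom = paste0("chr", ci),
      start = starts,
      end = starts + config$gene_len,
      gene = sprintf("g%05d", gi + seq_len(nc)),
      score = 0L,
      strand = strands[gi + seq_len(nc)]
    )
    gi <- gi + nc
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chromosomes))
  list(genome = genome, annotations = dplyr::bind_rows(ann))
}

#' Generate a synthetic expression matrix with planted structure groups
#'
#' Each structure's planted genes have mean expression elevated by
#' `effect_size_delta` in that structure's samples; all values carry Gaussian
#' noise with `noise_sd`.
#'
#' @param annotations annotation tibble from [generate_genome()]
#' @param config a [sim_config()]
#' @return list with `expression` (tibble: gene + one column per sample),
#'   `sample_map` (tibble: sample, structure) and `labels` (tibble: gene,
#'   structure, with "background" for unplanted genes)
#' @export
generate_expression <- function(annotations, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotations$gene
  n <- length(genes)
  ps <- config$ps_names
  labels <- rep("background", n)
  withr::with_seed(substream_seed(config$master_seed, "labels"), {
    pool <- sample(n)
    off <- 0L
    for (i in seq_along(ps)) {
      k <- config$genes_per_ps[i]
      if (k > 0) labels[pool[(off + 1):(off + k)]] <- ps[i]
      off <- off + k
    }
  })
  sample_names <- unlist(lapply(seq_along(ps), function(i)
    sprintf("%s_%02d", ps[i], seq_len(config$samples_per_ps[i]))))
  sample_ps <- rep(ps, config$samples_per_ps)
  m <- withr::with_seed(
    substream_seed(config$master_seed, "expression"),
    matrix(stats::rnorm(n * length(sample_names), 0, config$noise_sd),
           nrow = n))
  for (i in seq_along(ps)) {
    rows <- labels == ps[i]
    cols <- sample_ps == ps[i]
    m[rows, cols] <- m[rows, cols] + config$effect_size_delta
  }
  colnames(m) <- sample_names
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(m))
  list(expression = expr,
       sample_map = tibble::tibble(sample = sample_names, structure = sample_ps),
       labels = tibble::tibble(gene = genes, structure = labels))
}

# upstream promoter window of one gene in genomic 0-based half-open coords
promoter_window <- function(start, end, strand, L) {
  if (strand == "+") c(start - L, start) else c(end, end + L)
}

#' Implant motif sites into promoters
#'
#' For each [motif_spec()], a fraction of the target structure's genes gets
#' one site sampled column-wise from the spec's PFM, written into the 200 bp
#' promoter at a uniformly random offset wholly inside a randomly chosen
#' target bin. Minus-strand sites are reverse-complemented before writing.
#' Only bases inside promoter windows are ever rewritten.
#'
#' @param genome [Biostrings::DNAStringSet] from [generate_genome()]
#' @param annotations annotation tibble
#' @param labels gene-to-structure tibble from [generate_expression()]
#' @param config a [sim_config()]
#' @param L promoter length used for implant coordinates (200)
#' @return list with modified `genome` and `truth` (list: `labels`,
#'   `implants` tibble (gene, motif, bin, strand, offset, site),
#'   `planted_pfms`)
#' @export
implant_sites <- function(genome, annotations, labels, config, L = 200L) {
  stopifnot(inherits(config, "sim_config"))
  bins <- bin_scheme()
  recs <- list()
  ann <- annotations
  rownames_ann <- stats::setNames(seq_len(nrow(ann)), ann$gene)
  for (si in seq_along(config$motif_specs)) {
    sp <- config$motif_specs[[si]]
    w <- pfm_width(sp$pfm)
    if (w > 50) stop("motif '", sp$pfm$id, "' is wider than a 50 bp bin")
    for (b in sp$bins) {
      if (bins$hi[b] - w < bins$lo[b])
        stop("motif '", sp$pfm$id, "' (width ", w,
             ") cannot fit wholly inside bin ", b)
    }
    targets <- sort(labels$gene[labels$structure == sp$target_ps])
    n_impl <- round_half_up(sp$implant_fraction * length(targets))
    if (n_impl == 0) next
    seed <- substream_seed(config$master_seed, paste0("implant", si))
    recs[[si]] <- withr::with_seed(seed, {
      chosen <- sort(sample(targets, n_impl))
      purrr::map_dfr(chosen, function(g) {
        b <- if (length(sp$bins) == 1) sp$bins else sample(sp$bins, 1)
        s <- if (length(sp$strands) == 1) sp$strands else sample(sp$strands, 1)
        x <- sample(seq(bins$lo[b], bins$hi[b] - w), 1)
        tibble::tibble(gene = g, motif = sp$pfm$id, bin = as.integer(b),
                       strand = s, offset = as.integer(x),
                       site = sample_site(sp$pfm))
      })
    })
  }
  implants <- dplyr::bind_rows(recs)
  if (nrow(implants) > 0) {
    for (r in seq_len(nrow(implants))) {
      i <- rownames_ann[[implants$gene[r]]]
      w <- nchar(implants$site[r])
      x <- implants$offset[r]
      site <- implants$site[r]
      # promoter-local window [L-x-w, L-x) holds the site text
      text <- if (implants$strand[r] == "+") site else revcomp(site)
      if (ann$strand[i] == "+") {
        g0 <- ann$start[i] - x - w          # genomic 0-based start
      } else {
        g0 <- ann$end[i] + x
        text <- revcomp(text)
      }
      chrom <- ann$chrom[i]
      ch <- genome[[chrom]]
      Biostrings::subseq(ch, g0 + 1L, g0 + w) <- Biostrings::DNAString(text)
      genome[[chrom]] <- ch
    }
  }
  list(genome = genome,
       truth = list(labels = labels, implants = implants,
                    planted_pfms = lapply(config$motif_specs, `[[`, "pfm")))
}

#' Build a motif library of planted PFMs plus decoys
#'
#' Decoys are either sharp PFMs around random consensus words (default) or
#' column permutations of the planted PFMs (same column multiset, different
#' positional arrangement). Random decoys are the default because a
#' column-permuted decoy is an anagram of its source: a column-shuffle null,
#' as used by [compare_motifs()], can then reassemble the source exactly,
#' which inflates self-match p-values.
#'
#' @param planted list of [pfm()] (ids preserved)
#' @param n_decoys number of decoy PFMs to append
#' @param seed integer seed
#' @param method `"shuffle"` (column permutation) or `"random"`
#' @param decoy_width width of random decoys
#' @return list of [pfm()] of length `length(planted) + n_decoys`
#' @export
make_motif_library <- function(planted, n_decoys, seed = 1L,
                               method = c("random", "shuffle"),
                               decoy_width = 8L) {
  method <- match.arg(method)
  if (length(planted) == 0 && n_decoys == 0)
    stop("empty library: no planted motifs and no decoys requested")
  if (n_decoys < 0) stop("n_decoys must be >= 0")
  if (length(planted) == 0) method <- "random"
  decoys <- withr::with_seed(seed, lapply(seq_len(n_decoys), function(i) {
    if (method == "shuffle") {
      base <- planted[[(i - 1L) %% length(planted) + 1L]]
      w <- pfm_width(base)
      perm <- sample(w)
      while (w > 1 && all(perm == seq_len(w))) perm <- sample(w)
      pfm(base$counts[, perm, drop = FALSE],
          id = sprintf("decoy_%02d", i), pseudocount = base$pseudocount)
    } else {
      consensus_pfm(paste(sample(BASES, decoy_width, replace = TRUE),
                          collapse = ""),
                    id = sprintf("decoy_%02d", i))
    }
  }))
  c(planted, decoys)
}

#' Run the full simulator
#'
#' Convenience wrapper: genome, expression, implants and motif library in one
#' call, all driven by `config$master_seed`.
#'
#' @inheritParams generate_genome
#' @param n_decoys decoys appended to the planted motif library
#' @return list: `genome`, `annotations`, `expression`, `sample_map`,
#'   `truth`, `library`
#' @export
simulate_study <- function(config, n_decoys = 0L) {
  gen <- generate_genome(config)
  ex <- generate_expression(gen$annotations, config)
  imp <- implant_sites(gen$genome, gen$annotations, ex$labels, config)
  lib <- if (length(imp$truth$planted_pfms) > 0 || n_decoys > 0) {
    make_motif_library(imp$truth$planted_pfms, n_decoys,
                       seed = substream_seed(config$master_seed, "library"))
  } else list()
  list(genome = imp$genome, annotations = gen$annotations,
       expression = ex$expression, sample_map = ex$sample_map,
       truth = imp$truth, library = lib)
}

#' Write a simulated study to disk
#'
#' Writes genome FASTA, BED6 annotation, expression and sample-map TSVs, the
#' planted-truth sidecar TSVs, and the motif library in MEME minimal format.
#'
#' @param sim result of [simulate_study()]
#' @param dir output directory (created if needed)
#' @return invisibly, a named list of the paths written
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotations = file.path(dir, "genes.bed"),
    expression = file.path(dir, "expression.tsv"),
    sample_map = file.path(dir, "sample_map.tsv"),
    labels = file.path(dir, "truth_labels.tsv"),
    implants = file.path(dir, "truth_implants.tsv"),
    motifs = file.path(dir, "motifs.meme")
  )
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_bed(sim$annotations, paths$annotations)
  readr::write_tsv(sim$expression, paths$expression)
  readr::write_tsv(sim$sample_map, paths$sample_map)
  readr::write_tsv(sim$truth$labels, paths$labels)
  readr::write_tsv(sim$truth$implants, paths$implants)
  if (length(sim$library) > 0) write_motifs(sim$library, paths$motifs)
  invisible(paths)
}
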