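#' Per-structure average expression
#'
#' Averages each gene's expression over the samples of every plant structure.
#'
#' @param expr expression tibble (`gene` column + one column per sample)
#' @param sample_map tibble with columns `sample`, `structure`; every sample
#'   column of `expr` must be mapped to exactly one structure
#' @return tibble: `gene` plus one mean-expression column per structure
#' @export
ps_average <- function(expr, sample_map) {
  samples <- setdiff(names(expr), "gene")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  hits <- match(samples, sample_map$sample)
  if (anyNA(hits))
    stop("unmapped samples: ", paste(samples[is.na(hits)], collapse = ", "))
  if (anyDuplicated(sample_map$sample))
    stop("sample map assigns a sample to more than one structure")
  structures <- unique(sample_map$structure)
  empty <- setdiff(structures, sample_map$structure[hits])
  if (length(empty) > 0)
    stop("structure with zero samples: ", paste(empty, collapse = ", "))
  m <- as.matrix(expr[samples])
  ps <- sample_map$structure[hits]
  out <- vapply(structures,
                function(s) rowMeans(m[, ps == s, drop = FALSE]),
                numeric(nrow(m)))
  dplyr::bind_cols(tibble::tibble(gene = expr$gene),
                   tibble::as_tibble(out))
}

#' Assign genes to plant structures
#'
#' A gene joins the structure in which its average expression is greatest,
#' provided the gap between its two greatest structure-averages exceeds the
#' structure's threshold times the (population) standard deviation of the
#' gene's structure-averages. A tie for the greatest average leaves the gene
#' unassigned, as does a zero gap.
#'
#' @param ps_avg tibble from [ps_average()]
#' @param thresholds named numeric vector of per-structure thresholds (a
#'   single unnamed value is recycled). The study this models used
#'   2.05, 2.35, 2.36, 0.80 and 0.75 for flower, seed, root, shoot and
#'   whole plant.
#' @param sd_type `"population"` (divide by k, default) or `"sample"`
#' @return tibble: gene, structure (NA when unassigned), gap, sd_avg
#' @export
assign_genes <- function(ps_avg, thresholds,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  structures <- setdiff(names(ps_avg), "gene")
  if (length(structures) < 2) stop("need at least 2 structures")
  if (any(thresholds < 0)) stop("thresholds must be nonnegative")
  if (length(thresholds) == 1 && is.null(names(thresholds)))
    thresholds <- stats::setNames(rep(thresholds, length(structures)), structures)
  if (!all(structures %in% names(thresholds)))
    stop("thresholds must name every structure")
  m <- as.matrix(ps_avg[structures])
  k <- ncol(m)
  top_idx <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_idx)]
  second <- apply(m, 1, function(r) sort(r, decreasing = TRUE)[2])
  tied <- apply(m, 1, function(r) sum(r == max(r)) > 1)
  sds <- if (sd_type == "population") apply(m, 1, pop_sd) else apply(m, 1, stats::sd)
  s_star <- structures[top_idx]
  gap <- top - second
  ok <- unname(!tied & gap > thresholds[s_star] * sds)
  tibble::tibble(
    gene = ps_avg$gene,
    structure = ifelse(ok, s_star, NA_character_),
    gap = gap,
    sd_avg = sds
  )
}

#' Split structure gene sets into model-build and motif-prediction subsets
#'
#' Random 60/40 partition per structure; the model-build subset gets
#' round(0.6 n) genes (half-up), matching set sizes of 138 -> 83/55 and
#' 147 -> 88/59.
#'
#' @param assignments tibble with columns `gene`, `structure` (NA rows are
#'   dropped), e.g. from [assign_genes()]
#' @param prop fraction allotted to the model-build subset
#' @param seed integer seed; the partition is deterministic per seed
#' @return tibble: gene, structure, role (`"model_build"` or
#'   `"motif_prediction"`)
#' @export
split_sets <- function(assignments, prop = 0.6, seed = 1L) {
  df <- dplyr::filter(assignments, !is.na(.data$structure))
  if (nrow(df) == 0) stop("no assigned genes to split")
  df <- dplyr::arrange(df, .data$structure, .data$gene)
  withr::with_seed(seed, {
    dplyr::group_by(df, .data$structure) %>%
      dplyr::group_modify(function(d, key) {
        n <- nrow(d)
        n_mb <- round_half_up(prop * n)
        mb <- sample(n, n_mb)
        d$role <- "motif_prediction"
        d$role[mb] <- "model_build"
        d[c("gene", "role")]
      }) %>%
      dplyr::ungroup() %>%
      dplyr::select("gene", "structure", "role")
  })
}

#' Extract upstream promoter sequences
#'
#' Returns, for each gene, the `L` bases immediately upstream of the
#' annotated translation start site (TLS) on the gene's own strand, written
#' 5' to 3' with the TLS-adjacent base last. For minus-strand genes this is the
#' reverse complement of the downstream genomic slice. Sequences clipped at a
#' contig edge are flagged truncated.
#'
#' @param annotations annotation tibble (chrom, start, end, gene, strand;
#'   0-based half-open)
#' @param genome [Biostrings::DNAStringSet]
#' @param genes gene ids to extract (default: all annotated genes)
#' @param L promoter length, one of 50, 100, 150, 200
#' @return tibble: gene, seq, L, width, strand, truncated
#' @export
extract_promoters <- function(annotations, genome, genes = NULL, L = 200L) {
  if (!L %in% c(50L, 100L, 150L, 200L))
    stop("L must be one of 50, 100, 150, 200")
  ann <- annotations
  if (!is.null(genes)) {
    miss <- setdiff(genes, ann$gene)
    if (length(miss) > 0)
      stop("genes absent from the annotation: ", paste(miss, collapse = ", "))
    ann <- ann[match(genes, ann$gene), ]
  }
  miss_chr <- setdiff(unique(ann$chrom), names(genome))
  if (length(miss_chr) > 0)
    stop("chromosomes absent from the genome: ", paste(miss_chr, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- character(nrow(ann))
  trunc <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    if (ann$strand[i] == "+") {
      from <- max(0L, ann$start[i] - L)
      to <- ann$start[i]
      trunc[i] <- (to - from) < L
      seqs[i] <- as.character(Biostrings::subseq(genome[[ann$chrom[i]]],
                                                 from + 1L, to))
    } else {
      from <- ann$end[i]
      to <- min(lens[[ann$chrom[i]]], ann$end[i] + L)
      trunc[i] <- (to - from) < L
      seqs[i] <- revcomp(as.character(
        Biostrings::subseq(genome[[ann$chrom[i]]], from + 1L, to)))
    }
  }
  tibble::tibble(gene = ann$gene, seq = seqs, L = as.integer(L),
                 width = nchar(seqs), strand = ann$strand, truncated = trunc)
}

#' Sample background promoters
#'
#' Draws `m` genes uniformly without replacement from the annotated genes
#' outside `exclude` and extracts their promoters.
#'
#' @inheritParams extract_promoters
#' @param exclude gene ids that may not appear in the background
#' @param m number of background genes
#' @param seed integer seed
#' @export
sample_background <- function(annotations, genome, exclude, m, L = 200L,
                              seed = 1L) {
  pool <- sort(setdiff(annotations$gene, exclude))
  if (length(pool) == 0) stop("no eligible background genes (pool is empty)")
  if (m > length(pool))
    stop("requested ", m, " background genes but only ", length(pool),
         " are eligible")
  chosen <- withr::with_seed(seed, sort(sample(pool, m)))
  extract_promoters(annotations, genome, genes = chosen, L = L)
}
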