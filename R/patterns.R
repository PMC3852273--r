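#' The four-bin scheme over a 200 bp promoter
#'
#' Bins over the upstream distance x from the TLS: \[0,50), \[50,100),
#' \[100,150), \[150,200\] (the last bin closed). Bin 1 is TLS-proximal.
#'
#' @return tibble: bin, lo, hi
#' @export
bin_scheme <- function() {
  tibble::tibble(bin = 1:4,
                 lo = c(0L, 50L, 100L, 150L),
                 hi = c(50L, 100L, 150L, 200L))
}

# bin of a TLS distance; [0,50),... last bin closed at 200
assign_bin <- function(x) {
  pmin(x %/% 50L + 1L, 4L)
}

#' Bin-by-strand motif presence fractions
#'
#' Scans each promoter for every motif and, per (motif, bin, strand) cell,
#' reports the fraction of promoters with at least one hit whose
#' TLS-proximal edge falls in the bin.
#'
#' @param promoters promoter tibble at L = 200
#' @param motifs list of [pfm()]
#' @param params a [scan_params()]
#' @return `presence_table` tibble: motif, bin, strand, n_with_hit, fraction;
#'   attributes `n_promoters` and `params`
#' @export
bin_presence <- function(promoters, motifs, params = scan_params()) {
  if (any(promoters$L != 200L))
    stop("presence tables are defined over 200 bp promoters")
  n <- nrow(promoters)
  hits <- scan_promoters(promoters, motifs, params)
  ids <- vapply(motifs, `[[`, "", "id")
  grid <- tidyr::expand_grid(motif = ids, bin = 1:4, strand = c("+", "-"))
  counts <- if (nrow(hits) == 0) {
    tibble::tibble(motif = character(0), bin = integer(0),
                   strand = character(0), n_with_hit = integer(0))
  } else {
    hits %>%
      dplyr::mutate(bin = assign_bin(.data$x)) %>%
      dplyr::distinct(.data$gene, .data$motif, .data$bin, .data$strand) %>%
      dplyr::count(.data$motif, .data$bin, .data$strand, name = "n_with_hit")
  }
  out <- grid %>%
    dplyr::left_join(counts, by = c("motif", "bin", "strand")) %>%
    dplyr::mutate(n_with_hit = dplyr::coalesce(.data$n_with_hit, 0L),
                  fraction = .data$n_with_hit / n)
  attr(out, "n_promoters") <- n
  attr(out, "params") <- params
  class(out) <- c("presence_table", class(out))
  out
}

new_motif_pattern <- function(cells, threshold, motifs, n_promoters,
                              structure = NA_character_,
                              params = scan_params()) {
  structure(list(cells = cells, threshold = threshold, motifs = motifs,
                 n_promoters = n_promoters, structure = structure,
                 params = params, bins = bin_scheme()),
            class = "motif_pattern")
}

#' Build a motif pattern from a presence table
#'
#' The required cells are the (motif, bin, strand) cells whose presence
#' fraction strictly exceeds the threshold ("more than 60%" for the four
#' plant structures, more than 50% for the whole plant, in the study this
#' models).
#'
#' @param presence a [bin_presence()] table
#' @param threshold presence threshold in (0, 1); strict inequality
#' @param motifs list of [pfm()] referenced by the pattern (for matching)
#' @param structure optional structure name recorded with the pattern
#' @return a `motif_pattern` object
#' @export
build_pattern <- function(presence, threshold = 0.6, motifs = list(),
                          structure = NA_character_) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  cells <- presence %>%
    dplyr::filter(.data$fraction > threshold) %>%
    dplyr::select("motif", "bin", "strand") %>%
    dplyr::arrange(.data$motif, .data$bin, .data$strand)
  if (nrow(cells) == 0)
    warning("no cell exceeds the presence threshold: the pattern is empty")
  ids <- vapply(motifs, `[[`, "", "id")
  new_motif_pattern(tibble::as_tibble(cells), threshold,
                    motifs = motifs[ids %in% unique(cells$motif)],
                    n_promoters = attr(presence, "n_promoters") %||% NA_integer_,
                    structure = structure,
                    params = attr(presence, "params") %||% scan_params())
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", if (!is.na(x$structure)) x$structure else "",
      " ", nrow(x$cells), " required cell(s), presence > ",
      x$threshold, "\n", sep = "")
  print(x$cells, n = 20)
  invisible(x)
}

#' Does a promoter satisfy a motif pattern?
#'
#' TRUE iff every required (motif, bin, strand) cell has at least one hit of
#' that motif in that bin on that strand (a conjunction; the empty pattern
#' matches vacuously). Promoters shorter than 200 bp never match.
#'
#' @param seq one promoter sequence
#' @param pattern a `motif_pattern`
#' @param params a [scan_params()]; defaults to the pattern's own
#' @return logical scalar
#' @export
match_pattern <- function(seq, pattern, params = NULL) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (nrow(pattern$cells) == 0) return(TRUE)
  if (nchar(seq) < 200L) return(FALSE)
  params <- params %||% pattern$params
  ids <- vapply(pattern$motifs, `[[`, "", "id")
  need <- unique(pattern$cells$motif)
  if (!all(need %in% ids))
    stop("pattern references motifs without matrices: ",
         paste(setdiff(need, ids), collapse = ", "))
  for (m in need) {
    hits <- scan_promoter(pattern$motifs[[which(ids == m)]], seq, params)
    cells_m <- pattern$cells[pattern$cells$motif == m, ]
    if (nrow(hits) == 0) return(FALSE)
    hb <- assign_bin(hits$x)
    for (r in seq_len(nrow(cells_m))) {
      if (!any(hb == cells_m$bin[r] & hits$strand == cells_m$strand[r]))
        return(FALSE)
    }
  }
  TRUE
}

#' Remove near-duplicate promoters by sequence identity
#'
#' Pairwise similarity is the fraction of identical positions in the
#' ungapped, equal-length comparison. Promoters are visited in gene-id
#' order; one is dropped when its similarity to an already retained promoter
#' exceeds the cutoff (greedy, first kept wins).
#'
#' @param promoters promoter tibble (equal declared lengths)
#' @param cutoff similarity above which a promoter is removed (default 0.60)
#' @return the retained promoter tibble; dropped gene ids in attribute
#'   `dropped`
#' @export
similarity_filter <- function(promoters, cutoff = 0.60) {
  if (length(unique(promoters$width)) > 1)
    stop("similarity filtering needs promoters of equal length")
  prom <- dplyr::arrange(promoters, .data$gene)
  n <- nrow(prom)
  if (n == 0) return(prom)
  L <- prom$width[1]
  codes <- matrix(0L, n, L)
  for (i in seq_len(n)) codes[i, ] <- utf8ToInt(prom$seq[i])
  keep <- logical(n)
  keep[1] <- TRUE
  kept_rows <- 1L
  for (i in seq_len(n)[-1]) {
    block <- codes[kept_rows, , drop = FALSE]
    sims <- rowMeans(block == matrix(codes[i, ], nrow(block), L, byrow = TRUE))
    if (all(sims <= cutoff)) {
      keep[i] <- TRUE
      kept_rows <- c(kept_rows, i)
    }
  }
  out <- prom[keep, ]
  attr(out, "dropped") <- prom$gene[!keep]
  out
}

#' Genome-wide pattern scan
#'
#' Extracts the 200 bp promoter of every annotated gene, removes
#' near-duplicate promoters with [similarity_filter()], and reports which
#' retained promoters satisfy the pattern.
#'
#' @param genome [Biostrings::DNAStringSet]
#' @param annotations annotation tibble
#' @param pattern a nonempty `motif_pattern`
#' @param params a [scan_params()]; defaults to the pattern's own
#' @param similarity_cutoff cutoff for [similarity_filter()]
#' @param genes optional subset of genes to scan
#' @return tibble: gene, matched — one row per retained gene; dropped gene
#'   ids in attribute `dropped`
#' @export
genome_scan <- function(genome, annotations, pattern, params = NULL,
                        similarity_cutoff = 0.60, genes = NULL) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (nrow(pattern$cells) == 0)
    stop("refusing to scan with an empty pattern (it matches every promoter)")
  prom <- extract_promoters(annotations, genome, genes = genes, L = 200L)
  prom <- prom[!prom$truncated, ]
  prom <- similarity_filter(prom, cutoff = similarity_cutoff)
  params <- params %||% pattern$params
  matched <- vapply(prom$seq, match_pattern, TRUE,
                    pattern = pattern, params = params, USE.NAMES = FALSE)
  out <- tibble::tibble(gene = prom$gene, matched = matched)
  attr(out, "dropped") <- attr(prom, "dropped")
  out
}

#' Confusion-matrix rates of a genome-wide prediction
#'
#' Compares predicted genes against planted structure labels.
#'
#' @param predicted character vector of predicted gene ids
#' @param truth tibble with columns `gene`, `structure` covering all genes
#'   ("background" marks negatives)
#' @param positive_structures structures counted as positive (default: all
#'   non-background labels)
#' @return one-row tibble: tp, fp, fn, tn, sensitivity, precision,
#'   specificity
#' @export
evaluate_predictions <- function(predicted, truth,
                                 positive_structures = NULL) {
  if (is.null(positive_structures))
    positive_structures <- setdiff(unique(truth$structure), "background")
  pos <- truth$gene[truth$structure %in% positive_structures]
  neg <- setdiff(truth$gene, pos)
  unknown <- setdiff(predicted, truth$gene)
  if (length(unknown) > 0)
    stop("predicted genes missing from the truth labels: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  tp <- length(intersect(predicted, pos))
  fp <- length(intersect(predicted, neg))
  fn <- length(pos) - tp
  tn <- length(neg) - fp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}
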