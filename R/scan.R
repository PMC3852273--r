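#' Scan parameters
#'
#' Controls TFBS calling: background base composition, the pseudocount used
#' when forming PFM probabilities, and the calling threshold `theta` — a hit
#' is an offset whose log-odds score reaches at least `theta` times the
#' maximum achievable score of the matrix.
#'
#' @param bg named background probabilities for A, C, G, T
#' @param pseudocount per-cell pseudocount (default 0.25)
#' @param theta fraction of the maximal log-odds score, in (0, 1]
#' @export
scan_params <- function(bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        pseudocount = 0.25, theta = 0.8) {
  if (is.na(theta)) theta <- 0.8
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  if (abs(sum(bg) - 1) > 1e-6) stop("background must sum to 1")
  if (any(bg <= 0)) stop("background probabilities must be positive")
  names(bg) <- BASES
  structure(list(bg = bg, pseudocount = pseudocount, theta = theta),
            class = "scan_params")
}

# log-odds matrix with a 5th zero row so ambiguous bases score as background
log_odds_matrix <- function(pfm, params) {
  p <- pfm_prob(pfm(pfm$counts, pfm$id, params$pseudocount))
  rbind(log(p / params$bg), 0)
}

#' Scan one promoter for TFBS hits of one motif
#'
#' Scores the log-odds of the motif against background at every offset on the
#' promoter and its reverse complement. Hits are offsets scoring at least
#' `theta` times the maximum achievable score. Each hit reports `x`, the
#' distance in bp from the TLS to the hit's TLS-proximal edge (the promoter
#' is 5' to 3' with the TLS-adjacent base last, so `x = 0` means the site
#' ends at the TLS). Minus-strand hits are reported at the same promoter
#' coordinate. Overlapping hits are all reported.
#'
#' @param pfm a [pfm()]
#' @param seq one promoter sequence (character)
#' @param params a [scan_params()]
#' @return tibble: motif, strand, x, score
#' @export
scan_promoter <- function(pfm, seq, params = scan_params()) {
  w <- pfm_width(pfm)
  L <- nchar(seq)
  empty <- tibble::tibble(motif = character(0), strand = character(0),
                          x = integer(0), score = numeric(0))
  if (L < w) return(empty)
  lom <- log_odds_matrix(pfm, params)
  max_score <- sum(apply(lom[1:4, , drop = FALSE], 2, max))
  thr <- params$theta * max_score - 1e-9
  hit_one_strand <- function(codes) {
    n_off <- length(codes) - w + 1L
    s <- numeric(n_off)
    for (j in seq_len(w))
      s <- s + lom[cbind(codes[j:(j + n_off - 1L)], j)]
    which(s >= thr) -> idx
    list(idx = idx, score = s[idx])
  }
  fwd <- hit_one_strand(seq_codes(seq))
  rev <- hit_one_strand(seq_codes(revcomp(seq)))
  dplyr::bind_rows(
    tibble::tibble(motif = pfm$id, strand = "+",
                   x = L - (fwd$idx - 1L) - w, score = fwd$score),
    tibble::tibble(motif = pfm$id, strand = "-",
                   x = rev$idx - 1L, score = rev$score)
  )
}

#' Scan a promoter set for several motifs
#'
#' @param promoters promoter tibble ([extract_promoters()])
#' @param motifs list of [pfm()]
#' @param params a [scan_params()]
#' @return tibble: gene, motif, strand, x, score
#' @export
scan_promoters <- function(promoters, motifs, params = scan_params()) {
  purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
    hits <- purrr::map_dfr(motifs, scan_promoter,
                           seq = promoters$seq[i], params = params)
    if (nrow(hits) > 0) dplyr::bind_cols(tibble::tibble(gene = promoters$gene[i]),
                                         hits)
    else NULL
  })
}

#' Normalized average TFBS distance
#'
#' The average of the TLS distances of one motif's hits on one strand,
#' divided by the promoter length; zero when the motif is absent on that
#' strand.
#'
#' @param x integer vector of TLS distances (possibly empty)
#' @param L promoter length used for normalization (200 bp in the model)
#' @return value in \[0, 1\]
#' @export
#' @examples
#' average_distance(c(50, 150), 200)  # 0.5
#' average_distance(integer(0), 200)  # 0
average_distance <- function(x, L) {
  stopifnot(L > 0)
  if (length(x) == 0) return(0)
  mean(x) / L
}

#' Build the strand-aware feature vector of one promoter
#'
#' Components are ordered `[m1+, m1-, m2+, m2-, ...]` over the fixed motif
#' order; each is the normalized average TLS distance of that motif's hits on
#' that strand (0 when absent). With 6 motifs the promoter is characterized
#' by a 12-component vector.
#'
#' @param seq promoter sequence (scanned at its full length; the model uses
#'   200 bp promoters)
#' @param motifs list of [pfm()] in fixed order
#' @param params a [scan_params()]
#' @return named numeric vector of length `2 * length(motifs)`
#' @export
build_feature_vector <- function(seq, motifs, params = scan_params()) {
  L <- nchar(seq)
  out <- numeric(2L * length(motifs))
  nm <- character(length(out))
  for (i in seq_along(motifs)) {
    hits <- scan_promoter(motifs[[i]], seq, params)
    out[2L * i - 1L] <- average_distance(hits$x[hits$strand == "+"], L)
    out[2L * i] <- average_distance(hits$x[hits$strand == "-"], L)
    nm[2L * i - 1L] <- paste0(motifs[[i]]$id, "_plus")
    nm[2L * i] <- paste0(motifs[[i]]$id, "_minus")
  }
  stats::setNames(out, nm)
}

#' Build the training matrix for the promoter classifier
#'
#' One row per promoter: positives (label 1, sorted by gene id) then
#' background (label 0, sorted by gene id), with the feature vector of
#' [build_feature_vector()]. The background base composition for scanning
#' defaults to the positive set's own composition.
#'
#' @param positives positive promoter tibble
#' @param background background promoter tibble
#' @param motifs list of [pfm()] in fixed order
#' @param params a [scan_params()]; when `NULL`, built with the positive
#'   set's base composition as background
#' @return tibble: gene, label (1/0), then one column per feature; scan
#'   provenance in attributes `params` and `motif_ids`
#' @export
build_training_matrix <- function(positives, background, motifs,
                                  params = NULL) {
  if (nrow(positives) == 0 || nrow(background) == 0)
    stop("positive and background promoter sets must both be nonempty")
  dup <- intersect(positives$gene, background$gene)
  if (length(dup) > 0)
    stop("gene ids present in both sets: ", paste(dup, collapse = ", "))
  if (is.null(params))
    params <- scan_params(bg = base_composition(positives$seq))
  one_block <- function(prom, label) {
    prom <- dplyr::arrange(prom, .data$gene)
    feats <- t(vapply(prom$seq, build_feature_vector,
                      numeric(2L * length(motifs)),
                      motifs = motifs, params = params))
    dplyr::bind_cols(tibble::tibble(gene = prom$gene, label = label),
                     tibble::as_tibble(feats, .name_repair = "minimal"))
  }
  out <- dplyr::bind_rows(one_block(positives, 1L), one_block(background, 0L))
  attr(out, "params") <- params
  attr(out, "motif_ids") <- vapply(motifs, `[[`, "", "id")
  out
}

#' Base composition of a set of sequences
#'
#' @param seqs character vector of DNA sequences
#' @return named A/C/G/T frequency vector (ambiguous bases ignored)
#' @export
base_composition <- function(seqs) {
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 1))[BASES]
  counts / sum(counts)
}
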