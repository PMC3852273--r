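#' Dinucleotide-preserving sequence shuffle
#'
#' Euler-path shuffle: the shuffled sequence has exactly the same
#' dinucleotide (and hence mononucleotide) counts as the input. Used to build
#' the null for word over-representation. Non-ACGT characters are replaced by
#' random bases before shuffling.
#'
#' @param seq one DNA string
#' @return shuffled string of the same length
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  bad <- !ch %in% BASES
  if (any(bad)) ch[bad] <- sample(BASES, sum(bad), replace = TRUE)
  n <- length(ch)
  if (n < 3) return(paste(ch, collapse = ""))
  verts <- unique(ch)
  from <- ch[-n]; to <- ch[-1]
  last_v <- ch[n]
  edges <- split(seq_len(n - 1L), factor(from, levels = verts))
  # pick a random terminal edge per non-terminal vertex until they form an
  # in-tree to the last vertex (Altschul-Erickson condition)
  repeat {
    last_edge <- stats::setNames(rep(NA_integer_, length(verts)), verts)
    for (v in verts) {
      if (v == last_v) next
      ev <- edges[[v]]
      if (length(ev) == 0) next
      last_edge[v] <- ev[sample.int(length(ev), 1)]
    }
    ok <- TRUE
    for (v in verts) {
      if (v == last_v || is.na(last_edge[v])) next
      seen <- character(0); cur <- v
      while (cur != last_v) {
        if (cur %in% seen || is.na(last_edge[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- to[last_edge[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle the remaining out-edges, append the terminal edge last, walk
  adj <- lapply(stats::setNames(verts, verts), function(v) {
    ev <- edges[[v]]
    rest <- setdiff(ev, last_edge[v])
    if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
    c(rest, if (!is.na(last_edge[v])) last_edge[v])
  })
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]; cur <- ch[1]
  for (i in 2:n) {
    e <- adj[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    cur <- to[e]
    out[i] <- cur
  }
  paste(out, collapse = "")
}

# strand-symmetric word counts over a set of sequences
count_words <- function(seqs, k) {
  ss <- Biostrings::DNAStringSet(seqs)
  cf <- colSums(Biostrings::oligonucleotideFrequency(ss, width = k))
  cr <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::reverseComplement(ss), width = k))
  cf + cr
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' De-novo motif discovery by over-represented words
#'
#' A deliberately simple discovery engine: words of each length in `k_range`
#' are counted on both strands and scored by the z-score of their count
#' against `n_shuffles` dinucleotide-shuffled copies of the promoter set.
#' Top-scoring seeds (z descending; seeds within one mismatch of an already
#' chosen seed or its reverse complement are skipped) are expanded by
#' collecting all occurrences within one mismatch on both strands, and a PFM
#' is built from the aligned occurrences.
#'
#' @param promoters promoter tibble (at least 5 sequences)
#' @param k_range word lengths to enumerate (default c(6, 8))
#' @param max_motifs maximum number of PFMs returned
#' @param n_shuffles shuffled promoter sets for the null (default 50)
#' @param z_min minimum z-score for a seed to be reported (default 3)
#' @param seed integer seed (shuffles are the only randomness)
#' @return list of [pfm()] (ids `dn_01`, ...), each with attributes `seed_word`
#'   and `z`; the ranked seed table is in attribute `seeds`
#' @export
discover_motifs <- function(promoters, k_range = c(6L, 8L), max_motifs = 5L,
                            n_shuffles = 50L, z_min = 3, seed = 1L) {
  seqs <- promoters$seq
  keep <- nchar(seqs) >= min(k_range)
  if (any(!keep)) {
    warning(sum(!keep), " promoter(s) shorter than the minimum word length were skipped")
    seqs <- seqs[keep]
  }
  if (length(seqs) == 0) stop("all promoters shorter than the minimum word length")
  if (length(seqs) < 5) stop("need at least 5 promoters")
  k_range <- k_range[k_range <= max(nchar(seqs))]

  shuffled <- withr::with_seed(seed, lapply(seq_len(n_shuffles), function(b)
    vapply(seqs, dinucleotide_shuffle, "", USE.NAMES = FALSE)))

  tab <- purrr::map_dfr(k_range, function(k) {
    obs <- count_words(seqs, k)
    null <- vapply(shuffled, count_words, numeric(length(obs)), k = k)
    mu <- rowMeans(null)
    sdv <- pmax(apply(null, 1, stats::sd), 0.5)
    tibble::tibble(word = names(obs), k = k, count = as.numeric(obs),
                   null_mean = mu, null_sd = sdv, z = (obs - mu) / sdv)
  })
  tab <- dplyr::arrange(tab, dplyr::desc(.data$z), .data$word)

  chosen <- list()
  for (i in seq_len(nrow(tab))) {
    if (length(chosen) >= max_motifs) break
    wrd <- tab$word[i]
    if (tab$z[i] < z_min) break
    redundant <- any(vapply(chosen, function(cw) {
      hamming(wrd, cw) <= 1 || hamming(wrd, revcomp(cw)) <= 1 ||
        grepl(cw, wrd, fixed = TRUE) || grepl(revcomp(cw), wrd, fixed = TRUE) ||
        grepl(wrd, cw, fixed = TRUE) || grepl(revcomp(wrd), cw, fixed = TRUE)
    }, TRUE))
    if (!redundant) chosen[[length(chosen) + 1L]] <- wrd
  }

  out <- list()
  for (i in seq_along(chosen)) {
    wrd <- chosen[[i]]
    occs <- character(0)
    pat <- Biostrings::DNAString(wrd)
    for (s in seqs) {
      dna <- Biostrings::DNAString(s)
      for (strand_seq in list(dna, Biostrings::reverseComplement(dna))) {
        mm <- Biostrings::matchPattern(pat, strand_seq, max.mismatch = 1)
        # drop views hanging off the sequence edge
        mm <- mm[Biostrings::start(mm) >= 1 &
                   Biostrings::end(mm) <= length(strand_seq)]
        if (length(mm) > 0) occs <- c(occs, as.character(mm))
      }
    }
    if (length(occs) < 2) next
    counts <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(occs))[BASES, ,
                                                                          drop = FALSE]
    m <- pfm(counts, id = sprintf("dn_%02d", length(out) + 1L))
    attr(m, "seed_word") <- wrd
    attr(m, "z") <- tab$z[tab$word == wrd & nchar(tab$word) == nchar(wrd)][1]
    out[[length(out) + 1L]] <- m
  }
  attr(out, "seeds") <- utils::head(tab, 100L)
  out
}
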