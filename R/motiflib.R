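#' Convert a PFM to a k-mer frequency vector
#'
#' The component for k-mer `m` is the expected number of occurrences of `m`
#' under the independent-column probability model of the PFM, summed over all
#' offsets, for the PFM and its reverse complement (motifs are discovered on
#' both strands, so the representation is strand-symmetric). The components
#' therefore sum to `2 * (width - k + 1)`.
#'
#' @param x a [pfm()]
#' @param k k-mer length (default 4); must not exceed the motif width
#' @return named numeric vector of length `4^k`
#' @export
pfm_kmer_vector <- function(x, k = 4L) {
  w <- pfm_width(x)
  if (k > w) stop("k (", k, ") exceeds motif width (", w, ")")
  kmers <- all_kmers(k)
  one <- function(p) {
    v <- numeric(4^k)
    for (o in 0:(ncol(p) - k)) {
      block <- p[, (o + 1):(o + k), drop = FALSE]
      probs <- block[, 1]
      # outer(acc, col_j) keeps earlier positions fastest-varying, matching
      # the expand.grid ordering of all_kmers()
      for (j in 2:k) probs <- as.vector(outer(probs, block[, j]))
      v <- v + probs
    }
    v
  }
  if (k == 1) {
    p <- pfm_prob(x)
    v <- rowSums(p) + rowSums(pfm_prob(pfm_rc(x)))
    return(stats::setNames(as.numeric(v), BASES))
  }
  out <- one(pfm_prob(x)) + one(pfm_prob(pfm_rc(x)))
  stats::setNames(out, kmers)
}

# all k-mers with the first position varying fastest
all_kmers <- function(k) {
  g <- do.call(expand.grid, rep(list(BASES), k))
  apply(g, 1, paste, collapse = "")
}

#' Pearson-correlation distance matrix between k-mer vectors
#'
#' `d(i, j) = 1 - cor(v_i, v_j)`; a zero-variance vector has undefined
#' correlation and its off-diagonal distances are set to 1 with a warning.
#'
#' @param vectors list (or matrix with vectors in rows) of equal-length
#'   k-mer vectors, named by motif id
#' @return symmetric distance matrix with zero diagonal
#' @export
motif_distance_matrix <- function(vectors) {
  if (is.list(vectors)) {
    nm <- names(vectors) %||% paste0("m", seq_along(vectors))
    vectors <- do.call(rbind, vectors)
    rownames(vectors) <- nm
  }
  if (nrow(vectors) < 2) stop("need at least 2 vectors")
  sds <- apply(vectors, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance k-mer vector(s): correlation undefined, distance set to 1")
  cc <- suppressWarnings(stats::cor(t(vectors)))
  cc[is.na(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' Cluster motifs by average-linkage hierarchical clustering
#'
#' Agglomerative clustering with unweighted average linkage (UPGMA) on a
#' precomputed distance matrix. With `k = "auto"` the number of clusters is
#' chosen to maximize the mean silhouette width over `2..min(10, M - 1)`
#' (ties go to the smallest k).
#'
#' @param D symmetric distance matrix (e.g. [motif_distance_matrix()])
#' @param k number of clusters, or `"auto"`
#' @return tibble: motif, cluster; the `hclust` tree and the chosen k are in
#'   attributes `tree` and `k`
#' @export
cluster_motifs <- function(D, k = "auto") {
  M <- nrow(D)
  if (is.null(M) || M < 2) stop("need at least 2 motifs to cluster")
  ids <- rownames(D) %||% paste0("m", seq_len(M))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  if (identical(k, "auto")) {
    ks <- 2:min(10L, M - 1L)
    if (length(ks) == 0 || M == 2) {
      k <- min(2L, M)
    } else {
      sil <- vapply(ks, function(kk) {
        cl <- stats::cutree(hc, k = kk)
        mean(cluster::silhouette(cl, stats::as.dist(D))[, "sil_width"])
      }, 0)
      k <- ks[which.max(sil)]
    }
  }
  k <- as.integer(k)
  if (k < 1 || k > M) stop("k must lie in 1..", M)
  cl <- stats::cutree(hc, k = k)
  out <- tibble::tibble(motif = ids, cluster = as.integer(cl))
  attr(out, "tree") <- hc
  attr(out, "k") <- k
  out
}

#' Hypergeometric group-specificity score
#'
#' The probability of observing at least `k_group` motif-containing promoters
#' within a group of `n_group` promoters, when `K_genome` of the `N_genome`
#' promoters genome-wide contain the motif. Smaller scores mean the motif
#' targets the group more specifically.
#'
#' @param k_group motif-containing promoters inside the group
#' @param n_group group size
#' @param K_genome motif-containing promoters genome-wide
#' @param N_genome total promoters genome-wide
#' @return upper-tail probability in \[0, 1\]
#' @export
#' @examples
#' group_specificity(3, 5, 4, 10)  # 66/252
group_specificity <- function(k_group, n_group, K_genome, N_genome) {
  if (k_group > n_group || n_group > N_genome || k_group > K_genome ||
      K_genome > N_genome || any(c(k_group, n_group, K_genome, N_genome) < 0))
    stop("inconsistent counts: need k <= n <= N and k <= K <= N")
  stats::phyper(k_group - 1, K_genome, N_genome - K_genome, n_group,
                lower.tail = FALSE)
}

#' Group-specificity scores for a set of motifs
#'
#' "Contains the motif" means at least one scan hit at the given parameters
#' on the 200 bp promoter.
#'
#' @param motifs list of [pfm()]
#' @param group_promoters promoter tibble of the gene group
#' @param genome_promoters promoter tibble of all genes
#' @param params a [scan_params()]
#' @return tibble: motif, k_group, n_group, K_genome, N_genome, score
#' @export
score_motif_specificity <- function(motifs, group_promoters, genome_promoters,
                                    params = scan_params()) {
  purrr::map_dfr(motifs, function(m) {
    has_hit <- function(prom)
      vapply(prom$seq, function(s) nrow(scan_promoter(m, s, params)) > 0, TRUE)
    k <- sum(has_hit(group_promoters))
    K <- sum(has_hit(genome_promoters))
    tibble::tibble(motif = m$id, k_group = k, n_group = nrow(group_promoters),
                   K_genome = K, N_genome = nrow(genome_promoters),
                   score = group_specificity(k, nrow(group_promoters),
                                             K, nrow(genome_promoters)))
  })
}

#' Select cluster representatives by smallest specificity score
#'
#' One motif per cluster, the one with the smallest score; ties break to the
#' lexicographically smallest motif id.
#'
#' @param clusters tibble from [cluster_motifs()]
#' @param scores tibble with columns `motif`, `score`
#' @return tibble: cluster, motif, score
#' @export
select_representatives <- function(clusters, scores) {
  df <- dplyr::inner_join(clusters, scores[c("motif", "score")], by = "motif")
  if (nrow(df) != nrow(clusters))
    stop("every cluster member needs a score")
  df %>%
    dplyr::arrange(.data$cluster, .data$score, .data$motif) %>%
    dplyr::group_by(.data$cluster) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("cluster", "motif", "score")
}

# standardized columns: crossprod(std(A), std(B)) = matrix of column Pearson
# correlations; zero-variance columns yield 0
std_prob_cols <- function(p) {
  ctr <- sweep(p, 2, colMeans(p))
  ss <- sqrt(colSums(ctr^2))
  ss[ss == 0] <- Inf
  sweep(ctr, 2, ss, "/")
}

# best alignment over ungapped offsets with overlap >= min_ov; the score is
# the sum of column correlations normalized by the wider motif's width, so a
# short perfect sub-alignment cannot outscore a full-length match
best_diagonal <- function(cormat, min_ov = 4L) {
  wq <- nrow(cormat); wl <- ncol(cormat)
  norm <- max(wq, wl)
  best <- -Inf; best_shift <- NA_integer_
  for (s in (-(wq - min_ov)):(wl - min_ov)) {
    i <- max(1L, 1L - s):min(wq, wl - s)
    if (length(i) < min_ov) next
    sc <- sum(cormat[cbind(i, i + s)]) / norm
    if (sc > best) { best <- sc; best_shift <- s }
  }
  list(score = best, shift = best_shift)
}

#' Compare a motif against a reference library
#'
#' Ungapped alignment of probability columns (overlap of at least 4 columns,
#' both orientations); the column score is the Pearson correlation of the two
#' probability columns and the alignment score is the sum of column scores
#' normalized by the wider motif's width (an identical motif scores 1; a
#' short perfect sub-alignment cannot outscore a full-length match). The
#' p-value is empirical: the observed best score over the library is compared
#' with `n_null` best scores obtained against column-shuffled library motifs,
#' with the add-one rule `p = (1 + #null >= observed) / (1 + n_null)`. The
#' motif is called known when `p < alpha`, otherwise novel.
#'
#' @param query a [pfm()]
#' @param library list of [pfm()]
#' @param n_null null replicates (default 1000)
#' @param alpha significance cutoff for "known" (default 0.001)
#' @param seed integer seed for the null
#' @return a `motif_comparison` object (see [tidy()] for the tibble form)
#' @export
compare_motifs <- function(query, library, n_null = 1000L, alpha = 0.001,
                           seed = 1L) {
  if (length(library) == 0) stop("library must be nonempty")
  qF <- std_prob_cols(pfm_prob(query))
  qR <- std_prob_cols(pfm_prob(pfm_rc(query)))
  mats <- lapply(library, function(m) {
    p <- pfm_prob(m)
    lf <- std_prob_cols(p)
    # column signature: permutations that only swap identical columns would
    # reproduce the motif and must not count as a shuffled null draw
    list(id = m$id, F = crossprod(qF, lf), R = crossprod(qR, lf),
         key = apply(round(p, 9), 2, paste, collapse = ","))
  })
  obs <- list(score = -Inf, match = NA_character_, shift = NA_integer_,
              orientation = NA_character_)
  comparable <- FALSE
  for (mm in mats) {
    if (nrow(mm$F) < 4 || ncol(mm$F) < 4) next
    comparable <- TRUE
    for (ori in c("F", "R")) {
      bd <- best_diagonal(mm[[ori]])
      if (bd$score > obs$score)
        obs <- list(score = bd$score, match = mm$id, shift = bd$shift,
                    orientation = if (ori == "F") "+" else "-")
    }
  }
  if (!comparable) {
    res <- list(query = query$id, match = NA_character_, shift = NA_integer_,
                orientation = NA_character_, score = NA_real_, p_value = 1,
                verdict = "novel", n_null = as.integer(n_null), alpha = alpha)
    return(structure(res, class = "motif_comparison"))
  }
  null_best <- withr::with_seed(seed, vapply(seq_len(n_null), function(b) {
    best <- -Inf
    for (mm in mats) {
      wl <- ncol(mm$F)
      if (nrow(mm$F) < 4 || wl < 4) next
      perm <- sample.int(wl)
      for (tries in 1:20) {
        if (any(mm$key[perm] != mm$key)) break
        perm <- sample.int(wl)
      }
      best <- max(best,
                  best_diagonal(mm$F[, perm, drop = FALSE])$score,
                  best_diagonal(mm$R[, perm, drop = FALSE])$score)
    }
    best
  }, 0))
  p <- (1 + sum(null_best >= obs$score - 1e-12)) / (1 + n_null)
  res <- list(query = query$id, match = obs$match, shift = obs$shift,
              orientation = obs$orientation, score = obs$score, p_value = p,
              verdict = if (p < alpha) "known" else "novel",
              n_null = as.integer(n_null), alpha = alpha)
  structure(res, class = "motif_comparison")
}

#' @export
print.motif_comparison <- function(x, ...) {
  cat("<motif_comparison> ", x$query, " vs ", x$match %||% "NA",
      ": score=", round(x$score, 3), " p=", signif(x$p_value, 3),
      " -> ", x$verdict, "\n", sep = "")
  invisible(x)
}
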