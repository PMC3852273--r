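# Shared fixture builders. Everything is generated in code, deterministically.

# a small two-structure study with strongly planted motifs
small_planted_config <- function(master_seed = 1L,
                                 implant_fraction = 0.9,
                                 n_genes = 200L,
                                 genes_per_ps = 60L,
                                 strength = 0.99) {
  m1 <- consensus_pfm("TGACGT", id = "pm1", strength = strength)
  m2 <- consensus_pfm("GGATCCGG", id = "pm2", strength = strength)
  sim_config(
    n_genes = n_genes, n_chromosomes = 2L,
    ps_names = c("ps1", "ps2"),
    samples_per_ps = c(12L, 12L),
    genes_per_ps = genes_per_ps,
    # bins 2 and 3: the mean-distance feature cannot express sites at the
    # TLS itself (x ~ 0 looks like absence), so planted bins sit mid-promoter
    motif_specs = list(
      motif_spec(m1, "ps1", bins = 2L, strands = "+",
                 implant_fraction = implant_fraction),
      motif_spec(m2, "ps1", bins = 3L, strands = "-",
                 implant_fraction = implant_fraction)
    ),
    master_seed = master_seed
  )
}

# naive all-offset log-odds scanner used as the independent scan oracle
naive_scan <- function(pfm, seq, params) {
  w <- pfm_width(pfm)
  L <- nchar(seq)
  p <- (pfm$counts + params$pseudocount)
  p <- sweep(p, 2, colSums(p), "/")
  lo <- log(p / params$bg)
  score_at <- function(s, off) {
    bases <- strsplit(substr(s, off, off + w - 1), "")[[1]]
    sum(vapply(seq_len(w), function(j) {
      b <- match(bases[j], c("A", "C", "G", "T"))
      if (is.na(b)) 0 else lo[b, j]
    }, 0))
  }
  max_score <- sum(apply(lo, 2, max))
  out <- list()
  if (L >= w) {
    for (off in 1:(L - w + 1)) {
      sc <- score_at(seq, off)
      if (sc >= params$theta * max_score - 1e-9)
        out[[length(out) + 1]] <- data.frame(strand = "+", x = L - (off - 1) - w,
                                             score = sc)
    }
    rc <- revcomp(seq)
    for (off in 1:(L - w + 1)) {
      sc <- score_at(rc, off)
      if (sc >= params$theta * max_score - 1e-9)
        out[[length(out) + 1]] <- data.frame(strand = "-", x = off - 1, score = sc)
    }
  }
  if (length(out) == 0)
    return(data.frame(strand = character(0), x = integer(0), score = numeric(0)))
  do.call(rbind, out)
}

# exhaustive hypergeometric upper tail by subset enumeration (N <= 12)
enum_hyper_tail <- function(k, n, K, N) {
  marked <- seq_len(K)
  combos <- utils::combn(N, n)
  mean(apply(combos, 2, function(cc) sum(cc %in% marked) >= k))
}

# naive O(M^3) UPGMA: merge heights for average-linkage clustering
naive_upgma_heights <- function(D) {
  M <- nrow(D)
  clusters <- as.list(seq_len(M))
  active <- rep(TRUE, M + (M - 1))
  D <- as.matrix(D)
  heights <- numeric(M - 1)
  # distances between clusters = mean pairwise distance between members
  cdist <- function(a, b) mean(D[a, b])
  cl <- clusters
  for (step in seq_len(M - 1)) {
    ids <- which(active[seq_along(cl)])
    best <- c(Inf, NA, NA)
    for (i in ids) for (j in ids) {
      if (i >= j) next
      d <- cdist(cl[[i]], cl[[j]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights[step] <- best[1]
    cl[[length(cl) + 1]] <- c(cl[[best[2]]], cl[[best[3]]])
    active[c(best[2], best[3])] <- FALSE
    active[length(cl)] <- TRUE
  }
  heights
}

# exhaustive k-mer expectation: enumerate all 4^w sequences under the PFM
# (and its reverse complement) and count k-mer occurrences, weighted
enum_kmer_vector <- function(pfm, k) {
  bases <- c("A", "C", "G", "T")
  w <- pfm_width(pfm)
  expected_for <- function(p) {
    grid <- do.call(expand.grid, rep(list(1:4), w))
    v <- numeric(4^k)
    kmers <- promarch:::all_kmers(k)
    names(v) <- kmers
    for (r in seq_len(nrow(grid))) {
      idx <- as.integer(grid[r, ])
      prob <- prod(p[cbind(idx, seq_len(w))])
      s <- paste(bases[idx], collapse = "")
      for (o in 1:(w - k + 1)) {
        v[substr(s, o, o + k - 1)] <- v[substr(s, o, o + k - 1)] + prob
      }
    }
    v
  }
  expected_for(pfm_prob(pfm)) + expected_for(pfm_prob(pfm_rc(pfm)))
}

random_pfm <- function(w, id = "r", seed = 1) {
  withr::with_seed(seed, pfm(matrix(stats::runif(4 * w, 0, 10), 4, w), id = id))
}

random_promoters <- function(n, L = 200L, seed = 1,
                             comp = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)) {
  withr::with_seed(seed, tibble::tibble(
    gene = sprintf("g%04d", seq_len(n)),
    seq = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, TRUE, comp), collapse = ""), ""),
    L = as.integer(L), width = as.integer(L), strand = "+", truncated = FALSE
  ))
}
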