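test_that("k-mer vectors match the exhaustive sequence-enumeration oracle", {
  # deterministic PFM AAAA at k = 4: only AAAA (forward) and TTTT (rc)
  m <- consensus_pfm("AAAA", id = "a4", strength = 1, pseudocount = 0)
  v <- pfm_kmer_vector(m, k = 4)
  expect_equal(unname(v["AAAA"]), 1)
  expect_equal(unname(v["TTTT"]), 1)
  expect_equal(sum(v), 2)
  expect_equal(sum(v != 0), 2)

  # k = width: total mass is exactly 2
  r <- random_pfm(5, seed = 3)
  expect_equal(sum(pfm_kmer_vector(r, k = 5)), 2, tolerance = 1e-9)

  # random PFMs against brute-force enumeration of all 4^w sequences
  for (case in list(c(w = 5, k = 3), c(w = 6, k = 4), c(w = 6, k = 2))) {
    m <- random_pfm(case["w"], seed = case["w"] * 10 + case["k"])
    got <- pfm_kmer_vector(m, k = case["k"])
    want <- enum_kmer_vector(m, case["k"])
    expect_equal(got[names(want)], want, tolerance = 1e-9)
  }
  expect_error(pfm_kmer_vector(random_pfm(4, seed = 1), k = 5), "width")
})

test_that("k-mer vectors are strand-symmetric", {
  for (s in 1:5) {
    m <- random_pfm(7, seed = s)
    expect_equal(pfm_kmer_vector(m, 4), pfm_kmer_vector(pfm_rc(m), 4),
                 tolerance = 1e-12)
  }
})

test_that("Pearson-correlation distances match direct computation", {
  withr::with_seed(5, {
    vecs <- lapply(1:5, function(i) runif(64))
  })
  names(vecs) <- paste0("m", 1:5)
  D <- motif_distance_matrix(vecs)
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  expect_equal(D, t(D))
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(D[i, j], 1 - stats::cor(vecs[[i]], vecs[[j]]),
                 tolerance = 1e-12)
  }
  # affine invariance: v vs a*v + b at a > 0 has distance 0
  v <- vecs[[1]]
  D2 <- motif_distance_matrix(list(a = v, b = 2.5 * v + 1))
  expect_equal(D2[1, 2], 0, tolerance = 1e-12)
  # zero-variance vector: distance 1 with a warning
  expect_warning(D3 <- motif_distance_matrix(list(a = v, z = rep(1, 64))),
                 "zero-variance")
  expect_equal(D3[1, 2], 1)
})

test_that("average-linkage heights equal the naive O(M^3) UPGMA oracle", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      M <- sample(5:8, 1)
      pts <- matrix(rnorm(M * 3), M)
      D <- as.matrix(dist(pts))
      rownames(D) <- colnames(D) <- paste0("m", seq_len(M))
      cl <- cluster_motifs(D, k = 2)
      hc <- attr(cl, "tree")
      expect_equal(sort(hc$height), sort(naive_upgma_heights(D)),
                   tolerance = 1e-12)
    }
  })
})

test_that("silhouette-chosen k recovers separated groups; k = M gives singletons", {
  withr::with_seed(13, {
    a <- matrix(rnorm(4 * 8, 0, 0.1), 4)
    b <- matrix(rnorm(4 * 8, 10, 0.1), 4)
  })
  D <- as.matrix(dist(rbind(a, b)))
  rownames(D) <- colnames(D) <- paste0("m", 1:8)
  cl <- cluster_motifs(D, k = "auto")
  expect_equal(attr(cl, "k"), 2L)
  expect_equal(length(unique(cl$cluster[1:4])), 1)
  expect_equal(length(unique(cl$cluster[5:8])), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])
  singletons <- cluster_motifs(D, k = 8)
  expect_equal(sort(unique(singletons$cluster)), 1:8)
  expect_error(cluster_motifs(D[1, 1, drop = FALSE]), "at least 2")
})

test_that("group specificity equals exhaustive hypergeometric enumeration (N <= 12)", {
  expect_equal(group_specificity(3, 5, 4, 10), 66 / 252, tolerance = 1e-12)
  expect_equal(group_specificity(0, 5, 4, 10), 1)
  expect_equal(group_specificity(6, 6, 6, 6), 1)
  for (N in c(6, 9, 12)) {
    for (K in c(2, N %/% 2, N - 1)) {
      for (n in c(2, N %/% 2)) {
        for (k in 0:min(n, K)) {
          expect_equal(group_specificity(k, n, K, N),
                       enum_hyper_tail(k, n, K, N), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
  expect_error(group_specificity(6, 5, 4, 10), "inconsistent")
})

test_that("representatives take the smallest score, ties to the smallest id", {
  clusters <- tibble::tibble(motif = c("m1", "m2", "m3", "m4", "m5"),
                             cluster = c(1L, 1L, 1L, 2L, 3L))
  scores <- tibble::tibble(motif = c("m1", "m2", "m3", "m4", "m5"),
                           score = c(0.2, 0.01, 0.5, 0.3, 0.9))
  reps <- select_representatives(clusters, scores)
  expect_equal(reps$motif, c("m2", "m4", "m5"))
  # tie on score -> lexicographically smallest id
  scores2 <- scores
  scores2$score <- c(0.1, 0.1, 0.5, 0.3, 0.9)
  clusters2 <- clusters
  clusters2$motif <- c("m2", "m1", "m3", "m4", "m5")
  reps2 <- select_representatives(clusters2, scores2)
  expect_equal(reps2$motif[reps2$cluster == 1], "m1")
  expect_error(select_representatives(clusters, scores[1:3, ]), "score")
})

test_that("self-comparison is a perfect known match; determinism holds", {
  lib <- list(consensus_pfm("TACGTAGG", "lib1"), consensus_pfm("CCCGTTAA", "lib2"))
  res <- compare_motifs(lib[[1]], lib, seed = 4)
  expect_equal(res$score, 1, tolerance = 1e-9)
  expect_equal(res$match, "lib1")
  expect_lt(res$p_value, 0.001)
  expect_equal(res$verdict, "known")
  res2 <- compare_motifs(lib[[1]], lib, seed = 4)
  expect_identical(tidy(res), tidy(res2))
})

test_that("queries unrelated to a decoy-only library are called novel", {
  verdicts <- vapply(1:5, function(sd) {
    q <- withr::with_seed(sd, consensus_pfm(paste(
      sample(c("A", "C", "G", "T"), 8, TRUE), collapse = ""), id = "q"))
    lib <- make_motif_library(list(), n_decoys = 5, seed = sd + 50)
    compare_motifs(q, lib, n_null = 500, seed = sd)$verdict
  }, "")
  expect_gte(mean(verdicts == "novel"), 0.95)
})

test_that("redundant discovered motifs collapse to one representative per planted motif", {
  # near-duplicate PFMs of one planted consensus plus two unrelated motifs
  ok <- vapply(1:5, function(sd) {
    base <- consensus_pfm("TTACGTAA", "dup1", strength = 0.9)
    dup2 <- base; dup2$id <- "dup2"
    dup3 <- withr::with_seed(sd, {
      d <- base; d$counts <- d$counts + matrix(runif(32, 0, 3), 4); d$id <- "dup3"; d
    })
    other1 <- consensus_pfm("GGGGCCCC", "oth1", strength = 0.9)
    other2 <- consensus_pfm("ACACACAC", "oth2", strength = 0.9)
    motifs <- list(base, dup2, dup3, other1, other2)
    vecs <- lapply(motifs, pfm_kmer_vector, k = 4)
    names(vecs) <- vapply(motifs, `[[`, "", "id")
    cl <- cluster_motifs(motif_distance_matrix(vecs), k = "auto")
    scores <- tibble::tibble(motif = names(vecs),
                             score = c(0.01, 0.02, 0.03, 0.2, 0.3))
    reps <- select_representatives(cl, scores)
    sum(startsWith(reps$motif, "dup")) == 1
  }, TRUE)
  expect_true(all(ok))
})

test_that("re-clustering representatives yields no zero-distance merges", {
  motifs <- list(consensus_pfm("TTACGTAA", "a"), consensus_pfm("GGGGCCCC", "b"),
                 consensus_pfm("ACACACAC", "c"))
  vecs <- lapply(motifs, pfm_kmer_vector, k = 4)
  names(vecs) <- c("a", "b", "c")
  D <- motif_distance_matrix(vecs)
  cl <- cluster_motifs(D, k = 3)
  expect_equal(sort(unique(cl$cluster)), 1:3)
  expect_true(all(D[upper.tri(D)] > 0))
})
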