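#' Position frequency matrix (PFM)
#'
#' The unit of all motif operations: a 4 x width matrix of nonnegative base
#' counts (rows A, C, G, T), an identifier, and a pseudocount that is added
#' per cell when the counts are converted to column probabilities.
#'
#' @param counts numeric matrix of base counts. Either 4 x width with rows in
#'   A,C,G,T order, or width x 4 (transposed on input).
#' @param id motif identifier
#' @param pseudocount value added to every cell before normalization
#'   (default 0.25)
#' @return an object of class `pfm`
#' @export
#' @examples
#' m <- pfm(matrix(c(10, 0, 0, 0), 4, 6), id = "polyA")
#' pfm_consensus(m)
pfm <- function(counts, id = "motif", pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("PFM counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("PFM counts must be nonnegative")
  w <- ncol(counts)
  if (w < 4 || w > 30) stop("PFM width must be between 4 and 30, got ", w)
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  dimnames(counts) <- list(BASES, NULL)
  structure(
    list(id = as.character(id), counts = counts, pseudocount = pseudocount),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$id, "  width=", pfm_width(x),
      "  consensus=", pfm_consensus(x), "\n", sep = "")
  print(round(pfm_prob(x), 3))
  invisible(x)
}

#' @rdname pfm
#' @param x a `pfm`
#' @export
pfm_width <- function(x) ncol(x$counts)

#' Column probability matrix of a PFM
#'
#' Adds the pseudocount to every cell and normalizes each column to sum to 1.
#' @param x a `pfm`
#' @return 4 x width probability matrix
#' @export
pfm_prob <- function(x) {
  p <- x$counts + x$pseudocount
  sweep(p, 2, colSums(p), "/")
}

#' @rdname pfm
#' @export
pfm_consensus <- function(x) {
  paste(BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Reverse complement of a PFM
#'
#' Reverses the column order and swaps complementary base rows.
#' @param x a `pfm`
#' @export
pfm_rc <- function(x) {
  rc <- x$counts[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(x$counts))), drop = FALSE]
  pfm(rc, id = x$id, pseudocount = x$pseudocount)
}

#' Build a sharp PFM around a consensus sequence
#'
#' Convenience constructor for simulations: the consensus base of each column
#' receives `strength` of the total count mass, the rest is split evenly.
#'
#' @param consensus DNA string (ACGT)
#' @param strength fraction of counts on the consensus base per column
#' @param total total count per column
#' @inheritParams pfm
#' @export
consensus_pfm <- function(consensus, id = consensus, strength = 0.97,
                          total = 100, pseudocount = 0.25) {
  b <- seq_codes(consensus)
  if (any(b == 5L)) stop("consensus must contain only A/C/G/T")
  w <- length(b)
  counts <- matrix(total * (1 - strength) / 3, 4, w)
  counts[cbind(b, seq_len(w))] <- total * strength
  pfm(counts, id = id, pseudocount = pseudocount)
}

# sample one site column-wise from the PFM's raw count frequencies (the
# pseudocount regularizes scanning only, not site generation)
sample_site <- function(x) {
  if (any(colSums(x$counts) == 0)) stop("PFM has an empty column")
  p <- sweep(x$counts, 2, colSums(x$counts), "/")
  paste(vapply(seq_len(ncol(p)),
               function(j) sample(BASES, 1, prob = p[, j]), ""),
        collapse = "")
}
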