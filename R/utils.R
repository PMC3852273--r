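#' @keywords internal
BASES <- c("A", "C", "G", "T")

# lookup table: ASCII code -> base index (A/C/G/T = 1..4, anything else 5)
.base_code_table <- local({
  tbl <- rep(5L, 256L)
  tbl[utf8ToInt("A")] <- 1L; tbl[utf8ToInt("a")] <- 1L
  tbl[utf8ToInt("C")] <- 2L; tbl[utf8ToInt("c")] <- 2L
  tbl[utf8ToInt("G")] <- 3L; tbl[utf8ToInt("g")] <- 3L
  tbl[utf8ToInt("T")] <- 4L; tbl[utf8ToInt("t")] <- 4L
  tbl
})

#' Encode a DNA string as base indices
#'
#' A/C/G/T map to 1..4; any other character (e.g. N) maps to 5 and is scored
#' as background during scanning.
#' @param seq single DNA string
#' @return integer vector, one code per base
#' @keywords internal
seq_codes <- function(seq) {
  .base_code_table[utf8ToInt(seq)]
}

#' Reverse-complement character sequences
#'
#' @param x character vector of DNA sequences
#' @return character vector of the same length
#' @export
#' @examples
#' revcomp("ACGGT")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round-half-up, used for the 60/40 split (138 -> 83, 147 -> 88)
round_half_up <- function(x) floor(x + 0.5)

#' Derive a named substream seed from a master seed
#'
#' All randomness in the simulator flows from one master seed through named
#' substreams, so that adding a stage never perturbs the draws of another.
#' @param master integer master seed
#' @param name substream name
#' @return integer seed below 2^31
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# population (divide-by-k) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
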