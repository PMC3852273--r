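#' Read motif matrices
#'
#' Reads a motif library from MEME minimal format (probability matrices; the
#' stored `nsites` restores counts) or JASPAR PFM format (count matrices in
#' four bracketed rows).
#'
#' @param path file path
#' @param format `"meme"` (MEME minimal) or `"jaspar"`
#' @param pseudocount pseudocount attached to each returned [pfm()]
#' @return list of [pfm()] objects
#' @export
read_motifs <- function(path, format = c("meme", "jaspar"), pseudocount = 0.25) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "meme") read_meme_lines(lines, pseudocount)
  else read_jaspar_lines(lines, pseudocount)
}

read_meme_lines <- function(lines, pseudocount) {
  if (!any(grepl("^ALPHABET=\\s*ACGT", lines)))
    stop("not a MEME minimal file: missing 'ALPHABET= ACGT' line")
  idx <- grep("^MOTIF\\s+", lines)
  if (length(idx) == 0) stop("no MOTIF blocks found")
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[idx[i]])), "\\s+")[[1]][1]
    hdr_at <- idx[i] + which(grepl("^letter-probability matrix:",
                                   lines[(idx[i] + 1):length(lines)]))[1]
    if (is.na(hdr_at))
      stop("motif '", id, "': missing letter-probability matrix header (line ",
           idx[i], ")")
    hdr <- lines[hdr_at]
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- suppressWarnings(
      as.numeric(sub(".*\\bnsites=\\s*([0-9.eE+-]+).*", "\\1", hdr)))
    if (is.na(nsites)) nsites <- 20
    rows <- lines[(hdr_at + 1):(hdr_at + w)]
    vals <- lapply(seq_along(rows), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[j]), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v))
        stop("motif '", id, "': malformed probability row at line ",
             hdr_at + j, " (expected 4 numeric columns)")
      v
    })
    probs <- t(do.call(rbind, vals))       # 4 x w
    out[[i]] <- pfm(probs * nsites, id = id, pseudocount = pseudocount)
  }
  out
}

read_jaspar_lines <- function(lines, pseudocount) {
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no JASPAR '>' headers found")
  bounds <- c(idx, length(lines) + 1L)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    id <- strsplit(sub("^>\\s*", "", lines[idx[i]]), "\\s+")[[1]][1]
    block <- lines[(idx[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(trimws(block))]
    if (length(block) < 4)
      stop("motif '", id, "': expected 4 base rows (line ", idx[i], ")")
    rows <- lapply(1:4, function(j) {
      ln <- block[j]
      body <- sub("^\\s*[ACGTacgt]\\s*\\[?", "", ln)
      body <- sub("\\]\\s*$", "", body)
      v <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
      if (anyNA(v) || length(v) == 0)
        stop("motif '", id, "': malformed count row (line ", idx[i] + j, ")")
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif '", id, "': base rows have unequal widths")
    out[[i]] <- pfm(do.call(rbind, rows), id = id, pseudocount = pseudocount)
  }
  out
}

#' Write motif matrices
#'
#' @param motifs list of [pfm()] objects
#' @param path output file
#' @param format `"meme"` or `"jaspar"`
#' @param bg background frequencies written into the MEME header
#' @export
write_motifs <- function(motifs, path, format = c("meme", "jaspar"),
                         bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  format <- match.arg(format)
  if (inherits(motifs, "pfm")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "meme") {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
                 "Background letter frequencies",
                 sprintf("A %.5f C %.5f G %.5f T %.5f",
                         bg[1], bg[2], bg[3], bg[4]), ""), con)
    for (m in motifs) {
      nsites <- mean(colSums(m$counts))
      probs <- sweep(m$counts, 2, colSums(m$counts), "/")
      writeLines(sprintf("MOTIF %s", m$id), con)
      writeLines(sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %.8g E= 0",
        pfm_width(m), nsites), con)
      writeLines(apply(probs, 2, function(p)
        paste(sprintf("%.10f", p), collapse = " ")), con)
      writeLines("", con)
    }
  } else {
    for (m in motifs) {
      writeLines(sprintf(">%s %s", m$id, m$id), con)
      for (j in 1:4) {
        writeLines(sprintf("%s  [ %s ]", BASES[j],
                           paste(sprintf("%.6g", m$counts[j, ]),
                                 collapse = " ")), con)
      }
    }
  }
  invisible(path)
}
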