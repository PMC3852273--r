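#' Read a genome FASTA
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] named by sequence id
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read / write BED6 gene annotations
#'
#' Uses rtracklayer; coordinates are returned 0-based half-open as in the BED
#' file itself.
#'
#' @param path BED6 file
#' @return tibble: chrom, start, end, gene, score, strand
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    gene = gr$name,
    score = as.integer(gr$score %||% 0L),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' @rdname read_bed
#' @param annotations annotation tibble
#' @export
write_bed <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = annotations$strand,
    name = annotations$gene,
    score = annotations$score %||% 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read an expression matrix and its sample-to-structure map
#'
#' The expression TSV has a `gene` column followed by one column per sample;
#' the map TSV has columns `sample` and `structure`. Missing values are
#' rejected.
#'
#' @param expr_path expression TSV
#' @param map_path sample map TSV
#' @return list with `expression` and `sample_map` tibbles
#' @export
read_expression <- function(expr_path, map_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  map <- readr::read_tsv(map_path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(expr)) stop("expression file needs a 'gene' column")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (!all(c("sample", "structure") %in% names(map)))
    stop("sample map needs 'sample' and 'structure' columns")
  missing <- setdiff(setdiff(names(expr), "gene"), map$sample)
  if (length(missing) > 0)
    stop("samples missing from the map: ", paste(missing, collapse = ", "))
  list(expression = expr, sample_map = map)
}

#' Write / read a promoter set as FASTA
#'
#' Headers follow `geneid|L|strand|truncated` so a written set re-reads to an
#' identical tibble.
#'
#' @param promoters promoter tibble from [extract_promoters()]
#' @param path FASTA path
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$seq)
  names(ss) <- sprintf("%s|%d|%s|%d", promoters$gene, promoters$L,
                       promoters$strand, as.integer(promoters$truncated))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(ss), stringr::fixed("|"), 4)
  sq <- unname(as.character(ss))
  tibble::tibble(
    gene = parts[, 1],
    seq = sq,
    L = as.integer(parts[, 2]),
    width = nchar(sq),
    strand = parts[, 3],
    truncated = parts[, 4] == "1"
  )
}

#' Write / read a motif pattern file
#'
#' Structured text: comment header recording provenance (structure,
#' thresholds, scan parameters), then one required (motif, bin, strand) cell
#' per line.
#'
#' @param pattern a [build_pattern()] result
#' @param path output path
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "motif_pattern"))
  hdr <- c("# promarch motif pattern",
           sprintf("# structure: %s", pattern$structure %||% "NA"),
           sprintf("# presence_threshold: %g", pattern$threshold),
           sprintf("# theta: %g", pattern$params$theta %||% NA),
           sprintf("# n_promoters: %d", pattern$n_promoters),
           "motif\tbin\tstrand")
  rows <- sprintf("%s\t%d\t%s", pattern$cells$motif, pattern$cells$bin,
                  pattern$cells$strand)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_pattern
#' @param motifs list of [pfm()] to attach to the read pattern (matched by id)
#' @export
read_pattern <- function(path, motifs = list()) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(ln) == 0) NA_character_ else sub(paste0("^# ", key, ": "), "", ln[1])
  }
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE, progress = FALSE)
  ids <- vapply(motifs, `[[`, "", "id")
  new_motif_pattern(
    cells = tibble::tibble(motif = as.character(df$motif),
                           bin = as.integer(df$bin),
                           strand = as.character(df$strand)),
    threshold = as.numeric(get_meta("presence_threshold")),
    motifs = motifs[ids %in% df$motif],
    n_promoters = as.integer(get_meta("n_promoters")),
    structure = get_meta("structure"),
    params = scan_params(theta = as.numeric(get_meta("theta")))
  )
}
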