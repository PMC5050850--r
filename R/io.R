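#' @import methods
#' @importFrom stats median rnbinom runif rbinom rnorm setNames complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; sequences are
#' returned as uppercase character strings named by record id (first
#' whitespace-delimited token of the header).
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' Returns the plain read container used throughout the preprocessing
#' stages: a data frame with `id`, `seq` and `qual` (Phred+33 quality
#' string) columns.
#'
#' @param path file path.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on conversion
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x)),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ
#'
#' @param reads data frame with `id`, `seq`, `qual` columns.
#' @param path output file path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a BED6 file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Missing optional columns (name, score, strand) are filled with defaults.
#'
#' @param path file path.
#' @return interval table (`chrom`, `start`, `end`, `strand`, `name`,
#'   `score`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L)
    return(gi(character(0), integer(0), integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates")
  out <- data.frame(
    chrom = get(1, NA), start = start, end = end,
    strand = ifelse(get(6, "*") %in% c("+", "-"), get(6, "*"), "*"),
    name = ifelse(get(4, ".") == ".", NA_character_, get(4, ".")),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

#' Write an interval table to BED6
#'
#' @param x interval table.
#' @param path output file path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  nm <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  sc <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0
  st <- if ("strand" %in% names(x)) x$strand else "*"
  st[st == "*"] <- "."
  lines <- paste(x$chrom, x$start, x$end, nm, sc, st, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file
#'
#' GFF3 coordinates are 1-based closed; they are converted to the internal
#' 0-based half-open convention on the way in (start-1, end unchanged), so a
#' GFF line with start=101, end=200 becomes the internal interval (100, 200).
#' The `ID` and `Name` attributes are surfaced; all other attributes are kept
#' verbatim in an `attributes` column so that a write/read cycle is lossless.
#'
#' @param path file path.
#' @return interval table with additional columns `source`, `type`, `score`,
#'   `attributes`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- gi(character(0), integer(0), integer(0))
    out$source <- character(0); out$type <- character(0)
    out$score <- numeric(0); out$attributes <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L)
    stop("malformed GFF3 line ", lineno[bad[1]], ": expected 9 fields, got ",
         lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad) > 0L)
    stop("malformed GFF3 line ", lineno[bad[1]], ": non-integer coordinates")
  attr_field <- m[, 9]
  get_attr <- function(key) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    mt <- regmatches(attr_field, regexec(pat, attr_field))
    vapply(mt, function(g) if (length(g) == 2L) g[2] else NA_character_, "")
  }
  out <- data.frame(
    chrom = m[, 1], start = start1 - 1L, end = end1,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
    name = get_attr("Name"), id = get_attr("ID"),
    source = m[, 2], type = m[, 3],
    score = suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6]))),
    attributes = attr_field,
    stringsAsFactors = FALSE
  )
  validate_intervals(out)
  out
}

#' Write an interval table to GFF3
#'
#' The inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based closed (start+1, end unchanged). If the table
#' has an `attributes` column it is written verbatim; otherwise attributes
#' are assembled from `id`/`name`.
#'
#' @param x interval table (extra columns `source`, `type`, `score`,
#'   `attributes`, `id` used when present).
#' @param path output file path.
#' @export
write_gff3 <- function(x, path) {
  validate_intervals(x)
  n <- nrow(x)
  col <- function(nmcol, default) {
    if (nmcol %in% names(x)) x[[nmcol]] else rep(default, n)
  }
  src <- col("source", "mirstack")
  type <- col("type", "region")
  score <- col("score", NA_real_)
  strand <- col("strand", "*")
  strand[strand == "*"] <- "."
  attrs <- if ("attributes" %in% names(x)) {
    x$attributes
  } else {
    id <- col("id", NA_character_)
    nm <- col("name", NA_character_)
    a <- character(n)
    a[!is.na(id)] <- paste0("ID=", id[!is.na(id)])
    both <- !is.na(id) & !is.na(nm)
    a[both] <- paste0(a[both], ";Name=", nm[both])
    only_nm <- is.na(id) & !is.na(nm)
    a[only_nm] <- paste0("Name=", nm[only_nm])
    a[!nzchar(a)] <- "."
    a
  }
  lines <- paste(x$chrom, src, type, x$start + 1L, x$end,
                 ifelse(is.na(score), ".", format(score, trim = TRUE)),
                 strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a minimal SAM file
#'
#' Only the fields the pipeline needs are parsed: query name, the strand bit
#' of the flag, reference name, 1-based position (converted to internal
#' 0-based half-open) and the aligned length taken from the sequence (the
#' pipeline emits exact, gap-free matches only, so CIGAR is `<len>M`).
#' Unmapped records (flag bit 0x4) are skipped.
#'
#' @param path file path.
#' @return alignment table with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "@")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad) > 0L)
    stop("malformed SAM line ", lineno[bad[1]], ": fewer than 11 fields")
  m <- do.call(rbind, lapply(fields, function(f) f[1:11]))
  flag <- suppressWarnings(as.integer(m[, 2]))
  pos <- suppressWarnings(as.integer(m[, 4]))
  bad <- which(is.na(flag) | is.na(pos))
  if (length(bad) > 0L)
    stop("malformed SAM line ", lineno[bad[1]], ": non-integer flag/pos")
  mapped <- bitwAnd(flag, 4L) == 0L
  len <- nchar(m[, 10])
  data.frame(
    read_id = m[mapped, 1],
    chrom = m[mapped, 3],
    start = pos[mapped] - 1L,
    end = pos[mapped] - 1L + len[mapped],
    strand = ifelse(bitwAnd(flag[mapped], 16L) > 0L, "-", "+"),
    seq = m[mapped, 10],
    stringsAsFactors = FALSE
  )
}

#' Write alignments to a minimal SAM file
#'
#' Emits a valid header (`@HD`, `@SQ` from the supplied chromosome lengths)
#' and one gap-free record per alignment with CIGAR `<len>M` and MAPQ 255.
#' Minus-strand records store the reverse complement of the read, following
#' the SAM convention.
#'
#' @param aln alignment table (`read_id`, `chrom`, `start`, `end`, `strand`,
#'   `seq` holding the read sequence in original orientation).
#' @param chrom_lengths named integer vector of reference lengths.
#' @param path output file path.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(chrom_lengths), "\tLN:",
                  as.integer(chrom_lengths)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  o <- order(aln$chrom, aln$start, aln$end, aln$read_id)
  aln <- aln[o, , drop = FALSE]
  seq_out <- ifelse(aln$strand == "-", revcomp(aln$seq), aln$seq)
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  len <- aln$end - aln$start
  rec <- paste(aln$read_id, flag, aln$chrom, aln$start + 1L, 255L,
               paste0(len, "M"), "*", 0L, 0L, seq_out,
               strrep("I", len), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector over A/C/G/T/U/N (case-insensitive; U treated
#'   as T on the way in, output is DNA alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  up <- chartr("Uu", "TT", toupper(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}
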