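#' Trim the 3' sequencing adapter from reads
#'
#' Scans each read left to right for the first position where the remainder
#' of the read matches a prefix of the adapter with a mismatch rate of at
#' most `max_error_rate` (mismatches allowed: `floor(rate * overlap)`), over
#' an overlap of at least `min_overlap` bases. Everything from that position
#' onward is removed, quality string in step — so an internal adapter match
#' removes the adapter and any bases sequenced past it, and a partial match
#' at the read end removes the longest suffix matching an adapter prefix.
#' Reads without a qualifying match pass through untrimmed.
#'
#' @param reads read table (`id`, `seq`, `qual`).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum adapter overlap in nt.
#' @param max_error_rate maximum mismatch rate within the matched overlap.
#' @return the read table with trimmed `seq`/`qual` and a logical `trimmed`
#'   column.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L,
                         max_error_rate = 0.1) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  adapter <- toupper(adapter)
  n <- nrow(reads)
  if (n == 0L) {
    reads$trimmed <- logical(0)
    return(reads)
  }
  seq <- toupper(reads$seq)
  len <- nchar(seq)
  alen <- nchar(adapter)
  achar <- strsplit(adapter, "", fixed = TRUE)[[1]]
  cut_at <- rep(NA_integer_, n)   # 0-based offset where the adapter starts
  unresolved <- rep(TRUE, n)
  for (p in seq_len(max(len))) {
    idx <- which(unresolved & len - p + 1L >= min_overlap)
    if (length(idx) == 0L) break
    k <- pmin(alen, len[idx] - p + 1L)
    mism <- integer(length(idx))
    for (j in seq_len(max(k))) {
      active <- k >= j
      cmp <- substr(seq[idx[active]], p + j - 1L, p + j - 1L) != achar[j]
      mism[active] <- mism[active] + as.integer(cmp)
    }
    hit <- mism <= floor(max_error_rate * k)
    if (any(hit)) {
      cut_at[idx[hit]] <- p - 1L
      unresolved[idx[hit]] <- FALSE
    }
  }
  out <- reads
  found <- !is.na(cut_at)
  out$seq[found] <- substr(reads$seq[found], 1L, cut_at[found])
  if ("qual" %in% names(out))
    out$qual[found] <- substr(reads$qual[found], 1L, cut_at[found])
  out$trimmed <- found
  out
}

phred_values <- function(qual) {
  codes <- utf8ToInt(paste(qual, collapse = "")) - 33L
  split(codes, rep.int(seq_along(qual), nchar(qual)))
}

#' Quality-filter reads
#'
#' Keeps a read iff at least `min_fraction` of its bases have a Phred
#' quality of at least `min_q` (the FASTX `fastq_quality_filter -q 20 -p 80`
#' rule; a read with exactly 80 % qualifying bases is kept).
#'
#' @param reads read table with a `qual` column (Phred+33).
#' @param min_q Phred threshold.
#' @param min_fraction minimum fraction of bases at or above `min_q`.
#' @return the surviving rows of `reads`.
#' @export
quality_filter <- function(reads, min_q = 20L, min_fraction = 0.8) {
  if (nrow(reads) == 0L) return(reads)
  if (!"qual" %in% names(reads) || anyNA(reads$qual))
    stop("quality_filter requires per-base qualities")
  nch <- nchar(reads$qual)
  keep <- rep(FALSE, nrow(reads))   # fully-trimmed (empty) reads are dropped
  nz <- nch > 0L
  if (any(nz)) {
    codes <- utf8ToInt(paste(reads$qual[nz], collapse = "")) - 33L
    grp <- rep.int(seq_len(sum(nz)), nch[nz])
    n_ok <- as.vector(rowsum(as.integer(codes >= min_q), grp))
    keep[nz] <- n_ok / nch[nz] >= min_fraction
  }
  reads[keep, , drop = FALSE]
}

#' Length-filter reads
#'
#' Retains reads with `min_len <= length <= max_len`, preserving order.
#' Used twice in the pipeline: at QC with (15, 27) and before hairpin
#' discovery with the stricter (18, 23).
#'
#' @param reads read table.
#' @param min_len,max_len inclusive length bounds (nt).
#' @return the surviving rows of `reads`.
#' @export
length_filter <- function(reads, min_len, max_len) {
  stopifnot(min_len <= max_len)
  if (nrow(reads) == 0L) return(reads)
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Exact-match alignment of reads to a genome
#'
#' Reports every exact placement of each read on either strand of the
#' genome (no mismatches), suppressing reads with more than `max_hits` total
#' placements entirely — the `bowtie -v 0 -a -m 200` contract. A
#' minus-strand placement is an occurrence of the read's reverse complement
#' on the forward genome. Output is coordinate-sorted and deterministic.
#'
#' Matching is delegated to [Biostrings::matchPDict()] on constant-width
#' dictionaries of the unique read sequences (per width, per strand);
#' sequences containing N fall back to [Biostrings::matchPattern()].
#'
#' @param reads read table (`id`, `seq`).
#' @param genome named character vector of chromosome sequences.
#' @param max_hits suppress reads with more than this many placements.
#' @return alignment table: `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `seq` (read sequence, original orientation), `n_hits`.
#' @export
align_exact <- function(reads, genome, max_hits = 200L) {
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0),
                      n_hits = integer(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  seqs <- toupper(reads$seq)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("reads must contain only A/C/G/T/N")
  uniq <- unique(seqs)
  chroms <- lapply(genome, Biostrings::DNAString)
  # placements per unique sequence: list of (chrom, start0, strand)
  place <- vector("list", length(uniq))
  names(place) <- uniq
  for (u in uniq) place[[u]] <- list(chrom = character(0),
                                     start = integer(0),
                                     strand = character(0))
  add_hits <- function(useq, chrom_name, starts1, strand) {
    if (length(starts1) == 0L) return()
    p <- place[[useq]]
    p$chrom <- c(p$chrom, rep(chrom_name, length(starts1)))
    p$start <- c(p$start, starts1 - 1L)
    p$strand <- c(p$strand, rep(strand, length(starts1)))
    place[[useq]] <<- p
  }
  has_n <- grepl("N", uniq, fixed = TRUE)
  clean <- uniq[!has_n]
  if (length(clean) > 0L) {
    widths <- nchar(clean)
    for (w in unique(widths)) {
      sub <- clean[widths == w]
      fwd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
      rev <- Biostrings::PDict(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(sub)))
      for (cn in names(genome)) {
        mf <- Biostrings::matchPDict(fwd, chroms[[cn]])
        mr <- Biostrings::matchPDict(rev, chroms[[cn]])
        sf <- Biostrings::startIndex(mf)
        sr <- Biostrings::startIndex(mr)
        for (i in seq_along(sub)) {
          if (!is.null(sf[[i]])) add_hits(sub[i], cn, sf[[i]], "+")
          if (!is.null(sr[[i]])) add_hits(sub[i], cn, sr[[i]], "-")
        }
      }
    }
  }
  for (u in uniq[has_n]) {
    for (cn in names(genome)) {
      mf <- Biostrings::matchPattern(u, chroms[[cn]], fixed = TRUE)
      mr <- Biostrings::matchPattern(revcomp(u), chroms[[cn]], fixed = TRUE)
      add_hits(u, cn, Biostrings::start(mf), "+")
      add_hits(u, cn, Biostrings::start(mr), "-")
    }
  }
  n_place <- vapply(place, function(p) length(p$start), 0L)
  kept <- uniq[n_place >= 1L & n_place <= max_hits]
  if (length(kept) == 0L) return(empty)
  ids_by_seq <- split(reads$id, factor(seqs, levels = kept))
  out <- lapply(kept, function(u) {
    p <- place[[u]]
    ids <- ids_by_seq[[u]]
    m <- length(p$start)
    r <- length(ids)
    if (r == 0L) return(NULL)
    list(read_id = rep(ids, each = m), chrom = rep(p$chrom, r),
         start = rep(p$start, r), end = rep(p$start + nchar(u), r),
         strand = rep(p$strand, r), seq = rep(u, r * m),
         n_hits = rep(m, r * m))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  aln <- data.frame(
    read_id = unlist(lapply(out, `[[`, "read_id"), use.names = FALSE),
    chrom = unlist(lapply(out, `[[`, "chrom"), use.names = FALSE),
    start = unlist(lapply(out, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(out, `[[`, "end"), use.names = FALSE),
    strand = unlist(lapply(out, `[[`, "strand"), use.names = FALSE),
    seq = unlist(lapply(out, `[[`, "seq"), use.names = FALSE),
    n_hits = unlist(lapply(out, `[[`, "n_hits"), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  aln <- aln[order(aln$chrom, aln$start, aln$end, aln$strand, aln$read_id), ,
             drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Run the full read-preprocessing chain
#'
#' Adapter trimming, quality filtering, QC length filtering (15-27 nt) and
#' exact-match alignment, in that order, recording in/out read counts per
#' stage. The stricter discovery length window (18-23 nt) is applied later,
#' on the alignment table, via [discovery_alignments()].
#'
#' @param reads read table (`id`, `seq`, `qual`).
#' @param genome named character vector of chromosome sequences.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len QC length window (nt).
#' @param min_q,min_fraction quality-filter parameters.
#' @param max_hits multi-mapping cap.
#' @return list with `reads` (surviving QC reads), `alignments`, and `log`
#'   (per-stage in/out counts).
#' @export
preprocess_reads <- function(reads, genome, adapter,
                             min_len = 15L, max_len = 27L,
                             min_q = 20L, min_fraction = 0.8,
                             max_hits = 200L) {
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0), stringsAsFactors = FALSE)
  note <- function(stage, n_in, n_out) {
    log <<- rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                                  stringsAsFactors = FALSE))
  }
  n0 <- nrow(reads)
  trimmed <- trim_adapter(reads, adapter)
  note("trim_adapter", n0, nrow(trimmed))
  qc <- quality_filter(trimmed, min_q = min_q, min_fraction = min_fraction)
  note("quality_filter", nrow(trimmed), nrow(qc))
  lf <- length_filter(qc, min_len, max_len)
  note("length_filter_qc", nrow(qc), nrow(lf))
  aln <- align_exact(lf, genome, max_hits = max_hits)
  note("align_exact", nrow(lf), length(unique(aln$read_id)))
  list(reads = lf, alignments = aln, log = log)
}

#' Restrict alignments to the discovery length window
#'
#' @param alignments alignment table from [align_exact()].
#' @param min_len,max_len inclusive read-length bounds (default 18-23 nt,
#'   the discovery window).
#' @return the surviving alignment rows.
#' @export
discovery_alignments <- function(alignments, min_len = 18L, max_len = 23L) {
  if (nrow(alignments) == 0L) return(alignments)
  len <- alignments$end - alignments$start
  alignments[len >= min_len & len <= max_len, , drop = FALSE]
}
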