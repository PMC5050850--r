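#' Signature-score weights
#'
#' The candidate score is an additive surrogate for a full probabilistic
#' miRNA-prediction score: a weighted sum of read depth and four processing
#' signature fractions (see [score_candidate()]). The weights parameterize
#' the relative importance of each ingredient; all downstream calibration is
#' performed on this score's own empirical distribution, so only the
#' ordering it induces matters.
#'
#' @param w_depth weight on `log10(1 + total reads)`.
#' @param w_consistency weight on the modal-5'-start fraction of mature
#'   reads.
#' @param w_overhang weight on the fraction of star reads consistent with a
#'   2-nt 3' overhang.
#' @param w_structure weight on the paired fraction of arm positions.
#' @param w_five_prime weight on the mature/(mature+loop+1) read-ratio term.
#' @return a `score_weights` list.
#' @export
score_weights <- function(w_depth = 1, w_consistency = 2, w_overhang = 1,
                          w_structure = 1, w_five_prime = 2) {
  w <- list(w_depth = w_depth, w_consistency = w_consistency,
            w_overhang = w_overhang, w_structure = w_structure,
            w_five_prime = w_five_prime)
  if (any(unlist(w) < 0)) stop("score weights must be non-negative")
  if (all(unlist(w) == 0)) stop("at least one score weight must be positive")
  class(w) <- "score_weights"
  w
}

#' Cluster aligned reads into stacks
#'
#' A stack is a maximal run of alignments, per chromosome and strand, in
#' which consecutive reads are separated by a gap of at most `max_gap`
#' bases (gap measured from the running maximum end to the next start;
#' overlapping reads have gap <= 0).
#'
#' @param alignments coordinate-sorted alignment table.
#' @param max_gap maximum inter-read gap within a stack (bp).
#' @return list with `stacks` (one row per stack: `stack_id`, `chrom`,
#'   `start`, `end`, `strand`, `n_reads`, `modal_start`, `modal_end`,
#'   `modal_count`) and `assignment` (stack_id per alignment row).
#' @export
build_stacks <- function(alignments, max_gap = 30L) {
  n <- nrow(alignments)
  empty <- data.frame(stack_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_reads = integer(0),
                      modal_start = integer(0), modal_end = integer(0),
                      modal_count = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(list(stacks = empty, assignment = integer(0)))
  o <- order(alignments$chrom, alignments$strand, alignments$start,
             alignments$end)
  assignment <- integer(n)
  sid <- 0L
  rows <- list()
  grp_key <- paste(alignments$chrom[o], alignments$strand[o])
  start_v <- alignments$start[o]; end_v <- alignments$end[o]
  i <- 1L
  while (i <= n) {
    j <- i
    max_end <- end_v[i]
    while (j < n && grp_key[j + 1L] == grp_key[i] &&
           start_v[j + 1L] - max_end <= max_gap) {
      j <- j + 1L
      max_end <- max(max_end, end_v[j])
    }
    sid <- sid + 1L
    idx <- o[i:j]
    assignment[idx] <- sid
    key <- paste(alignments$start[idx], alignments$end[idx])
    tab <- table(key)
    top <- max(tab)
    cand <- names(tab)[tab == top]
    parts <- do.call(rbind, strsplit(cand, " ", fixed = TRUE))
    ms <- as.integer(parts[, 1]); me <- as.integer(parts[, 2])
    pick <- order(ms, me)[1]
    rows[[sid]] <- data.frame(
      stack_id = sid, chrom = alignments$chrom[idx[1]],
      start = min(alignments$start[idx]), end = max_end,
      strand = alignments$strand[idx[1]], n_reads = length(idx),
      modal_start = ms[pick], modal_end = me[pick],
      modal_count = as.integer(top), stringsAsFactors = FALSE
    )
    i <- j + 1L
  }
  list(stacks = do.call(rbind, rows), assignment = assignment)
}

#' Excise candidate precursor windows around a stack's modal read
#'
#' Two windows are proposed, sized to hold a mature arm, loop and star arm:
#' one extending downstream of the modal 5' end (the modal read as 5' arm)
#' and one extending upstream of the modal 3' end (the modal read as 3'
#' arm). Windows are clipped to chromosome bounds and deduplicated.
#'
#' @param stack one row of the stack table from [build_stacks()].
#' @param chrom_length length of the stack's chromosome.
#' @param flank window extension beyond the modal read (bp).
#' @param mature_len assumed mature length used to size the window (bp).
#' @return interval table of one or two candidate windows.
#' @export
excise_precursor <- function(stack, chrom_length, flank = 70L,
                             mature_len = 22L) {
  w <- flank + mature_len
  w1 <- c(stack$modal_start, stack$modal_start + w)
  w2 <- c(stack$modal_end - w, stack$modal_end)
  wins <- rbind(w1, w2)
  wins[, 1] <- pmax(wins[, 1], 0L)
  wins[, 2] <- pmin(wins[, 2], chrom_length)
  keep <- wins[, 2] > wins[, 1]
  wins <- wins[keep, , drop = FALSE]
  wins <- unique(wins)
  gi(stack$chrom, wins[, 1], wins[, 2], stack$strand)
}

#' Assign stack reads to the mature, star and loop precursor products
#'
#' Given a folded candidate window and the read stack it came from, takes
#' the stack's modal read as the mature sequence, infers the star as the
#' base-paired image of the mature on the opposite arm shifted by the 2-nt
#' 3' overhang Dicer leaves, and the loop as the region between the two
#' arms. Every stack read is then assigned to mature, star, loop or outside
#' by maximal overlap (ties favour mature, then star, then loop).
#'
#' The implied star position is the median, over paired mature positions,
#' of the partner extrapolated back to the mature 5' end; this is robust to
#' a few unpaired (mismatched) stem positions.
#'
#' @param window one-row interval table from [excise_precursor()].
#' @param fold result of [fold_hairpin()] on the window sequence.
#' @param stack_aln alignment table of the stack's reads.
#' @param modal_start,modal_end modal read coordinates (genomic, 0-based
#'   half-open).
#' @return `NULL` if the window does not fold into a usable hairpin
#'   (no mature position is paired), otherwise a list with `mature`,
#'   `star`, `loop` interval tables, read tallies `mature_reads`,
#'   `star_reads`, `loop_reads`, `outside_reads`, and the signature
#'   fractions `consistency_5p`, `overhang_frac`, `paired_arm_frac`.
#' @export
assign_arms <- function(window, fold, stack_aln, modal_start, modal_end) {
  wstart <- window$start
  wend <- window$end
  wlen <- wend - wstart
  if (identical(window$strand, "-")) {
    # mirror into transcript orientation (the fold is of the reverse
    # complement, so pairing indices already live in mirrored coordinates),
    # run the plus-strand geometry, then mirror the intervals back
    flip <- function(s, e) cbind(wstart + wend - e, wstart + wend - s)
    aln2 <- stack_aln
    fs <- flip(stack_aln$start, stack_aln$end)
    aln2$start <- fs[, 1]; aln2$end <- fs[, 2]
    fm <- flip(modal_start, modal_end)
    win2 <- window
    win2$strand <- "+"
    res <- assign_arms(win2, fold, aln2, fm[1], fm[2])
    if (is.null(res)) return(NULL)
    for (nm in c("mature", "star", "loop")) {
      iv <- res[[nm]]
      if (is.null(iv)) next
      fi <- flip(iv$start, iv$end)
      iv$start <- fi[, 1]; iv$end <- fi[, 2]; iv$strand <- "-"
      res[[nm]] <- iv
    }
    return(res)
  }
  m_first <- modal_start - wstart + 1L   # 1-based window positions
  m_last <- modal_end - wstart           # inclusive
  m_first_c <- max(m_first, 1L)
  m_last_c <- min(m_last, wlen)
  if (m_first_c > m_last_c) return(NULL)
  mpos <- m_first_c:m_last_c
  partners <- fold$pairing[mpos]
  paired <- !is.na(partners) & (partners < m_first | partners > m_last)
  if (!any(paired)) return(NULL)
  implied_p_first <- round(median(partners[paired] + (mpos[paired] - m_first)))
  m_len <- m_last - m_first + 1L
  star_first <- implied_p_first - m_len + 3L
  star_last <- implied_p_first + 2L
  star_first_c <- max(star_first, 1L)
  star_last_c <- min(star_last, wlen)
  if (star_first_c > star_last_c) return(NULL)
  # genomic intervals (0-based half-open)
  mature <- gi(window$chrom, wstart + m_first_c - 1L, wstart + m_last_c,
               window$strand)
  star <- gi(window$chrom, wstart + star_first_c - 1L, wstart + star_last_c,
             window$strand)
  left_end <- min(mature$end, star$end)
  right_start <- max(mature$start, star$start)
  loop <- if (right_start > left_end)
    gi(window$chrom, left_end, right_start, window$strand) else NULL

  ov_len <- function(iv) {
    if (is.null(iv)) return(rep(0L, nrow(stack_aln)))
    pmax(pmin(stack_aln$end, iv$end) - pmax(stack_aln$start, iv$start), 0L)
  }
  ov <- cbind(mature = ov_len(mature), star = ov_len(star), loop = ov_len(loop))
  best <- max.col(ov, ties.method = "first")
  best[ov[cbind(seq_len(nrow(ov)), best)] == 0L] <- 4L
  tallies <- tabulate(best, nbins = 4L)

  m_reads <- which(best == 1L)
  consistency <- if (length(m_reads) > 0L)
    mean(stack_aln$start[m_reads] == modal_start) else 0
  s_reads <- which(best == 2L)
  exp_star_last <- wstart + star_last_c - 1L      # genomic, 0-based
  overhang <- if (length(s_reads) > 0L)
    mean(stack_aln$end[s_reads] - 1L == exp_star_last) else 0
  arm_pos <- unique(c(mpos, star_first_c:star_last_c))
  paired_frac <- mean(!is.na(fold$pairing[arm_pos]))

  list(mature = mature, star = star, loop = loop,
       mature_reads = tallies[1], star_reads = tallies[2],
       loop_reads = tallies[3], outside_reads = tallies[4],
       consistency_5p = consistency, overhang_frac = overhang,
       paired_arm_frac = paired_frac)
}

#' Score a candidate precursor
#'
#' The signature score is a weighted sum of the processing evidence a true
#' Drosha/Dicer product leaves in read data:
#' \deqn{w_d \log_{10}(1 + n) + w_c f_{5'} + w_o f_{oh} + w_s f_{pair}
#'       + w_5 \frac{n_m}{n_m + n_l + 1}}
#' where `n = n_m + n_s + n_l` is the total precursor read count, `f_5'`
#' the fraction of mature reads sharing the modal 5' start, `f_oh` the
#' fraction of star reads with the expected 2-nt 3' overhang (0 when there
#' are no star reads), and `f_pair` the paired fraction of arm positions.
#' The score is monotone non-decreasing in every ingredient.
#'
#' @param arms result of [assign_arms()].
#' @param weights a [score_weights()] object.
#' @return numeric score.
#' @export
score_candidate <- function(arms, weights = score_weights()) {
  total <- arms$mature_reads + arms$star_reads + arms$loop_reads
  weights$w_depth * log10(1 + total) +
    weights$w_consistency * arms$consistency_5p +
    weights$w_overhang * arms$overhang_frac +
    weights$w_structure * arms$paired_arm_frac +
    weights$w_five_prime *
      (arms$mature_reads / (arms$mature_reads + arms$loop_reads + 1))
}

#' Discover candidate miRNA hairpins from aligned reads
#'
#' The full prediction stage: restrict alignments to the discovery length
#' window, cluster them into stacks, excise up to two precursor windows per
#' stack, fold each window, assign reads to precursor products, score, and
#' greedily resolve overlapping candidates in favour of the higher score.
#' Surviving candidates are named `<chrom>_novelMiR_<k>` in coordinate
#' order.
#'
#' @param alignments alignment table from [align_exact()] (all samples
#'   concatenated).
#' @param genome named character vector of chromosome sequences.
#' @param weights a [score_weights()] object.
#' @param max_gap stack clustering gap (bp).
#' @param flank precursor window extension (bp).
#' @param min_reads minimum reads in a stack for it to seed candidates.
#' @param min_len,max_len discovery read-length window (nt).
#' @return candidate table: one row per prediction with hairpin, mature,
#'   star and loop coordinates, read tallies, signature fractions,
#'   structure and score.
#' @export
discover_hairpins <- function(alignments, genome, weights = score_weights(),
                              max_gap = 30L, flank = 70L, min_reads = 3L,
                              min_len = 18L, max_len = 23L) {
  empty <- data.frame(
    id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0),
    mature_start = integer(0), mature_end = integer(0),
    star_start = integer(0), star_end = integer(0),
    mature_reads = integer(0), star_reads = integer(0),
    loop_reads = integer(0), consistency_5p = numeric(0),
    overhang_frac = numeric(0), paired_arm_frac = numeric(0),
    mature_seq = character(0), structure = character(0),
    score = numeric(0), stringsAsFactors = FALSE
  )
  da <- discovery_alignments(alignments, min_len, max_len)
  if (nrow(da) == 0L) return(empty)
  st <- build_stacks(da, max_gap = max_gap)
  stacks <- st$stacks
  cands <- list()
  for (s in seq_len(nrow(stacks))) {
    stk <- stacks[s, ]
    if (stk$n_reads < min_reads) next
    stack_aln <- da[st$assignment == stk$stack_id, , drop = FALSE]
    wins <- excise_precursor(stk, nchar(genome[[stk$chrom]]), flank = flank)
    for (w in seq_len(nrow(wins))) {
      win <- wins[w, ]
      wseq <- substr(genome[[win$chrom]], win$start + 1L, win$end)
      if (win$strand == "-") wseq <- revcomp(wseq)   # transcript orientation
      fold <- fold_hairpin(wseq)
      arms <- assign_arms(win, fold, stack_aln, stk$modal_start,
                          stk$modal_end)
      if (is.null(arms)) next
      if (arms$mature_reads == 0L) next
      cands[[length(cands) + 1L]] <- data.frame(
        id = NA_character_, chrom = win$chrom, start = win$start,
        end = win$end, strand = win$strand,
        mature_start = arms$mature$start, mature_end = arms$mature$end,
        star_start = arms$star$start, star_end = arms$star$end,
        mature_reads = arms$mature_reads, star_reads = arms$star_reads,
        loop_reads = arms$loop_reads,
        consistency_5p = arms$consistency_5p,
        overhang_frac = arms$overhang_frac,
        paired_arm_frac = arms$paired_arm_frac,
        mature_seq = {
          ms <- substr(genome[[win$chrom]], arms$mature$start + 1L,
                       arms$mature$end)
          if (win$strand == "-") revcomp(ms) else ms
        },
        structure = fold$structure,
        score = score_candidate(arms, weights),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(cands) == 0L) return(empty)
  out <- do.call(rbind, cands)
  # greedy non-overlap selection: keep the higher-scoring of any
  # overlapping pair of candidate windows
  o <- order(-out$score, out$chrom, out$start)
  kept <- integer(0)
  for (i in o) {
    if (length(kept) == 0L ||
        !any(gi_overlaps(out[rep(i, length(kept)), ], out[kept, ]))) {
      kept <- c(kept, i)
    }
  }
  out <- out[kept[order(out$chrom[kept], out$start[kept])], , drop = FALSE]
  out$id <- unlist(lapply(split(seq_len(nrow(out)), out$chrom), function(ix)
    sprintf("%s_novelMiR_%d", out$chrom[ix], seq_along(ix))),
    use.names = FALSE)
  rownames(out) <- NULL
  out
}
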