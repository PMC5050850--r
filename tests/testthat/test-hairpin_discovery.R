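mk_aln <- function(starts, ends, strand = "+", chrom = "chr1") {
  n <- length(starts)
  data.frame(read_id = if (n) paste0("r", seq_len(n)) else character(0),
             chrom = rep_len(chrom, n),
             start = as.integer(starts), end = as.integer(ends),
             strand = rep_len(strand, n),
             seq = rep_len(strrep("A", 20), n), n_hits = rep_len(1L, n),
             stringsAsFactors = FALSE)
}

test_that("stack clustering merges reads within the gap and splits beyond it", {
  # 10 bp gap: one stack
  st <- build_stacks(mk_aln(c(100, 130), c(120, 150)), max_gap = 30L)
  expect_equal(nrow(st$stacks), 1L)
  expect_equal(st$stacks$n_reads, 2L)
  # 31 bp gap: two stacks (boundary)
  st2 <- build_stacks(mk_aln(c(100, 151), c(120, 171)), max_gap = 30L)
  expect_equal(nrow(st2$stacks), 2L)
  # exactly 30 bp gap: still one stack
  st3 <- build_stacks(mk_aln(c(100, 150), c(120, 170)), max_gap = 30L)
  expect_equal(nrow(st3$stacks), 1L)
  # empty input
  st4 <- build_stacks(mk_aln(integer(0), integer(0)))
  expect_equal(nrow(st4$stacks), 0L)
  # strands never share a stack
  aln <- rbind(mk_aln(100, 120, "+"), mk_aln(105, 125, "-"))
  expect_equal(nrow(build_stacks(aln)$stacks), 2L)
})

test_that("the modal read is the most frequent start/end, smallest on ties", {
  aln <- mk_aln(c(100, 100, 100, 105, 105), c(122, 122, 122, 127, 127))
  st <- build_stacks(aln)
  expect_equal(st$stacks$modal_start, 100L)
  expect_equal(st$stacks$modal_count, 3L)
  tie <- build_stacks(mk_aln(c(100, 105), c(122, 127)))
  expect_equal(tie$stacks$modal_start, 100L)
  single <- build_stacks(mk_aln(200, 222))
  expect_equal(single$stacks$modal_start, 200L)
  expect_equal(single$stacks$modal_end, 222L)
})

test_that("precursor windows follow the stated excision arithmetic", {
  stk <- data.frame(chrom = "chr1", strand = "+", modal_start = 1000L,
                    modal_end = 1022L, stringsAsFactors = FALSE)
  wins <- excise_precursor(stk, chrom_length = 10000L, flank = 70L)
  expect_equal(nrow(wins), 2L)
  expect_setequal(paste(wins$start, wins$end),
                  c("1000 1092", "930 1022"))
  # clipping at the chromosome start
  stk0 <- data.frame(chrom = "chr1", strand = "+", modal_start = 10L,
                     modal_end = 32L, stringsAsFactors = FALSE)
  wins0 <- excise_precursor(stk0, chrom_length = 10000L, flank = 70L)
  expect_true(all(wins0$start >= 0L))
  expect_true(any(wins0$start == 0L))
})

test_that("hairpin folding maximizes base pairs with the min-loop constraint", {
  f <- fold_hairpin("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$n_pairs, 3L)
  expect_equal(fold_hairpin("AAAAAA")$n_pairs, 0L)
  # loop constraint blocks all pairs in a 4-mer
  expect_equal(fold_hairpin("GCGC")$n_pairs, 0L)
  expect_error(fold_hairpin("ACGX"), "A/C/G/T/U")
  # G-U wobble pairs count
  expect_equal(fold_hairpin("GGGAAATCC")$n_pairs, 3L)
})

test_that("folding pair counts match exhaustive enumeration on short sequences", {
  set.seed(23)
  for (rep in 1:150) {
    s <- random_seq(sample(4:12, 1))
    expect_equal(fold_hairpin(s)$n_pairs, bf_max_pairs(s), info = s)
  }
})

test_that("dot-bracket output is balanced and consistent with the pairing", {
  set.seed(29)
  for (rep in 1:25) {
    s <- random_seq(sample(20:60, 1))
    f <- fold_hairpin(s)
    expect_equal(nchar(f$structure), nchar(s))
    op <- gregexpr("\\(", f$structure)[[1]]
    cl <- gregexpr("\\)", f$structure)[[1]]
    n_open <- sum(op > 0); n_close <- sum(cl > 0)
    expect_equal(n_open, n_close)
    expect_equal(n_open, f$n_pairs)
    p <- f$pairing
    idx <- which(!is.na(p))
    expect_true(all(p[p[idx]] == idx))    # involution
  }
})

# a deterministic planted hairpin with a textbook read stack
planted_case <- function() {
  set.seed(77)
  mature <- random_seq(22)
  loop <- random_seq(15)
  hairpin <- paste0(mature, loop, revcomp(mature), random_seq(2))
  genome <- c(chr1 = paste0(random_seq(300), hairpin, random_seq(300)))
  h <- 300L
  mat_start <- h; mat_end <- h + 22L
  star_start <- h + 39L; star_end <- h + 61L
  starts <- c(rep(mat_start, 50), rep(star_start, 5),
              rep(h + 20L, 2))                     # 2 loop-ish fragments
  ends <- c(rep(mat_end, 50), rep(star_end, 5), rep(h + 38L, 2))
  list(genome = genome, aln = mk_aln(starts, ends),
       mat_start = mat_start, mat_end = mat_end)
}

test_that("arm assignment recovers mature, star and loop on a planted hairpin", {
  pc <- planted_case()
  win <- gi("chr1", pc$mat_start, pc$mat_start + 92L, "+")
  wseq <- substr(pc$genome[[1]], win$start + 1, win$end)
  arms <- assign_arms(win, fold_hairpin(wseq), pc$aln,
                      pc$mat_start, pc$mat_end)
  expect_equal(arms$mature$start, pc$mat_start)
  expect_equal(arms$star$start, pc$mat_start + 39L)
  expect_equal(arms$star$end, pc$mat_start + 61L)
  expect_equal(arms$mature_reads, 50L)
  expect_equal(arms$star_reads, 5L)
  expect_gt(arms$mature_reads, arms$star_reads)
  expect_gte(arms$star_reads, arms$loop_reads)
  expect_equal(arms$consistency_5p, 1)
  expect_equal(arms$overhang_frac, 1)        # perfect 2-nt 3' overhang
  expect_gte(arms$paired_arm_frac, 0.95)
})

test_that("a read straddling a boundary is assigned by maximal overlap", {
  pc <- planted_case()
  win <- gi("chr1", pc$mat_start, pc$mat_start + 92L, "+")
  wseq <- substr(pc$genome[[1]], win$start + 1, win$end)
  # 60% of this read overlaps the mature arm, 40% the loop
  straddle <- mk_aln(pc$mat_start + 10L, pc$mat_start + 30L)
  arms <- assign_arms(win, fold_hairpin(wseq), straddle,
                      pc$mat_start, pc$mat_end)
  expect_equal(arms$mature_reads, 1L)
  expect_equal(arms$loop_reads, 0L)
})

test_that("a window with no paired mature position is rejected", {
  # all-A window cannot fold; assign_arms signals rejection with NULL
  genome_seq <- strrep("A", 200)
  win <- gi("chr1", 0, 92, "+")
  fold <- fold_hairpin(substr(genome_seq, 1, 92))
  expect_null(assign_arms(win, fold, mk_aln(0, 22), 0L, 22L))
})

test_that("the signature score follows the documented additive form", {
  w <- score_weights()
  # single mature read, unpaired structure: only depth, consistency and
  # the mature/loop ratio term contribute
  arms1 <- list(mature_reads = 1L, star_reads = 0L, loop_reads = 0L,
                consistency_5p = 1, overhang_frac = 0, paired_arm_frac = 0)
  expect_equal(score_candidate(arms1, w),
               1 * log10(2) + 2 * 1 + 0 + 0 + 2 * (1 / 2))
  # perfect signature at 1000 reads
  armsP <- list(mature_reads = 1000L, star_reads = 0L, loop_reads = 0L,
                consistency_5p = 1, overhang_frac = 1, paired_arm_frac = 1)
  expect_equal(score_candidate(armsP, w),
               log10(1001) + 2 + 1 + 1 + 2 * (1000 / 1001),
               tolerance = 1e-12)
  # doubling reads with all fractions fixed strictly increases the score
  arms2 <- arms1; arms2$mature_reads <- 2L
  expect_gt(score_candidate(arms2, w), score_candidate(arms1, w))
  expect_error(score_weights(w_depth = -1), "non-negative")
  expect_error(score_weights(0, 0, 0, 0, 0), "positive")
})

test_that("scores are invariant to read order and coordinate translation", {
  pc <- planted_case()
  win <- gi("chr1", pc$mat_start, pc$mat_start + 92L, "+")
  wseq <- substr(pc$genome[[1]], win$start + 1, win$end)
  fold <- fold_hairpin(wseq)
  arms <- assign_arms(win, fold, pc$aln, pc$mat_start, pc$mat_end)
  shuf <- pc$aln[sample(nrow(pc$aln)), ]
  arms_shuf <- assign_arms(win, fold, shuf, pc$mat_start, pc$mat_end)
  expect_equal(score_candidate(arms), score_candidate(arms_shuf))
  # translate everything by +5000
  off <- 5000L
  aln_t <- pc$aln; aln_t$start <- aln_t$start + off; aln_t$end <- aln_t$end + off
  win_t <- gi("chr1", win$start + off, win$end + off, "+")
  arms_t <- assign_arms(win_t, fold, aln_t, pc$mat_start + off,
                        pc$mat_end + off)
  expect_equal(score_candidate(arms_t), score_candidate(arms))
})

test_that("minus-strand candidates mirror the plus-strand geometry", {
  pc <- planted_case()
  g <- pc$genome[[1]]
  # the same locus viewed on the minus strand of the reverse-complement
  # genome must yield identical tallies and fractions
  g_rc <- revcomp(g)
  L <- nchar(g)
  flip <- function(s, e) c(L - e, L - s)
  aln_m <- pc$aln
  fs <- t(mapply(flip, pc$aln$start, pc$aln$end))
  aln_m$start <- fs[, 1]; aln_m$end <- fs[, 2]; aln_m$strand <- "-"
  fm <- flip(pc$mat_start, pc$mat_end)
  fw <- flip(pc$mat_start, pc$mat_start + 92L)
  win_m <- gi("chr1", fw[1], fw[2], "-")
  wseq_m <- revcomp(substr(g_rc, win_m$start + 1, win_m$end))
  arms_m <- assign_arms(win_m, fold_hairpin(wseq_m), aln_m, fm[1], fm[2])
  win_p <- gi("chr1", pc$mat_start, pc$mat_start + 92L, "+")
  wseq_p <- substr(g, win_p$start + 1, win_p$end)
  arms_p <- assign_arms(win_p, fold_hairpin(wseq_p), pc$aln,
                        pc$mat_start, pc$mat_end)
  for (f in c("mature_reads", "star_reads", "loop_reads",
              "consistency_5p", "overhang_frac", "paired_arm_frac"))
    expect_equal(arms_m[[f]], arms_p[[f]], info = f)
  expect_equal(arms_m$mature$start, flip(arms_p$mature$start,
                                         arms_p$mature$end)[1])
})

test_that("planted miRNA scores stochastically dominate decoy scores", {
  pipe <- reference_pipeline()
  sim <- reference_sim()
  cand <- pipe$candidates
  mir <- sim$truth[sim$truth$kind == "mirna", ]
  dec <- sim$truth[sim$truth$kind %in% c("exon_fragment", "srna"), ]
  on_mir <- count_track_overlaps(cand, gi(mir$chrom, mir$start, mir$end)) > 0
  on_dec <- count_track_overlaps(cand, gi(dec$chrom, dec$start, dec$end)) > 0
  mir_scores <- cand$score[on_mir]
  dec_scores <- cand$score[on_dec & !on_mir]
  expect_gte(length(mir_scores), 20L)
  expect_gte(length(dec_scores), 20L)
  wt <- wilcox.test(mir_scores, dec_scores, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
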