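adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming removes the adapter and everything after it", {
  insert <- "ACGTACGTACGTACGTACGT"          # 20 nt
  read <- data.frame(id = "r1", seq = paste0(insert, adapter),
                     qual = strrep("I", 20 + nchar(adapter)),
                     stringsAsFactors = FALSE)
  out <- trim_adapter(read, adapter)
  expect_equal(out$seq, insert)
  expect_equal(nchar(out$qual), nchar(insert))
  expect_true(out$trimmed)

  # internal adapter followed by sequenced-through junk
  read2 <- data.frame(id = "r2",
                      seq = paste0(insert, adapter, "CCCCGGGG"),
                      qual = strrep("I", 20 + nchar(adapter) + 8),
                      stringsAsFactors = FALSE)
  expect_equal(trim_adapter(read2, adapter)$seq, insert)

  # no adapter anywhere: read passes through untouched
  clean <- data.frame(id = "r3", seq = "ACACACACACACACACACAC",
                      qual = strrep("I", 20), stringsAsFactors = FALSE)
  out3 <- trim_adapter(clean, adapter)
  expect_equal(out3$seq, clean$seq)
  expect_false(out3$trimmed)
})

test_that("adapter matching tolerates mismatches within the 10% error rate", {
  insert <- "ACGTACGTACGTACGTACGT"
  # 12 adapter bases with 1 mismatch: 1/12 = 0.083 <= 0.1, so trimmed
  part <- substr(adapter, 1, 12)
  substr(part, 6, 6) <- if (substr(part, 6, 6) == "A") "C" else "A"
  read <- data.frame(id = "r1", seq = paste0(insert, part),
                     qual = strrep("I", 32), stringsAsFactors = FALSE)
  expect_equal(trim_adapter(read, adapter)$seq, insert)
  # 1 mismatch in 9 bases: 1/9 > 0.1 allows floor(0.9) = 0 errors, untrimmed
  part9 <- substr(adapter, 1, 9)
  substr(part9, 5, 5) <- if (substr(part9, 5, 5) == "A") "C" else "A"
  read9 <- data.frame(id = "r2", seq = paste0(insert, part9),
                      qual = strrep("I", 29), stringsAsFactors = FALSE)
  expect_false(trim_adapter(read9, adapter)$trimmed)
})

test_that("quality filter keeps reads with >= 80% bases at Q20", {
  q30 <- data.frame(id = "a", seq = strrep("A", 10),
                    qual = strrep("?", 10), stringsAsFactors = FALSE)  # Q30
  expect_equal(nrow(quality_filter(q30)), 1L)
  # 7 of 10 bases at Q20+ (70%) is below the 80% requirement
  mix7 <- data.frame(id = "b", seq = strrep("A", 10),
                     qual = paste0(strrep("5", 7), strrep("!", 3)),
                     stringsAsFactors = FALSE)                         # Q20/Q0
  expect_equal(nrow(quality_filter(mix7)), 0L)
  # exactly 80% qualifies (inclusive boundary)
  mix8 <- data.frame(id = "c", seq = strrep("A", 10),
                     qual = paste0(strrep("5", 8), strrep("!", 2)),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(quality_filter(mix8)), 1L)
  expect_error(quality_filter(data.frame(id = "d", seq = "ACGT",
                                         stringsAsFactors = FALSE)),
               "qualities")
})

test_that("length filters apply the QC and discovery windows inclusively", {
  reads <- data.frame(id = paste0("r", 1:8),
                      seq = vapply(c(14, 15, 17, 18, 23, 24, 27, 28),
                                   function(n) strrep("A", n), ""),
                      stringsAsFactors = FALSE)
  qc <- length_filter(reads, 15, 27)
  expect_equal(nchar(qc$seq), c(15, 17, 18, 23, 24, 27))
  disc <- length_filter(reads, 18, 23)
  expect_equal(nchar(disc$seq), c(18, 23))
  expect_equal(nrow(length_filter(reads[0, ], 15, 27)), 0L)
  expect_equal(qc$id, reads$id[nchar(reads$seq) >= 15 & nchar(reads$seq) <= 27])
})

test_that("exact alignment reports all placements on both strands", {
  set.seed(3)
  genome <- c(chrA = random_seq(3000))
  read_seq <- substr(genome, 1001, 1022)
  reads <- data.frame(id = c("fwd", "rev"),
                      seq = c(read_seq, revcomp(read_seq)),
                      stringsAsFactors = FALSE)
  aln <- align_exact(reads, genome)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$start, c(1000L, 1000L))
  expect_equal(sort(aln$strand), c("+", "-"))
  expect_true(all(aln$n_hits == 1L))

  # one mismatch anywhere means no alignment (v = 0 semantics)
  mm <- read_seq
  substr(mm, 11, 11) <- if (substr(mm, 11, 11) == "A") "C" else "A"
  expect_equal(nrow(align_exact(data.frame(id = "m", seq = mm,
                                           stringsAsFactors = FALSE),
                                genome)), 0L)
  expect_error(align_exact(data.frame(id = "x", seq = "ACGTX",
                                      stringsAsFactors = FALSE), genome),
               "A/C/G/T/N")
})

test_that("reads with more than max_hits placements are suppressed entirely", {
  # 201 tandem copies of a 20-mer; the read occurs 201 times on the plus
  # strand, exceeding the cap, so no alignment is emitted at all
  unit <- "ACGTGACCTTGACGTGAACCT"
  genome <- c(chrT = paste(rep(unit, 201), collapse = ""))
  reads <- data.frame(id = "multi", seq = unit, stringsAsFactors = FALSE)
  expect_equal(nrow(align_exact(reads, genome, max_hits = 200L)), 0L)
  aln <- align_exact(reads, genome, max_hits = 201L)
  expect_equal(nrow(aln), 201L)
  expect_true(all(aln$n_hits == 201L))
})

test_that("exact alignment agrees with a brute-force scan of all positions", {
  set.seed(17)
  for (rep in 1:5) {
    genome <- c(g = random_seq(2000))
    # a mix of reads planted in the genome and random ones
    planted <- vapply(1:10, function(i) {
      s <- sample(1900, 1)
      substr(genome, s, s + sample(18:23, 1))
    }, "")
    reads <- data.frame(id = paste0("r", 1:15),
                        seq = c(planted, vapply(rep(20, 5),
                                                random_seq, "")),
                        stringsAsFactors = FALSE)
    aln <- align_exact(reads, genome)
    for (i in seq_len(nrow(reads))) {
      s <- reads$seq[i]
      fwd <- gregexpr(s, genome, fixed = TRUE)[[1]]
      rev <- gregexpr(revcomp(s), genome, fixed = TRUE)[[1]]
      want <- sort(c(if (fwd[1] > 0) fwd - 1L, if (rev[1] > 0) rev - 1L))
      got <- sort(aln$start[aln$read_id == reads$id[i]])
      expect_equal(got, as.integer(want))
    }
  }
})

test_that("the preprocessing chain logs stage counts in pipeline order", {
  sim <- small_sim()
  pp <- preprocess_reads(sim$reads[[1]], sim$genome, sim$config$adapter)
  expect_equal(pp$log$stage, c("trim_adapter", "quality_filter",
                               "length_filter_qc", "align_exact"))
  expect_true(all(pp$log$n_out <= pp$log$n_in))
  expect_true(all(diff(c(pp$log$n_in[1], pp$log$n_in[-1])) <= 0))
})
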