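mk_regions <- function(starts, width = 22L, chrom = "chr1") {
  out <- gi(chrom, starts, starts + width)
  out$id <- paste0("mir", seq_along(starts))
  out
}

test_that("union-mode counting drops reads overlapping multiple regions", {
  regions <- mk_regions(c(100, 115, 500))
  aln <- function(starts, ends) {
    data.frame(read_id = paste0("r", seq_along(starts)), chrom = "chr1",
               start = as.integer(starts), end = as.integer(ends),
               strand = "+", stringsAsFactors = FALSE)
  }
  s1 <- aln(c(100, 110, 505), c(122, 132, 527))
  # read 1 overlaps mir1 and mir2 (ambiguous)? no: [100,122) overlaps
  # mir1=[100,122) and mir2=[115,137) -> ambiguous; read 2 likewise;
  # read 3 hits mir3 only
  counts <- count_reads(list(S1 = s1), regions)
  expect_equal(unname(counts[, 1]), c(0L, 0L, 1L))
  # a read fully inside a single region increments it once
  counts2 <- count_reads(list(S1 = aln(500, 522)), mk_regions(500))
  expect_equal(unname(counts2[, 1]), 1L)
  # no reads: all-zero matrix of the right shape
  counts3 <- count_reads(list(S1 = s1[0, ], S2 = s1[0, ]), regions)
  expect_true(all(counts3 == 0L))
  expect_equal(dim(counts3), c(3L, 2L))
})

test_that("prevalence filter drops rows zero in more than half the samples", {
  m <- matrix(1L, 4, 10, dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
  m[2, 1:6] <- 0L   # zero in 6/10: dropped
  m[3, 1:5] <- 0L   # zero in exactly half: kept
  out <- prevalence_filter(m)
  expect_equal(rownames(out), c("m1", "m3", "m4"))
  # the study-scale boundary: zeros in 47 of 93 samples is "more than half"
  m93 <- matrix(1L, 2, 93)
  m93[1, 1:47] <- 0L
  m93[2, 1:46] <- 0L
  expect_equal(nrow(prevalence_filter(m93)), 1L)
  # never removes a row nonzero in at least half the samples
  set.seed(83)
  r <- matrix(rpois(50 * 8, 0.7), 50, 8)
  kept <- prevalence_filter(r)
  expect_true(all(rowSums(kept == 0) <= 4))
  expect_equal(nrow(kept), sum(rowSums(r == 0) <= 4))
})

test_that("the VST normalizes library size and stabilizes proportional samples", {
  m <- matrix(c(10L, 100L, 40L,
                20L, 200L, 80L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  v <- vst_counts(m)
  # the second sample is exactly double the first: after size-factor
  # normalization the transformed columns coincide
  expect_equal(v[, 1], v[, 2])
  sf <- attr(v, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  # zero counts map to log2(0.5 / sf)
  mz <- matrix(c(0L, 10L, 5L, 7L), 2, 2)
  vz <- vst_counts(mz)
  sfz <- attr(vz, "size_factors")
  expect_equal(vz[1, 1], log2(0 / sfz[1] + 0.5), ignore_attr = TRUE)
  # single sample: size factor 1
  m1 <- matrix(c(3L, 9L), 2, 1)
  expect_equal(unname(attr(vst_counts(m1), "size_factors")), 1)
  # monotone in counts within a sample
  expect_true(all(diff(vst_counts(matrix(c(1L, 5L, 9L), 3, 1))[, 1]) > 0))
})

test_that("batch adjustment removes a constant batch offset", {
  set.seed(89)
  base <- matrix(rnorm(20 * 10, 8), 20, 10)
  batch <- rep(c("b1", "b2"), each = 5)
  shifted <- base
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 2
  adj <- batch_adjust(shifted, batch)
  b1_means <- rowMeans(adj[, batch == "b1"])
  b2_means <- rowMeans(adj[, batch == "b2"])
  expect_equal(b1_means, b2_means, tolerance = 1e-10)
  # single batch: unchanged
  expect_equal(batch_adjust(base, rep("b1", 10)), base)
  # a fully constant row passes through unchanged
  const <- base
  const[1, ] <- 5
  expect_equal(unname(batch_adjust(const, batch)[1, ]), rep(5, 10))
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  # textbook case: all adjusted to the largest
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.01, 0.04, 0.2, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

mk_samples <- function(n_ctrl, n_dis, disease = "HD") {
  data.frame(sample = sprintf("S%02d", seq_len(n_ctrl + n_dis)),
             group = rep(c("control", disease), c(n_ctrl, n_dis)),
             batch = "b1",
             age = rep(seq(60, 90, length.out = n_ctrl), 2)[
               seq_len(n_ctrl + n_dis)],
             stringsAsFactors = FALSE)
}

test_that("identical group distributions give zero fold-change and p near 1", {
  samples <- mk_samples(5, 5)
  vals <- c(1, 5, 2, 4, 3)   # not collinear with the age covariate
  mat <- matrix(c(vals, vals), 1, 10,
                dimnames = list("mirX", samples$sample))
  res <- de_test(mat, samples, c("HD", "control"))
  expect_equal(res$log2fc, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("a planted fold-change is recovered by the linear model", {
  set.seed(97)
  samples <- mk_samples(20, 20)
  null_rows <- matrix(rnorm(30 * 40, 8, 0.3), 30, 40)
  de_row <- c(rnorm(20, 8, 0.3), rnorm(20, 9, 0.3))   # +1 on the VST scale
  mat <- rbind(de_row, null_rows)
  rownames(mat) <- paste0("m", 1:31)
  colnames(mat) <- samples$sample
  res <- de_test(mat, samples, c("HD", "control"))
  expect_lt(abs(res$log2fc[1] - 1), 0.2)
  expect_lt(res$fdr_adjusted_p[1], 0.05)
})

test_that("the sign convention is disease minus control", {
  # four miRNAs with lower disease-group means must all get negative log2FC
  set.seed(101)
  samples <- mk_samples(10, 10)
  mat <- do.call(rbind, lapply(1:4, function(i)
    c(rnorm(10, 8, 0.1), rnorm(10, 7, 0.1))))
  rownames(mat) <- paste0("m", 1:4)
  colnames(mat) <- samples$sample
  res <- de_test(mat, samples, c("HD", "control"))
  expect_true(all(res$log2fc < 0))
  expect_true(all(res$fdr_adjusted_p <= 1 & res$fdr_adjusted_p >= res$p_value))
})

test_that("a constant age covariate is dropped with a warning", {
  samples <- mk_samples(5, 5)
  samples$age <- 70
  mat <- matrix(rnorm(10, 8), 1, 10,
                dimnames = list("mirX", samples$sample))
  expect_warning(de_test(mat, samples, c("HD", "control")), "age")
})

test_that("null simulations yield essentially no discoveries", {
  set.seed(103)
  fracs <- vapply(1:10, function(run) {
    cfg <- sim_config(genome_length = 40000L, n_mirna = 30L, n_withheld = 0L,
                      n_dual_annotated = 0L, n_decoy_exon = 0L,
                      n_decoy_srna = 0L, n_noise = 0L, n_samples = 20L,
                      groups = rep(c("control", "HD"), each = 10L),
                      n_de = 0L, seed = 200L + run)
    sim <- generate_genome(cfg)
    counts <- simulate_counts(sim)
    v <- batch_adjust(vst_counts(prevalence_filter(counts)),
                      sim$samples$batch)
    res <- de_test(v, sim$samples, c("HD", "control"))
    mean(res$fdr_adjusted_p < 0.05)
  }, 0)
  expect_lte(mean(fracs), 0.01)
})
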