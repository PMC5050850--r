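#' Evaluate code under a fixed RNG seed, restoring the RNG state afterwards
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic small-RNA experiment. The defaults
#' describe the reference desk-scale scenario used throughout the test suite:
#' a 60 kb toy chromosome carrying 20 planted miRNA hairpins (8 of them
#' withheld from the known-miRNA annotation, i.e. "novel" ground truth),
#' decoy exon-fragment and degradation-sRNA loci with diffuse read stacks,
#' and 10 samples split into two disease groups and two library batches.
#'
#' Planted hairpins follow the canonical precursor layout: a 22-nt mature arm,
#' a 15-nt terminal loop, a 22-nt star arm that is the reverse complement of
#' the mature arm apart from `arm_mismatches` substitutions (so the stem pairs
#' over >= 80 % of arm positions but reads still map uniquely), plus a 2-nt
#' 3' tail that accommodates the star strand's 2-nt 3' overhang. Reads are
#' drawn negative-binomially per locus and sample, partitioned
#' mature:star:loop according to `arm_ratio`, given modal 5' ends with
#' occasional 1-nt jitter, appended with the 3' sequencing adapter, padded
#' with random bases to `read_length`, and overlaid with uniform base-call
#' errors.
#'
#' @param genome_length length of the single toy chromosome (bp).
#' @param n_mirna number of planted miRNA hairpins.
#' @param n_withheld how many planted miRNAs are withheld from the
#'   known-miRNA annotation (the "novel" truth set).
#' @param n_dual_annotated how many known planted miRNAs are additionally
#'   annotated as exons, exercising the dual-annotation exclusion rule.
#' @param n_decoy_exon,n_decoy_srna,n_noise numbers of decoy exon-fragment,
#'   decoy small-RNA and intergenic-noise loci.
#' @param n_genes,gene_length gene-body annotation features (for the
#'   proximity classifier).
#' @param n_samples number of samples.
#' @param groups,batches per-sample labels, recycled to `n_samples`.
#' @param ages per-sample age-at-death covariate (years); default draws from
#'   a normal distribution centred at 75.
#' @param adapter 3' adapter sequence ligated to every insert.
#' @param read_length raw read length in nt (single-end).
#' @param mature_len,loop_len mature-arm and terminal-loop lengths (nt).
#' @param arm_mismatches substitutions planted in the star arm relative to
#'   the perfect reverse complement of the mature arm.
#' @param arm_ratio expected mature:star:loop read proportions.
#' @param jitter_prob probability that a mature read's 5' end is shifted by
#'   1 nt (either direction) off the modal start.
#' @param base_error per-base substitution error rate.
#' @param low_quality_frac fraction of reads given a failing quality profile
#'   (exercises the quality filter).
#' @param mirna_mean_range,decoy_mean_range log-uniform range of expected
#'   reads per sample for planted miRNAs and decoy loci.
#' @param noise_mean expected reads per sample for intergenic-noise loci.
#' @param dispersion negative-binomial dispersion of per-sample counts
#'   (variance = mu + dispersion * mu^2).
#' @param n_de,de_log2fc,de_group number of planted miRNAs carrying a
#'   group-wise expression fold-change, its magnitude (log2), and the group
#'   it applies to.
#' @param batch_sd standard deviation (log2 scale) of per-locus, per-batch
#'   multiplicative shifts.
#' @param seed RNG seed; the same configuration and seed reproduce the
#'   simulation byte-for-byte.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome_length = 60000L,
                       n_mirna = 20L,
                       n_withheld = 8L,
                       n_dual_annotated = 2L,
                       n_decoy_exon = 20L,
                       n_decoy_srna = 20L,
                       n_noise = 20L,
                       n_genes = 6L,
                       gene_length = 4000L,
                       n_samples = 10L,
                       groups = rep(c("control", "HD"), length.out = n_samples),
                       batches = rep(c("b1", "b2"), length.out = n_samples),
                       ages = NULL,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 51L,
                       mature_len = 22L,
                       loop_len = 15L,
                       arm_mismatches = 3L,
                       arm_ratio = c(100, 10, 1),
                       jitter_prob = 0.1,
                       base_error = 0.001,
                       low_quality_frac = 0.01,
                       mirna_mean_range = c(50, 1000),
                       decoy_mean_range = c(50, 500),
                       noise_mean = 5,
                       dispersion = 0.1,
                       n_de = 0L,
                       de_log2fc = 1,
                       de_group = "HD",
                       batch_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_mirna = as.integer(n_mirna),
    n_withheld = as.integer(n_withheld),
    n_dual_annotated = as.integer(n_dual_annotated),
    n_decoy_exon = as.integer(n_decoy_exon),
    n_decoy_srna = as.integer(n_decoy_srna), n_noise = as.integer(n_noise),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    n_samples = as.integer(n_samples),
    groups = rep_len(as.character(groups), n_samples),
    batches = rep_len(as.character(batches), n_samples),
    ages = ages, adapter = toupper(adapter),
    read_length = as.integer(read_length),
    mature_len = as.integer(mature_len), loop_len = as.integer(loop_len),
    arm_mismatches = as.integer(arm_mismatches), arm_ratio = arm_ratio,
    jitter_prob = jitter_prob, base_error = base_error,
    low_quality_frac = low_quality_frac,
    mirna_mean_range = mirna_mean_range,
    decoy_mean_range = decoy_mean_range, noise_mean = noise_mean,
    dispersion = dispersion, n_de = as.integer(n_de),
    de_log2fc = de_log2fc, de_group = de_group, batch_sd = batch_sd,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_withheld <= cfg$n_mirna,
            cfg$n_dual_annotated <= cfg$n_mirna - cfg$n_withheld,
            cfg$jitter_prob >= 0, cfg$jitter_prob <= 1,
            cfg$base_error >= 0, cfg$base_error <= 1,
            cfg$n_de <= cfg$n_mirna,
            length(cfg$groups) == cfg$n_samples,
            length(cfg$batches) == cfg$n_samples)
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_positions <- function(seq, pos) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  }
  paste(s, collapse = "")
}

#' Generate the toy genome, planted-locus truth table and annotation tracks
#'
#' Places all planted loci on a single random chromosome without mutual
#' overlap (a 200-bp margin keeps excised precursor windows from touching a
#' neighbouring locus), writes hairpin sequences into the genome, and emits
#' the annotation tracks a real analysis would download: exons, non-miRNA
#' small RNAs, known miRNA hairpins and matures, and gene bodies. Withheld
#' planted miRNAs appear in the truth table but in no known-miRNA track —
#' they are the "novel" miRNAs the pipeline must rediscover. Dual-annotated
#' loci are listed in both the exon and the miRNA track to exercise the
#' exclusion rule.
#'
#' @param config a [sim_config()] object.
#' @return a `mirsim` list with elements `genome` (named character vector of
#'   chromosome sequences), `truth` (one row per planted locus), `tracks`
#'   (list of interval tables: `exon`, `srna`, `mirna_hairpin`,
#'   `mirna_mature`, `gene_body`), `samples` (sample metadata), and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    chrom <- "chr1"
    hp_len <- 2L * cfg$mature_len + cfg$loop_len + 2L
    kinds <- c(rep("mirna", cfg$n_mirna),
               rep("exon_fragment", cfg$n_decoy_exon),
               rep("srna", cfg$n_decoy_srna),
               rep("intergenic_noise", cfg$n_noise))
    lens <- c(rep(hp_len, cfg$n_mirna),
              rep(150L, cfg$n_decoy_exon),
              rep(80L, cfg$n_decoy_srna),
              rep(30L, cfg$n_noise))
    n_loci <- length(kinds)
    ord <- sample.int(n_loci)
    kinds <- kinds[ord]; lens <- lens[ord]
    margin <- 200L
    gaps <- margin + sample.int(100L, n_loci, replace = TRUE)
    starts <- cumsum(c(50L + gaps[1], lens[-n_loci] + gaps[-1]))
    if (starts[n_loci] + lens[n_loci] + margin > cfg$genome_length)
      stop("genome_length too small to place all loci without overlap; ",
           "need at least ", starts[n_loci] + lens[n_loci] + margin, " bp")
    genome_seq <- rand_dna(cfg$genome_length)

    idx_mirna <- which(kinds == "mirna")
    mirna_no <- seq_along(idx_mirna)
    withheld <- logical(n_loci)
    withheld[idx_mirna[mirna_no <= cfg$n_withheld]] <- TRUE
    known_idx <- idx_mirna[mirna_no > cfg$n_withheld]
    dual <- logical(n_loci)
    if (cfg$n_dual_annotated > 0L)
      dual[known_idx[seq_len(cfg$n_dual_annotated)]] <- TRUE
    de_lfc <- numeric(n_loci)
    if (cfg$n_de > 0L)
      de_lfc[idx_mirna[seq_len(min(cfg$n_de, length(idx_mirna)))]] <- cfg$de_log2fc

    truth <- data.frame(
      name = character(n_loci), kind = kinds, chrom = chrom,
      start = starts, end = starts + lens,
      mature_start = NA_integer_, mature_end = NA_integer_,
      star_start = NA_integer_, star_end = NA_integer_,
      loop_start = NA_integer_, loop_end = NA_integer_,
      mature_seq = NA_character_,
      expression_mean = NA_real_, log2fc = de_lfc,
      withheld = withheld, dual_annotated = dual,
      stringsAsFactors = FALSE
    )
    counters <- c(mirna = 0L, exon_fragment = 0L, srna = 0L,
                  intergenic_noise = 0L)
    for (i in seq_len(n_loci)) {
      counters[kinds[i]] <- counters[kinds[i]] + 1L
      prefix <- switch(kinds[i], mirna = "mir", exon_fragment = "exon",
                       srna = "srna", intergenic_noise = "noise")
      truth$name[i] <- sprintf("%s_%03d", prefix, counters[kinds[i]])
      if (kinds[i] == "mirna") {
        h <- starts[i]
        mature <- rand_dna(cfg$mature_len)
        star <- revcomp(mature)
        if (cfg$arm_mismatches > 0L)
          star <- mutate_positions(
            star, sample.int(cfg$mature_len, cfg$arm_mismatches))
        loop <- rand_dna(cfg$loop_len)
        tail2 <- rand_dna(2L)
        hairpin <- paste0(mature, loop, star, tail2)
        substr(genome_seq, h + 1L, h + hp_len) <- hairpin
        truth$mature_start[i] <- h
        truth$mature_end[i] <- h + cfg$mature_len
        truth$loop_start[i] <- h + cfg$mature_len
        truth$loop_end[i] <- h + cfg$mature_len + cfg$loop_len
        # star strand carries the canonical 2-nt 3' overhang: it is the
        # 3' arm shifted 2 nt downstream, ending 2 nt past the partner of
        # the mature 5' end
        truth$star_start[i] <- h + cfg$mature_len + cfg$loop_len + 2L
        truth$star_end[i] <- h + hp_len
        truth$mature_seq[i] <- mature
      }
      truth$expression_mean[i] <- switch(
        kinds[i],
        mirna = exp(runif(1, log(cfg$mirna_mean_range[1]),
                          log(cfg$mirna_mean_range[2]))),
        exon_fragment = ,
        srna = exp(runif(1, log(cfg$decoy_mean_range[1]),
                         log(cfg$decoy_mean_range[2]))),
        intergenic_noise = cfg$noise_mean
      )
    }

    batch_levels <- unique(cfg$batches)
    batch_shifts <- matrix(
      2^rnorm(n_loci * length(batch_levels), 0, cfg$batch_sd),
      nrow = n_loci, dimnames = list(truth$name, batch_levels))

    gene_starts <- sort(sample.int(
      max(cfg$genome_length - cfg$gene_length, 1L), cfg$n_genes))
    gene_track <- gi(chrom, gene_starts, gene_starts + cfg$gene_length,
                     "+", sprintf("gene_%02d", seq_len(cfg$n_genes)))

    is_known <- kinds == "mirna" & !withheld
    tracks <- list(
      exon = gi(chrom,
                c(truth$start[kinds == "exon_fragment"], truth$start[dual]),
                c(truth$end[kinds == "exon_fragment"], truth$end[dual]),
                "+",
                c(truth$name[kinds == "exon_fragment"],
                  paste0(truth$name[dual], "_exon"))),
      srna = gi(chrom, truth$start[kinds == "srna"],
                truth$end[kinds == "srna"], "+", truth$name[kinds == "srna"]),
      mirna_hairpin = gi(chrom, truth$start[is_known], truth$end[is_known],
                         "+", truth$name[is_known]),
      mirna_mature = gi(chrom, truth$mature_start[is_known],
                        truth$mature_end[is_known], "+",
                        paste0(truth$name[is_known], "_mature")),
      gene_body = gene_track
    )

    ages <- if (is.null(cfg$ages)) round(rnorm(cfg$n_samples, 75, 8), 1) else
      rep_len(cfg$ages, cfg$n_samples)
    samples <- data.frame(
      sample = sprintf("S%02d", seq_len(cfg$n_samples)),
      group = cfg$groups, batch = cfg$batches, age = ages,
      stringsAsFactors = FALSE
    )

    sim <- list(genome = stats::setNames(genome_seq, chrom), truth = truth,
                tracks = tracks, samples = samples, config = cfg,
                batch_shifts = batch_shifts)
    class(sim) <- "mirsim"
    sim
  })
}

#' Draw the per-locus, per-sample expected counts and NB counts
#'
#' Counts are negative binomial with mean
#' `expression_mean * 2^(log2fc * [sample in de_group]) * batch_shift`
#' and variance `mu + dispersion * mu^2`. Used both by the read simulator and
#' directly by the differential-expression tests (where simulating individual
#' reads would add nothing).
#'
#' @param sim a `mirsim` object from [generate_genome()].
#' @param seed optional seed; defaults to `config$seed + 1`.
#' @return integer matrix, loci x samples.
#' @export
simulate_counts <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "mirsim"))
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg$seed + 1L
  with_seed(seed, {
    mu <- outer(seq_len(nrow(sim$truth)), seq_len(cfg$n_samples),
                function(i, j) {
                  sim$truth$expression_mean[i] *
                    2^(sim$truth$log2fc[i] *
                         (sim$samples$group[j] == cfg$de_group)) *
                    sim$batch_shifts[cbind(i, match(sim$samples$batch[j],
                                                    colnames(sim$batch_shifts)))]
                })
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     nrow = nrow(mu),
                     dimnames = list(sim$truth$name, sim$samples$sample))
    counts[sim$truth$expression_mean == 0, ] <- 0L
    counts
  })
}

phred_string <- function(q) {
  vapply(q, function(v) intToUtf8(pmin(pmax(v, 2L), 41L) + 33L), "")
}

#' Simulate per-sample small-RNA FASTQ reads
#'
#' For planted miRNAs, reads are partitioned mature:star:loop by the
#' configured ratio; mature reads share a modal 5' end (with 1-nt jitter at
#' `jitter_prob`), star reads span the star arm whose 3' end sits 2 nt past
#' the partner of the mature 5' end (the Dicer overhang), and loop reads are
#' short fragments centred on the terminal loop. Decoy loci emit diffuse
#' stacks: uniform start positions and lengths 18-26 nt. Every insert gets
#' the 3' adapter appended, is padded with random bases (or truncated) to
#' `read_length`, and receives per-base qualities; a small fraction of reads
#' is given a failing quality profile and uniform substitution errors are
#' overlaid at `base_error`.
#'
#' @param sim a `mirsim` object.
#' @param counts optional count matrix from [simulate_counts()]; drawn fresh
#'   when omitted.
#' @param seed optional seed; defaults to `config$seed + 2`.
#' @return `sim` with an added `reads` element: a named list (one per
#'   sample) of read tables (`id`, `seq`, `qual`), and `counts`.
#' @export
simulate_reads <- function(sim, counts = NULL, seed = NULL) {
  stopifnot(inherits(sim, "mirsim"))
  cfg <- sim$config
  if (is.null(counts)) counts <- simulate_counts(sim)
  if (is.null(seed)) seed <- cfg$seed + 2L
  genome_seq <- sim$genome[[1]]
  truth <- sim$truth
  with_seed(seed, {
    ratio <- cfg$arm_ratio / sum(cfg$arm_ratio)
    per_sample <- vector("list", cfg$n_samples)
    names(per_sample) <- sim$samples$sample
    for (j in seq_len(cfg$n_samples)) {
      starts <- integer(0); ends <- integer(0); locus <- character(0)
      for (i in seq_len(nrow(truth))) {
        n <- counts[i, j]
        if (n == 0L) next
        if (truth$kind[i] == "mirna") {
          parts <- as.vector(stats::rmultinom(1, n, ratio))
          n_m <- parts[1]; n_s <- parts[2]; n_l <- parts[3]
          if (n_m > 0L) {
            jit <- sample(c(0L, -1L, 1L), n_m, replace = TRUE,
                          prob = c(1 - cfg$jitter_prob, cfg$jitter_prob / 2,
                                   cfg$jitter_prob / 2))
            jit3 <- sample(c(0L, -1L, 1L), n_m, replace = TRUE,
                           prob = c(1 - cfg$jitter_prob, cfg$jitter_prob / 2,
                                    cfg$jitter_prob / 2))
            starts <- c(starts, truth$mature_start[i] + jit)
            ends <- c(ends, truth$mature_end[i] + jit3)
          }
          if (n_s > 0L) {
            starts <- c(starts, rep(truth$star_start[i], n_s))
            ends <- c(ends, rep(truth$star_end[i], n_s))
          }
          if (n_l > 0L) {
            off <- sample(0:3, n_l, replace = TRUE)
            ls <- truth$loop_start[i] - off
            starts <- c(starts, ls)
            ends <- c(ends, ls + 18L)
          }
          locus <- c(locus, rep(truth$name[i], n_m + n_s + n_l))
        } else {
          len <- sample(18:26, n, replace = TRUE)
          smax <- pmax(truth$end[i] - len, truth$start[i] + 1L)
          st <- truth$start[i] +
            floor(runif(n) * (smax - truth$start[i]))
          starts <- c(starts, st)
          ends <- c(ends, st + len)
          locus <- c(locus, rep(truth$name[i], n))
        }
      }
      if (length(starts) == 0L) {
        per_sample[[j]] <- data.frame(id = character(0), seq = character(0),
                                      qual = character(0),
                                      stringsAsFactors = FALSE)
        next
      }
      inserts <- substring(genome_seq, starts + 1L, ends)
      raw <- paste0(inserts, cfg$adapter)
      short <- nchar(raw) < cfg$read_length
      if (any(short)) {
        pad <- vapply(cfg$read_length - nchar(raw[short]),
                      function(k) rand_dna(k), "")
        raw[short] <- paste0(raw[short], pad)
      }
      raw <- substr(raw, 1L, cfg$read_length)
      # base-call errors
      if (cfg$base_error > 0) {
        n_bases <- length(raw) * cfg$read_length
        n_err <- rbinom(1, n_bases, cfg$base_error)
        if (n_err > 0L) {
          pos <- sample.int(n_bases, n_err)
          ri <- ((pos - 1L) %/% cfg$read_length) + 1L
          pi <- ((pos - 1L) %% cfg$read_length) + 1L
          for (k in seq_len(n_err)) {
            old <- substr(raw[ri[k]], pi[k], pi[k])
            substr(raw[ri[k]], pi[k], pi[k]) <-
              sample(setdiff(c("A", "C", "G", "T"), old), 1)
          }
        }
      }
      n_reads <- length(raw)
      base_q <- matrix(sample(34:40, n_reads * cfg$read_length,
                              replace = TRUE),
                       nrow = n_reads)
      fail <- runif(n_reads) < cfg$low_quality_frac
      if (any(fail))
        base_q[fail, ] <- sample(2:19, sum(fail) * cfg$read_length,
                                 replace = TRUE)
      qual <- phred_string(split(base_q, row(base_q)))
      ids <- sprintf("%s:%s:%06d", sim$samples$sample[j], locus,
                     seq_len(n_reads))
      per_sample[[j]] <- data.frame(id = ids, seq = raw, qual = qual,
                                    stringsAsFactors = FALSE)
    }
    sim$reads <- per_sample
    sim$counts <- counts
    sim
  })
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `truth.tsv`, `samples.tsv`, one GFF3 per annotation
#' track and one FASTQ per sample, plus `known_mature.fa` (the catalogue of
#' known mature sequences).
#'
#' @param sim a `mirsim` object (with reads, for FASTQ output).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mirsim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(sim$tracks)) {
    tr <- sim$tracks[[nm]]
    tr$type <- nm
    write_gff3(tr, file.path(dir, paste0(nm, ".gff3")))
  }
  known <- sim$truth[sim$truth$kind == "mirna" & !sim$truth$withheld, ]
  if (nrow(known) > 0L)
    write_fasta(stats::setNames(known$mature_seq, known$name),
                file.path(dir, "known_mature.fa"))
  if (!is.null(sim$reads)) {
    for (s in names(sim$reads))
      write_fastq(sim$reads[[s]], file.path(dir, paste0(s, ".fastq")))
  }
  invisible(dir)
}
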