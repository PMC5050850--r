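#' Classify candidate proximity to annotated genes
#'
#' A candidate overlapping a gene body is `intronic` (exonic overlaps were
#' already removed as false positives upstream), one within 1000 bp of the
#' nearest gene is `near`, and anything farther — including candidates on
#' chromosomes without genes — is `distant`. Proximity is measured on the
#' mature interval, the reported miRNA unit; pass hairpin intervals instead
#' to measure from the precursor.
#'
#' @param query interval table (mature intervals).
#' @param gene_track interval table of gene bodies.
#' @param near_bp maximum gap for the `near` label (bp).
#' @return data frame with `label` (`intronic`/`near`/`distant`),
#'   `distance_bp`, and `nearest_gene`.
#' @export
classify_proximity <- function(query, gene_track, near_bp = 1000L) {
  nf <- nearest_feature_distance(query, gene_track)
  d <- nf$distance
  label <- rep("distant", nrow(query))
  label[!is.na(d) & d >= 1L & d <= near_bp] <- "near"
  label[!is.na(d) & d == 0L] <- "intronic"
  gene <- rep(NA_character_, nrow(query))
  has <- !is.na(nf$nearest) & label != "distant"
  if ("name" %in% names(gene_track))
    gene[has] <- gene_track$name[nf$nearest[has]]
  data.frame(label = label,
             distance_bp = ifelse(is.na(d), NA_integer_, d),
             nearest_gene = gene, stringsAsFactors = FALSE)
}

#' Smith-Waterman scoring parameters
#'
#' A fixed DNA scheme (match +5, mismatch -4, affine gaps: a gap of length
#' L costs `gap_open + L * gap_extend`).
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (penalties positive).
#' @return a `sw_params` list.
#' @export
sw_params <- function(match = 5, mismatch = -4, gap_open = 12,
                      gap_extend = 4) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman with affine gaps. The traceback starts from the
#' highest-scoring cell (ties broken toward the smallest query, then target,
#' coordinate) and is fully deterministic. The reported `overlap` is the
#' number of query bases inside the alignment (gap columns excluded — the
#' stricter reading of "nucleotide overlap"). The e-value comes from a
#' Gumbel tail fitted once on shuffled-sequence score distributions (see
#' [evalue_params()]) and scaled to the product of the two sequence
#' lengths.
#'
#' @param query,target nucleotide strings over A/C/G/T/U.
#' @param params a [sw_params()] object.
#' @param evalue a [evalue_params()] calibration (defaults to the cached
#'   package calibration).
#' @return list with `score`, `overlap`, `mismatches`, `e_value`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (1-based, inclusive), and
#'   `columns` (matrix with rows `q`/`t`: position indices, `NA` = gap).
#' @export
local_align <- function(query, target, params = sw_params(),
                        evalue = evalue_params()) {
  q <- chartr("Uu", "TT", toupper(query))
  t <- chartr("Uu", "TT", toupper(target))
  if (!nzchar(q) || !nzchar(t)) stop("sequences must be non-empty")
  qb <- strsplit(q, "", fixed = TRUE)[[1]]
  tb <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qb); m <- length(tb)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in query (consuming target)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in target (consuming query)
  go <- params$gap_open + params$gap_extend
  ge <- params$gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - go, E[i + 1L, j] - ge)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - go, F[i, j + 1L] - ge)
      s <- if (qb[i] == tb[j]) params$match else params$mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s,
                               E[i + 1L, j + 1L], F[i + 1L, j + 1L])
    }
  }
  best <- max(H)
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  ci <- hits[1, 1]; cj <- hits[1, 2]
  # traceback
  qcol <- integer(0); tcol <- integer(0)
  state <- "H"
  i <- ci; j <- cj
  while (i > 1L || j > 1L) {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (qb[i - 1L] == tb[j - 1L]) params$match else params$mismatch
      if (i > 1L && j > 1L && H[i, j] == H[i - 1L, j - 1L] + s) {
        qcol <- c(i - 1L, qcol); tcol <- c(j - 1L, tcol)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else if (H[i, j] == F[i, j]) {
        state <- "F"
      } else break
    } else if (state == "E") {
      qcol <- c(NA_integer_, qcol); tcol <- c(j - 1L, tcol)
      if (E[i, j] == E[i, j - 1L] - ge && j > 2L) {
        j <- j - 1L
      } else {
        j <- j - 1L; state <- "H"
      }
    } else {
      qcol <- c(i - 1L, qcol); tcol <- c(NA_integer_, tcol)
      if (F[i, j] == F[i - 1L, j] - ge && i > 2L) {
        i <- i - 1L
      } else {
        i <- i - 1L; state <- "H"
      }
    }
  }
  columns <- rbind(q = qcol, t = tcol)
  both <- !is.na(qcol) & !is.na(tcol)
  mism <- sum(qb[qcol[both]] != tb[tcol[both]])
  ev <- evalue$kmn_unit * n * m * exp(-evalue$lambda * best)
  list(score = best,
       overlap = sum(!is.na(qcol)),
       mismatches = mism,
       e_value = ev,
       q_start = if (any(!is.na(qcol))) min(qcol, na.rm = TRUE) else NA_integer_,
       q_end = if (any(!is.na(qcol))) max(qcol, na.rm = TRUE) else NA_integer_,
       t_start = if (any(!is.na(tcol))) min(tcol, na.rm = TRUE) else NA_integer_,
       t_end = if (any(!is.na(tcol))) max(tcol, na.rm = TRUE) else NA_integer_,
       columns = columns)
}

.mirstack_env <- new.env(parent = emptyenv())

#' Empirical Gumbel calibration of local-alignment e-values
#'
#' Local-alignment scores of unrelated sequences follow an extreme-value
#' (Gumbel) law, `P(S > x) ~ K m n exp(-lambda x)`. The parameters are
#' fitted once, by the method of moments, on the scores of `n_shuffle`
#' random sequence pairs of length `len` generated under a fixed internal
#' seed, and cached for the session; e-values for other sequence lengths
#' scale with the length product `m * n`. Absolute e-values from this
#' calibration are specific to the package's scoring scheme; the filtering
#' thresholds applied to them are the standard ones.
#'
#' @param n_shuffle number of random pairs.
#' @param len sequence length of the calibration pairs.
#' @param params a [sw_params()] object.
#' @param seed internal calibration seed.
#' @return list with `lambda` and `kmn_unit` (the fitted `K`, i.e. the
#'   e-value prefactor per unit of `m * n`).
#' @export
evalue_params <- function(n_shuffle = 400L, len = 22L, params = sw_params(),
                          seed = 424243L) {
  key <- paste("ev", n_shuffle, len, seed,
               paste(unlist(params), collapse = ","), sep = "_")
  cached <- .mirstack_env[[key]]
  if (!is.null(cached)) return(cached)
  dummy <- list(lambda = 1, kmn_unit = 0)   # self-use during fitting
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      a <- rand_dna(len); b <- rand_dna(len)
      local_align(a, b, params, evalue = dummy)$score
    }, 0)
  })
  lambda <- pi / (stats::sd(scores) * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lambda
  # P(S > mu + x/lambda) ~ exp(-x); anchor K m n at the calibration sizes
  fit <- list(lambda = lambda, kmn_unit = exp(lambda * mu) / (len * len))
  .mirstack_env[[key]] <- fit
  fit
}

#' Filter similarity hits on e-value and overlap
#'
#' Keeps hits with `e_value < max_e` (strict) and `overlap >= min_overlap`
#' (inclusive).
#'
#' @param hits data frame with `e_value` and `overlap` columns.
#' @param max_e e-value cutoff.
#' @param min_overlap minimum aligned query bases.
#' @return the surviving rows.
#' @export
filter_hits <- function(hits, max_e = 0.05, min_overlap = 15L) {
  hits[hits$e_value < max_e & hits$overlap >= min_overlap, , drop = FALSE]
}

#' Count mismatches and gaps in the seed region of an alignment
#'
#' The seed is mature positions 2-7 from the 5' end. Over those query
#' positions the count accumulates substitutions in aligned columns, seed
#' positions aligned to a gap, seed positions outside the aligned region
#' (counted as gaps), and insertion columns falling inside the aligned seed
#' span; the result is capped at 6.
#'
#' @param aln result of [local_align()].
#' @param query,target the aligned sequences (query = the mature).
#' @param seed_from,seed_to 1-based seed bounds on the query.
#' @return integer in `[0, 6]`.
#' @export
seed_mismatches <- function(aln, query, target, seed_from = 2L,
                            seed_to = 7L) {
  qb <- strsplit(chartr("Uu", "TT", toupper(query)), "", fixed = TRUE)[[1]]
  tb <- strsplit(chartr("Uu", "TT", toupper(target)), "", fixed = TRUE)[[1]]
  cols <- aln$columns
  count <- 0L
  for (p in seed_from:seed_to) {
    k <- which(!is.na(cols["q", ]) & cols["q", ] == p)
    if (length(k) == 0L) {
      count <- count + 1L        # outside the aligned region
    } else if (is.na(cols["t", k])) {
      count <- count + 1L        # aligned to a gap
    } else if (qb[p] != tb[cols["t", k]]) {
      count <- count + 1L        # substitution
    }
  }
  qcols <- cols["q", ]
  covered <- which(!is.na(qcols) & qcols >= seed_from & qcols <= seed_to)
  if (length(covered) >= 2L) {
    span <- min(covered):max(covered)
    count <- count + sum(is.na(qcols[span]))   # insertions inside the seed
  }
  min(count, 6L)
}

#' Align novel mature sequences to a catalogue of known matures
#'
#' Every query/catalogue pair is locally aligned; hits passing the e-value
#' and overlap filter are reported with their seed mismatch count. When
#' hairpin sequences are supplied for both sides, the hairpins of passing
#' pairs are aligned as well and their score and overlap appended.
#'
#' @param novel data frame with `id` and `mature_seq` (optional
#'   `hairpin_seq`).
#' @param catalogue named character vector of known mature sequences
#'   (optional attribute-free), or data frame with `id`, `mature_seq`,
#'   optional `hairpin_seq`.
#' @param max_e,min_overlap filter thresholds (see [filter_hits()]).
#' @param params,evalue alignment scoring and e-value calibration.
#' @return data frame of passing hits: `query`, `target`, `score`,
#'   `overlap`, `e_value`, `seed_mismatches` (plus `hairpin_score`,
#'   `hairpin_overlap` when hairpins are available).
#' @export
align_to_catalogue <- function(novel, catalogue, max_e = 0.05,
                               min_overlap = 15L, params = sw_params(),
                               evalue = evalue_params()) {
  if (!is.data.frame(catalogue))
    catalogue <- data.frame(id = names(catalogue),
                            mature_seq = unname(catalogue),
                            stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(novel))) {
    for (j in seq_len(nrow(catalogue))) {
      a <- local_align(novel$mature_seq[i], catalogue$mature_seq[j],
                       params, evalue)
      if (a$e_value < max_e && a$overlap >= min_overlap) {
        sm <- seed_mismatches(a, novel$mature_seq[i],
                              catalogue$mature_seq[j])
        row <- data.frame(query = novel$id[i], target = catalogue$id[j],
                          score = a$score, overlap = a$overlap,
                          e_value = a$e_value, seed_mismatches = sm,
                          stringsAsFactors = FALSE)
        if ("hairpin_seq" %in% names(novel) &&
            "hairpin_seq" %in% names(catalogue)) {
          h <- local_align(novel$hairpin_seq[i], catalogue$hairpin_seq[j],
                           params, evalue)
          row$hairpin_score <- h$score
          row$hairpin_overlap <- h$overlap
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(0), target = character(0),
                      score = numeric(0), overlap = integer(0),
                      e_value = numeric(0), seed_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' All-vs-all alignment within a novel set
#'
#' Same procedure as [align_to_catalogue()] with the set aligned against
#' itself: self-hits are excluded and each unordered pair is reported once
#' (query = the earlier row).
#'
#' @inheritParams align_to_catalogue
#' @return data frame of passing hits.
#' @export
pairwise_align <- function(novel, max_e = 0.05, min_overlap = 15L,
                           params = sw_params(), evalue = evalue_params()) {
  n <- nrow(novel)
  if (n < 2L)
    return(align_to_catalogue(novel[0, , drop = FALSE], novel))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    sub <- align_to_catalogue(novel[i, , drop = FALSE],
                              novel[(i + 1L):n, , drop = FALSE],
                              max_e, min_overlap, params, evalue)
    if (nrow(sub) > 0L) rows[[length(rows) + 1L]] <- sub
  }
  if (length(rows) == 0L)
    return(align_to_catalogue(novel[0, , drop = FALSE], novel))
  do.call(rbind, rows)
}

#' Collapse duplicate predictions sharing a mature sequence and location
#'
#' Two predictions with identical mature sequence and identical mature
#' coordinates but different hairpin windows describe the same miRNA read
#' stack excised differently; for counting and differential expression the
#' higher-scoring one is kept. The collapse is recorded so the report can
#' state which ids were merged.
#'
#' @param novel candidate table with `chrom`, `mature_start`, `mature_end`,
#'   `mature_seq`, `score`, `id`.
#' @return list with `collapsed` (deduplicated table) and `report` (data
#'   frame of `kept`/`dropped` id pairs).
#' @export
collapse_duplicates <- function(novel) {
  if (nrow(novel) == 0L)
    return(list(collapsed = novel,
                report = data.frame(kept = character(0),
                                    dropped = character(0),
                                    stringsAsFactors = FALSE)))
  key <- paste(novel$chrom, novel$mature_start, novel$mature_end,
               novel$mature_seq)
  keep <- logical(nrow(novel))
  kept_id <- dropped_id <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    best <- idx[order(-novel$score[idx], novel$id[idx])][1]
    keep[best] <- TRUE
    if (length(idx) > 1L) {
      drop <- setdiff(idx, best)
      kept_id <- c(kept_id, rep(novel$id[best], length(drop)))
      dropped_id <- c(dropped_id, novel$id[drop])
    }
  }
  list(collapsed = novel[keep, , drop = FALSE],
       report = data.frame(kept = kept_id, dropped = dropped_id,
                           stringsAsFactors = FALSE))
}
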