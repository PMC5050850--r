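# Independent brute-force oracles used by the property tests. Each is a
# deliberately naive implementation kept free of the package's code paths.

# all-pairs interval intersection (every query row against every track row,
# straight from the overlap definition)
bf_intersect <- function(query, track) {
  hits <- list()
  for (q in seq_len(nrow(query))) {
    ok <- which(query$chrom[q] == track$chrom &
                  pmin(query$end[q], track$end) -
                    pmax(query$start[q], track$start) >= 1)
    if (length(ok) > 0L)
      hits[[length(hits) + 1L]] <- data.frame(query = q, feature = ok)
  }
  if (length(hits) == 0L)
    return(data.frame(query = integer(0), feature = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$query, track$start[out$feature], track$end[out$feature],
            out$feature), , drop = FALSE]
}

# exhaustive enumeration of all nested structures (min-loop 3), returning
# the maximum number of base pairs
bf_max_pairs <- function(seq, min_loop = 3L) {
  b <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  can <- function(x, y) {
    paste0(x, y) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)                      # i unpaired
    for (k in (i + min_loop + 1L):j) {          # i paired with k
      if (can(b[i], b[k])) {
        left <- rec(i + 1L, k - 1L)
        right <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + left + right)
      }
    }
    best
  }
  if (length(b) < 2L) return(0L)
  rec(1L, length(b))
}

# brute-force affine-gap local alignment score by recursion over all
# alignment end points and edit paths (memoized on (i, j, state))
bf_local_align_score <- function(q, t, match = 5, mismatch = -4,
                                 gap_open = 12, gap_extend = 4) {
  qb <- strsplit(toupper(q), "")[[1]]
  tb <- strsplit(toupper(t), "")[[1]]
  n <- length(qb); m <- length(tb)
  memo <- new.env(parent = emptyenv())
  # best score of an alignment ENDING exactly at (i, j) in the given state
  sc <- function(i, j, state) {
    if (i < 1L || j < 1L) return(-Inf)
    key <- paste(i, j, state)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (state == "M") {
      s <- if (qb[i] == tb[j]) match else mismatch
      s + max(0, sc(i - 1L, j - 1L, "M"), sc(i - 1L, j - 1L, "E"),
              sc(i - 1L, j - 1L, "F"))
    } else if (state == "E") {   # gap consuming target base j
      max(sc(i, j - 1L, "M") - gap_open - gap_extend,
          sc(i, j - 1L, "E") - gap_extend)
    } else {                     # gap consuming query base i
      max(sc(i - 1L, j, "M") - gap_open - gap_extend,
          sc(i - 1L, j, "F") - gap_extend)
    }
    memo[[key]] <- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, sc(i, j, "M"))
  best
}

# probability that a random TP score exceeds a random FP score, ties 0.5
bf_ranking_auc <- function(fp, tp) {
  tot <- 0
  for (x in tp) for (y in fp)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(fp) * length(tp))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L,
                             max_len = 60L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  gi(sample(chroms, n, replace = TRUE), start,
     start + sample.int(max_len, n, replace = TRUE))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
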