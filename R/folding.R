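#' Fold a sequence into its maximum base-pair hairpin structure
#'
#' Base-pair maximization by dynamic programming (Nussinov-style) over
#' Watson-Crick pairs plus the G·U wobble, with a minimum hairpin loop of
#' `min_loop` unpaired bases. This is a deliberately simple, deterministic
#' substitute for thermodynamic folding: at hairpin-discovery scale the
#' question is "does this window fold back on itself", for which the
#' maximal pairing count and its paired fraction are an adequate signal.
#' The traceback is deterministic: at each subproblem the outermost
#' compatible pair is taken first, then left/right unpaired, then the
#' smallest bifurcation point.
#'
#' @param sequence nucleotide string over A/C/G/T/U (case-insensitive).
#' @param min_loop minimum number of unpaired bases enclosed by a pair.
#' @return list with `structure` (dot-bracket string), `n_pairs`, and
#'   `pairing` (integer vector: 1-based partner position or `NA`).
#' @examples
#' fold_hairpin("GGGAAACCC")$structure  # "(((...)))"
#' @export
fold_hairpin <- function(sequence, min_loop = 3L) {
  s <- chartr("Uu", "TT", toupper(sequence))
  if (grepl("[^ACGTN]", s)) stop("sequence must contain only A/C/G/T/U/N")
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  pairable <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
      (x == "C" & y == "G") | (x == "G" & y == "C") |
      (x == "G" & y == "T") | (x == "T" & y == "G")
  }
  if (n == 0L) return(list(structure = "", n_pairs = 0L, pairing = integer(0)))
  N <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- max(N[i + 1L, j], N[i, j - 1L])
        if (pairable(b[i], b[j])) best <- max(best, N[i + 1L, j - 1L] + 1L)
        kk <- i:(j - 1L)
        if (length(kk) > 1L) {
          bif <- max(N[i, kk] + N[cbind(kk + 1L, j)])
          best <- max(best, bif)
        }
        N[i, j] <- best
      }
    }
  }
  pairing <- rep(NA_integer_, n)
  # iterative traceback with an explicit stack of (i, j) subproblems
  todo <- list(c(1L, n))
  while (length(todo) > 0L) {
    ij <- todo[[length(todo)]]
    todo[[length(todo)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j) next
    if (j - i > min_loop && pairable(b[i], b[j]) &&
        N[i, j] == N[i + 1L, j - 1L] + 1L) {
      pairing[i] <- j; pairing[j] <- i
      todo[[length(todo) + 1L]] <- c(i + 1L, j - 1L)
    } else if (N[i, j] == N[i + 1L, j]) {
      todo[[length(todo) + 1L]] <- c(i + 1L, j)
    } else if (N[i, j] == N[i, j - 1L]) {
      todo[[length(todo) + 1L]] <- c(i, j - 1L)
    } else {
      for (k in i:(j - 1L)) {
        if (N[i, j] == N[i, k] + N[k + 1L, j]) {
          todo[[length(todo) + 1L]] <- c(i, k)
          todo[[length(todo) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  struct <- rep(".", n)
  paired <- which(!is.na(pairing))
  struct[paired[pairing[paired] > paired]] <- "("
  struct[paired[pairing[paired] < paired]] <- ")"
  list(structure = paste(struct, collapse = ""),
       n_pairs = sum(!is.na(pairing)) %/% 2L,
       pairing = pairing)
}
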