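#' Construct a table of genomic intervals
#'
#' Intervals are the currency of all overlap logic in the package. They are
#' stored in a plain data frame using 0-based, half-open coordinates (the BED
#' convention): `start` is the 0-based offset of the first base, `end` is one
#' past the last base. GFF input/output converts to and from 1-based closed
#' coordinates at the file boundary.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive start offsets (`>= 0`).
#' @param end integer vector, exclusive end offsets (`> start`).
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @param name optional feature names; recycled.
#' @return a data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, validated by [validate_intervals()].
#' @examples
#' gi("chr1", 99, 200)           # BED line "chr1 99 200"
#' gi("chr1", 100, 200, "+", "hairpin-1")
#' @export
gi <- function(chrom, start, end, strand = "*", name = NA_character_) {
  n <- length(start)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the structural invariants every interval must satisfy: non-empty
#' chromosome name, `start >= 0`, `end > start`, strand in `+`/`-`/`*`.
#'
#' @param x data frame with at least `chrom`, `start`, `end` columns.
#' @return `x`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_intervals <- function(x) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("interval table must be a data frame with chrom/start/end columns")
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$chrom) || any(!nzchar(x$chrom)))
    stop("interval chrom must be a non-empty string")
  if (anyNA(x$start) || anyNA(x$end))
    stop("interval start/end must not be NA")
  if (any(x$start < 0L))
    stop("interval start must be >= 0 (0-based half-open coordinates)")
  if (any(x$end <= x$start))
    stop("interval end must be > start (0-based half-open coordinates)")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' Pairwise interval overlap test
#'
#' Two intervals overlap when they share a chromosome and at least one base.
#' Strand is ignored unless `require_strand = TRUE`, in which case strands
#' must agree or at least one of the pair must be unstranded (`*`). The
#' default mirrors `bedtools intersect`, which is strand-agnostic.
#'
#' @param a,b interval tables of equal length (or length 1, recycled).
#' @param require_strand if `TRUE`, strands must be compatible as well.
#' @return logical vector.
#' @export
gi_overlaps <- function(a, b, require_strand = FALSE) {
  validate_intervals(a)
  validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(max(nrow(a), 1L)), n)
  bi <- rep_len(seq_len(max(nrow(b), 1L)), n)
  if (nrow(a) == 0L || nrow(b) == 0L) return(logical(0))
  hit <- a$chrom[ai] == b$chrom[bi] &
    pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]) >= 1L
  if (require_strand) {
    sa <- if ("strand" %in% names(a)) a$strand[ai] else "*"
    sb <- if ("strand" %in% names(b)) b$strand[bi] else "*"
    hit <- hit & (sa == sb | sa == "*" | sb == "*")
  }
  hit
}

#' Gap distance between two intervals on the same chromosome
#'
#' Returns 0 for overlapping intervals, otherwise the size of the gap between
#' the nearest ends (`bedtools closest` convention): `[100,200)` and
#' `[700,800)` are 500 bp apart, and abutting half-open intervals are 0 bp
#' apart while still not overlapping. Different chromosomes yield `NA`
#' (an "infinite" distance).
#'
#' @param a,b interval tables, recycled to a common length.
#' @return integer vector of distances; `NA` where chromosomes differ.
#' @export
gi_distance <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0L || nrow(b) == 0L) return(integer(0))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  gap <- pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi])
  d <- pmax(gap, 0L)
  d[a$chrom[ai] != b$chrom[bi]] <- NA_integer_
  as.integer(d)
}

#' Intersect query intervals with an annotation track
#'
#' For each query interval, reports every track feature sharing at least one
#' base with it. Hits are returned in deterministic order: by query, then by
#' feature coordinate. The overlap test is strand-agnostic, matching the
#' default behaviour of `bedtools intersect`.
#'
#' Internally the per-chromosome search is delegated to
#' [IRanges::findOverlaps()] after converting the half-open coordinates to
#' the 1-based closed convention IRanges uses.
#'
#' @param query interval table.
#' @param track interval table of annotation features (may be empty).
#' @return data frame with columns `query` (row index into `query`),
#'   `feature` (row index into `track`), plus the feature's `chrom`, `start`,
#'   `end`, `strand`, `name`.
#' @export
intersect_track <- function(query, track) {
  validate_intervals(query)
  validate_intervals(track)
  empty <- data.frame(
    query = integer(0), feature = integer(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    name = character(0), stringsAsFactors = FALSE
  )
  if (nrow(query) == 0L || nrow(track) == 0L) return(empty)
  out <- vector("list", 0L)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0L) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    tr <- IRanges::IRanges(start = track$start[ti] + 1L, end = track$end[ti])
    ov <- IRanges::findOverlaps(qr, tr)
    if (length(ov) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      query = qi[S4Vectors::queryHits(ov)],
      feature = ti[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty)
  hits <- do.call(rbind, out)
  # deterministic order: query index, then feature coordinate
  o <- order(hits$query, track$start[hits$feature], track$end[hits$feature],
             hits$feature)
  hits <- hits[o, , drop = FALSE]
  strand <- if ("strand" %in% names(track)) track$strand[hits$feature] else "*"
  nm <- if ("name" %in% names(track)) track$name[hits$feature] else NA_character_
  data.frame(
    query = hits$query, feature = hits$feature,
    chrom = track$chrom[hits$feature], start = track$start[hits$feature],
    end = track$end[hits$feature], strand = strand, name = nm,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Count overlapping features per query
#'
#' Convenience wrapper around [intersect_track()] returning, for each query
#' row, the number of track features it overlaps.
#'
#' @inheritParams intersect_track
#' @return integer vector of length `nrow(query)`.
#' @export
count_track_overlaps <- function(query, track) {
  hits <- intersect_track(query, track)
  tab <- tabulate(hits$query, nbins = nrow(query))
  as.integer(tab)
}

#' Distance from each query to the nearest feature of a track
#'
#' Used by the gene-proximity classifier: 0 when the query overlaps a
#' feature, otherwise the smallest base gap to any feature on the same
#' chromosome, `NA` when the chromosome carries no feature at all.
#'
#' @inheritParams intersect_track
#' @return list with `distance` (integer vector, `NA` = no feature on that
#'   chromosome) and `nearest` (row index into `track`, `NA` if none).
#' @export
nearest_feature_distance <- function(query, track) {
  validate_intervals(query)
  validate_intervals(track)
  n <- nrow(query)
  dist <- rep(NA_integer_, n)
  near <- rep(NA_integer_, n)
  if (n == 0L || nrow(track) == 0L)
    return(list(distance = dist, nearest = near))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ti <- which(track$chrom == ch)
    if (length(ti) == 0L) next
    for (q in qi) {
      gap <- pmax(pmax(query$start[q], track$start[ti]) -
                    pmin(query$end[q], track$end[ti]), 0L)
      k <- which.min(gap)
      dist[q] <- gap[k]
      near[q] <- ti[k]
    }
  }
  list(distance = dist, nearest = near)
}
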