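#' Compare two miRNA sets by genomic location
#'
#' Membership is by >= 1 bp location overlap: a member of A is "shared"
#' when it overlaps at least one member of B, and vice versa. Because the
#' relation need not be one-to-one, all overlapping id pairs are listed and
#' the shared counts are per-member (so `n_shared_a` can differ from
#' `n_shared_b`).
#'
#' @param set_a,set_b interval tables with an `id` column.
#' @return list with `n_a_only`, `n_b_only`, `n_shared_a`, `n_shared_b`,
#'   and `pairs` (data frame of overlapping `id_a`/`id_b`).
#' @export
compare_sets <- function(set_a, set_b) {
  hits <- intersect_track(set_a, set_b)
  shared_a <- unique(hits$query)
  shared_b <- unique(hits$feature)
  ids <- function(x, i) if ("id" %in% names(x)) x$id[i] else
    if ("name" %in% names(x)) x$name[i] else as.character(i)
  list(
    n_a_only = nrow(set_a) - length(shared_a),
    n_b_only = nrow(set_b) - length(shared_b),
    n_shared_a = length(shared_a),
    n_shared_b = length(shared_b),
    pairs = data.frame(id_a = ids(set_a, hits$query),
                       id_b = ids(set_b, hits$feature),
                       stringsAsFactors = FALSE)
  )
}

#' Three-way overlap (Venn) partition of miRNA sets
#'
#' Each member of each set is assigned to one of the seven Venn regions by
#' pairwise location overlap with the other two sets; region counts are
#' reported per set, so for each set the four regions it participates in
#' sum to its size.
#'
#' @param set_a,set_b,set_c interval tables.
#' @return named list of per-set region counts: e.g. `a_only`, `a_and_b`,
#'   `a_and_c`, `a_and_b_and_c` count members of A by which other sets they
#'   overlap, and likewise for B and C.
#' @export
three_way_venn <- function(set_a, set_b, set_c) {
  sets <- list(a = set_a, b = set_b, c = set_c)
  out <- list()
  for (s in names(sets)) {
    others <- setdiff(names(sets), s)
    in1 <- count_track_overlaps(sets[[s]], sets[[others[1]]]) > 0
    in2 <- count_track_overlaps(sets[[s]], sets[[others[2]]]) > 0
    out[[paste0(s, "_only")]] <- sum(!in1 & !in2)
    out[[paste0(s, "_and_", others[1])]] <- sum(in1 & !in2)
    out[[paste0(s, "_and_", others[2])]] <- sum(!in1 & in2)
    out[[paste0(s, "_and_", others[1], "_and_", others[2])]] <-
      sum(in1 & in2)
  }
  out
}
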