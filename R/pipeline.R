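#' Run the full discovery and calibration pipeline on a simulation
#'
#' Convenience driver used by the examples and the validation suite:
#' concatenates all samples' reads (discovery is performed on the pooled
#' library), preprocesses them (adapter trim, quality filter, QC length
#' filter, exact alignment), predicts hairpin candidates, categorizes them
#' against the annotation tracks, calibrates the score threshold to the
#' target FPR, and extracts the novel set.
#'
#' @param sim a `mirsim` object with simulated reads (see
#'   [simulate_reads()]), or a list with elements `reads` (list of read
#'   tables), `genome`, and `tracks` (with `exon`, `srna`,
#'   `mirna_hairpin`).
#' @param target_fpr calibration target.
#' @param weights a [score_weights()] object.
#' @param min_reads minimum stack size to seed a candidate.
#' @return list with `preprocess` (per-sample logs and pooled alignments),
#'   `candidates`, `categorized`, `auc`, `choice`, and `novel`.
#' @export
run_discovery_pipeline <- function(sim, target_fpr = 0.05,
                                   weights = score_weights(),
                                   min_reads = 3L) {
  stopifnot(!is.null(sim$reads), !is.null(sim$genome), !is.null(sim$tracks))
  adapter <- if (!is.null(sim$config)) sim$config$adapter else
    stop("simulation must carry its config (adapter sequence)")
  pooled <- do.call(rbind, sim$reads)
  pp <- preprocess_reads(pooled, sim$genome, adapter)
  candidates <- discover_hairpins(pp$alignments, sim$genome,
                                  weights = weights, min_reads = min_reads)
  categorized <- categorize_predictions(candidates, sim$tracks$exon,
                                        sim$tracks$srna,
                                        sim$tracks$mirna_hairpin)
  scores <- categorized$score[categorized$category %in%
                                c("false_positive", "true_positive")]
  dense <- sort(unique(c(scores, scores - 1e-9)))
  auc <- roc_auc(fpr_tpr_curve(categorized, dense))
  choice <- select_threshold(categorized, target_fpr = target_fpr)
  novel <- filter_novel(categorized, choice)
  list(preprocess = pp, candidates = candidates, categorized = categorized,
       auc = auc, choice = choice, novel = novel)
}

#' Recovery of withheld planted miRNAs by a novel set
#'
#' Ground-truth evaluation of a discovery run: among planted miRNAs that
#' were withheld from the known-miRNA annotation (and expressed at or above
#' `min_mean` expected reads per sample), the fraction whose hairpin
#' overlaps a reported novel candidate.
#'
#' @param sim the `mirsim` object the pipeline ran on.
#' @param novel novel candidate table (hairpin coordinates in
#'   `chrom`/`start`/`end`).
#' @param min_mean minimum per-sample expected reads for a planted miRNA to
#'   count as well-expressed.
#' @return list with `n_withheld`, `n_recovered`, `recovery`.
#' @export
novel_recovery <- function(sim, novel, min_mean = 200) {
  truth <- sim$truth
  wh <- truth[truth$kind == "mirna" & truth$withheld &
                truth$expression_mean >= min_mean, , drop = FALSE]
  if (nrow(wh) == 0L)
    return(list(n_withheld = 0L, n_recovered = 0L, recovery = NA_real_))
  hairpins <- gi(wh$chrom, wh$start, wh$end, "+", wh$name)
  hit <- count_track_overlaps(hairpins, novel) > 0
  list(n_withheld = nrow(wh), n_recovered = sum(hit),
       recovery = mean(hit))
}
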