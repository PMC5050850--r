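#' Categorize predictions by annotation overlap of the hairpin
#'
#' Each prediction's hairpin interval is intersected with the exon,
#' small-RNA and known-miRNA-hairpin tracks and assigned one of four
#' mutually exclusive categories:
#' * `false_positive` — overlaps exons and/or non-miRNA small RNAs only;
#' * `true_positive` — overlaps known miRNA hairpins only;
#' * `excluded` — overlaps both (it cannot be decided whether a true miRNA
#'   sits inside the exon or one annotation is wrong);
#' * `candidate` — overlaps neither and is therefore potentially novel.
#'
#' @param predictions candidate table (needs `chrom`, `start`, `end` of the
#'   hairpin, and `score`).
#' @param exon_track,srna_track,mirna_track interval tables.
#' @return `predictions` with an added `category` factor column.
#' @export
categorize_predictions <- function(predictions, exon_track, srna_track,
                                   mirna_track) {
  n_fp_ann <- count_track_overlaps(predictions, exon_track) +
    count_track_overlaps(predictions, srna_track)
  n_mirna <- count_track_overlaps(predictions, mirna_track)
  category <- rep("candidate", nrow(predictions))
  category[n_fp_ann > 0 & n_mirna == 0] <- "false_positive"
  category[n_fp_ann == 0 & n_mirna > 0] <- "true_positive"
  category[n_fp_ann > 0 & n_mirna > 0] <- "excluded"
  predictions$category <- factor(
    category, levels = c("false_positive", "true_positive", "excluded",
                         "candidate"))
  predictions
}

#' Empirical FPR/TPR over a set of score thresholds
#'
#' FPR(t) is the fraction of `false_positive` predictions with score
#' strictly above `t`; TPR(t) the analogous fraction of `true_positive`
#' predictions. The full categorized population is used at every threshold.
#'
#' @param categorized output of [categorize_predictions()].
#' @param thresholds numeric vector of thresholds.
#' @return data frame with `threshold`, `fpr`, `tpr`; attributes
#'   `n_fp_total` and `n_tp_total`.
#' @export
fpr_tpr_curve <- function(categorized, thresholds) {
  fp <- categorized$score[categorized$category == "false_positive"]
  tp <- categorized$score[categorized$category == "true_positive"]
  if (length(fp) == 0L || length(tp) == 0L)
    stop("FPR/TPR need at least one false positive and one true positive")
  curve <- data.frame(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) mean(fp > t), 0),
    tpr = vapply(thresholds, function(t) mean(tp > t), 0)
  )
  attr(curve, "n_fp_total") <- length(fp)
  attr(curve, "n_tp_total") <- length(tp)
  curve
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the (FPR, TPR) points of a threshold curve, with
#' the endpoints (0,0) and (1,1) included. With thresholds dense enough to
#' separate all scores this equals the probability that a random true
#' positive outscores a random false positive (ties counted half).
#'
#' @param curve output of [fpr_tpr_curve()].
#' @return numeric AUC in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  x <- c(0, sort(curve$fpr), 1)
  y <- c(0, sort(curve$tpr), 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Select the score threshold calibrated to a target FPR
#'
#' Two-stage grid search. Stage 1 scans every integer threshold from
#' `floor(min score)` to `ceil(max score)` and picks the integer `t*`
#' minimizing `|FPR(t) - target|`. Stage 2 rescans `t* - 1, t* - 0.99, ...,
#' t* + 1` in exact 0.01 steps and returns the refined minimizer. Ties are
#' broken toward the smallest threshold, which retains the most candidates
#' at equal calibrated error. Score comparison is strictly "above the
#' threshold" throughout, consistent with [fpr_tpr_curve()] and
#' [filter_novel()].
#'
#' @param categorized output of [categorize_predictions()].
#' @param target_fpr target false positive rate.
#' @return list with `threshold`, `achieved_fpr`, `achieved_tpr`,
#'   `integer_threshold`, and the stage-2 `curve`.
#' @export
select_threshold <- function(categorized, target_fpr = 0.05) {
  scores <- categorized$score[categorized$category %in%
                                c("false_positive", "true_positive")]
  grid1 <- seq.int(floor(min(scores)), ceiling(max(scores)))
  c1 <- fpr_tpr_curve(categorized, grid1)
  d1 <- abs(c1$fpr - target_fpr)
  t_int <- grid1[which.min(d1)]   # which.min takes the first (smallest) tie
  # 0.01-step grid in fixed point to avoid floating accumulation
  grid2 <- (t_int * 100L + seq.int(-100L, 100L)) / 100
  c2 <- fpr_tpr_curve(categorized, grid2)
  d2 <- abs(c2$fpr - target_fpr)
  k <- which.min(d2)
  list(threshold = grid2[k], achieved_fpr = c2$fpr[k],
       achieved_tpr = c2$tpr[k], integer_threshold = t_int, curve = c2)
}

#' Filter the novel candidate set at a calibrated threshold
#'
#' Keeps predictions categorized as `candidate` (no annotation overlap)
#' whose score is strictly above the chosen threshold.
#'
#' @param categorized output of [categorize_predictions()].
#' @param choice output of [select_threshold()] (or a number).
#' @return the surviving candidate rows.
#' @export
filter_novel <- function(categorized, choice) {
  thr <- if (is.list(choice)) choice$threshold else choice
  categorized[categorized$category == "candidate" & categorized$score > thr, ,
              drop = FALSE]
}
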