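#' Count reads per mature miRNA region (union-mode semantics)
#'
#' A read increments a region's count iff it overlaps exactly one region;
#' reads overlapping two or more regions are ambiguous and counted nowhere.
#' Counting uses each read's alignment interval; multi-mapped reads
#' contribute at every placement.
#'
#' @param alignments_by_sample named list (one element per sample) of
#'   alignment tables.
#' @param regions interval table of mature miRNA regions with unique `id`
#'   (or `name`) values.
#' @return integer matrix, regions x samples, with per-sample totals stored
#'   in the `"sample_totals"` attribute.
#' @export
count_reads <- function(alignments_by_sample, regions) {
  ids <- if ("id" %in% names(regions)) regions$id else
    if ("name" %in% names(regions)) regions$name else
      as.character(seq_len(nrow(regions)))
  if (anyDuplicated(ids)) stop("region ids must be unique")
  counts <- matrix(0L, nrow(regions), length(alignments_by_sample),
                   dimnames = list(ids, names(alignments_by_sample)))
  for (j in seq_along(alignments_by_sample)) {
    aln <- alignments_by_sample[[j]]
    if (is.null(aln) || nrow(aln) == 0L) next
    hits <- intersect_track(aln, regions)
    n_regions_hit <- tabulate(hits$query, nbins = nrow(aln))
    unambiguous <- hits[n_regions_hit[hits$query] == 1L, , drop = FALSE]
    tab <- tabulate(unambiguous$feature, nbins = nrow(regions))
    counts[, j] <- as.integer(tab)
  }
  attr(counts, "sample_totals") <- colSums(counts)
  counts
}

#' Drop miRNAs absent in more than half of the samples
#'
#' Removes rows with zero counts in strictly more than `n/2` samples; a row
#' that is zero in exactly half of them is kept.
#'
#' @param counts count matrix (rows = miRNAs, columns = samples).
#' @return the filtered matrix.
#' @export
prevalence_filter <- function(counts) {
  n_zero <- rowSums(counts == 0)
  counts[n_zero <= ncol(counts) / 2, , drop = FALSE]
}

#' Variance-stabilizing transform of a count matrix
#'
#' `log2(count / size_factor + 0.5)` with median-of-ratios size factors:
#' each sample's factor is the median, over rows with no zero count, of the
#' ratio of its count to the row's geometric mean. When no all-nonzero row
#' exists, library-size factors (column totals scaled to geometric mean 1)
#' are used instead and a message is emitted.
#'
#' @param counts count matrix.
#' @return numeric matrix of transformed values, with the factors in the
#'   `"size_factors"` attribute.
#' @export
vst_counts <- function(counts) {
  full <- rowSums(counts == 0) == 0
  if (any(full)) {
    logg <- rowMeans(log(counts[full, , drop = FALSE]))
    sf <- apply(counts[full, , drop = FALSE], 2, function(col)
      exp(median(log(col) - logg)))
  } else {
    message("no all-nonzero row; falling back to library-size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  out <- log2(sweep(counts, 2, sf, "/") + 0.5)
  attr(out, "size_factors") <- sf
  out
}

#' Location/scale batch adjustment
#'
#' Per row, each batch's values are standardized to the pooled row mean and
#' variance: a direct location/scale version of batch correction. Rows
#' constant within a batch, and batches with a single sample, get the
#' location shift only (the scale step is skipped).
#'
#' @param mat numeric matrix (typically VST output).
#' @param batch per-column batch labels.
#' @return adjusted matrix.
#' @export
batch_adjust <- function(mat, batch) {
  stopifnot(length(batch) == ncol(mat))
  if (length(unique(batch)) <= 1L) return(mat)
  out <- mat
  grand_mean <- rowMeans(mat)
  grand_sd <- apply(mat, 1, stats::sd)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    sub <- mat[, idx, drop = FALSE]
    b_mean <- rowMeans(sub)
    b_sd <- apply(sub, 1, stats::sd)
    scale_ok <- length(idx) > 1L & b_sd > 0 & grand_sd > 0
    sc <- ifelse(scale_ok, grand_sd / b_sd, 1)
    out[, idx] <- (sub - b_mean) * sc + grand_mean
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; input checked to lie in
#' `[0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-miRNA linear-model differential expression test
#'
#' For the requested contrast, fits `expression ~ group + age` by ordinary
#' least squares on the contrast's samples only, reports the group
#' coefficient as the log2 fold-change (disease minus control on the VST
#' scale, so lower disease expression gives a negative value), a two-sided
#' t-test p-value, and BH-adjusted p-values across the tested rows. If the
#' age covariate is constant (rank-deficient design) it is dropped with a
#' warning.
#'
#' @param mat adjusted expression matrix (rows = miRNAs).
#' @param samples sample metadata with `sample`, `group`, `age` columns
#'   matching the matrix columns.
#' @param contrast character of length 2: `c(disease_group, control_group)`.
#' @return data frame with `id`, `contrast`, `avg_log2_expr`, `log2fc`,
#'   `p_value`, `fdr_adjusted_p`.
#' @export
de_test <- function(mat, samples, contrast) {
  stopifnot(length(contrast) == 2L, all(contrast %in% samples$group))
  use <- samples$group %in% contrast
  sub <- mat[, use, drop = FALSE]
  grp <- factor(samples$group[use], levels = rev(contrast))  # control first
  age <- samples$age[use]
  use_age <- !is.null(age) && !anyNA(age) && stats::sd(age) > 0
  if (!use_age && !is.null(age))
    warning("age covariate constant or missing; dropped from the design")
  design <- if (use_age) stats::model.matrix(~ grp + age) else
    stats::model.matrix(~ grp)
  fit <- stats::lm.fit(design, t(sub))
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1L)
  coefs <- t(coefs)
  resid <- fit$residuals
  if (is.null(dim(resid))) resid <- matrix(resid, ncol = 1L)
  df_resid <- nrow(design) - ncol(design)
  resid_var <- colSums(resid^2) / df_resid
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(resid_var * xtx_inv[2, 2])
  tstat <- coefs[, 2] / se
  p <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  data.frame(
    id = rownames(mat),
    contrast = paste(contrast, collapse = "/"),
    avg_log2_expr = rowMeans(sub),
    log2fc = coefs[, 2],
    p_value = p,
    fdr_adjusted_p = bh_adjust(p),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
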