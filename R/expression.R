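#' Per-transcript log2 fold change between two stages
#'
#' `log2((FPKM_b + c) / (FPKM_a + c))` with pseudocount `c > 0`.
#'
#' @param mat expression matrix, rows = transcripts, columns = stages
#' @param stage_a reference stage label
#' @param stage_b comparison stage label
#' @param pseudocount positive stabilizer (default 1)
#' @return named numeric vector of log2 fold changes
#' @export
log2_fold_change <- function(mat, stage_a, stage_b, pseudocount = 1) {
  if (!all(c(stage_a, stage_b) %in% colnames(mat))) {
    stop("missing stage: ", paste(setdiff(c(stage_a, stage_b),
                                          colnames(mat)), collapse = ", "))
  }
  if (!(pseudocount > 0)) stop("pseudocount must be > 0")
  log2((mat[, stage_b] + pseudocount) / (mat[, stage_a] + pseudocount))
}

#' Poisson-rate stand-in test for two-sample differential expression
#'
#' For expression tables without replicates, compares FPKM-scaled
#' pseudo-counts of the two stages with an exact Poisson rate test. This is
#' a deliberately simple stand-in for assembly-level DE models and is not
#' equivalent to them; externally computed p-values can be supplied to
#' [differential_filter()] instead.
#'
#' @param mat expression matrix
#' @param stage_a,stage_b stage labels
#' @param scale pseudo-count scale factor applied to FPKM (default 10)
#' @param pseudocount passed to [log2_fold_change()]
#' @return data.frame with `id`, `log2FC`, `p`
#' @export
de_poisson_test <- function(mat, stage_a, stage_b, scale = 10,
                            pseudocount = 1e-3) {
  lfc <- log2_fold_change(mat, stage_a, stage_b, pseudocount)
  xa <- round(mat[, stage_a] * scale)
  xb <- round(mat[, stage_b] * scale)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    if (xa[i] + xb[i] == 0) return(1)
    stats::poisson.test(c(xb[i], xa[i]))$p.value
  }, numeric(1))
  data.frame(id = rownames(mat), log2FC = unname(lfc), p = p,
             stringsAsFactors = FALSE)
}

#' Differential-expression filter
#'
#' Benjamini-Hochberg adjusts the supplied p-values within the contrast and
#' flags transcripts passing all gates: `|log2FC| >= fc_thresh`, `p <
#' p_thresh`, `q < q_thresh`. The default fold-change gate is 1 on the log2
#' scale (2-fold); `fc_thresh = 2` gives the literal |log2FC| >= 2 reading.
#'
#' @param de_results data.frame with `id`, `log2FC`, `p`
#' @param fc_thresh log2 fold-change magnitude gate (default 1)
#' @param p_thresh p-value gate (default 0.005)
#' @param q_thresh BH-adjusted q-value gate (default 0.01)
#' @return input with `q` and logical `pass` columns added
#' @export
differential_filter <- function(de_results, fc_thresh = 1,
                                p_thresh = 0.005, q_thresh = 0.01) {
  if (nrow(de_results) == 0) stop("empty contrast")
  de_results$q <- stats::p.adjust(de_results$p, method = "BH")
  de_results$pass <- abs(de_results$log2FC) >= fc_thresh &
    de_results$p < p_thresh & de_results$q < q_thresh
  de_results
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation of two equal-length vectors (n >= 3).
#' Returns NA (flagged undefined) when either vector has zero variance;
#' such records are excluded from [bin_correlations()].
#'
#' @param vec_a,vec_b numeric vectors
#' @return correlation coefficient or NA
#' @export
pearson_correlation <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) stop("length mismatch")
  if (length(vec_a) < 3) stop("need at least 3 points")
  if (stats::sd(vec_a) == 0 || stats::sd(vec_b) == 0) return(NA_real_)
  stats::cor(vec_a, vec_b, method = "pearson")
}

#' Correlate expression changes of interacting pairs
#'
#' For each (lncRNA, target) pair, computes the Pearson correlation of the
#' per-stage log2 fold changes relative to a reference stage, across all
#' non-reference stages (optionally a subset).
#'
#' @param mat expression matrix
#' @param pairs data.frame with `lncrna_id` and a target id column
#'   (`target_id` or `gene_id`)
#' @param reference reference stage label (study design: the 0 DAA bud)
#' @param stages stages to correlate over (default: all except reference)
#' @param pseudocount passed to [log2_fold_change()]
#' @return data.frame `lncrna_id`, `target_id`, `r`, `n`
#' @export
correlate_pairs <- function(mat, pairs, reference,
                            stages = setdiff(colnames(mat), reference),
                            pseudocount = 1e-3) {
  tcol <- if ("target_id" %in% names(pairs)) "target_id" else "gene_id"
  lfc <- vapply(stages, function(st) {
    log2_fold_change(mat, reference, st, pseudocount)
  }, numeric(nrow(mat)))
  rownames(lfc) <- rownames(mat)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    lid <- pairs$lncrna_id[i]
    tid <- pairs[[tcol]][i]
    if (!(lid %in% rownames(lfc)) || !(tid %in% rownames(lfc))) {
      return(NULL)
    }
    data.frame(lncrna_id = lid, target_id = tid,
               r = pearson_correlation(lfc[lid, ], lfc[tid, ]),
               n = length(stages), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(lncrna_id = character(0), target_id = character(0),
                      r = numeric(0), n = integer(0))
  }
  out
}

#' Bin correlation records
#'
#' Fractions of defined correlations with |r| at or above 0.8, 0.6 and 0.5,
#' and the positive/negative split.
#'
#' @param records data.frame with an `r` column
#' @return one-row data.frame of fractions (`n_defined`, `frac_abs_ge_0.8`,
#'   `frac_abs_ge_0.6`, `frac_abs_ge_0.5`, `frac_positive`, `frac_negative`)
#' @export
bin_correlations <- function(records) {
  r <- records$r[!is.na(records$r)]
  if (length(r) == 0) stop("no defined correlations")
  data.frame(n_defined = length(r),
             frac_abs_ge_0.8 = mean(abs(r) >= 0.8),
             frac_abs_ge_0.6 = mean(abs(r) >= 0.6),
             frac_abs_ge_0.5 = mean(abs(r) >= 0.5),
             frac_positive = mean(r > 0),
             frac_negative = mean(r < 0))
}

#' Relative expression by the comparative Ct method
#'
#' `2^(-ddCt)` with `ddCt = (ct_target - ct_reference) - (ct_target_cal -
#' ct_ref_cal)`: the target gene normalized to the internal-control gene,
#' relative to a calibrator sample.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest
#' @param ct_target_cal,ct_ref_cal Ct values in the calibrator sample
#' @return relative expression fold value
#' @export
relative_expression_ddct <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_ref_cal) {
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}
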