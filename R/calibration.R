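# Threshold calibration: all-pairs disease/healthy log2FC lists, pooled
# randomized null lists, score distributions and FP/FN rates.

#' All-pairs log2 fold-change matrix over the panel genes
#'
#' Every disease sample is compared to every healthy sample: column `(d, h)`
#' holds `log2((count_d + c) / (count_h + c))` per panel gene, so `nd x nh`
#' pairings give `nd * nh` columns. These lists enumerate the relative
#' signature expression patterns present in the cohort.
#'
#' @param table normalized `count_table` containing both groups.
#' @param annot [probe_annotation].
#' @param sheet `sample_sheet` with `genotype` labels.
#' @param panel a [tds_panel]; rows are restricted to its genes.
#' @param pseudocount default 1.
#' @param disease,healthy genotype labels.
#' @return genes x pairs numeric matrix; columns named `"d|h"`.
#' @export
pairwise_lfc_matrix <- function(table, annot, sheet, panel, pseudocount = 1,
                                disease = "disease", healthy = "wt") {
  idx <- match(sample_ids(table), sheet$sample_id)
  if (anyNA(idx))
    stop("cross-reference error: samples missing from sheet")
  gt <- sheet$genotype[idx]
  d_cols <- which(gt == disease); h_cols <- which(gt == healthy)
  if (!length(d_cols) || !length(h_cols)) stop("empty group")
  m <- gene_counts(table, annot, panel$gene)
  out <- matrix(NA_real_, nrow = nrow(panel), ncol = length(d_cols) * length(h_cols),
                dimnames = list(panel$gene, NULL))
  cn <- character(ncol(out))
  k <- 0L
  for (d in d_cols) for (h in h_cols) {
    k <- k + 1L
    out[, k] <- log2((m[, d] + pseudocount) / (m[, h] + pseudocount))
    cn[k] <- paste(sample_ids(table)[d], sample_ids(table)[h], sep = "|")
  }
  colnames(out) <- cn
  out
}

#' Randomized null log2FC lists by pooled resampling
#'
#' Each null list draws one value per gene uniformly, with replacement, from
#' the pooled multiset of *all* entries of the disease-pair matrix. Pooling
#' (rather than per-gene resampling) destroys the gene-to-direction
#' association, so null lists carry no signature signal and score near zero.
#'
#' @param lfc_matrix genes x pairs matrix from [pairwise_lfc_matrix()].
#' @param n_lists number of null lists (>= 1).
#' @param seed integer RNG seed (mandatory: nulls must be reproducible).
#' @return genes x n_lists matrix with the same rownames.
#' @export
simulate_null_lists <- function(lfc_matrix, n_lists, seed) {
  if (!length(lfc_matrix)) stop("empty log2FC matrix")
  if (n_lists < 1) stop("n_lists must be >= 1")
  if (missing(seed) || is.null(seed)) stop("explicit seed required")
  set.seed(as.integer(seed))
  pool <- as.vector(lfc_matrix)
  matrix(sample(pool, nrow(lfc_matrix) * n_lists, replace = TRUE),
         nrow = nrow(lfc_matrix),
         dimnames = list(rownames(lfc_matrix), NULL))
}

#' Score columns of a log2FC matrix against a panel
#'
#' Applies [gene_states()], [activation_zscore()] and [ks_drug_score()] to
#' every column (one log2FC list per column).
#'
#' @param lfc_matrix genes x lists matrix; rownames must cover the panel.
#' @param panel a [tds_panel].
#' @param weighted use panel weights in the Z-score.
#' @param min_abs_lfc exclusion threshold for [gene_states()].
#' @return data.frame with one row per column: `z`, `ks_up`, `ks_down`, `s`.
#' @export
score_lfc_lists <- function(lfc_matrix, panel, weighted = FALSE,
                            min_abs_lfc = 0) {
  w <- if (weighted) panel$weight else NULL
  res <- vapply(seq_len(ncol(lfc_matrix)), function(k) {
    lfc <- lfc_matrix[, k]
    st <- gene_states(lfc, panel, min_abs_lfc = min_abs_lfc)
    z <- activation_zscore(st, weights = w)$z
    ks <- ks_drug_score(lfc, panel)
    c(z = z, ks_up = ks$ks_up, ks_down = ks$ks_down, s = ks$s)
  }, numeric(4))
  out <- as.data.frame(t(res))
  rownames(out) <- colnames(lfc_matrix)
  out
}

#' False-positive / false-negative rates at given thresholds
#'
#' The false-positive rate is the fraction of null lists whose score
#' magnitude reaches the threshold; the false-negative rate is the fraction
#' of disease pairs whose *signed* score fails to reach `+threshold`
#' (a disease list must read as signature-activating).
#'
#' @param disease_scores,null_scores data.frames with columns `z` and `s`
#'   (as from [score_lfc_lists()]).
#' @param z_threshold,s_threshold significance thresholds (defaults 2, 0.27).
#' @return object of class `calibration_result`: list with the two score
#'   tables, thresholds, and `fp_rate_z`, `fn_rate_z`, `fp_rate_s`,
#'   `fn_rate_s`.
#' @export
estimate_error_rates <- function(disease_scores, null_scores,
                                 z_threshold = 2, s_threshold = 0.27) {
  if (!nrow(disease_scores) || !nrow(null_scores)) stop("empty score list")
  structure(list(
    disease_scores = disease_scores, null_scores = null_scores,
    z_threshold = z_threshold, s_threshold = s_threshold,
    fp_rate_z = mean(abs(null_scores$z) >= z_threshold),
    fn_rate_z = mean(disease_scores$z < z_threshold),
    fp_rate_s = mean(abs(null_scores$s) >= s_threshold),
    fn_rate_s = mean(disease_scores$s < s_threshold)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: %d disease pairs, %d null lists\n",
              nrow(x$disease_scores), nrow(x$null_scores)))
  cat(sprintf("  z  >= %.2f: FP %.1f%%, FN %.1f%%\n", x$z_threshold,
              100 * x$fp_rate_z, 100 * x$fn_rate_z))
  cat(sprintf("  S  >= %.2f: FP %.1f%%, FN %.1f%%\n", x$s_threshold,
              100 * x$fp_rate_s, 100 * x$fn_rate_s))
  invisible(x)
}

#' Calibrate scoring thresholds on a case/control cohort
#'
#' Composes [pairwise_lfc_matrix()], [simulate_null_lists()] and
#' [estimate_error_rates()], and additionally scores two anchors: the
#' *reference signature* itself (its own `ref_log2fc` list — every gene
#' consistent, the maximal positive score) and the *model compound* (the
#' negated reference — a hypothetical full reversal, the maximal negative
#' score).
#'
#' @param table normalized `count_table` for the cohort.
#' @param annot,sheet,panel as in [pairwise_lfc_matrix()].
#' @param n_null number of randomized null lists (default 400).
#' @param seed integer RNG seed for the null resampling (mandatory).
#' @param weighted use panel weights for the Z-scores (default `TRUE`).
#' @param z_threshold,s_threshold thresholds (defaults 2, 0.27).
#' @param pseudocount for the pairwise fold changes.
#' @return a `calibration_result` with extra elements `anchors`
#'   (scores for `reference` and `model_compound`), `n_disease_pairs`,
#'   `n_null`, `seed`, `weighted`.
#' @export
calibrate <- function(table, annot, sheet, panel, n_null = 400, seed,
                      weighted = TRUE, z_threshold = 2, s_threshold = 0.27,
                      pseudocount = 1) {
  lfc <- pairwise_lfc_matrix(table, annot, sheet, panel,
                             pseudocount = pseudocount)
  nulls <- simulate_null_lists(lfc, n_null, seed = seed)
  disease_scores <- score_lfc_lists(lfc, panel, weighted = weighted)
  null_scores <- score_lfc_lists(nulls, panel, weighted = weighted)
  anchor_m <- cbind(reference = panel$ref_log2fc,
                    model_compound = -panel$ref_log2fc)
  rownames(anchor_m) <- panel$gene
  anchors <- score_lfc_lists(anchor_m, panel, weighted = weighted)
  out <- estimate_error_rates(disease_scores, null_scores,
                              z_threshold = z_threshold,
                              s_threshold = s_threshold)
  out$anchors <- anchors
  out$n_disease_pairs <- ncol(lfc)
  out$n_null <- n_null
  out$seed <- seed
  out$weighted <- weighted
  out
}

#' Write a calibration result to JSON (scalars) and CSV (score lists)
#'
#' @param calib a `calibration_result`.
#' @param json_path output JSON with thresholds, rates and anchors.
#' @param scores_path optional CSV of the per-list scores.
#' @export
write_calibration <- function(calib, json_path, scores_path = NULL) {
  rec <- list(z_threshold = calib$z_threshold,
              s_threshold = calib$s_threshold,
              fp_rate_z = calib$fp_rate_z, fn_rate_z = calib$fn_rate_z,
              fp_rate_s = calib$fp_rate_s, fn_rate_s = calib$fn_rate_s,
              n_disease_pairs = calib$n_disease_pairs,
              n_null = calib$n_null, seed = calib$seed,
              weighted = calib$weighted,
              anchors = calib$anchors)
  jsonlite::write_json(rec, json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(scores_path)) {
    both <- rbind(cbind(kind = "disease_pair", calib$disease_scores),
                  cbind(kind = "null", calib$null_scores))
    utils::write.csv(both, scores_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
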