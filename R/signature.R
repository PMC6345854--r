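# Building the weighted disease signature: per-gene two-group statistics
# (log2 fold change, Welch t, BH FDR, ROC AUC), preliminary selection,
# two-test cross-validation, AUC-based weighting and Spearman QC.

#' Log2 fold change between two groups of counts
#'
#' `log2((mean(a) + c) / (mean(b) + c))` with pseudocount `c` guarding
#' against zero means. Computed on untransformed counts.
#'
#' @param a,b numeric vectors (group A = numerator, e.g. disease/treated).
#' @param pseudocount nonnegative real, default 1.
#' @export
log2_fold_change <- function(a, b, pseudocount = 1) {
  if (!length(a) || !length(b)) stop("empty group")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  log2((mean(a) + pseudocount) / (mean(b) + pseudocount))
}

#' Welch two-sample t-test (two-sided)
#'
#' Thin wrapper over [stats::t.test()] with Satterthwaite degrees of freedom.
#' When both groups are constant with equal means (where the t statistic is
#' 0/0) the test returns `t = 0, p = 1` by convention instead of failing.
#'
#' @param a,b numeric vectors, each with `n >= 2`.
#' @return list with `t_stat`, `p_value`, `df`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t_stat = 0, p_value = 1, df = NA_real_))
    stop("both groups constant with unequal means: t undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], monotone-enforced and
#' capped at 1, returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' ROC AUC by pair counting (Mann-Whitney form)
#'
#' Probability that a randomly drawn disease value exceeds a randomly drawn
#' healthy value, ties counted one half: the normalized Mann-Whitney U.
#' Computed from midranks, which is exactly equivalent to enumerating all
#' `(d, h)` pairs.
#'
#' @param disease,healthy numeric vectors; disease is the positive class.
#' @export
roc_auc <- function(disease, healthy) {
  nd <- length(disease); nh <- length(healthy)
  if (!nd || !nh) stop("empty group")
  r <- rank(c(disease, healthy), ties.method = "average")
  (sum(r[seq_len(nd)]) - nd * (nd + 1) / 2) / (nd * nh)
}

# AUC oriented so either direction of separation scores >= 0.5.
oriented_auc <- function(auc) pmax(auc, 1 - auc)

#' Per-gene two-group statistics for a normalized count table
#'
#' For every endogenous gene (classes in `classes`) computes the log2 fold
#' change (disease vs healthy, untransformed means, pseudocount 1), the Welch
#' t-test on `log2(count + 1)` transformed values (variance stabilization),
#' the BH FDR across the tested genes, and the ROC AUC with disease as the
#' positive class.
#'
#' @param table normalized `count_table`.
#' @param annot [probe_annotation].
#' @param sheet `sample_sheet` covering the table's samples.
#' @param classes probe classes to test (default endogenous `tds` and
#'   `pathway` probes).
#' @param disease,healthy genotype labels identifying the two groups.
#' @return data.frame of class `gene_stats`: `gene`, `log2fc`, `t_stat`,
#'   `p_value`, `fdr`, `auc`.
#' @export
gene_stats <- function(table, annot, sheet, classes = c("tds", "pathway"),
                       disease = "disease", healthy = "wt") {
  idx <- match(sample_ids(table), sheet$sample_id)
  if (anyNA(idx))
    stop("cross-reference error: samples missing from sheet: ",
         paste(sample_ids(table)[is.na(idx)], collapse = ", "))
  gt <- sheet$genotype[idx]
  d_cols <- which(gt == disease); h_cols <- which(gt == healthy)
  if (length(d_cols) < 2 || length(h_cols) < 2)
    stop("need >= 2 samples per genotype group")
  rows <- class_rows(table, annot, classes)
  genes <- annot$gene[match(probe_ids(table)[rows], annot$probe_id)]
  m <- table$counts[rows, , drop = FALSE]
  lm2 <- log2(m + 1)
  stats_list <- lapply(seq_along(rows), function(i) {
    d <- m[i, d_cols]; h <- m[i, h_cols]
    wt <- welch_t(lm2[i, d_cols], lm2[i, h_cols])
    c(log2fc = log2_fold_change(d, h),
      t_stat = wt$t_stat, p_value = wt$p_value,
      auc = roc_auc(d, h))
  })
  st <- do.call(rbind, stats_list)
  out <- data.frame(gene = genes, log2fc = st[, "log2fc"],
                    t_stat = st[, "t_stat"], p_value = st[, "p_value"],
                    fdr = bh_adjust(st[, "p_value"]), auc = st[, "auc"],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Preliminary signature selection
#'
#' Genes pass when all three gates hold: `|log2fc| >= lfc`, `fdr <= fdr`,
#' and oriented AUC `max(auc, 1 - auc) >= auc` — the orientation makes the
#' AUC gate direction-agnostic, matching the fold-change gate.
#'
#' @param stats a [gene_stats] data.frame.
#' @param lfc,fdr,auc gate thresholds (defaults 0.7, 0.05, 0.7).
#' @return character vector of selected genes.
#' @export
select_preliminary_tds <- function(stats, lfc = 0.7, fdr = 0.05, auc = 0.7) {
  keep <- abs(stats$log2fc) >= lfc & stats$fdr <= fdr &
    oriented_auc(stats$auc) >= auc
  stats$gene[keep]
}

#' Cross-validate candidate genes over two independent tests
#'
#' Keeps genes whose log2 fold change has the same nonzero sign in both
#' tests and whose oriented AUC exceeds `auc` in at least one test. Genes
#' missing from either test are excluded with a warning.
#'
#' @param test1,test2 [gene_stats] for the two validation cohorts.
#' @param candidates genes to validate (default: all genes shared by both).
#' @param auc AUC threshold, default 0.7 (strict inequality).
#' @return data.frame `gene`, `log2fc1`, `log2fc2`, `auc1`, `auc2` (oriented)
#'   for the validated genes.
#' @export
cross_validate_panel <- function(test1, test2, candidates = NULL, auc = 0.7) {
  if (is.null(candidates)) candidates <- intersect(test1$gene, test2$gene)
  i1 <- match(candidates, test1$gene); i2 <- match(candidates, test2$gene)
  miss <- is.na(i1) | is.na(i2)
  if (any(miss)) {
    warning("genes missing from one test excluded: ",
            paste(candidates[miss], collapse = ", "))
    candidates <- candidates[!miss]; i1 <- i1[!miss]; i2 <- i2[!miss]
  }
  l1 <- test1$log2fc[i1]; l2 <- test2$log2fc[i2]
  a1 <- oriented_auc(test1$auc[i1]); a2 <- oriented_auc(test2$auc[i2])
  keep <- sign(l1) == sign(l2) & sign(l1) != 0 & pmax(a1, a2) > auc
  data.frame(gene = candidates[keep], log2fc1 = l1[keep], log2fc2 = l2[keep],
             auc1 = a1[keep], auc2 = a2[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign scoring weights and build the panel
#'
#' Genes with oriented AUC above `high_auc` (default 0.8) in *both* tests get
#' weight 2; the rest are weighted by their best oriented AUC, which lies in
#' (0.7, 1] after validation. Reference direction is the sign of the mean
#' log2 fold change across the two tests, and the reference log2FC is that
#' mean.
#'
#' @param validated data.frame from [cross_validate_panel()].
#' @param high_auc both-tests AUC threshold for weight 2.
#' @return A [tds_panel].
#' @export
assign_weights <- function(validated, high_auc = 0.8) {
  if (!nrow(validated)) stop("no validated genes")
  lfc <- (validated$log2fc1 + validated$log2fc2) / 2
  w <- ifelse(validated$auc1 > high_auc & validated$auc2 > high_auc,
              2, pmax(validated$auc1, validated$auc2))
  tds_panel(gene = validated$gene,
            ref_direction = sign(lfc), ref_log2fc = lfc,
            auc_test1 = validated$auc1, auc_test2 = validated$auc2,
            weight = w)
}

#' Build a TDS panel from two validation cohorts
#'
#' Convenience composition: per-gene statistics on each cohort,
#' preliminary selection on the first (unless `candidates` is given),
#' cross-validation over both, then weighting.
#'
#' @param table1,sheet1 normalized counts + sheet for validation test 1.
#' @param table2,sheet2 the same for test 2.
#' @param annot [probe_annotation].
#' @param candidates optional candidate gene set; default: preliminary
#'   selection from test 1 restricted to `tds`-class probes.
#' @param lfc,fdr,auc preliminary gate thresholds.
#' @return list with `panel` ([tds_panel]), `stats1`, `stats2`,
#'   `candidates`, `validated`.
#' @export
build_panel <- function(table1, sheet1, table2, sheet2, annot,
                        candidates = NULL, lfc = 0.7, fdr = 0.05, auc = 0.7) {
  stats1 <- gene_stats(table1, annot, sheet1, classes = "tds")
  stats2 <- gene_stats(table2, annot, sheet2, classes = "tds")
  if (is.null(candidates))
    candidates <- select_preliminary_tds(stats1, lfc = lfc, fdr = fdr, auc = auc)
  validated <- cross_validate_panel(stats1, stats2, candidates, auc = auc)
  list(panel = assign_weights(validated), stats1 = stats1, stats2 = stats2,
       candidates = candidates, validated = validated)
}

#' Spearman sample-sample correlation QC
#'
#' Rank-based correlation between all sample pairs of a count table, with
#' average-linkage clustering labels for a quick concordance check. Constant
#' samples (zero rank variance) yield `NA` correlations with a warning.
#'
#' @param table a `count_table` with >= 2 samples and >= 2 probes.
#' @return list with `correlation` (samples x samples matrix) and
#'   `dendrogram_order` (sample ids in average-linkage leaf order, `NULL`
#'   when any correlation is undefined).
#' @export
spearman_matrix <- function(table) {
  m <- table$counts
  if (ncol(m) < 2 || nrow(m) < 2) stop("need >= 2 samples and >= 2 probes")
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(constant))
    warning("constant sample(s), correlation undefined: ",
            paste(colnames(m)[constant], collapse = ", "))
  cc <- suppressWarnings(stats::cor(m, method = "spearman"))
  ord <- NULL
  if (!anyNA(cc)) {
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    ord <- colnames(m)[hc$order]
  }
  list(correlation = cc, dendrogram_order = ord)
}
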