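# Probe-count normalization: positive-control hybridization scaling,
# housekeeper RNA-content scaling, negative-control background subtraction.
# The three steps run in that fixed order.

geomean <- function(x) exp(mean(log(x)))

new_factor_report <- function(samples) {
  data.frame(sample_id = samples,
             pos_factor = NA_real_, hk_factor = NA_real_,
             background_mu = NA_real_, background_sigma = NA_real_,
             background_threshold = NA_real_,
             stringsAsFactors = FALSE)
}

#' Positive-control (hybridization efficiency) normalization
#'
#' Per-sample hybridization efficiency is summarized by the arithmetic mean
#' of the spiked positive-control counts. Each sample is rescaled by
#' `f_s = grand_mean / pos_mean_s`, where the reference `grand_mean` is the
#' arithmetic mean of the per-sample means, so factors average ~1 within a
#' run and cartridge-to-cartridge hybridization differences cancel. After
#' the step every sample has the same positive-control mean.
#'
#' @param table `count_table` at stage `raw`.
#' @param annot [probe_annotation] for the table's probes.
#' @return list with `table` (stage `pos_normalized`) and `factors`
#'   (data.frame `sample_id`, `pos_factor`).
#' @export
positive_control_normalize <- function(table, annot) {
  if (ncol(table$counts) == 0) stop("empty sample list")
  pos <- class_rows(table, annot, "positive_control")
  if (!length(pos)) stop("normalization error: no positive-control probes")
  pos_means <- colMeans(table$counts[pos, , drop = FALSE])
  if (any(pos_means <= 0))
    stop("normalization error: all-zero positive controls in sample(s): ",
         paste(sample_ids(table)[pos_means <= 0], collapse = ", "))
  f <- mean(pos_means) / pos_means
  counts <- sweep(table$counts, 2, f, `*`)
  list(table = count_table(counts, stage = "pos_normalized"),
       factors = data.frame(sample_id = sample_ids(table), pos_factor = f,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Housekeeper (RNA content) normalization
#'
#' The per-sample geometric mean of housekeeper counts summarizes RNA input;
#' each sample is rescaled by `grand_mean / g_s` with the reference again the
#' arithmetic mean of per-sample summaries. Housekeeper counts of exactly
#' zero are replaced by 0.5 inside the factor computation only (warning
#' issued); stored counts are never altered. The factor is applied to the
#' endogenous probes and the negative controls (keeping background on the
#' same scale as the expression counts it is later subtracted from), but not
#' to the positive controls: the spike-ins are physically independent of RNA
#' input, and rescaling them would undo the hybridization equalization of
#' the previous step.
#'
#' @param table `count_table` at stage `pos_normalized`.
#' @param annot [probe_annotation].
#' @return list with `table` (stage `hk_normalized`) and `factors`
#'   (data.frame `sample_id`, `hk_factor`).
#' @export
housekeeper_normalize <- function(table, annot) {
  hk <- class_rows(table, annot, "housekeeper")
  if (!length(hk)) stop("normalization error: no housekeeper probes")
  m <- table$counts[hk, , drop = FALSE]
  if (any(colSums(m) == 0))
    stop("normalization error: all housekeepers zero in sample(s): ",
         paste(sample_ids(table)[colSums(m) == 0], collapse = ", "))
  if (any(m == 0)) {
    warning("zero housekeeper counts replaced by 0.5 for factor computation")
    m[m == 0] <- 0.5
  }
  g <- apply(m, 2, geomean)
  f <- mean(g) / g
  counts <- table$counts
  scaled <- class_rows(table, annot,
                       c("tds", "pathway", "housekeeper", "negative_control"))
  counts[scaled, ] <- sweep(counts[scaled, , drop = FALSE], 2, f, `*`)
  list(table = count_table(counts, stage = "hk_normalized"),
       factors = data.frame(sample_id = sample_ids(table), hk_factor = f,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Background subtraction from negative controls
#'
#' Per sample, background is estimated from the negative-control probes as
#' `mu + 2 * sigma` (sample standard deviation, n - 1 denominator) and
#' subtracted from the expression readout probes (`tds` and `pathway`
#' classes), clamping at zero. Control and housekeeper rows are left
#' unmodified: housekeepers serve scaling, not expression readout, and
#' subtracting a per-sample threshold from them would destroy the equalized
#' geometric means established by the previous step.
#'
#' @param table `count_table` at stage `hk_normalized`.
#' @param annot [probe_annotation].
#' @return list with `table` (stage `background_subtracted`) and `factors`
#'   (data.frame `sample_id`, `background_mu`, `background_sigma`,
#'   `background_threshold`).
#' @export
subtract_background <- function(table, annot) {
  neg <- class_rows(table, annot, "negative_control")
  if (length(neg) < 2)
    stop("normalization error: need >= 2 negative-control probes")
  nm <- table$counts[neg, , drop = FALSE]
  mu <- colMeans(nm)
  sigma <- apply(nm, 2, stats::sd)
  thr <- mu + 2 * sigma
  endo <- class_rows(table, annot, c("tds", "pathway"))
  counts <- table$counts
  counts[endo, ] <- pmax(sweep(counts[endo, , drop = FALSE], 2, thr, `-`), 0)
  list(table = count_table(counts, stage = "background_subtracted"),
       factors = data.frame(sample_id = sample_ids(table),
                            background_mu = mu, background_sigma = sigma,
                            background_threshold = thr,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Full normalization pipeline
#'
#' Composes [positive_control_normalize()], [housekeeper_normalize()] and
#' [subtract_background()] in that fixed order. Housekeeper factors are
#' computed before background subtraction.
#'
#' @param table `count_table` at stage `raw`.
#' @param annot [probe_annotation].
#' @param report_path optional CSV path for the per-sample factor report.
#' @return list with `table` (stage `background_subtracted`) and `factors`
#'   (per-sample data.frame with all five factor columns).
#' @export
normalize_pipeline <- function(table, annot, report_path = NULL) {
  if (ncol(table$counts) == 0) stop("empty sample list")
  s1 <- positive_control_normalize(table, annot)
  s2 <- housekeeper_normalize(s1$table, annot)
  s3 <- subtract_background(s2$table, annot)
  factors <- new_factor_report(sample_ids(table))
  factors$pos_factor <- s1$factors$pos_factor
  factors$hk_factor <- s2$factors$hk_factor
  factors$background_mu <- s3$factors$background_mu
  factors$background_sigma <- s3$factors$background_sigma
  factors$background_threshold <- s3$factors$background_threshold
  if (!is.null(report_path))
    utils::write.csv(factors, report_path, row.names = FALSE, quote = FALSE)
  list(table = s3$table, factors = factors)
}
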