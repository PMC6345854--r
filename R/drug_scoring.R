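# Compound scoring against the reference signature: treatment-vs-vehicle
# DEG statistics, consistent/contradicting gene states, the signed
# activation Z-score, and the two-sided KS drug score.

#' Identify differentially expressed genes between treated and control arms
#'
#' Per gene: log2 fold change (treated vs control, untransformed means,
#' pseudocount 1) and a Welch two-sided p-value on `log2(count + 1)` values.
#' A gene is a DEG when `|log2fc| >= lfc` and `p <= p_threshold` (raw p;
#' no multiplicity correction is applied at this screening step).
#'
#' @param treated,control normalized `count_table`s (or probes x samples
#'   matrices with gene rownames) for the two arms, each with >= 2 samples.
#' @param annot optional [probe_annotation]; when given, rows are restricted
#'   to `classes` and keyed by gene symbol.
#' @param classes probe classes to test when `annot` is given.
#' @param lfc,p_threshold DEG gates (defaults 0.6 and 0.05).
#' @return data.frame `gene`, `log2fc`, `p_value`, `deg` (logical).
#' @export
identify_degs <- function(treated, control, annot = NULL,
                          classes = c("tds", "pathway"),
                          lfc = 0.6, p_threshold = 0.05) {
  tm <- if (inherits(treated, "count_table")) treated$counts else as.matrix(treated)
  cm <- if (inherits(control, "count_table")) control$counts else as.matrix(control)
  if (!is.null(annot)) {
    keep <- function(m) {
      idx <- match(rownames(m), annot$probe_id)
      rows <- which(annot$probe_class[idx] %in% classes)
      m <- m[rows, , drop = FALSE]
      rownames(m) <- annot$gene[idx][rows]
      m
    }
    tm <- keep(tm); cm <- keep(cm)
  }
  if (ncol(tm) < 2 || ncol(cm) < 2) stop("each arm needs n >= 2 samples")
  common <- intersect(rownames(tm), rownames(cm))
  if (!length(common)) stop("no shared genes between arms")
  tm <- tm[common, , drop = FALSE]; cm <- cm[common, , drop = FALSE]
  res <- vapply(seq_along(common), function(i) {
    c(log2_fold_change(tm[i, ], cm[i, ]),
      welch_t(log2(tm[i, ] + 1), log2(cm[i, ] + 1))$p_value)
  }, numeric(2))
  out <- data.frame(gene = common, log2fc = res[1, ], p_value = res[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$deg <- abs(out$log2fc) >= lfc & out$p_value <= p_threshold
  out
}

#' Gene states relative to the reference signature
#'
#' A panel gene whose drug-induced log2 fold change shares the sign of its
#' reference direction is consistent with the disease signature (`x = +1`,
#' the compound pushes it disease-ward); an opposite sign is contradicting
#' (`x = -1`). Genes with `drug_log2fc == 0` or `|drug_log2fc| <=
#' min_abs_lfc` carry no direction and are excluded, reducing `N`.
#'
#' @param drug_lfc named numeric vector of per-gene log2 fold changes
#'   (treated vs vehicle); must cover every panel gene.
#' @param panel a [tds_panel].
#' @param min_abs_lfc exclusion threshold on `|drug_log2fc|` (default 0:
#'   only exact zeros are excluded).
#' @return list with `states` (data.frame `gene`, `drug_log2fc`, `state`;
#'   excluded genes have `state = NA`), `n`, `n_plus`, `n_minus`.
#' @export
gene_states <- function(drug_lfc, panel, min_abs_lfc = 0) {
  missing <- setdiff(panel$gene, names(drug_lfc))
  if (length(missing))
    stop("panel genes missing from expression: ",
         paste(missing, collapse = ", "))
  lfc <- drug_lfc[panel$gene]
  excluded <- lfc == 0 | abs(lfc) <= min_abs_lfc
  x <- ifelse(sign(lfc) == panel$ref_direction, 1L, -1L)
  x[excluded] <- NA_integer_
  list(states = data.frame(gene = panel$gene, drug_log2fc = unname(lfc),
                           state = x, row.names = NULL,
                           stringsAsFactors = FALSE),
       n = sum(!excluded),
       n_plus = sum(x == 1L, na.rm = TRUE),
       n_minus = sum(x == -1L, na.rm = TRUE))
}

#' Activation Z-score
#'
#' Under the null that each included gene is independently consistent or
#' contradicting with probability 1/2, `x = sum(x_i) = N+ - N-` has variance
#' `N`, giving the standard-normal statistic `Z = (N+ - N-) / sqrt(N)`.
#' With per-gene weights the statistic is `sum(w_i x_i) / sqrt(sum(w_i^2))`,
#' which keeps unit variance under the same null. `Z >= 2` flags a
#' disease-activating compound, `Z <= -2` a disease-repressing one.
#'
#' @param states result of [gene_states()].
#' @param weights optional numeric per-gene weights, aligned with
#'   `states$states$gene` (e.g. `panel$weight`). `NULL` gives the unweighted
#'   statistic.
#' @return list with `z`, `n`, `n_plus`, `n_minus`, `sigma_x` (the
#'   denominator), `weighted`, and `status` (`"ok"`, or `"no-evidence"` with
#'   `z = NA` when no gene is included).
#' @export
activation_zscore <- function(states, weights = NULL) {
  x <- states$states$state
  inc <- !is.na(x)
  if (!any(inc))
    return(list(z = NA_real_, n = 0L, n_plus = 0L, n_minus = 0L,
                sigma_x = NA_real_, weighted = !is.null(weights),
                status = "no-evidence"))
  if (is.null(weights)) {
    sigma <- sqrt(sum(inc))
    z <- sum(x[inc]) / sigma
  } else {
    if (length(weights) != length(x))
      stop("weights must align with panel genes")
    if (any(weights[inc] <= 0)) stop("weights must be positive")
    sigma <- sqrt(sum(weights[inc]^2))
    z <- sum(weights[inc] * x[inc]) / sigma
  }
  list(z = z, n = states$n, n_plus = states$n_plus, n_minus = states$n_minus,
       sigma_x = sigma, weighted = !is.null(weights), status = "ok")
}

# Signed one-sided KS statistic from 1-based tag positions V (sorted
# ascending) in a ranking of n genes:
#   a = max_j [ j/t - V(j)/n ],  b = max_j [ V(j)/n - (j-1)/t ]
#   ks = a if a > b, -b if b > a, 0 on an exact tie.
ks_from_positions <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a <- max(j / t - V / n)
  b <- max(V / n - (j - 1) / t)
  if (a > b) a else if (b > a) -b else 0
}

#' Signed KS enrichment of a tag set in a ranked gene list
#'
#' Positive values mean the tags concentrate at the top of the ranking,
#' negative at the bottom; the magnitude is the larger of the two one-sided
#' running deviations (connectivity-map convention).
#'
#' @param ranked_genes character vector: all genes ordered by decreasing
#'   drug-induced expression change.
#' @param tags nonempty subset of `ranked_genes`.
#' @return ks in \[-1, 1\].
#' @export
ks_enrichment <- function(ranked_genes, tags) {
  if (!length(tags)) stop("empty tag set")
  V <- match(tags, ranked_genes)
  if (anyNA(V)) stop("tags must be a subset of the ranked list: ",
                     paste(tags[is.na(V)], collapse = ", "))
  ks_from_positions(sort(V), length(ranked_genes))
}

# Panel genes ranked by descending drug lfc, ties broken by gene name.
rank_panel_genes <- function(drug_lfc, panel) {
  lfc <- drug_lfc[panel$gene]
  panel$gene[order(-lfc, panel$gene)]
}

#' KS drug score
#'
#' Ranks the panel genes by decreasing drug-induced log2 fold change and
#' computes the signed KS enrichment of the reference up-regulated tags
#' (`ks_up`) and down-regulated tags (`ks_down`). The drug score is
#' `S = ks_up - ks_down` when the two have opposite (or zero) signs —
#' `S > 0` disease-activating, `S < 0` disease-repressing — and `S = 0` when
#' both deviate the same way, i.e. there is no coherent directional signal.
#'
#' @param drug_lfc named per-gene log2 fold changes covering the panel.
#' @param panel a [tds_panel] with at least one up and one down gene.
#' @param tags `"reference"` (default): tag sets are the panel's up/down
#'   genes; `"deg"`: tags are restricted to the compound's own DEGs
#'   (`deg_genes`), the restrictive reading of the tag-set definition.
#' @param deg_genes character vector of DEG names (required for
#'   `tags = "deg"`).
#' @return list with `ks_up`, `ks_down`, `s`.
#' @export
ks_drug_score <- function(drug_lfc, panel, tags = c("reference", "deg"),
                          deg_genes = NULL) {
  tags <- match.arg(tags)
  up <- panel$gene[panel$ref_direction == 1L]
  down <- panel$gene[panel$ref_direction == -1L]
  if (tags == "deg") {
    if (is.null(deg_genes)) stop("tags = 'deg' requires deg_genes")
    up <- intersect(up, deg_genes)
    down <- intersect(down, deg_genes)
  }
  if (!length(up) || !length(down))
    stop("need >= 1 up-regulated and >= 1 down-regulated tag gene")
  ranked <- rank_panel_genes(drug_lfc, panel)
  ks_up <- ks_enrichment(ranked, up)
  ks_down <- ks_enrichment(ranked, down)
  s <- if (ks_up * ks_down > 0) 0 else ks_up - ks_down
  list(ks_up = ks_up, ks_down = ks_down, s = s)
}

#' Score a compound against the reference signature
#'
#' End-to-end scoring of one treatment arm: DEG statistics treated vs
#' vehicle, gene states for the panel genes, the (optionally weighted)
#' activation Z-score, and the KS drug score.
#'
#' @param treated,vehicle normalized `count_table`s for the two arms.
#' @param panel a [tds_panel].
#' @param annot [probe_annotation] for the count tables.
#' @param weighted use panel weights in the Z-score (default `TRUE`).
#' @param min_abs_lfc exclusion threshold for [gene_states()].
#' @param z_restrict_deg when `TRUE`, only panel genes that are DEGs enter
#'   the Z-score (the restrictive reading; default uses all panel genes
#'   with nonzero fold change).
#' @param ks_tags `"reference"` or `"deg"`, see [ks_drug_score()].
#' @param lfc,p_threshold DEG gates (defaults 0.6, 0.05).
#' @return object of class `drug_score`: list with `z`, `sigma_x`, `n`,
#'   `n_plus`, `n_minus`, `ks_up`, `ks_down`, `s`, `status`, `weighted`,
#'   `states`, `degs` (full DEG report over endogenous genes).
#' @export
score_compound <- function(treated, vehicle, panel, annot,
                           weighted = TRUE, min_abs_lfc = 0,
                           z_restrict_deg = FALSE,
                           ks_tags = c("reference", "deg"),
                           lfc = 0.6, p_threshold = 0.05) {
  ks_tags <- match.arg(ks_tags)
  degs <- identify_degs(treated, vehicle, annot = annot,
                        lfc = lfc, p_threshold = p_threshold)
  drug_lfc <- stats::setNames(degs$log2fc, degs$gene)
  deg_genes <- degs$gene[degs$deg]
  z_panel <- panel
  if (z_restrict_deg) {
    keep <- panel$gene %in% deg_genes
    if (!any(keep)) {
      st <- list(states = data.frame(gene = character(), drug_log2fc = numeric(),
                                     state = integer()),
                 n = 0L, n_plus = 0L, n_minus = 0L)
      zres <- activation_zscore(st)
    } else {
      z_panel <- panel[keep, , drop = FALSE]
      st <- gene_states(drug_lfc, z_panel, min_abs_lfc = min_abs_lfc)
      zres <- activation_zscore(st, weights = if (weighted) z_panel$weight)
    }
  } else {
    st <- gene_states(drug_lfc, panel, min_abs_lfc = min_abs_lfc)
    zres <- activation_zscore(st, weights = if (weighted) panel$weight)
  }
  ks <- ks_drug_score(drug_lfc, panel, tags = ks_tags, deg_genes = deg_genes)
  structure(list(z = zres$z, sigma_x = zres$sigma_x, n = zres$n,
                 n_plus = zres$n_plus, n_minus = zres$n_minus,
                 ks_up = ks$ks_up, ks_down = ks$ks_down, s = ks$s,
                 status = zres$status, weighted = zres$weighted,
                 states = st$states, degs = degs),
            class = "drug_score")
}

#' @export
print.drug_score <- function(x, ...) {
  cat(sprintf("drug_score: z = %s (N+ = %d, N- = %d, N = %d%s)\n",
              if (is.na(x$z)) "no evidence" else sprintf("%.3f", x$z),
              x$n_plus, x$n_minus, x$n,
              if (x$weighted) ", weighted" else ""))
  cat(sprintf("  ks_up = %.3f, ks_down = %.3f, S = %.3f\n",
              x$ks_up, x$ks_down, x$s))
  cat(sprintf("  DEGs: %d of %d genes\n", sum(x$degs$deg), nrow(x$degs)))
  invisible(x)
}

#' Write a drug score to JSON plus a per-gene CSV report
#'
#' @param score a `drug_score`.
#' @param json_path output JSON for the scalar score record.
#' @param report_path optional CSV with per-gene lfc, p and state.
#' @export
write_drug_score <- function(score, json_path, report_path = NULL) {
  rec <- score[c("z", "sigma_x", "n", "n_plus", "n_minus",
                 "ks_up", "ks_down", "s", "status", "weighted")]
  jsonlite::write_json(rec, json_path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  if (!is.null(report_path)) {
    rep <- merge(score$degs, score$states[, c("gene", "state")],
                 by = "gene", all.x = TRUE, sort = FALSE)
    utils::write.csv(rep, report_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
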