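# Containers and file formats for probe-count assays: probe annotations,
# count tables, sample sheets and TDS panel files.

#' Probe classes recognized by the package
#'
#' Every probe on a panel belongs to exactly one class: `tds` (endogenous
#' disease-signature target), `pathway` (endogenous reference-pathway target),
#' `housekeeper` (RNA-content control), `positive_control` (spiked
#' hybridization control with a known concentration in fM) or
#' `negative_control` (background probe with no target).
#'
#' @export
PROBE_CLASSES <- c("tds", "pathway", "housekeeper",
                   "positive_control", "negative_control")

#' Normalization stages of a count table
#' @export
COUNT_STAGES <- c("raw", "pos_normalized", "hk_normalized",
                  "background_subtracted")

#' Construct a probe annotation table
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param gene character vector of gene symbols (defaults to `probe_id`).
#' @param probe_class character vector drawn from [PROBE_CLASSES].
#' @param expected_conc numeric vector of spike-in concentrations (fM).
#'   Must be present (non-`NA`, `>= 0`) for positive-control probes and
#'   absent (`NA`) for every other class.
#' @return A `data.frame` of class `probe_annotation` with columns
#'   `probe_id`, `gene`, `probe_class`, `expected_conc`.
#' @export
probe_annotation <- function(probe_id, gene = probe_id, probe_class,
                             expected_conc = NA_real_) {
  probe_id <- as.character(probe_id)
  gene <- as.character(gene)
  probe_class <- as.character(probe_class)
  expected_conc <- as.numeric(expected_conc)
  n <- length(probe_id)
  if (length(gene) != n || length(probe_class) != n)
    stop("probe_id, gene and probe_class must have equal length")
  expected_conc <- rep_len(expected_conc, n)
  if (anyDuplicated(probe_id))
    stop("integrity error: duplicate probe_id: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  bad <- setdiff(unique(probe_class), PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe_class: ", paste(bad, collapse = ", "))
  is_pos <- probe_class == "positive_control"
  if (any(is_pos & is.na(expected_conc)))
    stop("positive-control probes require expected_conc")
  if (any(!is_pos & !is.na(expected_conc)))
    stop("expected_conc is only meaningful for positive-control probes")
  if (any(is_pos & expected_conc < 0))
    stop("expected_conc must be nonnegative")
  out <- data.frame(probe_id = probe_id, gene = gene,
                    probe_class = probe_class,
                    expected_conc = expected_conc,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_annotation", "data.frame")
  out
}

#' Construct a count table
#'
#' A count table holds one row per probe and one column per sample, plus the
#' normalization stage the counts are at. Raw counts must be nonnegative
#' integers; normalized counts are kept as reals (no re-rounding, which would
#' distort downstream log2 statistics).
#'
#' @param counts numeric matrix, probes x samples, with rownames (probe ids)
#'   and colnames (sample ids).
#' @param stage one of [COUNT_STAGES].
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `stage`.
#' @export
count_table <- function(counts, stage = "raw") {
  stage <- match.arg(stage, COUNT_STAGES)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("integrity error: duplicate probe_id in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("integrity error: duplicate sample_id in count matrix")
  if (anyNA(counts))
    stop("integrity error: missing counts")
  if (any(counts < 0))
    stop("integrity error: negative count")
  if (stage == "raw" && any(counts != round(counts)))
    stop("integrity error: raw counts must be integers")
  structure(list(counts = counts, stage = stage), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d probes x %d samples, stage = %s\n",
              nrow(x$counts), ncol(x$counts), x$stage))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

probe_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

# Row indices of a count table belonging to the given probe classes.
class_rows <- function(table, annot, classes) {
  idx <- match(probe_ids(table), annot$probe_id)
  if (anyNA(idx))
    stop("cross-reference error: probes missing from annotation: ",
         paste(probe_ids(table)[is.na(idx)], collapse = ", "))
  which(annot$probe_class[idx] %in% classes)
}

#' Read a count table from CSV/TSV or a directory of RCC-dialect files
#'
#' CSV/TSV layout follows the platform export convention: probes as rows,
#' samples as columns, first column `probe_id`, header row of sample ids.
#' For `fmt = "rcc_dir"` every file in the directory is parsed as one sample
#' in the sectioned-CSV RCC dialect; the `Code_Summary` section must carry
#' `CodeClass,Name,Accession,Count` columns. CodeClass values are mapped to
#' probe classes (`Endogenous -> tds`, `Housekeeping -> housekeeper`,
#' `Positive -> positive_control`, `Negative -> negative_control`) and the
#' positive-control expected concentration is taken from the trailing
#' parenthetical of the probe name (e.g. `POS_A(128)`); the derived
#' [probe_annotation] is attached as attribute `"annotation"`.
#'
#' @param path file (csv/tsv) or directory (rcc_dir).
#' @param fmt one of `"csv"`, `"tsv"`, `"rcc_dir"`.
#' @return A `count_table` at stage `raw`.
#' @export
read_count_table <- function(path, fmt = c("csv", "tsv", "rcc_dir")) {
  fmt <- match.arg(fmt)
  if (fmt %in% c("csv", "tsv")) {
    if (!file.exists(path)) stop("no such file: ", path)
    sep <- if (fmt == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("format error: need probe_id column plus samples")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("format error: non-numeric counts")
    rownames(m) <- as.character(df[[1]])
    return(count_table(m, stage = "raw"))
  }
  read_rcc_dir(path)
}

RCC_CLASS_MAP <- c(Endogenous = "tds", Housekeeping = "housekeeper",
                   Positive = "positive_control", Negative = "negative_control")

parse_rcc_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  open <- grep("^<Code_Summary>", lines)
  close <- grep("^</Code_Summary>", lines)
  if (length(open) != 1 || length(close) != 1 || close <= open)
    stop("format error: no Code_Summary section in ", file)
  body <- lines[(open + 1):(close - 1)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% names(df)))
    stop("format error: Code_Summary must have columns ",
         paste(need, collapse = ", "), " in ", file)
  df
}

read_rcc_dir <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- list.files(path, pattern = "\\.(rcc|RCC|csv)$", full.names = TRUE)
  if (!length(files)) stop("format error: no RCC files in ", path)
  per_sample <- lapply(files, parse_rcc_file)
  ref <- per_sample[[1]]
  if (anyDuplicated(ref$Name))
    stop("integrity error: duplicate probe_id in ", files[1])
  counts <- vapply(per_sample, function(df) {
    i <- match(ref$Name, df$Name)
    if (anyNA(i)) stop("format error: RCC files disagree on probe set")
    as.numeric(df$Count[i])
  }, numeric(nrow(ref)))
  counts <- matrix(counts, nrow = nrow(ref))   # guard the 1-probe case
  if (any(is.na(counts)) || any(counts < 0))
    stop("integrity error: negative or missing count")
  dimnames(counts) <- list(ref$Name,
                           sub("\\.(rcc|RCC|csv)$", "", basename(files)))
  cls <- RCC_CLASS_MAP[ref$CodeClass]
  if (anyNA(cls))
    stop("format error: unknown CodeClass ",
         paste(unique(ref$CodeClass[is.na(cls)]), collapse = ", "))
  conc <- rep(NA_real_, nrow(ref))
  pos <- which(cls == "positive_control")
  if (length(pos)) {
    got <- regmatches(ref$Name[pos],
                      regexec("\\(([0-9.]+)\\)\\s*$", ref$Name[pos]))
    val <- vapply(got, function(g) if (length(g) == 2) as.numeric(g[2]) else NA_real_,
                  numeric(1))
    if (anyNA(val))
      stop("format error: positive-control name lacks (conc) suffix: ",
           paste(ref$Name[pos][is.na(val)], collapse = ", "))
    conc[pos] <- val
    # keep the bare probe id, concentration moves to the annotation
    bare <- sub("\\([0-9.]+\\)\\s*$", "", ref$Name[pos])
    rownames(counts)[pos] <- bare
    ref$Name[pos] <- bare
  }
  annot <- probe_annotation(probe_id = ref$Name, gene = ref$Name,
                            probe_class = unname(cls), expected_conc = conc)
  out <- count_table(counts, stage = "raw")
  attr(out, "annotation") <- annot
  out
}

#' Write a count table to CSV
#'
#' @param table a `count_table`.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(probe_id = probe_ids(table), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a probe annotation CSV
#' @param path CSV with columns probe_id, gene, probe_class, expected_conc.
#' @return A [probe_annotation].
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "probe_class")
  if (!all(need %in% names(df)))
    stop("format error: annotation needs columns ", paste(need, collapse = ", "))
  if (is.null(df$expected_conc)) df$expected_conc <- NA_real_
  probe_annotation(df$probe_id, df$gene, df$probe_class, df$expected_conc)
}

#' @rdname read_probe_annotation
#' @param annot a [probe_annotation].
#' @export
write_probe_annotation <- function(annot, path) {
  utils::write.csv(annot, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sheet maps samples to genotype (`wt`/`disease`), treatment, dose,
#' batch (cartridge/run) and trial. Unknown genotype or treatment strings are
#' preserved verbatim; only duplicated sample ids are rejected.
#'
#' @param path CSV file with at least a `sample_id` column.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df data.frame with a `sample_id` column; missing metadata columns
#'   (`genotype`, `treatment`, `dose`, `batch`, `trial`) are filled with "".
#' @export
sample_sheet <- function(df) {
  if (is.null(df$sample_id)) stop("format error: sample sheet needs sample_id")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("integrity error: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("genotype", "treatment", "dose", "batch", "trial"))
    if (is.null(df[[col]])) df[[col]] <- ""
    else df[[col]] <- as.character(df[[col]])
  df <- df[, c("sample_id", "genotype", "treatment", "dose", "batch", "trial")]
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a TDS panel
#'
#' The panel is the reference disease signature: one row per signature gene
#' with its reference direction of dysregulation in disease (+1 up, -1 down),
#' the reference log2 fold change (disease vs healthy), the ROC AUCs observed
#' in the two validation tests, and the scoring weight. Weights are either 2
#' (genes with AUC > 0.8 in both tests) or the best oriented AUC, hence in
#' (0.7, 1].
#'
#' @param gene character vector of gene symbols.
#' @param ref_direction integer vector of +1/-1.
#' @param ref_log2fc numeric; must agree in sign with `ref_direction`.
#' @param auc_test1,auc_test2 oriented AUCs in \[0, 1\].
#' @param weight numeric in `{2}` or `(0.7, 1]`.
#' @return A `data.frame` of class `tds_panel`.
#' @export
tds_panel <- function(gene, ref_direction, ref_log2fc,
                      auc_test1, auc_test2, weight) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("integrity error: duplicate panel gene")
  ref_direction <- as.integer(ref_direction)
  if (!all(ref_direction %in% c(-1L, 1L)))
    stop("ref_direction must be +1 or -1")
  if (any(sign(ref_log2fc) != ref_direction))
    stop("invariant error: sign(ref_log2fc) must equal ref_direction")
  for (a in list(auc_test1, auc_test2))
    if (any(a < 0 | a > 1)) stop("AUC outside [0, 1]")
  ok_w <- weight == 2 | (weight > 0.7 & weight <= 1)
  if (!all(ok_w))
    stop("invariant error: weight must be 2 or in (0.7, 1]; offending: ",
         paste(weight[!ok_w], collapse = ", "))
  out <- data.frame(gene = gene, ref_direction = ref_direction,
                    ref_log2fc = as.numeric(ref_log2fc),
                    auc_test1 = as.numeric(auc_test1),
                    auc_test2 = as.numeric(auc_test2),
                    weight = as.numeric(weight),
                    stringsAsFactors = FALSE)
  class(out) <- c("tds_panel", "data.frame")
  out
}

#' Read / write a TDS panel as JSON
#'
#' Round trips are lossless field-by-field. If `annot` is supplied, every
#' panel gene must be present among its `tds`-class probes.
#'
#' @param panel a [tds_panel].
#' @param path JSON file.
#' @param annot optional [probe_annotation] to cross-check against.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(as.data.frame(unclass(panel), stringsAsFactors = FALSE),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path, annot = NULL) {
  df <- jsonlite::fromJSON(path)
  panel <- tds_panel(df$gene, df$ref_direction, df$ref_log2fc,
                     df$auc_test1, df$auc_test2, df$weight)
  if (!is.null(annot)) validate_panel(panel, annot)
  panel
}

#' @rdname write_panel
#' @export
validate_panel <- function(panel, annot) {
  tds_genes <- annot$gene[annot$probe_class == "tds"]
  missing <- setdiff(panel$gene, tds_genes)
  if (length(missing))
    stop("cross-reference error: panel genes absent from tds annotation: ",
         paste(missing, collapse = ", "))
  invisible(panel)
}

# Named vector of counts for the probes mapping to the given genes, one
# sample's column or a probes x samples slice restricted to endogenous genes.
gene_counts <- function(table, annot, genes) {
  idx <- match(probe_ids(table), annot$probe_id)
  gmap <- annot$gene[idx]
  rows <- match(genes, gmap)
  if (anyNA(rows))
    stop("cross-reference error: genes missing from count table: ",
         paste(genes[is.na(rows)], collapse = ", "))
  m <- table$counts[rows, , drop = FALSE]
  rownames(m) <- genes
  m
}
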