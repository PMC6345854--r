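# Small deterministic fixtures shared across test files.

# Annotation with every probe class represented.
tiny_annot <- function() {
  probe_annotation(
    probe_id = c("g1", "g2", "g3", "hk1", "hk2", "POS_A", "POS_B",
                 paste0("neg", 1:8)),
    gene = c("g1", "g2", "g3", "hk1", "hk2", "POS_A", "POS_B",
             paste0("neg", 1:8)),
    probe_class = c("tds", "tds", "pathway", "housekeeper", "housekeeper",
                    "positive_control", "positive_control",
                    rep("negative_control", 8)),
    expected_conc = c(rep(NA, 5), 128, 32, rep(NA, 8)))
}

# Count table matching tiny_annot(), n samples, all counts constant per probe
# unless overridden.
tiny_table <- function(n = 2, base = 100) {
  ann <- tiny_annot()
  m <- matrix(base, nrow = nrow(ann), ncol = n,
              dimnames = list(ann$probe_id, paste0("s", seq_len(n))))
  count_table(m, stage = "raw")
}

# Minimal signature panel: genes u* up-regulated, d* down-regulated.
toy_panel <- function(n_up = 3, n_down = 3, weight = NULL) {
  genes <- c(paste0("u", seq_len(n_up)), paste0("d", seq_len(n_down)))
  dir <- rep(c(1L, -1L), c(n_up, n_down))
  if (is.null(weight)) weight <- rep(1, n_up + n_down)
  tds_panel(gene = genes, ref_direction = dir, ref_log2fc = dir * 1,
            auc_test1 = 0.9, auc_test2 = 0.9, weight = weight)
}

# A normalized cohort + ground-truth panel for scoring tests.
scored_cohort <- function(seed, n_wt = 20, n_disease = 20, ...) {
  cfg <- sim_config(seed = seed, n_wt = n_wt, n_disease = n_disease, ...)
  cohort <- simulate_cohort(cfg)
  norm <- normalize_pipeline(cohort$counts, cohort$annotation)
  list(cfg = cfg, cohort = cohort, norm = norm,
       panel = panel_from_truth(cohort$truth))
}

# Normalize a raw drug arm together with the cohort it belongs to and return
# the treated/vehicle slices (normalization factors must be computed on the
# union of samples in one invocation).
normalized_arms <- function(cohort, arm) {
  combined <- count_table(cbind(cohort$counts$counts, arm$counts$counts),
                          stage = "raw")
  norm <- normalize_pipeline(combined, cohort$annotation)$table
  vehicle_ids <- cohort$sheet$sample_id[cohort$sheet$genotype == "disease"]
  list(treated = count_table(norm$counts[, arm$sheet$sample_id, drop = FALSE],
                             stage = "background_subtracted"),
       vehicle = count_table(norm$counts[, vehicle_ids, drop = FALSE],
                             stage = "background_subtracted"))
}
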