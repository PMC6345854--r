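# End-to-end orchestration: simulate (optional) -> normalize -> build panel
# -> calibrate -> score, with a structured run log.

#' Assemble a run configuration
#'
#' Thresholds default to the pipeline's calibrated operating point: panel
#' gates `lfc_panel = 0.7`, `fdr = 0.05`, `auc = 0.7`; DEG gates
#' `lfc_deg = 0.6`, `p_deg = 0.05`; significance thresholds `z = 2`,
#' `s = 0.27`.
#'
#' @param counts,annotation,sheet,panel input file paths (all optional when
#'   `simulate = TRUE`, which generates them).
#' @param out_dir output directory.
#' @param seed integer seed, required (used for simulation and null lists).
#' @param simulate generate a synthetic cohort instead of reading inputs.
#' @param sim list of [sim_config()] overrides for simulation.
#' @param n_null number of randomized null lists for calibration.
#' @param weighted,ks_tags,z_restrict_deg scoring options.
#' @param drug_reversal rho of the simulated compound arm.
#' @param thresholds named list overriding any of `lfc_panel`, `fdr`, `auc`,
#'   `lfc_deg`, `p_deg`, `z`, `s`.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts = NULL, annotation = NULL, sheet = NULL,
                       panel = NULL, out_dir = "tds_run", seed,
                       simulate = is.null(counts), sim = list(),
                       n_null = 400, weighted = TRUE,
                       ks_tags = "reference", z_restrict_deg = FALSE,
                       drug_reversal = 1, thresholds = list()) {
  if (missing(seed) || is.null(seed)) stop("config field missing: seed")
  thr <- list(lfc_panel = 0.7, fdr = 0.05, auc = 0.7,
              lfc_deg = 0.6, p_deg = 0.05, z = 2, s = 0.27)
  thr[names(thresholds)] <- thresholds
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive")
  cfg <- list(counts = counts, annotation = annotation, sheet = sheet,
              panel = panel, out_dir = out_dir, seed = as.integer(seed),
              simulate = simulate, sim = sim, n_null = n_null,
              weighted = weighted, ks_tags = ks_tags,
              z_restrict_deg = z_restrict_deg,
              drug_reversal = drug_reversal, thresholds = thr)
  if (!simulate) {
    for (field in c("counts", "annotation", "sheet"))
      if (is.null(cfg[[field]]))
        stop("config field missing: ", field)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# dot-prefixed arguments so fields passed via ... (e.g. "s") can never
# partially match them
stage_log <- function(.log, .stage, ...) {
  entry <- c(list(stage = .stage), list(...))
  .log[[length(.log) + 1]] <- entry
  message(sprintf("[%s] %s", .stage,
                  paste(names(entry)[-1], unlist(entry[-1]),
                        sep = " = ", collapse = ", ")))
  .log
}

#' Run the full screening pipeline
#'
#' Executes the three phases end to end: cohort acquisition (simulation or
#' file input), normalization, signature construction, threshold
#' calibration, and compound scoring (for simulated runs, a drug arm with
#' the configured reversal coefficient). Every artifact lands in
#' `config$out_dir` together with `run_log.json` recording the seed, the
#' config hash and per-gate gene counts.
#'
#' @param config a [run_config()] (or a YAML path readable by
#'   [read_run_config()]).
#' @return Invisibly, a list with the main in-memory results
#'   (`panel`, `calibration`, `score`, `log`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  thr <- config$thresholds
  log <- list()

  if (config$simulate) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(cfg)
    # two validation cohorts for panel building, as in a two-test design
    cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
    cfg2$n_wt <- max(2L, ceiling(cfg$n_wt * 3 / 4))
    cfg2$n_disease <- max(2L, ceiling(cfg$n_disease * 3 / 4))
    cohort2 <- simulate_cohort(cfg2, truth = cohort$truth)
    write_cohort(cohort, file.path(out, "cohort"))
    annot <- cohort$annotation
    raw <- cohort$counts
    sheet <- cohort$sheet
    log <- stage_log(log, "simulate", n_samples = ncol(raw$counts),
                     seed = config$seed)
  } else {
    raw <- read_count_table(config$counts,
                            fmt = if (dir.exists(config$counts)) "rcc_dir"
                                  else "csv")
    annot <- read_probe_annotation(config$annotation)
    sheet <- read_sample_sheet(config$sheet)
    log <- stage_log(log, "load", n_samples = ncol(raw$counts))
  }

  norm <- normalize_pipeline(raw, annot,
                             report_path = file.path(out, "factors.csv"))
  write_count_table(norm$table, file.path(out, "normalized.csv"))
  log <- stage_log(log, "normalize", n_probes = nrow(norm$table$counts))

  if (!is.null(config$panel)) {
    panel <- read_panel(config$panel, annot = annot)
    log <- stage_log(log, "panel", source = "file", n_genes = nrow(panel))
  } else if (config$simulate) {
    norm2 <- normalize_pipeline(cohort2$counts, annot)
    built <- build_panel(norm$table, sheet, norm2$table, cohort2$sheet, annot,
                         lfc = thr$lfc_panel, fdr = thr$fdr, auc = thr$auc)
    panel <- built$panel
    log <- stage_log(log, "panel", source = "built",
                     n_candidates = length(built$candidates),
                     n_validated = nrow(built$validated),
                     n_weight2 = sum(panel$weight == 2))
  } else stop("config field missing: panel (required for non-simulated runs)")
  write_panel(panel, file.path(out, "panel.json"))

  calib <- calibrate(norm$table, annot, sheet, panel,
                     n_null = config$n_null, seed = config$seed + 1000L,
                     weighted = config$weighted,
                     z_threshold = thr$z, s_threshold = thr$s)
  write_calibration(calib, file.path(out, "calibration.json"),
                    scores_path = file.path(out, "calibration_scores.csv"))
  log <- stage_log(log, "calibrate", n_pairs = calib$n_disease_pairs,
                   n_null = calib$n_null,
                   fp_rate_z = calib$fp_rate_z, fn_rate_z = calib$fn_rate_z)

  score <- NULL
  if (config$simulate) {
    arm <- simulate_drug_arm(cohort, cfg, rho = config$drug_reversal,
                             n_treated = min(5L, cfg$n_disease),
                             seed = config$seed + 2000L)
    vehicle_ids <- sheet$sample_id[sheet$genotype == "disease"]
    all_counts <- count_table(cbind(raw$counts, arm$counts$counts),
                              stage = "raw")
    all_norm <- normalize_pipeline(all_counts, annot)$table
    treated <- count_table(
      all_norm$counts[, arm$sheet$sample_id, drop = FALSE],
      stage = "background_subtracted")
    vehicle <- count_table(all_norm$counts[, vehicle_ids, drop = FALSE],
                           stage = "background_subtracted")
    score <- score_compound(treated, vehicle, panel, annot,
                            weighted = config$weighted,
                            z_restrict_deg = config$z_restrict_deg,
                            ks_tags = config$ks_tags,
                            lfc = thr$lfc_deg, p_threshold = thr$p_deg)
    write_drug_score(score, file.path(out, "score.json"),
                     report_path = file.path(out, "deg_report.csv"))
    log <- stage_log(log, "score", z = score$z, s = score$s,
                     n_deg = sum(score$degs$deg))
  }

  cfg_file <- file.path(out, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "sim")], cfg_file,
                       digits = NA, auto_unbox = TRUE, force = TRUE,
                       null = "null")
  run_log <- list(seed = config$seed,
                  config_md5 = unname(tools::md5sum(cfg_file)),
                  stages = log)
  jsonlite::write_json(run_log, file.path(out, "run_log.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(panel = panel, calibration = calib, score = score,
                 log = run_log))
}
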