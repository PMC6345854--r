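# Synthetic probe-count cohorts with known ground truth. The generator
# emulates the structure of a custom nCounter-style assay: per-sample
# hybridization (lane) and RNA-input factors, additive background,
# housekeepers with no group effect, signature genes with signed effects of
# incomplete penetrance, and drug arms that reverse or amplify the disease
# effect to a chosen degree.

#' Simulation configuration
#'
#' Defaults mirror the screening panel this package targets: 97 signature
#' probes, 108 pathway probes, 29 housekeepers, 6 positive and 8 negative
#' controls; cohorts of 20 wild-type and 20 diseased individuals; log2
#' baselines ~ Normal(8, 2); disease effects of 0.7-2.5 log2 units with
#' per-gene penetrance 0.6-1 (so per-gene AUC varies, motivating AUC
#' weighting); negative-binomial counts with dispersion 0.05; lane factors
#' with 0.1 log-sd and RNA-input factors with 0.2 log-sd; mean additive
#' background of 10 counts.
#'
#' @param n_tds,n_pathway,n_housekeeper,n_pos,n_neg panel composition.
#' @param n_wt,n_disease cohort sizes.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale expression baseline.
#' @param effect_log2_range range of absolute disease effects (log2 units).
#' @param penetrance_range range of per-gene penetrance probabilities.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param background_mean mean additive background counts per probe.
#' @param lane_sd,input_sd log-scale sd of hybridization / RNA-input factors.
#' @param pos_gain counts per fM for the positive-control ladder.
#' @param off_target_fraction fraction of pathway genes a drug perturbs.
#' @param drug_reversal default reversal coefficient rho in \[-1, 1\].
#' @param seed integer RNG seed (mandatory at simulation time).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tds = 97, n_pathway = 108, n_housekeeper = 29,
                       n_pos = 6, n_neg = 8, n_wt = 20, n_disease = 20,
                       baseline_log2_mean = 8, baseline_log2_sd = 2,
                       effect_log2_range = c(0.7, 2.5),
                       penetrance_range = c(0.6, 1),
                       nb_dispersion = 0.05, background_mean = 10,
                       lane_sd = 0.1, input_sd = 0.2, pos_gain = 200,
                       off_target_fraction = 0, drug_reversal = 1,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (cfg$n_tds < 2 || cfg$n_housekeeper < 1 || cfg$n_pos < 1 || cfg$n_neg < 2)
    stop("invalid panel composition")
  if (diff(effect_log2_range) < 0 || effect_log2_range[1] < 0)
    stop("invalid effect_log2_range")
  if (any(penetrance_range < 0 | penetrance_range > 1))
    stop("penetrance_range must lie in [0, 1]")
  if (abs(drug_reversal) > 1) stop("drug_reversal must lie in [-1, 1]")
  if (nb_dispersion < 0 || background_mean < 0 ||
      lane_sd < 0 || input_sd < 0 || pos_gain <= 0)
    stop("invalid noise parameters")
  class(cfg) <- "sim_config"
  cfg
}

# 4-fold geometric concentration ladder, platform convention (128 ... fM).
pos_control_ladder <- function(n_pos) 128 / 4^(seq_len(n_pos) - 1)

sim_annotation <- function(cfg) {
  pad <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  probe_annotation(
    probe_id = c(pad("TDS", cfg$n_tds), pad("PATH", cfg$n_pathway),
                 pad("HK", cfg$n_housekeeper),
                 paste0("POS_", LETTERS[seq_len(cfg$n_pos)]),
                 pad("NEG", cfg$n_neg)),
    probe_class = rep(c("tds", "pathway", "housekeeper",
                        "positive_control", "negative_control"),
                      c(cfg$n_tds, cfg$n_pathway, cfg$n_housekeeper,
                        cfg$n_pos, cfg$n_neg)),
    expected_conc = c(rep(NA_real_, cfg$n_tds + cfg$n_pathway + cfg$n_housekeeper),
                      pos_control_ladder(cfg$n_pos),
                      rep(NA_real_, cfg$n_neg)))
}

nb_draw <- function(mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  else stats::rpois(length(mu), mu)
}

# Draw count columns for a set of samples given per-gene log2 expected
# endogenous expression (genes x samples matrix on log2 scale, effects
# already applied).
draw_counts <- function(cfg, annot, log2_expr, h, r, b) {
  n_s <- length(h)
  counts <- matrix(0, nrow = nrow(annot), ncol = n_s,
                   dimnames = list(annot$probe_id, names(h)))
  endo <- annot$probe_class %in% c("tds", "pathway", "housekeeper")
  pos <- annot$probe_class == "positive_control"
  neg <- annot$probe_class == "negative_control"
  for (s in seq_len(n_s)) {
    mu_endo <- h[s] * r[s] * 2^log2_expr[, s] + b[s]
    counts[endo, s] <- nb_draw(mu_endo, cfg$nb_dispersion)
    # positive controls measure hybridization only: independent of RNA input
    counts[pos, s] <- stats::rpois(sum(pos),
                                   h[s] * cfg$pos_gain * annot$expected_conc[pos])
    counts[neg, s] <- stats::rpois(sum(neg), h[s] * b[s])
  }
  counts
}

#' Simulate a case/control cohort with known ground truth
#'
#' Per gene `g`: log2 baseline `beta_g ~ Normal(baseline_log2_mean, sd)`.
#' Signature genes carry absolute effects `delta_g ~ Uniform(effect range)`
#' with directions drawn as a shuffled balanced +/-1 vector (a signature has
#' both up- and down-regulated members), and penetrance
#' `p_g ~ Uniform(penetrance range)`: each diseased individual expresses the
#' effect of gene `g` with probability `p_g`, which makes per-gene AUC vary.
#' Housekeepers and pathway genes carry no group effect. Expected endogenous
#' counts are `h_s * r_s * 2^(beta + effect) + b_s` with negative-binomial
#' noise; positive controls are Poisson around `h_s * gain * conc`
#' (independent of the RNA-input factor `r_s`); negative controls are
#' Poisson around `h_s * b_s`.
#'
#' @param cfg a [sim_config]; `cfg$seed` must be set.
#' @param truth optional `truth` element of a previous [simulate_cohort()]
#'   call: reuses its gene-level ground truth (baselines, directions,
#'   effects, penetrance) and only draws new individuals — the way a second
#'   validation cohort of the same disease is obtained.
#' @param sample_prefix prefixes for wt/disease sample ids.
#' @return list with `counts` (`count_table`, stage raw), `annotation`,
#'   `sheet`, and `truth` (list with `baseline` — named per-probe log2
#'   baselines — a per-gene `genes` data.frame — `gene`, `direction`,
#'   `delta`, `penetrance` — and a per-sample `samples` data.frame —
#'   `sample_id`, `lane_factor`, `input_factor`, `background`).
#' @export
simulate_cohort <- function(cfg, truth = NULL,
                            sample_prefix = c("wt", "dis")) {
  if (is.null(cfg$seed)) stop("explicit seed required (set cfg$seed)")
  set.seed(as.integer(cfg$seed))
  annot <- sim_annotation(cfg)
  n_s <- cfg$n_wt + cfg$n_disease
  sample_id <- c(sprintf("%s_%02d", sample_prefix[1], seq_len(cfg$n_wt)),
                 sprintf("%s_%02d", sample_prefix[2], seq_len(cfg$n_disease)))
  genotype <- rep(c("wt", "disease"), c(cfg$n_wt, cfg$n_disease))
  h <- stats::setNames(exp(stats::rnorm(n_s, 0, cfg$lane_sd)), sample_id)
  r <- exp(stats::rnorm(n_s, 0, cfg$input_sd))
  b <- cfg$background_mean * exp(stats::rnorm(n_s, 0, 0.1))

  endo <- annot$probe_class %in% c("tds", "pathway", "housekeeper")
  n_endo <- sum(endo)
  is_tds <- annot$probe_class[endo] == "tds"
  if (is.null(truth)) {
    beta <- stats::rnorm(n_endo, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    direction <- integer(n_endo)
    # balanced up/down composition: a signature carries both directions
    direction[is_tds] <- sample(rep(c(1L, -1L), length.out = cfg$n_tds))
    delta <- numeric(n_endo)
    delta[is_tds] <- stats::runif(cfg$n_tds, cfg$effect_log2_range[1],
                                  cfg$effect_log2_range[2])
    penetrance <- numeric(n_endo)
    penetrance[is_tds] <- stats::runif(cfg$n_tds, cfg$penetrance_range[1],
                                       cfg$penetrance_range[2])
  } else {
    beta <- unname(truth$baseline[annot$probe_id[endo]])
    if (anyNA(beta)) stop("supplied truth does not cover this panel")
    direction <- integer(n_endo); delta <- numeric(n_endo)
    penetrance <- numeric(n_endo)
    ti <- match(truth$genes$gene, annot$gene[endo])
    direction[ti] <- truth$genes$direction
    delta[ti] <- truth$genes$delta
    penetrance[ti] <- truth$genes$penetrance
  }

  log2_expr <- matrix(beta, nrow = n_endo, ncol = n_s)
  dis_cols <- which(genotype == "disease")
  for (s in dis_cols) {
    expressed <- stats::rbinom(n_endo, 1, penetrance)
    log2_expr[, s] <- beta + expressed * direction * delta
  }
  counts <- draw_counts(cfg, annot, log2_expr, h, r, b)

  truth <- list(
    baseline = stats::setNames(beta, annot$probe_id[endo]),
    genes = data.frame(gene = annot$gene[endo][is_tds],
                       direction = direction[is_tds],
                       delta = delta[is_tds],
                       penetrance = penetrance[is_tds],
                       stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sample_id, lane_factor = unname(h),
                         input_factor = r, background = b,
                         stringsAsFactors = FALSE))
  list(counts = count_table(counts, stage = "raw"),
       annotation = annot,
       sheet = sample_sheet(data.frame(sample_id = sample_id,
                                       genotype = genotype,
                                       treatment = "vehicle",
                                       stringsAsFactors = FALSE)),
       truth = truth)
}

#' Simulate a drug-treated arm of diseased individuals
#'
#' Generates new diseased individuals whose signature-gene effects are
#' shifted by `-rho * delta_g`: `rho = 1` removes the disease effect
#' entirely (the full-reversal "model compound"), `rho = 0` is inert, and
#' `rho = -1` doubles the disease-ward shift (disease-mimicking). A random
#' `off_target_fraction` of pathway genes is additionally shifted by
#' `sign * Uniform(0.6, 1.5)` log2 units.
#'
#' @param cohort result of [simulate_cohort()] (supplies panel structure and
#'   ground truth).
#' @param cfg the [sim_config] used for the cohort.
#' @param rho reversal coefficient in \[-1, 1\]
#'   (default `cfg$drug_reversal`).
#' @param n_treated number of treated individuals (default: the cohort's
#'   number of diseased individuals).
#' @param off_target_fraction default `cfg$off_target_fraction`.
#' @param seed integer RNG seed (mandatory).
#' @param treatment label written into the returned sheet.
#' @return list with `counts` (`count_table`, raw), `sheet`, and
#'   `off_target` (data.frame of perturbed pathway genes and shifts).
#' @export
simulate_drug_arm <- function(cohort, cfg, rho = cfg$drug_reversal,
                              n_treated = NULL, off_target_fraction =
                                cfg$off_target_fraction,
                              seed, treatment = "compound") {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (missing(seed) || is.null(seed)) stop("explicit seed required")
  set.seed(as.integer(seed))
  annot <- cohort$annotation
  if (is.null(n_treated)) n_treated <- sum(cohort$sheet$genotype == "disease")
  sample_id <- sprintf("trt_%02d", seq_len(n_treated))
  h <- stats::setNames(exp(stats::rnorm(n_treated, 0, cfg$lane_sd)), sample_id)
  r <- exp(stats::rnorm(n_treated, 0, cfg$input_sd))
  b <- cfg$background_mean * exp(stats::rnorm(n_treated, 0, 0.1))

  endo <- annot$probe_class %in% c("tds", "pathway", "housekeeper")
  endo_ids <- annot$probe_id[endo]
  is_tds <- annot$probe_class[endo] == "tds"
  is_path <- annot$probe_class[endo] == "pathway"
  beta <- unname(cohort$truth$baseline[endo_ids])
  if (anyNA(beta)) stop("cohort truth lacks baselines for some probes")
  g <- cohort$truth$genes
  direction <- integer(length(endo_ids)); delta <- numeric(length(endo_ids))
  penetrance <- numeric(length(endo_ids))
  ti <- match(g$gene, endo_ids)
  direction[ti] <- g$direction; delta[ti] <- g$delta
  penetrance[ti] <- g$penetrance

  n_off <- floor(off_target_fraction * sum(is_path))
  off_idx <- if (n_off > 0) sample(which(is_path), n_off) else integer(0)
  off_shift <- sample(c(-1, 1), n_off, replace = TRUE) *
    stats::runif(n_off, 0.6, 1.5)

  log2_expr <- matrix(beta, nrow = length(endo_ids), ncol = n_treated)
  for (s in seq_len(n_treated)) {
    expressed <- stats::rbinom(length(endo_ids), 1, penetrance)
    eff <- expressed * direction * delta - rho * direction * delta
    eff[off_idx] <- eff[off_idx] + off_shift
    log2_expr[, s] <- beta + eff
  }
  counts <- draw_counts(cfg, annot, log2_expr, h, r, b)
  list(counts = count_table(counts, stage = "raw"),
       sheet = sample_sheet(data.frame(sample_id = sample_id,
                                       genotype = "disease",
                                       treatment = treatment,
                                       stringsAsFactors = FALSE)),
       off_target = data.frame(gene = annot$gene[endo][off_idx],
                               shift = off_shift, stringsAsFactors = FALSE))
}

#' Reference panel from simulation ground truth
#'
#' Builds the ideal signature a perfect experiment would recover: reference
#' direction and log2FC from the true per-gene effects, AUC surrogates and
#' weights from penetrance (fully penetrant genes approach AUC 1). Useful
#' for calibration and scoring studies that should not be confounded by
#' panel-building noise.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @return A [tds_panel] over all simulated signature genes.
#' @export
panel_from_truth <- function(truth) {
  g <- truth$genes
  # penetrance p separates groups with probability ~ p + (1-p)/2 per pair
  auc <- pmin(0.5 + g$penetrance / 2, 1)
  w <- ifelse(auc > 0.8, 2, pmax(auc, 0.701))
  tds_panel(gene = g$gene, ref_direction = g$direction,
            ref_log2fc = g$direction * g$delta,
            auc_test1 = auc, auc_test2 = auc, weight = w)
}

#' Write a simulated cohort to plain-text files
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed); writes `counts.csv`,
#'   `annotation.csv`, `samples.csv`, `ground_truth.json`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.csv"))
  write_probe_annotation(cohort$annotation, file.path(dir, "annotation.csv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
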