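# Compound scoring: DEG gates, gene states, activation Z, KS drug score.

test_that("DEG gates require both fold change and significance", {
  set.seed(3)
  base <- matrix(rpois(40, 100), nrow = 4,
                 dimnames = list(c("up", "border", "quiet", "flat"),
                                 paste0("v", 1:10)))
  trt <- base
  trt["up", ] <- rpois(10, 100 * 2^0.9)
  trt["border", ] <- round(base["border", ] * 2^0.59)  # lfc just under 0.6
  colnames(trt) <- paste0("t", 1:10)
  degs <- identify_degs(trt, base)
  expect_true(degs$deg[degs$gene == "up"])
  expect_false(degs$deg[degs$gene == "border"])
  expect_false(degs$deg[degs$gene == "flat"])
  # treated == control: no DEGs at all
  none <- identify_degs(base, base)
  expect_equal(sum(none$deg), 0)
  expect_error(identify_degs(base[, 1, drop = FALSE], base), "n >= 2")
})

test_that("gene states encode consistency with the reference direction", {
  panel <- toy_panel(n_up = 2, n_down = 2)
  lfc <- c(u1 = 0.5, u2 = -0.3, d1 = -0.2, d2 = 0)
  st <- gene_states(lfc, panel)
  states <- setNames(st$states$state, st$states$gene)
  expect_equal(states[["u1"]], 1L)    # sign matches ref: disease-ward
  expect_equal(states[["u2"]], -1L)   # sign mismatch
  expect_equal(states[["d1"]], 1L)    # down gene moving down is consistent
  expect_true(is.na(states[["d2"]])) # exact zero excluded
  expect_equal(st$n, 3L)
  expect_equal(st$n_plus, 2L)
  expect_equal(st$n_minus, 1L)
  expect_error(gene_states(lfc[1:3], panel), "missing")
  # min_abs_lfc widens the exclusion
  st2 <- gene_states(lfc, panel, min_abs_lfc = 0.4)
  expect_equal(st2$n, 1L)
})

test_that("activation Z-score follows (N+ - N-)/sqrt(N) and its bounds", {
  mk_states <- function(x) {
    n <- length(x); inc <- !is.na(x)
    list(states = data.frame(gene = paste0("g", seq_len(n)),
                             drug_log2fc = ifelse(is.na(x), 0, x),
                             state = x),
         n = sum(inc), n_plus = sum(x == 1, na.rm = TRUE),
         n_minus = sum(x == -1, na.rm = TRUE))
  }
  expect_equal(activation_zscore(mk_states(rep(1L, 6)))$z, 6 / sqrt(6))
  expect_equal(activation_zscore(mk_states(c(1L, 1L, -1L, -1L)))$z, 0)
  expect_equal(activation_zscore(mk_states(rep(-1L, 97)))$z, -sqrt(97))
  # weighted: w = (2, 1), x = (+1, -1) -> 1/sqrt(5)
  wz <- activation_zscore(mk_states(c(1L, -1L)), weights = c(2, 1))
  expect_equal(wz$z, 1 / sqrt(5))
  # no included genes: explicit no-evidence, not zero
  ne <- activation_zscore(mk_states(c(NA_integer_, NA_integer_)))
  expect_true(is.na(ne$z))
  expect_equal(ne$status, "no-evidence")
  # bounds: |z| <= sqrt(N); weighted |z| <= sum(w)/sqrt(sum(w^2))
  set.seed(9)
  for (i in 1:20) {
    n <- sample(1:97, 1)
    x <- sample(c(-1L, 1L), n, replace = TRUE)
    w <- runif(n, 0.7, 2)
    expect_lte(abs(activation_zscore(mk_states(x))$z), sqrt(n) + 1e-12)
    expect_lte(abs(activation_zscore(mk_states(x), weights = w)$z),
               sum(w) / sqrt(sum(w^2)) + 1e-12)
  }
})

test_that("equiprobable gene states give near-nominal |z| >= 2 rates", {
  set.seed(14)
  n_rep <- 4000
  z <- replicate(n_rep, {
    x <- sample(c(-1, 1), 97, replace = TRUE)
    sum(x) / sqrt(97)
  })
  p_exact <- exact_z_tail(97, 2)
  se <- sqrt(p_exact * (1 - p_exact) / n_rep)
  expect_lt(abs(mean(abs(z) >= 2) - p_exact), 3 * se)
  expect_lt(abs(mean(z)), 3 / sqrt(n_rep))
})

test_that("ks_enrichment evaluates the two one-sided maxima", {
  ranked <- paste0("g", 1:10)
  expect_equal(ks_enrichment(ranked, c("g1", "g2")), 0.8)
  expect_equal(ks_enrichment(ranked, c("g9", "g10")), -0.9)
  # tags = all n genes: closed form -1/n
  expect_equal(ks_enrichment(ranked, ranked), -0.1)
  expect_error(ks_enrichment(ranked, character(0)), "empty")
  expect_error(ks_enrichment(ranked, "absent"), "subset")
})

test_that("ks_enrichment matches the cumulative-walk oracle exhaustively", {
  for (n in 1:7) {
    ranked <- paste0("g", seq_len(n))
    for (mask in 1:(2^n - 1)) {
      tags <- ranked[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      expect_equal(ks_enrichment(ranked, tags), walk_ks(ranked, tags),
                   info = sprintf("n=%d mask=%d", n, mask))
    }
  }
})

test_that("reversing the ranking exchanges the one-sided deviations", {
  # Under reversal position v maps to n + 1 - v and tag rank j to t + 1 - j,
  # so the top-deviation of the reversed list equals the bottom-deviation of
  # the original shifted by one rank step (and vice versa):
  #   a_rev = b - 1/n,  b_rev = a + 1/n.
  # Whenever the dominant side survives the exchange, the score is therefore
  # antisymmetric up to the discretization term 1/n.
  ab <- function(ranked, tags) {
    V <- sort(match(tags, ranked)); n <- length(ranked); t <- length(tags)
    j <- seq_len(t)
    c(a = max(j / t - V / n), b = max(V / n - (j - 1) / t))
  }
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    ranked <- paste0("g", sample(n))
    t <- sample(seq_len(n - 1), 1)
    tags <- sample(ranked, t)
    fwd <- ab(ranked, tags); bwd <- ab(rev(ranked), tags)
    expect_equal(unname(bwd["a"]), unname(fwd["b"]) - 1 / n)
    expect_equal(unname(bwd["b"]), unname(fwd["a"]) + 1 / n)
    ks_f <- ks_enrichment(ranked, tags)
    ks_r <- ks_enrichment(rev(ranked), tags)
    expect_lte(abs(ks_f), 1)
    expect_lte(abs(ks_r), 1)
    if (fwd["a"] > fwd["b"] && bwd["b"] > bwd["a"])
      expect_equal(ks_f + ks_r, -1 / n)
  }
})

test_that("the KS drug score combines up and down tags with the sign rule", {
  panel <- toy_panel(n_up = 3, n_down = 3)
  # compound pushes up-tags to the top, down-tags to the bottom: activator
  act <- c(u1 = 3, u2 = 2.5, u3 = 2, d1 = -1, d2 = -2, d3 = -3)
  res <- ks_drug_score(act, panel)
  expect_gt(res$ks_up, 0)
  expect_lt(res$ks_down, 0)
  expect_equal(res$s, res$ks_up - res$ks_down)
  # full reversal: repressor with the mirrored score
  rev <- ks_drug_score(-act, panel)
  expect_lt(rev$s, 0)
  # both tag sets pushed the same way: no coherent signal, S = 0
  same <- c(u1 = 3, u2 = 2.5, d1 = 2, d2 = 1.8, u3 = -2, d3 = -3)
  mixed <- ks_drug_score(same, panel)
  if (mixed$ks_up * mixed$ks_down > 0) expect_equal(mixed$s, 0)
  # one empty tag class is an error
  all_up <- tds_panel(c("a", "b"), c(1, 1), c(1, 1), 0.9, 0.9, c(1, 1))
  expect_error(ks_drug_score(c(a = 1, b = 2), all_up), "down-regulated")
})

test_that("score_compound composes DEGs, states, Z and KS", {
  sc <- scored_cohort(seed = 41, n_wt = 8, n_disease = 8)
  # vehicle-vs-vehicle split: null self-comparison stays non-significant
  dis <- sc$cohort$sheet$sample_id[sc$cohort$sheet$genotype == "disease"]
  half1 <- count_table(sc$norm$table$counts[, dis[1:4]],
                       stage = "background_subtracted")
  half2 <- count_table(sc$norm$table$counts[, dis[5:8]],
                       stage = "background_subtracted")
  null_score <- score_compound(half1, half2, sc$panel, sc$cohort$annotation)
  expect_lt(abs(null_score$z), 2)
  expect_s3_class(null_score, "drug_score")

  # full reversal scores as a strong repressor
  arm <- simulate_drug_arm(sc$cohort, sc$cfg, rho = 1, n_treated = 5, seed = 42)
  arms <- normalized_arms(sc$cohort, arm)
  rev_score <- score_compound(arms$treated, arms$vehicle, sc$panel,
                              sc$cohort$annotation)
  expect_lte(rev_score$z, -2)
  expect_lte(rev_score$s, -0.27)

  # disease-mimicking compound scores as an activator
  arm2 <- simulate_drug_arm(sc$cohort, sc$cfg, rho = -1, n_treated = 5, seed = 43)
  arms2 <- normalized_arms(sc$cohort, arm2)
  mim_score <- score_compound(arms2$treated, arms2$vehicle, sc$panel,
                              sc$cohort$annotation)
  expect_gte(mim_score$z, 2)

  # restrictive readings still produce coherent output
  restr <- score_compound(arms$treated, arms$vehicle, sc$panel,
                          sc$cohort$annotation, z_restrict_deg = TRUE,
                          ks_tags = "deg")
  if (restr$status == "ok") expect_lte(restr$z, 0)

  # score serialization round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_drug_score(rev_score, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$z, rev_score$z)
  expect_equal(back$s, rev_score$s)
})
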