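test_that("Welch test reproduces the textbook formulas", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  got <- welch_test(x, y)
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  expect_equal(got$t, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df_hand))

  ident <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  # scale invariance of t
  expect_equal(welch_test(3.7 * x, 3.7 * y)$t, got$t)

  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(c(2, 2), c(5, 5)), "nonzero variance")
})

test_that("random-subset NES draws are seeded and well defined", {
  m <- toy_expr(n_targets = 30, n_bg = 120, effect = 0.5, seed = 6)
  pt <- gene_set("PT", sprintf("T%03d", 1:30))
  cfg <- gsea_config(n_perm = 50)
  trip <- random_subset_nes(pt, 10, m, B = 3, config = cfg, seed = 11,
                            timepoint = 72)
  expect_length(trip, 3)
  expect_equal(random_subset_nes(pt, 10, m, B = 3, config = cfg, seed = 11,
                                 timepoint = 72), trip)
  expect_false(isTRUE(all.equal(
    random_subset_nes(pt, 10, m, B = 3, config = cfg, seed = 12,
                      timepoint = 72), trip)))

  expect_error(random_subset_nes(pt, 31, m, B = 2, config = cfg, seed = 1),
               "exceeds")

  # k = |pt|: every draw is the full set, variance only from permutations
  full <- random_subset_nes(pt, 30, m, B = 8, config = cfg, seed = 13,
                            timepoint = 72)
  es_full <- enrichment_score(rank_genes(m, timepoint = 72), pt, 1)$ES
  ref <- vapply(full, function(z) z, numeric(1))
  expect_true(all(is.finite(ref)))
  expect_lt(sd(full) / abs(mean(full)), 0.15)
  expect_equal(sign(mean(full)), sign(es_full))
})

test_that("resampling outcome is bit-identical under one top-level seed", {
  m <- toy_expr(n_targets = 30, n_bg = 120, effect = 1,
                ratios = runif(30, 0, 1.1), seed = 14)
  pt <- gene_set("PT", sprintf("T%03d", 1:30))
  pt50 <- gene_set("PT_50", sprintf("T%03d", 1:12))
  cfg <- gsea_config(n_perm = 50)
  a <- pt50_significance(pt, pt50, m, B = 40, R = 5, config = cfg,
                         seed = 21, timepoint = 72)
  b <- pt50_significance(pt, pt50, m, B = 40, R = 5, config = cfg,
                         seed = 21, timepoint = 72)
  expect_identical(a$observed_nes, b$observed_nes)
  expect_identical(a$null_nes, b$null_nes)
  expect_identical(a$welch_t, b$welch_t)
  expect_identical(a$empirical_percentile, b$empirical_percentile)

  expect_error(pt50_significance(pt, gene_set("x", "NOPE"), m, B = 40,
                                 R = 5, config = cfg, seed = 1),
               "subset of pt")
})

test_that("percentile and Welch t always agree in direction", {
  cfg <- gsea_config(n_perm = 50)
  for (i in 1:6) {
    set.seed(40 + i)
    m <- toy_expr(n_targets = 30, n_bg = 120, effect = (i %% 3) / 2,
                  ratios = runif(30, 0, 1.1), seed = 40 + i)
    pt <- gene_set("PT", sprintf("T%03d", 1:30))
    pres <- data.frame(gene_id = pt$members,
                       max_ratio = runif(30, 0, 1.1), expressed = TRUE)
    pres$bin <- ifelse(pres$max_ratio > 0.9, "high",
                       ifelse(pres$max_ratio >= 0.5, "mid", "low"))
    pt50 <- build_pt50(pres)
    out <- pt50_significance(pt, pt50, m, B = 60, R = 5, config = cfg,
                             seed = 50 + i, timepoint = 72)
    if (out$welch_t > 0) expect_gte(out$empirical_percentile, 0.5)
    if (out$welch_t < 0) expect_lte(out$empirical_percentile, 0.5)
  }
})

test_that("a no-signal-difference subset sits inside the null NES range", {
  m <- toy_expr(n_targets = 30, n_bg = 120, effect = 1, seed = 60)
  pt <- gene_set("PT", sprintf("T%03d", 1:30))
  cfg <- gsea_config(n_perm = 50)
  out <- pt50_significance(pt, pt, m, B = 60, R = 5, config = cfg,
                           seed = 61, timepoint = 72)   # pt50 = pt
  deciles <- quantile(out$null_nes, c(0.1, 0.9))
  expect_gte(mean(out$observed_nes), deciles[[1]])
  expect_lte(mean(out$observed_nes), deciles[[2]])
})

test_that("planted presence-proportional enrichment favors the PT50 subset", {
  cfg <- gsea_config(n_perm = 50)
  gap <- vapply(1:10, function(i) {
    set.seed(70 + i)
    ratios <- runif(60, 0, 1.1)
    m <- toy_expr(n_targets = 60, n_bg = 240, effect = 1, ratios = ratios,
                  seed = 70 + i)
    pres <- data.frame(gene_id = sprintf("T%03d", 1:60),
                       max_ratio = ratios, expressed = TRUE)
    pt <- gene_set("PT", pres$gene_id)
    pt50 <- build_pt50(pres)
    out <- pt50_significance(pt, pt50, m, B = 50, R = 5, config = cfg,
                             seed = 80 + i, timepoint = 72)
    mean(out$observed_nes) - mean(out$null_nes)
  }, numeric(1))
  expect_gt(mean(gap > 0), 0.9)
})

test_that("power grows with the planted effect size", {
  cfg <- gsea_config(n_perm = 50)
  run_at <- function(delta, i) {
    set.seed(90 + i)
    ratios <- runif(40, 0, 1.1)
    m <- toy_expr(n_targets = 40, n_bg = 160, effect = delta,
                  ratios = ratios, seed = 90 + i)
    pres <- data.frame(gene_id = sprintf("T%03d", 1:40),
                       max_ratio = ratios, expressed = TRUE)
    out <- pt50_significance(gene_set("PT", pres$gene_id),
                             build_pt50(pres), m, B = 50, R = 5,
                             config = cfg, seed = 90 + i, timepoint = 72)
    c(p = out$welch_p, gap = mean(out$observed_nes) - mean(out$null_nes))
  }
  deltas <- c(0, 0.5, 1, 2)
  res <- lapply(deltas, function(d) vapply(1:8, function(i) run_at(d, i),
                                           numeric(2)))
  med_p <- vapply(res, function(x) median(x["p", ]), numeric(1))
  med_gap <- vapply(res, function(x) median(x["gap", ]), numeric(1))
  # every planted effect is detected far more strongly than the null;
  # beyond that, power saturates (the ES is bounded) rather than growing
  expect_true(all(med_p[-1] < med_p[1]))
  expect_true(all(med_p[-1] <= 0.001))
  expect_true(all(med_gap[-1] > 0))
})

test_that("the empirical percentile is calibrated on exchangeable data", {
  cfg <- gsea_config(n_perm = 50)
  pct <- vapply(1:100, function(i) {
    set.seed(1234 + i)
    ratios <- runif(30, 0, 1.1)
    m <- toy_expr(n_targets = 30, n_bg = 120, effect = 0, seed = 200 + i)
    pres <- data.frame(gene_id = sprintf("T%03d", 1:30),
                       max_ratio = ratios, expressed = TRUE)
    out <- pt50_significance(gene_set("PT", pres$gene_id),
                             build_pt50(pres), m, B = 100, R = 5,
                             config = cfg, seed = 300 + i, timepoint = 72)
    out$empirical_percentile
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pct, "punif"))$p.value, 0.01)
})

test_that("derived seeds form a deterministic counter-based stream", {
  expect_equal(derive_seed(17, 1), derive_seed(17, 1))
  expect_false(derive_seed(17, 1) == derive_seed(17, 2))
  expect_false(derive_seed(17, 1) == derive_seed(18, 1))
  s <- vapply(0:1000, function(i) derive_seed(2^30, i), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
})
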