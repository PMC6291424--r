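test_that("ranking metrics instantiate their formulas", {
  vals <- rbind(up = c(4, 4, 4, 2, 2, 2),
                dn = c(1, 1, 1, 3, 3, 3),
                id = c(5, 5, 5, 5, 5, 5))
  sheet <- data.frame(sample = sprintf("s%d", 1:6),
                      arm = rep(c("antagomir_31", "antagomir_scr"), each = 3),
                      timepoint = 72, replicate = rep(1:3, 2))
  m <- expression_matrix(vals, sheet)

  r <- rank_genes(m, "difference_of_means")
  expect_equal(setNames(r$scores, r$genes), c(up = 2, id = 0, dn = -2))

  # signal-to-noise without the sigma floor: (4 - 2) / (0.5 + 0.5) = 2
  v2 <- rbind(g = c(4.5, 3.5, 4, 2.5, 1.5, 2))
  m2 <- expression_matrix(v2, sheet)
  s2n_raw <- rank_genes(m2, "signal_to_noise", sigma_floor = 0)$scores
  sds <- c(sd(c(4.5, 3.5, 4)), sd(c(2.5, 1.5, 2)))
  expect_equal(s2n_raw, (4 - 2) / sum(sds))
  # with the conventional floor, sd is raised to 0.2*|mean|
  s2n_floor <- rank_genes(m2, "signal_to_noise")$scores
  expect_equal(s2n_floor, (4 - 2) / (max(sds[1], 0.8) + max(sds[2], 0.4)))

  expect_equal(rank_genes(m2, "log2_ratio_of_means")$scores, 1)
})

test_that("identical class means give all-zero scores in tie-rule order", {
  vals <- matrix(rep(c(3, 3, 3, 3), 5), nrow = 5, byrow = TRUE,
                 dimnames = list(c("b", "d", "a", "e", "c"), NULL))
  sheet <- data.frame(sample = sprintf("s%d", 1:4),
                      arm = rep(c("antagomir_31", "antagomir_scr"), each = 2),
                      timepoint = 72, replicate = c(1, 2, 1, 2))
  r <- rank_genes(expression_matrix(vals, sheet), "difference_of_means")
  expect_equal(r$scores, rep(0, 5))
  expect_equal(r$genes, c("a", "b", "c", "d", "e"))
})

test_that("scores equal a brute-force per-gene recomputation", {
  set.seed(21)
  vals <- matrix(rnorm(20 * 8, 6, 1), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  sheet <- data.frame(sample = sprintf("s%d", 1:8),
                      arm = rep(c("antagomir_31", "antagomir_scr"), each = 4),
                      timepoint = 72, replicate = rep(1:4, 2))
  m <- expression_matrix(vals, sheet)
  r <- rank_genes(m, "signal_to_noise")
  oracle <- vapply(rownames(vals), function(g) {
    x <- vals[g, 1:4]; y <- vals[g, 5:8]
    fx <- max(sd(x), 0.2 * abs(mean(x)))
    fy <- max(sd(y), 0.2 * abs(mean(y)))
    (mean(x) - mean(y)) / (fx + fy)
  }, numeric(1))
  expect_equal(setNames(r$scores, r$genes),
               oracle[order(-oracle, names(oracle), method = "radix")])
})

test_that("enrichment score matches hand-checkable cases", {
  # single member at the top, weight 0: maximal deviation is 1
  r10 <- ranked_list(setNames(seq(10, 1), paste0("g", 1:10)))
  res <- enrichment_score(r10, gene_set("s", "g1"), weight = 0)
  expect_equal(res$ES, 1.0)
  expect_equal(res$leading_edge, "g1")

  # 4-step walks evaluated exhaustively: a symmetric one (walk -1/2, 0,
  # +1/2, 0 ties in magnitude and resolves to 0) and a decisive one
  r4 <- ranked_list(setNames(c(3, 2, -2, -3), c("a", "b", "c", "d")))
  s <- gene_set("s", c("b", "c"))
  res4 <- enrichment_score(r4, s, weight = 0)
  expect_equal(res4$ES,
               brute_force_es(r4$scores, r4$genes %in% s$members, 0))
  expect_equal(res4$ES, 0)
  s13 <- gene_set("s", c("a", "c"))
  res13 <- enrichment_score(r4, s13, weight = 0)
  expect_equal(res13$ES,
               brute_force_es(r4$scores, r4$genes %in% s13$members, 0))
  expect_equal(res13$ES, 0.5)  # walk: +1/2, 0, +1/2, 0

  # a set at the bottom of the list has negative ES
  bottom <- enrichment_score(r10, gene_set("s", c("g9", "g10")), weight = 0)
  expect_lt(bottom$ES, 0)
  expect_setequal(bottom$leading_edge, c("g9", "g10"))
})

test_that("running score is a balanced walk and ES its extremum", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    scores <- setNames(rnorm(n), sprintf("g%03d", 1:n))
    r <- ranked_list(scores)
    k <- sample(2:(n %/% 3), 1)
    s <- gene_set("s", sample(r$genes, k))
    for (w in c(0, 1)) {
      res <- enrichment_score(r, s, weight = w)
      if (w == 0)
        expect_equal(res$running_scores[n], 0, tolerance = 1e-12)
      expect_equal(res$ES,
                   res$running_scores[which.max(abs(res$running_scores))],
                   tolerance = 1e-12)
      expect_equal(res$ES, brute_force_es(r$scores,
                                          r$genes %in% s$members, w))
    }
  }
})

test_that("relabeling non-members without changing scores leaves ES unchanged", {
  set.seed(23)
  scores <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  r <- ranked_list(scores)
  s <- gene_set("s", r$genes[c(3, 9, 20)])
  before <- enrichment_score(r, s, 1)$ES
  non <- setdiff(r$genes, s$members)
  relabel <- setNames(r$genes, r$genes)
  relabel[non] <- sample(non)   # permute identities of non-members only
  r2 <- structure(list(genes = unname(relabel[r$genes]), scores = r$scores),
                  class = "ranked_list")
  expect_equal(enrichment_score(r2, s, 1)$ES, before)
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(24)
  for (i in 1:8) {
    n <- sample(30:120, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", 1:n)
    sel <- sort(sample(n, sample(3:10, 1)))
    r <- ranked_list(stats)
    s <- gene_set("s", names(stats)[sel])
    for (w in c(0, 1, 2)) {
      res <- enrichment_score(r, s, w)
      peaks <- range(res$running_scores)
      if (abs(sum(peaks)) < 1e-6) next  # tie conventions differ at a tie
      expect_equal(res$ES, fgsea::calcGseaStat(stats, sel, gseaParam = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate gene sets are rejected", {
  r <- ranked_list(setNames(5:1, paste0("g", 1:5)))
  expect_error(enrichment_score(r, gene_set("s", c("x", "y"))), "disjoint")
  expect_error(enrichment_score(r, gene_set("s", paste0("g", 1:5))),
               "whole ranked list")
  expect_error(permutation_null(r, gene_set("s", paste0("g", 1:4)),
                                n_perm = 5),
               "degenerate")
})

test_that("permutation nulls are reproducible under a seed", {
  set.seed(25)
  r <- ranked_list(setNames(rnorm(100), sprintf("g%03d", 1:100)))
  s <- gene_set("s", sample(r$genes, 10))
  one <- permutation_null(r, s, n_perm = 1, seed = 99)
  expect_equal(permutation_null(r, s, n_perm = 1, seed = 99), one)
  many <- permutation_null(r, s, n_perm = 50, seed = 7)
  expect_equal(permutation_null(r, s, n_perm = 50, seed = 7), many)
  expect_length(many, 50)

  m <- toy_expr(seed = 4)
  sp <- gene_set("s", rownames(m$values)[1:12])
  ph <- permutation_null(m, sp, n_perm = 10, mode = "phenotype", seed = 5)
  expect_equal(permutation_null(m, sp, n_perm = 10, mode = "phenotype",
                                seed = 5), ph)
})

test_that("NES and nominal p follow the stated normalization", {
  hand <- normalize_and_p(0.8, c(0.2, 0.4, -0.3))
  expect_equal(hand$NES, 0.8 / 0.3)
  expect_equal(hand$nominal_p, 1 / 3)

  same <- normalize_and_p(0.5, rep(0.5, 10))
  expect_equal(same$NES, 1)
  expect_equal(same$nominal_p, 1)

  # sign flip of every input negates NES and preserves p
  flip <- normalize_and_p(-0.8, -c(0.2, 0.4, -0.3))
  expect_equal(flip$NES, -hand$NES)
  expect_equal(flip$nominal_p, hand$nominal_p)

  expect_warning(bad <- normalize_and_p(0.7, c(-0.1, -0.5)), "undefined")
  expect_true(is.na(bad$NES))

  # add-one correction keeps p strictly positive and at most 1
  set.seed(26)
  for (i in 1:25) {
    nulls <- rnorm(50, 0, 0.3)
    obs <- rnorm(1, 0, 0.6)
    p <- normalize_and_p(obs, nulls)$nominal_p
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("gene-set permutation p is uniform under exchangeability", {
  set.seed(27)
  ps <- vapply(1:200, function(i) {
    r <- ranked_list(setNames(rnorm(80), sprintf("g%03d", 1:80)))
    s <- gene_set("s", sample(r$genes, 10))
    es <- enrichment_score(r, s, 1)$ES
    nulls <- permutation_null(r, s, n_perm = 200)
    normalize_and_p(es, nulls)$nominal_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("phenotype permutation p is uniform under label exchangeability", {
  set.seed(28)
  cfg <- gsea_config(n_perm = 60, perm_mode = "phenotype")
  ps <- vapply(1:120, function(i) {
    m <- toy_expr(n_targets = 20, n_bg = 100, effect = 0, seed = 1000 + i)
    s <- gene_set("s", rownames(m$values)[1:20])
    run_gsea(m, s, cfg, seed = 2000 + i)[[1]]$nominal_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("run_gsea detects planted de-repression and controls type I error", {
  cfg <- gsea_config(n_perm = 100)
  # power at delta = 1: PT50-like set of fully site-carrying genes
  hits <- vapply(1:30, function(i) {
    m <- toy_expr(n_targets = 25, n_bg = 100, effect = 1, seed = 3000 + i)
    s <- gene_set("s", sprintf("T%03d", 1:25))
    res <- run_gsea(m, s, cfg, seed = i, timepoint = 72)[[1]]
    res$NES > 0 && res$nominal_p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # size under the null: rejection rate within the binomial CI of 0.05
  rej <- vapply(1:400, function(i) {
    m <- toy_expr(n_targets = 25, n_bg = 100, effect = 0, seed = 5000 + i)
    s <- gene_set("s", sprintf("T%03d", 1:25))
    run_gsea(m, s, cfg, seed = i, timepoint = 72)[[1]]$nominal_p <= 0.05
  }, logical(1))
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])

  expect_equal(run_gsea(toy_expr(), list(), gsea_config()), list())
})

test_that("positively correlated members are extracted by strict sign", {
  r <- ranked_list(setNames(c(1.2, 0, -0.5, 2, -1), letters[1:5]))
  s <- gene_set("s", c("a", "b", "c"))
  res <- enrichment_score(r, s, 1)
  pos <- positive_correlation_genes(res, r)
  expect_setequal(pos$members, "a")   # zero and negative scores excluded

  s_neg <- gene_set("s", c("c", "e"))
  expect_length(positive_correlation_genes(enrichment_score(r, s_neg, 1),
                                           r)$members, 0)

  # strong planted de-repression recovers exactly the upregulated members
  m <- toy_expr(n_targets = 20, n_bg = 80, effect = 4, noise_sd = 0.05,
                seed = 31)
  rk <- rank_genes(m, timepoint = 72)
  res2 <- enrichment_score(rk, gene_set("s", sprintf("T%03d", 1:20)), 1)
  pos2 <- positive_correlation_genes(res2, rk)
  expect_setequal(pos2$members, sprintf("T%03d", 1:20))
})
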