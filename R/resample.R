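#' Derived seed for a named substream
#'
#' Counter-based scheme: stream `i` of top-level seed `s` is
#' `(s + 48271 * i) mod 2147483587`, kept within 32-bit integer range.
#' All stochastic steps of the resampling procedure draw their seed from
#' this scheme so a single top-level seed reproduces every substream.
#'
#' @param seed Top-level integer seed.
#' @param i Substream counter (non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483587)
}

#' Welch's unequal-variance two-sample t-test
#'
#' t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny), degrees of freedom by
#' the Welch-Satterthwaite expression, two-sided p from the t
#' distribution.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_test needs at least 2 observations per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("welch_test needs nonzero variance in at least one sample")
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' NES of random gene-set subsets
#'
#' Draws `B` uniform size-`k` subsets (without replacement) of a gene set
#' and runs one GSEA (ES, gene-set permutation null, NES) per subset, each
#' under an independent derived seed ([derive_seed()] streams 1..B).
#'
#' @param pt The parent [gene_set] (putative-target universe).
#' @param k Subset size.
#' @param m An [expression_matrix] or [ranked_list].
#' @param B Number of subsets (default 1000).
#' @param config A [gsea_config] (its `n_perm` governs each subset GSEA's
#'   null).
#' @param seed Top-level integer seed.
#' @param timepoint Optional timepoint subset for ranking.
#' @return Numeric vector of `B` NES values.
#' @export
random_subset_nes <- function(pt, k, m, B = 1000, config = gsea_config(),
                              seed = 1, timepoint = NULL) {
  stopifnot(inherits(pt, "gene_set"), B >= 2)
  ranked <- if (inherits(m, "ranked_list")) m
            else rank_genes(m, config$metric, config$positive_class,
                            timepoint)
  members <- intersect(pt$members, ranked$genes)
  if (k > length(members))
    stop("k exceeds the ", length(members),
         " set members present in the ranked list")
  vapply(seq_len(B), function(b) {
    set.seed(derive_seed(seed, b))
    sub <- gene_set(sprintf("%s_sub%d", pt$name, b), sample(members, k))
    res <- enrichment_score(ranked, sub, config$weight)
    nulls <- null_es_ranked(ranked, res$n_set_used, config$n_perm,
                            config$weight)
    normalize_and_p(res$ES, nulls)$NES
  }, numeric(1))
}

#' Resampling significance of the PT50 enrichment
#'
#' Tests whether the high-presence subset (PT50) is more enriched than
#' size-matched random subsets of the full putative-target list (PT):
#' `B` GSEAs on uniformly drawn subsets of PT of size |PT50| give the null
#' NES sample, `R` GSEA replicates of PT50 under independent permutation
#' seeds give the observed NES sample, and the two samples are compared by
#' Welch's t-test. The empirical percentile of the mean observed NES in
#' the null sample is reported alongside; because the observed replicates
#' vary only through the permutation-seed jitter of the NES denominator
#' while the null sample carries full subset-to-subset variance, the Welch
#' p is anti-conservative and the percentile is the calibrated summary
#' (see the methods vignette).
#'
#' @param pt Parent [gene_set] (all putative targets).
#' @param pt50 The subset [gene_set] under test; must satisfy
#'   `pt50$members` within `pt$members`.
#' @param m An [expression_matrix] or [ranked_list].
#' @param B Number of random subsets (default 1000).
#' @param R Number of PT50 NES replicates (default 20).
#' @param config A [gsea_config].
#' @param seed Top-level integer seed (mandatory for reproducibility).
#' @param timepoint Optional timepoint subset for ranking.
#' @return A list of class `resampling_outcome`: `observed_nes` (length
#'   R), `null_nes` (length B), `welch_t`, `welch_df`, `welch_p`,
#'   `empirical_percentile` (fraction of null NES below the mean observed
#'   NES), `seed`, `config`.
#' @export
pt50_significance <- function(pt, pt50, m, B = 1000, R = 20,
                              config = gsea_config(), seed = 1,
                              timepoint = NULL) {
  stopifnot(inherits(pt, "gene_set"), inherits(pt50, "gene_set"), R >= 2)
  if (!all(pt50$members %in% pt$members))
    stop("pt50 must be a subset of pt")
  ranked <- if (inherits(m, "ranked_list")) m
            else rank_genes(m, config$metric, config$positive_class,
                            timepoint)
  k <- length(intersect(pt50$members, ranked$genes))
  if (k == 0L) stop("pt50 has no members in the ranked list")
  null_nes <- random_subset_nes(pt, k, ranked, B, config, seed)
  obs_es <- enrichment_score(ranked, pt50, config$weight)
  observed_nes <- vapply(seq_len(R), function(r) {
    set.seed(derive_seed(seed, B + r))
    nulls <- null_es_ranked(ranked, obs_es$n_set_used, config$n_perm,
                            config$weight)
    normalize_and_p(obs_es$ES, nulls)$NES
  }, numeric(1))
  wt <- welch_test(observed_nes, null_nes)
  structure(list(observed_nes = observed_nes, null_nes = null_nes,
                 welch_t = wt$t, welch_df = wt$df, welch_p = wt$p,
                 empirical_percentile = mean(null_nes < mean(observed_nes)),
                 seed = seed, B = B, R = R, config = config),
            class = "resampling_outcome")
}

#' @export
print.resampling_outcome <- function(x, ...) {
  cat(sprintf(paste0("resampling_outcome: mean observed NES %.3f vs mean null",
                     " NES %.3f\n  Welch t %.3f (df %.1f), p %.4g;",
                     " empirical percentile %.3f (B=%d, R=%d, seed %d)\n"),
              mean(x$observed_nes), mean(x$null_nes), x$welch_t, x$welch_df,
              x$welch_p, x$empirical_percentile, x$B, x$R, x$seed))
  invisible(x)
}

#' Serialize a resampling outcome to JSON
#'
#' @param outcome A `resampling_outcome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_resampling_json <- function(outcome, path) {
  rec <- list(observed_nes = outcome$observed_nes,
              null_nes = outcome$null_nes,
              welch_t = outcome$welch_t, welch_df = outcome$welch_df,
              welch_p = outcome$welch_p,
              empirical_percentile = outcome$empirical_percentile,
              seed = outcome$seed, B = outcome$B, R = outcome$R,
              config = unclass(outcome$config))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
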