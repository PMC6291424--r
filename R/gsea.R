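#' GSEA configuration
#'
#' Defaults follow the conventional gene set enrichment analysis settings:
#' signal-to-noise ranking, weight 1, 1000 permutations, gene-set
#' permutation mode (with two arms and few replicates per arm, phenotype
#' permutation is underpowered).
#'
#' @param metric Ranking metric (see [rank_genes()]).
#' @param weight Exponent on |score| in the running sum (default 1;
#'   0 gives the classical Kolmogorov-Smirnov-like statistic).
#' @param n_perm Number of permutations for the null (default 1000).
#' @param perm_mode `"gene_set"` (default) or `"phenotype"`.
#' @param positive_class Arm treated as class 1.
#' @return A list of class `gsea_config`.
#' @export
gsea_config <- function(metric = "signal_to_noise", weight = 1,
                        n_perm = 1000, perm_mode = c("gene_set", "phenotype"),
                        positive_class = "antagomir_31") {
  perm_mode <- match.arg(perm_mode)
  stopifnot(weight >= 0, n_perm >= 1)
  structure(list(metric = metric, weight = weight, n_perm = n_perm,
                 perm_mode = perm_mode, positive_class = positive_class),
            class = "gsea_config")
}

#' Running enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list accumulating |score|^weight / NR at set members
#' ("hits", NR = the sum of hit weights) and -1/(N - k) at non-members.
#' The enrichment score is the signed extremum of the running sum (the
#' value of larger magnitude among the maximum and minimum; an exact
#' magnitude tie yields 0). The leading edge contains the members at or
#' before the extremum for positive ES, and at or after it for negative
#' ES. Set members absent from the ranked list are dropped and counted in
#' `n_dropped`.
#'
#' @param ranked A [ranked_list].
#' @param s A [gene_set] whose overlap with the list is non-empty and a
#'   proper subset of it.
#' @param weight Exponent on |score| (default 1).
#' @return A list of class `gsea_result` with `set_name`, `ES`,
#'   `running_scores`, `hit_positions`, `leading_edge`, `n_set_used`,
#'   `n_dropped`, and `NES`/`nominal_p` set to `NA` (filled by
#'   [normalize_and_p()] / [run_gsea()]).
#' @export
enrichment_score <- function(ranked, s, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(s, "gene_set"))
  N <- length(ranked$genes)
  hit <- ranked$genes %in% s$members
  k <- sum(hit)
  n_dropped <- length(s$members) - k
  if (k == 0L) stop("gene set '", s$name, "' is disjoint from the ranked list")
  if (k == N) stop("gene set '", s$name, "' covers the whole ranked list")
  aw <- abs(ranked$scores)^weight
  nr <- sum(aw[hit])
  inc <- if (nr > 0) aw / nr else rep(1 / k, N)  # all-zero hit weights
  run <- cumsum(ifelse(hit, inc, -1 / (N - k)))
  maxP <- max(run); minP <- min(run)
  # magnitude ties (symmetric walks) resolve to 0; the epsilon guards the
  # comparison against accumulation-order rounding
  es <- if (maxP + minP > 1e-9) maxP else if (maxP + minP < -1e-9) minP else 0
  hits <- which(hit)
  leading <- if (es > 0) {
    peak <- which.max(run)
    ranked$genes[hits[hits <= peak]]
  } else if (es < 0) {
    trough <- which.min(run)
    ranked$genes[hits[hits >= trough]]
  } else character(0)
  structure(list(set_name = s$name, ES = es, NES = NA_real_,
                 nominal_p = NA_real_, running_scores = run,
                 hit_positions = hits, leading_edge = leading,
                 n_set_used = k, n_dropped = n_dropped, weight = weight),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result '%s': ES %.3f, NES %s, nominal p %s (%d members%s)\n",
              x$set_name, x$ES,
              ifelse(is.na(x$NES), "NA", sprintf("%.3f", x$NES)),
              ifelse(is.na(x$nominal_p), "NA", sprintf("%.4g", x$nominal_p)),
              x$n_set_used,
              if (x$n_dropped > 0) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

# fast null ES for k random genes of a ranked list, reusing |score|^weight
null_es_ranked <- function(ranked, k, n_perm, weight) {
  aw <- abs(ranked$scores)^weight
  if (sum(aw) <= 0) aw <- rep(1, length(aw))
  null_es_gene_set_cpp(aw, as.integer(k), as.integer(n_perm))
}

#' Permutation null distribution of the enrichment score
#'
#' `gene_set` mode draws `n_perm` uniform random gene sets of the observed
#' overlap size from the ranked universe and recomputes the ES.
#' `phenotype` mode permutes the arm labels, re-ranks the genes, and
#' recomputes the ES of the original set; it requires at least two samples
#' per class.
#'
#' @param x An [expression_matrix] (required for `phenotype` mode), or a
#'   [ranked_list] (sufficient for `gene_set` mode).
#' @param s The [gene_set] under test.
#' @param n_perm Number of permutations.
#' @param mode `"gene_set"` or `"phenotype"`.
#' @param seed Integer seed (optional; the current RNG state is used when
#'   missing).
#' @param config A [gsea_config] supplying weight/metric/positive class.
#' @param timepoint Optional timepoint subset (phenotype mode ranking).
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(x, s, n_perm, mode = c("gene_set", "phenotype"),
                             seed = NULL, config = gsea_config(),
                             timepoint = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "gene_set") {
    ranked <- if (inherits(x, "ranked_list")) x
              else rank_genes(x, config$metric, config$positive_class,
                              timepoint)
    k <- sum(ranked$genes %in% s$members)
    if (k == 0L) stop("gene set is disjoint from the ranked list")
    if (k >= length(ranked$genes) - 1L)
      stop("gene set leaves fewer than one non-member; null is degenerate")
    null_es_ranked(ranked, k, n_perm, config$weight)
  } else {
    stopifnot(inherits(x, "expression_matrix"))
    m <- if (is.null(timepoint)) x else subset_timepoint(x, timepoint)
    cls <- m$samples$arm == config$positive_class
    if (sum(cls) < 2L || sum(!cls) < 2L)
      stop("phenotype mode needs >= 2 samples per class")
    vapply(seq_len(n_perm), function(i) {
      perm <- sample(cls)
      r <- ranked_list(metric_scores(m$values, perm, config$metric))
      enrichment_score(r, s, config$weight)$ES
    }, numeric(1))
  }
}

#' Normalized enrichment score and nominal p-value
#'
#' NES divides the observed ES by the mean absolute value of the null ES
#' sharing its sign; the nominal p is the add-one-corrected fraction of
#' same-sign null ES at least as extreme, so p is never exactly 0.
#'
#' @param es Observed enrichment score.
#' @param null_es Numeric vector of null enrichment scores.
#' @return List with `NES`, `nominal_p`, and `n_same_sign`. When no null
#'   ES shares the observed sign both values are `NA` (flagged undefined).
#' @export
normalize_and_p <- function(es, null_es) {
  same <- null_es[sign(null_es) == sign(es) & null_es != 0]
  if (es == 0 || length(same) == 0L) {
    warning("no same-sign null ES; NES undefined")
    return(list(NES = NA_real_, nominal_p = NA_real_, n_same_sign = 0L))
  }
  list(NES = es / mean(abs(same)),
       nominal_p = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)),
       n_same_sign = length(same))
}

#' Run GSEA for one or more gene sets
#'
#' Ranks the genes once, then computes ES, permutation null, NES and
#' nominal p for every set under a shared seed policy (set i uses the
#' derived seed `derive_seed(seed, i)`).
#'
#' @param m An [expression_matrix], or a [ranked_list] (gene-set
#'   permutation mode only).
#' @param sets A [gene_set] or list of them.
#' @param config A [gsea_config].
#' @param seed Integer seed for the permutation null.
#' @param timepoint Optional timepoint subset.
#' @return A list of `gsea_result` objects (one per set, named), each with
#'   `NES` and `nominal_p` filled.
#' @export
run_gsea <- function(m, sets, config = gsea_config(), seed = 1,
                     timepoint = NULL) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (length(sets) == 0L) return(list())
  ranked <- if (inherits(m, "ranked_list")) m
            else rank_genes(m, config$metric, config$positive_class,
                            timepoint)
  if (inherits(m, "ranked_list") && config$perm_mode == "phenotype")
    stop("phenotype permutation needs an expression_matrix")
  out <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    res <- enrichment_score(ranked, s, config$weight)
    nulls <- if (config$perm_mode == "gene_set") {
      set.seed(derive_seed(seed, i))
      null_es_ranked(ranked, res$n_set_used, config$n_perm, config$weight)
    } else {
      permutation_null(m, s, config$n_perm, "phenotype",
                       derive_seed(seed, i), config, timepoint)
    }
    np <- normalize_and_p(res$ES, nulls)
    res$NES <- np$NES
    res$nominal_p <- np$nominal_p
    res
  })
  names(out) <- vapply(sets, `[[`, character(1), "name")
  out
}

#' Positively correlated set members
#'
#' Members of the tested set whose rank metric score is strictly positive,
#' i.e. the genes de-repressed (upregulated) after miRNA knockdown that
#' drive a positive enrichment.
#'
#' @param result A `gsea_result` computed on `ranked`.
#' @param ranked The [ranked_list] the result was computed on.
#' @return A [gene_set] named `<set>_positive`.
#' @export
positive_correlation_genes <- function(result, ranked) {
  stopifnot(inherits(result, "gsea_result"), inherits(ranked, "ranked_list"))
  members <- ranked$genes[result$hit_positions]
  keep <- ranked$scores[result$hit_positions] > 0
  gene_set(paste0(result$set_name, "_positive"), members[keep])
}

#' Serialize GSEA results to JSON
#'
#' @param results List of `gsea_result` objects (from [run_gsea()]).
#' @param path Output path.
#' @param running_scores Include the per-rank running-score profile
#'   (default `FALSE`; profiles are long).
#' @return `path`, invisibly.
#' @export
write_gsea_json <- function(results, path, running_scores = FALSE) {
  recs <- lapply(results, function(r) {
    rec <- list(set = r$set_name, ES = r$ES, NES = r$NES,
                nominal_p = r$nominal_p, n_set_used = r$n_set_used,
                n_dropped = r$n_dropped, leading_edge = r$leading_edge)
    if (running_scores) rec$running_scores <- r$running_scores
    rec
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
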