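#' Ranked gene list
#'
#' @param scores Named numeric vector (one score per gene, names are gene
#'   ids, no duplicates). Sorted descending; ties are broken by
#'   lexicographic gene id (stable, deterministic).
#' @return An object of class `ranked_list` with fields `genes` and
#'   `scores`.
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by gene id")
  if (anyDuplicated(names(scores))) stop("duplicate gene ids in ranked list")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores), method = "radix")
  structure(list(genes = names(scores)[ord],
                 scores = unname(scores[ord])),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  n <- length(x$genes)
  cat(sprintf("ranked_list of %d genes (top: %s = %.3g; bottom: %s = %.3g)\n",
              n, x$genes[1], x$scores[1], x$genes[n], x$scores[n]))
  invisible(x)
}

#' @export
length.ranked_list <- function(x) length(x$genes)

# per-gene two-class metric scores; values: genes x samples, cls: logical
# vector marking the positive class
metric_scores <- function(values, cls, metric, sigma_floor = 0.2) {
  n1 <- sum(cls); n2 <- sum(!cls)
  m1 <- rowMeans(values[, cls, drop = FALSE])
  m2 <- rowMeans(values[, !cls, drop = FALSE])
  switch(metric,
    difference_of_means = m1 - m2,
    log2_ratio_of_means = {
      if (any(m1 <= 0) || any(m2 <= 0))
        stop("log2_ratio_of_means needs positive class means (linear-scale values)")
      log2(m1 / m2)
    },
    signal_to_noise = {
      s1 <- if (n1 > 1) apply(values[, cls, drop = FALSE], 1, sd) else 0
      s2 <- if (n2 > 1) apply(values[, !cls, drop = FALSE], 1, sd) else 0
      # conventional floor: sd no smaller than 0.2*|mean|, and 0.2 when the
      # mean is also 0 (keeps zero-variance genes finite)
      floor1 <- pmax(sigma_floor * abs(m1), ifelse(m1 == 0, sigma_floor, 0))
      floor2 <- pmax(sigma_floor * abs(m2), ifelse(m2 == 0, sigma_floor, 0))
      (m1 - m2) / (pmax(s1, floor1) + pmax(s2, floor2))
    },
    stop("unknown metric: ", metric))
}

#' Rank genes by a two-class differential metric
#'
#' Scores every gene by comparing the positive-class samples (miRNA
#' antagomir arm) against the rest and returns the genes in descending
#' score order, i.e. from most upregulated after miRNA knockdown to most
#' downregulated.
#'
#' @param m An [expression_matrix] (log-scale values for
#'   `signal_to_noise` / `difference_of_means`; linear for
#'   `log2_ratio_of_means`).
#' @param metric One of `"signal_to_noise"` (default; (mu1-mu2)/(s1+s2)
#'   with the conventional sigma floor max(s, 0.2|mu|)),
#'   `"log2_ratio_of_means"`, `"difference_of_means"`.
#' @param positive_class Arm treated as class 1 (default
#'   `"antagomir_31"`).
#' @param timepoint Optional timepoint to subset to before ranking.
#' @param sigma_floor Floor coefficient for the signal-to-noise sd
#'   (default 0.2; set to 0 for the unfloored formula).
#' @return A [ranked_list].
#' @export
rank_genes <- function(m, metric = c("signal_to_noise",
                                     "log2_ratio_of_means",
                                     "difference_of_means"),
                       positive_class = "antagomir_31", timepoint = NULL,
                       sigma_floor = 0.2) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "expression_matrix"))
  if (!is.null(timepoint)) m <- subset_timepoint(m, timepoint)
  cls <- m$samples$arm == positive_class
  if (!any(cls)) stop("positive class has zero samples: ", positive_class)
  if (all(cls)) stop("reference class has zero samples")
  ranked_list(metric_scores(m$values, cls, metric, sigma_floor))
}
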