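#' Expression matrix with arm/timepoint metadata and presence calls
#'
#' Container for a normalized (log-scale) gene-by-sample matrix from a
#' two-arm antagomir experiment, its sample sheet, and detection
#' ("present") calls.
#'
#' @param values Numeric matrix, genes x samples, with gene ids as
#'   rownames.
#' @param samples Data frame with columns `sample`, `arm` (levels
#'   `antagomir_31`, `antagomir_scr`), `timepoint` (hours), and optionally
#'   `replicate`; one row per matrix column, in column order.
#' @param presence Logical matrix of the same dimensions (default: all
#'   `TRUE`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, presence = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values needs gene ids as rownames")
  samples <- as.data.frame(samples)
  req <- c("sample", "arm", "timepoint")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet rows must match matrix columns")
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (is.null(presence)) {
    presence <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  } else {
    presence <- as.matrix(presence)
    if (!all(dim(presence) == dim(values)))
      stop("presence and values must share dimensions")
    storage.mode(presence) <- "logical"
    dimnames(presence) <- dimnames(values)
  }
  structure(list(values = values, samples = samples, presence = presence),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (arms: %s; timepoints: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$arm), collapse = "/"),
              paste(sort(unique(x$samples$timepoint)), collapse = "/")))
  invisible(x)
}

#' Subset an expression matrix to one timepoint
#'
#' @param m An [expression_matrix].
#' @param timepoint Timepoint to keep (hours).
#' @return An [expression_matrix] with only the matching samples.
#' @export
subset_timepoint <- function(m, timepoint) {
  stopifnot(inherits(m, "expression_matrix"))
  keep <- m$samples$timepoint == timepoint
  if (!any(keep)) stop("no samples at timepoint ", timepoint)
  expression_matrix(m$values[, keep, drop = FALSE],
                    m$samples[keep, , drop = FALSE],
                    m$presence[, keep, drop = FALSE])
}

#' Expressed-gene filter from detection calls
#'
#' A gene is kept when it is called present in at least `fraction` of the
#' samples of either arm. By default samples are pooled across timepoints
#' within each arm (the filter is applied once for the whole experiment);
#' with `per_timepoint = TRUE` a gene is kept when the rule holds within
#' any single timepoint.
#'
#' @param m An [expression_matrix] with presence calls.
#' @param fraction Minimum fraction of present calls within an arm
#'   (default 0.5).
#' @param per_timepoint Apply the rule within each timepoint instead of
#'   pooling (default `FALSE`).
#' @return A [gene_set] named `"expressed"`.
#' @export
presence_filter <- function(m, fraction = 0.5, per_timepoint = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  arms <- c("antagomir_31", "antagomir_scr")
  for (a in arms)
    if (!any(m$samples$arm == a)) stop("arm with zero samples: ", a)
  rule <- function(cols) {
    ok <- rep(FALSE, nrow(m$presence))
    for (a in arms) {
      idx <- cols[m$samples$arm[cols] == a]
      if (length(idx))
        ok <- ok | rowMeans(m$presence[, idx, drop = FALSE]) >= fraction
    }
    ok
  }
  if (per_timepoint) {
    keep <- rep(FALSE, nrow(m$presence))
    for (tp in unique(m$samples$timepoint))
      keep <- keep | rule(which(m$samples$timepoint == tp))
  } else {
    keep <- rule(seq_len(nrow(m$samples)))
  }
  gene_set("expressed", rownames(m$values)[keep])
}

#' qPCR relative expression by the change-in-threshold method
#'
#' Returns `2^-(target_ct - reference_ct)`, the relative abundance of the
#' target transcript with respect to the reference gene.
#'
#' @param target_ct,reference_ct Threshold cycles (vectorized).
#' @return Positive relative expression values.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  if (any(!is.finite(target_ct)) || any(!is.finite(reference_ct)))
    stop("CT values must be finite")
  2^-(target_ct - reference_ct)
}

#' Fold change of treated over control relative expressions
#'
#' @param treated,control Vectors of relative expression values (e.g. from
#'   [delta_ct()]).
#' @param mode `"arithmetic"` (default, matching mean +/- SEM plots) or
#'   `"geometric"`.
#' @return Scalar fold change mean(treated)/mean(control).
#' @export
fold_change_vs_control <- function(treated, control,
                                   mode = c("arithmetic", "geometric")) {
  mode <- match.arg(mode)
  if (length(treated) == 0L || length(control) == 0L)
    stop("treated and control must be non-empty")
  avg <- if (mode == "arithmetic") mean else function(x) exp(mean(log(x)))
  mc <- avg(control)
  if (!is.finite(mc) || mc <= 0) stop("control mean must be positive")
  avg(treated) / mc
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. In `auto` mode the
#' exact null distribution is enumerated when both samples have at most 8
#' observations and there are no ties; otherwise the tie-corrected normal
#' approximation is used. The two-sided p doubles the smaller tail, capped
#' at 1.
#'
#' @param a,b Numeric samples.
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   half) and `p`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(mode,
                  exact = TRUE,
                  normal_approx = FALSE,
                  auto = length(a) <= 8L && length(b) <= 8L && !ties)
  if (exact && ties)
    stop("exact mode is unavailable with ties; use normal_approx")
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                             correct = !exact))
  list(U = unname(res$statistic), p = unname(res$p.value))
}
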