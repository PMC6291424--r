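#' Median exonic depth of a transcript
#'
#' Pools per-base depths across all exon intervals and returns their median.
#' Positions without coverage count as depth 0.
#'
#' @param t A [transcript_model].
#' @param cov A [coverage_track].
#' @return Non-negative scalar.
#' @export
median_exon_depth <- function(t, cov) {
  stopifnot(inherits(t, "transcript_model"))
  depths <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    track_depths(cov, t$chrom, t$exons$start[i], t$exons$end[i])))
  stats::median(depths)
}

bin_of <- function(max_ratio, expressed) {
  if (!expressed) return("not_detected")
  if (max_ratio > 0.9) "high" else if (max_ratio >= 0.5) "mid" else "low"
}

#' Binding-site presence of one gene
#'
#' The presence ratio of site *i* is the mean (or median) per-base depth
#' over the site interval divided by the median exonic depth; the gene-level
#' statistic is the maximum over its sites. It estimates the fraction of
#' expressed mRNA molecules that retain the site through 3'-UTR shortening.
#' A gene is `expressed` when its median exonic depth reaches
#' `min_expressed_depth`; otherwise ratios are undefined (`NA`) and the gene
#' falls in the `not_detected` bin. Bins over the maximal ratio r:
#' `high` (r > 0.9), `mid` (0.5 <= r <= 0.9), `low` (r < 0.5). Ratios are
#' not capped at 1 (sampling noise can push them above).
#'
#' @param t A [transcript_model].
#' @param cov A [coverage_track].
#' @param min_expressed_depth Detectability threshold on the median exonic
#'   depth (default 1).
#' @param site_aggregate Depth aggregator over a site window, `"mean"`
#'   (default; robust for 7-22 nt windows) or `"median"`.
#' @param flank Bases added on both sides of each site interval (default 0).
#' @return A list of class `site_presence`: `gene_id`, `transcript_id`,
#'   `median_exon_depth`, `n_sites`, `site_ratios`, `max_ratio`,
#'   `best_site` (index of the maximizing site, first in genomic order on
#'   ties), `expressed`, `bin`.
#' @export
site_presence <- function(t, cov, min_expressed_depth = 1,
                          site_aggregate = c("mean", "median"), flank = 0) {
  site_aggregate <- match.arg(site_aggregate)
  agg <- if (site_aggregate == "mean") mean else stats::median
  med <- median_exon_depth(t, cov)
  expressed <- med >= min_expressed_depth
  n_sites <- nrow(t$sites)
  if (!expressed) {
    ratios <- rep(NA_real_, n_sites)
    max_ratio <- NA_real_
    best <- NA_integer_
  } else if (n_sites == 0L) {
    # expressed but no annotated site: no mRNA molecule can carry one
    ratios <- numeric(0)
    max_ratio <- 0
    best <- NA_integer_
  } else {
    ratios <- vapply(seq_len(n_sites), function(i) {
      s <- max(0, t$sites$start[i] - flank)
      e <- t$sites$end[i] + flank
      agg(track_depths(cov, t$chrom, s, e)) / med
    }, numeric(1))
    best <- which.max(ratios)   # first maximizing site in genomic order
    max_ratio <- ratios[best]
  }
  structure(list(gene_id = t$gene_id, transcript_id = t$transcript_id,
                 median_exon_depth = med, n_sites = n_sites,
                 site_ratios = ratios, max_ratio = max_ratio,
                 best_site = best, expressed = expressed,
                 bin = bin_of(max_ratio, expressed)),
            class = "site_presence")
}

#' Presence table for a set of transcript models
#'
#' Applies [site_presence()] to every model and returns one row per gene.
#'
#' @inheritParams site_presence
#' @param models List of [transcript_model] objects.
#' @return Data frame with columns `gene_id`, `median_exon_depth`,
#'   `n_sites`, `max_ratio`, `expressed`, `bin`.
#' @export
presence_table <- function(models, cov, min_expressed_depth = 1,
                           site_aggregate = "mean", flank = 0) {
  rows <- lapply(models, function(t) {
    p <- site_presence(t, cov, min_expressed_depth, site_aggregate, flank)
    data.frame(gene_id = p$gene_id, median_exon_depth = p$median_exon_depth,
               n_sites = p$n_sites, max_ratio = p$max_ratio,
               expressed = p$expressed, bin = p$bin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count genes per presence bin
#'
#' @param presences A presence table from [presence_table()] (or anything
#'   with a `bin` column).
#' @return Named integer vector with counts for `high`, `mid`, `low`,
#'   `not_detected`; sums to the number of input genes.
#' @export
classify_bins <- function(presences) {
  bins <- c("high", "mid", "low", "not_detected")
  b <- if (is.data.frame(presences)) presences$bin
       else vapply(presences, `[[`, character(1), "bin")
  out <- vapply(bins, function(x) sum(b == x), integer(1))
  stopifnot(sum(out) == length(b))
  out
}

#' Simple gene set
#'
#' @param name Non-empty set name.
#' @param members Character vector of gene ids (de-duplicated).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), nzchar(name))
  structure(list(name = name, members = unique(as.character(members))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' with %d member(s)\n", x$name, length(x$members)))
  invisible(x)
}

#' Build the high-presence target set (PT50)
#'
#' Members are the expressed genes whose maximal presence ratio is at least
#' `threshold`, i.e. genes retaining a binding site in more than
#' 100*threshold percent of their expressed mRNA molecules. With the default
#' 0.5 the set equals the union of the `mid` and `high` bins.
#'
#' @param presences A presence table from [presence_table()].
#' @param threshold Ratio cutoff (default 0.5).
#' @param name Set name (default `"PT_50"`).
#' @return A [gene_set].
#' @export
build_pt50 <- function(presences, threshold = 0.5, name = "PT_50") {
  keep <- presences$expressed & !is.na(presences$max_ratio) &
    presences$max_ratio >= threshold
  gene_set(name, presences$gene_id[keep])
}

#' Write / read a presence table as TSV
#'
#' @param presences Presence table ([presence_table()]).
#' @param path File path.
#' @return `path` (writer) or the table (reader).
#' @export
write_presence_tsv <- function(presences, path) {
  write.table(presences, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
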