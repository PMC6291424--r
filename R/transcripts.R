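#' Transcript model with exons, 3'-UTR and miRNA binding sites
#'
#' Coordinates are 0-based half-open throughout. Exons hold the coding /
#' exonic intervals used for the denominator of the presence ratio; the
#' 3'-UTR is a single interval; binding sites must be contained in it.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param exons Data frame with columns `start`, `end` (0-based half-open),
#'   pairwise non-overlapping; sorted by start on construction.
#' @param utr3 Numeric length-2 vector `c(start, end)`.
#' @param sites Data frame with columns `start`, `end`, each interval
#'   contained in `utr3`. May have zero rows.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand = "+",
                             exons, utr3, sites = NULL) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  if (nrow(exons) < 1L) stop(gene_id, ": at least one exon is required")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start < 0) || any(exons$start >= exons$end))
    stop(gene_id, ": exon intervals must satisfy 0 <= start < end")
  if (nrow(exons) > 1L && any(exons$end[-nrow(exons)] > exons$start[-1L]))
    stop(gene_id, ": exons must be pairwise non-overlapping")
  if (length(utr3) != 2L || utr3[1] < 0 || utr3[1] >= utr3[2])
    stop(gene_id, ": utr3 must be c(start, end) with 0 <= start < end")
  if (is.null(sites)) sites <- data.frame(start = numeric(0), end = numeric(0))
  sites <- as.data.frame(sites)
  if (nrow(sites)) {
    sites <- sites[order(sites$start), , drop = FALSE]
    rownames(sites) <- NULL
    if (any(sites$start < utr3[1]) || any(sites$end > utr3[2]))
      stop(gene_id, ": every binding site must lie within the 3'-UTR")
    if (any(sites$start >= sites$end))
      stop(gene_id, ": site intervals must satisfy start < end")
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons,
                 utr3 = unname(as.numeric(utr3)), sites = sites),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s  %d exon(s), 3'-UTR [%d,%d), %d site(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$utr3[1], x$utr3[2], nrow(x$sites)))
  invisible(x)
}

utr_feature_types <- c("three_prime_utr", "three_prime_UTR", "3UTR")

#' Load transcript models from annotation and binding-site files
#'
#' Reads exon and 3'-UTR features from a GTF/GFF3 file, selects one
#' transcript per gene, and assigns BED6 binding sites to the transcript
#' whose 3'-UTR contains them. Sites contained in no selected 3'-UTR are
#' dropped and reported via the `"dropped_sites"` attribute (and a message).
#'
#' When a gene has several annotated transcripts the default rule keeps the
#' transcript with the longest annotated 3'-UTR (ties broken by
#' lexicographic transcript id), maximizing site capture deterministically;
#' `isoform = "first"` keeps the lexicographically first transcript id.
#'
#' @param annotation Path to a GTF/GFF3 file with `exon` and
#'   `three_prime_utr` features.
#' @param sites Path to a BED file of binding-site intervals, named by gene
#'   or site id in column 4.
#' @param isoform Isoform selection rule, `"longest_utr3"` (default) or
#'   `"first"`.
#' @return A list of [transcript_model] objects, with attribute
#'   `dropped_sites` (data frame of sites contained in no 3'-UTR).
#' @export
load_transcripts <- function(annotation, sites,
                             isoform = c("longest_utr3", "first")) {
  isoform <- match.arg(isoform)
  if (!file.exists(annotation)) stop("annotation file not found: ", annotation)
  if (!file.exists(sites)) stop("sites file not found: ", sites)
  gr <- rtracklayer::import(annotation)
  type <- as.character(gr$type)
  keep <- type == "exon" | type %in% utr_feature_types
  gr <- gr[keep]
  type <- type[keep]
  txid <- gr$transcript_id
  if (is.null(txid) && !is.null(gr$Parent))
    txid <- vapply(gr$Parent, function(p) as.character(p)[1], character(1))
  if (is.null(txid)) stop("annotation lacks transcript_id/Parent attributes")
  gid <- gr$gene_id
  if (is.null(gid)) gid <- txid
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = ifelse(type == "exon", "exon", "utr3"),
                   transcript_id = txid, gene_id = gid,
                   stringsAsFactors = FALSE)

  per_tx <- split(df, df$transcript_id)
  tx_info <- lapply(per_tx, function(d) {
    u <- d[d$type == "utr3", , drop = FALSE]
    if (nrow(u) == 0L) return(NULL)
    list(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
         chrom = d$chrom[1], strand = d$strand[1],
         exons = d[d$type == "exon", c("start", "end"), drop = FALSE],
         utr3 = c(min(u$start), max(u$end)))
  })
  tx_info <- Filter(Negate(is.null), tx_info)
  if (length(tx_info) == 0L)
    stop("no transcript with both exon and three_prime_utr features found")

  # one transcript per gene
  genes <- vapply(tx_info, `[[`, character(1), "gene_id")
  chosen <- lapply(split(tx_info, genes), function(cands) {
    ids <- vapply(cands, `[[`, character(1), "transcript_id")
    if (isoform == "longest_utr3") {
      w <- vapply(cands, function(t) diff(t$utr3), numeric(1))
      cands[[order(-w, ids)[1]]]
    } else cands[[order(ids)[1]]]
  })

  bed <- rtracklayer::import(sites)
  site_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bed)),
                        start = GenomicRanges::start(bed) - 1L,
                        end = GenomicRanges::end(bed),
                        stringsAsFactors = FALSE)
  site_df$name <- if (is.null(bed$name))
    rep(NA_character_, nrow(site_df)) else bed$name

  assigned <- rep(FALSE, nrow(site_df))
  models <- lapply(chosen, function(t) {
    hit <- site_df$chrom == t$chrom &
      site_df$start >= t$utr3[1] & site_df$end <= t$utr3[2]
    assigned[hit] <<- TRUE
    transcript_model(t$gene_id, t$transcript_id, t$chrom, t$strand,
                     t$exons, t$utr3,
                     site_df[hit, c("start", "end"), drop = FALSE])
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  dropped <- site_df[!assigned, , drop = FALSE]
  rownames(dropped) <- NULL
  if (nrow(dropped))
    message(nrow(dropped), " binding site(s) contained in no selected 3'-UTR were dropped")
  attr(models, "dropped_sites") <- dropped
  models
}

#' Write transcript models as GTF
#'
#' Emits `exon` and `three_prime_utr` features (1-based inclusive GTF
#' coordinates) so models round-trip through [load_transcripts()].
#'
#' @param models List of [transcript_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(t) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     t$gene_id, t$transcript_id)
    ex <- sprintf("%s\tutrpresence\texon\t%d\t%d\t.\t%s\t.\t%s",
                  t$chrom, t$exons$start + 1L, t$exons$end, t$strand, attrs)
    utr <- sprintf("%s\tutrpresence\tthree_prime_utr\t%d\t%d\t.\t%s\t.\t%s",
                   t$chrom, t$utr3[1] + 1L, t$utr3[2], t$strand, attrs)
    c(ex, utr)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write binding sites of transcript models as BED6
#'
#' @param models List of [transcript_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(models, path) {
  rows <- lapply(models, function(t) {
    if (nrow(t$sites) == 0L) return(NULL)
    data.frame(chrom = t$chrom, start = t$sites$start, end = t$sites$end,
               name = sprintf("%s_site%d", t$gene_id, seq_len(nrow(t$sites))),
               score = 0L, strand = t$strand)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), name = character(),
                                    score = integer(), strand = character())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
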