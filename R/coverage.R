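#' Per-base coverage track
#'
#' A thin wrapper around an [S4Vectors::RleList] holding one run-length
#' encoded depth vector per chromosome. Positions absent from the track have
#' depth 0. All user-facing coordinates are 0-based half-open (BED
#' convention).
#'
#' @param x A `GRanges` with a numeric `score` column (e.g. from a bedGraph),
#'   an `RleList`, or a named list of numeric per-base depth vectors
#'   (position 1 of a vector is genomic position 0).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(x) {
  if (methods::is(x, "GRanges")) {
    if (is.null(x$score)) stop("GRanges input needs a 'score' column")
    if (any(x$score < 0)) stop("coverage depths must be non-negative")
    rle <- GenomicRanges::coverage(x, weight = "score")
  } else if (methods::is(x, "RleList")) {
    rle <- x
  } else if (is.list(x) && !is.null(names(x))) {
    rle <- methods::as(lapply(x, S4Vectors::Rle), "RleList")
  } else {
    stop("cannot build a coverage_track from class ", class(x)[1])
  }
  if (any(vapply(rle, function(r) any(S4Vectors::runValue(r) < 0), logical(1))))
    stop("coverage depths must be non-negative")
  structure(list(rle = rle), class = "coverage_track")
}

#' Read a bedGraph file into a coverage track
#'
#' Four-column bedGraph, 0-based half-open intervals, numeric depth.
#'
#' @param path Path to a bedGraph file.
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  coverage_track(rtracklayer::import(path, format = "bedGraph"))
}

#' Write a coverage track as bedGraph
#'
#' Only non-zero runs are emitted.
#'
#' @param track A [coverage_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- lapply(names(track$rle), function(chrom) {
    r <- track$rle[[chrom]]
    if (length(r) == 0L) return(NULL)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
               depth = vals[keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), depth = numeric())
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-base depths over an interval
#'
#' @param track A [coverage_track].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Numeric vector of length `end - start`; positions beyond the
#'   track (or on unknown chromosomes) are 0.
#' @export
track_depths <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "coverage_track"), start >= 0, start < end)
  n <- end - start
  if (!chrom %in% names(track$rle)) return(numeric(n))
  r <- track$rle[[chrom]]
  len <- length(r)
  if (start >= len) return(numeric(n))
  hi <- min(end, len)
  within <- as.numeric(S4Vectors::window(r, start + 1L, hi))
  c(within, numeric(n - length(within)))
}

#' Scale a coverage track by a positive constant
#'
#' Useful for testing scale invariance of presence ratios.
#' @param track A [coverage_track].
#' @param factor Positive multiplier.
#' @return A new [coverage_track].
#' @export
scale_coverage <- function(track, factor) {
  stopifnot(inherits(track, "coverage_track"), factor > 0)
  coverage_track(methods::as(lapply(track$rle, function(r) r * factor),
                             "RleList"))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track over", length(x$rle), "chromosome(s):",
      paste0(names(x$rle), " (", vapply(x$rle, length, integer(1)), " bp)",
             collapse = ", "), "\n")
  invisible(x)
}
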