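#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @param sets For the writer: a [gene_set], or a list of them.
#' @return Reader: a named list of character vectors. Writer: `path`,
#'   invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad))
    stop("GMT parse error at line ", bad[1], ": need name, description, >=1 gene")
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- vapply(fields, `[[`, character(1), 1L)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "utrpresence", s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write RNK ranked-list files
#'
#' Two tab-separated columns (gene, score), no header, sorted descending by
#' score on read.
#'
#' @param path File path.
#' @param ranked For the writer: a `ranked_list` from [rank_genes()].
#' @return Reader: a `ranked_list`. Writer: `path`, invisibly.
#' @export
read_rnk <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("RNK file needs two columns (gene, score)")
  ranked_list(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

#' @rdname read_rnk
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  write.table(data.frame(gene = ranked$genes, score = ranked$scores),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix and its sample sheet
#'
#' The matrix TSV has genes as rows (first column `gene_id`) and samples as
#' columns; the sample sheet TSV has columns `sample`, `arm`, `timepoint`,
#' `replicate`. An optional presence TSV mirrors the matrix layout with
#' TRUE/FALSE detection calls.
#'
#' @param matrix_path,sheet_path,presence_path File paths.
#' @param m For the writers: an [expression_matrix].
#' @param dir Output directory for [write_expression_tsv()].
#' @param prefix File-name prefix.
#' @return Reader: an [expression_matrix]. Writer: named vector of the
#'   written paths, invisibly.
#' @export
read_expression_tsv <- function(matrix_path, sheet_path,
                                presence_path = NULL) {
  for (p in c(matrix_path, sheet_path, presence_path))
    if (!file.exists(p)) stop("expression input not found: ", p)
  df <- read.delim(matrix_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  sheet <- read.delim(sheet_path, stringsAsFactors = FALSE)
  presence <- NULL
  if (!is.null(presence_path)) {
    pf <- read.delim(presence_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    presence <- as.matrix(pf[, -1, drop = FALSE]) > 0
    rownames(presence) <- pf[[1]]
  }
  expression_matrix(values, sheet, presence)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, dir, prefix = "expr") {
  stopifnot(inherits(m, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.tsv")),
             sheet = file.path(dir, paste0(prefix, "_samples.tsv")),
             presence = file.path(dir, paste0(prefix, "_presence.tsv")))
  write.table(data.frame(gene_id = rownames(m$values), m$values,
                         check.names = FALSE),
              paths["matrix"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$samples, paths["sheet"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = rownames(m$presence), m$presence * 1L,
                         check.names = FALSE),
              paths["presence"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
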