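#' Scan a 3'-UTR sequence for canonical miRNA seed-match sites
#'
#' Finds canonical seed matches of a miRNA in a UTR sequence. A candidate
#' is anchored at a 6mer core: the reverse complement of miRNA positions
#' 2-7. It is extended to
#' \itemize{
#'   \item `8mer`: additional match to position 8 (one base 5' of the core
#'     on the mRNA) and an adenine opposite miRNA position 1 (one base 3'
#'     of the core);
#'   \item `7mer-m8`: the position-8 match only;
#'   \item `7mer-A1`: the A1 adenine only.
#' }
#' Bare 6mer cores are not reported. Overlapping sites are allowed.
#'
#' @param utr_sequence UTR nucleotide string, 5' to 3' (DNA or RNA
#'   alphabet).
#' @param mirna_sequence Mature miRNA string, 5' to 3' (default
#'   [mir31_sequence]).
#' @return Data frame with columns `start`, `end` (0-based half-open,
#'   UTR-relative) and `type`, sorted by `start`.
#' @export
scan_seed_sites <- function(utr_sequence, mirna_sequence = mir31_sequence) {
  utr <- toupper(gsub("U", "T", toupper(utr_sequence)))
  mir <- toupper(gsub("U", "T", toupper(mirna_sequence)))
  if (grepl("[^ACGT]", utr)) stop("invalid character in UTR sequence")
  if (grepl("[^ACGT]", mir)) stop("invalid character in miRNA sequence")
  if (nchar(mir) < 8L) stop("miRNA sequence must be at least 8 nt")

  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  core6 <- rc(substr(mir, 2L, 7L))       # matches miRNA positions 2-7
  m8 <- rc(substr(mir, 8L, 8L))          # base 5' of the core on the mRNA

  empty <- data.frame(start = integer(0), end = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (nchar(utr) < 7L) return(empty)
  hits <- Biostrings::matchPattern(core6, Biostrings::DNAString(utr))
  if (length(hits) == 0L) return(empty)
  j <- Biostrings::start(hits)           # 1-based core start
  n <- nchar(utr)
  has_m8 <- j > 1L & substring(utr, j - 1L, j - 1L) == m8
  has_a1 <- (j + 6L) <= n & substring(utr, j + 6L, j + 6L) == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", NA_character_)))
  keep <- !is.na(type)
  if (!any(keep)) return(empty)
  j <- j[keep]; has_m8 <- has_m8[keep]; has_a1 <- has_a1[keep]
  out <- data.frame(start = (j - 1L) - ifelse(has_m8, 1L, 0L),   # 0-based
                    end = (j - 1L) + 6L + ifelse(has_a1, 1L, 0L),
                    type = type[keep], stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
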