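# Shared builders for small in-memory fixtures.

# transcript with contiguous toy geometry on one chromosome
toy_model <- function(gene_id = "G1", exons = data.frame(start = c(0, 20),
                                                         end = c(10, 40)),
                      utr3 = c(50, 100),
                      sites = data.frame(start = 60, end = 68),
                      chrom = "chr1") {
  transcript_model(gene_id, paste0(gene_id, ".t1"), chrom, "+",
                   exons, utr3, sites)
}

# coverage track from a single per-base depth vector (position 0 onward)
toy_track <- function(depths, chrom = "chr1") {
  coverage_track(setNames(list(depths), chrom))
}

# uniform-depth track long enough for toy_model()
flat_track <- function(depth, len = 120, chrom = "chr1") {
  toy_track(rep(depth, len), chrom)
}

# small two-arm three-timepoint matrix with planted 72 h de-repression
toy_expr <- function(n_targets = 20, n_bg = 80, effect = 0, noise_sd = 0.25,
                     ratios = NULL, seed = 1, n_per_group = 3) {
  if (is.null(ratios)) ratios <- rep(1, n_targets)
  pres <- data.frame(gene_id = sprintf("T%03d", seq_len(n_targets)),
                     max_ratio = ratios, expressed = TRUE)
  spec <- synthetic_spec(n_genes = max(n_targets, 1),
                         effect_size = effect, noise_sd = noise_sd,
                         background_ratio = n_bg / n_targets,
                         n_per_group = n_per_group, seed = seed)
  simulate_knockdown_matrix(pres, spec, seed = seed)
}

# independent O(N) running-walk oracle for the enrichment score
brute_force_es <- function(scores, hit, weight = 0) {
  N <- length(scores)
  k <- sum(hit)
  aw <- abs(scores)^weight
  nr <- sum(aw[hit])
  val <- 0
  best_max <- -Inf
  best_min <- Inf
  for (i in seq_len(N)) {
    val <- if (hit[i]) {
      val + (if (nr > 0) aw[i] / nr else 1 / k)
    } else {
      val - 1 / (N - k)
    }
    if (val > best_max) best_max <- val
    if (val < best_min) best_min <- val
  }
  if (best_max + best_min > 1e-9) best_max
  else if (best_max + best_min < -1e-9) best_min
  else 0
}

# brute-force sliding-window seed-site oracle
brute_force_sites <- function(utr, mir) {
  utr <- gsub("U", "T", toupper(utr))
  mir <- gsub("U", "T", toupper(mir))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  core <- rc(substr(mir, 2, 7))
  m8 <- rc(substr(mir, 8, 8))
  out <- data.frame(start = integer(0), end = integer(0),
                    type = character(0))
  n <- nchar(utr)
  for (j in seq_len(n - 5)) {
    if (substr(utr, j, j + 5) != core) next
    hm8 <- j > 1 && substr(utr, j - 1, j - 1) == m8
    ha1 <- j + 6 <= n && substr(utr, j + 6, j + 6) == "A"
    type <- if (hm8 && ha1) "8mer" else if (hm8) "7mer-m8"
            else if (ha1) "7mer-A1" else NA
    if (is.na(type)) next
    out <- rbind(out, data.frame(start = (j - 1) - as.integer(hm8),
                                 end = (j - 1) + 6 + as.integer(ha1),
                                 type = type))
  }
  rownames(out) <- NULL
  out
}
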