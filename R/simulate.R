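#' Specification for the synthetic-data generators
#'
#' Bundles every tunable of the simulators with defaults chosen to emulate
#' the study design: deep total RNA-seq of resting repeatedly-activated Th1
#' cells (per-base exonic depth around `base_depth`), partial 3'-UTR
#' retention through alternative polyadenylation (`retention`), and a
#' two-arm (antagomir vs scrambled control), three-timepoint microarray
#' experiment where true targets are de-repressed at 72 h with a log2
#' effect proportional to their site-presence ratio.
#'
#' @param n_genes Number of genes.
#' @param exon_count Integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length,utr_length,gene_gap Length ranges in
#'   bases.
#' @param base_depth Mean exonic per-base depth (default 300, typical of
#'   well-expressed transcripts in deep total RNA-seq).
#' @param retention Fraction f in `[0, 1]` of transcripts retaining the
#'   distal 3'-UTR through the binding site; scalar or per-gene vector.
#' @param noise Count noise for coverage: `"poisson"` (default),
#'   `"negative_binomial"`, or `"none"` (exact expected depths).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param n_per_group Samples per arm and timepoint (default 3).
#' @param timepoints Timepoints in hours (default 36, 48, 72).
#' @param effect_size Planted de-repression delta in log2 units at 72 h
#'   (default 1).
#' @param noise_sd Log2 expression noise sd (default 0.25).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression
#'   distribution (default Normal(7, 1), an RMA-like scale).
#' @param background_ratio Non-target genes per target gene (default 4).
#' @param dropout Probability that a presence call is absent (default 0).
#' @param seed Default seed for the generators.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20, exon_count = c(3, 6),
                           exon_length = c(100, 300),
                           intron_length = c(100, 400),
                           utr_length = c(300, 900),
                           gene_gap = c(500, 1000),
                           base_depth = 300, retention = 0.7,
                           noise = c("poisson", "negative_binomial", "none"),
                           nb_dispersion = 0.1,
                           n_per_group = 3, timepoints = c(36, 48, 72),
                           effect_size = 1, noise_sd = 0.25,
                           baseline_mean = 7, baseline_sd = 1,
                           background_ratio = 4, dropout = 0, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_genes >= 1, base_depth >= 0, all(retention >= 0),
            all(retention <= 1), effect_size >= 0, noise_sd > 0,
            dropout >= 0, dropout < 1, n_per_group >= 1)
  for (r in list(exon_count, exon_length, intron_length, utr_length,
                 gene_gap))
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1)
      stop("length ranges must be c(min, max) with 1 <= min <= max")
  if (utr_length[1] < 100L)
    stop("utr_length minimum below 100 cannot host a distal binding site")
  structure(list(n_genes = n_genes, exon_count = exon_count,
                 exon_length = exon_length, intron_length = intron_length,
                 utr_length = utr_length, gene_gap = gene_gap,
                 base_depth = base_depth, retention = retention,
                 noise = noise, nb_dispersion = nb_dispersion,
                 n_per_group = n_per_group, timepoints = timepoints,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 background_ratio = background_ratio, dropout = dropout,
                 seed = seed),
            class = "synthetic_spec")
}

rand_len <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate transcript models with planted binding sites
#'
#' Lays out `n_genes` non-overlapping loci on a synthetic chromosome
#' `chrS`, each with exons, introns and a 3'-UTR containing one planted
#' canonical 8mer binding site for `mirna` in its distal half, and draws a
#' random UTR sequence carrying the planted site (so that
#' [scan_seed_sites()] recovers it). The proximal/distal polyadenylation
#' switch point (midpoint between UTR start and site) is stored as the
#' `"switch_point"` attribute of each model for the coverage simulator.
#'
#' @param spec A [synthetic_spec].
#' @param seed Integer seed (default `spec$seed`).
#' @param mirna miRNA sequence whose seed is planted (default
#'   [mir31_sequence]).
#' @param gene_ids Optional gene id vector (default `G0001`...).
#' @return List with `models` (named list of [transcript_model]) and
#'   `utr_seqs` (named character vector of UTR sequences, 5' to 3').
#' @export
simulate_transcripts <- function(spec, seed = spec$seed,
                                 mirna = mir31_sequence, gene_ids = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  mir <- gsub("U", "T", toupper(mirna))
  site_seq <- paste0(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(mir, 2L, 8L)))), "A")  # 8mer site
  if (is.null(gene_ids))
    gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  stopifnot(length(gene_ids) == spec$n_genes)
  cursor <- 1000
  models <- vector("list", spec$n_genes)
  utr_seqs <- character(spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    n_ex <- rand_len(1, spec$exon_count)
    ex_len <- rand_len(n_ex, spec$exon_length)
    introns <- rand_len(n_ex, spec$intron_length)  # last gap precedes the UTR
    starts <- cursor + c(0, cumsum(ex_len + introns))[seq_len(n_ex)]
    exons <- data.frame(start = starts, end = starts + ex_len)
    utr_len <- rand_len(1, spec$utr_length)
    utr_start <- exons$end[n_ex] + introns[n_ex]
    utr3 <- c(utr_start, utr_start + utr_len)
    # plant one 8mer in the distal half, away from the UTR end
    off_max <- utr_len - nchar(site_seq) - 10L
    off_min <- min(ceiling(utr_len * 0.6), off_max)
    offset <- if (off_min >= off_max) off_min
              else sample(seq(off_min, off_max), 1)
    sites <- data.frame(start = utr_start + offset,
                        end = utr_start + offset + nchar(site_seq))
    seq_chars <- sample(c("A", "C", "G", "T"), utr_len, replace = TRUE)
    seq_chars[seq(offset + 1L, offset + nchar(site_seq))] <-
      strsplit(site_seq, "")[[1]]
    utr_seqs[g] <- paste(seq_chars, collapse = "")
    mod <- transcript_model(gene_ids[g], paste0(gene_ids[g], ".t1"), "chrS",
                            "+", exons, utr3, sites)
    attr(mod, "switch_point") <- floor((utr3[1] + sites$start[1]) / 2)
    models[[g]] <- mod
    cursor <- utr3[2] + rand_len(1, spec$gene_gap)
  }
  names(models) <- gene_ids
  names(utr_seqs) <- gene_ids
  list(models = models, utr_seqs = utr_seqs)
}

#' Write simulated UTR sequences as FASTA
#'
#' @param utr_seqs Named character vector (from
#'   [simulate_transcripts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utr_seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(utr_seqs), path)
  invisible(path)
}

draw_depth <- function(n, mu, spec) {
  if (mu <= 0) return(numeric(n))
  switch(spec$noise,
         poisson = rpois(n, mu),
         negative_binomial = rnbinom(n, mu = mu, size = 1 / spec$nb_dispersion),
         none = rep(mu, n))
}

#' Simulate a coverage track with planted 3'-UTR retention
#'
#' Emulates the measurement model behind the presence ratio: exons and the
#' proximal 3'-UTR (upstream of the polyadenylation switch point) are
#' covered at the gene's full depth, the distal 3'-UTR segment containing
#' the binding site at fraction `f` of it, with per-base count noise.
#'
#' @param models List of [transcript_model] (from
#'   [simulate_transcripts()]).
#' @param spec A [synthetic_spec].
#' @param seed Integer seed (default `spec$seed`).
#' @param depth Per-gene mean exonic depth (default `spec$base_depth`,
#'   recycled).
#' @param retention Per-gene retained fraction f (default
#'   `spec$retention`, recycled).
#' @return A [coverage_track] on `chrS`.
#' @export
simulate_coverage <- function(models, spec, seed = spec$seed,
                              depth = NULL, retention = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- length(models)
  depth <- rep(if (is.null(depth)) spec$base_depth else depth, length.out = n)
  f <- rep(if (is.null(retention)) spec$retention else retention,
           length.out = n)
  total <- max(vapply(models, function(t) t$utr3[2], numeric(1))) + 100
  vec <- numeric(total)
  for (g in seq_len(n)) {
    t <- models[[g]]
    for (i in seq_len(nrow(t$exons))) {
      idx <- seq(t$exons$start[i] + 1L, t$exons$end[i])
      vec[idx] <- draw_depth(length(idx), depth[g], spec)
    }
    sw <- attr(t, "switch_point")
    if (is.null(sw))
      sw <- if (nrow(t$sites)) floor((t$utr3[1] + t$sites$start[1]) / 2)
            else floor(mean(t$utr3))
    prox <- seq(t$utr3[1] + 1L, sw)
    dist <- seq(sw + 1L, t$utr3[2])
    vec[prox] <- draw_depth(length(prox), depth[g], spec)
    vec[dist] <- draw_depth(length(dist), f[g] * depth[g], spec)
  }
  coverage_track(list(chrS = vec))
}

#' Fixture reproducing the published presence-bin counts
#'
#' Builds the 421-gene putative-target fixture: planted retention
#' fractions and depths place exactly 134, 72 and 76 expressed genes in
#' the high (> 0.9), mid ([0.5, 0.9]) and low (< 0.5) bins, and 139 genes
#' have zero coverage (no detectable transcript). Depths are noise-free so
#' the recomputed ratios equal the planted fractions exactly, every ratio
#' at least 0.05 away from a bin boundary; the high/mid union yields the
#' 206-gene PT50 set.
#'
#' @param seed Integer seed (governs locus geometry, group shuffling and
#'   the planted fractions).
#' @return List with `models`, `coverage` (a [coverage_track]), `roster`
#'   (data frame of gene id, planted bin, fraction and depth), and `pt`
#'   (the full 421-gene [gene_set]).
#' @export
make_fig2b_fixture <- function(seed = 1) {
  counts <- c(high = 134L, mid = 72L, low = 76L, not_detected = 139L)
  spec <- synthetic_spec(n_genes = sum(counts), exon_count = c(2, 4),
                         exon_length = c(80, 160),
                         intron_length = c(50, 150),
                         utr_length = c(200, 500), gene_gap = c(100, 300),
                         base_depth = 100, noise = "none", seed = seed)
  sim <- simulate_transcripts(spec, seed = derive_seed(seed, 1),
                              gene_ids = sprintf("PT%04d", seq_len(421)))
  set.seed(derive_seed(seed, 2))
  bin <- sample(rep(names(counts), counts))
  f <- numeric(421)
  f[bin == "high"] <- runif(counts["high"], 0.95, 1.08)
  f[bin == "mid"] <- runif(counts["mid"], 0.55, 0.85)
  f[bin == "low"] <- runif(counts["low"], 0.05, 0.45)
  depth <- ifelse(bin == "not_detected", 0, spec$base_depth)
  coverage <- simulate_coverage(sim$models, spec,
                                seed = derive_seed(seed, 3),
                                depth = depth, retention = pmin(f, 1))
  # retention is capped at 1 for the mixture model; ratios above 1 are
  # planted directly through the site-region depth
  over <- which(f > 1)
  if (length(over)) {
    vec <- as.numeric(coverage$rle[["chrS"]])
    for (g in over) {
      t <- sim$models[[g]]
      idx <- seq(t$sites$start[1] + 1L, t$sites$end[1])
      vec[idx] <- f[g] * depth[g]
    }
    coverage <- coverage_track(list(chrS = vec))
  }
  list(models = sim$models, coverage = coverage,
       roster = data.frame(gene_id = names(sim$models), planted_bin = bin,
                           planted_f = f, planted_depth = depth,
                           stringsAsFactors = FALSE),
       pt = gene_set("PT", names(sim$models)))
}

#' Simulate a two-arm antagomir knockdown expression matrix
#'
#' Baseline log2 expression per gene is Normal(`baseline_mean`,
#' `baseline_sd`) plus Normal(0, `noise_sd`) per sample. Antagomir-arm
#' samples at 72 h additionally receive `effect_size * w_g` for putative
#' targets, where `w_g = min(max_ratio, 1)` - de-repression proportional
#' to the fraction of mRNA molecules carrying the binding site.
#' Non-target background genes (`background_ratio` per target) carry no
#' effect. Presence calls are `TRUE` except for random dropout.
#'
#' @param pt_presence Presence table for the putative targets (columns
#'   `gene_id`, `max_ratio`, `expressed`; from [presence_table()]).
#' @param spec A [synthetic_spec].
#' @param seed Integer seed (default `spec$seed`).
#' @return An [expression_matrix].
#' @export
simulate_knockdown_matrix <- function(pt_presence, spec,
                                      seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$effect_size > 0 && !72 %in% spec$timepoints)
    stop("timepoint 72 is required when effect_size > 0")
  set.seed(seed)
  w <- ifelse(pt_presence$expressed & !is.na(pt_presence$max_ratio),
              pmin(pt_presence$max_ratio, 1), 0)
  n_bg <- round(spec$background_ratio * nrow(pt_presence))
  genes <- c(pt_presence$gene_id, sprintf("BG%04d", seq_len(n_bg)))
  w <- c(w, numeric(n_bg))
  samples <- expand.grid(replicate = seq_len(spec$n_per_group),
                         timepoint = spec$timepoints,
                         arm = c("antagomir_31", "antagomir_scr"),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%dh_r%d",
                            ifelse(samples$arm == "antagomir_31", "A31",
                                   "SCR"),
                            samples$timepoint, samples$replicate)
  samples <- samples[, c("sample", "arm", "timepoint", "replicate")]
  mu <- rnorm(length(genes), spec$baseline_mean, spec$baseline_sd)
  values <- matrix(rnorm(length(genes) * nrow(samples), 0, spec$noise_sd),
                   nrow = length(genes)) + mu
  hit_cols <- samples$arm == "antagomir_31" & samples$timepoint == 72
  values[, hit_cols] <- values[, hit_cols] + spec$effect_size * w
  dimnames(values) <- list(genes, samples$sample)
  presence <- matrix(TRUE, length(genes), nrow(samples),
                     dimnames = dimnames(values))
  if (spec$dropout > 0)
    presence[matrix(runif(length(presence)) < spec$dropout,
                    nrow(presence))] <- FALSE
  expression_matrix(values, samples, presence)
}

#' Simulate a qPCR CT table
#'
#' Reference CT is Normal(20, 0.2); target CT is the reference minus
#' log2(planted relative expression) plus Normal(0, 0.1), so applying
#' [delta_ct()] recovers the planted value on average.
#'
#' @param planted_relative Planted relative expression (scalar).
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @param group Group label stored in the table.
#' @return Data frame with columns `sample`, `target_ct`, `reference_ct`,
#'   `group`.
#' @export
simulate_qpcr <- function(planted_relative = 1, n = 6, seed = 1,
                          group = "treated") {
  stopifnot(planted_relative > 0, n >= 1)
  set.seed(seed)
  ref <- rnorm(n, 20, 0.2)
  target <- ref - log2(planted_relative) + rnorm(n, 0, 0.1)
  data.frame(sample = sprintf("%s_%02d", group, seq_len(n)),
             target_ct = target, reference_ct = ref, group = group,
             stringsAsFactors = FALSE)
}
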