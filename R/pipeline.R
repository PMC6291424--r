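#' End-to-end pipeline configuration
#'
#' Collects all input paths, thresholds and stochastic settings for
#' [run_pipeline()]. Every stochastic step derives its seed from the
#' single top-level `seed` through [derive_seed()] substreams.
#'
#' @param annotation,sites,coverage Paths to the GTF/GFF3 annotation, the
#'   BED binding sites and the bedGraph coverage track.
#' @param expr,sample_sheet,presence_calls Paths to the expression matrix
#'   TSV, its sample sheet, and (optionally) the detection-call TSV.
#' @param out_dir Output directory.
#' @param min_expressed_depth Detectability threshold on median exonic
#'   depth (default 1).
#' @param pt50_threshold Presence-ratio cutoff for the PT50 set (default
#'   0.5).
#' @param expressed_fraction Presence-call fraction for the expressed-gene
#'   filter (default 0.5).
#' @param gsea A [gsea_config].
#' @param B,R Resampling sample sizes (see [pt50_significance()]).
#' @param seed Top-level integer seed (mandatory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, sites, coverage, expr, sample_sheet,
                            presence_calls = NULL, out_dir,
                            min_expressed_depth = 1, pt50_threshold = 0.5,
                            expressed_fraction = 0.5,
                            gsea = gsea_config(), B = 1000, R = 20, seed) {
  stopifnot(pt50_threshold >= 0, min_expressed_depth >= 0,
            expressed_fraction >= 0, expressed_fraction <= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(annotation = annotation, sites = sites, coverage = coverage,
                 expr = expr, sample_sheet = sample_sheet,
                 presence_calls = presence_calls, out_dir = out_dir,
                 min_expressed_depth = min_expressed_depth,
                 pt50_threshold = pt50_threshold,
                 expressed_fraction = expressed_fraction,
                 gsea = gsea, B = B, R = R, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full presence -> PT50 -> GSEA -> resampling pipeline
#'
#' Chains the whole analysis: load transcript models and binding sites,
#' compute the presence table from coverage, bin genes and build the PT50
#' set, filter expressed genes from detection calls, run GSEA for the full
#' putative-target set (PT) and PT50 at every timepoint, and run the
#' random-subset resampling significance test at 72 h. All artifacts
#' (presence TSV, GMTs, per-timepoint GSEA JSON, resampling JSON, run
#' manifest with config echo, seed, package version and input checksums)
#' are written under `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config].
#' @return The report bundle (named list of all results and artifact
#'   paths), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  inputs <- c(annotation = cfg$annotation, sites = cfg$sites,
              coverage = cfg$coverage, expr = cfg$expr,
              sample_sheet = cfg$sample_sheet,
              presence_calls = cfg$presence_calls)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  models <- load_transcripts(cfg$annotation, cfg$sites)
  message("loaded ", length(models), " transcript model(s)")
  cov <- read_bedgraph(cfg$coverage)
  pres <- presence_table(models, cov, cfg$min_expressed_depth)
  bins <- classify_bins(pres)
  message("presence bins: ", paste(names(bins), bins, sep = "=",
                                   collapse = ", "),
          " (expressed: ", sum(pres$expressed), ")")
  pt <- gene_set("PT", pres$gene_id)
  pt50 <- build_pt50(pres, cfg$pt50_threshold)
  message("PT50 members: ", length(pt50$members))

  expr <- read_expression_tsv(cfg$expr, cfg$sample_sheet,
                              cfg$presence_calls)
  mismatch <- setdiff(pt$members, rownames(expr$values))
  if (length(mismatch) == length(pt$members))
    stop("identifier mismatch: no annotation gene is in the expression ",
         "matrix (e.g. ", paste(head(mismatch, 3), collapse = ", "), ")")
  expressed <- presence_filter(expr, cfg$expressed_fraction)
  message(length(expressed$members), " of ", nrow(expr$values),
          " genes pass the expressed-gene filter")
  keep <- rownames(expr$values) %in% expressed$members
  expr_f <- expression_matrix(expr$values[keep, , drop = FALSE],
                              expr$samples,
                              expr$presence[keep, , drop = FALSE])

  timepoints <- sort(unique(expr_f$samples$timepoint))
  gsea_res <- lapply(timepoints, function(tp)
    run_gsea(expr_f, list(pt, pt50), cfg$gsea,
             seed = derive_seed(cfg$seed, 100 + tp), timepoint = tp))
  names(gsea_res) <- paste0("t", timepoints, "h")
  for (tp in names(gsea_res))
    message(tp, ": ", paste(vapply(gsea_res[[tp]], function(r)
      sprintf("%s NES %.2f p %.3g", r$set_name, r$NES, r$nominal_p),
      character(1)), collapse = "; "))

  resamp <- pt50_significance(pt, pt50, expr_f, B = cfg$B, R = cfg$R,
                              config = cfg$gsea,
                              seed = derive_seed(cfg$seed, 7000),
                              timepoint = 72)

  paths <- c(presence = file.path(cfg$out_dir, "presence.tsv"),
             pt = file.path(cfg$out_dir, "pt.gmt"),
             pt50 = file.path(cfg$out_dir, "pt50.gmt"),
             resampling = file.path(cfg$out_dir, "resampling.json"),
             manifest = file.path(cfg$out_dir, "manifest.json"))
  write_presence_tsv(pres, paths["presence"])
  write_gmt(pt, paths["pt"])
  write_gmt(pt50, paths["pt50"])
  for (tp in names(gsea_res))
    write_gsea_json(gsea_res[[tp]],
                    file.path(cfg$out_dir, paste0("gsea_", tp, ".json")))
  write_resampling_json(resamp, paths["resampling"])

  manifest <- list(package = "utrpresence",
                   version = as.character(utils::packageVersion("utrpresence")),
                   seed = cfg$seed,
                   config = lapply(unclass(cfg), function(x)
                     if (inherits(x, "gsea_config")) unclass(x) else x),
                   input_md5 = as.list(tools::md5sum(inputs)),
                   bin_counts = as.list(bins),
                   n_expressed_rnaseq = sum(pres$expressed),
                   n_pt50 = length(pt50$members),
                   n_expressed_array = length(expressed$members))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(presence = pres, bins = bins, pt = pt, pt50 = pt50,
                 expressed = expressed, gsea = gsea_res,
                 resampling = resamp, paths = paths, manifest = manifest))
}
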