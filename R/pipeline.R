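# End-to-end orchestration over the simulated study: generator -> design
# -> screen -> context -> thermo -> model, writing every stage's outputs
# plus a machine-readable run manifest. Deterministic given the seed.

#' Run the full pipeline on a simulated study
#'
#' Generates a study with known ground truth, designs and filters
#' candidate sites, processes the screen into efficacy records, calls
#' poly(A) sites and translation efficiencies, compares effective vs
#' ineffective windows thermodynamically, trains and evaluates the
#' random-forest classifier, and writes all stage outputs as TSV plus a
#' JSON manifest recording seed, thresholds and filter attrition counts.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed for every source of randomness.
#' @param config [simConfig()].
#' @param thresholds [labelThresholds()].
#' @param grubbs_alpha Grubbs test level.
#' @param n_repeats model segmentation repeats (kept small here; raise
#'   for production estimates).
#' @param n_tags 3'-end tags per gene.
#' @return invisibly, a list with the in-memory stage results
#'   (`study`, `records`, `hotspots`, `pas`, `te`, `ddg`, `model`,
#'   `manifest`).
#' @export
runPipeline <- function(out_dir, seed = 1, config = simConfig(),
                        thresholds = labelThresholds(),
                        grubbs_alpha = 0.2, n_repeats = 20,
                        n_tags = 10000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()

  # --- simulate
  study <- simulateStudy(config, seed = seed)
  writeFastaRna(genesToFasta(study$genes),
                file.path(out_dir, "merged_transcripts.fasta"))
  writeTsv(genesToAnnotation(study$genes),
           file.path(out_dir, "annotation.tsv"))
  writeTsv(study$measurements, file.path(out_dir, "measurements.tsv"))

  # --- design: enumerate and filter each gene against the others
  fasta <- genesToFasta(study$genes)
  reports <- lapply(names(fasta), function(g) {
    cand <- enumerateCandidates(fasta[[g]], gene_id = g)
    fr <- filterCandidates(cand, transcriptome = fasta[names(fasta) != g])
    log[[paste0("filter_", g)]] <<- table(
      factor(fr$report$reason,
             levels = c("gc_content", "homopolymer",
                        "off_target_homology")), useNA = "ifany")
    fr$report
  })
  writeTsv(do.call(rbind, reports), file.path(out_dir, "candidates.tsv"))

  # --- screen
  records <- processScreen(study$measurements, thresholds, grubbs_alpha)
  writeTsv(records, file.path(out_dir, "efficacy_records.tsv"))
  asym <- config$scaffolds[["permissive"]]
  native <- records[records$scaffold == asym & records$assay == "native", ]
  hotspots <- do.call(rbind, lapply(names(study$genes), function(g) {
    sites <- study$panel[study$panel$gene_id == g, ]
    sub <- native[native$site_id %in% sites$site_id, ]
    hits <- sites$start[match(
      sub$site_id[sub$label == "effective"], sites$site_id)]
    hs <- findHotspots(hits,
                       mergedLength(study$genes[[g]]$merged))
    if (nrow(hs)) cbind(gene_id = g, hs) else NULL
  }))
  if (!is.null(hotspots))
    writeTsv(hotspots, file.path(out_dir, "hotspots.tsv"))

  # --- context: poly(A) sites and translation efficiency
  pas <- do.call(rbind, lapply(seq_along(study$genes), function(i) {
    gn <- study$genes[[i]]
    tags <- simulateTags(gn, n_tags = n_tags,
                         seed = childSeed(seed, 50 + i))
    callPolyASites(tags)
  }))
  writePasBed(pas, file.path(out_dir, "polya_sites.tsv"))
  te <- do.call(rbind, lapply(seq_along(study$genes), function(i) {
    gn <- study$genes[[i]]
    cv <- simulateCoverage(gn, rna_tpm = 10,
                           translation_efficiency =
                             gn$translation_efficiency,
                           seed = childSeed(seed, 80 + i))
    data.frame(gene_id = gn$gene_id,
               translation_efficiency =
                 ribosomeDensity(cv$tpm$ribo_tpm, cv$tpm$rna_tpm))
  }))
  writeTsv(te, file.path(out_dir, "translation_efficiency.tsv"))

  # --- thermo: effective vs ineffective 50-mer windows, native assay
  win <- vapply(seq_len(nrow(study$panel)), function(i) {
    g <- study$panel$gene_id[i]
    common50mer(study$genes[[g]]$merged, study$panel$start[i])$window
  }, character(1))
  full <- nchar(win) == 50
  lab <- native$label[match(study$panel$site_id, native$site_id)]
  eff <- win[full & lab == "effective"]
  ineff <- win[full & lab == "ineffective"]
  ddg <- if (length(eff) >= 2 && length(ineff) >= 2)
    groupDdg(eff, ineff) else NULL
  if (!is.null(ddg)) writeTsv(ddg, file.path(out_dir, "ddg_profile.tsv"))

  # --- model: reporter assay, permissive scaffold
  rep_rec <- records[records$scaffold == asym &
                     records$assay == "reporter", ]
  lab_rep <- rep_rec$label[match(study$panel$site_id, rep_rec$site_id)]
  model <- repeatPipeline(win[full], lab_rep[full],
                          scheme = splitScheme(n_repeats = n_repeats),
                          seed = childSeed(seed, 999), do_cv = FALSE)
  writeTsv(data.frame(repeat_id = seq_along(model$holdout_aucpr_adj),
                      holdout_aucpr_adj = model$holdout_aucpr_adj),
           file.path(out_dir, "model_holdout.tsv"))

  manifest <- list(
    seed = seed,
    thresholds = thresholds,
    grubbs_alpha = grubbs_alpha,
    n_repeats = n_repeats,
    n_tags = n_tags,
    config = config[setdiff(names(config), "scaffolds")],
    scaffolds = as.list(config$scaffolds),
    n_sites = nrow(study$panel),
    n_records = nrow(records),
    filter_attrition = lapply(log, as.list),
    package_version = as.character(utils::packageVersion("siRNAscreen")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, records = records, hotspots = hotspots,
                 pas = pas, te = te, ddg = ddg, model = model,
                 manifest = manifest))
}
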