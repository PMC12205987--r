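# Synthetic-data generator. Every downstream stage of the pipeline can be
# exercised against a recoverable ground truth: multi-isoform genes with an
# alternative exon and two poly(A) sites, siRNA panels with planted hotspot
# intervals, scaffold-specific penalties and isoform-dilution ceilings,
# replicate plate measurements with Gaussian percent-scale noise, multinomial
# 3'-end tag data, and coverage/TPM tables with known translation
# efficiencies. All generators are deterministic for a fixed seed.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with validation.
#' Defaults describe the study conditions the pipeline is built for:
#' four genes, three replicates, percent-scale replicate noise of SD 10
#' (the screening assays' observed average SDs are 9.1--11.5 percent),
#' two poly(A) sites with 70/30 usage, and per-gene translation
#' efficiencies spanning 0.6--2.6.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene two isoforms when `isoform_dilution > 0`,
#'   otherwise one; kept as a field for reporting.
#' @param utr5_range,orf_range,utr3_range nt length ranges (min, max) for
#'   the 5'UTR, ORF and 3'UTR of the merged transcript.
#' @param usage_fractions per-gene poly(A)-site usage fractions, 5'->3';
#'   must sum to 1.
#' @param hotspot_count planted hotspots per gene (1--3): the first two
#'   lie in constitutively expressed regions (early ORF; the ORF/3'UTR
#'   boundary upstream of the first poly(A) site), the third in the
#'   3'UTR downstream of the first poly(A) site, where isoform dilution
#'   masks native efficacy.
#' @param hotspot_width nt width of each planted hotspot interval.
#' @param hotspot_au_bias A/U fraction of hotspot-interval sequence
#'   (background is uniform, 0.5): effective regions carry the AU-rich,
#'   thermodynamically less stable sequence context characteristic of
#'   accessible target sites, giving the sequence classifier a learnable
#'   signal.
#' @param scaffold_penalty additive percent-expression shift applied to the
#'   restrictive scaffold on a designated subset of sites.
#' @param restrictive_fraction fraction of sites subject to the scaffold
#'   penalty.
#' @param isoform_dilution expression fraction carried by the
#'   alternative-exon-skipping isoform (per-site fraction of expression
#'   lacking sites inside that exon).
#' @param replicate_sd percent-scale SD of replicate measurement noise.
#' @param n_replicates replicates per site/scaffold/assay.
#' @param snp_rate per-position probability of an isoform sequence
#'   disagreement (drives `?` consensus positions).
#' @param accessibility_sd lognormal SD of the per-site native
#'   inaccessibility factor (>= 1) degrading native silencing.
#' @param translation_efficiencies per-gene ribosome densities
#'   (ribo TPM / RNA TPM), recycled across genes.
#' @param site_spacing nt spacing of the ground-truth site panel.
#' @return object of class `SimConfig` (a validated list).
#' @export
simConfig <- function(n_genes = 4,
                      isoforms_per_gene = 2,
                      utr5_range = c(100, 180),
                      orf_range = c(700, 1100),
                      utr3_range = c(900, 1400),
                      usage_fractions = c(0.7, 0.3),
                      hotspot_count = 3,
                      hotspot_width = 240,
                      hotspot_au_bias = 0.75,
                      scaffold_penalty = 30,
                      restrictive_fraction = 0.6,
                      isoform_dilution = 0.2,
                      replicate_sd = 10,
                      n_replicates = 3,
                      snp_rate = 0.002,
                      accessibility_sd = 0.5,
                      translation_efficiencies = c(2.6, 1.6, 1.0, 0.6),
                      site_spacing = 40) {
  stopifnot(n_genes >= 1, hotspot_width > 0, n_replicates >= 1,
            site_spacing >= 1, hotspot_count >= 1, hotspot_count <= 3)
  if (abs(sum(usage_fractions) - 1) > 1e-9)
    stop("usage_fractions must sum to 1")
  if (any(usage_fractions < 0)) stop("usage_fractions must be nonnegative")
  if (replicate_sd < 0) stop("replicate_sd must be >= 0")
  if (any(c(utr5_range, orf_range, utr3_range) <= 0))
    stop("all region lengths must be positive")
  if (isoform_dilution < 0 || isoform_dilution >= 1)
    stop("isoform_dilution must be in [0, 1)")
  if (hotspot_au_bias <= 0 || hotspot_au_bias >= 1)
    stop("hotspot_au_bias must be in (0, 1)")
  cfg <- list(
    n_genes = as.integer(n_genes),
    isoforms_per_gene = as.integer(isoforms_per_gene),
    utr5_range = utr5_range, orf_range = orf_range, utr3_range = utr3_range,
    usage_fractions = usage_fractions,
    hotspot_count = as.integer(hotspot_count),
    hotspot_width = as.integer(hotspot_width),
    hotspot_au_bias = hotspot_au_bias,
    scaffold_penalty = scaffold_penalty,
    restrictive_fraction = restrictive_fraction,
    isoform_dilution = isoform_dilution,
    replicate_sd = replicate_sd,
    n_replicates = as.integer(n_replicates),
    snp_rate = snp_rate,
    accessibility_sd = accessibility_sd,
    translation_efficiencies = translation_efficiencies,
    site_spacing = as.integer(site_spacing),
    scaffolds = c(permissive = "asym_omef", restrictive = "asym_omerich")
  )
  class(cfg) <- "SimConfig"
  cfg
}

.randSeq <- function(n, au_bias = 0.5) {
  p <- c(au_bias / 2, (1 - au_bias) / 2, (1 - au_bias) / 2, au_bias / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

.plantMotif <- function(seq, motif, at) {
  substring(seq, at, at + nchar(motif) - 1L) <- motif
  seq
}

#' Generate synthetic gene models and sequences
#'
#' Each gene gets a merged transcript with 5'UTR/ORF/3'UTR, four exons of
#' which the second (inside the ORF) is alternative, two isoforms (the
#' minor one skipping the alternative exon, carrying `isoform_dilution` of
#' expression), poly(A) sites inside the 3'UTR with planted `AAUAAA`
#' motifs ~30 nt upstream, and planted hotspot intervals: one in the
#' constitutive early ORF and one in the 3'UTR downstream of the first
#' poly(A) site.
#'
#' @param config [simConfig()] object.
#' @param seed integer seed; the gene set is deterministic given it.
#' @return object of class `SimGeneSet`: a list of per-gene models, each
#'   with elements `gene_id`, `merged` ([MergedTranscript-class]),
#'   `exons`, `isoforms`, `isoform_seqs`, `pas`, `hotspots`,
#'   `translation_efficiency`.
#' @export
simulateGenes <- function(config = simConfig(), seed = 1) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(seed, {
    genes <- lapply(seq_len(config$n_genes), function(g) {
      u5 <- sample(config$utr5_range[1]:config$utr5_range[2], 1)
      orf <- sample(config$orf_range[1]:config$orf_range[2], 1)
      u3 <- sample(config$utr3_range[1]:config$utr3_range[2], 1)
      L <- u5 + orf + u3
      sq <- .randSeq(L)

      # exon skeleton: e2 is the alternative exon inside the ORF
      x1 <- u5 + floor(orf * 0.45)
      x2 <- u5 + floor(orf * 0.65)
      x3 <- u5 + orf + floor(u3 * 0.3)
      exons <- data.frame(
        exon_id = paste0("E", 1:4),
        start = c(1L, x1 + 1L, x2 + 1L, x3 + 1L),
        end = c(x1, x2, x3, L),
        alternative = c(FALSE, TRUE, FALSE, FALSE)
      )

      # poly(A) sites in the 3'UTR; PAS signal motif ~30 nt upstream
      n_pas <- length(config$usage_fractions)
      pas_pos <- if (n_pas == 1) L - 25L else
        round(seq(u5 + orf + floor(u3 * 0.55), L - 25L, length.out = n_pas))
      pas <- data.frame(position = as.integer(pas_pos),
                        usage = config$usage_fractions)

      # hotspots: two in constitutive regions, one diluted (after PAS 1);
      # hotspot intervals get AU-rich (less stable) sequence
      anchors <- c(u5 + floor(orf * 0.05),
                   u5 + orf - floor(config$hotspot_width / 2),
                   pas_pos[1] + 40L)
      hotspots <- IRanges::IRanges(
        start = anchors[seq_len(config$hotspot_count)],
        width = config$hotspot_width)
      for (k in seq_along(hotspots))
        sq <- .plantMotif(sq, .randSeq(config$hotspot_width,
                                       config$hotspot_au_bias),
                          IRanges::start(hotspots)[k])
      for (p in pas_pos) sq <- .plantMotif(sq, "AAUAAA", p - 30L)

      # isoforms: major carries all exons, minor skips the alternative exon
      if (config$isoform_dilution > 0) {
        isoforms <- data.frame(
          isoform_id = c("I1", "I2"),
          fraction = c(1 - config$isoform_dilution, config$isoform_dilution))
        iso_exons <- list(I1 = exons$exon_id, I2 = c("E1", "E3", "E4"))
      } else {
        isoforms <- data.frame(isoform_id = "I1", fraction = 1)
        iso_exons <- list(I1 = exons$exon_id)
      }

      # minor-isoform SNPs drive '?' consensus positions
      snps <- integer(0)
      iso_seqs <- stats::setNames(
        rep(NA_character_, nrow(isoforms)), isoforms$isoform_id)
      for (i in seq_len(nrow(isoforms))) {
        keep <- exons$exon_id %in% iso_exons[[isoforms$isoform_id[i]]]
        pieces <- substring(sq, exons$start[keep], exons$end[keep])
        iso_seqs[i] <- paste(pieces, collapse = "")
      }
      if (nrow(isoforms) > 1 && config$snp_rate > 0) {
        shared <- setdiff(seq_len(L),
                          seq(exons$start[2], exons$end[2]))
        shared <- setdiff(shared, unlist(lapply(pas_pos - 30L,
                                                function(p) p:(p + 5L))))
        n_snp <- stats::rbinom(1, length(shared), config$snp_rate)
        if (n_snp > 0) {
          snps <- sort(sample(shared, n_snp))
          # mutate the minor isoform at those merged positions
          alt_len <- exons$end[2] - exons$start[2] + 1L
          iso2 <- strsplit(iso_seqs["I2"], "")[[1]]
          for (p in snps) {
            p2 <- if (p > exons$end[2]) p - alt_len else p
            iso2[p2] <- sample(setdiff(RNA_BASES, iso2[p2]), 1)
          }
          iso_seqs["I2"] <- paste(iso2, collapse = "")
        }
      }

      cons <- strsplit(sq, "")[[1]]
      cons[snps] <- "?"
      merged <- MergedTranscript(
        geneId = paste0("G", g), sequence = sq,
        blocks = IRanges::IRanges(exons$start, exons$end),
        regions = stats::setNames(
          IRanges::IRanges(start = c(1L, u5 + 1L, u5 + orf + 1L),
                           end = c(u5, u5 + orf, L)),
          c("five_prime_utr", "orf", "three_prime_utr")),
        consensus = paste(cons, collapse = ""))

      te <- config$translation_efficiencies[
        (g - 1L) %% length(config$translation_efficiencies) + 1L]
      list(gene_id = paste0("G", g), merged = merged, exons = exons,
           isoforms = isoforms, isoform_exons = iso_exons,
           isoform_seqs = iso_seqs, snps = snps, pas = pas,
           hotspots = hotspots, translation_efficiency = te)
    })
    names(genes) <- vapply(genes, `[[`, "", "gene_id")
    class(genes) <- "SimGeneSet"
    genes
  })
}

#' Ground-truth site panel over simulated genes
#'
#' Sites of 20 nt are placed at regular spacing along each merged
#' transcript, starting in the ORF, so that consecutive panel sites are
#' close enough to chain into hotspots when both are hits.
#'
#' @param genes a `SimGeneSet`.
#' @param spacing nt between consecutive site starts.
#' @return data.frame with `gene_id`, `site_id`, `start`, `target_seq`,
#'   `region`.
#' @export
panelFromGenes <- function(genes, spacing = 40) {
  do.call(rbind, lapply(genes, function(gn) {
    sq <- as.character(mergedSeq(gn$merged))
    L <- nchar(sq)
    reg <- regionBounds(gn$merged)
    starts <- seq.int(IRanges::start(reg["orf"]), L - 19L, by = spacing)
    data.frame(
      gene_id = gn$gene_id,
      site_id = sprintf("%s_%d", gn$gene_id, starts),
      start = as.integer(starts),
      target_seq = substring(sq, starts, starts + 19L),
      region = regionOfPosition(gn$merged, starts),
      row.names = NULL)
  }))
}

#' Generate per-site ground-truth expression
#'
#' Reporter truth reflects RISC competence only: sites inside planted
#' hotspot intervals are intrinsically effective, other sites are not.
#' Native truth composes the reporter truth with (i) a per-site
#' inaccessibility factor >= 1 and (ii) the fraction of gene expression
#' lacking the site (alternative-exon skipping and upstream poly(A)-site
#' usage), which floors native expression: a site absent from all
#' expressed transcripts has native truth 100. The restrictive scaffold
#' additionally shifts a designated subset of sites up by
#' `scaffold_penalty` percent.
#'
#' @param genes `SimGeneSet` from [simulateGenes()].
#' @param panel site panel (e.g. [panelFromGenes()]).
#' @param config [simConfig()].
#' @param seed integer seed.
#' @return object of class `SimTruth`: data.frame with one row per
#'   site x scaffold carrying `reporter_truth` and `native_truth`
#'   (percent of untreated), plus `in_hotspot`, `dilution`, `penalized`;
#'   gene-level truths are in `attr(, "genes")`.
#' @export
simulateTruth <- function(genes, panel, config = simConfig(), seed = 1) {
  withSeed(seed, {
    per_site <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
      gn <- genes[[panel$gene_id[i]]]
      s <- panel$start[i]; e <- s + 19L
      in_hs <- any(s >= IRanges::start(gn$hotspots) &
                   s <= IRanges::end(gn$hotspots))
      reporter <- if (in_hs) stats::runif(1, 10, 30) else stats::runif(1, 55, 95)
      # fraction of expression lacking the site
      alt <- gn$exons[gn$exons$alternative, , drop = FALSE]
      d_exon <- if (nrow(alt) && s >= alt$start[1] && e <= alt$end[1])
        config$isoform_dilution else 0
      d_pas <- sum(gn$pas$usage[gn$pas$position < e])
      d <- 1 - (1 - d_exon) * (1 - d_pas)
      inacc <- exp(abs(stats::rnorm(1, 0, config$accessibility_sd)))
      native <- min(100, 100 * d + (1 - d) * min(100, reporter * inacc))
      data.frame(site_id = panel$site_id[i], gene_id = panel$gene_id[i],
                 start = s, in_hotspot = in_hs, dilution = d,
                 reporter_base = reporter, native_base = native)
    }))
    penal <- stats::runif(nrow(per_site)) < config$restrictive_fraction
    truth <- do.call(rbind, lapply(seq_along(config$scaffolds), function(k) {
      sc <- config$scaffolds[k]
      shift <- if (names(config$scaffolds)[k] == "restrictive")
        ifelse(penal, config$scaffold_penalty, 0) else 0
      data.frame(per_site[c("site_id", "gene_id", "start",
                            "in_hotspot", "dilution")],
                 scaffold = unname(sc),
                 penalized = penal & names(config$scaffolds)[k] == "restrictive",
                 reporter_truth = pmin(100, per_site$reporter_base + shift),
                 native_truth = pmin(100, per_site$native_base + shift))
    }))
    rownames(truth) <- NULL
    attr(truth, "genes") <- data.frame(
      gene_id = names(genes),
      translation_efficiency = vapply(genes, `[[`, 0,
                                      "translation_efficiency"))
    attr(truth, "hotspots") <- lapply(genes, `[[`, "hotspots")
    attr(truth, "pas_usage") <- lapply(genes, `[[`, "pas")
    class(truth) <- c("SimTruth", "data.frame")
    truth
  })
}

#' Simulate replicate plate measurements from ground truth
#'
#' Emits a raw-signal table in the layout [processScreen()] consumes:
#' sample, untreated and blank wells for each scaffold x assay, with two
#' channels per well (target `signal` and normalization `norm_signal`).
#' Percent-scale Gaussian noise of SD `replicate_sd`, truncated at 0, is
#' applied per replicate; with `replicate_sd = 0` the normalized percents
#' recover the truth exactly.
#'
#' @param truth `SimTruth` from [simulateTruth()].
#' @param config [simConfig()].
#' @param seed integer seed.
#' @return data.frame with `site_id`, `scaffold`, `assay`, `well_role`,
#'   `replicate`, `signal`, `norm_signal`.
#' @export
simulateScreen <- function(truth, config = simConfig(), seed = 1) {
  blank_t <- 100; blank_n <- 50; gain <- 1000; norm_span <- 1000
  withSeed(seed, {
    rows <- list()
    for (assay in c("native", "reporter")) {
      tcol <- paste0(assay, "_truth")
      for (sc in unique(truth$scaffold)) {
        sub <- truth[truth$scaffold == sc, ]
        for (r in seq_len(config$n_replicates)) {
          p <- pmax(0, sub[[tcol]] + stats::rnorm(nrow(sub), 0,
                                                  config$replicate_sd))
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = sub$site_id, scaffold = sc, assay = assay,
            well_role = "sample", replicate = r,
            signal = blank_t + gain * p / 100,
            norm_signal = blank_n + norm_span)
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = "UNT", scaffold = sc, assay = assay,
            well_role = "untreated", replicate = r,
            signal = blank_t + gain,
            norm_signal = blank_n + norm_span)
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = "BLANK", scaffold = sc, assay = assay,
            well_role = "blank", replicate = r,
            signal = blank_t, norm_signal = blank_n)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate 3'-end tag data for one gene
#'
#' Tags are drawn multinomially across the gene's poly(A) sites according
#' to their usage fractions, with Gaussian positional jitter. Most tags at
#' a genuine poly(A) position carry a terminal 3' adenosine run of >= 4;
#' every poly(A) site whose expected tag count is >= 10 is guaranteed at
#' least one such tag.
#'
#' @param gene one element of a `SimGeneSet`.
#' @param n_tags total tags to draw (conserved in the output).
#' @param jitter_sd SD of positional jitter in nt.
#' @param seed integer seed.
#' @return data.frame with `gene_id`, `position`, `count`,
#'   `terminal_a_run` (max run among tags at that position).
#' @export
simulateTags <- function(gene, n_tags = 10000, jitter_sd = 2, seed = 1) {
  stopifnot(n_tags >= 1)
  withSeed(seed, {
    pas <- gene$pas
    assign_pas <- sample(seq_len(nrow(pas)), n_tags, replace = TRUE,
                         prob = pas$usage)
    pos <- pas$position[assign_pas] +
      round(stats::rnorm(n_tags, 0, jitter_sd))
    pos <- pmax(1L, as.integer(pos))
    arun <- ifelse(stats::runif(n_tags) < 0.8,
                   sample(4:8, n_tags, replace = TRUE),
                   sample(0:3, n_tags, replace = TRUE))
    cnt <- tapply(rep(1L, n_tags), pos, sum)
    mx <- tapply(arun, pos, max)
    out <- data.frame(gene_id = gene$gene_id,
                      position = as.integer(names(cnt)),
                      count = as.integer(cnt),
                      terminal_a_run = as.integer(mx))
    # guarantee terminal-A evidence at well-supported poly(A) sites
    for (i in seq_len(nrow(pas))) {
      if (pas$usage[i] * n_tags >= 10) {
        near <- which(abs(out$position - pas$position[i]) <= 3 * jitter_sd + 1)
        if (length(near) && max(out$terminal_a_run[near]) < 4) {
          peak <- near[which.max(out$count[near])]
          out$terminal_a_run[peak] <- 5L
        }
      }
    }
    out <- out[order(out$position), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate coverage tracks and a TPM table for one gene
#'
#' Per-base RNA counts follow the isoform mixture (positions in the
#' alternative exon and downstream of used poly(A) sites get
#' proportionally less coverage); ribosome-protected counts cover the ORF.
#' The TPM table encodes the translation efficiency exactly:
#' `ribo_tpm = translation_efficiency * rna_tpm`.
#'
#' @param gene one element of a `SimGeneSet`.
#' @param rna_tpm gene-level RNA abundance (TPM).
#' @param translation_efficiency ribosome density to encode (> 0).
#' @param depth mean per-base read depth of the RNA track.
#' @param seed integer seed.
#' @return list with `coverage` (data.frame `position`, `rna_count`,
#'   `ribo_count`) and `tpm` (data.frame `gene_id`, `rna_tpm`, `ribo_tpm`).
#' @export
simulateCoverage <- function(gene, rna_tpm = 10,
                             translation_efficiency = 1,
                             depth = 50, seed = 1) {
  stopifnot(translation_efficiency > 0)
  withSeed(seed, {
    L <- mergedLength(gene$merged)
    frac <- rep(1, L)
    alt <- gene$exons[gene$exons$alternative, , drop = FALSE]
    if (nrow(alt))
      frac[alt$start[1]:alt$end[1]] <- 1 - sum(
        gene$isoforms$fraction[
          !vapply(gene$isoform_exons, function(e) alt$exon_id[1] %in% e,
                  TRUE)[gene$isoforms$isoform_id]])
    for (i in seq_len(nrow(gene$pas))) {
      p <- gene$pas$position[i]
      if (p < L) frac[(p + 1L):L] <- frac[(p + 1L):L] - gene$pas$usage[i]
    }
    frac <- pmax(frac, 0)
    reg <- regionBounds(gene$merged)
    orf <- seq(IRanges::start(reg["orf"]), IRanges::end(reg["orf"]))
    ribo_lambda <- rep(0, L)
    ribo_lambda[orf] <- depth * translation_efficiency
    cov <- data.frame(
      position = seq_len(L),
      rna_count = stats::rpois(L, depth * frac),
      ribo_count = stats::rpois(L, ribo_lambda * frac[seq_len(L)]))
    list(coverage = cov,
         tpm = data.frame(gene_id = gene$gene_id, rna_tpm = rna_tpm,
                          ribo_tpm = translation_efficiency * rna_tpm))
  })
}

#' Run the whole generator: genes, panel, truth and measurements
#'
#' @param config [simConfig()].
#' @param seed master integer seed; stage seeds are derived from it.
#' @return list with `genes`, `panel`, `truth`, `measurements`, `config`.
#' @export
simulateStudy <- function(config = simConfig(), seed = 1) {
  genes <- simulateGenes(config, seed = childSeed(seed, 1))
  panel <- panelFromGenes(genes, spacing = config$site_spacing)
  truth <- simulateTruth(genes, panel, config, seed = childSeed(seed, 2))
  meas <- simulateScreen(truth, config, seed = childSeed(seed, 3))
  list(genes = genes, panel = panel, truth = truth, measurements = meas,
       config = config)
}

#' Export simulated gene models as a GTF-like annotation table
#'
#' Coordinates are the merged-transcript coordinates (the simulation's
#' "genome"), 1-based inclusive, so [mergeIsoforms()] on this annotation
#' plus the merged FASTA round-trips the gene models.
#'
#' @param genes `SimGeneSet`.
#' @return data.frame with `gene_id`, `isoform_id`, `feature`, `start`,
#'   `end`.
#' @export
genesToAnnotation <- function(genes) {
  do.call(rbind, lapply(genes, function(gn) {
    reg <- regionBounds(gn$merged)
    do.call(rbind, lapply(seq_len(nrow(gn$isoforms)), function(i) {
      iso <- gn$isoforms$isoform_id[i]
      keep <- gn$exons$exon_id %in% gn$isoform_exons[[iso]]
      ex <- data.frame(gene_id = gn$gene_id, isoform_id = iso,
                       feature = "exon",
                       start = gn$exons$start[keep],
                       end = gn$exons$end[keep])
      rg <- data.frame(gene_id = gn$gene_id, isoform_id = iso,
                       feature = names(reg),
                       start = IRanges::start(reg),
                       end = IRanges::end(reg))
      rbind(ex, rg)
    }))
  }))
}

#' Export merged transcript sequences as an RNAStringSet
#' @param genes `SimGeneSet`.
#' @return named [Biostrings::RNAStringSet].
#' @export
genesToFasta <- function(genes) {
  out <- Biostrings::RNAStringSet(vapply(
    genes, function(gn) as.character(mergedSeq(gn$merged)), character(1)))
  names(out) <- names(genes)
  out
}
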