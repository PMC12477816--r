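# End-to-end orchestration: a one-call synthetic demo running every stage
# (simulate -> curate -> annotate -> landscape -> gene context -> regulation)
# plus stage entry points reusable on real inputs. The exported functions are
# the pipeline interface; scripts/acceptance.R drives them from the shell.

.density_in <- function(features, region) {
  bp <- .union_bp(region)
  if (bp == 0) return(NA_real_)
  sum(.bp_in_regions(features, region)) / bp
}

#' TE density within each compartment label (exact, base-level)
#'
#' @param annotation A `repeat_annotation`.
#' @param compartment_map data.frame with `chrom`, `start`, `end`, `label`.
#' @return Named numeric vector of TE base fractions per label.
#' @export
compartment_te_density <- function(annotation, compartment_map) {
  labels <- unique(compartment_map$label)
  vapply(stats::setNames(labels, labels), function(l) {
    .density_in(annotation$te_copies,
                compartment_map[compartment_map$label == l, , drop = FALSE])
  }, numeric(1))
}

#' Run the full synthetic end-to-end demonstration
#'
#' Simulates a genome under the configured study conditions, then runs every
#' analysis stage of the package on the simulated files' in-memory
#' equivalents: library curation, copy annotation, windowed landscape and
#' compartment statistics, gene-context analyses and sRNA/peak association
#' statistics. Deterministic given `seed`.
#'
#' @param seed Integer seed driving all randomness.
#' @param dir Optional directory; when given, simulation inputs and stage
#'   outputs are written there with a manifest.
#' @param config Optional `simulation_config` (defaults to the study
#'   conditions at 5 Mb).
#' @param curate Run the (alignment-heavy) library curation stage.
#' @return A list of stage results; see the methods vignette for a guided
#'   tour.
#' @export
run_demo <- function(seed = 1, dir = NULL, config = NULL, curate = TRUE) {
  cfg <- config %||% simulation_config(seed = seed)
  cfg$seed <- as.integer(seed)
  sim <- plant_genome(cfg)
  cl <- chrom_lengths(sim$genome)
  res <- list(config = cfg, sim = sim)

  ## --- library curation ------------------------------------------------
  if (curate) {
    noisy <- add_library_redundancy(sim$library, cfg$redundant_variants)
    cl80 <- cluster_library(noisy, 0.8, 0.8)
    rec <- reclassify_by_cluster(cl80, noisy)
    cl95 <- cluster_library(rec$library, 0.95, 0.95)
    dd <- deduplicate(rec$library, cl95)
    res$curation <- list(n_input = nrow(noisy), n_clusters80 = length(cl80$clusters),
                         n_reclassified = nrow(rec$changes),
                         removed = dd$removed, library = dd$library)
  }

  ## --- copy annotation --------------------------------------------------
  cons_len <- stats::setNames(sim$library$length, sim$library$id)
  copies <- merge_fragments(sim$hits, cons_len)
  annotation <- resolve_precedence(copies, sim$tandem)
  res$summary <- summarize_by_superfamily(annotation, sum(cl))
  res$genome_te_fraction <- .union_bp(copies) / sum(cl)
  res$frac_bp_lt5 <- divergence_fraction_below(copies, 5)
  res$landscape_table <- divergence_landscape(copies)

  ## --- landscape --------------------------------------------------------
  comp <- sim$compartments
  w100 <- assign_compartment(make_windows(cl, 100000), comp)
  cds_iv <- sim$models$features[sim$models$features$type == "CDS", , drop = FALSE]
  w100 <- window_density(annotation, w100, cds = cds_iv)
  comp_labels <- intersect(c("autosome", "PAR", "SDR_male"), unique(comp$label))
  res$compartment_test <- NULL
  for (width in c(100000, 50000, 10000)) {  # fall back for scaled-down genomes
    ww <- window_density(annotation, assign_compartment(make_windows(cl, width), comp))
    main <- ww[!ww$partial & ww$compartment %in% comp_labels, ]
    if (all(table(factor(main$compartment, levels = comp_labels)) >= 2)) {
      res$compartment_test <- compare_compartments(main$te_density, main$compartment)
      res$compartment_test$window_bp <- width
      break
    }
  }
  res$compartment_density <- compartment_te_density(annotation, comp)
  res$cut_copy <- lapply(stats::setNames(c("autosome", "PAR", "SDR_male"),
                                         c("autosome", "PAR", "SDR_male")),
                         function(l) {
    cut_copy_ratio(annotation, comp[comp$label == l, , drop = FALSE])
  })
  res$enrichment <- superfamily_enrichment(annotation, comp)
  w5 <- make_windows(cl, 5000, anchors = sim$anchors)
  res$subtelomere <- subtelomere_profile(window_density(annotation, w5))
  res$windows <- w100

  ## --- gene context -----------------------------------------------------
  filt <- filter_te_genes(sim$models, copies)
  part <- partition_site_classes(filt$models, cl)
  res$site_class_density <- site_class_density(annotation, part)
  copies <- assign_copy_site_class(copies, part)
  res$copies <- copies
  res$copy_properties <- compare_copy_properties(copies)
  interg <- copies[startsWith(copies$site_class, "intergenic"), , drop = FALSE]
  res$nearest_te <- nearest_te_distance(filt$models, interg)
  ratios <- genic_te_cds_ratio(filt$models, copies)
  set.seed(cfg$seed + 1L)
  x <- ifelse(is.na(ratios$ratio), 0, ratios$ratio)
  tpm <- data.frame(gene_id = ratios$gene_id,
                    GA = simulate_correlated_tpm(x, 0.14),
                    gametes = simulate_correlated_tpm(x, 0.13),
                    pSP = simulate_correlated_tpm(x, 0.20))
  res$expression_vs_te <- expression_vs_te(ratios, tpm)
  intr <- copies[copies$site_class == "intron", , drop = FALSE]
  spans <- .gene_spans(filt$models)
  host <- rep(NA_character_, nrow(intr))
  for (ch in unique(intr$chrom)) {
    ii <- which(intr$chrom == ch)
    sp <- spans[spans$chrom == ch, , drop = FALSE]
    if (!nrow(sp)) next
    h <- IRanges::findOverlaps(.ir(intr[ii, , drop = FALSE]), .ir(sp), select = "first")
    host[ii] <- sp$gene_id[h]
  }
  intr$gene_id <- host
  intr <- intr[!is.na(intr$gene_id), , drop = FALSE]
  res$age_mosaic <- tryCatch(
    age_mosaic(intr, sim$truth$genes[, c("gene_id", "rank")]),
    error = function(e) NULL)

  ## --- regulation -------------------------------------------------------
  pk <- simulate_peaks(sim$truth$copies, cfg$peak_plan, cfg$seed + 2L, cl)
  stages <- cfg$srna_plan$stages
  reps <- cfg$srna_plan$replicates
  covered <- draw_srna_coverage(sim$truth$copies, cfg$srna_plan, cfg$seed + 9L,
                                peak_copy_ids = pk$provenance$copy_id)
  reads_by_sample <- list()
  for (si in seq_along(stages)) {
    for (ri in seq_len(reps)) {
      nm <- sprintf("%s_rep%d", stages[si], ri)
      reads_by_sample[[nm]] <- filter_reads_by_length(
        simulate_reads(sim$truth$copies, cfg$srna_plan, stages[si],
                       cfg$seed + 10L * si + ri, genome = sim$genome,
                       covered_ids = covered))
    }
  }
  cm <- count_matrix(reads_by_sample, copies)
  res$prefiltered_counts <- prefilter_counts(cm$counts, 10)
  cpm_all <- cpm(cm$counts, cm$library_sizes)
  cpm_by_stage <- vapply(stages, function(st) {
    rowMeans(cpm_all[, grep(paste0("^", st, "_"), colnames(cpm_all)), drop = FALSE])
  }, numeric(nrow(copies)))
  res$assoc <- association_table(copies, cpm_by_stage, pk$peaks)
  res$srna_flags <- flag_srna_associated(cpm_by_stage, copies$intact)
  res$intersection <- intersection_stats(res$assoc)
  all_reads <- do.call(rbind, reads_by_sample)
  res$profile5 <- strand_and_5prime_profile(all_reads, copies, sim$genome)
  ## synthetic normalized signal: background 0.5, peak bodies 2.0
  genome_iv <- data.frame(chrom = names(cl), start = 0L, end = as.integer(cl),
                          stringsAsFactors = FALSE)
  pk_red <- reduce_intervals(pk$peaks)
  bg <- subtract_intervals(genome_iv, pk_red)
  signal <- rbind(cbind(bg, value = 0.5),
                  cbind(pk_red, value = 2.0))
  res$metaprofile <- metaprofile(signal, copies,
                                 groups = ifelse(copies$intact, "intact", "non_intact"),
                                 flank_bp = 2000)
  fm <- consensus_feature_map(cfg$family_plan)
  res$consensus_coverage <- consensus_feature_coverage(
    all_reads, attr(copies, "fragments"), fm, cfg$family_plan)
  res$family_panel <- simulate_family_panel(150, seed = cfg$seed + 3L)
  res$expression_correlations <- expression_correlations(res$family_panel)
  res$peaks <- pk

  if (!is.null(dir)) {
    paths <- write_simulation(sim, dir)
    write_broadpeak(pk$peaks, file.path(dir, "peaks.broadPeak"))
    for (nm in names(reads_by_sample)) {
      write_alignments_bed(reads_by_sample[[nm]],
                           file.path(dir, sprintf("reads_%s.bed", nm)))
    }
    write_bedgraph(signal[order(signal$chrom, signal$start), ],
                   file.path(dir, "signal.bedGraph"))
    thresholds <- c("intact_divergence=20", "intact_coverage=0.8",
                    "tandem_reclass=0.60", "cluster_identity=0.8/0.95",
                    "proximal_bp=500", "copy_proximal_frac=0.01",
                    "transcript_te_filter=0.70", "read_lengths=20-24",
                    "count_prefilter=10", "windows=100kb/50kb/5kb",
                    "metaprofile=10bp/10kb/1kb")
    write_tsv(res$summary, file.path(dir, "superfamily_summary.tsv"),
              comments = thresholds)
    write_tsv(res$site_class_density, file.path(dir, "site_class_density.tsv"),
              comments = thresholds)
    write_copies_bed(copies, file.path(dir, "te_copies.bed"))
    files <- list.files(dir, full.names = TRUE)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    manifest <- manifest[manifest$file != "manifest.tsv", ]
    write_tsv(manifest, file.path(dir, "manifest.tsv"),
              comments = c(sprintf("seed=%d", cfg$seed), thresholds))
    res$manifest <- manifest
  }
  res
}
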