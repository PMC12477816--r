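# Gene-context analyses: site-class partitioning, TE-gene proximity, genic
# TE:CDS ratios, expression association and the gene-age contingency analysis.

.gene_spans <- function(models) {
  tx <- models$transcripts
  sp <- split(tx, tx$gene_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Remove TE-derived transcripts before gene-context analyses
#'
#' A transcript is removed when strictly more than `threshold` of its CDS bp
#' intersects TE copies (genes carried by TEs must not enter gene analyses);
#' a gene is retained while at least one of its transcripts survives.
#'
#' @param models A `gene_models` object.
#' @param copies A `te_copies` data.frame.
#' @param threshold Removal threshold on the CDS TE-overlap fraction.
#' @return List with `models` (filtered), `removed_transcripts` (data.frame
#'   with the offending fraction) and `removed_genes`.
#' @export
filter_te_genes <- function(models, copies, threshold = 0.70) {
  feats <- models$features
  tx_ids <- unique(models$transcripts$transcript_id)
  frac <- stats::setNames(numeric(length(tx_ids)), tx_ids)
  for (t_id in tx_ids) {
    cds <- feats[feats$transcript_id == t_id & feats$type == "CDS", , drop = FALSE]
    total <- .union_bp(cds)
    frac[t_id] <- if (total == 0) 0 else
      .total_bp(intersect_intervals(cds, copies)) / total
  }
  drop_tx <- names(frac)[frac > threshold]
  tx <- models$transcripts[!models$transcripts$transcript_id %in% drop_tx, , drop = FALSE]
  drop_genes <- setdiff(models$genes$gene_id, tx$gene_id)
  out <- list(
    genes = models$genes[!models$genes$gene_id %in% drop_genes, , drop = FALSE],
    transcripts = tx,
    features = feats[!feats$transcript_id %in% drop_tx, , drop = FALSE])
  class(out) <- "gene_models"
  list(models = out,
       removed_transcripts = data.frame(transcript_id = drop_tx,
                                        te_fraction = unname(frac[drop_tx]),
                                        stringsAsFactors = FALSE),
       removed_genes = drop_genes)
}

#' Partition every genomic base into a site class
#'
#' Disjoint labelling with precedence CDS > 5'UTR > 3'UTR > intron >
#' intergenic; intergenic bases within `proximal_bp` of any gene boundary
#' (either flank of either neighbour, gene span taken UTR-inclusive from the
#' outermost transcript boundaries) are proximal, the rest distal. The labels
#' tile each chromosome exactly.
#'
#' @param models A `gene_models` object.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param proximal_bp Gene-proximal distance threshold (bp).
#' @return data.frame of class `site_class_partition` with `chrom`, `start`,
#'   `end`, `class` in {CDS, UTR5, UTR3, intron, intergenic_proximal,
#'   intergenic_distal}.
#' @export
partition_site_classes <- function(models, chrom_lengths, proximal_bp = 500) {
  feats <- models$features
  pick <- function(type) reduce_intervals(feats[feats$type %in% type, , drop = FALSE])
  cds <- pick("CDS")
  utr5 <- subtract_intervals(pick("five_prime_UTR"), cds)
  genic <- reduce_intervals(rbind(cds, utr5))
  utr3 <- subtract_intervals(pick("three_prime_UTR"), genic)
  genic <- reduce_intervals(rbind(genic, utr3))
  intron <- subtract_intervals(pick("intron"), genic)
  genic <- reduce_intervals(rbind(genic, intron))
  genome <- data.frame(chrom = names(chrom_lengths), start = 0L,
                       end = as.integer(chrom_lengths), stringsAsFactors = FALSE)
  intergenic <- subtract_intervals(genome, genic)
  spans <- if (nrow(models$genes)) .gene_spans(models) else NULL
  if (!is.null(spans) && nrow(spans)) {
    flanks <- rbind(
      data.frame(chrom = spans$chrom, start = pmax(0L, spans$start - proximal_bp),
                 end = spans$start, stringsAsFactors = FALSE),
      data.frame(chrom = spans$chrom, start = spans$end,
                 end = pmin(chrom_lengths[spans$chrom], spans$end + proximal_bp),
                 stringsAsFactors = FALSE))
    flanks <- flanks[flanks$end > flanks$start, , drop = FALSE]
    proximal <- intersect_intervals(intergenic, flanks)
  } else {
    proximal <- .empty_intervals()
  }
  distal <- subtract_intervals(intergenic, proximal)
  lab <- function(df, class) if (nrow(df)) cbind(df, class = class, stringsAsFactors = FALSE) else NULL
  out <- do.call(rbind, list(lab(cds, "CDS"), lab(utr5, "UTR5"), lab(utr3, "UTR3"),
                             lab(intron, "intron"),
                             lab(proximal, "intergenic_proximal"),
                             lab(distal, "intergenic_distal")))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_class_partition", "data.frame")
  out
}

#' Repeat density by site class
#'
#' @param annotation A `repeat_annotation`.
#' @param partition A `site_class_partition`.
#' @return data.frame with `class`, `bp`, `te_fraction`, `tandem_fraction`,
#'   `nonrepeat_fraction`.
#' @export
site_class_density <- function(annotation, partition) {
  classes <- unique(partition$class)
  out <- do.call(rbind, lapply(classes, function(cl) {
    reg <- partition[partition$class == cl, , drop = FALSE]
    bp <- .total_bp(reg)
    te <- sum(.bp_in_regions(annotation$te_copies, reg))
    td <- sum(.bp_in_regions(annotation$tandem, reg))
    data.frame(class = cl, bp = bp,
               te_fraction = if (bp) te / bp else 0,
               tandem_fraction = if (bp) td / bp else 0,
               nonrepeat_fraction = if (bp) (bp - te - td) / bp else 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign each TE copy to a site class
#'
#' Copies overlapping genic bases take the majority genic label (CDS > UTR5 >
#' UTR3 > intron on ties). Fully intergenic copies are proximal when strictly
#' more than `proximal_min_frac` of their bases lie in gene-proximal
#' intergenic sequence, else distal.
#'
#' @param copies A `te_copies` data.frame.
#' @param partition A `site_class_partition`.
#' @param proximal_min_frac Strict fraction threshold for the proximal call.
#' @return `copies` with a `site_class` column.
#' @export
assign_copy_site_class <- function(copies, partition, proximal_min_frac = 0.01) {
  genic_classes <- c("CDS", "UTR5", "UTR3", "intron")
  ov <- sapply(genic_classes, function(cl) {
    .bp_in_regions(partition[partition$class == cl, , drop = FALSE], copies)
  })
  ov <- matrix(ov, nrow = nrow(copies), dimnames = list(NULL, genic_classes))
  prox_bp <- .bp_in_regions(partition[partition$class == "intergenic_proximal", , drop = FALSE],
                            copies)
  len <- copies$end - copies$start
  site <- character(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    if (sum(ov[i, ]) > 0) {
      site[i] <- genic_classes[which.max(ov[i, ])]
    } else {
      site[i] <- if (prox_bp[i] / len[i] > proximal_min_frac)
        "intergenic_proximal" else "intergenic_distal"
    }
  }
  copies$site_class <- site
  copies
}

#' Compare TE copy length and divergence between site classes
#'
#' Kruskal-Wallis plus Dunn's test (or Wilcoxon for two classes) on copy
#' lengths and divergences, optionally stratified by intact status and with
#' a divergence ceiling (degraded copies excluded as in landscape plots).
#'
#' @param copies A `te_copies` with a `site_class` column.
#' @param classes Site classes to compare.
#' @param max_divergence Optional cutoff; copies with divergence above it are
#'   excluded from the divergence comparison.
#' @param by_intact Also return the comparisons stratified by intact status.
#' @return List with `length` and `divergence` test reports (see
#'   [compare_compartments()]), plus `by_intact` when requested.
#' @export
compare_copy_properties <- function(copies,
                                    classes = c("intron", "intergenic_proximal",
                                                "intergenic_distal"),
                                    max_divergence = NULL, by_intact = FALSE) {
  d <- copies[copies$site_class %in% classes, , drop = FALSE]
  if (nrow(d) == 0) stop("no copies in the requested site classes")
  ddiv <- if (is.null(max_divergence)) d else
    d[d$divergence_pct <= max_divergence, , drop = FALSE]
  out <- list(length = compare_compartments(d$length, d$site_class),
              divergence = compare_compartments(ddiv$divergence_pct, ddiv$site_class))
  if (by_intact) {
    out$by_intact <- lapply(split(d, d$intact), function(s) {
      list(length = compare_compartments(s$length, s$site_class))
    })
  }
  out
}

#' Distance from each gene to its nearest (intergenic) TE copy
#'
#' Distance is the minimum gap between the gene span and any supplied copy
#' (0 for abutting or overlapping copies); genes are binned as within 500 bp,
#' 500 bp-1 kb, 1-2 kb, and beyond 2 kb. Intronic copies should be excluded
#' from `copies` by the caller (e.g. via `site_class`).
#'
#' @param models A `gene_models` object.
#' @param copies TE copies to measure against.
#' @param max_bp Bin boundary for the open-ended last bin.
#' @return data.frame with `gene_id`, `distance`, `bin`, `nearest_intact`.
#' @export
nearest_te_distance <- function(models, copies, max_bp = 2000) {
  spans <- .gene_spans(models)
  out <- data.frame(gene_id = spans$gene_id, distance = Inf,
                    nearest_intact = NA, stringsAsFactors = FALSE)
  for (ch in unique(spans$chrom)) {
    gi <- which(spans$chrom == ch)
    cp <- copies[copies$chrom == ch, , drop = FALSE]
    if (nrow(cp) == 0) next
    hits <- IRanges::distanceToNearest(.ir(spans[gi, , drop = FALSE]), .ir(cp))
    qh <- S4Vectors::queryHits(hits)
    out$distance[gi[qh]] <- S4Vectors::mcols(hits)$distance
    out$nearest_intact[gi[qh]] <- cp$intact[S4Vectors::subjectHits(hits)]
  }
  brk <- c(-1, 500, 1000, max_bp, Inf)
  labs <- c("within_500bp", "500bp_1kb", "1_2kb", "beyond_2kb")
  out$bin <- labs[pmin(findInterval(pmin(out$distance, 8.9e15), brk + 1e-9), 4L)]
  out
}

#' Genic TE to CDS nucleotide ratio per gene
#'
#' Ratio of TE bases inside the gene span but outside CDS (introns and UTRs)
#' to CDS bases. Mono-exonic genes are excluded (reported with a reason).
#'
#' @param models A `gene_models` object.
#' @param copies A `te_copies` data.frame.
#' @return data.frame with `gene_id`, `cds_bp`, `genic_te_bp`, `ratio`,
#'   `mono_exonic`.
#' @export
genic_te_cds_ratio <- function(models, copies) {
  spans <- .gene_spans(models)
  feats <- models$features
  n_exons <- tapply(feats$type[feats$type == "exon"],
                    feats$transcript_id[feats$type == "exon"], length)
  tx <- models$transcripts
  gene_max_exons <- tapply(n_exons[tx$transcript_id], tx$gene_id, max, na.rm = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
    g <- spans[i, ]
    cds <- feats[feats$gene_id == g$gene_id & feats$type == "CDS", , drop = FALSE]
    cds_bp <- .union_bp(cds)
    span_df <- g[, c("chrom", "start", "end")]
    noncds <- subtract_intervals(span_df, cds)
    te_bp <- .total_bp(intersect_intervals(noncds, copies))
    mono <- isTRUE(gene_max_exons[[g$gene_id]] <= 1)
    data.frame(gene_id = g$gene_id, cds_bp = cds_bp, genic_te_bp = te_bp,
               ratio = if (mono || cds_bp == 0) NA_real_ else te_bp / cds_bp,
               mono_exonic = mono, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Spearman correlation between genic TE content and gene expression
#'
#' Expression enters as log2(TPM + 1); ties receive average ranks. Mono-exonic
#' genes (NA ratio) are dropped.
#'
#' @param ratios Output of [genic_te_cds_ratio()].
#' @param tpm data.frame with `gene_id` and one numeric TPM column per stage.
#' @return data.frame with `stage`, `rho`, `p_value`, `n`.
#' @export
expression_vs_te <- function(ratios, tpm) {
  stages <- setdiff(names(tpm), "gene_id")
  m <- merge(ratios[!is.na(ratios$ratio), c("gene_id", "ratio")], tpm, by = "gene_id")
  out <- do.call(rbind, lapply(stages, function(st) {
    x <- m$ratio
    y <- log2(m[[st]] + 1)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(stage = st, rho = unname(ct$estimate), p_value = ct$p.value,
               n = nrow(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expression summarized by nearest-TE distance bin
#'
#' Groups genes by their distance bin to the nearest (intergenic) TE copy
#' and summarizes log2(TPM + 1) per bin and stage, optionally split by the
#' intact status of the nearest copy.
#'
#' @param nearest Output of [nearest_te_distance()].
#' @param tpm data.frame with `gene_id` and one numeric TPM column per stage.
#' @param by_intact Split bins by whether the nearest copy is intact.
#' @return data.frame with `stage`, `bin`, (`nearest_intact`), `n`,
#'   `median_log2_tpm`, `q1`, `q3`.
#' @export
expression_by_nearest_te <- function(nearest, tpm, by_intact = FALSE) {
  stages <- setdiff(names(tpm), "gene_id")
  m <- merge(nearest, tpm, by = "gene_id")
  keys <- if (by_intact) list(bin = m$bin, nearest_intact = m$nearest_intact) else
    list(bin = m$bin)
  out <- list()
  for (st in stages) {
    y <- log2(m[[st]] + 1)
    agg <- stats::aggregate(y, by = keys, FUN = function(v) {
      c(n = length(v), stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE))
    })
    res <- data.frame(stage = st, agg[setdiff(names(agg), "x")],
                      n = agg$x[, 1], q1 = agg$x[, 2],
                      median_log2_tpm = agg$x[, 3], q3 = agg$x[, 4],
                      stringsAsFactors = FALSE)
    out[[st]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-age by intronic-TE-superfamily contingency analysis
#'
#' Pearson chi-square on the superfamily x phylostratum-rank table of intronic
#' TE insertions, with standardized residuals to show which cells drive the
#' association; cells with expected counts below 5 are flagged.
#'
#' @param intronic_copies TE copies with a `gene_id` column (their host gene).
#' @param gene_ranks data.frame with `gene_id` and `rank` (1 = oldest ...
#'   11 = species-specific), or a named vector.
#' @return List with `table`, `chi_square`, `df`, `p_value`, `stdres`,
#'   `low_expected` (count of cells with expected < 5).
#' @export
age_mosaic <- function(intronic_copies, gene_ranks) {
  if (is.data.frame(gene_ranks)) {
    gene_ranks <- stats::setNames(gene_ranks$rank, gene_ranks$gene_id)
  }
  rk <- gene_ranks[intronic_copies$gene_id]
  keep <- !is.na(rk)
  tab <- table(superfamily = intronic_copies$classification[keep], rank = rk[keep])
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin (need two non-empty levels per dimension)")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, chi_square = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, stdres = ct$stdres,
       low_expected = sum(ct$expected < 5))
}
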