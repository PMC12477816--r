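# sRNA and histone-mark association statistics over TE copies: containment
# counting, CPM, prefiltering, association flags, strand/5' profiles, peak
# overlap, conditional intersection, scale-regions metaprofiles and
# consensus-feature coverage.

#' Filter reads by length (inclusive bounds)
#'
#' @param reads Alignments data.frame (see [read_alignments()]).
#' @param min_nt,max_nt Inclusive length bounds (default 20-24 nt, the
#'   small-RNA window used throughout).
#' @return Filtered alignments.
#' @export
filter_reads_by_length <- function(reads, min_nt = 20, max_nt = 24) {
  reads[reads$read_length >= min_nt & reads$read_length <= max_nt, , drop = FALSE]
}

#' Count read alignments over TE copies (full containment, multi-overlap)
#'
#' featureCounts-style semantics: an alignment is counted for a copy iff its
#' interval is fully contained in the copy interval (fracOverlap = 1); a
#' contained alignment is counted for every containing copy
#' (allowMultiOverlap); every alignment row of a multi-mapped read counts
#' (countMultiMappingReads). Edge-overlapping reads contribute nothing.
#'
#' @param reads Alignments data.frame.
#' @param copies A `te_copies` data.frame.
#' @return Integer vector of counts along rows of `copies`.
#' @export
count_reads_over_copies <- function(reads, copies) {
  counts <- integer(nrow(copies))
  if (nrow(reads) == 0 || nrow(copies) == 0) return(counts)
  for (ch in unique(copies$chrom)) {
    ci <- which(copies$chrom == ch)
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(rd) == 0) next
    hits <- IRanges::findOverlaps(.ir(rd), .ir(copies[ci, , drop = FALSE]),
                                  type = "within")
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = length(ci))
    counts[ci] <- counts[ci] + tab
  }
  counts
}

#' Counts per million mapped reads
#'
#' @param counts Numeric vector or matrix of counts.
#' @param library_size Total filtered mapped reads (per column for a matrix).
#' @return CPM on the same shape.
#' @export
cpm <- function(counts, library_size) {
  if (is.matrix(counts)) {
    sweep(counts, 2, library_size, "/") * 1e6
  } else {
    counts / library_size * 1e6
  }
}

#' Count matrix over copies for several samples
#'
#' @param reads_by_sample Named list of alignment data.frames.
#' @param copies A `te_copies` data.frame.
#' @return List with `counts` (copies x samples matrix, rownames = copy ids)
#'   and `library_sizes` (distinct mapped reads per sample).
#' @export
count_matrix <- function(reads_by_sample, copies) {
  counts <- vapply(reads_by_sample, count_reads_over_copies, integer(nrow(copies)),
                   copies = copies)
  counts <- matrix(counts, nrow = nrow(copies),
                   dimnames = list(copies$copy_id, names(reads_by_sample)))
  libs <- vapply(reads_by_sample, function(r) length(unique(r$read_id)), numeric(1))
  list(counts = counts, library_sizes = libs)
}

#' Prefilter a count matrix on minimum read support
#'
#' Keeps loci with at least `min_total` reads summed across all samples (the
#' differential-analysis prefilter); `per_sample = TRUE` applies the stricter
#' reading of at least `min_total` in every sample.
#'
#' @param counts Count matrix (loci x samples).
#' @param min_total Minimum read support (inclusive).
#' @param per_sample Apply the threshold per sample instead of to row sums.
#' @return The filtered matrix.
#' @export
prefilter_counts <- function(counts, min_total = 10, per_sample = FALSE) {
  keep <- if (per_sample) apply(counts >= min_total, 1, all) else
    rowSums(counts) >= min_total
  counts[keep, , drop = FALSE]
}

#' Flag sRNA-associated copies and compare accumulation by intact status
#'
#' A copy is sRNA-associated when its CPM is positive in every stage (the
#' stage-union reading is available via `rule = "any_stage"`). Association
#' proportions are reported overall and by intact status, and total CPM is
#' compared between intact and non-intact copies with a Wilcoxon rank-sum
#' test.
#'
#' @param cpm_by_stage Matrix of CPM values, copies x stages.
#' @param intact Logical vector along rows.
#' @param rule "every_stage" or "any_stage".
#' @return List with `associated` (logical), `prop_all`, `prop_intact`,
#'   `prop_nonintact`, `wilcoxon_p`.
#' @export
flag_srna_associated <- function(cpm_by_stage, intact,
                                 rule = c("every_stage", "any_stage")) {
  rule <- match.arg(rule)
  cpm_by_stage <- as.matrix(cpm_by_stage)
  associated <- if (rule == "every_stage") apply(cpm_by_stage > 0, 1, all) else
    apply(cpm_by_stage > 0, 1, any)
  total <- rowSums(cpm_by_stage)
  wp <- if (length(unique(intact)) == 2) {
    stats::wilcox.test(total[intact], total[!intact], correct = TRUE,
                       exact = FALSE)$p.value
  } else NA_real_
  list(associated = associated,
       prop_all = mean(associated),
       prop_intact = mean(associated[intact]),
       prop_nonintact = mean(associated[!intact]),
       wilcoxon_p = wp)
}

#' Strand and 5' nucleotide profile of reads over TE copies
#'
#' Sense means the read strand equals the strand of a containing copy; the 5'
#' base is read from the genome at the biological 5' end (reverse-complemented
#' for minus-strand reads), so a 5' T on the genome corresponds to a 5' U on
#' the small RNA.
#'
#' @param reads Alignments data.frame.
#' @param copies A `te_copies` data.frame (features the reads are profiled
#'   against).
#' @param genome A `DNAStringSet`.
#' @return List with `by_length` (read_length, n, sense_fraction),
#'   `five_prime` (base, fraction) and `u5_fraction`.
#' @export
strand_and_5prime_profile <- function(reads, copies, genome) {
  sense <- rep(NA, nrow(reads))
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    cp <- copies[copies$chrom == ch, , drop = FALSE]
    if (nrow(cp) == 0) next
    hits <- IRanges::findOverlaps(.ir(reads[ri, , drop = FALSE]), .ir(cp),
                                  type = "within", select = "first")
    has <- !is.na(hits)
    sense[ri[has]] <- reads$strand[ri[has]] == cp$strand[hits[has]]
  }
  base5 <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    seq_ch <- genome[[ch]]
    plus <- reads$strand[ri] == "+"
    pos <- ifelse(plus, reads$start[ri] + 1L, reads$end[ri])
    b <- strsplit(as.character(Biostrings::extractAt(
      seq_ch, IRanges::IRanges(pos, pos))), "")
    b <- vapply(b, `[`, character(1), 1)
    b[!plus] <- chartr("ACGT", "TGCA", b[!plus])
    base5[ri] <- b
  }
  in_copy <- !is.na(sense)
  by_len <- do.call(rbind, lapply(split(which(in_copy), reads$read_length[in_copy]),
                                  function(idx) {
    data.frame(read_length = reads$read_length[idx[1]], n = length(idx),
               sense_fraction = mean(sense[idx]), stringsAsFactors = FALSE)
  }))
  rownames(by_len) <- NULL
  comp <- table(factor(base5, levels = c("A", "C", "G", "T")))
  five_prime <- data.frame(base = names(comp),
                           fraction = as.numeric(comp) / length(base5),
                           stringsAsFactors = FALSE)
  list(by_length = by_len, five_prime = five_prime,
       u5_fraction = five_prime$fraction[five_prime$base == "T"])
}

#' Per-copy peak overlap fraction
#'
#' Fraction of each copy's bases covered by the union of the supplied peaks;
#' a copy is peak-associated from 1 bp of overlap.
#'
#' @param copies A `te_copies` data.frame.
#' @param peaks data.frame of peak intervals.
#' @return data.frame with `copy_id`, `peak_overlap_fraction`,
#'   `peak_associated`.
#' @export
peak_overlap <- function(copies, peaks) {
  ov <- .bp_in_regions(peaks, copies)
  frac <- ov / (copies$end - copies$start)
  data.frame(copy_id = copies$copy_id, peak_overlap_fraction = frac,
             peak_associated = ov > 0, stringsAsFactors = FALSE)
}

#' Build the per-copy association table
#'
#' @param copies A `te_copies` data.frame (with `site_class` if available).
#' @param cpm_by_stage CPM matrix, copies x stages.
#' @param peaks Peak intervals data.frame.
#' @param rule Association rule passed to [flag_srna_associated()].
#' @return data.frame of class `association_table`.
#' @export
association_table <- function(copies, cpm_by_stage, peaks, rule = "every_stage") {
  fl <- flag_srna_associated(cpm_by_stage, copies$intact, rule = rule)
  po <- peak_overlap(copies, peaks)
  out <- data.frame(copy_id = copies$copy_id, intact = copies$intact,
                    stringsAsFactors = FALSE)
  if (!is.null(copies$site_class)) out$site_class <- copies$site_class
  out <- cbind(out, as.data.frame(cpm_by_stage))
  out$srna_associated <- fl$associated
  out$peak_overlap_fraction <- po$peak_overlap_fraction
  out$peak_associated <- po$peak_associated
  class(out) <- c("association_table", "data.frame")
  out
}

.set_stats <- function(df) {
  A <- sum(df$peak_associated)
  B <- sum(df$srna_associated)
  AB <- sum(df$peak_associated & df$srna_associated)
  list(n = nrow(df), peak = A, srna = B, both = AB,
       p_srna_given_peak = if (A) AB / A else NA_real_,
       p_peak_given_srna = if (B) AB / B else NA_real_)
}

#' Intersection statistics between sRNA and peak association
#'
#' Venn counts and conditional proportions overall and by intact status, a
#' chi-square test of independence between the two associations among intact
#' copies, and (when site classes are available) a chi-square comparing peak
#' association between intact intergenic and intronic copies.
#'
#' @param assoc An `association_table`.
#' @return Nested list of counts, conditional proportions and tests.
#' @export
intersection_stats <- function(assoc) {
  out <- list(overall = .set_stats(assoc),
              intact = .set_stats(assoc[assoc$intact, , drop = FALSE]),
              nonintact = .set_stats(assoc[!assoc$intact, , drop = FALSE]))
  ia <- assoc[assoc$intact, , drop = FALSE]
  if (nrow(ia) > 1 && length(unique(ia$peak_associated)) == 2 &&
      length(unique(ia$srna_associated)) == 2) {
    out$independence_chisq_p <- suppressWarnings(
      stats::chisq.test(table(ia$peak_associated, ia$srna_associated),
                        correct = FALSE)$p.value)
  }
  if (!is.null(assoc$site_class)) {
    grp <- ifelse(startsWith(ia$site_class, "intergenic"), "intergenic",
                  ifelse(ia$site_class == "intron", "intron", NA))
    keep <- !is.na(grp)
    if (length(unique(grp[keep])) == 2) {
      tab <- table(grp[keep], ia$peak_associated[keep])
      out$site_class_chisq_p <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
      out$p_peak_by_site <- tapply(ia$peak_associated[keep], grp[keep], mean)
    }
  }
  out
}

# piecewise-constant signal integrals per chromosome: value and coverage
.signal_integrals <- function(signal) {
  lapply(.split_chrom(signal), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    list(ss = d$start, ee = d$end, vv = d$value,
         cumV = cumsum(d$value * (d$end - d$start)),
         cumC = cumsum(as.numeric(d$end - d$start)))
  })
}

.integral_at <- function(idx, x, value = TRUE) {
  i <- findInterval(x, idx$ss)
  out <- numeric(length(x))
  pos <- i > 0
  ii <- i[pos]
  full <- (if (value) idx$cumV else idx$cumC)[ii]
  seg_len <- idx$ee[ii] - idx$ss[ii]
  seg_val <- if (value) idx$vv[ii] else 1
  inside <- pmax(0, pmin(x[pos], idx$ee[ii]) - idx$ss[ii])
  out[pos] <- full - seg_val * (seg_len - inside)
  out
}

#' Scale-regions metaprofile of a binned signal over regions
#'
#' Each region body is rescaled to `body_bp / bin_bp` bins; flanks are taken
#' in native `bin_bp` bins. A bin's value is the coverage-weighted mean of the
#' signal over its genomic span; bins without any signal data are missing and
#' ignored by the group mean. Minus-strand regions are reversed.
#'
#' @param signal data.frame with `chrom`, `start`, `end`, `value`
#'   (non-overlapping, e.g. from [read_bedgraph()]).
#' @param regions data.frame of regions with optional `strand`.
#' @param groups Optional grouping vector along regions (one mean profile per
#'   group).
#' @param body_bp,flank_bp,bin_bp Profile geometry (defaults 1 kb body, 10 kb
#'   flanks, 10 bp bins).
#' @return List with `profile` (group x bin matrix of means), `n` (regions per
#'   group) and `bin_centers` (bp relative to the region start, body
#'   rescaled).
#' @export
metaprofile <- function(signal, regions, groups = NULL,
                        body_bp = 1000, flank_bp = 10000, bin_bp = 10) {
  nf <- as.integer(flank_bp / bin_bp)
  nb <- as.integer(body_bp / bin_bp)
  nbins <- 2L * nf + nb
  if (is.null(groups)) groups <- rep("all", nrow(regions))
  idx_by_chrom <- .signal_integrals(signal)
  vals <- matrix(NA_real_, nrow(regions), nbins)
  for (i in seq_len(nrow(regions))) {
    ch <- as.character(regions$chrom[i])
    idx <- idx_by_chrom[[ch]]
    if (is.null(idx)) next
    s <- regions$start[i]; e <- regions$end[i]
    xs <- c(s - flank_bp + bin_bp * (0:nf),
            s + (e - s) / nb * (1:nb),
            e + bin_bp * (1:nf))
    vi <- .integral_at(idx, xs, value = TRUE)
    ci <- .integral_at(idx, xs, value = FALSE)
    dv <- diff(vi); dc <- diff(ci)
    m <- ifelse(dc > 1e-12, dv / dc, NA_real_)
    st <- if (!is.null(regions$strand)) regions$strand[i] else "+"
    vals[i, ] <- if (identical(st, "-")) rev(m) else m
  }
  gs <- split(seq_len(nrow(regions)), groups)
  prof <- do.call(rbind, lapply(gs, function(ri) {
    colMeans(vals[ri, , drop = FALSE], na.rm = TRUE)
  }))
  rownames(prof) <- names(gs)
  centers <- c(-flank_bp + bin_bp * (1:nf) - bin_bp / 2,
               body_bp / nb * (1:nb) - body_bp / nb / 2,
               body_bp + bin_bp * (1:nf) - bin_bp / 2)
  list(profile = prof, n = vapply(gs, length, integer(1)), bin_centers = centers)
}

#' Build a consensus feature map for a family table
#'
#' Autonomous families are split into left terminus, internal genic sequence
#' and right terminus; retrotransposon internals are labelled CDS, DNA
#' transposon internals alternate exon/intron.
#'
#' @param families data.frame with `family_id`, `subclass`, `consensus_length`,
#'   `autonomous` (logical).
#' @param terminus_bp Terminus length on each side.
#' @param dna_intron_bp Intron length carved out of DNA-transposon internals.
#' @return data.frame with `family_id`, `feature`, `start`, `end` (consensus
#'   coordinates, 0-based half-open, non-overlapping).
#' @export
consensus_feature_map <- function(families, terminus_bp = 200, dna_intron_bp = 300) {
  aut <- families[families$autonomous, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(aut))) {
    f <- aut[i, ]
    L <- f$consensus_length
    t <- min(terminus_bp, floor(L / 4))
    rows <- data.frame(family_id = f$family_id,
                       feature = c("left_terminus", "right_terminus"),
                       start = c(0L, L - t), end = c(t, L),
                       stringsAsFactors = FALSE)
    if (f$subclass == "DNA" && (L - 2 * t) > 3 * dna_intron_bp) {
      third <- floor((L - 2 * t - dna_intron_bp) / 2)
      rows <- rbind(rows, data.frame(
        family_id = f$family_id, feature = c("exon", "intron", "exon"),
        start = c(t, t + third, t + third + dna_intron_bp),
        end = c(t + third, t + third + dna_intron_bp, L - t),
        stringsAsFactors = FALSE))
    } else {
      rows <- rbind(rows, data.frame(family_id = f$family_id, feature = "CDS",
                                     start = t, end = L - t,
                                     stringsAsFactors = FALSE))
    }
    out[[f$family_id]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# lift genomic read intervals onto consensus coordinates via fragment spans
.lift_to_consensus <- function(reads, fragments) {
  out <- list()
  for (ch in unique(reads$chrom)) {
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(rd) == 0 || nrow(fr) == 0) next
    hits <- IRanges::findOverlaps(.ir(rd), .ir(fr), type = "within")
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (!length(qh)) next
    f <- fr[sh, , drop = FALSE]
    r <- rd[qh, , drop = FALSE]
    cs <- ifelse(f$strand == "+",
                 f$consensus_start + (r$start - f$start),
                 f$consensus_start + (f$end - r$end))
    out[[ch]] <- data.frame(family_id = f$family_id, start = cs,
                            end = cs + (r$end - r$start), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(family_id = character(), start = integer(),
                                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Coverage over consensus features and across-feature tests
#'
#' Reads (or signal read-intervals) are lifted onto consensus coordinates via
#' the fragment consensus spans, depth is averaged over each feature's bases,
#' and per-subclass differences across features are tested with
#' Kruskal-Wallis (family as unit) and Dunn's test with Benjamini-Hochberg
#' correction. Families with an `autonomous` column are additionally compared
#' autonomous vs non-autonomous by total depth (Wilcoxon).
#'
#' @param reads Alignments data.frame (genomic coordinates).
#' @param fragments Fragment table with consensus spans (attribute
#'   `"fragments"` of [merge_fragments()] output).
#' @param feature_map Output of [consensus_feature_map()].
#' @param families data.frame with `family_id`, `subclass` and optionally
#'   `autonomous`, `consensus_length`.
#' @return List with `coverage` (family, feature, mean_depth), `tests`
#'   (per subclass: kruskal p and Dunn table) and optionally
#'   `autonomous_wilcoxon_p`.
#' @export
consensus_feature_coverage <- function(reads, fragments, feature_map, families) {
  lifted <- .lift_to_consensus(reads, fragments)
  cov_rows <- list()
  for (fam in unique(feature_map$family_id)) {
    fm <- feature_map[feature_map$family_id == fam, , drop = FALSE]
    lf <- lifted[lifted$family_id == fam, , drop = FALSE]
    for (j in seq_len(nrow(fm))) {
      flen <- fm$end[j] - fm$start[j]
      if (flen <= 0) {
        warning(sprintf("empty feature %s in family %s excluded", fm$feature[j], fam))
        next
      }
      ovl <- if (nrow(lf)) sum(pmax(0, pmin(lf$end, fm$end[j]) - pmax(lf$start, fm$start[j]))) else 0
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        family_id = fam, feature = fm$feature[j], mean_depth = ovl / flen,
        stringsAsFactors = FALSE)
    }
  }
  coverage <- do.call(rbind, cov_rows)
  coverage$subclass <- families$subclass[match(coverage$family_id, families$family_id)]
  tests <- list()
  for (sc in unique(coverage$subclass)) {
    d <- coverage[coverage$subclass == sc, , drop = FALSE]
    if (length(unique(d$feature)) < 2 || min(table(d$feature)) < 2) next
    kw <- stats::kruskal.test(d$mean_depth, factor(d$feature))
    dn <- dunn_test(d$mean_depth, d$feature)
    dn$p_adj <- stats::p.adjust(dn$p, method = "BH")
    tests[[sc]] <- list(kruskal_p = kw$p.value, pairwise = dn)
  }
  out <- list(coverage = coverage, tests = tests)
  if (!is.null(families$autonomous)) {
    tot <- tapply(coverage$mean_depth, coverage$family_id, mean)
    auto <- families$autonomous[match(names(tot), families$family_id)]
    if (length(unique(auto)) == 2) {
      out$autonomous_wilcoxon_p <- stats::wilcox.test(tot[auto], tot[!auto],
                                                      exact = FALSE)$p.value
    }
  }
  out
}

#' Family-level correlations between expression and regulatory association
#'
#' Spearman correlations (average-rank ties) between per-family TE gene
#' expression (TPM) and (i) mean sRNA CPM on intact copies, (ii) mean
#' peak-overlap fraction; a loess trend (span 0.75) is fitted for description
#' when at least 10 families are available, and families whose mean body
#' overlap exceeds 0.75 are flagged (the regime of pronounced repression).
#'
#' @param family_stats data.frame with `family_id`, `tpm`, `mean_cpm_intact`,
#'   `mean_peak_overlap`.
#' @return List with `rho_srna`, `p_srna`, `rho_peak`, `p_peak`,
#'   `trend_srna`, `trend_peak` (fitted curves or NULL), `high_overlap`
#'   (flagged family ids).
#' @export
expression_correlations <- function(family_stats) {
  fs <- family_stats
  ct1 <- suppressWarnings(stats::cor.test(fs$tpm, fs$mean_cpm_intact,
                                          method = "spearman", exact = FALSE))
  ct2 <- suppressWarnings(stats::cor.test(fs$tpm, fs$mean_peak_overlap,
                                          method = "spearman", exact = FALSE))
  fit_trend <- function(x, y) {
    if (length(x) < 10) {
      warning("fewer than 10 families; loess trend skipped")
      return(NULL)
    }
    o <- order(x)
    lo <- stats::loess(y[o] ~ x[o], span = 0.75)
    data.frame(x = x[o], fitted = stats::predict(lo))
  }
  list(rho_srna = unname(ct1$estimate), p_srna = ct1$p.value,
       rho_peak = unname(ct2$estimate), p_peak = ct2$p.value,
       trend_srna = fit_trend(fs$mean_cpm_intact, fs$tpm),
       trend_peak = fit_trend(fs$mean_peak_overlap, fs$tpm),
       high_overlap = fs$family_id[fs$mean_peak_overlap > 0.75])
}
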