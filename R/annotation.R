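# Copy-level annotation: defragmentation of repeat hits into TE copies,
# LTR chain assembly, intactness classification, TE/tandem precedence and the
# divergence landscape.

#' Merge RepeatMasker fragments into TE copies
#'
#' Hits sharing a link id (the final `.out` column joining fragments of one
#' element) merge into one copy spanning `[min start, max end)`. Copy
#' divergence is the genomic-length-weighted mean of fragment divergences;
#' consensus coverage is the union of fragment consensus spans over the
#' consensus length (robust to nested insertions of other families).
#'
#' @param hits Repeat hits data.frame (see [read_repeatmasker_out()]).
#' @param consensus_lengths Named vector, family id -> consensus length (bp).
#' @return data.frame of class `te_copies` with one row per copy: `copy_id`,
#'   `chrom`, `start`, `end`, `strand`, `family_id`, `classification`,
#'   `length`, `n_fragments`, `divergence_pct`, `consensus_coverage`,
#'   `intact`, `subclass`, `mechanism`. The per-fragment table with its
#'   `copy_id` assignment is attached as attribute `"fragments"`.
#' @export
merge_fragments <- function(hits, consensus_lengths) {
  if (nrow(hits) == 0) {
    out <- data.frame(copy_id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character(), family_id = character(),
                      classification = character(), length = integer(),
                      n_fragments = integer(), divergence_pct = numeric(),
                      consensus_coverage = numeric(), intact = logical(),
                      subclass = character(), mechanism = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("te_copies", "data.frame")
    return(out)
  }
  groups <- split(seq_len(nrow(hits)), hits$link_id)
  rows <- vector("list", length(groups))
  frag_copy <- character(nrow(hits))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    h <- hits[idx, , drop = FALSE]
    if (length(unique(h$chrom)) > 1) {
      stop(sprintf("link group %s spans multiple chromosomes", names(groups)[k]))
    }
    if (length(unique(h$family_id)) > 1) {
      stop(sprintf("link group %s mixes families %s", names(groups)[k],
                   paste(unique(h$family_id), collapse = ",")))
    }
    fam <- h$family_id[1]
    clen <- consensus_lengths[fam]
    if (is.na(clen)) stop(sprintf("no consensus length for family %s", fam))
    w <- h$end - h$start
    cons_union <- sum(BiocGenerics::width(IRanges::reduce(
      IRanges::IRanges(h$consensus_start + 1L, h$consensus_end))))
    copy_id <- sprintf("%s_%s_%d", fam, h$chrom[1], min(h$start))
    frag_copy[idx] <- copy_id
    rows[[k]] <- data.frame(
      copy_id = copy_id, chrom = h$chrom[1],
      start = min(h$start), end = max(h$end), strand = h$strand[1],
      family_id = fam, classification = h$classification[1],
      length = max(h$end) - min(h$start), n_fragments = nrow(h),
      divergence_pct = sum(w * h$divergence_pct) / sum(w),
      consensus_coverage = cons_union / clen,
      stringsAsFactors = FALSE)
  }
  copies <- do.call(rbind, rows)
  copies <- copies[order(copies$chrom, copies$start), , drop = FALSE]
  rownames(copies) <- NULL
  copies$intact <- classify_intact(copies$divergence_pct, copies$consensus_coverage)
  copies$subclass <- te_subclass(copies$classification)
  copies$mechanism <- te_mechanism(copies$classification)
  frags <- hits
  frags$copy_id <- frag_copy
  attr(copies, "fragments") <- frags
  class(copies) <- c("te_copies", "data.frame")
  copies
}

#' Classify copies as intact
#'
#' A copy is intact when it diverges strictly less than `max_divergence`
#' percent from its family consensus AND covers strictly more than
#' `min_coverage` of the consensus length — i.e. copies that plausibly retain
#' transposition competence. Both boundaries are strict.
#'
#' @param divergence_pct Numeric vector of copy divergences (%).
#' @param consensus_coverage Numeric vector of consensus coverage fractions.
#' @param max_divergence,min_coverage Thresholds (defaults 20% and 0.8).
#' @return Logical vector.
#' @export
classify_intact <- function(divergence_pct, consensus_coverage,
                            max_divergence = 20, min_coverage = 0.8) {
  divergence_pct < max_divergence & consensus_coverage > min_coverage
}

#' Assemble full-length LTR retrotransposons from terminus/internal copies
#'
#' A same-strand chain LTR-internal-LTR of paired families with inter-copy
#' gaps of at most `max_gap` bp merges into a single full-length copy; solo
#' LTRs and opposite-strand internals are left untouched.
#'
#' @param copies A `te_copies` data.frame.
#' @param ltr_pairs data.frame with columns `ltr_family`, `internal_family`.
#' @param consensus_lengths Named vector of consensus lengths covering both
#'   terminus and internal families.
#' @param max_gap Maximum allowed gap between chained copies (bp).
#' @return Updated `te_copies` with merged rows (flagged `ltr_assembled`).
#' @export
assemble_ltr <- function(copies, ltr_pairs, consensus_lengths, max_gap = 500) {
  copies <- copies[order(copies$chrom, copies$start), , drop = FALSE]
  copies$ltr_assembled <- FALSE
  internal_of <- stats::setNames(ltr_pairs$internal_family, ltr_pairs$ltr_family)
  drop <- logical(nrow(copies))
  i <- 1
  while (i <= nrow(copies) - 2) {
    a <- copies[i, ]; b <- copies[i + 1, ]; c <- copies[i + 2, ]
    fam_int <- internal_of[a$family_id]
    chainable <- !is.na(fam_int) &&
      b$family_id == fam_int && c$family_id == a$family_id &&
      a$chrom == b$chrom && b$chrom == c$chrom &&
      a$strand == b$strand && b$strand == c$strand &&
      (b$start - a$end) <= max_gap && (b$start - a$end) >= 0 &&
      (c$start - b$end) <= max_gap && (c$start - b$end) >= 0
    if (chainable) {
      l_ltr <- consensus_lengths[a$family_id]
      l_int <- consensus_lengths[b$family_id]
      full_len <- 2 * l_ltr + l_int
      covered <- a$consensus_coverage * l_ltr + b$consensus_coverage * l_int +
        c$consensus_coverage * l_ltr
      w <- c(a$length, b$length, c$length)
      copies$start[i] <- a$start
      copies$end[i] <- c$end
      copies$length[i] <- c$end - a$start
      copies$family_id[i] <- b$family_id
      copies$classification[i] <- b$classification
      copies$n_fragments[i] <- a$n_fragments + b$n_fragments + c$n_fragments
      copies$divergence_pct[i] <-
        sum(w * c(a$divergence_pct, b$divergence_pct, c$divergence_pct)) / sum(w)
      copies$consensus_coverage[i] <- covered / full_len
      copies$ltr_assembled[i] <- TRUE
      copies$copy_id[i] <- sprintf("%s_%s_%d_full", b$family_id, a$chrom, a$start)
      drop[c(i + 1, i + 2)] <- TRUE
      i <- i + 3
    } else {
      i <- i + 1
    }
  }
  out <- copies[!drop, , drop = FALSE]
  out$intact <- classify_intact(out$divergence_pct, out$consensus_coverage)
  out$subclass <- te_subclass(out$classification)
  out$mechanism <- te_mechanism(out$classification)
  rownames(out) <- NULL
  class(out) <- c("te_copies", "data.frame")
  out
}

#' Resolve TE / tandem-repeat precedence
#'
#' Tandem intervals are clipped to exclude every base covered by a TE copy
#' (TEs take precedence when annotations overlap); TE intervals are untouched.
#' After resolution no base counts as both TE and tandem.
#'
#' @param te_copies A `te_copies` data.frame.
#' @param tandem_intervals data.frame of tandem repeat intervals.
#' @return Object of class `repeat_annotation`: list with `te_copies` and the
#'   clipped `tandem`.
#' @export
resolve_precedence <- function(te_copies, tandem_intervals) {
  tandem <- subtract_intervals(tandem_intervals,
                               te_copies[, c("chrom", "start", "end"), drop = FALSE])
  structure(list(te_copies = te_copies, tandem = tandem),
            class = "repeat_annotation")
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("repeat_annotation: %d TE copies (%.0f bp), %d tandem intervals (%.0f bp)\n",
              nrow(x$te_copies), .total_bp(x$te_copies),
              nrow(x$tandem), .total_bp(x$tandem)))
  invisible(x)
}

#' Divergence landscape of TE copies
#'
#' Each copy contributes its genomic bp to the divergence bin of its
#' length-weighted divergence, split by subclass (the cumulative-content-
#' against-age landscape). Copies above `max_divergence` can be excluded.
#'
#' @param copies A `te_copies` data.frame.
#' @param bin_width Bin width in divergence percent.
#' @param max_divergence Optional upper divergence cutoff (exclusive filter
#'   `divergence > max_divergence` removed).
#' @return data.frame with `bin` (left edge), `subclass`, `bp`.
#' @export
divergence_landscape <- function(copies, bin_width = 1, max_divergence = NULL) {
  if (!is.null(max_divergence)) {
    copies <- copies[copies$divergence_pct <= max_divergence, , drop = FALSE]
  }
  if (nrow(copies) == 0) {
    return(data.frame(bin = numeric(), subclass = character(), bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  bin <- floor(copies$divergence_pct / bin_width) * bin_width
  agg <- stats::aggregate(list(bp = as.numeric(copies$length)),
                          by = list(bin = bin, subclass = copies$subclass), sum)
  agg[order(agg$bin, agg$subclass), , drop = FALSE]
}

#' Fraction of total TE bp below a divergence cutoff
#'
#' @param copies A `te_copies` data.frame.
#' @param cutoff Divergence cutoff in percent (strict `<`).
#' @return Fraction in [0, 1].
#' @export
divergence_fraction_below <- function(copies, cutoff = 5) {
  total <- sum(as.numeric(copies$length))
  if (total == 0) return(NA_real_)
  sum(as.numeric(copies$length[copies$divergence_pct < cutoff])) / total
}

#' Per-superfamily summary statistics
#'
#' @param annotation A `repeat_annotation` or `te_copies`.
#' @param genome_size Genome size in bp.
#' @return data.frame with `classification`, `families`, `copies`,
#'   `intact_copies`, `genome_pct`.
#' @export
summarize_by_superfamily <- function(annotation, genome_size) {
  copies <- if (inherits(annotation, "repeat_annotation")) annotation$te_copies else annotation
  if (nrow(copies) == 0) {
    return(data.frame(classification = character(), families = integer(),
                      copies = integer(), intact_copies = integer(),
                      genome_pct = numeric(), stringsAsFactors = FALSE))
  }
  sp <- split(copies, copies$classification)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(classification = d$classification[1],
               families = length(unique(d$family_id)),
               copies = nrow(d),
               intact_copies = sum(d$intact),
               genome_pct = 100 * sum(as.numeric(d$length)) / genome_size,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$classification), , drop = FALSE]
}

#' Export TE copies as BED6 (name = family, score = divergence x 10)
#'
#' @param copies A `te_copies` data.frame.
#' @param path Output path.
#' @export
write_copies_bed <- function(copies, path) {
  df <- data.frame(chrom = copies$chrom, start = copies$start, end = copies$end,
                   label = copies$family_id,
                   score = round(copies$divergence_pct * 10),
                   strand = copies$strand, stringsAsFactors = FALSE)
  write_bed(df, path)
}
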