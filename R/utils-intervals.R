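# Interval algebra helpers. All coordinates in this package are 0-based
# half-open (BED convention); conversion to the 1-based closed convention of
# IRanges happens only inside these helpers, so no other file does coordinate
# arithmetic across conventions.

.empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

# data.frame(chrom,start,end) -> IRanges (per chromosome use .split_chrom first)
.ir <- function(df) {
  IRanges::IRanges(start = as.integer(df$start) + 1L, end = as.integer(df$end))
}

.from_ir <- function(ir, chrom) {
  data.frame(chrom = rep_len(chrom, length(ir)),
             start = BiocGenerics::start(ir) - 1L,
             end = BiocGenerics::end(ir),
             stringsAsFactors = FALSE)
}

.split_chrom <- function(df) split(df, as.character(df$chrom))

.assert_intervals <- function(df, what = "intervals", chrom_lengths = NULL) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s: invalid coordinates (start < 0 or start >= end) at rows %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(as.character(df$chrom)), names(chrom_lengths))
    if (length(unknown)) {
      stop(sprintf("%s: unknown chromosome(s) not in genome: %s",
                   what, paste(unknown, collapse = ", ")))
    }
    over <- df$end > chrom_lengths[as.character(df$chrom)]
    if (any(over)) {
      stop(sprintf("%s: %d interval(s) exceed declared chromosome length (first at row %d)",
                   what, sum(over), which(over)[1]))
    }
  }
  invisible(df)
}

#' Total bp spanned by a set of intervals (counting overlaps once)
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Total number of distinct bases covered.
#' @keywords internal
#' @noRd
.union_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(vapply(.split_chrom(df), function(d) {
    sum(as.numeric(BiocGenerics::width(IRanges::reduce(.ir(d)))))
  }, numeric(1)))
}

# Raw bp (overlaps counted multiply)
.total_bp <- function(df) sum(as.numeric(df$end - df$start))

# Merge overlapping/adjacent intervals, per chromosome
reduce_intervals <- function(df) {
  if (nrow(df) == 0) return(.empty_intervals())
  out <- lapply(.split_chrom(df), function(d) .from_ir(IRanges::reduce(.ir(d)), d$chrom[1]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Intersection of two interval sets (as reduced intervals)
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(.empty_intervals())
  chroms <- intersect(unique(as.character(a$chrom)), unique(as.character(b$chrom)))
  if (!length(chroms)) return(.empty_intervals())
  out <- lapply(chroms, function(ch) {
    ia <- IRanges::reduce(.ir(a[a$chrom == ch, , drop = FALSE]))
    ib <- IRanges::reduce(.ir(b[b$chrom == ch, , drop = FALSE]))
    .from_ir(IRanges::intersect(ia, ib), ch)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$end > out$start, , drop = FALSE]
}

# a minus b (per-base set difference)
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(.empty_intervals())
  if (nrow(b) == 0) return(reduce_intervals(a))
  out <- lapply(.split_chrom(a), function(d) {
    ch <- as.character(d$chrom[1])
    ia <- IRanges::reduce(.ir(d))
    bb <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(bb) == 0) return(.from_ir(ia, ch))
    .from_ir(IRanges::setdiff(ia, IRanges::reduce(.ir(bb))), ch)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$end > out$start, , drop = FALSE]
}

# bp of `features` falling inside each row of `regions` (overlaps in features
# counted once). Returns numeric vector along rows of `regions`.
.bp_in_regions <- function(features, regions) {
  out <- numeric(nrow(regions))
  if (nrow(regions) == 0) return(out)
  if (nrow(features) == 0) return(out)
  red <- reduce_intervals(features)
  for (ch in unique(as.character(regions$chrom))) {
    idx <- which(regions$chrom == ch)
    f <- red[red$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0) next
    ir_r <- .ir(regions[idx, , drop = FALSE])
    ir_f <- .ir(f)
    hits <- IRanges::findOverlaps(ir_r, ir_f)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(BiocGenerics::end(ir_r)[qi], BiocGenerics::end(ir_f)[si]) -
      pmax(BiocGenerics::start(ir_r)[qi], BiocGenerics::start(ir_f)[si]) + 1L
    agg <- tapply(ov, qi, sum)
    out[idx[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample one element of a vector (safe for length-1 numeric vectors)
.sample1 <- function(v) v[sample.int(length(v), 1L)]
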