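# RepeatMasker .out dialect. No installed R package parses this format, so the
# reader/writer live here. Genomic and consensus coordinates are 1-based
# inclusive on disk and 0-based half-open in memory; minus-strand hits print
# their consensus span as "(left) end begin" and are normalized on read so
# consensus_start < consensus_end always holds.

#' Read RepeatMasker `.out` repeat hits
#'
#' Parses the standard whitespace-delimited `.out` dialect (with or without the
#' 3-line header). Strand `C` is mapped to `-`, the parenthesized consensus
#' coordinate of minus-strand hits is resolved, and all coordinates are
#' converted to the package-internal 0-based half-open convention.
#'
#' @param path Path to a `.out` file.
#' @param chrom_lengths Optional named vector of chromosome lengths; when given,
#'   hits on unknown chromosomes or past chromosome ends are an error.
#' @return A data.frame of repeat hits with columns `score`, `divergence_pct`,
#'   `perc_del`, `perc_ins`, `chrom`, `start`, `end`, `strand`, `family_id`,
#'   `classification`, `consensus_start`, `consensus_end`, `consensus_left`,
#'   `link_id`, `higher_score_overlap`. The overlap asterisk is retained but
#'   never used for filtering (overlap resolution is the defragmentation
#'   step's job).
#' @export
read_repeatmasker_out <- function(path, chrom_lengths = NULL) {
  lines <- readLines(path)
  out <- vector("list", length(lines))
  n_header <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    fields <- strsplit(line, "[[:space:]]+")[[1]]
    first_num <- suppressWarnings(as.numeric(fields[1]))
    if (is.na(first_num)) {
      n_header <- n_header + 1L
      if (i > 3L) stop(sprintf("malformed .out row at line %d: non-numeric score field", i))
      next
    }
    if (length(fields) < 15L) {
      stop(sprintf("malformed .out row at line %d: expected >= 15 fields, got %d",
                   i, length(fields)))
    }
    strand <- fields[9]
    if (!strand %in% c("+", "C")) {
      stop(sprintf("malformed .out row at line %d: strand must be '+' or 'C'", i))
    }
    qb <- suppressWarnings(as.integer(fields[6]))
    qe <- suppressWarnings(as.integer(fields[7]))
    if (is.na(qb) || is.na(qe) || qb < 1L || qb > qe) {
      stop(sprintf("malformed .out row at line %d: bad genomic coordinates", i))
    }
    strip_paren <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") {
      cb <- strip_paren(fields[12]); ce <- strip_paren(fields[13]); cl <- strip_paren(fields[14])
    } else {
      cl <- strip_paren(fields[12]); ce <- strip_paren(fields[13]); cb <- strip_paren(fields[14])
    }
    if (is.na(cb) || is.na(ce) || cb < 1L || cb > ce) {
      stop(sprintf("malformed .out row at line %d: bad consensus coordinates", i))
    }
    div <- as.numeric(fields[2])
    if (div < 0 || div > 100) {
      stop(sprintf("malformed .out row at line %d: divergence %.2f outside [0,100]", i, div))
    }
    out[[i]] <- data.frame(
      score = as.numeric(fields[1]),
      divergence_pct = div,
      perc_del = as.numeric(fields[3]),
      perc_ins = as.numeric(fields[4]),
      chrom = fields[5],
      start = qb - 1L,
      end = qe,
      strand = if (strand == "C") "-" else "+",
      family_id = fields[10],
      classification = fields[11],
      consensus_start = cb - 1L,
      consensus_end = ce,
      consensus_left = cl,
      link_id = as.integer(fields[15]),
      higher_score_overlap = length(fields) >= 16L && fields[16] == "*",
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(score = numeric(), divergence_pct = numeric(),
                       perc_del = numeric(), perc_ins = numeric(),
                       chrom = character(), start = integer(), end = integer(),
                       strand = character(), family_id = character(),
                       classification = character(), consensus_start = integer(),
                       consensus_end = integer(), consensus_left = integer(),
                       link_id = integer(), higher_score_overlap = logical(),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  .assert_intervals(hits, "repeat hits", chrom_lengths)
  hits
}

#' Write repeat hits in RepeatMasker `.out` layout
#'
#' Inverse of [read_repeatmasker_out()]: emits the 3-line header and re-applies
#' the on-disk conventions (1-based inclusive coordinates, `C` strand with
#' `(left) end begin` consensus fields).
#'
#' @param hits Repeat hits data.frame as returned by [read_repeatmasker_out()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_repeatmasker_out <- function(hits, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left)  ID",
    "")
  rows <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$strand == "+") {
      cons <- c(h$consensus_start + 1L, h$consensus_end, sprintf("(%d)", h$consensus_left))
      strand <- "+"
    } else {
      cons <- c(sprintf("(%d)", h$consensus_left), h$consensus_end, h$consensus_start + 1L)
      strand <- "C"
    }
    rows[i] <- paste(
      format(h$score, trim = TRUE), sprintf("%.1f", h$divergence_pct),
      sprintf("%.1f", h$perc_del), sprintf("%.1f", h$perc_ins),
      h$chrom, h$start + 1L, h$end, sprintf("(0)"),
      strand, h$family_id, h$classification,
      cons[1], cons[2], cons[3], h$link_id,
      if (isTRUE(h$higher_score_overlap)) "*" else "")
  }
  writeLines(c(header, trimws(rows, which = "right")), path)
  invisible(path)
}
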