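# Track I/O. Standard dialects are delegated to rtracklayer/Rsamtools; the
# only conversion done here is to the internal 0-based half-open convention.

#' Read a BED3/BED6 file
#'
#' @param path Path to a BED file.
#' @param chrom_lengths Optional named vector for coordinate validation.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and,
#'   when present in the file, `label` (BED name), `score`, `strand`.
#' @export
read_bed <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$label <- as.character(mc$name)
  if (!is.null(mc$score)) df$score <- as.numeric(mc$score)
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  .assert_intervals(df, basename(path), chrom_lengths)
  df
}

#' Write intervals as BED
#'
#' Emits BED6 when `label`/`score`/`strand` columns are present, BED3 otherwise.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `label`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$chrom, df$start, df$end)
  if (!is.null(df$label) || !is.null(df$score) || !is.null(df$strand)) {
    cols <- c(cols, list(df$label %||% rep(".", nrow(df)),
                         df$score %||% rep(0, nrow(df)),
                         df$strand %||% rep(".", nrow(df))))
  }
  tab <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a broadPeak file (treated as BED6+3; only chrom/start/end/name used)
#'
#' @inheritParams read_bed
#' @return data.frame with `chrom`, `start`, `end`, `label`.
#' @export
read_broadpeak <- function(path, chrom_lengths = NULL) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("broadPeak file must have at least 3 columns")
  df <- data.frame(chrom = as.character(tab[[1]]),
                   start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                   label = if (ncol(tab) >= 4) as.character(tab[[4]]) else ".",
                   stringsAsFactors = FALSE)
  .assert_intervals(df, basename(path), chrom_lengths)
  df
}

#' Write peak intervals as broadPeak (BED6+3)
#' @inheritParams write_bed
#' @export
write_broadpeak <- function(df, path) {
  n <- nrow(df)
  tab <- data.frame(df$chrom, df$start, df$end,
                    df$label %||% sprintf("peak_%d", seq_len(n)),
                    0L, ".", 0, -1, -1, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @inheritParams read_bed
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   value = as.numeric(S4Vectors::mcols(gr)$score),
                   stringsAsFactors = FALSE)
  .assert_intervals(df, basename(path), chrom_lengths)
  df
}

#' Write a bedGraph signal track
#' @param df data.frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  tab <- data.frame(df$chrom, df$start, df$end, df$value, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Builds a gene-model object from `gene`/`mRNA`/`exon`/`CDS`/UTR records.
#' Introns are derived as the gaps between the exons of each transcript;
#' overlapping exons within one transcript are an error.
#'
#' @param path Path to a GFF3 file.
#' @param chrom_lengths Optional named vector for coordinate validation.
#' @return An object of class `gene_models`: a list with data.frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`), `transcripts`
#'   (`transcript_id`, `gene_id`, ...), and `features` (`chrom`, `start`,
#'   `end`, `strand`, `type` in CDS/five_prime_UTR/three_prime_UTR/exon/intron,
#'   `transcript_id`, `gene_id`). All coordinates 0-based half-open.
#' @export
read_gff3 <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(S4Vectors::mcols(gr)$type),
                   id = as.character(S4Vectors::mcols(gr)$ID),
                   stringsAsFactors = FALSE)
  par <- S4Vectors::mcols(gr)$Parent
  df$parent <- vapply(seq_along(gr), function(i) {
    p <- par[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  .assert_intervals(df, basename(path), chrom_lengths)

  genes <- df[df$type == "gene", c("id", "chrom", "start", "end", "strand")]
  names(genes)[1] <- "gene_id"
  tx <- df[df$type %in% c("mRNA", "transcript"), c("id", "parent", "chrom", "start", "end", "strand")]
  names(tx)[1:2] <- c("transcript_id", "gene_id")
  feat <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"),
             c("chrom", "start", "end", "strand", "type", "parent")]
  names(feat)[6] <- "transcript_id"
  tx_gene <- stats::setNames(tx$gene_id, tx$transcript_id)
  feat$gene_id <- unname(tx_gene[feat$transcript_id])

  introns <- list()
  for (t_id in unique(feat$transcript_id[feat$type == "exon"])) {
    ex <- feat[feat$transcript_id == t_id & feat$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop(sprintf("transcript %s has overlapping exons", t_id))
    }
    if (nrow(ex) > 1) {
      introns[[t_id]] <- data.frame(
        chrom = ex$chrom[1], start = ex$end[-nrow(ex)], end = ex$start[-1],
        strand = ex$strand[1], type = "intron", transcript_id = t_id,
        gene_id = ex$gene_id[1], stringsAsFactors = FALSE)
    }
  }
  if (length(introns)) feat <- rbind(feat, do.call(rbind, introns))
  rownames(feat) <- NULL
  structure(list(genes = genes, transcripts = tx, features = feat),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d features\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$features)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' @param models A `gene_models` object (see [read_gff3()]).
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  attr_col <- function(id, parent = NULL) {
    if (is.null(parent)) sprintf("ID=%s", id) else sprintf("ID=%s;Parent=%s", id, parent)
  }
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, src, type,
            start + 1L, end, strand, attrs)
  }
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    lines <- c(lines, fmt(g$chrom, "telandscape", "gene", g$start, g$end,
                          g$strand, attr_col(g$gene_id)))
    txs <- models$transcripts[models$transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      lines <- c(lines, fmt(t$chrom, "telandscape", "mRNA", t$start, t$end,
                            t$strand, attr_col(t$transcript_id, g$gene_id)))
      fe <- models$features[models$features$transcript_id == t$transcript_id &
                              models$features$type != "intron", , drop = FALSE]
      fe <- fe[order(fe$start), , drop = FALSE]
      for (k in seq_len(nrow(fe))) {
        lines <- c(lines, fmt(fe$chrom[k], "telandscape", fe$type[k], fe$start[k],
                              fe$end[k], fe$strand[k],
                              sprintf("Parent=%s", t$transcript_id)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# reference-consumed width of a CIGAR string (M/D/N/=/X)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops)) return(NA_integer_)
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read small-RNA read alignments (SAM/BAM or 6-column BED)
#'
#' For SAM/BAM, alignment multiplicity is taken from the `NH` tag when present
#' (1 otherwise). For BED alignments the columns are chrom, start, end, read
#' id, multiplicity (score column), strand; read length is the interval
#' length.
#'
#' @param path Path to a `.sam`, `.bam` or BED file.
#' @param format One of "auto", "sam", "bam", "bed".
#' @param chrom_lengths Optional named vector for coordinate validation.
#' @return data.frame with `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `read_length`, `multiplicity`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam", "bed"),
                            chrom_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) ext else "bed"
  }
  if (format %in% c("sam", "bam")) {
    bam <- if (format == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "strand", "cigar", "qwidth"),
      tag = "NH",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    rw <- .cigar_ref_width(b$cigar)
    df <- data.frame(read_id = b$qname,
                     chrom = as.character(b$rname),
                     start = b$pos - 1L,
                     end = b$pos - 1L + rw,
                     strand = as.character(b$strand),
                     read_length = b$qwidth,
                     multiplicity = {
                       nh <- b$tag$NH
                       if (is.null(nh)) rep(1L, length(b$pos)) else ifelse(is.na(nh), 1L, nh)
                     },
                     stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(tab) < 6) stop("BED alignments need 6 columns (chrom,start,end,id,multiplicity,strand)")
    df <- data.frame(read_id = as.character(tab[[4]]),
                     chrom = as.character(tab[[1]]),
                     start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                     strand = as.character(tab[[6]]),
                     read_length = as.integer(tab[[3]]) - as.integer(tab[[2]]),
                     multiplicity = as.integer(tab[[5]]),
                     stringsAsFactors = FALSE)
  }
  .assert_intervals(df, basename(path), chrom_lengths)
  df
}

#' Write read alignments as 6-column BED
#' @param reads Alignments data.frame (see [read_alignments()]).
#' @param path Output path.
#' @export
write_alignments_bed <- function(reads, path) {
  tab <- data.frame(reads$chrom, reads$start, reads$end, reads$read_id,
                    reads$multiplicity, reads$strand, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
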