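# Consensus-library post-processing: clustering, reclassification, tandem
# purging, redundancy removal, majority-rule consensus building.

#' Build a TE consensus library object
#'
#' A library is a data.frame with one row per consensus record. Classification
#' is parsed from RepeatMasker-style headers `name#Class/Superfamily`; records
#' without a `#` are classified "Unknown". Unknown classification strings are
#' preserved verbatim and grouped under subclass "Unknown".
#'
#' @param seqs Named character vector or `DNAStringSet` of consensus sequences.
#' @param curated Logical vector (recycled) flagging manually curated records.
#' @return data.frame of class `te_library` with columns `id`, `classification`,
#'   `curated`, `length`, `sequence`.
#' @export
te_library <- function(seqs, curated = FALSE) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("sequences must be named")
  headers <- names(seqs)
  has_class <- grepl("#", headers, fixed = TRUE)
  id <- ifelse(has_class, sub("#.*$", "", headers), headers)
  classification <- ifelse(has_class, sub("^[^#]*#", "", headers), "Unknown")
  if (anyDuplicated(id)) stop("duplicate record ids in library")
  out <- data.frame(id = id, classification = classification,
                    curated = rep_len(as.logical(curated), length(seqs)),
                    length = nchar(unname(seqs)), sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  class(out) <- c("te_library", "data.frame")
  out
}

#' TE subclass of a classification string
#'
#' Maps `Class/Superfamily` strings onto the six subclasses used throughout
#' (LTR, LINE, DIRS, PLE, DNA, Helitron) plus "Unknown" and "TandemRepeat";
#' unrecognized strings map to "Unknown" for grouping but are never rewritten.
#'
#' @param classification Character vector of `Class/Superfamily` strings.
#' @return Character vector of subclasses.
#' @export
te_subclass <- function(classification) {
  cls <- sub("/.*$", "", classification)
  known <- c("LTR", "LINE", "DIRS", "PLE", "DNA", "Helitron", "TandemRepeat")
  ifelse(cls %in% known, cls, "Unknown")
}

#' Transposition mechanism of a classification string
#'
#' DD(E/D) DNA transposons excise and reinsert ("cut"); retrotransposons and
#' Helitrons replicate ("copy"). Unknown subclasses return "unknown" and are
#' excluded from cut:copy ratio computations.
#'
#' @inheritParams te_subclass
#' @return Character vector in {"cut", "copy", "unknown"}.
#' @export
te_mechanism <- function(classification) {
  sub <- te_subclass(classification)
  out <- rep("unknown", length(sub))
  out[sub %in% c("LTR", "LINE", "DIRS", "PLE", "Helitron")] <- "copy"
  out[sub == "DNA"] <- "cut"
  out
}

#' Write a TE library as FASTA with `name#Class/Superfamily` headers
#' @param library A `te_library`.
#' @param path Output path.
#' @export
write_library_fasta <- function(library, path) {
  headers <- ifelse(library$classification == "Unknown", library$id,
                    paste0(library$id, "#", library$classification))
  write_fasta(stats::setNames(library$sequence, headers), path)
}

#' Read a TE library from a classification-header FASTA
#' @param path Input FASTA.
#' @param curated Logical, recycled over records.
#' @return A `te_library`.
#' @export
read_library_fasta <- function(path, curated = FALSE) {
  te_library(read_fasta(path), curated = curated)
}

#' Best-local-alignment identity and coverage between two sequences
#'
#' Identity is matches over alignment columns of the best local alignment
#' (match +1, mismatch -1, gap -2 by default); coverage is the aligned span of
#' the shorter sequence over its length. Both orientations are attempted
#' (consensus strands are arbitrary) and the better-scoring one is used.
#'
#' @param a,b Nucleotide sequences (character).
#' @param match,mismatch,gap Alignment scores (gap is a linear per-position
#'   penalty).
#' @param try_revcomp Also align against the reverse complement of `b`.
#' @return List with `identity`, `coverage_of_shorter`, `score`, `orientation`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2,
                              try_revcomp = TRUE) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in pairwise_identity")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                  baseOnly = TRUE)
  align1 <- function(bb) {
    Biostrings::pairwiseAlignment(a, bb, type = "local", substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = -gap)
  }
  aln <- align1(b)
  orientation <- "+"
  if (try_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    aln_rc <- align1(rc)
    if (Biostrings::score(aln_rc) > Biostrings::score(aln)) {
      aln <- aln_rc
      orientation <- "-"
    }
  }
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  ident <- if (ncol_aln == 0) 0 else Biostrings::nmatch(aln) / ncol_aln
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  span_p <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
  span_s <- BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L
  shorter_is_a <- nchar(a) <= nchar(b)
  cov <- if (shorter_is_a) span_p / nchar(a) else span_s / nchar(b)
  list(identity = ident, coverage_of_shorter = cov,
       score = Biostrings::score(aln), orientation = orientation)
}

#' Greedy incremental clustering of a consensus library
#'
#' Sequences are processed longest first (ties by id); each joins the first
#' existing cluster whose representative reaches both the identity and the
#' shorter-sequence coverage thresholds, otherwise it founds a new cluster.
#' This is the defined stand-in for CD-HIT-EST style clustering
#' (`-c`/`-aS` contract).
#'
#' @param library A `te_library`.
#' @param identity_thr,coverage_thr Thresholds in (0, 1].
#' @param ... Passed on to [pairwise_identity()].
#' @return Object of class `te_clusters`: list with `clusters` (list of
#'   `list(representative, members)`), `membership` (named vector id ->
#'   representative) and the thresholds.
#' @export
cluster_library <- function(library, identity_thr = 0.8, coverage_thr = 0.8, ...) {
  stopifnot(identity_thr > 0, identity_thr <= 1, coverage_thr > 0, coverage_thr <= 1)
  ord <- order(-library$length, library$id)
  lib <- library[ord, , drop = FALSE]
  reps <- character(0)
  members <- list()
  membership <- character(nrow(lib))
  names(membership) <- lib$id
  seq_of <- stats::setNames(lib$sequence, lib$id)
  for (i in seq_len(nrow(lib))) {
    placed <- FALSE
    for (r in reps) {
      pi <- pairwise_identity(seq_of[[r]], lib$sequence[i], ...)
      if (pi$identity >= identity_thr && pi$coverage_of_shorter >= coverage_thr) {
        members[[r]] <- c(members[[r]], lib$id[i])
        membership[lib$id[i]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      r <- lib$id[i]
      reps <- c(reps, r)
      members[[r]] <- r
      membership[r] <- r
    }
  }
  clusters <- lapply(reps, function(r) list(representative = r, members = members[[r]]))
  structure(list(clusters = clusters, membership = membership,
                 identity_threshold = identity_thr, coverage_threshold = coverage_thr),
            class = "te_clusters")
}

#' @export
print.te_clusters <- function(x, ...) {
  cat(sprintf("te_clusters: %d clusters over %d sequences (identity >= %.2f, coverage >= %.2f)\n",
              length(x$clusters), length(x$membership),
              x$identity_threshold, x$coverage_threshold))
  invisible(x)
}

#' Reclassify unclassified records by cluster co-membership
#'
#' Within each cluster that contains a classified member, unclassified
#' ("Unknown") members adopt the classification of the best donor: curated
#' members are preferred over merely classified ones, ties broken by length.
#' Clusters whose curated members disagree are left unchanged and flagged.
#'
#' @param clusters A `te_clusters` from [cluster_library()].
#' @param library The `te_library` that was clustered.
#' @return List with `library` (updated), `changes` (data.frame id,
#'   old, new, donor) and `conflicts` (representative ids of skipped clusters).
#' @export
reclassify_by_cluster <- function(clusters, library) {
  lib <- library
  rownames(lib) <- lib$id
  changes <- list()
  conflicts <- character(0)
  for (cl in clusters$clusters) {
    mem <- lib[cl$members, , drop = FALSE]
    classified <- mem[mem$classification != "Unknown", , drop = FALSE]
    if (nrow(classified) == 0) next
    cur <- classified[classified$curated, , drop = FALSE]
    if (nrow(cur) >= 2 && length(unique(cur$classification)) > 1) {
      conflicts <- c(conflicts, cl$representative)
      next
    }
    donors <- if (nrow(cur)) cur else classified
    donor <- donors[order(-donors$length, donors$id)[1], ]
    targets <- mem$id[mem$classification == "Unknown"]
    for (id in targets) {
      changes[[id]] <- data.frame(id = id, old = lib[id, "classification"],
                                  new = donor$classification, donor = donor$id,
                                  stringsAsFactors = FALSE)
      lib[id, "classification"] <- donor$classification
    }
  }
  rownames(lib) <- NULL
  list(library = lib,
       changes = if (length(changes)) do.call(rbind, unname(changes)) else
         data.frame(id = character(), old = character(), new = character(),
                    donor = character(), stringsAsFactors = FALSE),
       conflicts = conflicts)
}

#' Reclassify families whose genomic copies are mostly tandem repeats
#'
#' Per family, the fraction of its genomic copy bases intersecting tandem
#' repeat intervals is computed; families strictly above the threshold are
#' reclassified as "TandemRepeat" (the documented repeat-library artefact
#' purge; the boundary is strict, exactly 60% is retained).
#'
#' @param library A `te_library`.
#' @param copies data.frame of genomic copies with `chrom`, `start`, `end`,
#'   `family_id`.
#' @param tandem data.frame of tandem repeat intervals.
#' @param threshold Overlap fraction above which a family is reclassified.
#' @return List with `library` (updated) and `fractions` (per-family overlap
#'   fraction with `reclassified` flag).
#' @export
tandem_overlap_reclassify <- function(library, copies, tandem, threshold = 0.60) {
  fams <- unique(library$id)
  frac <- rep(NA_real_, length(fams))
  names(frac) <- fams
  for (f in fams) {
    cp <- copies[copies$family_id == f, , drop = FALSE]
    total <- .total_bp(cp)
    if (total == 0) {
      warning(sprintf("family %s has zero genomic bp; skipped", f))
      next
    }
    frac[f] <- sum(.bp_in_regions(tandem, cp)) / total
  }
  hit <- !is.na(frac) & frac > threshold
  lib <- library
  lib$classification[lib$id %in% names(frac)[hit]] <- "TandemRepeat"
  list(library = lib,
       fractions = data.frame(family_id = fams, overlap_fraction = unname(frac),
                              reclassified = unname(hit), stringsAsFactors = FALSE))
}

#' Remove redundant records using 95%-threshold clusters
#'
#' Per cluster one record is kept: a curated member when present (longest
#' curated on ties), otherwise the longest member. Curated records are never
#' removed.
#'
#' @param library A `te_library`.
#' @param clusters A `te_clusters`, normally from
#'   `cluster_library(library, 0.95, 0.95)`.
#' @return List with `library` (deduplicated) and `removed` (ids).
#' @export
deduplicate <- function(library, clusters) {
  keep <- character(0)
  rownames(library) <- library$id
  for (cl in clusters$clusters) {
    mem <- library[cl$members, , drop = FALSE]
    cur <- mem[mem$curated, , drop = FALSE]
    keep_cl <- if (nrow(cur)) cur$id[order(-cur$length, cur$id)] else
      mem$id[order(-mem$length, mem$id)][1]
    keep <- c(keep, keep_cl)
  }
  removed <- setdiff(library$id, keep)
  out <- library[library$id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  list(library = out, removed = removed)
}

#' Majority-rule consensus from a gapped alignment
#'
#' Per column the majority non-gap character wins; columns where gaps are the
#' strict majority are dropped; base ties resolve alphabetically (A<C<G<T).
#'
#' @param msa Character vector of equal-length gapped sequences.
#' @return Consensus sequence (character scalar).
#' @export
consensus_from_alignment <- function(msa) {
  stopifnot(length(msa) >= 1)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1) stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    n_gap <- sum(col == "-")
    if (n_gap > length(col) / 2) next
    bases <- col[col != "-"]
    tab <- table(factor(bases, levels = sort(unique(bases))))
    out <- c(out, names(tab)[which.max(tab)])  # which.max takes first => alphabetical tie-break
  }
  paste(out, collapse = "")
}
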