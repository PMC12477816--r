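# Synthetic mobilome generation with a complete truth table: genomes with
# compartments, planted TE copies of known family/divergence/truncation,
# genes with introns and UTRs, tandem arrays, small-RNA alignments and broad
# peaks. Every emitted record maps back to a planted one, so downstream
# stages can be validated against planted parameters.

.BASES <- c("A", "C", "G", "T")

.rand_seq_chars <- function(n) sample(.BASES, n, replace = TRUE)

.rand_seq <- function(n) paste(.rand_seq_chars(n), collapse = "")

#' Simulate a consensus library from a family plan
#'
#' @param config A `simulation_config`; only `seed` and `family_plan` are
#'   used.
#' @return A `te_library` with one random consensus per planned family
#'   (classification encoded as `name#Class/Superfamily`); autonomous
#'   families are flagged curated.
#' @export
simulate_library <- function(config) {
  set.seed(config$seed)
  .sim_library_records(config$family_plan)
}

.sim_library_records <- function(family_plan) {
  if (nrow(family_plan) == 0) stop("family plan is empty")
  if (anyDuplicated(family_plan$family_id)) stop("duplicate family ids in plan")
  seqs <- vapply(family_plan$consensus_length, .rand_seq, character(1))
  names(seqs) <- ifelse(family_plan$classification == "Unknown",
                        family_plan$family_id,
                        paste0(family_plan$family_id, "#", family_plan$classification))
  te_library(seqs, curated = family_plan$autonomous)
}

#' Add near-duplicate unclassified records to a library
#'
#' Emulates the redundancy and lack of classification of automated repeat
#' libraries so that clustering/reclassification/deduplication have real work
#' to do.
#'
#' @param library A `te_library`.
#' @param n_variants Number of records to duplicate (longest first).
#' @param divergence Percent divergence of each duplicate from its source.
#' @return The augmented `te_library`.
#' @export
add_library_redundancy <- function(library, n_variants = 3, divergence = 3) {
  if (n_variants == 0) return(library)
  src <- library[order(-library$length), , drop = FALSE]
  src <- src[seq_len(min(n_variants, nrow(src))), , drop = FALSE]
  dup_seqs <- vapply(src$sequence, function(s) {
    mutate_copy(s, divergence = divergence, truncation = 0)$sequence
  }, character(1))
  names(dup_seqs) <- paste0(src$id, "_dup")
  dup <- te_library(dup_seqs, curated = FALSE)
  dup$classification <- "Unknown"
  out <- rbind(library, dup)
  class(out) <- c("te_library", "data.frame")
  out
}

#' Mutate a consensus into a diverged, optionally truncated copy
#'
#' Per-site substitution with probability `divergence`/100 (uniform over the
#' three alternative bases), followed by 5' truncation. The realized
#' divergence (mismatches over retained aligned length) is reported; with
#' substitution-only divergence it has a closed-form binomial check.
#'
#' @param consensus Consensus nucleotide sequence (character).
#' @param divergence Requested divergence in percent (0-50).
#' @param truncation Number of 5' consensus bases removed (< consensus
#'   length).
#' @param seed Optional seed for a self-contained deterministic call.
#' @return List with `sequence` and `realized_divergence_pct`.
#' @export
mutate_copy <- function(consensus, divergence, truncation = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(divergence >= 0, divergence <= 50)
  v <- strsplit(consensus, "")[[1]]
  n <- length(v)
  if (truncation >= n) stop("truncation must be smaller than the consensus length")
  hit <- stats::runif(n) < divergence / 100
  if (any(hit)) {
    orig_idx <- match(v[hit], .BASES)
    offset <- sample.int(3, sum(hit), replace = TRUE)
    v[hit] <- .BASES[((orig_idx - 1 + offset) %% 4) + 1]
  }
  keep <- (truncation + 1):n
  out <- v[keep]
  orig <- strsplit(consensus, "")[[1]][keep]
  list(sequence = paste(out, collapse = ""),
       realized_divergence_pct = 100 * mean(out != orig))
}

# Draw copy specifications for one segment until the TE budget is met.
# The budget is split cut/copy by the target ratio (Unknown families get
# `unknown_share` of the budget and are excluded from the ratio).
.draw_copy_specs <- function(config, te_target, ratio) {
  fp <- config$family_plan
  unknown_bp <- round(te_target * config$unknown_share)
  known <- te_target - unknown_bp
  budgets <- c(cut = known * ratio / (1 + ratio), copy = known / (1 + ratio),
               unknown = unknown_bp)
  fams_by_mech <- split(seq_len(nrow(fp)), fp$mechanism)
  budgets <- budgets[names(budgets) %in% names(fams_by_mech) | budgets > 0]
  specs <- list()
  repeat {
    open <- budgets > 120 & names(budgets) %in% names(fams_by_mech)
    if (!any(open)) break
    mech <- sample(names(budgets)[open], 1, prob = budgets[open])
    fi <- fams_by_mech[[mech]][sample.int(length(fams_by_mech[[mech]]), 1)]
    clen <- fp$consensus_length[fi]
    type <- sample(names(config$copy_type_probs), 1, prob = config$copy_type_probs)
    div <- if (type == "degraded") stats::runif(1, config$divergence_old[1], config$divergence_old[2])
           else stats::runif(1, config$divergence_young[1], config$divergence_young[2])
    cov <- switch(type,
                  intact = 1,
                  young_truncated = stats::runif(1, config$coverage_truncated[1],
                                                 config$coverage_truncated[2]),
                  degraded = stats::runif(1, config$coverage_degraded[1],
                                          config$coverage_degraded[2]))
    trunc <- round((1 - cov) * clen)
    copy_len <- clen - trunc
    if (copy_len > budgets[mech]) {
      # clip the last copy to the remaining budget via extra truncation
      copy_len <- floor(budgets[mech])
      if (copy_len < 120) { budgets[mech] <- 0; next }
      trunc <- clen - copy_len
    }
    budgets[mech] <- budgets[mech] - copy_len
    specs[[length(specs) + 1L]] <- data.frame(
      family_id = fp$family_id[fi], classification = fp$classification[fi],
      mechanism = mech, autonomous = fp$autonomous[fi],
      consensus_length = clen, type = type, divergence_req = div,
      trunc_bp = as.integer(trunc), copy_len = as.integer(copy_len),
      stringsAsFactors = FALSE)
  }
  specs <- do.call(rbind, specs)
  if (is.null(specs)) return(NULL)
  specs$intronic <- stats::runif(nrow(specs)) < config$intronic_te_fraction &
    specs$copy_len <= 2000
  # intronic copies are planted more degraded (selection against intronic
  # insertions); the shift stays clear of the 20% intactness boundary
  shift <- config$intronic_divergence_shift %||% 3
  young_intronic <- specs$intronic & specs$type != "degraded"
  specs$divergence_req[young_intronic] <-
    pmin(specs$divergence_req[young_intronic] + shift, 15)
  specs
}

.rank_weights <- function(classification) {
  w <- rep(1, 11)
  sub <- te_subclass(classification)
  if (sub == "LINE") w[1:3] <- c(6, 3, 2)
  if (classification == "DNA/Harbinger") w[8:11] <- 3
  if (sub == "LTR") { w[8:11] <- 3; w[11] <- 6 }
  if (sub == "Helitron") w[11] <- 6
  w
}

.draw_gene_struct <- function(gp) {
  mono <- stats::runif(1) < gp$p_mono
  u5 <- round(stats::runif(1, gp$utr5[1], gp$utr5[2]))
  u3 <- round(stats::runif(1, gp$utr3[1], gp$utr3[2]))
  n_ex <- if (mono) 1L else .sample1(gp$n_exons)
  cds <- round(stats::runif(n_ex, gp$cds_exon_len[1], gp$cds_exon_len[2]))
  introns <- if (n_ex > 1) {
    60L + round(stats::rlnorm(n_ex - 1, gp$intron_meanlog, gp$intron_sdlog))
  } else integer(0)
  list(u5 = u5, u3 = u3, cds = cds, introns = introns, mono = mono, n_ex = n_ex)
}

#' Plant a synthetic genome with known TE, gene and tandem content
#'
#' Builds each chromosome segment by segment: subtelomere-anchor segments are
#' satellite arrays; other segments are filled with TE copies (drawn to meet
#' the compartment's TE density and cut:copy targets almost exactly), genes
#' (a fraction of copies embedded in introns), interspersed tandem blocks and
#' log-normal intergenic gaps. Everything emitted is recorded in the truth
#' table.
#'
#' @param config A `simulation_config`.
#' @return List of class `mobilome_sim` with `genome` (DNAStringSet), `hits`
#'   (RepeatMasker-style hit table), `models` (`gene_models`), `compartments`,
#'   `tandem`, `library` (`te_library`), `anchors` (subtelomere anchors) and
#'   `truth` (list with `copies`, `genes`, plus the configuration).
#' @export
plant_genome <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  set.seed(config$seed)
  fp <- config$family_plan
  lib <- .sim_library_records(fp)
  cons_chars <- lapply(stats::setNames(lib$sequence, lib$id), function(s) strsplit(s, "")[[1]])
  gp <- config$gene_plan
  satellite_monomer <- .rand_seq(171)

  pieces <- list(); cursor <- list()
  copies <- list(); hits <- list(); genes <- list(); txs <- list(); feats <- list()
  comps <- list(); tandem <- list(); anchors <- numeric(0)
  copy_n <- 0L; gene_n <- 0L; link_n <- 0L

  emit_piece <- function(ch, s) pieces[[ch]][[length(pieces[[ch]]) + 1L]] <<- s

  emit_copy <- function(spec, ch, pos, site_truth, compartment) {
    copy_n <<- copy_n + 1L; link_n <<- link_n + 1L
    cc <- cons_chars[[spec$family_id]]
    clen <- length(cc)
    n_keep <- spec$copy_len
    trunc <- clen - n_keep
    hitmask <- stats::runif(clen) < spec$divergence_req / 100
    mut <- cc
    if (any(hitmask)) {
      oi <- match(cc[hitmask], .BASES)
      off <- sample.int(3, sum(hitmask), replace = TRUE)
      mut[hitmask] <- .BASES[((oi - 1 + off) %% 4) + 1]
    }
    keep <- (trunc + 1):clen
    realized <- 100 * mean(mut[keep] != cc[keep])
    strand <- sample(c("+", "-"), 1)
    gseq <- if (strand == "+") mut[keep] else
      rev(chartr("ACGT", "TGCA", mut[keep]))
    emit_piece(ch, paste(gseq, collapse = ""))
    s <- pos; e <- pos + n_keep
    cov <- n_keep / clen
    id <- sprintf("p%06d", copy_n)
    copies[[copy_n]] <<- data.frame(
      planted_id = id, chrom = ch, start = s, end = e, strand = strand,
      family_id = spec$family_id, classification = spec$classification,
      subclass = te_subclass(spec$classification), mechanism = spec$mechanism,
      autonomous = spec$autonomous, length = n_keep,
      divergence_pct = realized, consensus_coverage = cov,
      intact = realized < 20 & cov > 0.8, type = spec$type,
      site_truth = site_truth, compartment = compartment,
      stringsAsFactors = FALSE)
    make_hit <- function(s1, e1, cs1, ce1) {
      data.frame(score = round(1000 - 10 * realized), divergence_pct = round(realized, 1),
                 perc_del = 0, perc_ins = 0, chrom = ch, start = s1, end = e1,
                 strand = strand, family_id = spec$family_id,
                 classification = spec$classification,
                 consensus_start = cs1, consensus_end = ce1,
                 consensus_left = clen - ce1, link_id = link_n,
                 higher_score_overlap = FALSE, stringsAsFactors = FALSE)
    }
    if (stats::runif(1) < config$fragment_prob && n_keep >= 400) {
      k <- .sample1(150:(n_keep - 150))
      if (strand == "+") {
        hits[[length(hits) + 1L]] <<- make_hit(s, s + k, trunc, trunc + k)
        hits[[length(hits) + 1L]] <<- make_hit(s + k, e, trunc + k, clen)
      } else {
        hits[[length(hits) + 1L]] <<- make_hit(s, s + k, clen - k, clen)
        hits[[length(hits) + 1L]] <<- make_hit(s + k, e, trunc, clen - k)
      }
    } else {
      hits[[length(hits) + 1L]] <<- make_hit(s, e, trunc, clen)
    }
    e
  }

  emit_gene <- function(gobj, ch, pos, compartment) {
    gene_n <<- gene_n + 1L
    gid <- sprintf("g%05d", gene_n)
    tid <- paste0(gid, ".t1")
    strand <- sample(c("+", "-"), 1)
    st <- gobj$struct
    add_feat <- function(type, s, e) {
      feats[[length(feats) + 1L]] <<- data.frame(
        chrom = ch, start = s, end = e, strand = strand, type = type,
        transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
    }
    cur <- pos
    utr_left <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
    utr_right <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
    add_feat(utr_left, cur, cur + st$u5)
    emit_piece(ch, .rand_seq(st$u5))
    cur <- cur + st$u5
    first_exon_start <- pos
    for (i in seq_len(st$n_ex)) {
      add_feat("CDS", cur, cur + st$cds[i])
      emit_piece(ch, .rand_seq(st$cds[i]))
      cds_start <- cur
      cur <- cur + st$cds[i]
      if (i == 1 && st$n_ex > 1) add_feat("exon", first_exon_start, cur)
      if (i > 1 && i < st$n_ex) add_feat("exon", cds_start, cur)
      if (i == st$n_ex) {
        exon_s <- if (st$n_ex == 1) first_exon_start else cds_start
        add_feat("exon", exon_s, cur + st$u3)
      }
      if (i < st$n_ex) {
        intron_s <- cur
        te_here <- gobj$intron_tes[[i]]
        base <- st$introns[i]
        if (!is.null(te_here)) {
          off <- .sample1(20:(base - 20))
          emit_piece(ch, .rand_seq(off)); cur <- cur + off
          cur <- emit_copy(te_here, ch, cur, "intron", compartment)
          emit_piece(ch, .rand_seq(base - off)); cur <- cur + (base - off)
        } else {
          emit_piece(ch, .rand_seq(base)); cur <- cur + base
        }
        add_feat("intron", intron_s, cur)
      }
    }
    add_feat(utr_right, cur, cur + st$u3)
    emit_piece(ch, .rand_seq(st$u3))
    cur <- cur + st$u3
    sfams <- vapply(gobj$intron_tes, function(x) if (is.null(x)) NA_character_ else x$classification,
                    character(1))
    sfams <- sfams[!is.na(sfams)]
    w <- if (length(sfams)) .rank_weights(sfams[1]) else rep(1, 11)
    rank <- sample(1:11, 1, prob = w)
    genes[[gene_n]] <<- data.frame(gene_id = gid, chrom = ch, start = pos, end = cur,
                                   strand = strand, rank = rank,
                                   mono_exonic = st$mono, stringsAsFactors = FALSE)
    txs[[gene_n]] <<- data.frame(transcript_id = tid, gene_id = gid, chrom = ch,
                                 start = pos, end = cur, strand = strand,
                                 stringsAsFactors = FALSE)
    cur
  }

  for (si in seq_len(nrow(config$chrom_plan))) {
    seg <- config$chrom_plan[si, ]
    ch <- seg$chrom
    if (is.null(pieces[[ch]])) { pieces[[ch]] <- list(); cursor[[ch]] <- 0L }
    seg_start <- cursor[[ch]]
    L <- seg$length
    comps[[si]] <- data.frame(chrom = ch, start = seg_start, end = seg_start + L,
                              label = seg$label, stringsAsFactors = FALSE)
    if (seg$label == "subtelomere_anchor") {
      reps <- ceiling(L / nchar(satellite_monomer))
      emit_piece(ch, substr(strrep(satellite_monomer, reps), 1, L))
      tandem[[length(tandem) + 1L]] <- data.frame(
        chrom = ch, start = seg_start, end = seg_start + L, label = "satellite",
        stringsAsFactors = FALSE)
      anchors[ch] <- seg_start + L
      cursor[[ch]] <- seg_start + L
      next
    }
    te_frac <- if (!is.na(seg$te_target)) seg$te_target else
      config$density_targets[[seg$label]]
    ratio <- if (!is.na(seg$cut_copy)) seg$cut_copy else
      config$cut_copy_targets[[seg$label]]
    specs <- if (te_frac > 0) .draw_copy_specs(config, round(L * te_frac), ratio) else NULL

    intronic_pool <- if (!is.null(specs)) which(specs$intronic) else integer(0)
    standalone <- if (!is.null(specs)) which(!specs$intronic) else integer(0)

    gene_fill <- gp$gene_fill[[seg$label]] %||% 0.30
    mean_span <- mean(gp$utr5) + mean(gp$utr3) +
      mean(gp$n_exons) * mean(gp$cds_exon_len) +
      (mean(gp$n_exons) - 1) * (60 + exp(gp$intron_meanlog + gp$intron_sdlog^2 / 2))
    n_genes <- max(1L, floor(L * gene_fill / mean_span))
    gene_structs <- replicate(n_genes, .draw_gene_struct(gp), simplify = FALSE)
    gene_objs <- lapply(gene_structs, function(st) {
      list(struct = st, intron_tes = vector("list", max(0L, st$n_ex - 1L)))
    })
    slot_gene <- integer(0); slot_idx <- integer(0)
    for (gi in seq_along(gene_structs)) {
      if (gene_structs[[gi]]$n_ex > 1) {
        slot_gene <- c(slot_gene, rep(gi, gene_structs[[gi]]$n_ex - 1L))
        slot_idx <- c(slot_idx, seq_len(gene_structs[[gi]]$n_ex - 1L))
      }
    }
    free <- sample.int(length(slot_gene))  # each intron hosts at most one copy
    for (k in intronic_pool) {
      if (!length(free)) { standalone <- c(standalone, k); next }
      sl <- free[1]; free <- free[-1]
      gene_objs[[slot_gene[sl]]]$intron_tes[[slot_idx[sl]]] <- specs[k, ]
    }
    gene_span <- vapply(seq_along(gene_objs), function(gi) {
      st <- gene_objs[[gi]]$struct
      te_bp <- sum(vapply(gene_objs[[gi]]$intron_tes,
                          function(x) if (is.null(x)) 0 else as.numeric(x$copy_len),
                          numeric(1)))
      st$u5 + st$u3 + sum(st$cds) + sum(st$introns) + te_bp
    }, numeric(1))

    tnd_target <- round(L * config$tandem_share)
    tnd_lens <- integer(0)
    while (sum(tnd_lens) < tnd_target) {
      tnd_lens <- c(tnd_lens, .sample1(200:800))
    }

    blocks <- c(lapply(standalone, function(k) list(kind = "te", spec = specs[k, ])),
                lapply(seq_along(gene_objs), function(gi) list(kind = "gene", obj = gene_objs[[gi]])),
                lapply(tnd_lens, function(l) list(kind = "tandem", len = l)))
    block_len <- c(if (length(standalone)) specs$copy_len[standalone] else numeric(0),
                   gene_span, tnd_lens)
    # drop TE-free genes if the segment overflows
    ord_all <- seq_along(blocks)
    while (sum(block_len) > 0.97 * L) {
      droppable <- which(vapply(blocks, function(b) {
        b$kind == "gene" && all(vapply(b$obj$intron_tes, is.null, logical(1)))
      }, logical(1)))
      if (!length(droppable)) break
      d <- droppable[length(droppable)]
      blocks <- blocks[-d]; block_len <- block_len[-d]
    }
    ord <- sample.int(length(blocks))
    blocks <- blocks[ord]; block_len <- block_len[ord]
    gap_total <- L - sum(block_len)
    n_gaps <- length(blocks) + 1L
    gw <- stats::rlnorm(n_gaps, gp$gap_meanlog, gp$gap_sdlog)
    gaps <- floor(gw / sum(gw) * gap_total)
    gaps[n_gaps] <- gap_total - sum(gaps[-n_gaps])

    pos <- seg_start
    for (bi in seq_along(blocks)) {
      if (gaps[bi] > 0) { emit_piece(ch, .rand_seq(gaps[bi])); pos <- pos + gaps[bi] }
      b <- blocks[[bi]]
      if (b$kind == "te") {
        site <- "intergenic"
        pos <- emit_copy(b$spec, ch, pos, site, seg$label)
      } else if (b$kind == "gene") {
        pos <- emit_gene(b$obj, ch, pos, seg$label)
      } else {
        reps <- ceiling(b$len / nchar(satellite_monomer))
        emit_piece(ch, substr(strrep(satellite_monomer, reps), 1, b$len))
        tandem[[length(tandem) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = pos + b$len, label = "microsat",
          stringsAsFactors = FALSE)
        pos <- pos + b$len
      }
    }
    if (gaps[n_gaps] > 0) {
      emit_piece(ch, .rand_seq(gaps[n_gaps]))
      pos <- pos + gaps[n_gaps]
    }
    if (pos != seg_start + L) {  # rounding drift: pad or trim background
      if (pos < seg_start + L) {
        emit_piece(ch, .rand_seq(seg_start + L - pos))
      } else {
        stop("internal error: segment overflow")
      }
    }
    cursor[[ch]] <- seg_start + L
  }

  genome <- Biostrings::DNAStringSet(vapply(pieces, function(p) {
    paste(unlist(p), collapse = "")
  }, character(1)))
  names(genome) <- names(pieces)

  copies_df <- do.call(rbind, copies); rownames(copies_df) <- NULL
  hits_df <- do.call(rbind, hits); rownames(hits_df) <- NULL
  genes_df <- do.call(rbind, genes)
  feats_df <- do.call(rbind, feats)
  models <- structure(list(genes = genes_df, transcripts = do.call(rbind, txs),
                           features = feats_df), class = "gene_models")
  comps_df <- do.call(rbind, comps)
  tandem_df <- do.call(rbind, tandem)
  structure(list(
    genome = genome, hits = hits_df, models = models,
    compartments = comps_df, tandem = tandem_df, library = lib,
    anchors = anchors,
    truth = list(copies = copies_df, genes = genes_df, config = config)),
    class = "mobilome_sim")
}

#' @export
print.mobilome_sim <- function(x, ...) {
  cat(sprintf("mobilome_sim: %d chromosomes (%.1f Mb), %d planted copies, %d genes\n",
              length(x$genome), sum(BiocGenerics::width(x$genome)) / 1e6,
              nrow(x$truth$copies), nrow(x$truth$genes)))
  invisible(x)
}

#' Simulate H3K79me2-style broad peaks over planted copies
#'
#' Each copy receives a peak with a probability set by its intact status; the
#' peak covers at least the configured fraction of the copy body and may
#' extend a short way into the flanks.
#'
#' @param copies Truth copies data.frame (needs `chrom`, `start`, `end`,
#'   `intact`, `planted_id` or `copy_id`).
#' @param peak_plan Peak plan list (see [simulation_config()]).
#' @param seed Integer seed.
#' @param chrom_lengths Optional named vector used to clip flanks.
#' @return List with `peaks` (intervals with `label`) and `provenance`
#'   (copy id per peak).
#' @export
simulate_peaks <- function(copies, peak_plan, seed, chrom_lengths = NULL) {
  set.seed(seed)
  ids <- copies$planted_id %||% copies$copy_id
  p <- ifelse(copies$intact, peak_plan$p_peak_intact, peak_plan$p_peak_nonintact)
  hit <- stats::runif(nrow(copies)) < p
  idx <- which(hit)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    len <- copies$end[i] - copies$start[i]
    frac <- stats::runif(1, peak_plan$min_body_fraction, 1)
    cov <- round(frac * len)
    off <- .sample1(0:(len - cov))
    s <- copies$start[i] + off - round(stats::runif(1, peak_plan$flank[1], peak_plan$flank[2]))
    e <- copies$start[i] + off + cov + round(stats::runif(1, peak_plan$flank[1], peak_plan$flank[2]))
    s <- max(0, s)
    if (!is.null(chrom_lengths)) e <- min(e, chrom_lengths[[as.character(copies$chrom[i])]])
    out[[j]] <- data.frame(chrom = copies$chrom[i], start = s, end = e,
                           label = sprintf("peak_%s", ids[i]),
                           stringsAsFactors = FALSE)
  }
  peaks <- if (length(out)) do.call(rbind, out) else .empty_intervals()
  list(peaks = peaks,
       provenance = data.frame(copy_id = ids[idx], stringsAsFactors = FALSE))
}

#' Draw the set of sRNA-covered copies
#'
#' sRNA targeting is a per-copy property held constant across stages and
#' replicates: intact copies are covered with `p_covered_intact` (split by
#' peak status when `p_covered_intact_peak` is set, preserving the marginal),
#' non-intact copies with `p_covered_nonintact`.
#'
#' @param copies Truth copies data.frame.
#' @param srna_plan sRNA plan list.
#' @param seed Integer seed.
#' @param peak_copy_ids Optional ids of peak-bearing copies.
#' @return Character vector of covered copy ids.
#' @export
draw_srna_coverage <- function(copies, srna_plan, seed, peak_copy_ids = NULL) {
  set.seed(seed)
  ids <- copies$planted_id %||% copies$copy_id
  p_int <- srna_plan$p_covered_intact
  p_non <- srna_plan$p_covered_nonintact
  p <- ifelse(copies$intact, p_int, p_non)
  if (!is.null(peak_copy_ids) && !is.null(srna_plan$p_covered_intact_peak)) {
    p_pk <- srna_plan$p_covered_intact_peak
    p_peak_marg <- mean(ids[copies$intact] %in% peak_copy_ids)
    p_nopk <- if (p_peak_marg < 1) {
      max(0, min(1, (p_int - p_peak_marg * p_pk) / (1 - p_peak_marg)))
    } else p_pk
    peaked <- ids %in% peak_copy_ids
    p[copies$intact & peaked] <- p_pk
    p[copies$intact & !peaked] <- p_nopk
  }
  ids[stats::runif(nrow(copies)) < p]
}

#' Simulate small-RNA read alignments over planted copies
#'
#' Covered copies are chosen by intact status (optionally conditioned on peak
#' association to plant a joint sRNA/peak structure); each covered copy
#' receives Poisson-many reads falling fully inside it, with the configured
#' length distribution (21-nt mode) and, when the genome is supplied, a
#' planted 5'-U bias achieved by preferentially starting reads on a genomic T
#' (strand-aware).
#'
#' @param copies Truth copies data.frame.
#' @param srna_plan sRNA plan list (see [simulation_config()]).
#' @param stage Stage label used in read ids.
#' @param seed Integer seed.
#' @param genome Optional `DNAStringSet` for the 5'-U bias.
#' @param peak_copy_ids Optional copy ids that carry a peak; when given
#'   together with `p_covered_intact_peak`, intact copies are covered with
#'   that probability if peaked, and with the complementary probability that
#'   preserves the marginal `p_covered_intact` otherwise.
#' @param covered_ids Optional precomputed covered set (see
#'   [draw_srna_coverage()]) shared across stages and replicates.
#' @return Alignments data.frame with an extra `source_copy` column.
#' @export
simulate_reads <- function(copies, srna_plan, stage, seed, genome = NULL,
                           peak_copy_ids = NULL, covered_ids = NULL) {
  set.seed(seed)
  ids <- copies$planted_id %||% copies$copy_id
  if ((srna_plan$depth_per_copy %||% 0) <= 0) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      read_length = integer(), multiplicity = integer(),
                      source_copy = character(), stringsAsFactors = FALSE))
  }
  covered <- if (!is.null(covered_ids)) ids %in% covered_ids else
    ids %in% draw_srna_coverage(copies, srna_plan, seed, peak_copy_ids)
  lens_avail <- as.integer(names(srna_plan$length_probs))
  # forcing probability that yields the target observed 5'-U fraction given
  # the 0.25 background frequency of T
  q_force <- max(0, min(1, (srna_plan$u5_bias - 0.25) / 0.75))
  out <- list()
  counter <- 0L
  for (i in which(covered)) {
    len_copy <- copies$end[i] - copies$start[i]
    n_reads <- 1L + stats::rpois(1, max(0, srna_plan$depth_per_copy - 1))
    ch <- as.character(copies$chrom[i])
    cseq <- if (!is.null(genome)) {
      strsplit(as.character(Biostrings::subseq(genome[[ch]], copies$start[i] + 1L,
                                               copies$end[i])), "")[[1]]
    } else NULL
    for (r in seq_len(n_reads)) {
      rl <- sample(lens_avail, 1, prob = srna_plan$length_probs)
      if (rl >= len_copy) rl <- min(lens_avail)
      if (rl >= len_copy) next
      strand <- sample(c("+", "-"), 1)
      max_off <- len_copy - rl
      off <- NULL
      if (!is.null(cseq) && stats::runif(1) < q_force) {
        cand <- if (strand == "+") which(cseq[1:(max_off + 1)] == "T") - 1L else
          which(cseq[rl:len_copy] == "A") - 1L
        if (length(cand)) off <- cand[sample.int(length(cand), 1)]
      }
      if (is.null(off)) off <- .sample1(0:max_off)
      counter <- counter + 1L
      out[[counter]] <- data.frame(
        read_id = sprintf("%s_r%07d", stage, counter),
        chrom = ch, start = copies$start[i] + off,
        end = copies$start[i] + off + rl, strand = strand, read_length = rl,
        multiplicity = sample(c(1L, 1L, 1L, 2L, 4L), 1),
        source_copy = ids[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      read_length = integer(), multiplicity = integer(),
                      source_copy = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Simulate a bare panel of TE copies (no genome) for association studies
#'
#' Tiles `n` copies along one synthetic chromosome with the requested intact
#' fraction; useful for validating association estimators at large n without
#' building a full genome.
#'
#' @param n Number of copies.
#' @param p_intact Probability a copy is intact.
#' @param copy_len,spacing Copy length and inter-copy spacing (bp).
#' @param seed Integer seed.
#' @return List with `copies` (a `te_copies`-like data.frame) and
#'   `chrom_lengths`.
#' @export
simulate_copy_panel <- function(n, p_intact = 0.5, copy_len = 1000,
                                spacing = 200, seed = 1) {
  set.seed(seed)
  starts <- (seq_len(n) - 1L) * (copy_len + spacing)
  intact <- stats::runif(n) < p_intact
  copies <- data.frame(
    copy_id = sprintf("panel%06d", seq_len(n)),
    planted_id = sprintf("panel%06d", seq_len(n)),
    chrom = "panel_chr", start = starts, end = starts + copy_len,
    strand = "+", family_id = "PanelFam-1", classification = "Unknown",
    length = copy_len, divergence_pct = ifelse(intact, 5, 25),
    consensus_coverage = ifelse(intact, 1, 0.5),
    intact = intact, stringsAsFactors = FALSE)
  list(copies = copies,
       chrom_lengths = c(panel_chr = n * (copy_len + spacing)))
}

.spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate expression with a planted Spearman correlation to a covariate
#'
#' Gaussian-copula construction: normal scores of the covariate are mixed
#' with noise at the Pearson correlation that induces the requested Spearman
#' correlation, then mapped to a log-normal TPM scale.
#'
#' @param x Numeric covariate (e.g. genic TE:CDS ratios).
#' @param rho Target Spearman correlation.
#' @return Numeric TPM vector (uses the current RNG stream).
#' @export
simulate_correlated_tpm <- function(x, rho) {
  n <- length(x)
  zx <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  rp <- .spearman_to_pearson(rho)
  z <- rp * zx + sqrt(1 - rp^2) * stats::rnorm(n)
  2^(4 + 1.5 * z)
}

#' Simulate a family-level expression/regulation panel
#'
#' Per-family TPM, mean sRNA CPM on intact copies and mean peak-overlap
#' fraction with planted Spearman correlations (TPM~CPM positive, TPM~overlap
#' negative), for validating the family-level correlation analysis.
#'
#' @param n Number of families.
#' @param rho_srna,rho_peak Target Spearman correlations.
#' @param seed Integer seed.
#' @return data.frame with `family_id`, `tpm`, `mean_cpm_intact`,
#'   `mean_peak_overlap`.
#' @export
simulate_family_panel <- function(n = 150, rho_srna = 0.319, rho_peak = -0.28,
                                  seed = 1) {
  set.seed(seed)
  z0 <- stats::rnorm(n)
  tpm <- 2^(4 + 1.5 * z0)
  r1 <- .spearman_to_pearson(rho_srna)
  r2 <- .spearman_to_pearson(rho_peak)
  z_cpm <- r1 * z0 + sqrt(1 - r1^2) * stats::rnorm(n)
  z_pk <- r2 * z0 + sqrt(1 - r2^2) * stats::rnorm(n)
  data.frame(family_id = sprintf("fam%04d", seq_len(n)),
             tpm = tpm,
             mean_cpm_intact = 2^(3 + z_cpm),
             mean_peak_overlap = stats::pnorm(z_pk),
             stringsAsFactors = FALSE)
}

#' Write all simulation outputs to a directory
#'
#' Emits genome FASTA, library FASTA, RepeatMasker-style `.out` hits, gene
#' GFF3, compartment and tandem BED, and the truth tables as TSV.
#'
#' @param sim A `mobilome_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             library = file.path(dir, "library.fa"),
             hits = file.path(dir, "hits.out"),
             genes = file.path(dir, "genes.gff3"),
             compartments = file.path(dir, "compartments.bed"),
             tandem = file.path(dir, "tandem.bed"),
             truth_copies = file.path(dir, "truth_copies.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_library_fasta(sim$library, paths["library"])
  write_repeatmasker_out(sim$hits, paths["hits"])
  write_gff3(sim$models, paths["genes"])
  write_bed(sim$compartments[, c("chrom", "start", "end", "label")], paths["compartments"])
  write_bed(sim$tandem, paths["tandem"])
  write_tsv(sim$truth$copies, paths["truth_copies"],
            comments = sprintf("seed=%d", sim$truth$config$seed))
  write_tsv(sim$truth$genes, paths["truth_genes"])
  invisible(paths)
}
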