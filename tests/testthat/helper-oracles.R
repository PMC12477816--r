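# Independent oracles used throughout the suite. These deliberately take the
# dumbest correct route (per-base label vectors, quadratic DP, double loops)
# so they share no code with the implementation they check.

# --- Smith-Waterman local alignment with traceback -------------------------
# Returns best score plus identity (matches / alignment columns) and the
# aligned span on each sequence for the optimal path (ties broken toward
# diagonal moves, matching the convention of affine-free alignments).
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- H[i, j] + if (A[i] == B[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, sub, H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  i <- best[1]; j <- best[2]
  matches <- 0; cols <- 0
  end_a <- i - 1; end_b <- j - 1
  while (i > 1 && j > 1 && H[i, j] > 0) {
    sub <- if (A[i - 1] == B[j - 1]) match else mismatch
    if (H[i, j] == H[i - 1, j - 1] + sub) {
      matches <- matches + (A[i - 1] == B[j - 1])
      cols <- cols + 1; i <- i - 1; j <- j - 1
    } else if (H[i, j] == H[i - 1, j] + gap) {
      cols <- cols + 1; i <- i - 1
    } else {
      cols <- cols + 1; j <- j - 1
    }
  }
  start_a <- i - 1; start_b <- j - 1
  list(score = max(H),
       identity = if (cols) matches / cols else 0,
       span_a = end_a - start_a, span_b = end_b - start_b)
}

sw_oracle_best_orientation <- function(a, b, ...) {
  fwd <- sw_oracle(a, b, ...)
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(b, "")[[1]])), collapse = "")
  rev_ <- sw_oracle(a, rc, ...)
  if (rev_$score > fwd$score) rev_ else fwd
}

# all-pairs oracle clustering: connected components of the graph joining
# pairs that satisfy both thresholds in their best orientation
oracle_cluster_components <- function(library, identity_thr, coverage_thr) {
  n <- nrow(library)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      o <- sw_oracle_best_orientation(library$sequence[i], library$sequence[j])
      cov <- min(o$span_a / nchar(library$sequence[i]),
                 o$span_b / nchar(library$sequence[j]))
      shorter <- which.min(c(nchar(library$sequence[i]), nchar(library$sequence[j])))
      cov <- c(o$span_a / nchar(library$sequence[i]),
               o$span_b / nchar(library$sequence[j]))[shorter]
      if (o$identity >= identity_thr && cov >= coverage_thr) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# --- per-base labelling oracles --------------------------------------------
# label vector over one chromosome: 0-based position k is element k+1
label_vector <- function(len, intervals, label = TRUE) {
  v <- rep(FALSE, len)
  for (r in seq_len(nrow(intervals))) {
    if (intervals$end[r] > intervals$start[r]) {
      v[(intervals$start[r] + 1):intervals$end[r]] <- label
    }
  }
  v
}

# per-base site-class oracle for a single chromosome
site_class_oracle <- function(models, len, chrom, proximal_bp = 500) {
  v <- rep("intergenic_distal", len)
  fe <- models$features[models$features$chrom == chrom, , drop = FALSE]
  paint <- function(v, iv, lab) {
    for (r in seq_len(nrow(iv))) v[(iv$start[r] + 1):iv$end[r]] <- lab
    v
  }
  for (ty in c("intron", "three_prime_UTR", "five_prime_UTR", "CDS")) {
    iv <- fe[fe$type == ty, , drop = FALSE]
    lab <- switch(ty, CDS = "CDS", five_prime_UTR = "UTR5",
                  three_prime_UTR = "UTR3", intron = "intron")
    if (nrow(iv)) v <- paint(v, iv, lab)
  }
  tx <- models$transcripts[models$transcripts$chrom == chrom, , drop = FALSE]
  if (nrow(tx)) {
    spans <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d) {
      data.frame(start = min(d$start), end = max(d$end))
    }))
    near <- rep(FALSE, len)
    for (r in seq_len(nrow(spans))) {
      s <- max(0, spans$start[r] - proximal_bp)
      e <- min(len, spans$end[r] + proximal_bp)
      near[(s + 1):e] <- TRUE
    }
    v[v == "intergenic_distal" & near] <- "intergenic_proximal"
  }
  v
}

# brute-force full-containment read counting
count_oracle <- function(reads, copies) {
  counts <- integer(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    counts[i] <- sum(reads$chrom == copies$chrom[i] &
                       reads$start >= copies$start[i] &
                       reads$end <= copies$end[i])
  }
  counts
}

# --- rank-statistic reference formulas -------------------------------------
kruskal_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, sum)
  n <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rbar^2 / n) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

wilcoxon_oracle_p <- function(x, y) {
  # normal approximation with continuity and tie correction, two-sided,
  # matching the large-sample path of the rank-sum test
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  mu <- n1 * n2 / 2
  z <- W - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
}

chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# --- random fixture builders ------------------------------------------------
random_intervals <- function(n, len, chrom = "c1", min_w = 50, max_w = 2000) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi, 1) - 1L, integer(1))
  data.frame(chrom = chrom, start = s, end = s + w, stringsAsFactors = FALSE)
}

# random non-overlapping gene models on one chromosome
random_gene_models <- function(n_genes, len, chrom = "c1") {
  genes <- list(); txs <- list(); feats <- list()
  pos <- sample(200:800, 1)
  g <- 0L
  while (g < n_genes && pos < len - 6000) {
    g <- g + 1L
    gid <- sprintf("%s_g%03d", chrom, g); tid <- paste0(gid, ".t1")
    u5 <- sample(50:200, 1); u3 <- sample(50:200, 1)
    n_ex <- sample(2:4, 1)
    cds <- sample(100:400, n_ex, replace = TRUE)
    intr <- sample(80:600, n_ex - 1, replace = TRUE)
    cur <- pos
    add <- function(type, s, e) feats[[length(feats) + 1L]] <<- data.frame(
      chrom = chrom, start = s, end = e, strand = "+", type = type,
      transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
    add("five_prime_UTR", cur, cur + u5); cur <- cur + u5
    first_exon <- pos
    for (i in seq_len(n_ex)) {
      add("CDS", cur, cur + cds[i])
      cds_start <- cur; cur <- cur + cds[i]
      if (i == 1) add("exon", first_exon, cur)
      if (i > 1 && i < n_ex) add("exon", cds_start, cur)
      if (i == n_ex && n_ex > 1) add("exon", cds_start, cur + u3)
      if (i < n_ex) { add("intron", cur, cur + intr[i]); cur <- cur + intr[i] }
    }
    add("three_prime_UTR", cur, cur + u3); cur <- cur + u3
    genes[[g]] <- data.frame(gene_id = gid, chrom = chrom, start = pos, end = cur,
                             strand = "+", stringsAsFactors = FALSE)
    txs[[g]] <- data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
                           start = pos, end = cur, strand = "+",
                           stringsAsFactors = FALSE)
    pos <- cur + sample(300:2500, 1)
  }
  structure(list(genes = do.call(rbind, genes), transcripts = do.call(rbind, txs),
                 features = do.call(rbind, feats)), class = "gene_models")
}

# minimal te_copies-like data.frame from intervals
as_copies <- function(iv, family_id = "FamA", classification = "DNA/Test",
                      divergence = 5, coverage = 0.9) {
  n <- nrow(iv)
  if (n == 0) {
    out <- data.frame(copy_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      family_id = character(), classification = character(),
                      length = integer(), n_fragments = integer(),
                      divergence_pct = numeric(), consensus_coverage = numeric(),
                      intact = logical(), subclass = character(),
                      mechanism = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(copy_id = sprintf("%s_c%04d", iv$chrom, seq_len(n)),
                    chrom = iv$chrom, start = iv$start, end = iv$end,
                    strand = "+", family_id = family_id,
                    classification = classification,
                    length = iv$end - iv$start, n_fragments = 1L,
                    divergence_pct = divergence, consensus_coverage = coverage,
                    stringsAsFactors = FALSE)
  out$intact <- classify_intact(out$divergence_pct, out$consensus_coverage)
  out$subclass <- te_subclass(out$classification)
  out$mechanism <- te_mechanism(out$classification)
  out
}

small_sim_config <- function(seed = 11, total_kb = 500) {
  kb <- total_kb * 1000 / 500
  plan <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    label = c("subtelomere_anchor", "autosome", "autosome",
              "PAR", "SDR_male", "PAR"),
    length = as.integer(c(20, 40, 240, 60, 100, 40) * kb),
    te_target = c(NA, 0.47, NA, NA, NA, NA),
    cut_copy = NA_real_, stringsAsFactors = FALSE)
  fp <- default_family_plan()
  fp$consensus_length <- pmin(fp$consensus_length, 4000L)
  simulation_config(seed = seed, chrom_plan = plan, family_plan = fp)
}
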