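# Read counting semantics, CPM, association flags, profiles, peak overlap,
# intersection statistics, metaprofiles and consensus-feature coverage.

mk_reads <- function(chrom, start, end, strand = "+", mult = 1L) {
  n <- length(start)
  data.frame(read_id = sprintf("r%04d", seq_len(n)), chrom = chrom,
             start = start, end = end,
             strand = rep_len(strand, n),
             read_length = end - start, multiplicity = rep_len(mult, n),
             stringsAsFactors = FALSE)
}

test_that("read length filter bounds are inclusive", {
  reads <- mk_reads("c1", c(0L, 0L, 0L), c(19L, 20L, 24L))
  kept <- filter_reads_by_length(reads, 20, 24)
  expect_equal(kept$read_length, c(20L, 24L))
})

test_that("counting requires full containment, counts all containing copies", {
  copies <- as_copies(data.frame(chrom = "c1", start = c(100L, 150L, 500L),
                                 end = c(300L, 250L, 600L)))
  reads <- mk_reads("c1",
                    start = c(160L, 90L, 170L),
                    end = c(181L, 111L, 191L))
  counts <- count_reads_over_copies(reads, copies)
  # read 1 and 3 sit inside both nested copies; read 2 spans copy 1's edge
  expect_equal(counts, c(2L, 2L, 0L))
  expect_equal(counts, count_oracle(reads, copies))
})

test_that("counting equals the brute-force double loop on a large random instance", {
  set.seed(37)
  len <- 1000000L
  copies <- as_copies(random_intervals(1000, len, min_w = 100, max_w = 1500))
  starts <- sample.int(len - 30L, 10000) - 1L
  reads <- mk_reads("c1", starts, starts + sample(20:24, 10000, replace = TRUE))
  expect_identical(count_reads_over_copies(reads, copies),
                   count_oracle(reads, copies))
})

test_that("CPM is linear in counts and inversely linear in library size", {
  expect_equal(cpm(10, 1e6), 10)
  expect_equal(cpm(0, 1e6), 0)
  expect_equal(cpm(10, 2e6), 5)
  m <- matrix(c(10, 20, 30, 40), 2)
  expect_equal(cpm(m, c(1e6, 2e6)), matrix(c(10, 20, 15, 20), 2))
})

test_that("count prefilter keeps row sums of at least 10, strict per-sample variant", {
  m <- rbind(a = c(5, 5), b = c(5, 4), c = c(0, 0), d = c(12, 0))
  kept <- prefilter_counts(m, 10)
  expect_equal(rownames(kept), c("a", "d"))
  kept_strict <- prefilter_counts(rbind(a = c(10, 10), b = c(12, 9)), 10,
                                  per_sample = TRUE)
  expect_equal(rownames(kept_strict), "a")
})

test_that("sRNA association flags follow the every-stage rule and stratify by intactness", {
  cpm_mat <- rbind(c(1, 2, 3), c(1, 0, 3), c(0, 0, 0), c(5, 5, 5))
  intact <- c(TRUE, TRUE, FALSE, FALSE)
  fl <- flag_srna_associated(cpm_mat, intact)
  expect_equal(fl$associated, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(fl$prop_intact, 0.5)
  expect_equal(fl$prop_nonintact, 0.5)
  fl_any <- flag_srna_associated(cpm_mat, intact, rule = "any_stage")
  expect_equal(fl_any$associated, c(TRUE, TRUE, FALSE, TRUE))
  # all-zero CPM: nothing associated
  expect_equal(flag_srna_associated(matrix(0, 3, 2), c(TRUE, FALSE, TRUE))$prop_all, 0)
})

test_that("strand and 5' profiles read the biological 5' base from the genome", {
  genome <- Biostrings::DNAStringSet(c(c1 = "TTTTTTTTTTAAAAAAAAAACCCCCCCCCC"))
  copies <- as_copies(data.frame(chrom = "c1", start = 0L, end = 30L))
  copies$strand <- "+"
  # plus-strand read starting on T -> sense, 5' U-equivalent
  r_plus <- mk_reads("c1", 0L, 21L, strand = "+")
  # minus-strand read whose last genomic base is A -> 5' U-equivalent, antisense
  r_minus <- mk_reads("c1", 5L, 20L, strand = "-")
  prof <- strand_and_5prime_profile(rbind(r_plus, r_minus), copies, genome)
  expect_equal(prof$u5_fraction, 1)
  expect_equal(prof$by_length$sense_fraction[prof$by_length$read_length == 21], 1)
  expect_equal(prof$by_length$sense_fraction[prof$by_length$read_length == 15], 0)
})

test_that("peak overlap fraction equals the per-base union oracle", {
  copies <- as_copies(data.frame(chrom = "c1", start = 0L, end = 300L))
  # two peaks covering disjoint thirds -> 2/3; overlapping peaks counted once
  peaks <- data.frame(chrom = "c1", start = c(0L, 100L, 50L), end = c(100L, 200L, 120L))
  po <- peak_overlap(copies, peaks)
  expect_equal(po$peak_overlap_fraction, 2 / 3)
  expect_true(po$peak_associated)
  none <- peak_overlap(copies, peaks[0, ])
  expect_equal(none$peak_overlap_fraction, 0)
  expect_false(none$peak_associated)
  # half-covering peak
  half <- peak_overlap(copies, data.frame(chrom = "c1", start = 0L, end = 150L))
  expect_equal(half$peak_overlap_fraction, 0.5)
  # random instances vs per-base oracle, exact
  set.seed(38)
  len <- 100000L
  cp <- as_copies(random_intervals(50, len))
  pk <- random_intervals(30, len, min_w = 100, max_w = 3000)
  po_r <- peak_overlap(cp, pk)
  v <- label_vector(len, pk)
  for (i in seq_len(nrow(cp))) {
    expect_equal(po_r$peak_overlap_fraction[i],
                 sum(v[(cp$start[i] + 1):cp$end[i]]) / (cp$end[i] - cp$start[i]))
  }
})

test_that("intersection statistics report conditional proportions and chi-square strata", {
  n <- 100
  assoc <- data.frame(copy_id = sprintf("c%03d", 1:n), intact = TRUE,
                      site_class = rep(c("intergenic_distal", "intron"), 50),
                      srna_associated = FALSE, peak_associated = FALSE)
  assoc$peak_associated[1:30] <- TRUE
  assoc$srna_associated[c(1:22, 31:33)] <- TRUE
  class(assoc) <- c("association_table", "data.frame")
  st <- intersection_stats(assoc)
  expect_equal(st$intact$both, 22)
  expect_equal(st$intact$p_srna_given_peak, 22 / 30)
  expect_equal(st$intact$p_peak_given_srna, 22 / 25)
  # disjoint sets -> zero conditionals
  assoc2 <- assoc
  assoc2$srna_associated <- rep(c(TRUE, FALSE), 50)
  assoc2$peak_associated <- rep(c(FALSE, TRUE), 50)
  st2 <- intersection_stats(assoc2)
  expect_equal(st2$intact$p_srna_given_peak, 0)
  expect_true(!is.null(st$site_class_chisq_p))
})

test_that("metaprofile of an all-ones track is exactly flat", {
  len <- 50000L
  signal <- data.frame(chrom = "c1", start = 0L, end = len, value = 1)
  set.seed(39)
  regions <- random_intervals(60, len, min_w = 40, max_w = 4000)
  regions$strand <- sample(c("+", "-"), 60, replace = TRUE)
  regions$start <- pmax(regions$start, 3000L)          # keep flanks in-track
  regions$end <- pmin(regions$end, len - 3000L)
  regions <- regions[regions$end > regions$start, ]
  mp <- metaprofile(signal, regions, body_bp = 1000, flank_bp = 2000, bin_bp = 10)
  expect_lt(max(abs(mp$profile - 1)), 1e-9)
})

test_that("body bins average the underlying native signal (resampling oracle)", {
  # 1-bp resolution signal whose value equals its position
  len <- 2000L
  signal <- data.frame(chrom = "c1", start = 0:(len - 1), end = 1:len,
                       value = 0:(len - 1))
  regions <- data.frame(chrom = "c1", start = 500L, end = 1000L, strand = "+")
  mp <- metaprofile(signal, regions, body_bp = 1000, flank_bp = 100, bin_bp = 10)
  body <- mp$profile[1, 11:110]
  # 500-bp body rescaled to 100 bins: bin k averages 5 native bp
  oracle <- vapply(seq_len(100), function(k) {
    mean(500 + ((k - 1) * 5):((k * 5) - 1))
  }, numeric(1))
  expect_equal(unname(body), oracle, tolerance = 1e-9)
  # minus-strand regions are reversed
  regions$strand <- "-"
  mp_rev <- metaprofile(signal, regions, body_bp = 1000, flank_bp = 100, bin_bp = 10)
  expect_equal(unname(mp_rev$profile[1, 11:110]), rev(oracle), tolerance = 1e-9)
})

test_that("planted body enrichment appears in the metaprofile", {
  set.seed(40)
  len <- 200000L
  regions <- random_intervals(40, len, min_w = 500, max_w = 1500)
  regions <- regions[order(regions$start), ]
  regions <- regions[c(TRUE, diff(regions$start) > 5000), ]  # spread out
  pk <- reduce_intervals(regions)
  genome_iv <- data.frame(chrom = "c1", start = 0L, end = len)
  bg <- subtract_intervals(genome_iv, pk)
  signal <- rbind(cbind(bg, value = 1), cbind(pk, value = 2))
  mp <- metaprofile(signal, regions, body_bp = 1000, flank_bp = 2000, bin_bp = 10)
  nb <- ncol(mp$profile)   # 200 flank + 100 body + 200 flank bins
  body_mean <- mean(mp$profile[1, 201:300])
  flank_mean <- mean(mp$profile[1, c(1:100, (nb - 99):nb)])
  expect_gt(body_mean / flank_mean, 1.8)
})

test_that("consensus feature coverage detects planted internal enrichment", {
  set.seed(43)
  n_fam <- 20
  fams <- data.frame(family_id = sprintf("F%02d", 1:n_fam),
                     subclass = "LTR", consensus_length = 2000L,
                     autonomous = TRUE, stringsAsFactors = FALSE)
  fmap <- consensus_feature_map(fams, terminus_bp = 400)
  # one genomic copy per family, identity-mapped to consensus
  frags <- do.call(rbind, lapply(seq_len(n_fam), function(i) {
    data.frame(chrom = "c1", start = (i - 1) * 3000L, end = (i - 1) * 3000L + 2000L,
               strand = "+", family_id = fams$family_id[i],
               consensus_start = 0L, consensus_end = 2000L, link_id = i,
               stringsAsFactors = FALSE)
  }))
  # plant 3x CDS-over-terminus read density
  reads <- do.call(rbind, lapply(seq_len(n_fam), function(i) {
    base <- (i - 1) * 3000L
    n_cds <- 30 + rpois(1, 5); n_term <- 10 + rpois(1, 3)
    s_cds <- base + sample(400:1959, n_cds, replace = TRUE)
    s_term <- base + sample(c(0:379, 1600:1979), n_term, replace = TRUE)
    mk_reads("c1", c(s_cds, s_term), c(s_cds, s_term) + 21L)
  }))
  cfc <- consensus_feature_coverage(reads, frags, fmap, fams)
  expect_lt(cfc$tests$LTR$kruskal_p, 0.01)
  cov <- cfc$coverage
  expect_gt(mean(cov$mean_depth[cov$feature == "CDS"]),
            mean(cov$mean_depth[cov$feature == "left_terminus"]))
  # near-uniform coverage: no significant feature differences
  reads_u <- do.call(rbind, lapply(seq_len(n_fam), function(i) {
    base <- (i - 1) * 3000L
    s <- base + sample(0:1979, 40, replace = TRUE)
    mk_reads("c1", s, s + 21L)
  }))
  cfc_u <- consensus_feature_coverage(reads_u, frags, fmap, fams)
  expect_gt(cfc_u$tests$LTR$kruskal_p, 0.05)
})

test_that("family-level correlations: monotone checks, planted recovery, small-n warning", {
  fs <- data.frame(family_id = sprintf("f%d", 1:20), tpm = 2^(1:20),
                   mean_cpm_intact = 1:20, mean_peak_overlap = seq(1, 0.05, length.out = 20))
  ec <- expression_correlations(fs)
  expect_equal(ec$rho_srna, 1)
  expect_equal(ec$rho_peak, -1)
  expect_equal(ec$high_overlap, fs$family_id[fs$mean_peak_overlap > 0.75])
  # planted rho -0.3 at n = 150 recovered within 0.1
  panel <- simulate_family_panel(150, rho_srna = 0.319, rho_peak = -0.3, seed = 4)
  ecp <- expression_correlations(panel)
  expect_lt(abs(ecp$rho_peak - (-0.3)), 0.1)
  expect_lt(abs(ecp$rho_srna - 0.319), 0.15)
  # fewer than 10 families: loess skipped with a warning
  w <- capture_warnings(expression_correlations(fs[1:5, ]))
  expect_true(any(grepl("loess", w)))
})
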