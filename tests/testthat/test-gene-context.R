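# Site-class partitioning, TE-gene proximity, genic ratios, expression and
# the gene-age contingency analysis.

test_that("TE-derived transcripts are removed above the strict 70% CDS overlap", {
  # hand-built two-exon gene with exactly 1000 bp of CDS
  gm <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = "c1", start = 0L, end = 2000L,
                       strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "g1.t1", gene_id = "g1",
                             chrom = "c1", start = 0L, end = 2000L,
                             strand = "+", stringsAsFactors = FALSE),
    features = data.frame(chrom = "c1",
                          start = c(0L, 0L, 600L, 1600L, 1600L),
                          end = c(600L, 600L, 1600L, 2000L, 2000L),
                          strand = "+",
                          type = c("CDS", "exon", "intron", "CDS", "exon"),
                          transcript_id = "g1.t1", gene_id = "g1",
                          stringsAsFactors = FALSE)),
    class = "gene_models")
  cover <- function(bp) {
    # cover exactly `bp` CDS bases (first exon holds 600 of the 1000)
    take1 <- min(bp, 600L)
    rows <- data.frame(chrom = "c1", start = c(0L, 1600L),
                       end = c(take1, 1600L + (bp - take1)))
    as_copies(rows[rows$end > rows$start, , drop = FALSE])
  }
  f71 <- filter_te_genes(gm, cover(710L))   # 71% of CDS under TEs
  expect_equal(nrow(f71$models$genes), 0)
  f70 <- filter_te_genes(gm, cover(700L))
  expect_equal(nrow(f70$models$genes), 1)   # exactly 70%: retained
  no_te <- as_copies(data.frame(chrom = character(), start = integer(),
                                end = integer()))
  f0 <- filter_te_genes(gm, no_te)
  expect_equal(nrow(f0$models$genes), 1)
})

test_that("site-class partition applies the precedence ladder and the 500-bp rule", {
  set.seed(51)
  gm <- random_gene_models(3, 40000)
  len <- 40000L
  part <- partition_site_classes(gm, c(c1 = len))
  # tiles the chromosome exactly, no overlaps
  expect_equal(sum(part$end - part$start), len)
  ord <- part[order(part$start), ]
  expect_true(all(ord$start[-1] == ord$end[-nrow(ord)]))
  # agrees with the per-base oracle exactly
  oracle <- site_class_oracle(gm, len, "c1")
  for (cl in unique(part$class)) {
    expect_equal(telandscape:::.total_bp(part[part$class == cl, ]),
                 sum(oracle == cl), info = cl)
  }
  # a base 400 bp from a gene is proximal; 600 bp from both neighbours distal
  g1_end <- gm$genes$end[1]
  g2_start <- gm$genes$start[2]
  if (g2_start - g1_end > 1200) {
    expect_equal(oracle[g1_end + 400], "intergenic_proximal")
    mid <- g1_end + 600
    if (g2_start - mid > 500) expect_equal(oracle[mid], "intergenic_distal")
  }
  # zero genes: the whole genome is distal intergenic
  empty <- structure(list(genes = gm$genes[0, ], transcripts = gm$transcripts[0, ],
                          features = gm$features[0, ]), class = "gene_models")
  p0 <- partition_site_classes(empty, c(c1 = 1000L))
  expect_equal(p0$class, "intergenic_distal")
  expect_equal(p0$end - p0$start, 1000L)
})

test_that("site-class densities equal per-base counting on random instances", {
  set.seed(34)
  len <- 100000L
  gm <- random_gene_models(8, len)
  te <- as_copies(random_intervals(40, len))
  ann <- resolve_precedence(te, random_intervals(10, len, min_w = 30, max_w = 400))
  part <- partition_site_classes(gm, c(c1 = len))
  dens <- site_class_density(ann, part)
  oracle <- site_class_oracle(gm, len, "c1")
  v_te <- label_vector(len, ann$te_copies)
  v_td <- label_vector(len, ann$tandem)
  for (i in seq_len(nrow(dens))) {
    cl <- dens$class[i]
    expect_equal(dens$te_fraction[i], sum(v_te[oracle == cl]) / sum(oracle == cl),
                 info = cl)
    expect_equal(dens$tandem_fraction[i], sum(v_td[oracle == cl]) / sum(oracle == cl))
  }
  # empty annotation: zero everywhere
  ann0 <- resolve_precedence(te[0, ], te[0, c("chrom", "start", "end")])
  d0 <- site_class_density(ann0, part)
  expect_true(all(d0$te_fraction == 0))
  expect_true(all(d0$nonrepeat_fraction == 1))
})

test_that("copy site-class assignment uses the strict >1% proximal rule and majority genic label", {
  set.seed(52)
  gm <- random_gene_models(2, 30000)
  part <- partition_site_classes(gm, c(c1 = 30000L))
  prox <- part[part$class == "intergenic_proximal", ][1, ]
  # 1000-bp copy with 11 bp in the proximal zone -> proximal
  c11 <- as_copies(data.frame(chrom = "c1", start = prox$start - 989L,
                              end = prox$start + 11L))
  # exactly 1% (10 bp of 1000) -> distal (strict)
  c10 <- as_copies(data.frame(chrom = "c1", start = prox$start - 990L,
                              end = prox$start + 10L))
  intr <- part[part$class == "intron", ][1, ]
  cin <- as_copies(data.frame(chrom = "c1", start = intr$start,
                              end = intr$end))
  got <- assign_copy_site_class(rbind(c11, c10, cin), part)
  expect_equal(got$site_class, c("intergenic_proximal", "intergenic_distal", "intron"))
})

test_that("nearest-TE distances bin correctly and mirror symmetrically", {
  set.seed(53)
  gm <- random_gene_models(1, 20000)
  g <- gm$genes[1, ]
  copies <- as_copies(data.frame(chrom = "c1",
                                 start = c(g$end + 450L, g$end + 3000L),
                                 end = c(g$end + 550L, g$end + 3100L)))
  nd <- nearest_te_distance(gm, copies)
  expect_equal(nd$distance, 450)
  expect_equal(nd$bin, "within_500bp")
  # abutting copy: distance 0, first bin
  ab <- as_copies(data.frame(chrom = "c1", start = g$end, end = g$end + 100L))
  expect_equal(nearest_te_distance(gm, ab)$distance, 0)
  # no copy within 2 kb -> open-ended bin
  far <- as_copies(data.frame(chrom = "c1", start = g$end + 2001L,
                              end = g$end + 2101L))
  expect_equal(nearest_te_distance(gm, far)$bin, "beyond_2kb")
  # boundary: exactly 2000 falls in the 1-2 kb bin
  b2k <- as_copies(data.frame(chrom = "c1", start = g$end + 2000L,
                              end = g$end + 2100L))
  expect_equal(nearest_te_distance(gm, b2k)$bin, "1_2kb")
  # mirroring the chromosome leaves distances unchanged
  L <- 20000L
  mirror <- function(df) {
    out <- df
    out$start <- L - df$end
    out$end <- L - df$start
    out
  }
  gmm <- gm
  gmm$genes <- mirror(gm$genes); gmm$transcripts <- mirror(gm$transcripts)
  gmm$features <- mirror(gm$features)
  ndm <- nearest_te_distance(gmm, mirror(copies))
  expect_equal(ndm$distance, nd$distance)
})

test_that("genic TE:CDS ratio excludes mono-exonic genes and counts non-CDS TE bp", {
  set.seed(54)
  gm <- random_gene_models(1, 20000)
  intr <- gm$features[gm$features$type == "intron", ][1, ]
  te <- as_copies(data.frame(chrom = "c1", start = intr$start,
                             end = intr$start + min(500L, intr$end - intr$start)))
  rt <- genic_te_cds_ratio(gm, te)
  cds_bp <- sum(with(gm$features[gm$features$type == "CDS", ], end - start))
  expect_equal(rt$ratio, (te$end - te$start) / cds_bp)
  # no genic TE -> 0
  far <- as_copies(data.frame(chrom = "c1", start = 19000L, end = 19100L))
  expect_equal(genic_te_cds_ratio(gm, far)$ratio, 0)
  # mono-exonic gene excluded with NA ratio
  mono <- structure(list(
    genes = data.frame(gene_id = "m1", chrom = "c1", start = 100L, end = 1100L,
                       strand = "+", stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "m1.t1", gene_id = "m1",
                             chrom = "c1", start = 100L, end = 1100L,
                             strand = "+", stringsAsFactors = FALSE),
    features = data.frame(chrom = "c1", start = c(100L, 200L),
                          end = c(1100L, 1000L), strand = "+",
                          type = c("exon", "CDS"), transcript_id = "m1.t1",
                          gene_id = "m1", stringsAsFactors = FALSE)),
    class = "gene_models")
  rm_ <- genic_te_cds_ratio(mono, far)
  expect_true(rm_$mono_exonic)
  expect_true(is.na(rm_$ratio))
})

test_that("Spearman machinery: monotone pairs and copula recovery at n = 5000", {
  ratios <- data.frame(gene_id = sprintf("g%d", 1:20), cds_bp = 1000,
                       genic_te_bp = 1:20, ratio = (1:20) / 10,
                       mono_exonic = FALSE)
  tpm <- data.frame(gene_id = ratios$gene_id, up = 2^(1:20), down = 2^(20:1))
  ev <- expression_vs_te(ratios, tpm)
  expect_equal(ev$rho[ev$stage == "up"], 1)
  expect_equal(ev$rho[ev$stage == "down"], -1)
  # planted rho 0.15 via the Gaussian copula, n = 5000, recovered within 0.05
  set.seed(35)
  x <- rexp(5000)
  tpm2 <- data.frame(gene_id = sprintf("g%d", 1:5000),
                     st = simulate_correlated_tpm(x, 0.15))
  ratios2 <- data.frame(gene_id = tpm2$gene_id, cds_bp = 1000,
                        genic_te_bp = 0, ratio = x, mono_exonic = FALSE)
  ev2 <- expression_vs_te(ratios2, tpm2)
  expect_lt(abs(ev2$rho - 0.15), 0.05)
})

test_that("expression summaries by nearest-TE bin aggregate log2 TPM correctly", {
  nearest <- data.frame(gene_id = sprintf("g%d", 1:6),
                        distance = c(0, 400, 700, 1500, 2500, 3000),
                        bin = c("within_500bp", "within_500bp", "500bp_1kb",
                                "1_2kb", "beyond_2kb", "beyond_2kb"),
                        nearest_intact = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  tpm <- data.frame(gene_id = nearest$gene_id, GA = c(3, 1, 7, 15, 31, 63))
  eb <- expression_by_nearest_te(nearest, tpm)
  expect_equal(eb$median_log2_tpm[eb$bin == "within_500bp"], mean(c(2, 1)))
  expect_equal(eb$n[eb$bin == "beyond_2kb"], 2)
  ebi <- expression_by_nearest_te(nearest, tpm, by_intact = TRUE)
  expect_equal(ebi$median_log2_tpm[ebi$bin == "beyond_2kb" & ebi$nearest_intact], 5)
})

test_that("gene-age contingency analysis: worked chi-square, calibration and errors", {
  # the worked 2x2 example: chi-square 6.667 to 3 dp, df 1
  copies <- data.frame(classification = rep(c("DNA/Test", "LTR/Gypsy"), c(30, 30)),
                       gene_id = sprintf("g%d", 1:60))
  ranks <- data.frame(gene_id = copies$gene_id,
                      rank = c(rep(1, 10), rep(2, 20), rep(1, 20), rep(2, 10)))
  am <- age_mosaic(copies, ranks)
  expect_equal(round(am$chi_square, 3), 6.667)
  expect_equal(am$df, 1)
  expect_equal(am$chi_square, chisq_oracle(am$table), tolerance = 1e-12)
  # zero margin -> error
  ranks0 <- ranks; ranks0$rank <- 1
  expect_error(age_mosaic(copies, ranks0), "zero margin")
  # calibration under planted independence: rejection rate near alpha
  set.seed(36)
  rej <- 0
  for (i in 1:400) {
    cp <- data.frame(classification = sample(c("A", "B"), 200, replace = TRUE),
                     gene_id = sprintf("g%d", 1:200))
    rk <- data.frame(gene_id = cp$gene_id,
                     rank = sample(1:3, 200, replace = TRUE))
    rej <- rej + (age_mosaic(cp, rk)$p_value < 0.05)
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.09)
})

test_that("planted intronic/intergenic contrasts are detected", {
  cfg <- small_sim_config(seed = 23, total_kb = 1000)
  cfg$intronic_te_fraction <- 0.45
  cfg$intronic_divergence_shift <- 6
  sim <- plant_genome(cfg)
  cons <- stats::setNames(sim$library$length, sim$library$id)
  copies <- merge_fragments(sim$hits, cons)
  part <- partition_site_classes(sim$models, chrom_lengths(sim$genome))
  copies <- assign_copy_site_class(copies, part)
  keep <- copies$site_class %in% c("intron", "intergenic_distal")
  cp <- compare_copy_properties(copies[keep, ],
                                classes = c("intron", "intergenic_distal"))
  expect_lt(cp$length$p_value, 0.01)
  expect_lt(cp$divergence$p_value, 0.01)
  # intronic copies planted shorter and more diverged: direction check
  expect_lt(median(copies$length[copies$site_class == "intron"]),
            median(copies$length[copies$site_class == "intergenic_distal"]))
  expect_error(compare_copy_properties(copies[0, ]), "no copies")
})
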