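# Library post-processing: alignment identity vs a quadratic DP oracle,
# greedy clustering fidelity, reclassification and deduplication rules.

mutseq <- function(s, frac) {
  v <- strsplit(s, "")[[1]]
  idx <- sample(length(v), round(frac * length(v)))
  bases <- c("A", "C", "G", "T")
  v[idx] <- vapply(v[idx], function(b) sample(setdiff(bases, b), 1), character(1))
  paste(v, collapse = "")
}

test_that("pairwise identity and coverage behave on identity and containment", {
  set.seed(56)
  a <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  pi <- pairwise_identity(a, a)
  expect_equal(pi$identity, 1)
  expect_equal(pi$coverage_of_shorter, 1)
  # exact prefix: perfect identity, full coverage measured on the shorter
  pi2 <- pairwise_identity(a, substr(a, 1, 50))
  expect_equal(pi2$identity, 1)
  expect_equal(pi2$coverage_of_shorter, 1)
  expect_error(pairwise_identity("", a), "empty")
})

test_that("pairwise identity matches the Smith-Waterman oracle on random pairs", {
  set.seed(41)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    b <- if (rep <= 3) mutseq(a, 0.1 * rep) else
      paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    impl <- pairwise_identity(a, b, try_revcomp = FALSE)
    orac <- sw_oracle(a, b)
    expect_equal(impl$score, orac$score)
    # co-optimal paths can trade a mismatch for gaps, so identity gets a
    # small tolerance while the optimal score is exact
    expect_lt(abs(impl$identity - orac$identity), 0.06)
  }
})

test_that("reverse-complement orientation is detected", {
  set.seed(42)
  a <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(a, "")[[1]])), collapse = "")
  pi <- pairwise_identity(a, rc)
  expect_equal(pi$orientation, "-")
  expect_equal(pi$identity, 1)
})

make_planted_library <- function(seed = 7, n_groups = 4, per_group = 5,
                                 len = 400, within_div = 0.03) {
  set.seed(seed)
  seqs <- character(0)
  truth <- integer(0)
  for (g in seq_len(n_groups)) {
    anc <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    for (m in seq_len(per_group)) {
      seqs[sprintf("grp%d_m%d", g, m)] <- mutseq(anc, within_div)
      truth <- c(truth, g)
    }
  }
  list(library = te_library(seqs), truth = truth)
}

test_that("greedy clustering recovers planted groups and matches the all-pairs oracle", {
  pl <- make_planted_library()
  cl <- cluster_library(pl$library, 0.8, 0.8)
  expect_equal(length(cl$clusters), 4)
  # planted labels define the same partition as the recovered membership
  memb <- cl$membership[pl$library$id]
  expect_equal(length(unique(tapply(pl$truth, memb, function(x) length(unique(x))))), 1)
  expect_true(all(tapply(pl$truth, memb, function(x) length(unique(x))) == 1))
  comp <- oracle_cluster_components(pl$library, 0.8, 0.8)
  expect_equal(length(unique(comp)), 4)
  expect_true(all(tapply(comp, memb, function(x) length(unique(x))) == 1))
})

test_that("clustering is idempotent on representatives and splits distant pairs", {
  pl <- make_planted_library(seed = 8)
  cl <- cluster_library(pl$library, 0.8, 0.8)
  reps <- vapply(cl$clusters, `[[`, character(1), "representative")
  lib_reps <- pl$library[pl$library$id %in% reps, , drop = FALSE]
  cl2 <- cluster_library(lib_reps, 0.8, 0.8)
  expect_true(all(lengths(lapply(cl2$clusters, `[[`, "members")) == 1))
  # a ~70% identity pair stays apart at 0.8 thresholds (oracle confirms < 0.8)
  set.seed(9)
  a <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  b <- mutseq(a, 0.30)
  expect_lt(sw_oracle(a, b)$identity, 0.8)
  cl3 <- cluster_library(te_library(c(s1 = a, s2 = b)), 0.8, 0.8)
  expect_equal(length(cl3$clusters), 2)
  # identical trio collapses
  cl4 <- cluster_library(te_library(c(x = a, y = a, z = a)), 0.8, 0.8)
  expect_equal(length(cl4$clusters), 1)
})

test_that("cluster-based reclassification prefers curated donors and flags conflicts", {
  set.seed(10)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  lib <- te_library(c(`cur#LTR/Gypsy` = base, unk1 = mutseq(base, 0.02)),
                    curated = c(TRUE, FALSE))
  cl <- cluster_library(lib, 0.8, 0.8)
  rec <- reclassify_by_cluster(cl, lib)
  expect_equal(rec$library$classification[rec$library$id == "unk1"], "LTR/Gypsy")
  # all-Unknown cluster unchanged
  lib2 <- te_library(c(u1 = base, u2 = mutseq(base, 0.02)))
  rec2 <- reclassify_by_cluster(cluster_library(lib2, 0.8, 0.8), lib2)
  expect_true(all(rec2$library$classification == "Unknown"))
  # conflicting curated members: flag, nothing reassigned
  lib3 <- te_library(c(`a#DNA/hAT` = base, `b#LTR/Copia` = mutseq(base, 0.01),
                       u = mutseq(base, 0.02)),
                     curated = c(TRUE, TRUE, FALSE))
  rec3 <- reclassify_by_cluster(cluster_library(lib3, 0.8, 0.8), lib3)
  expect_equal(length(rec3$conflicts), 1)
  expect_equal(rec3$library$classification[rec3$library$id == "u"], "Unknown")
})

test_that("tandem-overlap reclassification uses a strict 60% boundary", {
  lib <- te_library(c(`f61#DNA/Test` = strrep("ACGT", 25),
                      `f60#DNA/Test` = strrep("ACGT", 25),
                      `f0#DNA/Test` = strrep("ACGT", 25)))
  copies <- data.frame(chrom = "c1",
                       start = c(0L, 1000L, 2000L),
                       end = c(100L, 1100L, 2100L),
                       family_id = c("f61", "f60", "f0"),
                       stringsAsFactors = FALSE)
  tandem <- data.frame(chrom = "c1", start = c(0L, 1000L), end = c(61L, 1060L),
                       stringsAsFactors = FALSE)
  out <- tandem_overlap_reclassify(lib, copies, tandem, threshold = 0.60)
  cls <- stats::setNames(out$library$classification, out$library$id)
  expect_equal(unname(cls["f61"]), "TandemRepeat")   # 61% > 60%: reclassified
  expect_equal(unname(cls["f60"]), "DNA/Test")       # exactly 60%: retained
  expect_equal(unname(cls["f0"]), "DNA/Test")
  expect_equal(out$fractions$overlap_fraction[out$fractions$family_id == "f61"], 0.61)
  # result depends only on aggregate fractions, not copy order
  out2 <- tandem_overlap_reclassify(lib, copies[c(3, 1, 2), ], tandem)
  expect_equal(out2$library$classification, out$library$classification)
  # zero-bp family skipped with a warning
  lib4 <- rbind(lib, te_library(c(`ghost#DNA/Test` = "ACGTACGT")))
  expect_warning(tandem_overlap_reclassify(lib4, copies, tandem), "ghost")
})

test_that("deduplication keeps curated or longest members and never drops curated", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  lib <- te_library(c(`short_cur#DNA/Test` = substr(base, 1, 960),
                      long_unc = base),
                    curated = c(TRUE, FALSE))
  cl <- cluster_library(lib, 0.95, 0.95)
  expect_equal(length(cl$clusters), 1)
  dd <- deduplicate(lib, cl)
  expect_equal(dd$library$id, "short_cur")
  expect_equal(dd$removed, "long_unc")
  # n identical duplicates -> one survivor
  libn <- te_library(stats::setNames(rep(base, 4), paste0("d", 1:4)))
  ddn <- deduplicate(libn, cluster_library(libn, 0.95, 0.95))
  expect_equal(nrow(ddn$library), 1)
  expect_equal(length(ddn$removed), 3)
  # singleton kept
  lib1 <- te_library(c(solo = base))
  dd1 <- deduplicate(lib1, cluster_library(lib1, 0.95, 0.95))
  expect_equal(dd1$library$id, "solo")
})

test_that("majority consensus drops gap-majority columns and breaks ties alphabetically", {
  expect_equal(consensus_from_alignment(rep("ACGT", 3)), "ACGT")
  expect_equal(consensus_from_alignment(c("AA", "AA", "GA")), "AA")
  # column {A,-,-}: gaps are the strict majority -> dropped
  expect_equal(consensus_from_alignment(c("AC", "-C", "-C")), "C")
  # tie {A,A,G,G} resolves to A (alphabetical)
  expect_equal(consensus_from_alignment(c("A", "A", "G", "G")), "A")
  expect_error(consensus_from_alignment(c("AC", "ACG")), "equal length")
})
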