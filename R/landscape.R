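# Windowed densities, compartment statistics, cut:copy ratio, superfamily
# enrichment and subtelomere proximity profiles.

#' Tile chromosomes into non-overlapping windows
#'
#' In plain mode windows tile each chromosome from 0; the last partial window
#' is retained and flagged. In anchored mode (named `anchors` vector of
#' per-chromosome anchor positions, e.g. the inner edge of the subtelomeric
#' satellite) windows are numbered from the anchor toward increasing
#' coordinates (centromere-ward); chromosomes without an anchor are skipped.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param width Window width in bp.
#' @param anchors Optional named vector chrom -> anchor bp.
#' @return data.frame with `chrom`, `start`, `end`, `window_index`, `partial`.
#' @export
make_windows <- function(chrom_lengths, width, anchors = NULL) {
  stopifnot(width > 0)
  out <- list()
  chroms <- if (is.null(anchors)) names(chrom_lengths) else
    intersect(names(chrom_lengths), names(anchors))
  for (ch in chroms) {
    len <- chrom_lengths[[ch]]
    from <- if (is.null(anchors)) 0L else as.integer(anchors[[ch]])
    if (from >= len) next
    starts <- seq.int(from, len - 1L, by = width)
    ends <- pmin(starts + width, len)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            window_index = seq_along(starts),
                            partial = (ends - starts) < width,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label windows by compartment (majority-bp rule)
#'
#' @param windows Windows data.frame from [make_windows()].
#' @param compartment_map data.frame with `chrom`, `start`, `end`, `label`.
#' @return `windows` with a `compartment` column (NA when no overlap).
#' @export
assign_compartment <- function(windows, compartment_map) {
  labels <- unique(compartment_map$label)
  bp <- sapply(labels, function(l) {
    .bp_in_regions(compartment_map[compartment_map$label == l, , drop = FALSE], windows)
  })
  bp <- matrix(bp, nrow = nrow(windows), dimnames = list(NULL, labels))
  best <- apply(bp, 1, function(r) if (all(r == 0)) NA_character_ else labels[which.max(r)])
  windows$compartment <- best
  windows
}

#' Per-window repeat and CDS densities
#'
#' Densities are covered bp over window length, computed after TE/tandem
#' precedence resolution; TEs spanning a window boundary contribute
#' proportionally to each side.
#'
#' @param annotation A `repeat_annotation` (see [resolve_precedence()]).
#' @param windows Windows data.frame.
#' @param cds Optional data.frame of CDS intervals for `cds_density`.
#' @return `windows` with columns `te_density`, `tandem_density`,
#'   (`cds_density`), `te_bp`, `cut_bp`, `copy_bp`.
#' @export
window_density <- function(annotation, windows, cds = NULL) {
  te <- annotation$te_copies
  w <- windows
  width <- w$end - w$start
  w$te_bp <- .bp_in_regions(te, w)
  w$te_density <- w$te_bp / width
  w$tandem_density <- .bp_in_regions(annotation$tandem, w) / width
  if (!is.null(cds)) w$cds_density <- .bp_in_regions(cds, w) / width
  w$cut_bp <- .bp_in_regions(te[te$mechanism == "cut", , drop = FALSE], w)
  w$copy_bp <- .bp_in_regions(te[te$mechanism == "copy", , drop = FALSE], w)
  w
}

#' Dunn's post-hoc test (tie-corrected, Bonferroni-adjusted)
#'
#' Pairwise z statistics on rank means after a Kruskal-Wallis test, with the
#' usual tie correction; two-sided p-values are Bonferroni-multiplied by the
#' number of comparisons performed.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of the same length.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  tie_sizes <- table(values)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  mean_r <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  k <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (mean_r[[g1]] - mean_r[[g2]]) / se
    out$z[j] <- z
    out$p[j] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adj <- pmin(1, out$p * k)
  out
}

#' Compare a statistic between compartments or other groupings
#'
#' Two groups: Wilcoxon rank-sum with continuity correction. More than two:
#' Kruskal-Wallis followed by Dunn's test with Bonferroni correction.
#'
#' @param values Numeric vector (e.g. per-window TE densities).
#' @param groups Grouping vector of the same length.
#' @param method "auto" (Wilcoxon for two groups, Kruskal-Wallis + Dunn
#'   otherwise) or "kruskal" to force the Kruskal-Wallis route.
#' @return List with `method`, `n` (per group), `statistic`, `p_value`, and
#'   for the Kruskal-Wallis route a `pairwise` data.frame from [dunn_test()].
#' @export
compare_compartments <- function(values, groups, method = c("auto", "kruskal")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  n <- table(groups)
  if (any(n < 2)) {
    stop(sprintf("group(s) with fewer than 2 observations: %s",
                 paste(names(n)[n < 2], collapse = ", ")))
  }
  if (nlevels(groups) == 2 && method == "auto") {
    lv <- levels(groups)
    wt <- stats::wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                             correct = TRUE, exact = FALSE)
    list(method = "wilcoxon", n = as.list(n),
         statistic = unname(wt$statistic), p_value = wt$p.value)
  } else {
    kw <- stats::kruskal.test(values, groups)
    list(method = "kruskal-dunn", n = as.list(n),
         statistic = unname(kw$statistic), p_value = kw$p.value,
         pairwise = dunn_test(values, groups))
  }
}

#' Cut:copy abundance ratio within a region
#'
#' Ratio of cut-and-paste TE abundance (DD(E/D) DNA transposons) to
#' copy-and-paste abundance (retrotransposons and Helitrons) inside a region.
#' Abundance is measured in bases by default (copy-count mode behind
#' `units`); Unknown-subclass abundance is excluded from the ratio and
#' reported separately. When copy abundance is zero the ratio is `NA`.
#'
#' @param annotation A `repeat_annotation` or `te_copies` data.frame.
#' @param region Optional data.frame of intervals to restrict to (whole
#'   annotation when NULL).
#' @param units "bp" (clipped to the region) or "copies".
#' @return List with `ratio`, `cut`, `copy`, `unknown` abundances.
#' @export
cut_copy_ratio <- function(annotation, region = NULL, units = c("bp", "copies")) {
  units <- match.arg(units)
  copies <- if (inherits(annotation, "repeat_annotation")) annotation$te_copies else annotation
  amount <- function(mech) {
    d <- copies[copies$mechanism == mech, , drop = FALSE]
    if (units == "copies") {
      if (is.null(region)) return(nrow(d))
      return(sum(.bp_in_regions(region, d) > 0))
    }
    if (is.null(region)) return(.total_bp(d))
    sum(.bp_in_regions(region, d))
  }
  cut <- amount("cut"); cop <- amount("copy"); unk <- amount("unknown")
  list(ratio = if (cop == 0) NA_real_ else cut / cop,
       cut = cut, copy = cop, unknown = unk)
}

#' Superfamily densities per megabase and enrichment vs autosomes
#'
#' @param annotation A `repeat_annotation` or `te_copies`.
#' @param compartment_map data.frame with `chrom`, `start`, `end`, `label`.
#' @param reference Compartment label used as the baseline.
#' @param eps Pseudodensity (bp/Mb) added to both sides of the fold change.
#' @return data.frame with `classification`, `compartment`, `density_per_mb`,
#'   `log2fc`, `enriched` (strict log2FC > 1).
#' @export
superfamily_enrichment <- function(annotation, compartment_map,
                                   reference = "autosome", eps = 1) {
  copies <- if (inherits(annotation, "repeat_annotation")) annotation$te_copies else annotation
  labels <- unique(compartment_map$label)
  comp_mb <- vapply(labels, function(l) {
    .union_bp(compartment_map[compartment_map$label == l, , drop = FALSE]) / 1e6
  }, numeric(1))
  sfams <- unique(copies$classification)
  grid <- expand.grid(classification = sfams, compartment = labels,
                      stringsAsFactors = FALSE)
  grid$density_per_mb <- mapply(function(sf, lab) {
    cp <- copies[copies$classification == sf, , drop = FALSE]
    reg <- compartment_map[compartment_map$label == lab, , drop = FALSE]
    sum(.bp_in_regions(reg, cp)) / comp_mb[[lab]]
  }, grid$classification, grid$compartment)
  ref_density <- stats::setNames(
    grid$density_per_mb[grid$compartment == reference],
    grid$classification[grid$compartment == reference])
  grid$log2fc <- log2((grid$density_per_mb + eps) /
                        (ref_density[grid$classification] + eps))
  grid$enriched <- grid$log2fc > 1
  grid
}

#' Median/quartile TE density profile away from the subtelomeric satellite
#'
#' Summarizes anchored window densities across chromosomes: per window index
#' the median, first and third quartile. Chromosomes without an anchor are
#' absent from the input by construction of anchored [make_windows()].
#'
#' @param window_stats Anchored windows with a `te_density` column.
#' @return data.frame with `window_index`, `n`, `median`, `q1`, `q3`.
#' @export
subtelomere_profile <- function(window_stats) {
  sp <- split(window_stats$te_density, window_stats$window_index)
  out <- do.call(rbind, lapply(names(sp), function(i) {
    v <- sp[[i]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(window_index = as.integer(i), n = length(v),
               median = q[2], q1 = q[1], q3 = q[3])
  }))
  out <- out[order(out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
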