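# Simulation configuration. The defaults are the study conditions the rest of
# the package is validated against: compartment TE densities and cut:copy
# ratios of the autosome/PAR/SDR system, a mobilome dominated by young
# elements with a minority of intact copies, 20-24 nt small RNAs with a 21-nt
# mode and 5'-U bias preferentially covering intact copies, and broad peaks
# preferentially covering intact copies. See the methods vignette for the
# rationale behind each default.

#' Default TE family plan
#'
#' A compact family panel spanning the six subclasses (LTR, LINE, DIRS, PLE,
#' DNA, Helitron) plus an Unknown family, with autonomous and non-autonomous
#' members and consensus lengths in the ranges typical of each group.
#'
#' @return data.frame with `family_id`, `classification`, `consensus_length`,
#'   `autonomous`, `subclass`, `mechanism`.
#' @export
default_family_plan <- function() {
  fp <- data.frame(
    family_id = c("Gypsy-1", "Copia-1", "RTEX-1", "RTEX-N1", "Ngaro-1",
                  "Chlamys-1", "TcMar-1", "TcMar-N1", "Harbinger-1",
                  "Harbinger-N4", "KDZ-1", "Helitron-1", "Unknown-1"),
    classification = c("LTR/Gypsy", "LTR/Copia", "LINE/RTE-X", "LINE/RTE-X",
                       "DIRS/Ngaro", "PLE/Chlamys", "DNA/Mariner-Tc1",
                       "DNA/Mariner-Tc1", "DNA/Harbinger", "DNA/Harbinger",
                       "DNA/KDZ", "Helitron/Helitron", "Unknown"),
    consensus_length = c(5000L, 4800L, 3200L, 600L, 4500L, 3000L, 2000L,
                         250L, 3500L, 400L, 9000L, 4000L, 800L),
    autonomous = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                   FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  fp$subclass <- te_subclass(fp$classification)
  fp$mechanism <- te_mechanism(fp$classification)
  fp
}

#' Default chromosome/compartment layout
#'
#' Three chromosomes totalling 5 Mb: two 1.7-Mb autosomes, each opening with a
#' 25-kb subtelomeric satellite followed by a 70-kb TE-dense flank, and a
#' 1.6-Mb sex chromosome laid out PAR | male SDR | PAR with the PARs larger
#' than the SDR, mirroring the real sex-chromosome geometry (no satellite
#' anchor on it, so it is excluded from subtelomere profiles). Per-segment
#' `te_target`/`cut_copy` overrides default to the per-label targets of the
#' configuration.
#'
#' @return data.frame with `chrom`, `label`, `length`, `te_target`,
#'   `cut_copy`.
#' @export
default_chrom_plan <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2",
              "chr3", "chr3", "chr3"),
    label = c("subtelomere_anchor", "autosome", "autosome",
              "subtelomere_anchor", "autosome", "autosome",
              "PAR", "SDR_male", "PAR"),
    length = c(25000L, 70000L, 1605000L, 25000L, 70000L, 1605000L,
               550000L, 500000L, 550000L),
    te_target = c(NA, 0.47, NA, NA, 0.47, NA, NA, NA, NA),
    cut_copy = rep(NA_real_, 9),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' All probabilities, lengths and targets of the synthetic mobilome. Defaults
#' encode the study conditions; override individual pieces for scaled-down or
#' specialised simulations.
#'
#' @param seed Integer seed controlling every random choice.
#' @param chrom_plan Segment layout (see [default_chrom_plan()]).
#' @param family_plan Family panel (see [default_family_plan()]).
#' @param density_targets Per-compartment target TE base fractions.
#' @param cut_copy_targets Per-compartment target cut:copy base ratios.
#' @param copy_type_probs Probabilities of planting an intact, young-truncated
#'   or degraded copy.
#' @param divergence_young,divergence_old Uniform divergence ranges (%) for
#'   young and degraded copies (kept away from the 20% intactness boundary).
#' @param coverage_truncated,coverage_degraded Uniform consensus-coverage
#'   ranges for truncated and degraded copies (away from the 0.8 boundary).
#' @param unknown_share Fraction of the TE budget planted as Unknown-subclass
#'   copies (excluded from cut:copy ratios).
#' @param intronic_te_fraction Fraction of copies (<= 2 kb) embedded in gene
#'   introns rather than intergenic space.
#' @param fragment_prob Probability that a planted copy is emitted as two
#'   link-joined RepeatMasker fragments instead of one hit.
#' @param gene_plan Gene structure distributions (exon/intron/UTR lengths,
#'   mono-exonic probability, per-compartment gene fill fractions, intergenic
#'   gap log-normal).
#' @param srna_plan Small-RNA plan: per-copy read depth, coverage
#'   probabilities by intact/peak status, read length distribution (21-nt
#'   mode), target observed 5'-U fraction, stages and replicates.
#' @param peak_plan Peak plan: association probabilities by intact status,
#'   minimum covered body fraction, flank range.
#' @param tandem_share Fraction of each segment planted as interspersed
#'   tandem-repeat blocks.
#' @param redundant_variants Number of near-duplicate unclassified library
#'   records added so curation has redundancy to remove.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_plan = default_chrom_plan(),
    family_plan = default_family_plan(),
    density_targets = c(autosome = 0.22, PAR = 0.39, SDR_male = 0.51,
                        SDR_female = 0.65, subtelomere_anchor = 0),
    cut_copy_targets = c(autosome = 0.48, PAR = 0.71, SDR_male = 0.79,
                         SDR_female = 0.52),
    copy_type_probs = c(intact = 0.146, young_truncated = 0.550,
                        degraded = 0.304),
    divergence_young = c(0.5, 6),
    divergence_old = c(21, 29),
    coverage_truncated = c(0.30, 0.75),
    coverage_degraded = c(0.55, 1.0),
    unknown_share = 0.05,
    intronic_te_fraction = 0.30,
    fragment_prob = 0.25,
    gene_plan = list(p_mono = 0.05, n_exons = 2:6,
                     cds_exon_len = c(150, 600),
                     intron_meanlog = log(450), intron_sdlog = 0.5,
                     utr5 = c(80, 250), utr3 = c(100, 300),
                     gap_meanlog = log(1302), gap_sdlog = 0.7,
                     gene_fill = c(autosome = 0.42, PAR = 0.30,
                                   SDR_male = 0.18, SDR_female = 0.12)),
    srna_plan = list(depth_per_copy = 4,
                     p_covered_intact = 0.647,
                     p_covered_nonintact = 0.218,
                     p_covered_intact_peak = 0.736,
                     length_probs = c(`20` = 0.12, `21` = 0.55, `22` = 0.13,
                                      `23` = 0.10, `24` = 0.10),
                     u5_bias = 0.8,
                     stages = c("GA", "fGA", "gametes"),
                     replicates = 2),
    peak_plan = list(p_peak_intact = 0.302, p_peak_nonintact = 0.231,
                     min_body_fraction = 0.8, flank = c(0, 100)),
    tandem_share = 0.004,
    redundant_variants = 3) {
  stopifnot(all(density_targets >= 0 & density_targets < 0.95),
            all(cut_copy_targets > 0),
            abs(sum(copy_type_probs) - 1) < 1e-8,
            intronic_te_fraction >= 0, intronic_te_fraction <= 1)
  cfg <- list(seed = as.integer(seed), chrom_plan = chrom_plan,
              family_plan = family_plan, density_targets = density_targets,
              cut_copy_targets = cut_copy_targets,
              copy_type_probs = copy_type_probs,
              divergence_young = divergence_young,
              divergence_old = divergence_old,
              coverage_truncated = coverage_truncated,
              coverage_degraded = coverage_degraded,
              unknown_share = unknown_share,
              intronic_te_fraction = intronic_te_fraction,
              fragment_prob = fragment_prob, gene_plan = gene_plan,
              srna_plan = srna_plan, peak_plan = peak_plan,
              tandem_share = tandem_share,
              redundant_variants = redundant_variants)
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: seed %d, %d segments (%.1f Mb), %d families\n",
              x$seed, nrow(x$chrom_plan), sum(x$chrom_plan$length) / 1e6,
              nrow(x$family_plan)))
  invisible(x)
}

#' Validate a simulation/pipeline configuration
#'
#' @param config A `simulation_config`.
#' @return Character vector of problems (length 0 when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed must be a single integer")
  chk(all(config$chrom_plan$length > 0), "all segment lengths must be positive")
  chk(!anyDuplicated(config$family_plan$family_id), "duplicate family ids")
  chk(all(config$family_plan$consensus_length > 0), "consensus lengths must be positive")
  chk(all(config$density_targets >= 0 & config$density_targets < 0.95),
      "density targets must lie in [0, 0.95)")
  pr <- c(config$srna_plan$p_covered_intact, config$srna_plan$p_covered_nonintact,
          config$peak_plan$p_peak_intact, config$peak_plan$p_peak_nonintact,
          config$srna_plan$u5_bias)
  chk(all(pr >= 0 & pr <= 1), "probabilities must lie in [0, 1]")
  labels <- setdiff(unique(config$chrom_plan$label), "subtelomere_anchor")
  chk(all(labels %in% names(config$density_targets)),
      "every segment label needs a density target")
  errs
}
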