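#' Simulation parameters for a synthetic nanochromosome genome
#'
#' Bundles and validates every knob of the synthetic genome/read generator.
#' Defaults encode the statistical structure the downstream analyses assume:
#' gene-sized telomere-capped chromosomes with mean length ~3.2 kb and a
#' right-skewed (truncated lognormal) length distribution, ~58% of loci
#' heterozygous with ~4% SNP heterozygosity, ~10% of loci alternatively
#' fragmented with directional isoforms, lognormal relative copy number,
#' paired-end fragments with outer distance 362 +/- 52 bp, and a
#' subtelomeric coverage gap spanning ~160 bp starting ~100 bp inside each
#' telomere (a size-selection artifact of the paired-end library).
#'
#' @param n_loci number of simulated loci.
#' @param length_mean_bp,length_sd_bp mean/SD of total contig length
#'   (telomeres included); lengths are drawn truncated-lognormal with a
#'   600 bp floor.
#' @param het_locus_fraction probability a locus is heterozygous.
#' @param snp_rate per-site substitution probability between the two
#'   alleles of a heterozygous locus.
#' @param minor_allele_fraction weight of the minor allele in `(0, 0.5]`;
#'   0.5 is balanced, 0.083 emulates a skewed ~1:11 allele ratio.
#' @param altfrag_fraction probability a locus is alternatively fragmented.
#' @param altfrag_short_isoform_share total molecule weight carried by the
#'   shorter isoform(s) of a fragmented locus.
#' @param altfrag_two_site_prob probability a fragmented locus carries two
#'   internal sites rather than one (directional single-site default 0.25).
#' @param copy_number_lognormal_sigma sigma of the mean-1 lognormal
#'   relative copy number distribution.
#' @param pe_outer_mean_bp,pe_outer_sd_bp outer distance of paired-end
#'   fragments.
#' @param read_len_bp read length.
#' @param coverage_x mean paired-end depth for a copy-number-1 locus.
#' @param se_coverage_x mean single-end depth (the SE library has no
#'   subtelomeric gap; set 0 to disable).
#' @param gap_depletion_prob probability that a PE fragment terminating in
#'   the subtelomeric gap window (160 bp starting 100 bp inside either
#'   telomere) is discarded.
#' @param telo_pair_depth expected telomere-paired read pairs (both reads
#'   starting in the two telomeres of one molecule, emulating the 454
#'   telomere-capture library) per unit copy weight.
#' @param telo_se_depth expected telomere-anchored single reads per
#'   molecule end per unit copy weight (emulates the Illumina telomeric
#'   read subset at a controllable support level; 0 disables and leaves
#'   telomeric reads to arise naturally from the PE/SE libraries).
#' @param base_error_rate uniform substitution sequencing error rate.
#' @param noisy_quals if `TRUE`, a low-quality (Q10) tail is embedded in
#'   half of the reads to exercise quality trimming; otherwise constant Q30.
#' @param frag_intra_cds if `TRUE`, fragmentation sites are placed uniformly
#'   (including inside CDS) instead of restricted to inter-CDS spacers.
#' @param telomere_len_bp fixed telomere length (20 bp).
#' @param seed master integer seed; all per-locus randomness is derived
#'   deterministically from it.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_loci = 200L,
                       length_mean_bp = 3200,
                       length_sd_bp = 1600,
                       het_locus_fraction = 0.58,
                       snp_rate = 0.04,
                       minor_allele_fraction = 0.5,
                       altfrag_fraction = 0.10,
                       altfrag_short_isoform_share = 0.5,
                       altfrag_two_site_prob = 0.25,
                       copy_number_lognormal_sigma = 0.5,
                       pe_outer_mean_bp = 362,
                       pe_outer_sd_bp = 52,
                       read_len_bp = 100L,
                       coverage_x = 50,
                       se_coverage_x = coverage_x / 2,
                       gap_depletion_prob = 0.9,
                       telo_pair_depth = 20,
                       telo_se_depth = 0,
                       base_error_rate = 0.002,
                       noisy_quals = FALSE,
                       frag_intra_cds = FALSE,
                       telomere_len_bp = 20L,
                       seed = 1L) {
  p <- list(n_loci = as.integer(n_loci), length_mean_bp = length_mean_bp,
            length_sd_bp = length_sd_bp,
            het_locus_fraction = het_locus_fraction, snp_rate = snp_rate,
            minor_allele_fraction = minor_allele_fraction,
            altfrag_fraction = altfrag_fraction,
            altfrag_short_isoform_share = altfrag_short_isoform_share,
            altfrag_two_site_prob = altfrag_two_site_prob,
            copy_number_lognormal_sigma = copy_number_lognormal_sigma,
            pe_outer_mean_bp = pe_outer_mean_bp,
            pe_outer_sd_bp = pe_outer_sd_bp,
            read_len_bp = as.integer(read_len_bp), coverage_x = coverage_x,
            se_coverage_x = se_coverage_x,
            gap_depletion_prob = gap_depletion_prob,
            telo_pair_depth = telo_pair_depth, telo_se_depth = telo_se_depth,
            base_error_rate = base_error_rate, noisy_quals = noisy_quals,
            frag_intra_cds = frag_intra_cds,
            telomere_len_bp = as.integer(telomere_len_bp),
            seed = as.integer(seed))
  probs <- c("het_locus_fraction", "snp_rate", "altfrag_fraction",
             "altfrag_short_isoform_share", "altfrag_two_site_prob",
             "gap_depletion_prob", "base_error_rate")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]")
  }
  if (p$minor_allele_fraction <= 0 || p$minor_allele_fraction > 0.5)
    stop("minor_allele_fraction must be in (0, 0.5]")
  pos <- c("n_loci", "length_mean_bp", "length_sd_bp", "pe_outer_mean_bp",
           "pe_outer_sd_bp", "read_len_bp", "coverage_x", "telomere_len_bp",
           "copy_number_lognormal_sigma")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || is.na(p[[nm]]) || p[[nm]] <= 0)
      stop(nm, " must be strictly positive")
  }
  if (p$se_coverage_x < 0 || p$telo_pair_depth < 0 || p$telo_se_depth < 0)
    stop("library depths must be non-negative")
  if (p$length_mean_bp < 2 * p$telomere_len_bp + 50)
    stop("degenerate parameters: length_mean_bp < 2*telomere_len_bp + 50")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params:", x$n_loci, "loci, mean length", x$length_mean_bp,
      "bp, het fraction", x$het_locus_fraction, ", altfrag fraction",
      x$altfrag_fraction, ", coverage", x$coverage_x, "x, seed", x$seed, "\n")
  invisible(x)
}
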