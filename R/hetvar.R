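## Pileup-based variant detection, homozygous/heterozygous nanochromosome
## classification, variant-frequency profiles, pairwise-alignment
## heterozygosity, 4-fold synonymous diversity and effective population
## size.

#' Build a pileup from alignments
#'
#' Accumulates per-position base counts from contig-forward aligned read
#' sequences (no indels; `N` bases are ignored). Telomere masking is
#' assumed to have happened upstream — masked telomeric read parts never
#' reach the pileup.
#'
#' @param alignments `data.frame` with `contig`, `start` (0-based) and
#'   `seq` (contig-forward aligned sequence, as produced by [map_reads()]
#'   or the simulator truth).
#' @param contig_lengths named integer vector.
#' @return `data.frame`: `contig`, `pos` (0-based), `A`,`C`,`G`,`T`,
#'   `coverage` — one row per position with nonzero coverage.
#' @export
pileup_from_alignments <- function(alignments, contig_lengths) {
  stopifnot(all(c("contig", "start", "seq") %in% names(alignments)))
  res <- list()
  by_contig <- split(seq_len(nrow(alignments)), alignments$contig)
  for (id in intersect(names(contig_lengths), names(by_contig))) {
    a <- alignments[by_contig[[id]], , drop = FALSE]
    L <- contig_lengths[[id]]
    lens <- nchar(a$seq)
    pos <- sequence(lens) - 1L + rep(a$start, lens)
    base <- unlist(strsplit(a$seq, "", fixed = TRUE), use.names = FALSE)
    keep <- base %in% DNA_BASES & pos >= 0L & pos < L
    bi <- match(base[keep], DNA_BASES)
    counts <- matrix(tabulate((pos[keep]) * 4L + bi, nbins = 4L * L),
                     nrow = 4L)
    nz <- which(colSums(counts) > 0L)
    if (!length(nz)) next
    res[[id]] <- data.frame(contig = id, pos = nz - 1L,
                            A = counts[1L, nz], C = counts[2L, nz],
                            G = counts[3L, nz], T = counts[4L, nz],
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(contig = character(), pos = integer(), A = integer(),
               C = integer(), G = integer(), T = integer(),
               stringsAsFactors = FALSE)
  out$coverage <- out$A + out$C + out$G + out$T
  rownames(out) <- NULL
  out
}

## minor (second most frequent) base count per pileup row
minor_count <- function(pileup) {
  m <- as.matrix(pileup[, c("A", "C", "G", "T")])
  apply(m, 1L, function(x) sort(x, decreasing = TRUE)[2L])
}

#' Call variant sites from a pileup
#'
#' A position qualifies as a variant site when coverage is at least
#' `min_cov`, the second most frequent base reaches `min_freq` of the
#' coverage, and the position lies at least `end_margin` bp from both
#' contig ends (guards against unmasked telomeric bases). Substitutions
#' only; indels are out of scope.
#'
#' @param pileup from [pileup_from_alignments()].
#' @param contig_lengths named integer vector.
#' @param min_cov minimum coverage (default 20).
#' @param min_freq minimum minor-base frequency (default 0.05).
#' @param end_margin bp excluded at each contig end (default 40).
#' @return `data.frame`: `contig`, `pos`, `coverage`, `A`,`C`,`G`,`T`,
#'   `minor_freq`.
#' @export
call_variant_sites <- function(pileup, contig_lengths, min_cov = 20L,
                               min_freq = 0.05, end_margin = 40L) {
  if (!nrow(pileup)) {
    return(cbind(pileup, minor_freq = numeric(0)))
  }
  L <- contig_lengths[pileup$contig]
  eligible <- pileup$coverage >= min_cov & pileup$pos >= end_margin &
    pileup$pos < L - end_margin
  p <- pileup[eligible, , drop = FALSE]
  if (!nrow(p)) {
    p$minor_freq <- numeric(0)
    return(p)
  }
  p$minor_freq <- minor_count(p) / p$coverage
  out <- p[p$minor_freq >= min_freq,
           c("contig", "pos", "coverage", "A", "C", "G", "T", "minor_freq")]
  rownames(out) <- NULL
  out
}

#' Count examined positions per contig
#'
#' Positions meeting the coverage and end-margin criteria of
#' [call_variant_sites()] — the denominator of per-contig heterozygosity.
#'
#' @inheritParams call_variant_sites
#' @return named integer vector (one entry per contig in `pileup`).
#' @export
examined_positions <- function(pileup, contig_lengths, min_cov = 20L,
                               end_margin = 40L) {
  if (!nrow(pileup)) return(setNames(integer(), character()))
  L <- contig_lengths[pileup$contig]
  ok <- pileup$coverage >= min_cov & pileup$pos >= end_margin &
    pileup$pos < L - end_margin
  tab <- table(factor(pileup$contig[ok],
                      levels = unique(pileup$contig)))
  setNames(as.integer(tab), names(tab))
}

#' Classify a nanochromosome as homozygous or heterozygous
#'
#' A contig with variant sites at >= `het_threshold_pct` percent of its
#' examined positions is heterozygous; otherwise homozygous. Contigs with
#' no examined positions are unclassifiable (`NA` classification,
#' flagged).
#'
#' @param contig contig id.
#' @param sites variant sites for this contig (from
#'   [call_variant_sites()]).
#' @param n_examined number of examined positions for this contig.
#' @param match_status `"matchless"` or `"matched"` (from
#'   [nonself_matches()]).
#' @param het_threshold_pct classification threshold in percent
#'   (default 0.5).
#' @return one-row `data.frame`: `contig`, `match_status`, `n_examined`,
#'   `n_variant`, `het_pct` (two decimals), `median_variant_freq`,
#'   `classification`, `flagged`.
#' @export
classify_het <- function(contig, sites, n_examined,
                         match_status = c("matchless", "matched"),
                         het_threshold_pct = 0.5) {
  match_status <- match.arg(match_status)
  sites <- sites[sites$contig == contig, , drop = FALSE]
  nv <- nrow(sites)
  if (n_examined == 0L) {
    return(data.frame(contig = contig, match_status = match_status,
                      n_examined = 0L, n_variant = nv, het_pct = NA_real_,
                      median_variant_freq = NA_real_,
                      classification = NA_character_, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  het_pct <- round(100 * nv / n_examined, 2L)
  data.frame(contig = contig, match_status = match_status,
             n_examined = as.integer(n_examined), n_variant = nv,
             het_pct = het_pct,
             median_variant_freq = if (nv) median(sites$minor_freq) else
               NA_real_,
             classification = if (het_pct >= het_threshold_pct)
               "heterozygous" else "homozygous",
             flagged = FALSE, stringsAsFactors = FALSE)
}

#' Classify every contig in a pileup
#'
#' Convenience wrapper running [call_variant_sites()],
#' [examined_positions()] and [classify_het()] across contigs.
#'
#' @inheritParams call_variant_sites
#' @param match_status named character vector
#'   (`"matchless"`/`"matched"`) per contig; defaults to matchless.
#' @param het_threshold_pct see [classify_het()].
#' @return `data.frame` of per-contig reports.
#' @export
classify_het_all <- function(pileup, contig_lengths, match_status = NULL,
                             min_cov = 20L, min_freq = 0.05,
                             end_margin = 40L, het_threshold_pct = 0.5) {
  sites <- call_variant_sites(pileup, contig_lengths, min_cov, min_freq,
                              end_margin)
  nex <- examined_positions(pileup, contig_lengths, min_cov, end_margin)
  ids <- unique(pileup$contig)
  do.call(rbind, lapply(ids, function(id) {
    ms <- if (!is.null(match_status) && id %in% names(match_status))
      match_status[[id]] else "matchless"
    classify_het(id, sites, if (id %in% names(nex)) nex[[id]] else 0L,
                 ms, het_threshold_pct)
  }))
}

#' Genome-wide homozygous fraction
#'
#' Fraction of nanochromosomes that are homozygous, computed over the
#' total of matchless and matched contigs. Matched contigs (those with a
#' separately assembled allele) are counted individually and treated as
#' heterozygous; only matchless contigs classified homozygous count
#' toward the numerator.
#'
#' @param reports `data.frame` with `match_status` and `classification`
#'   columns (one row per contig), e.g. from [classify_het_all()].
#' @return fraction in `[0, 1]`.
#' @export
genome_homozygous_fraction <- function(reports) {
  if (!nrow(reports)) stop("empty report set")
  n_hom <- sum(reports$match_status == "matchless" &
               reports$classification == "homozygous", na.rm = TRUE)
  n_hom / nrow(reports)
}

#' Per-contig median variant frequency profile
#'
#' Median minor-variant frequency per contig plus a pooled histogram of
#' those medians in 5% bins labelled by lower bound. The allele-balance
#' profile of a genome: balanced alleles put mass near 40-50%, assorted or
#' skewed alleles near the 5% calling floor.
#'
#' @param sites variant sites from [call_variant_sites()].
#' @param bin_width histogram bin width (default 0.05).
#' @return list with `medians` (`contig`, `median_freq`, `n_sites`) and
#'   `histogram` (`bin_low`, `count`).
#' @export
variant_freq_profile <- function(sites, bin_width = 0.05) {
  if (!nrow(sites)) {
    return(list(medians = data.frame(contig = character(),
                                     median_freq = numeric(),
                                     n_sites = integer()),
                histogram = data.frame(bin_low = numeric(),
                                       count = integer())))
  }
  med <- do.call(rbind, lapply(split(sites, sites$contig), function(s) {
    data.frame(contig = s$contig[1L], median_freq = median(s$minor_freq),
               n_sites = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(med) <- NULL
  bins <- seq(0, 1 - bin_width, by = bin_width)
  cnt <- vapply(bins, function(b) sum(med$median_freq >= b &
                                      med$median_freq < b + bin_width),
                integer(1))
  list(medians = med, histogram = data.frame(bin_low = bins, count = cnt))
}

#' Pairwise-alignment heterozygosity between two allele contigs
#'
#' Globally aligns two sequences (match +1, mismatch -1, gap open -5, gap
#' extend -1) and returns substitutions per aligned non-gap column. Pairs
#' where one sequence is more than 10% longer than the other, or where the
#' difference fraction exceeds 15%, are excluded (`NA` with an exclusion
#' reason attribute).
#'
#' @param seq_a,seq_b DNA strings.
#' @param max_len_ratio maximum long/short length ratio (default 1.1).
#' @param max_diff maximum difference fraction (default 0.15).
#' @return numeric heterozygosity, or `NA` with attribute `reason`.
#' @export
pairwise_het <- function(seq_a, seq_b, max_len_ratio = 1.1,
                         max_diff = 0.15) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (max(la, lb) / min(la, lb) > max_len_ratio) {
    return(structure(NA_real_, reason = "length-ratio"))
  }
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  nongap <- p != "-" & s != "-"
  het <- sum(p[nongap] != s[nongap]) / sum(nongap)
  if (het > max_diff) return(structure(NA_real_, reason = "divergence"))
  het
}

## dinucleotide prefixes whose codons are 4-fold degenerate under a code
fourfold_prefixes <- function(code = Biostrings::getGeneticCode("6")) {
  pre <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  keep <- vapply(pre, function(p) {
    aa <- code[paste0(p, DNA_BASES)]
    length(unique(aa)) == 1L
  }, logical(1))
  pre[keep]
}

#' SNP diversity at 4-fold synonymous sites
#'
#' For codon-aware aligned CDS pairs, counts differences at third codon
#' positions where all four bases are synonymous in both aligned codons,
#' under the ciliate nuclear genetic code (translation table 6, TAA/TAG =
#' Gln). Pairs with more than `max_gap_frac` gaps in either sequence, or
#' with no qualifying 4-fold site, are excluded.
#'
#' @param cds_pairs `data.frame` with columns `a` and `b`: aligned CDS
#'   sequences (gaps as `-`, equal lengths, multiples of 3).
#' @param max_gap_frac maximum gap fraction per sequence (default 0.05).
#' @return mean over qualifying pairs of (4-fold differences / 4-fold
#'   sites), with attribute `per_pair` (`data.frame`: `sites`, `diffs`,
#'   `pi`, `excluded`).
#' @export
pi4s <- function(cds_pairs, max_gap_frac = 0.05) {
  code <- Biostrings::getGeneticCode("6")
  ff <- fourfold_prefixes(code)
  per <- lapply(seq_len(nrow(cds_pairs)), function(i) {
    a <- toupper(cds_pairs$a[i]); b <- toupper(cds_pairs$b[i])
    if (nchar(a) != nchar(b) || nchar(a) %% 3L != 0L)
      stop("pair ", i, ": aligned CDS must be equal length, multiple of 3")
    gap_a <- lengths(regmatches(a, gregexpr("-", a, fixed = TRUE)))
    gap_b <- lengths(regmatches(b, gregexpr("-", b, fixed = TRUE)))
    if (gap_a / nchar(a) > max_gap_frac || gap_b / nchar(b) > max_gap_frac)
      return(data.frame(sites = 0L, diffs = 0L, pi = NA_real_,
                        excluded = "gaps"))
    n_cod <- nchar(a) %/% 3L
    ca <- substring(a, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    cb <- substring(b, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    clean <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
    ca <- ca[clean]; cb <- cb[clean]
    qual <- substr(ca, 1L, 2L) %in% ff & substr(cb, 1L, 2L) %in% ff
    sites <- sum(qual)
    if (!sites) return(data.frame(sites = 0L, diffs = 0L, pi = NA_real_,
                                  excluded = "no-4fold-sites"))
    diffs <- sum(substr(ca[qual], 3L, 3L) != substr(cb[qual], 3L, 3L))
    data.frame(sites = sites, diffs = diffs, pi = diffs / sites,
               excluded = NA_character_)
  })
  per <- do.call(rbind, per)
  if (all(is.na(per$pi))) stop("no qualifying CDS pairs")
  structure(mean(per$pi, na.rm = TRUE), per_pair = per)
}

#' Effective population size from corrected 4-fold diversity
#'
#' Pairwise alignments of co-assembled alleles underestimate read-based
#' heterozygosity; the raw 4-fold diversity is therefore scaled by the
#' ratio of read-based to alignment-based genome-wide heterozygosity
#' before applying the neutral expectation `pi_4S = 4 Ne mu`.
#'
#' @param pi4s_raw raw mean 4-fold synonymous diversity (fraction).
#' @param het_read_based genome-wide read-based SNP heterozygosity
#'   (fraction).
#' @param het_alignment_based alignment-based SNP heterozygosity
#'   (fraction).
#' @param mu per-base per-generation mutation rate (default 1e-9).
#' @return `data.frame`: `pi4s_raw`, `correction_factor`,
#'   `pi4s_corrected`, `mu`, `Ne`.
#' @export
effective_pop_size <- function(pi4s_raw, het_read_based,
                               het_alignment_based, mu = 1e-9) {
  if (het_alignment_based <= 0) stop("alignment-based heterozygosity must be > 0")
  if (pi4s_raw < 0 || het_read_based < 0 || mu <= 0)
    stop("inputs must be positive")
  f <- het_read_based / het_alignment_based
  corr <- pi4s_raw * f
  data.frame(pi4s_raw = pi4s_raw, correction_factor = f,
             pi4s_corrected = corr, mu = mu, Ne = corr / (4 * mu))
}
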