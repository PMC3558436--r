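## Relative nanochromosome copy-number estimation and group comparisons.

#' Estimate relative copy number per contig
#'
#' Two estimators per contig of length >= `min_len`: (i) telomere-less
#' reads aligned entirely inside the non-subtelomeric interior
#' (`margin` bp from either end), normalised per interior bp; (ii)
#' telomeric read counts split by the 5'/3' end they support. Relative
#' copy number is interior reads-per-bp over the mean reads-per-bp of the
#' qualifying set (so it has mean 1 by construction).
#'
#' @param alignments alignment `data.frame` with `contig`, `start`, `end`,
#'   `is_telomeric` and `telo_polarity` columns (simulator truth or mapped
#'   telomeric/telomere-less reads).
#' @param contig_lengths named integer vector.
#' @param min_len minimum qualifying contig length (default 1800).
#' @param margin subtelomeric margin excluded at each end (default 600).
#' @return `data.frame`: `contig`, `length`, `interior_reads`,
#'   `interior_len_bp`, `reads_per_bp`, `telomeric_reads_5`,
#'   `telomeric_reads_3`, `telomeric_reads`, `relative_cn`. Excluded
#'   (short) contigs are listed in attribute `excluded`.
#' @export
estimate_cn <- function(alignments, contig_lengths, min_len = 1800L,
                        margin = 600L) {
  ids <- names(contig_lengths)
  qual <- ids[contig_lengths >= min_len]
  excluded <- setdiff(ids, qual)
  a <- data.table::as.data.table(
    alignments[, intersect(c("contig", "start", "end", "is_telomeric",
                             "telo_polarity"), names(alignments))])
  if (is.null(a$is_telomeric)) a$is_telomeric <- FALSE
  if (is.null(a$telo_polarity)) a$telo_polarity <- NA_character_
  a <- a[contig %in% qual]
  a[, L := contig_lengths[contig]]
  agg <- a[, .(
    interior_reads = sum(!is_telomeric & start >= margin &
                           end <= L[1L] - margin),
    telomeric_reads_5 = sum(is_telomeric &
                              !is.na(telo_polarity) & telo_polarity == "5p"),
    telomeric_reads_3 = sum(is_telomeric &
                              !is.na(telo_polarity) & telo_polarity == "3p")),
    by = contig]
  est <- data.frame(contig = qual, length = as.integer(contig_lengths[qual]),
                    stringsAsFactors = FALSE)
  est <- merge(est, as.data.frame(agg), by = "contig", all.x = TRUE)
  for (cc in c("interior_reads", "telomeric_reads_5", "telomeric_reads_3"))
    est[[cc]][is.na(est[[cc]])] <- 0L
  est$interior_len_bp <- est$length - 2L * margin
  if (!nrow(est)) stop("no contig meets the length floor")
  est$reads_per_bp <- est$interior_reads / est$interior_len_bp
  est$telomeric_reads <- est$telomeric_reads_5 + est$telomeric_reads_3
  est$relative_cn <- est$reads_per_bp / mean(est$reads_per_bp)
  structure(est, excluded = excluded)
}

#' Cross-validate the two copy-number estimators
#'
#' Pearson correlation between interior reads-per-bp and total telomeric
#' reads, plus the through-origin regression of 5' on 3' telomeric read
#' counts (slope and r-squared) — agreement of the two estimators
#' licenses telomeric-read-only analyses.
#'
#' @param estimates result of [estimate_cn()] (at least 10 rows).
#' @return list: `r` (Pearson), `slope_5_on_3`, `r2_5_on_3`, `n`.
#' @export
cross_validate <- function(estimates) {
  if (nrow(estimates) < 10L) stop("need at least 10 estimates")
  x <- estimates$reads_per_bp
  y <- estimates$telomeric_reads
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, slope_5_on_3 = NA_real_,
                r2_5_on_3 = NA_real_, n = nrow(estimates),
                flagged = "zero variance"))
  }
  t5 <- estimates$telomeric_reads_5
  t3 <- estimates$telomeric_reads_3
  slope <- sum(t5 * t3) / sum(t3^2)
  r2 <- if (sd(t5) == 0 || sd(t3) == 0) NA_real_ else cor(t5, t3)^2
  list(r = cor(x, y), slope_5_on_3 = slope, r2_5_on_3 = r2,
       n = nrow(estimates))
}

#' One-sided two-sample Kolmogorov-Smirnov comparison
#'
#' Tests the alternative that sample `a` is stochastically greater than
#' sample `b`: `D = max over x of (ECDF_b(x) - ECDF_a(x))`, evaluated
#' over the pooled sample points, with the asymptotic p-value
#' `exp(-2 D^2 m n / (m + n))`.
#'
#' @param values_a,values_b numeric samples (non-empty).
#' @param label_a,label_b group labels for the report.
#' @return one-row `data.frame`: `group_a`, `group_b`, `D`, `p`,
#'   `mean_a`, `mean_b`, `ratio` (`mean_a/mean_b`).
#' @export
ks_one_sided <- function(values_a, values_b, label_a = "a", label_b = "b") {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  pooled <- sort(unique(c(values_a, values_b)))
  ea <- vapply(pooled, function(x) mean(values_a <= x), numeric(1))
  eb <- vapply(pooled, function(x) mean(values_b <= x), numeric(1))
  D <- max(0, eb - ea)
  m <- length(values_a); n <- length(values_b)
  p <- exp(-2 * D^2 * m * n / (m + n))
  data.frame(group_a = label_a, group_b = label_b, D = D, p = p,
             mean_a = mean(values_a), mean_b = mean(values_b),
             ratio = mean(values_a) / mean(values_b),
             stringsAsFactors = FALSE)
}

#' Copy-number group comparisons
#'
#' For each logical annotation flag (e.g. alternatively fragmented,
#' ribosomal-protein, tRNA), compares flagged versus unflagged contigs:
#' mean/SD of relative copy number and telomeric reads, mean ratios, and
#' the one-sided K-S test with the alternative that the flagged group is
#' more highly amplified. Groups with fewer than 2 members are skipped.
#'
#' @param estimates result of [estimate_cn()].
#' @param labels `data.frame` with `contig` plus one logical column per
#'   group flag.
#' @param measure `"relative_cn"` or `"telomeric_reads"`.
#' @return `data.frame`, one row per comparison.
#' @export
group_report <- function(estimates, labels,
                         measure = c("relative_cn", "telomeric_reads")) {
  measure <- match.arg(measure)
  m <- merge(estimates, labels, by = "contig")
  flags <- setdiff(names(labels), "contig")
  rows <- lapply(flags, function(fl) {
    g <- m[[fl]]
    if (sum(g) < 2L || sum(!g) < 2L) return(NULL)
    va <- m[[measure]][g]
    vb <- m[[measure]][!g]
    ks <- ks_one_sided(va, vb, fl, paste0("non-", fl))
    cbind(ks, data.frame(sd_a = sd(va), sd_b = sd(vb), n_a = length(va),
                         n_b = length(vb), measure = measure,
                         stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group_a = character(), group_b = character(),
                      D = numeric(), p = numeric(), mean_a = numeric(),
                      mean_b = numeric(), ratio = numeric(),
                      sd_a = numeric(), sd_b = numeric(),
                      n_a = integer(), n_b = integer(),
                      measure = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Haploid genome size arithmetic
#'
#' Labelled, assumption-documented estimates: `haploid_count()` reduces an
#' assembly's nanochromosome-like contig count by the expected allelic
#' redundancy (each heterozygous nanochromosome contributes on average two
#' assembled contigs, homozygous ones contribute one);
#' `haploid_genome_size()` multiplies a haploid nanochromosome count by
#' the mean nanochromosome length.
#'
#' @param n_two_tel,n_multi_tel,n_one_tel contig counts by telomere class.
#' @param hom_fraction genome-wide homozygous fraction.
#' @return `haploid_count()`: numeric estimate of the haploid
#'   nanochromosome number.
#' @export
haploid_count <- function(n_two_tel, n_multi_tel, n_one_tel, hom_fraction) {
  stopifnot(hom_fraction >= 0, hom_fraction <= 1)
  (n_two_tel + n_multi_tel + n_one_tel) *
    (hom_fraction + (1 - hom_fraction) / 2)
}

#' @rdname haploid_count
#' @param n_nanochromosomes haploid nanochromosome count.
#' @param mean_len_bp mean nanochromosome length in bp.
#' @return `haploid_genome_size()`: list with `bp` and `mb` (nearest
#'   megabase, as printed in genome reports).
#' @export
haploid_genome_size <- function(n_nanochromosomes, mean_len_bp) {
  bp <- n_nanochromosomes * mean_len_bp
  list(bp = bp, mb = round(bp / 1e6))
}
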