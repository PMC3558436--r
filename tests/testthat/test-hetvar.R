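# a pileup row constructor: coverage split between ref A and alt C
pu_row <- function(contig, pos, cov, alt = 0L) {
  data.frame(contig = contig, pos = pos, A = cov - alt, C = alt, G = 0L,
             T = 0L, coverage = cov, stringsAsFactors = FALSE)
}

test_that("variant calling applies coverage, frequency and margin filters", {
  lens <- c(ctg = 1000L)
  pu <- rbind(pu_row("ctg", 100L, 30L, 3L),  # 10% -> variant
              pu_row("ctg", 200L, 30L, 1L),  # 3.3% -> no
              pu_row("ctg", 300L, 15L, 5L),  # below 20x -> not examined
              pu_row("ctg", 20L, 30L, 10L),  # inside 40 bp margin -> no
              pu_row("ctg", 980L, 30L, 10L)) # inside 3' margin -> no
  v <- call_variant_sites(pu, lens)
  expect_equal(v$pos, 100L)
  expect_equal(v$minor_freq, 0.1)
  expect_equal(unname(examined_positions(pu, lens)["ctg"]), 2L)
})

test_that("heterozygosity classification follows the 0.5% rule", {
  lens <- c(ctg = 1500L)
  # worked example: 12 variants over 1,350 examined positions
  pu <- do.call(rbind, lapply(50:1399, function(p)
    pu_row("ctg", p, 30L, if (p <= 61) 10L else 0L)))
  sites <- call_variant_sites(pu, lens)
  expect_equal(nrow(sites), 12L)
  rep <- classify_het("ctg", sites, examined_positions(pu, lens)[["ctg"]],
                      "matchless")
  expect_equal(rep$n_examined, 1350L)
  expect_equal(rep$het_pct, 0.89)
  expect_equal(rep$classification, "heterozygous")

  # 0 variants -> homozygous; 5/2000 (0.25%) -> homozygous
  none <- sites[0, ]
  expect_equal(classify_het("ctg", none, 1350L)$classification, "homozygous")
  five <- do.call(rbind, lapply(1:5, function(i) {
    r <- pu_row("ctg", 100L + i, 30L, 10L); r$minor_freq <- 1 / 3; r
  }))
  expect_equal(classify_het("ctg", five, 2000L)$classification, "homozygous")
  # no examined positions -> unclassifiable, flagged
  un <- classify_het("ctg", none, 0L)
  expect_true(un$flagged)
  expect_true(is.na(un$classification))
})

test_that("genome homozygous fraction matches printed-count arithmetic", {
  # all matchless, no variants -> 100% homozygous
  rep_all <- data.frame(match_status = "matchless",
                        classification = rep("homozygous", 10))
  expect_equal(genome_homozygous_fraction(rep_all), 1.0)
  expect_error(genome_homozygous_fraction(rep_all[0, ]), "empty")

  # simulated genome at het fraction 0.58: recovered homozygous fraction
  # within 3 binomial SDs of 42%
  sim <- shared_sim()
  a <- sim$reads$alignments
  pu <- pileup_from_alignments(a[!a$is_telomeric &
                                 a$library %in% c("pe", "se"), ],
                               sim$lens)
  reports <- classify_het_all(pu, sim$lens)
  frac <- genome_homozygous_fraction(reports)
  n <- nrow(reports)
  expect_lt(abs(frac - 0.42), 3 * sqrt(0.42 * 0.58 / n))

  # per-locus classification agrees with simulation truth
  m <- merge(reports, sim$genome$loci, by.x = "contig", by.y = "locus")
  expect_lt(mean((m$classification == "heterozygous") != m$het), 0.05)
  # estimated het_pct within 20% of the truth SNP rate on het loci
  expect_lt(abs(mean(m$het_pct[m$het]) / 100 - 0.04) / 0.04, 0.20)
})

test_that("variant frequency profiles separate balanced and skewed alleles", {
  sites <- data.frame(contig = "c", pos = 1:3, coverage = 100L,
                      A = 0L, C = 0L, G = 0L, T = 0L,
                      minor_freq = c(0.40, 0.45, 0.50))
  prof <- variant_freq_profile(sites)
  expect_equal(prof$medians$median_freq, 0.45)
  expect_equal(variant_freq_profile(sites[1, ])$medians$median_freq, 0.40)
  expect_equal(nrow(variant_freq_profile(sites[0, ])$medians), 0L)

  # 50:50 mixture of balanced (0.45) and skewed (0.083) loci -> bimodal
  p_bal <- sim_params(n_loci = 25, het_locus_fraction = 1, seed = 71,
                      minor_allele_fraction = 0.45, coverage_x = 60,
                      altfrag_fraction = 0)
  p_skw <- sim_params(n_loci = 25, het_locus_fraction = 1, seed = 72,
                      minor_allele_fraction = 0.083, coverage_x = 60,
                      altfrag_fraction = 0)
  meds <- unlist(lapply(list(p_bal, p_skw), function(p) {
    g <- simulate_genome(p)
    r <- simulate_reads(g, libraries = "pe")
    a <- r$alignments
    pu <- pileup_from_alignments(a[!a$is_telomeric, ],
                                 setNames(nchar(g$contigs),
                                          names(g$contigs)))
    sites <- call_variant_sites(pu, setNames(nchar(g$contigs),
                                             names(g$contigs)))
    variant_freq_profile(sites)$medians$median_freq
  }))
  hist_bins <- floor(meds / 0.05) * 0.05
  tab <- table(hist_bins)
  # modes in the 40-45% and 5-10% bins
  low_mode <- sum(meds >= 0.05 & meds < 0.10)
  high_mode <- sum(meds >= 0.40 & meds < 0.50)
  mid <- sum(meds >= 0.15 & meds < 0.35)
  expect_gt(low_mode, mid)
  expect_gt(high_mode, mid)
})

test_that("pairwise heterozygosity counts substitutions per aligned column", {
  set.seed(401)
  s <- motif_free_dna(1000)
  expect_equal(pairwise_het(s, s), 0)

  ch <- strsplit(s, "")[[1]]
  at <- sample(1000, 40)
  ch[at] <- vapply(ch[at],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   "")
  s2 <- paste(ch, collapse = "")
  expect_equal(pairwise_het(s, s2), 0.04)

  # 20% divergence excluded by the 15% rule
  at2 <- sample(1000, 200)
  ch2 <- strsplit(s, "")[[1]]
  ch2[at2] <- vapply(ch2[at2],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1), "")
  div <- pairwise_het(s, paste(ch2, collapse = ""))
  expect_true(is.na(div))
  expect_equal(attr(div, "reason"), "divergence")

  # >10% length difference excluded
  lr <- pairwise_het(s, substr(s, 1, 800))
  expect_true(is.na(lr))
  expect_equal(attr(lr, "reason"), "length-ratio")
})

test_that("pi4s counts 4-fold third-position differences under code 6", {
  cds <- "GGAGGAGGAGGAGGAGGAGGAGGAGGAGGA" # ten GGx (Gly, 4-fold) codons
  expect_equal(as.numeric(pi4s(data.frame(a = cds, b = cds))), 0)
  # one difference among ten 4-fold sites
  alt <- paste0(substr(cds, 1, 29), "C") # GGA -> GGC at the last codon
  expect_equal(as.numeric(pi4s(data.frame(a = cds, b = alt))), 0.10)
  # TAT <-> TAC is a 2-fold Tyr site under the ciliate code: not counted
  tat <- paste0(cds, "TAT")
  tac <- paste0(cds, "TAC")
  expect_equal(as.numeric(pi4s(data.frame(a = tat, b = tac))), 0)
  # under code 6 TAA/TAG are Gln codons, still not 4-fold (TAT/TAC = Tyr)
  expect_false("TA" %in% nanochromkit:::fourfold_prefixes())
  # gap-heavy pairs are excluded
  gap <- paste0(strrep("-", 6), substr(cds, 7, 30))
  expect_error(pi4s(data.frame(a = cds, b = gap)), "no qualifying")
})

test_that("pi4s equals the brute-force per-site count on random codon pairs", {
  set.seed(402)
  code <- Biostrings::getGeneticCode("6")
  bases <- c("A", "C", "G", "T")
  for (rep in 1:20) {
    n <- 60L
    cod_a <- paste0(sample(bases, n, TRUE), sample(bases, n, TRUE),
                    sample(bases, n, TRUE))
    cod_b <- cod_a
    flip <- sample(n, 12)
    substr(cod_b[flip], 3, 3) <- sample(bases, 12, TRUE)
    # drop stop codons to keep the pair CDS-like
    ok <- !code[cod_a] %in% "*" & !code[cod_b] %in% "*"
    cod_a <- cod_a[ok]; cod_b <- cod_b[ok]
    # oracle: enumerate third-position degeneracy directly
    is4 <- function(cod) {
      length(unique(code[paste0(substr(cod, 1, 2), bases)])) == 1L
    }
    qual <- vapply(cod_a, is4, TRUE) & vapply(cod_b, is4, TRUE)
    oracle <- sum(qual & substr(cod_a, 3, 3) != substr(cod_b, 3, 3)) /
      sum(qual)
    got <- pi4s(data.frame(a = paste(cod_a, collapse = ""),
                           b = paste(cod_b, collapse = "")))
    expect_equal(as.numeric(got), oracle)
  }
})

test_that("effective population size follows pi4S = 4 Ne mu", {
  est <- effective_pop_size(0.083, 0.040, 0.030, mu = 1e-9)
  expect_equal(round(est$pi4s_corrected, 3), 0.111)
  expect_equal(est$Ne, est$pi4s_corrected / 4e-9)
  expect_equal(effective_pop_size(0, 0.04, 0.03)$Ne, 0)
  expect_error(effective_pop_size(0.1, 0.04, 0), "must be > 0")
  # linear in pi, inverse in mu, over a grid
  for (pi in c(0.01, 0.05, 0.2)) {
    for (mu in c(1e-9, 5e-9, 1e-8)) {
      expect_equal(effective_pop_size(pi, 1, 1, mu)$Ne, pi / (4 * mu))
    }
  }
})
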