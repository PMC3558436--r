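# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# brute-force N50: scan candidate lengths descending, cumulative coverage
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  for (L in s) {
    if (sum(s[s >= L]) >= tot / 2) return(L)
  }
  s[length(s)]
}

# brute-force one-sided KS D+ for "a stochastically greater than b":
# sup over all pooled points of ECDF_b - ECDF_a
oracle_ks_dplus <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(0, vapply(xs, function(x) mean(b <= x) - mean(a <= x), numeric(1)))
}

# dynamic-programming alignment identity oracle (global, affine gaps)
oracle_dp_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

# random DNA guaranteed free of telomere-like motifs (>= 3 mismatches from
# either 12 bp core), by rejection
motif_free_dna <- function(n, max_degenerate = 2L) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    hits <- nanochromkit::find_telomeres(s, max_degenerate)
    if (!nrow(hits)) return(s)
  }
}

# memoised medium-scale simulation shared across test files
.fixture_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    p <- sim_params(n_loci = 120, coverage_x = 50, telo_se_depth = 30,
                    telo_pair_depth = 30, seed = 42)
    g <- simulate_genome(p)
    r <- simulate_reads(g, libraries = c("pe", "se", "tp", "telo_se"),
                        sequences = TRUE)
    .fixture_env$sim <- list(params = p, genome = g, reads = r,
                             lens = stats::setNames(nchar(g$contigs),
                                                    names(g$contigs)))
  }
  .fixture_env$sim
}
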