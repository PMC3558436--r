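---
title: "Methods: models, thresholds and design choices in nanochromkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The biological model

Spirotrich ciliates carry two genomes: a germline micronucleus and a
somatic macronucleus in which each locus is processed into a tiny,
telomere-capped **nanochromosome**, typically bearing a single gene. This
architecture has three statistical consequences that every module of this
package is built around:

1. **Telomeres everywhere.** Each chromosome starts and ends with a short
   C4A4-type repeat. A read overlapping a chromosome end therefore carries
   telomeric sequence; after hard-masking, the first non-telomeric base of
   such a read marks a **telomere addition site** (TAS).
2. **Alternative fragmentation.** A minority of loci (~10%) are processed
   into several stable isoforms sharing sequence: an internal TAS on an
   assembled contig is the signature. Fragmentation is usually
   *directional* — one internal site, hence one of the two possible short
   isoforms.
3. **Nonuniform amplification.** Chromosome copy number varies
   (right-skewed, roughly lognormal), so read depth per contig is an
   estimator of relative copy number rather than a nuisance.

Diploidy adds a fourth axis: a locus may be homozygous or heterozygous,
and assemblers either co-assemble the two alleles into one contig (allelic
variants then surface as high-frequency pileup "variants") or assemble
them separately (surfacing as near-identical "matched" contig pairs).

# The synthetic world

`sim_params()` fixes the world the analyses are tested against. Defaults
are the conditions the analyses assume, not tuning knobs:

| Parameter | Default | Meaning |
|---|---|---|
| `length_mean_bp`, `length_sd_bp` | 3200, 1600 | truncated lognormal contig lengths, 600 bp floor. The empirical length law is right-skewed with mean ~3.2 kb; a lognormal is our choice (the exact family is not published), with user-settable moments. |
| `het_locus_fraction` | 0.58 | fraction of heterozygous loci (so ~42% homozygous) |
| `snp_rate` | 0.04 | per-site substitution rate between alleles |
| `minor_allele_fraction` | 0.5 | allele balance; 0.083 emulates a skewed ~1:11 ratio |
| `altfrag_fraction` | 0.10 | alternatively fragmented loci; 1–2 internal sites, placed in inter-CDS spacers |
| `copy_number_lognormal_sigma` | 0.5 | mean-1 lognormal relative copy number |
| `pe_outer_mean_bp`, `pe_outer_sd_bp` | 362, 52 | paired-end outer distance |
| `gap_depletion_prob` | 0.9 | probability a fragment terminating in the 160 bp window starting 100 bp inside a telomere is discarded — the size-selection artifact that motivates both the 400 bp chimera end zone and the 600 bp copy-number margins |
| `base_error_rate` | 0.002 | uniform substitutions; **no indels**, matching a substitution-only variant model |
| `telomere_len_bp` | 20 | fixed 20 bp telomere (CCCCAAAACCCCAAAACCCC / reverse complement); real telomere-length variation is not modelled because the analyses only need detectability |

One master `seed` governs everything; per-locus and per-molecule
sub-seeds are derived deterministically, so identical parameters give
byte-identical FASTA/FASTQ/TSV output.

Two deliberate departures from a literal shotgun model:

* **Motif scrubbing.** Interior sequence is re-randomised wherever it
  falls within 3 mismatches of a telomere core, so that truth contigs
  carry exactly two telomeres and single substitutions (SNPs, sequencing
  errors) cannot create a spurious telomeric hit. Real genomes do contain
  internal telomere-like repeats (the "multi" contig class exists for
  them); the simulator intentionally excludes them so recall tests are
  exact.
* **The `telo_se` library.** With 20 bp telomeres and 100 bp reads,
  shotgun coverage alone yields only ~2–3 telomere-bearing reads per
  chromosome end at 50×, whereas real telomeric-read counts per
  nanochromosome are in the hundreds (separate enriched libraries and far
  deeper sequencing). Rather than inflate everything, the simulator emits
  the telomeric subset directly as telomere-anchored single reads at a
  configurable per-end depth. Support-threshold behaviour (the ≥10-read
  "strong" rule) is exercised at depths where the condition actually
  binds.

**What a green test does *not* establish.** The synthetic world has no
indels, no paralogy, no GC or amplification bias along chromosomes, no
contamination, uniform error rates, and scrubbed internal telomere
motifs. Green recovery tests certify the *estimators* under the stated
model; they say nothing about robustness to these real-data features.

# Numerical and algorithmic choices

* **Telomere detection** scans for the 12 bp core with ≤2 mismatches
  (configurable; the degree of degeneracy tolerated in practice is not
  quantified anywhere we could anchor to) and extends across the maximal
  `[AC]*`/`[GT]*` run, mirroring the masking regular expression.
  Masking replaces each span with a single `N` and is idempotent.
* **Contig classes** count *all* detected spans (an internal motif makes
  a contig "multi"); the assembly telomere-count statistic counts
  terminal spans (within 100 bp of an end) only.
* **N50** is defined on total assembly length, ties resolved to the
  smaller qualifying length; verified against a brute-force scan.
* **End extension** seeds the 100 bp terminal anchor with exact 31-mers
  and verifies at ≥94% identity — a deliberate stand-in for BLAST.
  Candidates rank by source priority, anchor identity, extension length,
  then source id; telomere-bearing ends are never extended (extension
  stops once both telomeres are present). Two rounds by default.
* **Chimera splitting**: spans are inter-mate regions excluding the reads;
  uncovered interior intervals outside the 400 bp end zones are cut at
  their midpoint (the true junction being unknowable) and 200 bp is
  trimmed from each new end. Note that under this rule a single unspanned
  interval on a *long* contig always leaves two surviving fragments; only
  short contigs can be eliminated entirely.
* **Mapping** is seed-and-verify (21-mers, ungapped verification,
  identity = matches/alignment columns, ≥0.94 floor). Ungapped rather
  than banded verification is sufficient because the simulated regime is
  substitution-only; the identity computation is tested against a
  dynamic-programming oracle, where the two agree exactly in the absence
  of indels. Multi-best placements resolve to the lexicographically
  smallest (contig, position, strand) and are flagged; reruns are
  byte-identical.
* **Variant calling** takes the second most frequent base at ≥20×
  coverage, ≥5% frequency, ≥40 bp from contig ends; `n_examined` is the
  count of positions passing the coverage and margin filters, which
  reproduces the style of the 12/1,350 worked example. Heterozygous iff
  variants occupy ≥0.5% of examined positions. Matched contigs are
  treated as heterozygous in the genome-wide fraction — the only
  arithmetic consistent with the printed 42% (≈66% matchless × 63%
  homozygous-of-matchless).
* **4-fold diversity** uses NCBI translation table 6 (ciliate nuclear;
  TAA/TAG = Gln). A third position qualifies only when all four bases are
  synonymous in *both* aligned codons. `Ne = π4S/(4μ)` with μ = 1e-9 by
  default. The formula on the printed inputs gives 2.775e7 while the
  source report prints 2.6e7 (its exact π is unstated); we report the
  formula's value.
* **TAS calling** is greedy maximal-coverage windowing: the best-supported
  position wins (ties to the smaller coordinate), same-polarity reads
  within ±100 bp are assigned to it, and no second site may seed within
  200 bp. Polarity convention: a 5′ TAS retains sequence to its right, a
  3′ TAS to its left. Sites of one polarity within 50 bp are merged
  before isoform prediction. Both the 100 bp and 250 bp internal-site
  margins are exposed (different analyses use different margins; neither
  is hard-coded).
* **One-sided K–S**: D⁺ = sup(ECDF_b − ECDF_a) for the alternative that
  sample *a* is stochastically greater, p = exp(−2D²mn/(m+n))
  (asymptotic; exact small-sample p is out of scope). The D⁺ is verified
  against a brute-force ECDF maximum over pooled points.
* **Copy number**: a read is "interior" only when its alignment lies
  entirely within [600, L−600); the telomere-less requirement applies to
  the counted read, not its mate. Relative copy number is normalised to
  mean 1 over qualifying (≥1,800 bp) contigs — a published mean of 0.94
  under an unstated normalisation is therefore not reproduced, by
  construction.

# Known limitations

* The mapper indexes every contig k-mer in memory and is intended for
  desk-scale genomes (tens of Mb), not mammalian-scale references.
* No indel handling anywhere (simulator, mapper, caller) — matching the
  substitution-only scope.
* Isoform prediction reports a minimum set: sites with no linking
  telomere-pair yield no isoform, and long isoforms beyond the pair
  library's size selection are invisible, as in the real protocol.
* `haploid_count()` is labelled arithmetic, not an estimator: it reduces
  a contig census by the expected allelic redundancy
  ((1 + hom)/2) and documents its assumptions rather than claiming to
  reproduce any particular published census exactly.
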