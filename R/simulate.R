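## Synthetic nanochromosome genome and read simulator.
##
## A locus is a telomere-capped contig: 20 bp 5' telomere + interior + 20 bp
## 3' telomere. Heterozygous loci carry a second allele differing by
## substitutions at `snp_rate`. Alternatively fragmented loci carry 1-2
## internal fragmentation sites placed in inter-CDS spacers; each site
## defines a shorter telomere-to-telomere isoform (a 3' site at boundary b
## retains [0,b), a 5' site retains [b,L)). Reads are drawn per
## (allele, isoform) molecule proportional to copy number x allele weight x
## isoform weight, together with ground-truth alignment records.

## rebuild interior windows that come within `min_mm` mismatches of a
## telomere core motif, so truth contigs have no spurious telomeric hits
## and single substitutions (SNPs, sequencing errors) cannot create one
scrub_telomere_motifs <- function(seq, min_mm = 4L) {
  cores <- list(strsplit(TELOMERE_CORE_5P, "")[[1]],
                strsplit(TELOMERE_CORE_3P, "")[[1]])
  for (iter in 1:20) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hits <- integer()
    for (core in cores) {
      h <- core_hits(chars, core, min_mm - 1L)
      hits <- c(hits, h$pos)
    }
    if (!length(hits)) return(seq)
    for (p in unique(hits)) {
      chars[(p + 1L):(p + 12L)] <- sample(DNA_BASES, 12L, replace = TRUE)
    }
    seq <- paste(chars, collapse = "")
  }
  seq
}

## simple gene model on the interior: lead/tail spacers, genes separated by
## internal spacers; returns CDS intervals in contig coordinates (0-based)
place_genes <- function(contig_len, telo, n_genes) {
  lead <- 80L
  spacer <- 150L
  interior <- contig_len - 2L * telo
  avail <- interior - 2L * lead - (n_genes - 1L) * spacer
  if (avail < n_genes * 150L) { # too short for requested genes
    n_genes <- max(1L, (interior - 2L * lead) %/% 400L)
    avail <- interior - 2L * lead - (n_genes - 1L) * spacer
  }
  glen <- (avail %/% n_genes) %/% 3L * 3L # whole codons
  start <- telo + lead
  cds <- data.frame(start = integer(n_genes), end = integer(n_genes),
                    strand = "+", stringsAsFactors = FALSE)
  for (g in seq_len(n_genes)) {
    cds$start[g] <- start
    cds$end[g] <- start + glen
    start <- start + glen + spacer
  }
  cds
}

#' Simulate a nanochromosome genome with ground truth
#'
#' Generates `n_loci` telomere-capped loci with heterozygosity, alternative
#' fragmentation and relative copy number drawn per [sim_params()], plus all
#' ground-truth tables. Identical parameters and seed give byte-identical
#' output.
#'
#' @param params a [sim_params()] object.
#' @return list of class `sim_genome` with elements:
#'   `params`; `contigs` (named character vector, the reference assembly =
#'   major allele of each locus); `loci` (`data.frame`: locus, length, het,
#'   altfrag, copy_number); `alleles` (locus, allele, weight, seq);
#'   `snps` (locus, pos, ref, alt); `frag_sites` (locus, pos, polarity);
#'   `isoforms` (locus, isoform, start, end, weight); `cds` (locus, start,
#'   end, strand). All coordinates are 0-based half-open on the contig.
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_loci
  telo <- p$telomere_len_bp

  # lengths: truncated lognormal matched to the requested mean/SD
  sdlog <- sqrt(log(1 + (p$length_sd_bp / p$length_mean_bp)^2))
  meanlog <- log(p$length_mean_bp) - sdlog^2 / 2
  min_len <- max(600L, 2L * telo + 200L)
  lens <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- round(rlnorm(length(todo), meanlog, sdlog))
    ok <- draw >= min_len
    lens[todo[ok]] <- as.integer(draw[ok])
    todo <- todo[!ok]
  }

  cn <- rlnorm(n, -p$copy_number_lognormal_sigma^2 / 2,
               p$copy_number_lognormal_sigma)
  is_het <- runif(n) < p$het_locus_fraction
  is_frag <- runif(n) < p$altfrag_fraction

  ids <- sprintf("locus_%04d", seq_len(n))
  contigs <- character(n)
  alleles <- vector("list", n)
  snps <- vector("list", n)
  frag_sites <- vector("list", n)
  isoforms <- vector("list", n)
  cds_all <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(derive_seed(p$seed, i))
    L <- lens[i]
    interior <- scrub_telomere_motifs(random_dna(L - 2L * telo))
    a_seq <- paste0(TELOMERE_SEQ_5P, interior, TELOMERE_SEQ_3P)
    contigs[i] <- a_seq

    # genes: fragmented loci get >= 2 so internal spacers exist
    n_genes <- if (is_frag[i]) max(2L, 1L + rbinom(1L, 1L, 0.3)) else
      1L + rbinom(1L, 1L, 0.3)
    cds <- place_genes(L, telo, n_genes)
    cds_all[[i]] <- data.frame(locus = ids[i], cds,
                               stringsAsFactors = FALSE)

    # second allele for heterozygous loci: substitutions at snp_rate
    if (is_het[i]) {
      int_chars <- strsplit(interior, "", fixed = TRUE)[[1]]
      n_snp <- rbinom(1L, length(int_chars), p$snp_rate)
      pos <- sort(sample.int(length(int_chars), n_snp))
      ref <- int_chars[pos]
      alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1))
      b_chars <- int_chars
      b_chars[pos] <- alt
      b_seq <- paste0(TELOMERE_SEQ_5P, paste(b_chars, collapse = ""),
                      TELOMERE_SEQ_3P)
      snps[[i]] <- data.frame(locus = ids[i], pos = pos - 1L + telo,
                              ref = ref, alt = alt, stringsAsFactors = FALSE,
                              row.names = NULL)
      alleles[[i]] <- data.frame(
        locus = ids[i], allele = c("A", "B"),
        weight = c(1 - p$minor_allele_fraction, p$minor_allele_fraction),
        seq = c(a_seq, b_seq), stringsAsFactors = FALSE)
    } else {
      alleles[[i]] <- data.frame(locus = ids[i], allele = "A", weight = 1,
                                 seq = a_seq, stringsAsFactors = FALSE)
    }

    # fragmentation sites in internal inter-CDS spacers (or uniform when
    # frag_intra_cds); each site defines one shorter isoform
    iso <- data.frame(locus = ids[i], isoform = "full", start = 0L,
                      end = L, weight = 1, stringsAsFactors = FALSE)
    if (is_frag[i]) {
      n_sites <- 1L + rbinom(1L, 1L, p$altfrag_two_site_prob)
      margin <- 400L
      if (p$frag_intra_cds) {
        cand <- sample(seq.int(margin, L - margin), n_sites)
      } else {
        # midpoints between consecutive CDS (internal spacers only)
        mids <- if (nrow(cds) >= 2L)
          as.integer((cds$end[-nrow(cds)] + cds$start[-1L]) %/% 2L)
        else integer()
        mids <- mids[mids >= margin & mids <= L - margin]
        if (!length(mids)) mids <- as.integer(L %/% 2L)
        n_sites <- min(n_sites, length(mids))
        cand <- mids[sample.int(length(mids), n_sites)]
      }
      n_sites <- length(cand)
      polarity <- sample(c("5p", "3p"), n_sites, replace = TRUE)
      frag_sites[[i]] <- data.frame(locus = ids[i], pos = as.integer(cand),
                                    polarity = polarity,
                                    stringsAsFactors = FALSE)
      w_short <- p$altfrag_short_isoform_share / n_sites
      iso$weight <- 1 - p$altfrag_short_isoform_share
      for (s in seq_len(n_sites)) {
        rng <- if (polarity[s] == "3p") c(0L, cand[s]) else c(cand[s], L)
        iso <- rbind(iso, data.frame(
          locus = ids[i], isoform = sprintf("iso%d", s),
          start = rng[1L], end = rng[2L], weight = w_short,
          stringsAsFactors = FALSE))
      }
    }
    isoforms[[i]] <- iso
  }

  names(contigs) <- ids
  empty_sites <- data.frame(locus = character(), pos = integer(),
                            polarity = character(), stringsAsFactors = FALSE)
  empty_snps <- data.frame(locus = character(), pos = integer(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
  structure(list(
    params = p,
    contigs = contigs,
    loci = data.frame(locus = ids, length = lens, het = is_het,
                      altfrag = is_frag, copy_number = cn,
                      stringsAsFactors = FALSE),
    alleles = do.call(rbind, alleles),
    snps = if (any(is_het)) do.call(rbind, snps[!vapply(snps, is.null,
                                                        logical(1))])
           else empty_snps,
    frag_sites = if (any(is_frag))
        do.call(rbind, frag_sites[!vapply(frag_sites, is.null, logical(1))])
      else empty_sites,
    isoforms = do.call(rbind, isoforms),
    cds = do.call(rbind, cds_all)), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", nrow(x$loci), "loci,", sum(x$loci$het), "heterozygous,",
      sum(x$loci$altfrag), "alternatively fragmented; total",
      sum(x$loci$length), "bp\n")
  invisible(x)
}

## molecule table: one row per (locus, allele, isoform) with retained
## contig interval [c0, c1), molecule length and sampling weight
molecule_table <- function(genome) {
  al <- genome$alleles[, c("locus", "allele", "weight")]
  names(al)[3] <- "allele_weight"
  m <- merge(genome$isoforms, al, by = "locus")
  m <- merge(m, genome$loci[, c("locus", "length", "copy_number")],
             by = "locus")
  telo <- genome$params$telomere_len_bp
  # appended telomere at fragmented ends keeps molecules telomere-capped
  m$mol_len <- ifelse(m$start > 0L | m$end < m$length,
                      (m$end - m$start) + telo, m$length)
  # non-telomeric (mappable) region of the molecule, molecule coords:
  # left telo is native when start==0, appended (len `telo`) when start>0
  m$mr0 <- telo
  m$mr1 <- m$mol_len - telo
  # contig coordinate of molecule position mr0
  m$c0 <- ifelse(m$start > 0L, m$start, telo)
  m$c1 <- m$c0 + (m$mr1 - m$mr0)
  m$sample_weight <- m$copy_number * m$allele_weight * m$weight
  m[order(m$locus, m$allele, m$isoform), ]
}

## apply uniform substitution errors to molecule-forward read strings
apply_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  k <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(nchar(reads[i]), k[i])
    for (q in pos) {
      old <- substr(reads[i], q, q)
      substr(reads[i], q, q) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  reads
}

## clip molecule-interval reads to the mappable region; returns alignment
## fields (contig coords) incl. telomere flags, or NA when aligned part is
## too short
clip_to_contig <- function(f, e, mol, min_aligned = 30L) {
  a0 <- pmax(f, mol$mr0)
  a1 <- pmin(e, mol$mr1)
  ok <- (a1 - a0) >= min_aligned
  ov_left <- pmax(0L, mol$mr0 - f)
  ov_right <- pmax(0L, e - mol$mr1)
  telo_pol <- rep(NA_character_, length(f))
  telo_pol[ov_right >= 12L] <- "3p"
  telo_pol[ov_left >= 12L & ov_left >= ov_right] <- "5p"
  tas <- rep(NA_integer_, length(f))
  tas[!is.na(telo_pol) & telo_pol == "5p"] <- mol$c0
  tas[!is.na(telo_pol) & telo_pol == "3p"] <- mol$c1
  off <- mol$c0 - mol$mr0
  list(ok = ok, start = a0 + off, end = a1 + off,
       clip_left = a0 - f, clip_right = e - a1,
       is_telomeric = !is.na(telo_pol), telo_polarity = telo_pol,
       tas_pos = tas)
}

#' Simulate sequencing reads from a synthetic genome
#'
#' Draws reads per (allele, isoform) molecule proportional to copy number x
#' allele weight x isoform weight at the configured depths:
#' \describe{
#'   \item{pe}{paired-end reads, Normal outer distance, with probabilistic
#'     depletion of fragments terminating in the subtelomeric gap window
#'     (160 bp starting 100 bp inside either telomere).}
#'   \item{se}{single-end reads, no gap depletion.}
#'   \item{tp}{telomere-paired pairs: the two reads start inside the two
#'     telomeres of one molecule (telomere-capture library).}
#'   \item{telo_se}{telomere-anchored single reads at a controllable
#'     per-end depth (the telomeric-read subset; off by default).}
#' }
#' Ground-truth alignment records are always produced; clipping removes the
#' telomeric part of a read (alignments keep the contig-forward aligned
#' sequence), reads with < 30 aligned bp get no alignment record.
#'
#' @param genome a [simulate_genome()] result.
#' @param params optional [sim_params()] overriding `genome$params`
#'   (e.g. a different coverage).
#' @param libraries subset of `c("pe","se","tp","telo_se")`.
#' @param sequences if `FALSE`, only truth alignments are generated (no
#'   read strings, no sequencing errors) — much faster for depth-only
#'   analyses.
#' @return list of class `sim_reads`: `pe1`,`pe2`,`se`,`tp1`,`tp2` (each a
#'   list with `seq`,`qual`, present when requested and `sequences=TRUE`),
#'   and `alignments`, a `data.frame` with `read_id`,`contig`,`start`,`end`
#'   (0-based half-open), `strand`, `library`, `is_telomeric`,
#'   `telo_polarity`, `tas_pos`, `mate_id`, `allele`, `isoform` and (when
#'   `sequences=TRUE`) the aligned contig-forward `seq`.
#' @export
simulate_reads <- function(genome, params = genome$params,
                           libraries = c("pe", "se", "tp"),
                           sequences = TRUE) {
  stopifnot(inherits(genome, "sim_genome"))
  p <- params
  if (p$coverage_x <= 0) stop("coverage_x must be positive")
  rl <- p$read_len_bp
  mol_tab <- molecule_table(genome)
  mol_tab$seq <- NULL
  aln <- list()
  fq <- list(pe1 = list(), pe2 = list(), se = list(),
             tp1 = list(), tp2 = list(), telo_se = list())

  mol_seq_cache <- function(mol) {
    # molecule sequence from allele sequence + appended telomeres
    aseq <- genome$alleles$seq[genome$alleles$locus == mol$locus &
                               genome$alleles$allele == mol$allele]
    L <- nchar(aseq)
    if (mol$start == 0L && mol$end == L) return(aseq)
    core <- substr(aseq, mol$start + 1L, mol$end)
    if (mol$start > 0L) core <- paste0(TELOMERE_SEQ_5P, core)
    if (mol$end < L) core <- paste0(core, TELOMERE_SEQ_3P)
    core
  }

  for (mi in seq_len(nrow(mol_tab))) {
    mol <- mol_tab[mi, ]
    set.seed(derive_seed(p$seed + 131071L, mi))
    M <- mol$mol_len
    w <- mol$sample_weight
    mseq <- if (sequences) mol_seq_cache(mol) else NULL
    tag <- sprintf("%s_%s_%s", mol$locus, mol$allele, mol$isoform)

    grab <- function(f, e) substring(mseq, f + 1L, e) # 0-based half-open

    emit <- function(lib, f, e, strand, role, serial, mate_serial = NULL) {
      # returns fastq-oriented seqs + alignment rows
      n <- length(f)
      if (!n) return(NULL)
      ids <- sprintf("%s_%s_%05d", tag, lib, serial)
      raw <- NULL
      if (sequences) {
        raw <- grab(f, e) # molecule-forward, errors applied here
        raw <- apply_errors(raw, p$base_error_rate)
      }
      cl <- clip_to_contig(f, e, mol)
      ok <- cl$ok
      arows <- list(
        read_id = paste0(ids, "/", role)[ok],
        contig = rep(mol$locus, sum(ok)),
        start = cl$start[ok], end = cl$end[ok],
        strand = rep_len(strand, n)[ok], library = rep(lib, sum(ok)),
        is_telomeric = cl$is_telomeric[ok],
        telo_polarity = cl$telo_polarity[ok],
        tas_pos = cl$tas_pos[ok],
        mate_id = if (is.null(mate_serial)) rep(NA_character_, sum(ok)) else
          sprintf("%s_%s_%05d/%s", tag, lib, mate_serial$serial,
                  mate_serial$role)[ok],
        allele = rep(mol$allele, sum(ok)),
        isoform = rep(mol$isoform, sum(ok)))
      if (sequences) {
        arows$seq <- substring(raw, cl$clip_left + 1L,
                               nchar(raw) - cl$clip_right)[ok]
      }
      out_seq <- NULL
      if (sequences) {
        neg <- rep_len(strand == "-", n)
        out_seq <- raw
        if (any(neg)) out_seq[neg] <- revcomp(raw[neg])
        names(out_seq) <- paste0(ids, "/", role)
      }
      list(aln = arows, seq = out_seq)
    }

    ## paired-end library
    if ("pe" %in% libraries) {
      n_frag <- rpois(1L, w * p$coverage_x * M / (2 * rl))
      if (n_frag > 0L) {
        F <- pmin(M, pmax(rl, as.integer(round(
          rnorm(n_frag, p$pe_outer_mean_bp, p$pe_outer_sd_bp)))))
        f <- as.integer(floor(runif(n_frag) * (M - F + 1L)))
        e <- f + F
        # subtelomeric gap: drop fragments terminating in the depleted
        # window [100, 260) from either molecule end
        in_gap <- function(x) (x >= 100L & x < 260L) |
          (x >= M - 260L & x < M - 100L)
        drop <- (in_gap(f) | in_gap(e)) &
          (runif(n_frag) < p$gap_depletion_prob)
        f <- f[!drop]; e <- e[!drop]
        if (length(f)) {
          serial <- seq_along(f)
          r1 <- emit("pe", f, pmin(f + rl, e), "+", "1", serial,
                     list(serial = serial, role = "2"))
          r2 <- emit("pe", pmax(e - rl, f), e, "-", "2", serial,
                     list(serial = serial, role = "1"))
          aln[[length(aln) + 1L]] <- r1$aln
          aln[[length(aln) + 1L]] <- r2$aln
          if (sequences) {
            fq$pe1[[length(fq$pe1) + 1L]] <- r1$seq
            fq$pe2[[length(fq$pe2) + 1L]] <- r2$seq
          }
        }
      }
    }

    ## single-end library (no gap)
    if ("se" %in% libraries && p$se_coverage_x > 0) {
      n_se <- rpois(1L, w * p$se_coverage_x * M / rl)
      if (n_se > 0L) {
        f <- as.integer(floor(runif(n_se) * (M - rl + 1L)))
        strand <- sample(c("+", "-"), n_se, replace = TRUE)
        r <- emit("se", f, f + rl, strand, "0", seq_len(n_se))
        aln[[length(aln) + 1L]] <- r$aln
        if (sequences) fq$se[[length(fq$se) + 1L]] <- r$seq
      }
    }

    ## telomere-paired library: read 1 starts in the 5' telomere, read 2
    ## in the 3' telomere of the same molecule
    if ("tp" %in% libraries && p$telo_pair_depth > 0) {
      n_tp <- rpois(1L, w * p$telo_pair_depth)
      if (n_tp > 0L) {
        u1 <- sample.int(9L, n_tp, replace = TRUE) - 1L
        u2 <- sample.int(9L, n_tp, replace = TRUE) - 1L
        serial <- seq_len(n_tp)
        f1 <- u1
        f2 <- pmax(0L, M - u2 - rl)
        r1 <- emit("tp", f1, pmin(f1 + rl, M), "+", "1", serial,
                   list(serial = serial, role = "2"))
        r2 <- emit("tp", f2, M - u2, "-", "2", serial,
                   list(serial = serial, role = "1"))
        aln[[length(aln) + 1L]] <- r1$aln
        aln[[length(aln) + 1L]] <- r2$aln
        if (sequences) {
          fq$tp1[[length(fq$tp1) + 1L]] <- r1$seq
          fq$tp2[[length(fq$tp2) + 1L]] <- r2$seq
        }
      }
    }

    ## telomere-anchored single reads at controllable per-end depth
    if ("telo_se" %in% libraries && p$telo_se_depth > 0) {
      n5 <- rpois(1L, w * p$telo_se_depth)
      n3 <- rpois(1L, w * p$telo_se_depth)
      if (n5 + n3 > 0L) {
        u5 <- sample.int(9L, n5, replace = TRUE) - 1L
        u3 <- sample.int(9L, n3, replace = TRUE) - 1L
        f <- c(u5, pmax(0L, M - u3 - rl))
        e <- c(pmin(u5 + rl, M), M - u3)
        strand <- c(rep("+", n5), rep("-", n3))
        r <- emit("telo_se", f, e, strand, "0", seq_len(n5 + n3))
        aln[[length(aln) + 1L]] <- r$aln
        if (sequences) fq$telo_se[[length(fq$telo_se) + 1L]] <- r$seq
      }
    }
  }

  alignments <- if (length(aln)) {
    as.data.frame(data.table::rbindlist(aln))
  } else {
    data.frame(read_id = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               library = character(), is_telomeric = logical(),
               telo_polarity = character(), tas_pos = integer(),
               mate_id = character(), allele = character(),
               isoform = character(), stringsAsFactors = FALSE)
  }

  quals_for <- function(seqs) {
    if (!length(seqs)) return(character())
    q <- strrep("?", nchar(seqs)) # Q30
    if (p$noisy_quals) {
      noisy <- seq_along(seqs) %% 2L == 0L
      tail_len <- pmin(nchar(seqs[noisy]), 30L)
      q[noisy] <- paste0(strrep("?", nchar(seqs[noisy]) - tail_len),
                         strrep("+", tail_len)) # Q10 tail
    }
    names(q) <- names(seqs)
    q
  }
  pack <- function(lst) {
    s <- unlist(lst)
    if (is.null(s)) s <- character()
    list(seq = s, qual = quals_for(s))
  }

  out <- list(alignments = alignments, params = p)
  if (sequences) {
    if ("pe" %in% libraries) { out$pe1 <- pack(fq$pe1); out$pe2 <- pack(fq$pe2) }
    if ("se" %in% libraries) out$se <- pack(fq$se)
    if ("tp" %in% libraries) { out$tp1 <- pack(fq$tp1); out$tp2 <- pack(fq$tp2) }
    if ("telo_se" %in% libraries) out$telo_se <- pack(fq$telo_se)
  }
  structure(out, class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$alignments), "truth alignment records (",
      paste(unique(x$alignments$library), collapse = ", "), ")\n")
  invisible(x)
}

#' Write simulator outputs to disk
#'
#' Writes the reference contigs (FASTA), per-allele truth sequences
#' (FASTA), truth tables (TSV), telomere spans and fragmentation sites
#' (BED, 0-based half-open) and a GFF3 of simulated CDS features.
#'
#' @param genome a `sim_genome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_sim_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome$contigs, file.path(dir, "contigs.fasta"))
  al <- setNames(genome$alleles$seq,
                 paste0(genome$alleles$locus, "_", genome$alleles$allele))
  write_fasta(al, file.path(dir, "alleles.fasta"))
  write_tsv(genome$loci, file.path(dir, "loci.tsv"))
  write_tsv(genome$alleles[, c("locus", "allele", "weight")],
            file.path(dir, "allele_weights.tsv"))
  write_tsv(genome$snps, file.path(dir, "snps.tsv"))
  write_tsv(genome$frag_sites, file.path(dir, "frag_sites.tsv"))
  write_tsv(genome$isoforms, file.path(dir, "isoforms.tsv"))
  if (nrow(genome$frag_sites)) {
    write_bed(data.frame(genome$frag_sites$locus, genome$frag_sites$pos,
                         genome$frag_sites$pos + 1L,
                         genome$frag_sites$polarity),
              file.path(dir, "frag_sites.bed"))
  }
  telo <- genome$params$telomere_len_bp
  lens <- genome$loci$length
  write_bed(data.frame(
    chrom = rep(genome$loci$locus, 2L),
    start = c(rep(0L, nrow(genome$loci)), lens - telo),
    end = c(rep(telo, nrow(genome$loci)), lens),
    name = rep(c("telomere_5p", "telomere_3p"), each = nrow(genome$loci))),
    file.path(dir, "telomeres.bed"))
  gff <- sprintf("%s\tnanochromkit\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s_%d",
                 genome$cds$locus, genome$cds$start + 1L, genome$cds$end,
                 genome$cds$strand, genome$cds$locus,
                 stats::ave(seq_len(nrow(genome$cds)), genome$cds$locus,
                            FUN = seq_along))
  writeLines(c("##gff-version 3", gff), file.path(dir, "annotations.gff3"))
  invisible(dir)
}

#' @rdname write_sim_genome
#' @param reads a `sim_reads` object (with sequences).
#' @export
write_sim_reads <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, stem) {
    if (!is.null(x) && length(x$seq))
      write_fastq(x$seq, x$qual, file.path(dir, paste0(stem, ".fastq")))
  }
  wr(reads$pe1, "pe_1"); wr(reads$pe2, "pe_2")
  wr(reads$se, "se")
  wr(reads$tp1, "telopair_1"); wr(reads$tp2, "telopair_2")
  wr(reads$telo_se, "telo_se")
  write_tsv(reads$alignments[, setdiff(names(reads$alignments), "seq")],
            file.path(dir, "truth_alignments.tsv"))
  invisible(dir)
}
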