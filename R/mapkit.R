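## Minimal seeded read mapper and contig-contig matcher.
##
## Seed-and-verify: exact k-mer seeds (default k = 21) against an index of
## every contig position, ungapped verification of candidate placements,
## identity = matches / alignment columns. Adequate for the no-indel,
## <= 6% divergence regime the synthetic data emulates; `N` bases (masked
## telomeres) never match. Designed for modest (desk-scale) genomes: the
## index holds every contig k-mer in memory.

build_kmer_index <- function(contigs, k) {
  idx <- lapply(names(contigs), function(id) {
    s <- contigs[[id]]
    L <- nchar(s)
    if (L < k) return(NULL)
    data.table::data.table(
      kmer = substring(s, 1:(L - k + 1L), k:L),
      contig = id, tpos = 0:(L - k))
  })
  dt <- data.table::rbindlist(idx)
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  data.table::setkey(dt, kmer)
  dt
}

## seed table for a set of reads: k-mers at stepped offsets, one strand
seed_table <- function(seqs, ids, k, step) {
  rl <- nchar(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    if (rl[i] < k) return(NULL)
    off <- unique(c(seq(0L, rl[i] - k, by = step), rl[i] - k))
    data.table::data.table(read = ids[i],
                           kmer = substring(seqs[i], off + 1L, off + k),
                           off = off, rlen = rl[i])
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt)) dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  dt
}

#' Map reads to contigs (seed-and-verify)
#'
#' Places each read at its best-scoring ungapped location on either strand.
#' Placements below `min_identity` are dropped; among equal-best placements
#' the lexicographically smallest `(contig, position, strand)` is kept
#' deterministically and the read is flagged `multimap`. `n_contigs_hit`
#' counts the distinct contigs carrying a qualifying placement of the read
#' (used by the cross-mapping filter).
#'
#' @param reads named character vector of read sequences (may contain `N`
#'   from telomere masking).
#' @param contigs named character vector of reference contigs.
#' @param min_identity identity floor (default 0.94).
#' @param k seed length (default 21).
#' @param seed_step offset step between seeds within a read (default 20).
#' @param max_candidates verified candidate placements per read/strand.
#' @return alignment `data.frame`: `read_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `identity`, `multimap`,
#'   `n_contigs_hit`, `seq` (contig-forward read sequence).
#' @export
map_reads <- function(reads, contigs, min_identity = 0.94, k = 21L,
                      seed_step = 20L, max_candidates = 3L) {
  if (!length(contigs)) stop("empty contig index")
  empty <- data.frame(read_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      multimap = logical(), n_contigs_hit = integer(),
                      seq = character(), stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d",
                                                     seq_along(reads))
  idx <- build_kmer_index(contigs, k)
  clen <- setNames(nchar(contigs), names(contigs))

  cand_all <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") reads else setNames(revcomp(reads),
                                                   names(reads))
    st <- seed_table(seqs, names(reads), k, seed_step)
    if (!nrow(st)) next
    hits <- idx[st, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hits)) next
    hits[, start := tpos - off]
    votes <- hits[, .(votes = .N, rlen = rlen[1L]),
                  by = .(read, contig, start)]
    votes[, strand := strand]
    cand_all[[strand]] <- votes
  }
  cand <- data.table::rbindlist(cand_all)
  if (!nrow(cand)) return(empty)
  # keep in-bounds candidates, best-voted few per read/strand
  cand <- cand[start >= 0L & start + rlen <= clen[contig]]
  if (!nrow(cand)) return(empty)
  data.table::setorder(cand, read, -votes, contig, start)
  cand <- cand[, head(.SD, max_candidates), by = .(read, strand)]

  # ungapped verification
  q <- ifelse(cand$strand == "+", reads[cand$read],
              revcomp(reads[cand$read]))
  r <- substring(contigs[cand$contig], cand$start + 1L,
                 cand$start + cand$rlen)
  cand[, identity := ungapped_identity(q, r)]
  cand <- cand[identity >= min_identity]
  if (!nrow(cand)) return(empty)
  cand <- unique(cand, by = c("read", "contig", "start", "strand"))

  nhit <- cand[, .(n_contigs_hit = data.table::uniqueN(contig)), by = read]
  data.table::setorder(cand, read, -identity, contig, start, strand)
  best <- cand[, {
    top <- identity[1L]
    .(contig = contig[1L], start = start[1L], rlen = rlen[1L],
      strand = strand[1L], identity = top,
      multimap = sum(identity == top) > 1L)
  }, by = read]
  best <- nhit[best, on = "read"]
  fwd <- ifelse(best$strand == "+", reads[best$read],
                revcomp(reads[best$read]))
  data.frame(read_id = best$read, contig = best$contig,
             start = best$start, end = best$start + best$rlen,
             strand = best$strand, identity = best$identity,
             multimap = best$multimap, n_contigs_hit = best$n_contigs_hit,
             seq = unname(fwd), stringsAsFactors = FALSE)
}

#' Non-self local matches between contigs
#'
#' Finds qualifying local similarity matches between distinct contigs on
#' both strands (k-mer seeded, single-diagonal ungapped chaining). Used to
#' split contigs into "matched" (a separately assembled allele exists) and
#' "matchless" classes.
#'
#' @param contigs named character vector (at least 2 contigs).
#' @param min_len minimum match length in bp (default 100).
#' @param min_identity minimum identity (default 0.90).
#' @param k seed length.
#' @return `data.frame`: `query`, `target`, `strand`, `length`, `identity`
#'   (query/target unordered pairs reported once per orientation with
#'   `query < target`).
#' @export
nonself_matches <- function(contigs, min_len = 100L, min_identity = 0.90,
                            k = 21L) {
  stopifnot(length(contigs) >= 2L)
  idx <- build_kmer_index(contigs, k)
  out <- list()
  for (strand in c("+", "-")) {
    rows <- lapply(names(contigs), function(qid) {
      qs <- if (strand == "+") contigs[[qid]] else revcomp(contigs[[qid]])
      L <- nchar(qs)
      if (L < k) return(NULL)
      st <- data.table::data.table(
        kmer = substring(qs, 1:(L - k + 1L), k:L), qpos = 0:(L - k))
      st <- st[!grepl("N", kmer, fixed = TRUE)]
      hits <- idx[st, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      hits <- hits[contig != qid]
      if (!nrow(hits)) return(NULL)
      hits[, diag := qpos - tpos]
      seg <- hits[, .(q0 = min(qpos), q1 = max(qpos) + k, n = .N),
                  by = .(contig, diag)]
      seg <- seg[q1 - q0 >= min_len]
      if (!nrow(seg)) return(NULL)
      qsub <- substring(qs, seg$q0 + 1L, seg$q1)
      tsub <- substring(contigs[seg$contig], seg$q0 - seg$diag + 1L,
                        seg$q1 - seg$diag)
      seg[, identity := ungapped_identity(qsub, tsub)]
      seg <- seg[identity >= min_identity]
      if (!nrow(seg)) return(NULL)
      # best segment per target
      data.table::setorder(seg, contig, -identity, diag)
      seg <- seg[, head(.SD, 1L), by = contig]
      data.table::data.table(query = qid, target = seg$contig,
                             strand = strand, length = seg$q1 - seg$q0,
                             identity = seg$identity)
    })
    out[[strand]] <- data.table::rbindlist(rows)
  }
  dt <- data.table::rbindlist(out)
  if (!nrow(dt)) {
    return(data.frame(query = character(), target = character(),
                      strand = character(), length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  # canonical unordered pair per orientation, keep the longer record
  dt[, `:=`(a = pmin(query, target), b = pmax(query, target))]
  data.table::setorder(dt, a, b, strand, -length)
  dt <- dt[, head(.SD, 1L), by = .(a, b, strand)]
  data.frame(query = dt$a, target = dt$b, strand = dt$strand,
             length = dt$length, identity = dt$identity,
             stringsAsFactors = FALSE)
}

#' Count cross-mapped reads for a contig
#'
#' Number of reads placed on `contig` whose qualifying placements include
#' any other contig (paralogy filter: analyses restrict to contigs with at
#' most 4 such reads).
#'
#' @param contig contig id.
#' @param alignments alignments from [map_reads()].
#' @return integer count.
#' @export
count_cross_mapped <- function(contig, alignments) {
  sum(alignments$contig == contig & alignments$n_contigs_hit > 1L)
}

#' Prepare telomeric reads for TAS mapping
#'
#' Masks telomeric repeats, keeps reads with a telomere at exactly one end,
#' strips the masking `N` and records which read end carried it. The
#' stripped sequences are mapped with [map_reads()]; combine results with
#' [telomeric_alignments()] to obtain polarity and TAS coordinates.
#'
#' @param seqs named character vector of raw read sequences.
#' @param min_len minimum remaining length after stripping (default 30).
#' @inheritParams find_telomeres
#' @return `data.frame`: `read_id`, `seq` (stripped), `telo_at`
#'   (`"start"`/`"end"` in read orientation).
#' @export
prepare_telomeric_reads <- function(seqs, min_len = 30L,
                                    max_degenerate = 2L) {
  masked <- mask_telomeres(seqs, max_degenerate)
  starts_n <- startsWith(masked, "N")
  ends_n <- endsWith(masked, "N")
  keep <- xor(starts_n, ends_n)
  stripped <- sub("^N", "", sub("N$", "", masked[keep]))
  ok <- nchar(stripped) >= min_len & !grepl("N", stripped, fixed = TRUE)
  data.frame(read_id = names(seqs)[keep][ok], seq = unname(stripped[ok]),
             telo_at = ifelse(starts_n[keep], "start", "end")[ok],
             stringsAsFactors = FALSE)
}

#' Attach TAS polarity to mapped telomeric reads
#'
#' A read whose masked telomere sits at the left of its contig-forward
#' alignment supports a 5' telomere addition site at the alignment start
#' (sequence retained to the right); a telomere at the right supports a 3'
#' site at the alignment end.
#'
#' @param alignments result of [map_reads()] on stripped telomeric reads.
#' @param prepared result of [prepare_telomeric_reads()].
#' @return alignments with `telo_polarity` (`"5p"`/`"3p"`), `tas_pos`
#'   (0-based) and `is_telomeric = TRUE`.
#' @export
telomeric_alignments <- function(alignments, prepared) {
  m <- merge(alignments, prepared[, c("read_id", "telo_at")],
             by = "read_id")
  left <- (m$telo_at == "start") == (m$strand == "+")
  m$telo_polarity <- ifelse(left, "5p", "3p")
  m$tas_pos <- ifelse(left, m$start, m$end)
  m$is_telomeric <- TRUE
  m$telo_at <- NULL
  m
}
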