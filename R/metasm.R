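## Telomere-aware contig finishing: quality trimming, anchored end
## extension, greedy overlap merging, and chimera splitting from unspanned
## paired-end intervals.

#' Quality-trim reads
#'
#' Keeps, for each read, the longest contiguous run of bases at or above
#' the Phred threshold; reads whose retained run is shorter than `min_len`
#' are discarded.
#'
#' @param seq named character vector of read sequences.
#' @param qual character vector of Phred+33 quality strings.
#' @param threshold minimum per-base quality (default 20).
#' @param min_len minimum retained length (default 100).
#' @return list with trimmed `seq` and `qual` (named, discarded reads
#'   removed) and `n_discarded`.
#' @export
quality_trim <- function(seq, qual, threshold = 20L, min_len = 100L) {
  stopifnot(length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) stop("malformed FASTQ: length mismatch")
  qints <- phred_to_int(qual)
  out_s <- character(length(seq))
  out_q <- character(length(seq))
  for (i in seq_along(seq)) {
    ok <- qints[[i]] >= threshold
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values)
    j <- good[which.max(r$lengths[good])]
    out_s[i] <- substr(seq[i], starts[j], ends[j])
    out_q[i] <- substr(qual[i], starts[j], ends[j])
  }
  keep <- nchar(out_s) >= min_len
  list(seq = setNames(out_s[keep], names(seq)[keep]),
       qual = setNames(out_q[keep], names(seq)[keep]),
       n_discarded = sum(!keep))
}

## locate a ~100 bp anchor inside one source sequence (either strand) via
## exact k-mer seeds + ungapped verification; returns best hit or NULL
anchor_hits <- function(anchor, source_seq, min_identity, k = 31L) {
  alen <- nchar(anchor)
  offs <- unique(c(seq(0L, alen - k, by = max(1L, (alen - k) %/% 2L)),
                   alen - k))
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") source_seq else revcomp(source_seq)
    L <- nchar(s)
    starts <- integer()
    for (off in offs) {
      kmer <- substr(anchor, off + 1L, off + k)
      m <- gregexpr(kmer, s, fixed = TRUE)[[1]]
      if (m[1L] == -1L) next
      starts <- c(starts, as.integer(m) - 1L - off)
    }
    starts <- unique(starts)
    starts <- starts[starts >= 0L & starts + alen <= L]
    if (!length(starts)) next
    ident <- ungapped_identity(rep(anchor, length(starts)),
                               substring(s, starts + 1L, starts + alen))
    i <- which(ident >= min_identity)
    if (!length(i)) next
    i <- i[order(-ident[i], starts[i])][1L]
    hit <- list(strand = strand, start = starts[i], identity = ident[i],
                oriented_seq = s)
    if (is.null(best) || hit$identity > best$identity) best <- hit
  }
  best
}

#' Find the best end extension for each non-telomeric contig end
#'
#' For each contig end without a terminal telomere, searches the source
#' sets (in priority order) for a 100 bp anchor match at or above
#' `min_identity` and proposes the sequence extending beyond the anchor.
#' Candidates are ranked by source priority, then anchor identity, then
#' extension length, then source id.
#'
#' @param contig a single named contig (named character vector of length 1
#'   or a plain string).
#' @param sources list of named character vectors, highest priority first
#'   (e.g. meta-assembly contigs, auxiliary assembly contigs, raw reads).
#' @param min_identity anchor identity floor (default 0.94).
#' @param anchor_len anchor length (default 100).
#' @param terminal_window bp window used to call an end telomere-bearing.
#' @return list with elements `left` and `right`, each `NULL` or a list
#'   `(source_priority, source_id, anchor_identity, extension, strand)`.
#' @export
find_end_extensions <- function(contig, sources, min_identity = 0.94,
                                anchor_len = 100L, terminal_window = 100L) {
  s <- if (is.null(names(contig))) contig[[1L]] else unname(contig[[1L]])
  L <- nchar(s)
  sp <- find_telomeres(s)
  has5 <- any(sp$polarity == "5p" & sp$start < terminal_window)
  has3 <- any(sp$polarity == "3p" & sp$end > L - terminal_window)
  out <- list(left = NULL, right = NULL)
  if (L < anchor_len) return(out)
  for (side in c("left", "right")) {
    if (side == "left" && has5) next
    if (side == "right" && has3) next
    anchor <- if (side == "left") substr(s, 1L, anchor_len) else
      substr(s, L - anchor_len + 1L, L)
    best <- NULL
    for (pri in seq_along(sources)) {
      src <- sources[[pri]]
      for (sid in names(src)) {
        hit <- anchor_hits(anchor, src[[sid]], min_identity)
        if (is.null(hit)) next
        os <- hit$oriented_seq
        ext <- if (side == "left") substr(os, 1L, hit$start) else
          substr(os, hit$start + anchor_len + 1L, nchar(os))
        if (!nchar(ext)) next
        cand <- list(source_priority = pri, source_id = sid,
                     anchor_identity = hit$identity, extension = ext,
                     strand = hit$strand)
        better <- is.null(best) ||
          cand$source_priority < best$source_priority ||
          (cand$source_priority == best$source_priority &&
           (cand$anchor_identity > best$anchor_identity ||
            (cand$anchor_identity == best$anchor_identity &&
             (nchar(cand$extension) > nchar(best$extension) ||
              (nchar(cand$extension) == nchar(best$extension) &&
               cand$source_id < best$source_id)))))
        if (better) best <- cand
      }
    }
    out[[side]] <- best
  }
  out
}

#' Iteratively extend contig ends
#'
#' Applies [find_end_extensions()] to every contig for `rounds` rounds in
#' deterministic (lexicographic) order. Extension only appends sequence;
#' an end stops being extended as soon as it carries a terminal telomere.
#'
#' @param contigs named character vector.
#' @inheritParams find_end_extensions
#' @param rounds extension rounds (default 2).
#' @return list with `contigs` (extended) and `report` (`data.frame` of
#'   applied extensions).
#' @export
extend_contigs <- function(contigs, sources, rounds = 2L,
                           min_identity = 0.94, anchor_len = 100L) {
  report <- list()
  ids <- sort(names(contigs))
  for (r in seq_len(rounds)) {
    for (id in ids) {
      ext <- find_end_extensions(contigs[id], sources, min_identity,
                                 anchor_len)
      if (!is.null(ext$left)) {
        contigs[[id]] <- paste0(ext$left$extension, contigs[[id]])
        report[[length(report) + 1L]] <- data.frame(
          contig = id, round = r, side = "left",
          source = ext$left$source_id, bp = nchar(ext$left$extension),
          identity = ext$left$anchor_identity, stringsAsFactors = FALSE)
      }
      if (!is.null(ext$right)) {
        contigs[[id]] <- paste0(contigs[[id]], ext$right$extension)
        report[[length(report) + 1L]] <- data.frame(
          contig = id, round = r, side = "right",
          source = ext$right$source_id, bp = nchar(ext$right$extension),
          identity = ext$right$anchor_identity, stringsAsFactors = FALSE)
      }
    }
  }
  list(contigs = contigs,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(contig = character(), round = integer(),
                    side = character(), source = character(),
                    bp = integer(), identity = numeric(),
                    stringsAsFactors = FALSE))
}

## best qualifying suffix(a)-prefix(b) overlap; seeds tolerate one
## mismatched seed by trying several offsets into b's prefix
best_suffix_prefix <- function(a, b, min_overlap, min_identity, k = 16L) {
  la <- nchar(a); lb <- nchar(b)
  if (la < min_overlap || lb < min_overlap) return(NULL)
  best <- NULL
  for (off in c(0L, 8L, 16L, 24L)) {
    if (off + k > lb) break
    kmer <- substr(b, off + 1L, off + k)
    m <- gregexpr(kmer, a, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (pos in as.integer(m)) {
      o <- la - (pos - 1L) + off # implied overlap length
      if (o < min_overlap || o > la || o > lb) next
      ident <- ungapped_identity(substr(a, la - o + 1L, la),
                                 substr(b, 1L, o))
      if (ident < min_identity) next
      score <- o * ident
      if (is.null(best) || score > best$score)
        best <- list(overlap = o, identity = ident, score = score)
    }
  }
  best
}

#' Greedily merge overlapping contigs
#'
#' Repeatedly merges the highest-scoring qualifying suffix-prefix overlap
#' (either strand) until none remains; a stand-in for strict-parameter
#' overlap assembly (40 bp/99% or 100 bp/99% regimes). Consensus over the
#' overlap is by per-column majority with ties resolved toward the longer
#' contig's base.
#'
#' @param contigs named character vector.
#' @param min_overlap_bp minimum overlap length (default 40).
#' @param min_identity minimum overlap identity (default 0.99).
#' @return named character vector of merged contigs (merged ids joined
#'   with `+`).
#' @export
greedy_overlap_merge <- function(contigs, min_overlap_bp = 40L,
                                 min_identity = 0.99) {
  stopifnot(min_overlap_bp >= 1L, min_identity > 0, min_identity <= 1)
  ctg <- contigs[order(names(contigs))]
  repeat {
    ids <- names(ctg)
    if (length(ids) < 2L) break
    best <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i == j) next
        a <- ids[i]; b <- ids[j]
        for (rc_b in c(FALSE, TRUE)) {
          if (rc_b && j < i) next # rc case symmetric; evaluate once
          bseq <- if (rc_b) revcomp(ctg[[b]]) else ctg[[b]]
          ov <- best_suffix_prefix(ctg[[a]], bseq, min_overlap_bp,
                                   min_identity)
          if (is.null(ov)) next
          if (is.null(best) || ov$score > best$score ||
              (ov$score == best$score && paste(a, b) < paste(best$a, best$b)))
            best <- c(ov, list(a = a, b = b, rc_b = rc_b))
        }
      }
    }
    if (is.null(best)) break
    aseq <- ctg[[best$a]]
    bseq <- if (best$rc_b) revcomp(ctg[[best$b]]) else ctg[[best$b]]
    o <- best$overlap
    la <- nchar(aseq)
    ov_a <- substr(aseq, la - o + 1L, la)
    ov_b <- substr(bseq, 1L, o)
    # two-sequence "majority": disagreements fall to the longer contig
    cons <- if (la >= nchar(bseq)) ov_a else ov_b
    merged <- paste0(substr(aseq, 1L, la - o), cons,
                     substr(bseq, o + 1L, nchar(bseq)))
    newid <- paste(best$a, best$b, sep = "+")
    ctg <- ctg[!names(ctg) %in% c(best$a, best$b)]
    ctg[[newid]] <- merged
    ctg <- ctg[order(names(ctg))]
  }
  ctg
}

#' Detect unspanned (potentially chimeric) intervals
#'
#' Computes the union of inter-mate spans (regions between the two reads of
#' a proper pair, excluding the reads themselves) and reports maximal
#' interior intervals not covered by any span. Intervals lying within
#' `end_zone` bp of either contig end are suppressed (the paired-end
#' library's subtelomeric gap would otherwise trigger false splits).
#' Contig ends with no mapped reads at all are reported as
#' `zero-coverage-end`.
#'
#' @param contig_len contig length in bp.
#' @param alignments alignment `data.frame` for this contig with
#'   `read_id`, `mate_id`, `start`, `end` (0-based half-open); both mates
#'   present.
#' @param end_zone bp from either end where no-pair-span intervals are not
#'   reported (default 400).
#' @return `data.frame`: `start`, `end`, `reason`
#'   (`no-pair-span`/`zero-coverage-end`).
#' @export
detect_unspanned <- function(contig_len, alignments, end_zone = 400L) {
  empty <- data.frame(start = integer(), end = integer(),
                      reason = character(), stringsAsFactors = FALSE)
  out <- empty
  a <- alignments
  # zero-coverage ends from read coverage
  if (!nrow(a)) {
    return(data.frame(start = 0L, end = contig_len,
                      reason = "zero-coverage-end",
                      stringsAsFactors = FALSE))
  }
  lo <- min(a$start); hi <- max(a$end)
  if (lo > 0L) out <- rbind(out, data.frame(start = 0L, end = lo,
                                            reason = "zero-coverage-end"))
  if (hi < contig_len) out <- rbind(out, data.frame(
    start = hi, end = contig_len, reason = "zero-coverage-end"))

  # inter-mate spans
  paired <- a[!is.na(a$mate_id) & a$mate_id %in% a$read_id, , drop = FALSE]
  spans <- NULL
  if (nrow(paired)) {
    mate <- paired[match(paired$mate_id, paired$read_id), ]
    s0 <- pmin(paired$end, mate$end)
    s1 <- pmax(paired$start, mate$start)
    keep <- paired$read_id < paired$mate_id & s1 > s0 # one record per pair
    spans <- IRanges::IRanges(start = s0[keep] + 1L, end = s1[keep])
  }
  covered <- if (!is.null(spans) && length(spans))
    IRanges::reduce(spans) else IRanges::IRanges()
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, contig_len), covered)
  if (length(gaps)) {
    g0 <- IRanges::start(gaps) - 1L
    g1 <- IRanges::end(gaps)
    # clip to the interior zone; drop what the end zones absorb
    g0c <- pmax(g0, end_zone)
    g1c <- pmin(g1, contig_len - end_zone)
    keep <- g1c > g0c
    if (any(keep)) out <- rbind(out, data.frame(
      start = g0c[keep], end = g1c[keep], reason = "no-pair-span"))
  }
  rownames(out) <- NULL
  out
}

#' Split a contig at unspanned intervals and trim
#'
#' Cuts at the midpoint of each `no-pair-span` interval (the precise
#' chimerism site being unknown), trims 200 bp back from each newly
#' created end, removes `zero-coverage-end` regions outright, and drops
#' fragments shorter than `floor_bp`.
#'
#' @param contig a single contig sequence (string).
#' @param intervals result of [detect_unspanned()].
#' @param trim_bp trim at each cut (default 200).
#' @param floor_bp minimum surviving fragment length (default 100).
#' @return named character vector of fragments (`<name>.1`, `<name>.2`,
#'   ...) with attribute `coords`, a `data.frame` of fragment intervals on
#'   the original contig.
#' @export
split_and_trim <- function(contig, intervals, trim_bp = 200L,
                           floor_bp = 100L) {
  s <- if (is.null(names(contig))) contig[[1L]] else unname(contig[[1L]])
  nm <- if (is.null(names(contig))) "contig" else names(contig)[1L]
  L <- nchar(s)
  zc <- intervals[intervals$reason == "zero-coverage-end", , drop = FALSE]
  lo <- 0L; hi <- L
  for (i in seq_len(nrow(zc))) {
    if (zc$start[i] == 0L) lo <- max(lo, zc$end[i])
    if (zc$end[i] == L) hi <- min(hi, zc$start[i])
  }
  cuts <- intervals[intervals$reason == "no-pair-span", , drop = FALSE]
  mids <- sort(as.integer((cuts$start + cuts$end) %/% 2L))
  bounds <- c(lo, mids, hi)
  frags <- list()
  coords <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    f0 <- bounds[i]; f1 <- bounds[i + 1L]
    if (i > 1L) f0 <- f0 + trim_bp          # new end from a cut
    if (i < length(bounds) - 1L) f1 <- f1 - trim_bp
    if (f1 - f0 < floor_bp) next
    frags[[length(frags) + 1L]] <- substr(s, f0 + 1L, f1)
    coords[[length(coords) + 1L]] <- data.frame(start = f0, end = f1)
  }
  out <- unlist(frags)
  if (is.null(out)) return(structure(character(),
                                     coords = data.frame(start = integer(),
                                                         end = integer())))
  names(out) <- sprintf("%s.%d", nm, seq_along(out))
  structure(out, coords = do.call(rbind, coords))
}
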