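## Telomere addition site (TAS) calling, alternative fragmentation
## detection, isoform prediction from telomere-paired reads, and
## CDS-context enrichment.

#' Call telomere addition sites from telomeric-read alignments
#'
#' Greedy window calling per contig and polarity: repeatedly take the
#' position with maximal telomeric-read support (ties to the smaller
#' coordinate), assign every same-polarity read within half a window
#' (+/- 100 bp) to it, and exclude positions closer than `window` bp to an
#' accepted site from seeding further sites — so two sites of one polarity
#' are always at least 200 bp apart. Sites with at least `strong_min`
#' supporting reads are `strong`, others `weak`.
#'
#' @param telo_alignments `data.frame` with `contig`, `tas_pos` (0-based)
#'   and `telo_polarity` (`"5p"`/`"3p"`), e.g. from
#'   [telomeric_alignments()] or simulator truth rows with
#'   `is_telomeric = TRUE`.
#' @param contig_lengths named integer vector.
#' @param window exclusive window per site (default 200 bp).
#' @param strong_min strong-support read threshold (default 10).
#' @param terminal_window bp from a contig end within which a TAS is
#'   flagged terminal (default 100).
#' @return `data.frame`: `contig`, `pos`, `polarity`, `n_reads`,
#'   `support` (`strong`/`weak`), `terminal`.
#' @export
call_tas <- function(telo_alignments, contig_lengths, window = 200L,
                     strong_min = 10L, terminal_window = 100L) {
  stopifnot(all(c("contig", "tas_pos", "telo_polarity") %in%
                names(telo_alignments)))
  ta <- telo_alignments[!is.na(telo_alignments$tas_pos), , drop = FALSE]
  half <- window %/% 2L
  out <- list()
  for (id in unique(ta$contig)) {
    L <- contig_lengths[[id]]
    for (pol in c("5p", "3p")) {
      pos <- ta$tas_pos[ta$contig == id & ta$telo_polarity == pol]
      if (!length(pos)) next
      blocked <- integer()
      repeat {
        live <- pos[!pos %in% NA]
        if (!length(live)) break
        tab <- sort(table(live))
        cand <- as.integer(names(tab))
        cand <- cand[order(-as.integer(tab[as.character(cand)]), cand)]
        cand <- cand[!vapply(cand, function(p)
          any(abs(p - blocked) < window), logical(1))]
        if (!length(cand)) break
        center <- cand[1L]
        assign_idx <- abs(pos - center) <= half
        n <- sum(assign_idx)
        out[[length(out) + 1L]] <- data.frame(
          contig = id, pos = center, polarity = pol, n_reads = n,
          stringsAsFactors = FALSE)
        blocked <- c(blocked, center)
        pos <- pos[!assign_idx]
        if (!length(pos)) break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), pos = integer(),
                      polarity = character(), n_reads = integer(),
                      support = character(), terminal = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df$support <- ifelse(df$n_reads >= strong_min, "strong", "weak")
  L <- contig_lengths[df$contig]
  df$terminal <- df$pos <= terminal_window | df$pos >= L - terminal_window
  df <- df[order(df$contig, df$pos, df$polarity), ]
  rownames(df) <- NULL
  df
}

#' Detect alternatively fragmented nanochromosomes
#'
#' A 2-telomere contig is alternatively fragmented when it carries at
#' least one internal TAS more than `end_margin` bp from either end
#' (strong-support sites only, unless `strong_only = FALSE`). The margin
#' is 100 bp for detection-style analyses and 250 bp for length-profile
#' analyses.
#'
#' @param tas result of [call_tas()].
#' @param classes result of [classify_contigs()] (only class `"two"`
#'   contigs are assessed; others are reported unfragmented with
#'   `assessed = FALSE`).
#' @param end_margin internal-site margin in bp (default 100).
#' @param strong_only count only strong sites (default `TRUE`).
#' @return `data.frame`: `contig`, `assessed`, `n_internal_sites`,
#'   `fragmented`, `directionality` (`none`/`single-site`/`multi-site`).
#' @export
detect_altfrag <- function(tas, classes, end_margin = 100L,
                           strong_only = TRUE) {
  lens <- setNames(classes$length, classes$contig)
  res <- lapply(classes$contig, function(id) {
    assessed <- classes$class[classes$contig == id] == "two"
    t <- tas[tas$contig == id, , drop = FALSE]
    if (strong_only) t <- t[t$support == "strong", , drop = FALSE]
    internal <- t$pos > end_margin & t$pos < lens[[id]] - end_margin
    n <- if (assessed) sum(internal) else 0L
    data.frame(contig = id, assessed = assessed, n_internal_sites = n,
               fragmented = n >= 1L,
               directionality = if (n == 0L) "none" else
                 if (n == 1L) "single-site" else "multi-site",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## merge called TAS of one polarity lying within merge_bp of each other,
## keeping the better-supported position
merge_close_tas <- function(tas, merge_bp = 50L) {
  res <- list()
  for (key in unique(paste(tas$contig, tas$polarity))) {
    t <- tas[paste(tas$contig, tas$polarity) == key, , drop = FALSE]
    t <- t[order(t$pos), , drop = FALSE]
    i <- 1L
    while (i <= nrow(t)) {
      j <- i
      while (j < nrow(t) && t$pos[j + 1L] - t$pos[j] <= merge_bp) j <- j + 1L
      grp <- t[i:j, , drop = FALSE]
      keep <- grp[which.max(grp$n_reads), , drop = FALSE]
      keep$n_reads <- sum(grp$n_reads)
      keep$support <- ifelse(keep$n_reads >= 10L, "strong", keep$support)
      res[[length(res) + 1L]] <- keep
      i <- j + 1L
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Predict nanochromosome isoforms from telomere-paired read pairs
#'
#' Each read pair whose two telomeric reads land within `link_bp` of a
#' called 5' TAS and a called 3' TAS links those sites into an isoform;
#' isoforms are reported with their supporting pair counts. TAS of one
#' polarity within `merge_bp` of each other are first merged and treated
#' as a single point. Pairs are assigned to the nearest qualifying site
#' pair; sites with no linking pair yield no isoform.
#'
#' @param contig contig id.
#' @param tas result of [call_tas()] for this contig.
#' @param pair_alignments telomere-paired alignments: `data.frame` with
#'   `read_id`, `mate_id`, `contig`, `tas_pos`, `telo_polarity`.
#' @param link_bp maximum distance between a read's TAS coordinate and a
#'   called site (default 100).
#' @param merge_bp near-site merge radius (default 50).
#' @return `data.frame`: `contig`, `left_tas`, `right_tas`, `n_pairs`,
#'   ordered by `left_tas`, `right_tas`.
#' @export
predict_isoforms <- function(contig, tas, pair_alignments, link_bp = 100L,
                             merge_bp = 50L) {
  empty <- data.frame(contig = character(), left_tas = integer(),
                      right_tas = integer(), n_pairs = integer(),
                      stringsAsFactors = FALSE)
  t <- tas[tas$contig == contig, , drop = FALSE]
  if (nrow(t) > 1L) t <- merge_close_tas(t, merge_bp)
  p5 <- sort(t$pos[t$polarity == "5p"])
  p3 <- sort(t$pos[t$polarity == "3p"])
  if (!length(p5) || !length(p3)) return(empty)
  a <- pair_alignments[pair_alignments$contig == contig &
                       !is.na(pair_alignments$tas_pos), , drop = FALSE]
  if (!nrow(a)) return(empty)
  a5 <- a[a$telo_polarity == "5p", c("read_id", "mate_id", "tas_pos")]
  a3 <- a[a$telo_polarity == "3p", c("read_id", "mate_id", "tas_pos")]
  pairs <- merge(a5, a3, by.x = "mate_id", by.y = "read_id",
                 suffixes = c("_5", "_3"))
  if (!nrow(pairs)) return(empty)
  nearest <- function(x, sites) {
    i <- vapply(x, function(v) which.min(abs(sites - v)), integer(1))
    ifelse(abs(sites[i] - x) <= link_bp, sites[i], NA_integer_)
  }
  left <- nearest(pairs$tas_pos_5, p5)
  right <- nearest(pairs$tas_pos_3, p3)
  ok <- !is.na(left) & !is.na(right) & left < right
  if (!any(ok)) return(empty)
  tab <- table(paste(left[ok], right[ok]))
  parts <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(contig = contig,
                    left_tas = as.integer(parts[, 1L]),
                    right_tas = as.integer(parts[, 2L]),
                    n_pairs = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$left_tas, out$right_tas), ]
  rownames(out) <- NULL
  out
}

#' CDS context of fragmentation sites and enrichment ratio
#'
#' Labels each site inter-CDS (between two CDS intervals, two-gene mode)
#' or non-CDS (anywhere outside a CDS, single-gene mode) versus intra-CDS,
#' and reports per-bp density enrichment
#' `(sites_inter/bp_inter) / (sites_intra/bp_intra)`. When no intra-CDS
#' site exists the ratio is infinite and flagged.
#'
#' @param sites `data.frame` with `contig`, `pos` (and optionally
#'   `n_reads`).
#' @param cds CDS intervals: `data.frame` with `locus` (or `contig`),
#'   `start`, `end` (0-based half-open).
#' @param contig_lengths named integer vector for the contigs analysed.
#' @param mode `"two_gene"` (inter-CDS spacers only as the non-coding
#'   context) or `"single_gene"` (all non-CDS bp).
#' @return list: `sites` (labelled), `bp_inter`, `bp_intra`,
#'   `enrichment`, `infinite` flag, `mean_reads` per context (when
#'   `n_reads` present).
#' @export
cds_context <- function(sites, cds, contig_lengths,
                        mode = c("two_gene", "single_gene")) {
  mode <- match.arg(mode)
  if ("locus" %in% names(cds) && !"contig" %in% names(cds))
    names(cds)[names(cds) == "locus"] <- "contig"
  ids <- names(contig_lengths)
  bp_intra <- 0L; bp_inter <- 0L
  inter_iv <- list()
  for (id in ids) {
    cc <- cds[cds$contig == id, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    bp_intra <- bp_intra + sum(cc$end - cc$start)
    if (mode == "two_gene") {
      if (nrow(cc) >= 2L) {
        iv <- data.frame(contig = id, start = cc$end[-nrow(cc)],
                         end = cc$start[-1L])
        iv <- iv[iv$end > iv$start, , drop = FALSE]
        inter_iv[[id]] <- iv
        bp_inter <- bp_inter + sum(iv$end - iv$start)
      }
    } else {
      bp_inter <- bp_inter + (contig_lengths[[id]] - sum(cc$end - cc$start))
    }
  }
  in_cds <- vapply(seq_len(nrow(sites)), function(i) {
    cc <- cds[cds$contig == sites$contig[i], , drop = FALSE]
    any(sites$pos[i] >= cc$start & sites$pos[i] < cc$end)
  }, logical(1))
  sites$context <- ifelse(in_cds, "intra",
                          if (mode == "two_gene") "inter" else "non-CDS")
  if (mode == "two_gene") {
    # sites outside both CDS and internal spacers (e.g. subtelomeric)
    in_spacer <- vapply(seq_len(nrow(sites)), function(i) {
      iv <- inter_iv[[sites$contig[i]]]
      !is.null(iv) && any(sites$pos[i] >= iv$start & sites$pos[i] < iv$end)
    }, logical(1))
    sites$context[!in_cds & !in_spacer] <- "other"
  }
  n_inter <- sum(sites$context %in% c("inter", "non-CDS"))
  n_intra <- sum(sites$context == "intra")
  if (bp_inter == 0L || bp_intra == 0L) {
    return(list(sites = sites, bp_inter = bp_inter, bp_intra = bp_intra,
                enrichment = NA_real_, infinite = FALSE,
                mean_reads = NULL))
  }
  dens_inter <- n_inter / bp_inter
  dens_intra <- n_intra / bp_intra
  inf <- dens_intra == 0 && dens_inter > 0
  enr <- if (inf) Inf else if (dens_intra == 0) NA_real_ else
    dens_inter / dens_intra
  mr <- NULL
  if ("n_reads" %in% names(sites)) {
    mr <- tapply(sites$n_reads, sites$context, mean)
  }
  list(sites = sites, bp_inter = bp_inter, bp_intra = bp_intra,
       enrichment = enr, infinite = inf, mean_reads = mr)
}

#' Fragmentation directionality summary
#'
#' Distribution of alternatively fragmented contigs by number of internal
#' sites; the single-site ("directional") share is the headline figure.
#'
#' @param status result of [detect_altfrag()] (or any `data.frame` with
#'   `fragmented` and `n_internal_sites`).
#' @return list: `n_fragmented`, `by_site_count` (`data.frame`), and
#'   `single_site_pct` (nearest integer percent).
#' @export
directionality_summary <- function(status) {
  fr <- status[status$fragmented, , drop = FALSE]
  if (!nrow(fr)) {
    return(list(n_fragmented = 0L,
                by_site_count = data.frame(n_sites = integer(),
                                           n_contigs = integer(),
                                           fraction = numeric()),
                single_site_pct = NA_real_))
  }
  tab <- table(fr$n_internal_sites)
  by_cnt <- data.frame(n_sites = as.integer(names(tab)),
                       n_contigs = as.integer(tab),
                       fraction = as.numeric(tab) / nrow(fr))
  list(n_fragmented = nrow(fr), by_site_count = by_cnt,
       single_site_pct = round(100 * mean(fr$n_internal_sites == 1L)))
}
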