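## Telomere detection, masking and telomere-class assembly statistics.
##
## Nanochromosomes carry a 5' telomeric repeat (C4A4-type) at their left end
## and its reverse complement (G4T4-type) at their right end, in assembly
## orientation. Detection scans for the 12 bp core motif with a configurable
## number of tolerated mismatches ("degenerate bases"), then extends the span
## left (5') or right (3') across the maximal [AC]* / [GT]* run, mirroring
## the regular expression [AC]*CCCCAAAACCCC used for read masking.

#' Telomere motif constants
#'
#' 12 bp core motifs and the fixed 20 bp telomere used by the simulator.
#' @export
TELOMERE_CORE_5P <- "CCCCAAAACCCC"

#' @rdname TELOMERE_CORE_5P
#' @export
TELOMERE_CORE_3P <- "GGGGTTTTGGGG"

#' @rdname TELOMERE_CORE_5P
#' @export
TELOMERE_SEQ_5P <- "CCCCAAAACCCCAAAACCCC"

#' @rdname TELOMERE_CORE_5P
#' @export
TELOMERE_SEQ_3P <- "GGGGTTTTGGGGTTTTGGGG"

## positions (0-based) where `core` occurs in `s` with <= max_mm mismatches
core_hits <- function(chars, core_chars, max_mm) {
  L <- length(chars)
  k <- length(core_chars)
  if (L < k) return(list(pos = integer(), mm = integer()))
  npos <- L - k + 1L
  mm <- integer(npos)
  for (j in seq_len(k)) {
    mm <- mm + (chars[j:(j + npos - 1L)] != core_chars[j])
  }
  keep <- which(mm <= max_mm)
  list(pos = keep - 1L, mm = mm[keep])
}

## maximal run extension over an allowed alphabet; returns new boundary
extend_left <- function(chars, start0, allowed) {
  i <- start0 # 0-based position just right of the prefix
  while (i > 0L && chars[i] %in% allowed) i <- i - 1L
  i
}

extend_right <- function(chars, end0, allowed) {
  L <- length(chars)
  i <- end0 # 0-based half-open end
  while (i < L && chars[i + 1L] %in% allowed) i <- i + 1L
  i
}

## merge overlapping/adjacent spans of one polarity, keeping min mismatch count
merge_spans <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  out <- df[1L, , drop = FALSE]
  for (i in 2L:nrow(df)) {
    last <- nrow(out)
    if (df$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], df$end[i])
      out$n_mismatch[last] <- min(out$n_mismatch[last], df$n_mismatch[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Find telomeric repeat spans in a sequence
#'
#' Locates all occurrences of the 5' core motif (`CCCCAAAACCCC`, up to
#' `max_degenerate` mismatches, extended across the maximal preceding
#' `[AC]*` run) and of the 3' core motif (its reverse complement, extended
#' across the maximal following `[GT]*` run). Overlapping hits of one
#' polarity are merged, so a full 20 bp telomere is reported as one span.
#'
#' @param sequence a single uppercase DNA string over `A,C,G,T,N`.
#' @param max_degenerate mismatches tolerated in the 12 bp core (default 2).
#' @return `data.frame` with 0-based half-open `start`,`end`, `polarity`
#'   (`"5p"`/`"3p"`) and `n_mismatch`, ordered by `start`.
#' @export
find_telomeres <- function(sequence, max_degenerate = 2L) {
  stopifnot(length(sequence) == 1L)
  assert_dna(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res <- list()
  for (pol in c("5p", "3p")) {
    core <- strsplit(if (pol == "5p") TELOMERE_CORE_5P else TELOMERE_CORE_3P,
                     "", fixed = TRUE)[[1]]
    h <- core_hits(chars, core, max_degenerate)
    if (!length(h$pos)) next
    if (pol == "5p") {
      start <- vapply(h$pos, function(p) extend_left(chars, p, c("A", "C")),
                      integer(1))
      end <- h$pos + 12L
    } else {
      start <- h$pos
      end <- vapply(h$pos + 12L, function(e) extend_right(chars, e, c("G", "T")),
                    integer(1))
    }
    res[[pol]] <- merge_spans(data.frame(
      start = start, end = end, polarity = pol, n_mismatch = h$mm,
      stringsAsFactors = FALSE))
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      polarity = character(), n_mismatch = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$polarity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hard-mask telomeric repeats
#'
#' Replaces every telomeric span (as reported by [find_telomeres()]) with a
#' single `N`. Idempotent: masking a masked sequence is a no-op.
#'
#' @param sequence character vector of DNA sequences.
#' @inheritParams find_telomeres
#' @return character vector of masked sequences.
#' @export
mask_telomeres <- function(sequence, max_degenerate = 2L) {
  vapply(sequence, function(s) {
    sp <- find_telomeres(s, max_degenerate)
    if (!nrow(sp)) return(s)
    # replace right-to-left so earlier coordinates stay valid
    for (i in rev(seq_len(nrow(sp)))) {
      s <- paste0(substr(s, 1L, sp$start[i]), "N",
                  substr(s, sp$end[i] + 1L, nchar(s)))
    }
    s
  }, character(1), USE.NAMES = !is.null(names(sequence)))
}

#' Classify contigs by telomere content
#'
#' Counts 5' and 3' telomeric spans per contig and assigns the telomere
#' class used in assembly reporting: `zero`, `one`, `two` (one 5' and one
#' 3') or `multi` (two or more spans of the same polarity, e.g. internal
#' telomere-like repeats or collapsed alternative isoforms). All detected
#' spans count toward the class; `n_terminal` additionally reports how many
#' lie within `terminal_window` bp of a contig end.
#'
#' @param contigs named character vector of contig sequences.
#' @param terminal_window bp from a contig end within which a span counts
#'   as terminal (default 100).
#' @inheritParams find_telomeres
#' @return `data.frame` with `contig`, `length`, `n5`, `n3`, `n_terminal`,
#'   `class` (factor levels zero/one/two/multi).
#' @export
classify_contigs <- function(contigs, terminal_window = 100L,
                             max_degenerate = 2L) {
  stopifnot(length(contigs) >= 1L, !is.null(names(contigs)))
  rows <- lapply(names(contigs), function(id) {
    s <- contigs[[id]]
    sp <- find_telomeres(s, max_degenerate)
    L <- nchar(s)
    n5 <- sum(sp$polarity == "5p")
    n3 <- sum(sp$polarity == "3p")
    term <- sum(sp$start < terminal_window | sp$end > L - terminal_window)
    data.frame(contig = id, length = L, n5 = n5, n3 = n3,
               n_terminal = term, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$class <- with(out, ifelse(
    n5 >= 2L | n3 >= 2L, "multi",
    ifelse(n5 >= 1L & n3 >= 1L, "two",
           ifelse(n5 + n3 == 1L, "one", "zero"))))
  out$class <- factor(out$class, levels = c("zero", "one", "two", "multi"))
  out
}

#' Assembly N50
#'
#' Length `L` such that contigs of length `>= L` cover at least half of the
#' total assembly length (smaller qualifying length on ties).
#'
#' @param lengths integer vector of contig lengths.
#' @return scalar N50.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Telomere-class assembly statistics
#'
#' Summarises an assembly the way nanochromosome genome reports do: contig
#' counts and mean lengths per telomere class, overall N50, total assembly
#' size and number of terminal telomeres.
#'
#' @inheritParams classify_contigs
#' @return list with `overall` (one-row `data.frame`: `n_contigs`,
#'   `assembly_bp`, `n50`, `mean_length`, `n_telomeres`) and `by_class`
#'   (counts and mean lengths per telomere class).
#' @export
assembly_stats <- function(contigs, terminal_window = 100L,
                           max_degenerate = 2L) {
  if (!length(contigs)) stop("empty contig set")
  cls <- classify_contigs(contigs, terminal_window, max_degenerate)
  by_class <- do.call(rbind, lapply(levels(cls$class), function(cl) {
    sub <- cls[cls$class == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(sub),
               mean_length = if (nrow(sub)) mean(sub$length) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(
    n_contigs = nrow(cls),
    assembly_bp = sum(cls$length),
    n50 = n50(cls$length),
    mean_length = mean(cls$length),
    n_telomeres = sum(cls$n_terminal))
  list(overall = overall, by_class = by_class)
}
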