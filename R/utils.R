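#' @import data.table
#' @importFrom stats rnorm rlnorm rbinom rpois runif median sd cor setNames
#'   complete.cases quantile
#' @importFrom utils write.table read.table head tail
#' @importFrom tools md5sum
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character DNA (A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## stop unless every sequence is uppercase DNA over the allowed alphabet
assert_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-DNA characters in sequence(s): ",
         paste(head(which(bad), 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

## random uniform DNA of given lengths (one string per length)
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

## deterministic per-unit sub-seed derived from a master seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 1000003) %% (.Machine$integer.max - 1L)) + 1L
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings keeping the package's plain-character
#' sequence representation (named character vectors, uppercase DNA).
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x)
  names(ss) <- names(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' @param path file path.
#' @param seq named character vector of read sequences.
#' @param qual character vector of quality strings (same lengths as `seq`);
#'   if `NULL`, constant Q30 is written.
#' @return `read_fastq()` returns a list with elements `seq` and `qual`,
#'   both named character vectors.
#' @export
read_fastq <- function(path) {
  qs <- Biostrings::readQualityScaledDNAStringSet(path)
  list(seq  = setNames(toupper(as.character(qs)), names(qs)),
       qual = setNames(as.character(Biostrings::quality(qs)), names(qs)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seq, qual = NULL, path) {
  if (is.null(qual)) {
    qual <- vapply(nchar(seq), function(n) strrep("?", n), character(1)) # Q30
  }
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seq),
    Biostrings::PhredQuality(Biostrings::BStringSet(qual)))
  names(qs) <- names(seq)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

## decode a Phred+33 quality string into integer scores
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Minimal SAM import/export
#'
#' Reads/writes the minimal SAM dialect used by the pipeline:
#' QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/RNEXT/PNEXT/TLEN/SEQ/QUAL. Only
#' coordinates, strand (from FLAG bit 0x10) and sequence are interpreted;
#' CIGAR is assumed to be a single match run (the mapper emits none other).
#'
#' @param path SAM file path.
#' @param alignments an alignment `data.frame` as produced by [map_reads()].
#' @param contig_lengths named integer vector used for the `@SQ` header.
#' @return `read_sam()` returns an alignment `data.frame` with 0-based
#'   half-open `start`/`end` columns.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(read_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(f)
  if (any(n < 11L)) stop("malformed SAM record (fewer than 11 fields)")
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  seq <- vapply(f, `[[`, "", 10L)
  keep <- rname != "*" & !bitwAnd(flag, 4L)
  data.frame(
    read_id = vapply(f, `[[`, "", 1L)[keep],
    contig  = rname[keep],
    start   = pos[keep] - 1L,
    end     = pos[keep] - 1L + nchar(seq[keep]),
    strand  = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    seq     = seq[keep],
    stringsAsFactors = FALSE)
}

#' @rdname read_sam
#' @export
write_sam <- function(alignments, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  a <- alignments
  flag <- ifelse(a$strand == "-", 16L, 0L)
  seq <- if ("seq" %in% names(a)) a$seq else strrep("N", a$end - a$start)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                 a$read_id, flag, a$contig, a$start + 1L, nchar(seq), seq)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

## write a BED (0-based half-open) data.frame: chrom,start,end,name[,score,strand]
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

## ungapped identity between equal-length string pairs, vectorised in chunks;
## N (masked) counts as mismatch
ungapped_identity <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (!n) return(numeric())
  la <- nchar(a)
  if (any(la != nchar(b))) stop("ungapped_identity: length mismatch")
  out <- numeric(n)
  idx <- seq_len(n)
  for (chunk in split(idx, ceiling(idx / 20000L))) {
    av <- strsplit(a[chunk], "", fixed = TRUE)
    bv <- strsplit(b[chunk], "", fixed = TRUE)
    out[chunk] <- mapply(function(x, y) sum(x == y & x != "N") / length(x),
                         av, bv)
  }
  out
}
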