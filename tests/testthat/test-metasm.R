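q30 <- function(n) strrep("?", n) # Phred+33 Q30
q10 <- function(n) strrep("+", n) # Q10

test_that("quality_trim keeps the longest high-quality run", {
  set.seed(201)
  r <- motif_free_dna(150)
  out <- quality_trim(c(a = r), q30(150))
  expect_identical(unname(out$seq), r)

  # run-scan oracle: Q10 x 60 then Q30 x 90 -> best run is the last 90 bp,
  # below the 100 bp floor -> discarded
  r2 <- motif_free_dna(150)
  out2 <- quality_trim(c(a = r2), paste0(q10(60), q30(90)))
  expect_length(out2$seq, 0L)
  expect_equal(out2$n_discarded, 1L)
  out2b <- quality_trim(c(a = r2), paste0(q10(60), q30(90)), min_len = 80)
  expect_identical(unname(out2b$seq), substr(r2, 61, 150))

  out3 <- quality_trim(c(a = motif_free_dna(120)), q10(120))
  expect_length(out3$seq, 0L)
  expect_error(quality_trim("ACGT", "??"), "malformed")
})

test_that("end extension restores a truncated contig from a source", {
  set.seed(202)
  full <- paste0(TELOMERE_SEQ_5P, motif_free_dna(1500), TELOMERE_SEQ_3P)
  trunc <- substr(full, 1, 1100) # 3' end lost
  src <- list(c(src1 = full))
  ext <- find_end_extensions(c(ctg = trunc), src)
  expect_null(ext$left) # 5' end is telomere-bearing
  expect_false(is.null(ext$right))
  expect_identical(paste0(trunc, ext$right$extension), full)

  # extension appends only: original bases untouched
  res <- extend_contigs(c(ctg = trunc), src, rounds = 1)
  expect_identical(substr(res$contigs[["ctg"]], 1, nchar(trunc)), trunc)
  expect_identical(res$contigs[["ctg"]], full)
})

test_that("extension candidates rank by identity then length", {
  set.seed(203)
  core <- motif_free_dna(900)
  trunc <- substr(core, 1, 500)
  anchor <- substr(core, 401, 500)
  # perfect source extends 200 bp; mutated-anchor source extends 400 bp
  perfect <- paste0(substr(core, 1, 700))
  mut_anchor <- anchor
  substr(mut_anchor, 10, 10) <- if (substr(mut_anchor, 10, 10) == "A") "C" else "A"
  substr(mut_anchor, 50, 50) <- if (substr(mut_anchor, 50, 50) == "G") "T" else "G"
  mutated <- paste0(substr(core, 1, 400), mut_anchor, motif_free_dna(400))
  ext <- find_end_extensions(c(ctg = trunc),
                             list(c(p = perfect, m = mutated)))
  expect_equal(ext$right$source_id, "p") # highest identity wins
  expect_equal(ext$right$anchor_identity, 1.0)

  # equal identity: longest extension wins
  longsrc <- paste0(substr(core, 1, 700), motif_free_dna(300))
  ext2 <- find_end_extensions(c(ctg = trunc),
                              list(c(s80 = perfect, s200 = longsrc)))
  expect_equal(ext2$right$source_id, "s200")
})

test_that("greedy merge joins exact overlaps and recovers tiled loci", {
  set.seed(204)
  whole <- motif_free_dna(600)
  a <- substr(whole, 1, 330)
  b <- substr(whole, 271, 600) # 60 bp exact suffix-prefix overlap
  merged <- greedy_overlap_merge(c(a = a, b = b), 40, 0.99)
  expect_length(merged, 1L)
  expect_equal(nchar(merged[[1]]), 330 + 330 - 60)
  expect_identical(unname(merged[[1]]), whole)

  # unrelated contigs stay apart; total length never grows
  u1 <- motif_free_dna(400); u2 <- motif_free_dna(400)
  out <- greedy_overlap_merge(c(x = u1, y = u2), 40, 0.99)
  expect_length(out, 2L)
  expect_lte(sum(nchar(out)), 800)

  # three tiles of one simulated locus, middle tile reverse-complemented
  p <- sim_params(n_loci = 1, length_mean_bp = 2000, length_sd_bp = 1e-3,
                  het_locus_fraction = 0, altfrag_fraction = 0, seed = 11)
  g <- simulate_genome(p)
  s <- g$contigs[[1]]
  L <- nchar(s)
  tiles <- c(t1 = substr(s, 1, 800), t2 = revcomp(substr(s, 701, 1500)),
             t3 = substr(s, 1401, L))
  rec <- greedy_overlap_merge(tiles, 40, 0.99)
  expect_length(rec, 1L)
  expect_true(rec[[1]] == s || revcomp(rec[[1]]) == s)
})

test_that("merge is strand-symmetric", {
  set.seed(205)
  whole <- motif_free_dna(500)
  inp <- c(a = substr(whole, 1, 300), b = substr(whole, 251, 500))
  fwd <- greedy_overlap_merge(inp, 40, 0.99)
  rc <- greedy_overlap_merge(setNames(revcomp(inp), names(inp)), 40, 0.99)
  expect_setequal(unname(vapply(fwd, revcomp, "")), unname(unlist(rc)))
})

test_that("unspanned interval detection follows the span rule", {
  # synthetic proper pairs on a 5 kb contig: span = inter-mate region
  mk_pairs <- function(starts, frag = 400, rl = 100, contig_len = 5000) {
    n <- length(starts)
    data.frame(
      read_id = c(sprintf("p%03d/1", 1:n), sprintf("p%03d/2", 1:n)),
      mate_id = c(sprintf("p%03d/2", 1:n), sprintf("p%03d/1", 1:n)),
      start = c(starts, starts + frag - rl),
      end = c(starts + rl, starts + frag),
      stringsAsFactors = FALSE)
  }
  # pairs tiling the whole interior -> no interval
  tiling <- mk_pairs(seq(0, 4600, by = 50))
  expect_equal(nrow(detect_unspanned(5000, tiling)), 0L)

  # no fragment crossing [2000, 2100): spans miss it
  starts <- c(seq(0, 1500, by = 25), seq(2200, 4600, by = 25))
  gap <- detect_unspanned(5000, mk_pairs(starts))
  gap <- gap[gap$reason == "no-pair-span", ]
  expect_equal(nrow(gap), 1L)
  expect_lt(gap$start, 2100)
  expect_gt(gap$end, 1900)

  # a missing span wholly within 400 bp of the 5' end is not reported
  starts2 <- seq(250, 4500, by = 25) # spans cover [350, 4600)
  gaps2 <- detect_unspanned(5000, mk_pairs(starts2))
  expect_false(any(gaps2$reason == "no-pair-span"))
})

test_that("split_and_trim cuts at midpoints and trims 200 bp", {
  set.seed(206)
  s <- motif_free_dna(5000)
  none <- split_and_trim(c(ctg = s),
                         data.frame(start = integer(), end = integer(),
                                    reason = character()))
  expect_identical(unname(none[[1]]), s)

  # arithmetic oracle: interval [2000,2100) -> midpoint 2050,
  # fragments [0,1850) and [2250,5000)
  iv <- data.frame(start = 2000L, end = 2100L, reason = "no-pair-span")
  fr <- split_and_trim(c(ctg = s), iv)
  co <- attr(fr, "coords")
  expect_equal(co$start, c(0L, 2250L))
  expect_equal(co$end, c(1850L, 5000L))
  expect_identical(unname(fr[[1]]), substr(s, 1, 1850))
  expect_identical(unname(fr[[2]]), substr(s, 2251, 5000))

  # degenerate: interval covering almost a short contig -> nothing survives
  short <- substr(s, 1, 600)
  iv2 <- data.frame(start = 50L, end = 550L, reason = "no-pair-span")
  fr2 <- split_and_trim(c(ctg = short), iv2, floor_bp = 200L)
  expect_length(fr2, 0L)
  # zero-coverage ends are removed outright
  iv3 <- data.frame(start = c(0L, 4800L), end = c(300L, 5000L),
                    reason = "zero-coverage-end")
  fr3 <- split_and_trim(c(ctg = s), iv3)
  expect_identical(unname(fr3[[1]]), substr(s, 301, 4800))
})

test_that("injected chimeras are split and clean contigs are not", {
  # chimera of two simulated loci; reads simulated per locus only
  p <- sim_params(n_loci = 2, length_mean_bp = 3000, length_sd_bp = 1e-3,
                  het_locus_fraction = 0, altfrag_fraction = 0,
                  coverage_x = 50, se_coverage_x = 0, seed = 17)
  g <- simulate_genome(p)
  r <- simulate_reads(g, libraries = "pe", sequences = FALSE)
  a <- r$alignments
  L1 <- g$loci$length[1]
  L2 <- g$loci$length[2]
  chim_len <- L1 + L2
  a2 <- a
  a2$start <- ifelse(a$contig == g$loci$locus[2], a$start + L1, a$start)
  a2$end <- ifelse(a$contig == g$loci$locus[2], a$end + L1, a$end)
  gaps <- detect_unspanned(chim_len, a2)
  gaps <- gaps[gaps$reason == "no-pair-span", ]
  expect_equal(nrow(gaps), 1L)
  expect_true(gaps$start <= L1 && gaps$end >= L1 - 400)

  # clean contig: no false split
  clean <- detect_unspanned(L1, a[a$contig == g$loci$locus[1], ])
  expect_false(any(clean$reason == "no-pair-span"))
})
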