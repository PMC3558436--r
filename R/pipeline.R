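## End-to-end orchestration: simulate -> (map) -> heterozygosity /
## fragmentation / copy number, with a single config and a manifest.

#' Pipeline configuration
#'
#' Central configuration with every module threshold at its documented
#' default: 0.94 mapping identity, 20x coverage and 5% variant frequency,
#' 0.5% heterozygosity threshold, 10-read strong TAS support, 200 bp TAS
#' window, 100/250 bp internal-site margins, 600 bp subtelomeric margin,
#' 1,800 bp copy-number length floor, 40 bp variant end margin. The config
#' round-trips losslessly through JSON.
#'
#' @param sim a [sim_params()] object (or arguments for one, as a list).
#' @param stages character subset of
#'   `c("simulate","telomere","hetvar","fragsites","copynum")`.
#' @param map_identity,min_cov,min_freq,het_threshold_pct,tas_strong_min
#'   thresholds (see module docs).
#' @param tas_window,altfrag_margin,variant_end_margin,cn_margin,cn_min_len
#'   window/margin parameters in bp.
#' @param use_truth_alignments if `TRUE` (default) downstream stages
#'   consume the simulator's ground-truth alignments; if `FALSE` reads are
#'   re-mapped with [map_reads()] (slower).
#' @param seed master seed (overrides `sim$seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_params(),
                            stages = c("simulate", "telomere", "hetvar",
                                       "fragsites", "copynum"),
                            map_identity = 0.94,
                            min_cov = 20L, min_freq = 0.05,
                            het_threshold_pct = 0.5,
                            tas_strong_min = 10L, tas_window = 200L,
                            altfrag_margin = 100L,
                            variant_end_margin = 40L,
                            cn_margin = 600L, cn_min_len = 1800L,
                            use_truth_alignments = TRUE,
                            seed = NULL) {
  if (!inherits(sim, "sim_params")) sim <- do.call(sim_params, sim)
  if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
  }
  stopifnot(map_identity > 0, map_identity <= 1,
            min_cov >= 1, min_freq >= 0, min_freq <= 1,
            het_threshold_pct >= 0, tas_strong_min >= 1,
            tas_window >= 1, altfrag_margin >= 0,
            cn_margin >= 0, cn_min_len >= 1)
  structure(list(sim = sim, stages = stages, map_identity = map_identity,
                 min_cov = as.integer(min_cov), min_freq = min_freq,
                 het_threshold_pct = het_threshold_pct,
                 tas_strong_min = as.integer(tas_strong_min),
                 tas_window = as.integer(tas_window),
                 altfrag_margin = as.integer(altfrag_margin),
                 variant_end_margin = as.integer(variant_end_margin),
                 cn_margin = as.integer(cn_margin),
                 cn_min_len = as.integer(cn_min_len),
                 use_truth_alignments = use_truth_alignments),
            class = "pipeline_config")
}

#' Save / load a pipeline config
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_params, x$sim)
  x$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), x))
}

#' Run the full pipeline
#'
#' Simulates a genome and reads, then runs the enabled analysis stages,
#' writing one report TSV per stage plus a JSON manifest (parameters and
#' md5 checksums of every output) into `outdir`. Outputs are deterministic
#' under a fixed seed; stages never modify another stage's outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created; existing files overwritten).
#' @param quiet suppress progress messages.
#' @return invisibly, a list of in-memory results per stage.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[nanochromkit] ", ...)
  res <- list()

  say("simulate: ", config$sim$n_loci, " loci, seed ", config$sim$seed)
  genome <- simulate_genome(config$sim)
  libs <- c("pe", "se", "tp",
            if (config$sim$telo_se_depth > 0) "telo_se")
  reads <- simulate_reads(genome, libraries = libs,
                          sequences = !config$use_truth_alignments)
  res$genome <- genome
  write_sim_genome(genome, file.path(outdir, "sim"))
  lens <- setNames(nchar(genome$contigs), names(genome$contigs))

  if (config$use_truth_alignments) {
    aln <- reads$alignments
  } else {
    masked <- mask_telomeres(c(reads$pe1$seq, reads$pe2$seq, reads$se$seq))
    aln <- map_reads(masked, genome$contigs,
                     min_identity = config$map_identity)
    aln$is_telomeric <- grepl("N", masked[aln$read_id], fixed = TRUE)
    aln$library <- "mapped"
    aln$telo_polarity <- NA_character_
    aln$tas_pos <- NA_integer_
    truth_telo <- reads$alignments[reads$alignments$is_telomeric, ]
    aln <- rbind(aln[, names(truth_telo)[names(truth_telo) %in% names(aln)]],
                 truth_telo[, names(truth_telo) %in% names(aln)])
  }

  if ("telomere" %in% config$stages) {
    say("telomere: classifying ", length(genome$contigs), " contigs")
    stats <- assembly_stats(genome$contigs)
    res$telomere <- stats
    write_tsv(stats$by_class, file.path(outdir, "telomere_classes.tsv"))
    write_tsv(stats$overall, file.path(outdir, "assembly_stats.tsv"))
  }

  if ("hetvar" %in% config$stages) {
    say("hetvar: variant calling and classification")
    seq_aln <- if ("seq" %in% names(aln) && !all(is.na(aln$seq))) aln else {
      # pileup needs sequences; regenerate the PE/SE libraries with them
      r2 <- simulate_reads(genome, libraries = c("pe", "se"),
                           sequences = TRUE)
      r2$alignments
    }
    pu <- pileup_from_alignments(
      seq_aln[!seq_aln$is_telomeric & seq_aln$library %in% c("pe", "se"), ],
      lens)
    nm <- nonself_matches(genome$contigs)
    matched <- unique(c(nm$query, nm$target))
    status <- setNames(ifelse(names(lens) %in% matched, "matched",
                              "matchless"), names(lens))
    reports <- classify_het_all(pu, lens, status,
                                min_cov = config$min_cov,
                                min_freq = config$min_freq,
                                end_margin = config$variant_end_margin,
                                het_threshold_pct = config$het_threshold_pct)
    res$hetvar <- list(reports = reports,
                       homozygous_fraction =
                         genome_homozygous_fraction(reports))
    write_tsv(reports, file.path(outdir, "het_reports.tsv"))
  }

  tas <- NULL
  if ("fragsites" %in% config$stages) {
    say("fragsites: TAS calling and fragmentation detection")
    telo_aln <- aln[aln$is_telomeric & !is.na(aln$tas_pos), ]
    tas <- call_tas(telo_aln, lens, window = config$tas_window,
                    strong_min = config$tas_strong_min)
    classes <- classify_contigs(genome$contigs)
    status <- detect_altfrag(tas, classes,
                             end_margin = config$altfrag_margin)
    dirs <- directionality_summary(status)
    res$fragsites <- list(tas = tas, status = status,
                          directionality = dirs)
    write_tsv(tas, file.path(outdir, "tas.tsv"))
    write_tsv(status, file.path(outdir, "altfrag_status.tsv"))
  }

  if ("copynum" %in% config$stages) {
    say("copynum: depth and telomeric-read estimators")
    cn_aln <- aln[aln$library %in% c("pe", "se", "telo_se"), ]
    est <- estimate_cn(cn_aln, lens, min_len = config$cn_min_len,
                       margin = config$cn_margin)
    labels <- data.frame(contig = genome$loci$locus,
                         altfrag = genome$loci$altfrag)
    cmp <- group_report(est, labels)
    res$copynum <- list(estimates = est, comparisons = cmp)
    write_tsv(est, file.path(outdir, "copy_number.tsv"))
    write_tsv(cmp, file.path(outdir, "copy_number_comparisons.tsv"))
  }

  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "nanochromkit",
    version = as.character(utils::packageVersion("nanochromkit")),
    seed = config$sim$seed,
    parameters = unclass(config$sim),
    thresholds = unclass(config)[setdiff(names(unclass(config)),
                                         c("sim", "stages"))],
    stages = config$stages,
    outputs = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", length(files), " report files in ", outdir)
  invisible(res)
}
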