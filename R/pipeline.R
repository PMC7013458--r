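# Umbrella workflows: configuration with schema validation, seed management
# and the two end-to-end analyses (amplicon specificity; genome-wide MBD).
# Every artifact is written to disk and checksummed so a config + seed fully
# determines the run.

#' Default run configuration
#'
#' All stage parameters with their defaults: 2 x 250 bp paired reads, quality
#' and overlap thresholds of 20, 10 bp bins, top-K CGI re-calibration, 1 kb
#' matrix flanks, and the synthetic study conditions (wild-type affinity 1
#' versus a low-affinity mutant). Sizes are desk-scale so a full run completes
#' in seconds.
#'
#' @param seed global integer seed
#' @return nested named list of class `RunConfig`
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    genome = list(n_cgis = 40, cgi_width = 300, gap = 700, n_chrom = 2,
                  frac_methylated = 0.5, cgi_cpg_rate = 0.25,
                  background_cpg_rate = 0.01,
                  protospacer = "GTTCGCTGCCTCTCAGCCGC", pam = "AGG"),
    methylome = list(theta_wt = 1, theta_mut = 0.12, p_on = 0.85,
                     p_max = 0.6),
    reads = list(conversion_rate = 0.998, inappropriate_conversion = 0.002,
                 sequencing_error_rate = 0.001, read_length = 250,
                 n_read_pairs = 600),
    bisseq = list(q_trim = 20, min_overlap = 20, max_mismatch_frac = 0.1,
                  min_identity = 0.9, min_base_quality = 20, min_reads = 100),
    mbd = list(fragment_mean = 150, fragment_sd = 30, n_fragments = 20000,
               mbd_capture_q = 0.1, bin_size = 10, k = 15),
    peaks = list(background_quantile = 0.99, min_width = 100, merge_gap = 50),
    offtarget = list(max_mismatches = 4, pam = "NGG"),
    matrix = list(flank = 1000, body_bins = 50),
    metrics = list(reference = "WT")
  ), class = "RunConfig")
}

#' Validate a run configuration against the schema
#'
#' Rejects unknown keys (top-level and within each stage) and missing stages;
#' values are type-checked by the stages that consume them.
#'
#' @param config RunConfig or plain nested list
#' @return the config, invisibly; errors on violation
#' @export
validate_config <- function(config) {
  ref <- unclass(default_config())
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(config)) {
    if (is.list(ref[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(ref[[nm]]))
      if (length(bad))
        stop("unknown config key(s) in '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

# amplicon workflow: simulate, analyze both loci for WT and mutant, report
.run_amplicon <- function(config, outdir) {
  cfg <- config
  genome <- do.call(simulate_genome, c(cfg$genome, list(seed = cfg$seed)))
  write_fasta(genome$seqs, file.path(outdir, "genome.fa"))
  on_amp <- amplicon_from_genome(genome)
  unm <- setdiff(which(S4Vectors::mcols(genome$cgis)$class == "unmethylated"),
                 genome$target_idx)
  off_amp <- amplicon_from_genome(genome, unm[1])
  params <- function(s) sim_params(
    conversion_rate = cfg$reads$conversion_rate,
    inappropriate_conversion = cfg$reads$inappropriate_conversion,
    sequencing_error_rate = cfg$reads$sequencing_error_rate,
    read_length = cfg$reads$read_length,
    n_read_pairs = cfg$reads$n_read_pairs, seed = s)
  truth <- list(WT = simulate_methylome(genome, theta = cfg$methylome$theta_wt,
                                        p_on = cfg$methylome$p_on,
                                        p_max = cfg$methylome$p_max,
                                        seed = cfg$seed),
                mutant = simulate_methylome(genome,
                                            theta = cfg$methylome$theta_mut,
                                            p_on = cfg$methylome$p_on,
                                            p_max = cfg$methylome$p_max,
                                            seed = cfg$seed))
  probs_for <- function(tr, amp) {
    pos0 <- attr(amp, "genome_start") + amp$cpg_offsets - 1
    i <- match(paste(attr(amp, "chrom"), pos0),
               paste(tr$sites$chrom, tr$sites$pos))
    tr$sites$treated[i]
  }
  rows <- lapply(names(truth), function(nm) {
    tr <- truth[[nm]]
    means <- vapply(list(on = on_amp, off = off_amp), function(amp) {
      sim <- simulate_bisulfite_reads(amp, probs_for(tr, amp),
                                      params(derive_seed(cfg$seed, nm)))
      write_fastq(sim$r1, file.path(outdir, paste0(nm, "_", amp$name, "_R1.fastq")))
      write_fastq(sim$r2, file.path(outdir, paste0(nm, "_", amp$name, "_R2.fastq")))
      res <- bisseq_pipeline(sim$r1, sim$r2, amp,
                             q_trim = cfg$bisseq$q_trim,
                             min_overlap = cfg$bisseq$min_overlap,
                             max_mismatch_frac = cfg$bisseq$max_mismatch_frac,
                             min_identity = cfg$bisseq$min_identity,
                             min_base_quality = cfg$bisseq$min_base_quality)
      write_bisseq_tables(res, amp,
                          file.path(outdir, paste0(nm, "_", amp$name)),
                          min_reads = cfg$bisseq$min_reads)
      region_mean(res$profile, amp, min_reads = cfg$bisseq$min_reads)
    }, numeric(1))
    data.frame(sample = nm, on_pct = means[["on"]], off_pct = means[["off"]])
  })
  summaries <- do.call(rbind, rows)
  write_tsv_table(summaries, file.path(outdir, "amplicon_summaries.tsv"))
  report <- build_report(summaries, reference = cfg$metrics$reference)
  write_tsv_table(report, file.path(outdir, "specificity_report.tsv"))
  write_report_json(report, file.path(outdir, "specificity_report.json"))
  report
}

# mbd workflow: fragments -> tracks -> recalibrate -> classify -> peaks -> fold
.run_mbd <- function(config, outdir) {
  cfg <- config
  genome <- do.call(simulate_genome, c(cfg$genome, list(seed = cfg$seed)))
  mp <- function(s) sim_params(fragment_mean = cfg$mbd$fragment_mean,
                               fragment_sd = cfg$mbd$fragment_sd,
                               n_fragments = cfg$mbd$n_fragments,
                               mbd_capture_q = cfg$mbd$mbd_capture_q,
                               seed = s)
  tr_wt <- simulate_methylome(genome, theta = cfg$methylome$theta_wt,
                              p_on = cfg$methylome$p_on,
                              p_max = cfg$methylome$p_max, seed = cfg$seed)
  tr_mut <- simulate_methylome(genome, theta = cfg$methylome$theta_mut,
                               p_on = cfg$methylome$p_on,
                               p_max = cfg$methylome$p_max, seed = cfg$seed)
  frags <- list(
    untreated = simulate_mbd_fragments(genome, tr_wt, "untreated",
                                       mp(derive_seed(cfg$seed, "u")),
                                       bin_size = cfg$mbd$bin_size),
    WT = simulate_mbd_fragments(genome, tr_wt, "treated",
                                mp(derive_seed(cfg$seed, "wt")),
                                bin_size = cfg$mbd$bin_size),
    mutant = simulate_mbd_fragments(genome, tr_mut, "treated",
                                    mp(derive_seed(cfg$seed, "mut")),
                                    bin_size = cfg$mbd$bin_size))
  tracks <- lapply(frags, function(fr)
    rpkm_normalize(bin_coverage(fr, genome$chrom_sizes, cfg$mbd$bin_size)))
  for (nm in names(frags))
    write_bed(frags[[nm]], file.path(outdir, paste0(nm, "_fragments.bed")))
  rec <- recalibrate(tracks, genome$cgis, reference = "untreated",
                     k = cfg$mbd$k)
  for (nm in names(rec$tracks))
    track_to_bedgraph(rec$tracks[[nm]],
                      file.path(outdir, paste0(nm, "_recal.bedGraph")))
  jsonlite::write_json(as.list(rec$scale_factors),
                       file.path(outdir, "scale_factors.json"),
                       auto_unbox = TRUE, digits = NA)
  cls <- classify_cgis(rec$tracks$untreated, genome$cgis)
  unm <- genome$cgis[cls$class == "unmethylated"]
  peaks <- call_new_peaks(rec$tracks$WT, rec$tracks$untreated, genome$cgis,
                          background_quantile = cfg$peaks$background_quantile,
                          min_width = cfg$peaks$min_width,
                          merge_gap = cfg$peaks$merge_gap)
  write_bed(peaks, file.path(outdir, "wt_new_peaks.bed"))
  ic <- intersect_counts(peaks, genome$cgis, unm)
  means <- lapply(rec$tracks, quantify_intervals, intervals = unm)
  fr <- fold_reduction(means$WT, means$mutant, means$untreated)
  mat <- cgi_matrix(rec$tracks$WT, genome$cgis, flank = cfg$matrix$flank,
                    body_bins = cfg$matrix$body_bins)
  utils::write.table(mat, file.path(outdir, "wt_cgi_matrix.tsv"), sep = "\t",
                     quote = FALSE, col.names = FALSE)
  per_cgi <- data.frame(cgi_id = S4Vectors::mcols(genome$cgis)$cgi_id,
                        class = as.character(cls$class),
                        untreated = quantify_intervals(rec$tracks$untreated,
                                                       genome$cgis),
                        WT = quantify_intervals(rec$tracks$WT, genome$cgis),
                        mutant = quantify_intervals(rec$tracks$mutant,
                                                    genome$cgis))
  write_tsv_table(per_cgi, file.path(outdir, "cgi_quantification.tsv"))
  summary <- data.frame(metric = c("n_peaks", "n_peaks_in_cgis",
                                   "n_peaks_in_unmethylated_cgis",
                                   "fold_reduction"),
                        value = c(ic$n_peaks, ic$n_in_cgis, ic$n_in_subset,
                                  fr$fold))
  write_tsv_table(summary, file.path(outdir, "mbd_summary.tsv"))
  list(scale_factors = rec$scale_factors, classes = cls$class,
       intersections = ic, fold_reduction = fr)
}

#' Run an end-to-end workflow
#'
#' Executes simulate -> analyze -> metrics for the amplicon specificity
#' workflow, the genome-wide MBD workflow, or both, writing every artifact
#' under `outdir` plus a JSON manifest with an MD5 checksum per file.
#' Identical config + seed yields identical checksums.
#'
#' @param config [default_config()]-shaped list (validated; unknown keys are
#'   rejected)
#' @param workflow "amplicon", "mbd" or "full"
#' @param outdir output directory (created if needed)
#' @return data.frame manifest (file, md5), invisibly; the workflow results
#'   are attached as the `results` attribute
#' @export
run_pipeline <- function(config = default_config(),
                         workflow = c("amplicon", "mbd", "full"),
                         outdir = tempfile("methyledit_run_")) {
  workflow <- match.arg(workflow)
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  if (workflow %in% c("amplicon", "full"))
    results$amplicon <- tryCatch(.run_amplicon(config, outdir),
      error = function(e) stop("[amplicon] ", conditionMessage(e),
                               call. = FALSE))
  if (workflow %in% c("mbd", "full"))
    results$mbd <- tryCatch(.run_mbd(config, outdir),
      error = function(e) stop("[mbd] ", conditionMessage(e), call. = FALSE))
  jsonlite::write_json(list(seed = config$seed, workflow = workflow,
                            config = unclass(config)),
                       file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  attr(manifest, "results") <- results
  invisible(manifest)
}
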