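# Targeted bisulfite-amplicon analysis: quality trimming, pair merging,
# bisulfite-aware ungapped alignment, per-CpG methylation calling,
# conversion-rate QC and region summaries.
#
# Alignment is a reduced-alphabet (C->T collapsed) ungapped scan: amplicon
# reads are indel-free by construction, so a full bisulfite mapper would add
# nothing but an external dependency. This is the one intentional
# methodological substitution in the amplicon workflow.

#' Amplicon specification
#'
#' Describes an amplicon reference: its top-strand sequence, the ordered CpG
#' sites, the subset blocked by the dCas9-sgRNA footprint (inaccessible to the
#' methyltransferase) and the subset entering the region average. With
#' `cpg_offsets = NULL` CpGs are auto-detected from the sequence.
#'
#' @param name amplicon name
#' @param sequence top-strand reference sequence (uppercase ACGT)
#' @param cpg_offsets 1-based offsets of the CpG cytosines; auto-detected when
#'   NULL
#' @param blocked_indices CpG indices (1-based into `cpg_offsets`) under the
#'   dCas9 footprint, excluded from the analysis subset
#' @param analysis_indices CpG indices used for the region average; defaults
#'   to all non-blocked indices
#' @return object of class `AmpliconSpec`
#' @export
amplicon_spec <- function(name, sequence, cpg_offsets = NULL,
                          blocked_indices = integer(0),
                          analysis_indices = NULL) {
  sequence <- toupper(sequence)
  stopifnot(grepl("^[ACGT]+$", sequence))
  if (is.null(cpg_offsets)) {
    m <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
    cpg_offsets <- if (m[1] == -1) integer(0) else as.integer(m)
  }
  cpg_offsets <- as.integer(cpg_offsets)
  if (is.unsorted(cpg_offsets, strictly = TRUE))
    stop("cpg_offsets must be strictly increasing", call. = FALSE)
  if (length(cpg_offsets) &&
      any(substring(sequence, cpg_offsets, cpg_offsets + 1) != "CG"))
    stop("every CpG offset must point at 'CG' in the reference", call. = FALSE)
  nc <- length(cpg_offsets)
  blocked_indices <- as.integer(blocked_indices)
  stopifnot(all(blocked_indices >= 1 & blocked_indices <= nc))
  if (is.null(analysis_indices))
    analysis_indices <- setdiff(seq_len(nc), blocked_indices)
  analysis_indices <- as.integer(analysis_indices)
  stopifnot(all(analysis_indices >= 1 & analysis_indices <= nc))
  if (length(intersect(blocked_indices, analysis_indices)))
    stop("blocked and analysis CpG subsets must be disjoint", call. = FALSE)
  structure(list(name = name, sequence = sequence,
                 cpg_offsets = cpg_offsets,
                 blocked_indices = blocked_indices,
                 analysis_indices = analysis_indices),
            class = "AmpliconSpec")
}

#' Build an AmpliconSpec from a CGI of a synthetic genome
#'
#' Extracts the island sequence as the amplicon reference. For the target
#' CGI, CpGs under the planted protospacer are marked blocked and excluded
#' from the analysis subset (the on-target convention).
#'
#' @param genome SyntheticGenome
#' @param cgi_index index into `genome$cgis`; defaults to the target CGI
#' @return AmpliconSpec
#' @export
amplicon_from_genome <- function(genome, cgi_index = genome$target_idx) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  g <- genome$cgis[cgi_index]
  ch <- as.character(GenomicRanges::seqnames(g))
  s0 <- GenomicRanges::start(g) - 1L            # 0-based start
  seq <- substr(genome$seqs[[ch]], s0 + 1, GenomicRanges::end(g))
  spec <- amplicon_spec(S4Vectors::mcols(g)$cgi_id, seq)
  if (cgi_index == genome$target_idx) {
    sg <- genome$sgrna
    pos0 <- s0 + spec$cpg_offsets - 1L          # genomic 0-based positions
    blocked <- which(pos0 >= sg$start & pos0 <= sg$start + 19)
    spec <- amplicon_spec(spec$name, seq, spec$cpg_offsets,
                          blocked_indices = blocked)
  }
  attr(spec, "chrom") <- ch
  attr(spec, "genome_start") <- s0
  spec
}

#' Trim low-quality 3' tails
#'
#' Removes the maximal 3' run of bases with Phred quality below the threshold,
#' keeping the longest prefix that ends on a base at or above it. An entirely
#' low-quality read becomes empty.
#'
#' @param seq,qual character vectors of sequences and Phred+33 quality strings
#' @param q_threshold minimum quality to keep (default 20)
#' @return list with trimmed `seq` and `qual`
#' @export
quality_trim <- function(seq, qual, q_threshold = 20) {
  if (any(nchar(seq) != nchar(qual)))
    stop("quality string length differs from sequence length", call. = FALSE)
  keep <- vapply(qual, function(q) {
    if (!nzchar(q)) return(0L)
    ph <- utf8ToInt(q) - 33L
    if (any(ph < 0L | ph > 93L))
      stop("malformed Phred+33 quality string", call. = FALSE)
    ok <- which(ph >= q_threshold)
    if (length(ok)) max(ok) else 0L
  }, integer(1), USE.NAMES = FALSE)
  list(seq = substr(seq, 1, keep), qual = substr(qual, 1, keep))
}

#' Merge read pairs by exhaustive overlap scan
#'
#' Mate 2 is supplied in sequencer orientation and reverse-complemented
#' internally. All overlap lengths at or above `min_overlap` are scored by
#' matched bases; the best-scoring overlap with mismatch fraction at most
#' `max_mismatch_frac` is accepted (ties to the longest overlap) and the
#' consensus takes the higher-quality base at disagreements. Pairs with no
#' acceptable overlap are rejected (counted, not fatal).
#'
#' @param r1,r2 data.frames with columns `seq`, `qual` (mate 2 in sequencer
#'   orientation)
#' @param min_overlap minimum overlap length (default 20)
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#' @return data.frame with `merged` (logical), `seq`, `qual`, `overlap`
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20, max_mismatch_frac = 0.1) {
  stopifnot(nrow(r1) == nrow(r2))
  if (nrow(r1) == 0L)
    return(data.frame(merged = logical(), seq = character(),
                      qual = character(), overlap = integer()))
  r2rc <- revcomp(r2$seq)
  q2rev <- rev_string(r2$qual)
  res <- cpp_merge_pairs(r1$seq, r1$qual, r2rc, q2rev,
                         as.integer(min_overlap), max_mismatch_frac)
  data.frame(merged = res$merged, seq = res$seq, qual = res$qual,
             overlap = res$overlap, stringsAsFactors = FALSE)
}

#' Bisulfite-aware ungapped alignment to an amplicon reference
#'
#' Both read and reference are collapsed C->T (so bisulfite conversion is
#' invisible to the aligner) and the read is slid over the reference; the
#' offset with the most matches wins, ties to the leftmost. Reads whose
#' reduced-alphabet identity falls below `min_identity` are rejected.
#'
#' @param seqs character vector of (merged) read sequences
#' @param amplicon AmpliconSpec
#' @param min_identity minimum reduced-alphabet identity (default 0.9)
#' @return data.frame with `offset` (0-based, NA when rejected), `identity`,
#'   `accepted`
#' @export
align_bisulfite <- function(seqs, amplicon, min_identity = 0.9) {
  stopifnot(inherits(amplicon, "AmpliconSpec"))
  if (length(seqs) == 0L)
    return(data.frame(offset = integer(), identity = numeric(),
                      accepted = logical()))
  ok <- !is.na(seqs) & nzchar(seqs)
  red <- chartr("C", "T", seqs)
  ref_red <- chartr("C", "T", amplicon$sequence)
  res <- list(offset = rep(-1L, length(seqs)),
              identity = rep(0, length(seqs)))
  if (any(ok)) {
    r <- cpp_align_ungapped(red[ok], ref_red)
    res$offset[ok] <- r$offset
    res$identity[ok] <- r$identity
  }
  accepted <- ok & res$offset >= 0 & res$identity >= min_identity
  data.frame(offset = ifelse(accepted, res$offset, NA_integer_),
             identity = res$identity, accepted = accepted)
}

# base and quality at reference position `refpos` (1-based) for each aligned read
.base_at <- function(seqs, quals, offsets, refpos) {
  rel <- refpos - offsets                      # 1-based position in read
  inside <- !is.na(offsets) & rel >= 1 & rel <= nchar(seqs)
  b <- rep(NA_character_, length(seqs))
  q <- rep(NA_integer_, length(seqs))
  b[inside] <- substr(seqs[inside], rel[inside], rel[inside])
  q[inside] <- utf8ToInt(paste(substr(quals[inside], rel[inside], rel[inside]),
                               collapse = "")) - 33L
  list(base = b, qual = q)
}

#' Call per-CpG methylation from aligned amplicon reads
#'
#' At each reference CpG cytosine, a read base C counts as methylated and T as
#' unmethylated; other bases, or bases below `min_base_quality`, are ignored.
#' Sites with zero coverage report a missing level.
#'
#' @param seqs,quals,offsets aligned reads: sequences, quality strings and
#'   0-based alignment offsets from [align_bisulfite()] (rejected reads NA)
#' @param amplicon AmpliconSpec
#' @param min_base_quality minimum Phred base quality (default 20)
#' @return object of class `MethylationProfile`: list with `sites`
#'   (data.frame: index, offset, meth, unmeth, level) and `n_reads_used`
#' @export
call_methylation <- function(seqs, quals, offsets, amplicon,
                             min_base_quality = 20) {
  stopifnot(inherits(amplicon, "AmpliconSpec"))
  use <- !is.na(offsets)
  seqs <- seqs[use]; quals <- quals[use]; offsets <- offsets[use]
  nc <- length(amplicon$cpg_offsets)
  meth <- integer(nc); unmeth <- integer(nc)
  for (k in seq_len(nc)) {
    at <- .base_at(seqs, quals, offsets, amplicon$cpg_offsets[k])
    good <- !is.na(at$base) & at$qual >= min_base_quality
    meth[k] <- sum(good & at$base == "C")
    unmeth[k] <- sum(good & at$base == "T")
  }
  cov <- meth + unmeth
  level <- ifelse(cov > 0, meth / cov, NA_real_)
  structure(list(sites = data.frame(index = seq_len(nc),
                                    offset = amplicon$cpg_offsets,
                                    meth = meth, unmeth = unmeth,
                                    level = level),
                 n_reads_used = length(seqs)),
            class = "MethylationProfile")
}

#' Estimate the bisulfite conversion rate from non-CpG cytosines
#'
#' Non-CpG cytosines are expected unmethylated, so the fraction read as T over
#' all non-CpG reference C positions estimates the conversion rate.
#'
#' @inheritParams call_methylation
#' @return conversion rate estimate in percent
#' @export
conversion_qc <- function(seqs, quals, offsets, amplicon,
                          min_base_quality = 20) {
  stopifnot(inherits(amplicon, "AmpliconSpec"))
  a <- strsplit(amplicon$sequence, "")[[1]]
  noncpg_c <- setdiff(which(a == "C"), amplicon$cpg_offsets)
  if (length(noncpg_c) == 0L)
    stop("amplicon has no non-CpG cytosine: conversion QC not computable",
         call. = FALSE)
  use <- !is.na(offsets)
  seqs <- seqs[use]; quals <- quals[use]; offsets <- offsets[use]
  n_t <- 0; n_c <- 0
  for (p in noncpg_c) {
    at <- .base_at(seqs, quals, offsets, p)
    good <- !is.na(at$base) & at$qual >= min_base_quality
    n_t <- n_t + sum(good & at$base == "T")
    n_c <- n_c + sum(good & at$base == "C")
  }
  if (n_t + n_c == 0)
    stop("no covered non-CpG cytosine: conversion QC not computable",
         call. = FALSE)
  100 * n_t / (n_t + n_c)
}

#' Average methylation over the analysis CpG subset
#'
#' Unweighted mean of per-site levels over the amplicon's analysis indices
#' (e.g. CpGs 1-15 of a 19-CpG amplicon whose sites 16-19 sit under the dCas9
#' footprint), in percent.
#'
#' @param profile MethylationProfile
#' @param amplicon AmpliconSpec
#' @param min_reads minimum merged reads required (coverage floor)
#' @return percent methylation, rounded half away from zero to 1 decimal
#' @export
region_mean <- function(profile, amplicon, min_reads = 100) {
  stopifnot(inherits(profile, "MethylationProfile"),
            inherits(amplicon, "AmpliconSpec"))
  if (profile$n_reads_used < min_reads)
    stop("only ", profile$n_reads_used, " reads used; coverage floor is ",
         min_reads, call. = FALSE)
  lv <- profile$sites$level[amplicon$analysis_indices]
  if (anyNA(lv))
    stop("uncovered analysis CpG site: region mean undefined", call. = FALSE)
  round_half_away(100 * mean(lv), 1)
}

#' Run the full amplicon workflow on a pair of read sets
#'
#' quality trim -> merge -> align -> per-CpG calls + conversion QC.
#'
#' @param r1,r2 data.frames with `id`, `seq`, `qual` (or FASTQ paths)
#' @param amplicon AmpliconSpec
#' @param q_trim quality-trim threshold
#' @param min_overlap,max_mismatch_frac merge parameters
#' @param min_identity alignment identity threshold
#' @param min_base_quality base-quality floor for calling
#' @return list with `profile` (MethylationProfile), `conversion_pct`, and a
#'   `qc` vector of stage counters
#' @export
bisseq_pipeline <- function(r1, r2, amplicon, q_trim = 20, min_overlap = 20,
                            max_mismatch_frac = 0.1, min_identity = 0.9,
                            min_base_quality = 20) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  t1 <- quality_trim(r1$seq, r1$qual, q_trim)
  t2 <- quality_trim(r2$seq, r2$qual, q_trim)
  m <- merge_pairs(data.frame(seq = t1$seq, qual = t1$qual),
                   data.frame(seq = t2$seq, qual = t2$qual),
                   min_overlap, max_mismatch_frac)
  mm <- m[m$merged, , drop = FALSE]
  al <- align_bisulfite(mm$seq, amplicon, min_identity)
  profile <- call_methylation(mm$seq, mm$qual, al$offset, amplicon,
                              min_base_quality)
  conv <- conversion_qc(mm$seq, mm$qual, al$offset, amplicon,
                        min_base_quality)
  list(profile = profile, conversion_pct = conv,
       qc = c(n_pairs = nrow(r1), n_merged = nrow(mm),
              n_aligned = sum(al$accepted),
              n_rejected_merge = nrow(r1) - nrow(mm),
              n_rejected_align = sum(!al$accepted)))
}

#' Write the per-site, QC and region-summary tables of an amplicon analysis
#'
#' @param result [bisseq_pipeline()] output
#' @param amplicon AmpliconSpec
#' @param prefix output path prefix (writes `<prefix>_sites.tsv`,
#'   `<prefix>_qc.tsv`, `<prefix>_region.tsv`)
#' @param min_reads coverage floor passed to [region_mean()]
#' @return character vector of written paths, invisibly
#' @export
write_bisseq_tables <- function(result, amplicon, prefix, min_reads = 100) {
  p1 <- paste0(prefix, "_sites.tsv")
  write_tsv_table(result$profile$sites, p1)
  p2 <- paste0(prefix, "_qc.tsv")
  write_tsv_table(data.frame(metric = c("conversion_pct", names(result$qc)),
                             value = c(result$conversion_pct, result$qc)), p2)
  p3 <- paste0(prefix, "_region.tsv")
  write_tsv_table(data.frame(amplicon = amplicon$name,
                             mean_pct = region_mean(result$profile, amplicon,
                                                    min_reads)), p3)
  invisible(c(p1, p2, p3))
}
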