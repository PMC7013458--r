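# Deterministic fixture builders shared across test files.

# Amplicon with exactly n_cpg CpGs, evenly spaced, plus one non-CpG cytosine
# per spacer for conversion QC. Spacers are distinct (aperiodic) so alignment
# and merge overlaps are unambiguous; the builder restores the caller's RNG.
make_test_amplicon <- function(n_cpg = 15) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20200502)
  filler <- function() {
    x <- sample(c("A", "T", "G"), 16, replace = TRUE)  # no C: no stray CpG
    x[6] <- "C"; x[7] <- "A"                           # one non-CpG C
    paste(x, collapse = "")
  }
  body <- paste(vapply(seq_len(n_cpg), function(i) paste0("CG", filler()),
                       character(1)), collapse = "")
  amplicon_spec("synthamp", paste0("T", filler(), filler(), body, "TGA"))
}

# GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), ...)
}

# CoverageTrack from explicit bin vectors
make_track <- function(signal, bin_size = 10, state = "recalibrated",
                       total_fragments = 1e6) {
  chrom_sizes <- stats::setNames(lengths(signal) * bin_size, names(signal))
  coverage_track(signal, bin_size, chrom_sizes, state = state,
                 total_fragments = total_fragments)
}

# random read set (sequence + constant quality)
rand_reads <- function(n, len, qual_char = "F") {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  data.frame(id = paste0("r", seq_len(n)), seq = seqs,
             qual = strrep(qual_char, len), stringsAsFactors = FALSE)
}

# quality string from integer Phred scores
qual_str <- function(phreds) intToUtf8(phreds + 33L)

# exhaustive per-position Hamming oracle for the off-target scanner: window
# strings via substring, per-window character comparison (independent of the
# scanner's sliding vectorized implementation)
oracle_scan <- function(seqs, guide, k, pam = "GG") {
  gch <- strsplit(guide, "")[[1]]
  hits <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    L <- nchar(s)
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      for (i in seq_len(max(L - 22, 0))) {
        if (substr(ss, i + 21, i + 22) != pam) next
        win <- strsplit(substr(ss, i, i + 19), "")[[1]]
        if (any(!win %in% c("A", "C", "G", "T"))) next
        if (!substr(ss, i + 20, i + 20) %in% c("A", "C", "G", "T")) next
        mm <- sum(win != gch)
        if (mm <= k) {
          start <- if (strand == "+") i - 1L else L - (i - 1L) - 20L
          hits[[length(hits) + 1L]] <- data.frame(chrom = ch, start = start,
                                                  strand = strand,
                                                  mismatches = mm)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  df <- do.call(rbind, hits)
  df <- df[order(df$chrom, df$start, df$strand), ]
  rownames(df) <- NULL
  df
}
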