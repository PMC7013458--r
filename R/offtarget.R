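# sgRNA off-target enumeration: every genomic 20-mer adjacent to an NGG PAM
# (both strands) within a bounded Hamming distance of the protospacer.

.pam_ok <- function(chars_by_pos, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, length(chars_by_pos[[1]]))
  for (j in seq_along(pat)) {
    cj <- chars_by_pos[[j]]
    ok <- ok & if (pat[j] == "N") cj %in% c("A", "C", "G", "T") else cj == pat[j]
  }
  ok
}

.scan_strand <- function(seq_chars, guide_chars, max_mm, pam) {
  L <- length(seq_chars)
  w <- 20L + nchar(pam)
  np <- L - w + 1L
  if (np < 1L) return(data.frame(start = integer(), mm = integer()))
  idx <- seq_len(np)
  mm <- integer(np)
  valid <- rep(TRUE, np)
  for (j in 1:20) {
    cj <- seq_chars[idx + j - 1L]
    mm <- mm + (cj != guide_chars[j])
    valid <- valid & cj %in% c("A", "C", "G", "T")   # genome Ns never match
  }
  pam_chars <- lapply(seq_len(nchar(pam)),
                      function(j) seq_chars[idx + 19L + j])
  hit <- valid & mm <= max_mm & .pam_ok(pam_chars, pam)
  data.frame(start = idx[hit] - 1L, mm = mm[hit])   # 0-based
}

#' Scan a genome for sgRNA off-target sites
#'
#' Enumerates every position, on both strands, where the 20-mer immediately 5'
#' of a PAM (default NGG; the N position is unconstrained, the rest must match
#' exactly) has Hamming distance at most `max_mismatches` to the protospacer.
#' Bulges (indels) are not modeled. Reverse-strand hits are reported in
#' forward coordinates (0-based start of the 20-mer on the forward strand);
#' the matched 20-mer and PAM are reported on the hit strand.
#'
#' @param genome SyntheticGenome, named character vector of sequences, or a
#'   FASTA path
#' @param guide 20-mer protospacer over ACGT
#' @param max_mismatches maximum Hamming distance (default 4)
#' @param pam PAM pattern 3' of the protospacer, IUPAC N = any base
#' @return data.frame sorted by (chrom, start, strand): `chrom`, `start`
#'   (0-based start of the 20-mer), `strand`, `mismatches`, `site` (hit-strand
#'   20-mer), `pam`
#' @export
scan_offtargets <- function(genome, guide, max_mismatches = 4, pam = "NGG") {
  seqs <- if (inherits(genome, "SyntheticGenome")) genome$seqs
          else if (is.character(genome) && length(genome) == 1L &&
                   file.exists(genome)) read_fasta(genome)
          else genome
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  guide <- toupper(guide)
  if (nchar(guide) != 20L || !grepl("^[ACGT]+$", guide))
    stop("protospacer must be a 20-mer over ACGT", call. = FALSE)
  gch <- strsplit(guide, "")[[1]]
  w <- 20L + nchar(pam)
  out <- list()
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    L <- nchar(s)
    fwd <- strsplit(s, "")[[1]]
    h <- .scan_strand(fwd, gch, max_mismatches, pam)
    if (nrow(h)) {
      h$chrom <- ch; h$strand <- "+"
      h$site <- substring(s, h$start + 1, h$start + 20)
      h$pam <- substring(s, h$start + 21, h$start + w)
      out[[length(out) + 1L]] <- h
    }
    rc <- revcomp(s)
    h <- .scan_strand(strsplit(rc, "")[[1]], gch, max_mismatches, pam)
    if (nrow(h)) {
      h$site <- substring(rc, h$start + 1, h$start + 20)
      h$pam <- substring(rc, h$start + 21, h$start + w)
      h$chrom <- ch; h$strand <- "-"
      h$start <- L - h$start - 20L    # forward 0-based start of the 20-mer
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      site = character(), pam = character()))
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start, df$strand),
           c("chrom", "start", "strand", "mm", "site", "pam")]
  names(df)[4] <- "mismatches"
  rownames(df) <- NULL
  df
}

#' Write off-target hits as TSV and BED6
#'
#' @param hits [scan_offtargets()] result
#' @param prefix output prefix (writes `<prefix>.tsv` and `<prefix>.bed`)
#' @return written paths, invisibly
#' @export
write_offtargets <- function(hits, prefix) {
  p1 <- paste0(prefix, ".tsv")
  write_tsv_table(hits, p1)
  p2 <- paste0(prefix, ".bed")
  if (nrow(hits)) {
    gr <- GenomicRanges::GRanges(hits$chrom,
                                 IRanges::IRanges(hits$start + 1,
                                                  hits$start + 20),
                                 strand = hits$strand,
                                 name = paste0("hit_mm", hits$mismatches),
                                 score = hits$mismatches)
    write_bed(gr, p2)
  } else writeLines(character(0), p2)
  invisible(c(p1, p2))
}
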