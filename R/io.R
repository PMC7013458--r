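#' Read a FASTA file
#'
#' @param path FASTA file (free line wrap)
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path FASTQ file
#' @return data.frame with columns `id`, `seq`, `qual`
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  data.frame(id = unname(names(x)),
             seq = unname(as.character(x)),
             qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned [GenomicRanges::GRanges]
#' follows the usual 1-based closed convention. Columns 4-6 (name, score,
#' strand), when present, become `name`, `score` and the strand.
#'
#' @param path BED3-BED6 file
#' @return GRanges
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED record at line ", bad[1], ": fewer than 3 fields",
         call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop("malformed BED record at line ", bad[1],
         ": start/end not 0-based half-open integers", call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (all(nf >= 4L)) S4Vectors::mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L))
    S4Vectors::mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
  if (all(nf >= 6L)) {
    st <- vapply(fields, `[[`, "", 6L)
    bad <- which(!st %in% c("+", "-", "."))
    if (length(bad))
      stop("malformed BED record at line ", bad[1], ": bad strand", call. = FALSE)
    GenomicRanges::strand(gr) <- sub("\\.", "*", st)
  }
  gr
}

#' Write a GRanges to BED6
#'
#' @param gr GRanges; `name` and `score` metadata columns are used if present
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  nm <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name
        else paste0("region_", seq_len(max(n, 1))[seq_len(n)])
  sc <- if (!is.null(S4Vectors::mcols(gr)$score)) S4Vectors::mcols(gr)$score
        else rep(0, n)
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   nm, sc, st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' Validates the 4-column format and rejects tracks whose intervals overlap
#' (a bedGraph must partition its covered bases).
#'
#' @param path bedGraph file
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `value`
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed bedGraph record at line ", lineno[bad[1]],
         ": expected 4 fields", call. = FALSE)
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = as.numeric(vapply(fields, `[[`, "", 2L)),
                   end = as.numeric(vapply(fields, `[[`, "", 3L)),
                   value = as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) |
                 df$start < 0 | df$end <= df$start)
  if (length(bad))
    stop("malformed bedGraph record at line ", lineno[bad[1]], call. = FALSE)
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    o <- i[order(df$start[i])]
    if (length(o) > 1L) {
      ov <- which(df$start[o][-1] < df$end[o][-length(o)])
      if (length(ov))
        stop("overlapping bedGraph intervals on ", ch, " at line ",
             lineno[o[ov[1] + 1L]], call. = FALSE)
    }
  }
  df
}

#' Write a bedGraph file
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  utils::write.table(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers enforcing the package's TSV dialect (header row, tab
#' separator, no quoting, no row names).
#'
#' @param path file path
#' @return data.frame
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path two-column TSV (chrom, length)
#' @return named numeric vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes needs 2 columns", call. = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}
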