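# Genome-wide MBD-seq style analysis: binned coverage, RPKM, internal top-K
# re-calibration against stably methylated CGIs, CGI classification and
# quantification, differential peak calling, intersections and CGI-centered
# signal matrices.
#
# Coordinates are 0-based half-open throughout this module's track logic
# (BED convention); bin b covers [b*s, (b+1)*s).

#' Coverage track constructor
#'
#' @param signal named list of per-chromosome numeric bin vectors
#' @param bin_size bin width in bp
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param state normalization state: "raw", "rpkm" or "recalibrated"
#' @param total_fragments fragment count backing the track
#' @param scale_factor re-calibration factor applied (1 before recalibration)
#' @return object of class `CoverageTrack`
#' @export
coverage_track <- function(signal, bin_size, chrom_sizes,
                           state = "raw", total_fragments = 0,
                           scale_factor = 1) {
  stopifnot(state %in% c("raw", "rpkm", "recalibrated"),
            all(names(signal) %in% names(chrom_sizes)))
  for (ch in names(signal)) {
    stopifnot(all(signal[[ch]] >= 0),
              length(signal[[ch]]) == ceiling(chrom_sizes[[ch]] / bin_size))
  }
  structure(list(signal = signal, bin_size = bin_size,
                 chrom_sizes = chrom_sizes, state = state,
                 total_fragments = total_fragments,
                 scale_factor = scale_factor),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$signal), "chromosome(s),",
      sum(lengths(x$signal)), "bins of", x$bin_size, "bp;",
      "state =", x$state, "; fragments =", x$total_fragments, "\n")
  invisible(x)
}

# 0-based bin index range covered by a 0-based half-open interval
.bin_range <- function(start, end, bin_size) {
  list(b1 = floor(start / bin_size), b2 = floor((end - 1) / bin_size))
}

#' Bin fragment coverage
#'
#' Each bin's raw signal is the number of fragments overlapping it (half-open
#' overlap).
#'
#' @param fragments GRanges of fragments
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param bin_size bin width in bp (default 10)
#' @return raw-state [coverage_track()]
#' @export
bin_coverage <- function(fragments, chrom_sizes, bin_size = 10) {
  ch <- as.character(GenomicRanges::seqnames(fragments))
  s0 <- GenomicRanges::start(fragments) - 1
  e0 <- GenomicRanges::end(fragments)
  if (any(!ch %in% names(chrom_sizes)) || any(s0 < 0) ||
      any(e0 > chrom_sizes[ch]))
    stop("fragment outside genome bounds", call. = FALSE)
  signal <- lapply(names(chrom_sizes), function(cc) {
    nb <- ceiling(chrom_sizes[[cc]] / bin_size)
    v <- numeric(nb)
    i <- which(ch == cc)
    if (length(i)) {
      br <- .bin_range(s0[i], e0[i], bin_size)
      # difference-array accumulation of [b1, b2] increments
      d <- numeric(nb + 1)
      add <- tabulate(br$b1 + 1, nbins = nb + 1)
      sub <- tabulate(pmin(br$b2 + 2, nb + 1), nbins = nb + 1)
      v <- cumsum(add - sub)[seq_len(nb)]
    }
    v
  })
  names(signal) <- names(chrom_sizes)
  coverage_track(signal, bin_size, chrom_sizes, state = "raw",
                 total_fragments = length(fragments))
}

#' RPKM-normalize a raw coverage track
#'
#' signal = raw * 1e9 / (total_fragments * bin_size): reads per kilobase of
#' bin per million fragments.
#'
#' @param track raw-state CoverageTrack
#' @return rpkm-state CoverageTrack
#' @export
rpkm_normalize <- function(track) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$state != "raw")
    stop("rpkm_normalize expects a raw track", call. = FALSE)
  if (track$total_fragments <= 0)
    stop("cannot RPKM-normalize a track with zero fragments", call. = FALSE)
  f <- 1e9 / (track$total_fragments * track$bin_size)
  track$signal <- lapply(track$signal, function(v) v * f)
  track$state <- "rpkm"
  track
}

#' Mean bin signal per interval
#'
#' Mean of the signals of all bins overlapping each interval (bins weighted
#' equally, as a binned summary tool would).
#'
#' @param track CoverageTrack
#' @param intervals GRanges
#' @return numeric vector of per-interval means
#' @export
quantify_intervals <- function(track, intervals) {
  stopifnot(inherits(track, "CoverageTrack"))
  ch <- as.character(GenomicRanges::seqnames(intervals))
  s0 <- GenomicRanges::start(intervals) - 1
  e0 <- GenomicRanges::end(intervals)
  if (any(e0 <= s0)) stop("zero-length interval", call. = FALSE)
  if (any(!ch %in% names(track$signal)) || any(s0 < 0) ||
      any(e0 > track$chrom_sizes[ch]))
    stop("interval outside genome bounds", call. = FALSE)
  out <- numeric(length(intervals))
  for (cc in unique(ch)) {
    i <- which(ch == cc)
    v <- track$signal[[cc]]
    cs <- c(0, cumsum(v))
    br <- .bin_range(s0[i], e0[i], track$bin_size)
    out[i] <- (cs[br$b2 + 2] - cs[br$b1 + 1]) / (br$b2 - br$b1 + 1)
  }
  out
}

#' Internal re-calibration against the top-K stably methylated CGIs
#'
#' RPKM alone is misleading when treatment creates many new methylated
#' regions: the added pulldown mass dilutes coverage everywhere else, so
#' stably methylated CGIs appear to lose signal. The fix anchors every sample
#' to the reference (untreated) scale: the K most highly methylated CGIs of
#' the reference sample are selected (already fully methylated, so their true
#' signal cannot increase), and each sample is multiplied by
#' `f_i = mean_R(reference) / mean_R(sample_i)` where `mean_R` averages the
#' per-CGI mean signals over that reference set. The reference sample gets
#' `f = 1` exactly.
#'
#' @param tracks named list of rpkm-state CoverageTracks (same bin size and
#'   genome); already-recalibrated tracks are accepted, making re-application
#'   with the same reference set the identity
#' @param cgis GRanges of CGIs
#' @param reference name of the reference (untreated) sample in `tracks`
#' @param k number of reference CGIs (default 1000); ties in the selection are
#'   broken by genomic order
#' @return list with `tracks` (recalibrated), `scale_factors` (named numeric)
#'   and `reference_set` (indices into `cgis`)
#' @export
recalibrate <- function(tracks, cgis, reference = "untreated", k = 1000) {
  stopifnot(is.list(tracks), reference %in% names(tracks))
  if (k < 1 || k > length(cgis))
    stop("k must lie in [1, number of CGIs]", call. = FALSE)
  for (t in tracks) {
    stopifnot(inherits(t, "CoverageTrack"))
    if (!t$state %in% c("rpkm", "recalibrated"))
      stop("recalibrate expects rpkm-state tracks", call. = FALSE)
    stopifnot(t$bin_size == tracks[[reference]]$bin_size)
  }
  ref_means <- quantify_intervals(tracks[[reference]], cgis)
  ord <- order(-ref_means)      # stable: ties resolved by genomic order
  ref_set <- sort(ord[seq_len(k)])
  ref_level <- mean(ref_means[ref_set])
  factors <- vapply(names(tracks), function(nm) {
    if (nm == reference) return(1)
    m <- mean(quantify_intervals(tracks[[nm]], cgis)[ref_set])
    if (m == 0)
      stop("sample '", nm, "' has zero signal over the reference CGI set",
           call. = FALSE)
    ref_level / m
  }, numeric(1))
  out <- tracks
  for (nm in names(tracks)) {
    f <- factors[[nm]]
    out[[nm]]$signal <- lapply(out[[nm]]$signal, function(v) v * f)
    out[[nm]]$state <- "recalibrated"
    out[[nm]]$scale_factor <- f
  }
  list(tracks = out, scale_factors = factors, reference_set = ref_set)
}

#' Two-class split of CGIs into methylated / unmethylated
#'
#' 1-D two-means clustering of per-CGI mean signal on the log1p scale, with
#' deterministic initialization at the 25th and 75th percentiles; the class
#' boundary is the midpoint of the final cluster centers.
#'
#' @param track CoverageTrack (any state)
#' @param cgis GRanges of CGIs (at least 2)
#' @return list with `class` (factor "unmethylated"/"methylated" per CGI),
#'   `boundary` (signal scale), `centers` (log1p scale) and `means`
#' @export
classify_cgis <- function(track, cgis) {
  if (length(cgis) < 2L) stop("need at least 2 CGIs", call. = FALSE)
  means <- quantify_intervals(track, cgis)
  x <- log1p(means)
  if (max(x) == min(x))
    stop("all CGI signals identical: two-class split is degenerate",
         call. = FALSE)
  cen <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (cen[1] == cen[2]) cen <- range(x)
  for (it in seq_len(100)) {
    cl <- ifelse(abs(x - cen[1]) <= abs(x - cen[2]), 1L, 2L)
    new <- c(mean(x[cl == 1L]), mean(x[cl == 2L]))
    if (anyNA(new)) break
    if (isTRUE(all.equal(new, cen))) { cen <- new; break }
    cen <- new
  }
  lab <- factor(ifelse(cl == which.min(cen), "unmethylated", "methylated"),
                levels = c("unmethylated", "methylated"))
  list(class = lab, boundary = expm1(mean(cen)), centers = sort(cen),
       means = means)
}

#' Call new (treatment-gained) peaks from a treated/untreated track pair
#'
#' Peaks are maximal runs of bins where the treated signal reaches the
#' background threshold (a quantile of untreated non-CGI bins) and the
#' differential treated - untreated reaches `min_diff`; runs shorter than
#' `min_width` are discarded, then gaps of at most `merge_gap` are fused.
#'
#' @param treated,untreated recalibrated CoverageTracks
#' @param cgis GRanges of CGIs (excluded from the background quantile)
#' @param background_quantile quantile of untreated non-CGI bins defining the
#'   threshold (default 0.99)
#' @param min_diff minimum differential; defaults to the background threshold
#' @param min_width minimum peak width in bp (default 100)
#' @param merge_gap maximum gap fused between adjacent peaks in bp (default 50)
#' @return GRanges of peaks, sorted and disjoint, with `score` = mean
#'   differential over the peak's bins
#' @export
call_new_peaks <- function(treated, untreated, cgis,
                           background_quantile = 0.99, min_diff = NULL,
                           min_width = 100, merge_gap = 50) {
  stopifnot(inherits(treated, "CoverageTrack"),
            inherits(untreated, "CoverageTrack"))
  if (treated$state != "recalibrated" || untreated$state != "recalibrated")
    stop("call_new_peaks expects recalibrated tracks", call. = FALSE)
  stopifnot(background_quantile > 0, background_quantile < 1)
  bs <- treated$bin_size
  # background = untreated bins not overlapping any CGI
  bg <- unlist(lapply(names(untreated$signal), function(cc) {
    v <- untreated$signal[[cc]]
    mask <- rep(TRUE, length(v))
    i <- which(as.character(GenomicRanges::seqnames(cgis)) == cc)
    if (length(i)) {
      br <- .bin_range(GenomicRanges::start(cgis)[i] - 1,
                       GenomicRanges::end(cgis)[i], bs)
      for (j in seq_along(i))
        mask[(br$b1[j] + 1):min(br$b2[j] + 1, length(v))] <- FALSE
    }
    v[mask]
  }))
  thr <- unname(stats::quantile(bg, background_quantile))
  if (is.null(min_diff)) min_diff <- thr
  res <- list()
  for (cc in names(treated$signal)) {
    tv <- treated$signal[[cc]]; uv <- untreated$signal[[cc]]
    hit <- tv >= thr & (tv - uv) >= min_diff
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & (r$lengths * bs >= min_width)
    if (!any(keep)) next
    b1 <- starts[keep] - 1; b2 <- ends[keep] - 1   # 0-based bin indices
    # fuse runs separated by <= merge_gap bp
    if (length(b1) > 1) {
      gap_bins <- floor(merge_gap / bs)
      grp <- cumsum(c(1, (b1[-1] - b2[-length(b2)] - 1) > gap_bins))
      b1 <- tapply(b1, grp, min); b2 <- tapply(b2, grp, max)
    }
    s0 <- b1 * bs
    e0 <- pmin((b2 + 1) * bs, treated$chrom_sizes[[cc]])
    score <- vapply(seq_along(b1), function(j) {
      idx <- (b1[j] + 1):(b2[j] + 1)
      mean(tv[idx] - uv[idx])
    }, numeric(1))
    res[[cc]] <- data.frame(chrom = cc, start = s0, end = e0, score = score)
  }
  if (!length(res)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, res)
  gr <- GenomicRanges::sort(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, df$end), score = df$score))
  S4Vectors::mcols(gr)$name <- sprintf("peak_%05d", seq_along(gr))
  gr
}

#' Count peak/CGI intersections
#'
#' A peak "is in" an interval set when it overlaps at least 1 bp of any
#' interval.
#'
#' @param peaks GRanges of peaks
#' @param cgis GRanges of all CGIs
#' @param subset GRanges of a CGI subset (e.g. originally unmethylated CGIs)
#' @return list with `n_peaks`, `n_in_cgis`, `n_in_subset` and the overlap
#'   `pairs` (data.frame of peak/CGI index pairs)
#' @export
intersect_counts <- function(peaks, cgis, subset = NULL) {
  if (length(peaks) == 0L)
    return(list(n_peaks = 0L, n_in_cgis = 0L,
                n_in_subset = if (is.null(subset)) NA_integer_ else 0L,
                pairs = data.frame(peak = integer(), cgi = integer())))
  hits <- GenomicRanges::findOverlaps(peaks, cgis)
  n_in_cgis <- length(unique(S4Vectors::queryHits(hits)))
  n_in_subset <- if (is.null(subset)) NA_integer_ else
    sum(GenomicRanges::countOverlaps(peaks, subset) > 0)
  list(n_peaks = length(peaks), n_in_cgis = n_in_cgis,
       n_in_subset = n_in_subset,
       pairs = data.frame(peak = S4Vectors::queryHits(hits),
                          cgi = S4Vectors::subjectHits(hits)))
}

#' Fold reduction of off-target methylation gain
#'
#' Compares the background-subtracted mean MBD signal gained by the wild-type
#' effector over originally unmethylated CGIs with that of a mutant:
#' `fold = (mean_WT - mean_untreated) / (mean_mut - mean_untreated)`.
#'
#' @param wt_means,mut_means,untreated_means per-CGI mean signals over the
#'   originally unmethylated CGIs, one value per CGI
#' @param fold_ceiling value reported when the mutant shows no gain
#' @return list with `fold`, and `capped` (TRUE when the mutant gain was
#'   non-positive and the ceiling was reported)
#' @export
fold_reduction <- function(wt_means, mut_means, untreated_means,
                           fold_ceiling = Inf) {
  stopifnot(length(wt_means) == length(mut_means),
            length(wt_means) == length(untreated_means))
  wt_gain <- mean(wt_means) - mean(untreated_means)
  mut_gain <- mean(mut_means) - mean(untreated_means)
  if (wt_gain <= 0)
    stop("wild-type shows no off-target gain over untreated", call. = FALSE)
  if (mut_gain <= 0)
    return(list(fold = fold_ceiling, capped = TRUE))
  list(fold = wt_gain / mut_gain, capped = FALSE)
}

#' CGI-centered signal matrix
#'
#' One row per CGI: real-coordinate flank bins on both sides and the island
#' body rescaled to a fixed number of columns (length-normalized by
#' nearest-bin lookup). Bins outside the chromosome are NA.
#'
#' @param track CoverageTrack
#' @param cgis GRanges (row order preserved)
#' @param flank flank width in bp, a multiple of the bin size (default 1000)
#' @param body_bins number of columns the CGI body is rescaled to
#' @return numeric matrix, `length(cgis)` rows
#' @export
cgi_matrix <- function(track, cgis, flank = 1000, body_bins = 50) {
  stopifnot(inherits(track, "CoverageTrack"))
  bs <- track$bin_size
  if (flank %% bs != 0)
    stop("flank must be a multiple of the bin size", call. = FALSE)
  fb <- flank / bs
  ncol_out <- 2 * fb + body_bins
  out <- matrix(NA_real_, nrow = length(cgis), ncol = ncol_out)
  ch <- as.character(GenomicRanges::seqnames(cgis))
  s0 <- GenomicRanges::start(cgis) - 1
  e0 <- GenomicRanges::end(cgis)
  for (i in seq_along(cgis)) {
    v <- track$signal[[ch[i]]]
    nb <- length(v)
    get_bin <- function(b) {
      r <- rep(NA_real_, length(b))
      ok <- b >= 0 & b < nb
      r[ok] <- v[b[ok] + 1]
      r
    }
    br <- .bin_range(s0[i], e0[i], bs)
    body <- br$b1:br$b2
    left <- if (fb > 0) (br$b1 - fb):(br$b1 - 1) else integer(0)
    right <- if (fb > 0) (br$b2 + 1):(br$b2 + fb) else integer(0)
    body_rescaled <- body[ceiling(seq_len(body_bins) * length(body) / body_bins)]
    out[i, ] <- get_bin(c(left, body_rescaled, right))
  }
  rownames(out) <- if (!is.null(S4Vectors::mcols(cgis)$cgi_id))
    S4Vectors::mcols(cgis)$cgi_id else NULL
  out
}

#' Export a CoverageTrack as bedGraph
#'
#' Adjacent equal-valued bins are collapsed into runs; zero bins are kept so
#' the track partitions the genome.
#'
#' @param track CoverageTrack
#' @param path output file
#' @return `path`, invisibly
#' @export
track_to_bedgraph <- function(track, path) {
  rows <- lapply(names(track$signal), function(cc) {
    v <- track$signal[[cc]]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    data.frame(chrom = cc, start = starts_bin * track$bin_size,
               end = pmin(ends_bin * track$bin_size, track$chrom_sizes[[cc]]),
               value = r$values)
  })
  write_bedgraph(do.call(rbind, rows), path)
}

#' Load a bedGraph file into a CoverageTrack
#'
#' Accepts externally produced bedGraphs whose intervals align to the bin
#' grid; values fill all bins they span, uncovered bins are 0.
#'
#' @param path bedGraph file
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param bin_size bin width in bp
#' @param state normalization state to record for the loaded track
#' @return CoverageTrack
#' @export
bedgraph_to_track <- function(path, chrom_sizes, bin_size = 10,
                              state = "rpkm") {
  df <- read_bedgraph(path)
  signal <- lapply(names(chrom_sizes), function(cc) {
    nb <- ceiling(chrom_sizes[[cc]] / bin_size)
    v <- numeric(nb)
    i <- which(df$chrom == cc)
    if (length(i)) {
      br <- .bin_range(df$start[i], df$end[i], bin_size)
      for (j in seq_along(i))
        v[(br$b1[j] + 1):(br$b2[j] + 1)] <- df$value[i[j]]
    }
    v
  })
  names(signal) <- names(chrom_sizes)
  coverage_track(signal, bin_size, chrom_sizes, state = state,
                 total_fragments = NA_integer_)
}
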