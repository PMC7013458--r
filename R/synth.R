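# Synthetic genomes, methylomes, bisulfite amplicon reads and MBD-enriched
# fragment sets with known ground truth. The generator emulates the study
# design: a CGI-rich genome split into constitutively methylated and
# unmethylated islands, one unmethylated island carrying the sgRNA target
# site, and treatment conditions in which the effector methylates the target
# strongly while depositing untargeted methylation at accessible off-target
# CGIs in proportion to its free-DNA binding affinity.

.dinucs_non_cg <- c("AA","AC","AG","AT","CA","CC","CT",
                    "GA","GC","GG","GT","TA","TC","TG","TT")

# Random sequence assembled from dinucleotides so the CpG density is
# controlled: each dinucleotide is "CG" with probability cpg_rate.
.gen_seq <- function(n, cpg_rate) {
  k <- ceiling(n / 2)
  is_cg <- stats::runif(k) < cpg_rate
  d <- character(k)
  d[is_cg] <- "CG"
  d[!is_cg] <- sample(.dinucs_non_cg, sum(!is_cg), replace = TRUE)
  substr(paste(d, collapse = ""), 1, n)
}

#' Simulate a CGI-structured genome with a planted sgRNA target site
#'
#' Builds a small genome of alternating background and CpG-island sequence.
#' Each CGI carries a class label: "methylated" islands model constitutively
#' methylated regions, "unmethylated" islands model open promoter CGIs. One
#' unmethylated island is designated the on-target region and the 20-mer
#' protospacer plus PAM is planted inside it at a recorded coordinate.
#'
#' @param n_cgis total number of CGIs
#' @param cgi_width CGI width in bp
#' @param gap background spacer between CGIs in bp
#' @param n_chrom number of chromosomes (CGIs split evenly)
#' @param frac_methylated fraction of CGIs in the methylated class
#' @param cgi_cpg_rate per-dinucleotide CpG probability inside CGIs
#' @param background_cpg_rate per-dinucleotide CpG probability outside CGIs
#' @param protospacer 20-mer sgRNA protospacer planted in the target CGI
#' @param pam PAM trinucleotide planted 3' of the protospacer
#' @param seed integer seed; fully determines the genome
#' @return an object of class `SyntheticGenome`: list with `seqs` (named
#'   uppercase DNA strings), `cgis` (GRanges with `cgi_id` and `class`),
#'   `target` (GRanges of the on-target CGI), `sgrna` (protospacer, pam,
#'   chrom, 0-based start, strand) and `chrom_sizes`
#' @export
simulate_genome <- function(n_cgis = 60, cgi_width = 300, gap = 700,
                            n_chrom = 2, frac_methylated = 0.5,
                            cgi_cpg_rate = 0.25, background_cpg_rate = 0.01,
                            protospacer = "GTTCGCTGCCTCTCAGCCGC",
                            pam = "AGG", seed = 1) {
  stopifnot(n_cgis >= 2, cgi_width >= 50, gap >= 50,
            nchar(protospacer) == 20, grepl("^[ACGT]+$", protospacer),
            nchar(pam) == 3)
  with_seed(derive_seed(seed, "genome"), {
    per <- diff(round(seq(0, n_cgis, length.out = n_chrom + 1)))
    chroms <- paste0("chr", seq_len(n_chrom))
    seqs <- character(n_chrom)
    names(seqs) <- chroms
    cgi_chrom <- character(0); cgi_start <- numeric(0)
    for (ci in seq_len(n_chrom)) {
      parts <- character(2 * per[ci] + 1)
      pos <- 0
      starts <- numeric(per[ci])
      for (j in seq_len(per[ci])) {
        parts[2 * j - 1] <- .gen_seq(gap, background_cpg_rate)
        pos <- pos + gap
        starts[j] <- pos
        parts[2 * j] <- .gen_seq(cgi_width, cgi_cpg_rate)
        pos <- pos + cgi_width
      }
      parts[2 * per[ci] + 1] <- .gen_seq(gap, background_cpg_rate)
      seqs[ci] <- paste(parts, collapse = "")
      cgi_chrom <- c(cgi_chrom, rep(chroms[ci], per[ci]))
      cgi_start <- c(cgi_start, starts)
    }
    n <- length(cgi_chrom)
    cls <- rep("unmethylated", n)
    cls[sample.int(n, round(frac_methylated * n))] <- "methylated"
    # target: one unmethylated CGI, away from the chromosome ends
    unm <- which(cls == "unmethylated")
    if (!length(unm))
      stop("the target must be an unmethylated CGI; lower frac_methylated",
           call. = FALSE)
    target_idx <- unm[ceiling(length(unm) / 2)]
    site <- paste0(protospacer, pam)
    off_in_cgi <- floor((cgi_width - nchar(site)) / 2)
    sg_start <- cgi_start[target_idx] + off_in_cgi  # 0-based
    tchrom <- cgi_chrom[target_idx]
    substr(seqs[tchrom], sg_start + 1, sg_start + nchar(site)) <- site
    cgis <- GenomicRanges::GRanges(
      cgi_chrom, IRanges::IRanges(cgi_start + 1, cgi_start + cgi_width),
      cgi_id = paste0("CGI_", seq_len(n)), class = cls)
    genome <- structure(list(
      seqs = seqs,
      cgis = cgis,
      target = cgis[target_idx],
      target_idx = target_idx,
      sgrna = list(protospacer = protospacer, pam = pam, chrom = tchrom,
                   start = sg_start, strand = "+"),
      chrom_sizes = stats::setNames(nchar(seqs), chroms),
      seed = seed), class = "SyntheticGenome")
    validate_genome(genome)
    genome
  })
}

#' Validate a SyntheticGenome's structural invariants
#'
#' Checks that CGIs lie within their chromosomes and do not overlap, that the
#' target region is exactly one CGI, and that the planted protospacer+PAM is
#' present at its recorded coordinate.
#'
#' @param genome SyntheticGenome
#' @return `genome`, invisibly; errors on violation
#' @export
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  g <- genome$cgis
  for (ch in names(genome$seqs)) {
    i <- as.character(GenomicRanges::seqnames(g)) == ch
    if (any(GenomicRanges::end(g)[i] > nchar(genome$seqs[[ch]])))
      stop("CGI outside chromosome ", ch)
  }
  if (length(GenomicRanges::reduce(g)) != length(g))
    stop("overlapping CGIs")
  if (sum(GenomicRanges::countOverlaps(g, genome$target)) != 1L)
    stop("target region must overlap exactly one CGI")
  sg <- genome$sgrna
  planted <- substr(genome$seqs[[sg$chrom]], sg$start + 1,
                    sg$start + nchar(sg$protospacer) + nchar(sg$pam))
  if (planted != paste0(sg$protospacer, sg$pam))
    stop("planted protospacer+PAM not found at recorded coordinate")
  invisible(genome)
}

#' Enumerate CpG sites of a genome
#'
#' @param genome SyntheticGenome or named character vector of sequences
#' @return data.frame with `chrom`, `pos` (0-based position of the CpG
#'   cytosine on the top strand) and, for a SyntheticGenome, `cgi` (index into
#'   `genome$cgis`, NA outside islands)
#' @export
cpg_sites <- function(genome) {
  seqs <- if (inherits(genome, "SyntheticGenome")) genome$seqs else genome
  out <- lapply(names(seqs), function(ch) {
    m <- gregexpr("CG", seqs[[ch]], fixed = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(chrom = ch, pos = as.integer(m) - 1L)
  })
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(chrom = character(), pos = integer())
  if (inherits(genome, "SyntheticGenome") && nrow(df)) {
    sites <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos + 1,
                                                               df$pos + 2))
    hit <- GenomicRanges::findOverlaps(sites, genome$cgis, select = "first")
    df$cgi <- hit
  }
  df
}

#' Simulate ground-truth methylomes for untreated and treated conditions
#'
#' Untreated baseline: CpGs in methylated-class CGIs draw their methylation
#' probability from `Beta(beta_meth)` (high), all other CpGs from
#' `Beta(beta_unmeth)` (near zero). Treatment with an effector of relative
#' untargeted DNA-binding affinity `theta` sets every non-blocked target-CGI
#' CpG to `p_on` and raises each unmethylated off-target CGI `r` by
#' `theta * a_r * p_max`, where `a_r ~ Beta(beta_access)` is the island's
#' chromatin accessibility. CpGs under the dCas9-sgRNA footprint (the planted
#' protospacer) are blocked and keep their untreated baseline.
#'
#' @param genome SyntheticGenome
#' @param theta relative untargeted DNA-binding affinity of the effector, in
#'   (0, 1]; 1 for the wild-type enzyme
#' @param p_on methylation probability installed at non-blocked target CpGs
#' @param p_max maximal off-target gain at a fully accessible island
#' @param seed integer seed
#' @param accessibility optional per-CGI accessibility vector in \[0,1\]
#'   (recycled); drawn from `Beta(beta_access)` when NULL
#' @param beta_meth,beta_unmeth,beta_access shape parameters of the baseline
#'   and accessibility Beta distributions
#' @return object of class `MethylomeTruth`: list with `sites` (data.frame:
#'   chrom, pos, cgi, class, blocked, untreated, treated), `accessibility`,
#'   and the parameters
#' @export
simulate_methylome <- function(genome, theta = 1, p_on = 0.85, p_max = 0.6,
                               seed = 1, accessibility = NULL,
                               beta_meth = c(20, 2), beta_unmeth = c(1, 30),
                               beta_access = c(2, 2)) {
  stopifnot(inherits(genome, "SyntheticGenome"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    stop("theta must lie in (0, 1]", call. = FALSE)
  stopifnot(p_on >= 0, p_on <= 1, p_max >= 0, p_max <= 1)
  df <- cpg_sites(genome)
  n_cgi <- length(genome$cgis)
  cls <- S4Vectors::mcols(genome$cgis)$class
  with_seed(derive_seed(seed, "methylome"), {
    df$class <- ifelse(is.na(df$cgi), "background", cls[df$cgi])
    base <- stats::rbeta(nrow(df), beta_unmeth[1], beta_unmeth[2])
    im <- df$class == "methylated"
    base[im] <- stats::rbeta(sum(im), beta_meth[1], beta_meth[2])
    df$untreated <- base
    if (is.null(accessibility))
      accessibility <- stats::rbeta(n_cgi, beta_access[1], beta_access[2])
    accessibility <- rep_len(accessibility, n_cgi)
    stopifnot(all(accessibility >= 0 & accessibility <= 1))
    sg <- genome$sgrna
    df$blocked <- df$chrom == sg$chrom &
      df$pos >= sg$start & df$pos <= sg$start + 19
    treated <- base
    on_t <- !is.na(df$cgi) & df$cgi == genome$target_idx
    treated[on_t & !df$blocked] <- p_on
    off_t <- !is.na(df$cgi) & df$cgi != genome$target_idx &
      df$class == "unmethylated"
    treated[off_t] <- pmin(1, base[off_t] +
                             theta * accessibility[df$cgi[off_t]] * p_max)
    df$treated <- treated
    structure(list(sites = df, accessibility = accessibility,
                   theta = theta, p_on = p_on, p_max = p_max, seed = seed),
              class = "MethylomeTruth")
  })
}

#' Simulation parameter set
#'
#' Bundles the sequencing / enrichment parameters with validation. Defaults
#' mirror the study conditions: 2 x 250 paired-end reads over a ~292 bp
#' amplicon, bisulfite conversion above 99.5%, and a small per-methylated-CpG
#' MBD capture probability.
#'
#' @param conversion_rate probability an unmethylated C reads as T
#' @param inappropriate_conversion probability a methylated C reads as T
#' @param sequencing_error_rate per-base substitution error probability
#' @param read_length read length in bp
#' @param n_read_pairs number of amplicon read pairs
#' @param fragment_mean,fragment_sd MBD fragment length distribution (bp)
#' @param n_fragments number of retained MBD fragments to emit
#' @param mbd_capture_q per-methylated-CpG capture probability
#' @param lowq_tail number of 3' bases given quality 2 (tests the
#'   quality-trimming path); 0 for constant Q37
#' @param seed integer seed; fully determines all outputs
#' @return list of class `SimulationParams`
#' @export
sim_params <- function(conversion_rate = 0.998, inappropriate_conversion = 0.002,
                       sequencing_error_rate = 0.001, read_length = 250,
                       n_read_pairs = 5000, fragment_mean = 150,
                       fragment_sd = 30, n_fragments = 50000,
                       mbd_capture_q = 0.1, lowq_tail = 0, seed = 1) {
  p <- list(conversion_rate = conversion_rate,
            inappropriate_conversion = inappropriate_conversion,
            sequencing_error_rate = sequencing_error_rate,
            read_length = as.integer(read_length),
            n_read_pairs = as.integer(n_read_pairs),
            fragment_mean = fragment_mean, fragment_sd = fragment_sd,
            n_fragments = as.integer(n_fragments),
            mbd_capture_q = mbd_capture_q, lowq_tail = as.integer(lowq_tail),
            seed = seed)
  probs <- c(conversion_rate, inappropriate_conversion, sequencing_error_rate,
             mbd_capture_q)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p$n_read_pairs <= 0 || p$n_fragments <= 0 || p$read_length <= 0)
    stop("n_read_pairs, n_fragments and read_length must be positive",
         call. = FALSE)
  structure(p, class = "SimulationParams")
}

# substitute bases at random positions of a character matrix of bases
.apply_seq_errors <- function(mat, rate) {
  if (rate <= 0) return(mat)
  hit <- which(stats::runif(length(mat)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    # shift each hit base by 1-3 positions in the alphabet: always a different base
    shift <- sample.int(3, length(hit), replace = TRUE)
    idx <- match(mat[hit], alt)
    idx[is.na(idx)] <- 1L
    mat[hit] <- alt[((idx - 1L + shift) %% 4L) + 1L]
  }
  mat
}

#' Simulate paired bisulfite amplicon reads (top strand)
#'
#' Each read pair covers one copy of the amplicon. Per copy, every CpG
#' cytosine is methylated with its site probability; unmethylated cytosines
#' (CpG and non-CpG) convert to T with `conversion_rate`, methylated ones with
#' `inappropriate_conversion`; sequencing errors are applied last. Mate 1 is
#' the 5' end of the converted top strand, mate 2 the reverse complement of
#' the 3' end (sequencer orientation). Qualities are constant Q37, optionally
#' with a planted low-quality 3' tail.
#'
#' @param amplicon [amplicon_spec()] object
#' @param site_probs methylation probability per amplicon CpG (recycled to the
#'   number of CpGs)
#' @param params [sim_params()] object
#' @return list with data.frames `r1`, `r2` (columns id, seq, qual) and the
#'   number of pairs
#' @export
simulate_bisulfite_reads <- function(amplicon, site_probs, params = sim_params()) {
  stopifnot(inherits(amplicon, "AmpliconSpec"),
            inherits(params, "SimulationParams"))
  L <- nchar(amplicon$sequence)
  RL <- params$read_length
  if (L < RL)
    stop("amplicon (", L, " bp) shorter than read_length (", RL, " bp)",
         call. = FALSE)
  ncpg <- length(amplicon$cpg_offsets)
  site_probs <- rep_len(site_probs, ncpg)
  stopifnot(all(site_probs >= 0 & site_probs <= 1))
  with_seed(derive_seed(params$seed, "bisreads"), {
    n <- params$n_read_pairs
    a <- strsplit(amplicon$sequence, "")[[1]]
    c_pos <- which(a == "C")
    cpg_c <- amplicon$cpg_offsets          # 1-based offsets of CpG cytosines
    noncpg_c <- setdiff(c_pos, cpg_c)
    M <- matrix(rep(a, each = n), nrow = n)
    # non-CpG cytosines: always unmethylated
    for (j in noncpg_c) {
      conv <- stats::runif(n) < params$conversion_rate
      M[conv, j] <- "T"
    }
    for (k in seq_along(cpg_c)) {
      j <- cpg_c[k]
      meth <- stats::runif(n) < site_probs[k]
      pconv <- ifelse(meth, params$inappropriate_conversion,
                      params$conversion_rate)
      conv <- stats::runif(n) < pconv
      M[conv, j] <- "T"
    }
    m1 <- .apply_seq_errors(M[, seq_len(RL), drop = FALSE],
                            params$sequencing_error_rate)
    m2 <- .apply_seq_errors(M[, (L - RL + 1):L, drop = FALSE],
                            params$sequencing_error_rate)
    r1 <- do.call(paste0, asplit(m1, 2))
    r2 <- revcomp(do.call(paste0, asplit(m2, 2)))
    qual <- strrep(rawToChar(as.raw(37 + 33)), RL)
    if (params$lowq_tail > 0) {
      k <- min(params$lowq_tail, RL)
      qual <- paste0(substr(qual, 1, RL - k), strrep("#", k))
    }
    ids <- sprintf("%s_read_%06d", amplicon$name, seq_len(n))
    list(r1 = data.frame(id = paste0(ids, "/1"), seq = r1, qual = qual,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = paste0(ids, "/2"), seq = r2, qual = qual,
                         stringsAsFactors = FALSE),
         n_pairs = n)
  })
}

#' Simulate an MBD-pulldown enriched fragment set
#'
#' Candidate fragments are drawn uniformly over the genome with Gaussian
#' lengths; a fragment carrying methylated CpGs is captured by the
#' methyl-binding-domain pulldown with probability
#' `1 - (1 - q)^(# methylated CpGs)`, where each CpG on the fragment is
#' methylated independently with its ground-truth probability. The
#' implementation draws retention directly from the exact marginal
#' `1 - prod_i(1 - q * p_i)` over the fragment's CpGs, which is equivalent in
#' distribution. Exactly `n_fragments` retained fragments are returned.
#'
#' @param genome SyntheticGenome
#' @param truth [simulate_methylome()] result
#' @param condition which truth column drives capture ("untreated"/"treated")
#' @param params [sim_params()] object
#' @param bin_size downstream bin size (bp); fragment_mean must be at least
#'   twice this
#' @return GRanges of retained fragments (sorted)
#' @export
simulate_mbd_fragments <- function(genome, truth,
                                   condition = c("treated", "untreated"),
                                   params = sim_params(), bin_size = 10) {
  stopifnot(inherits(genome, "SyntheticGenome"),
            inherits(truth, "MethylomeTruth"),
            inherits(params, "SimulationParams"))
  condition <- match.arg(condition)
  if (params$fragment_mean < 2 * bin_size)
    stop("fragment_mean must be at least twice the bin size", call. = FALSE)
  sites <- truth$sites
  if (nrow(sites) == 0L)
    stop("genome contains no CpGs; MBD enrichment is undefined", call. = FALSE)
  q <- params$mbd_capture_q
  chroms <- names(genome$seqs)
  lens <- genome$chrom_sizes
  # per-chromosome cumulative log(1 - q * p) over sorted CpG positions
  pre <- lapply(chroms, function(ch) {
    i <- sites$chrom == ch
    pos <- sites$pos[i]
    o <- order(pos)
    p <- sites[[condition]][i][o]
    lp <- log1p(-q * p)
    lp[q * p >= 1] <- -700       # certain capture; keep the cumsum finite
    list(pos = pos[o], cum = c(0, cumsum(lp)))
  })
  names(pre) <- chroms
  with_seed(derive_seed(params$seed, paste0("mbd_", condition)), {
    kept_ch <- character(0); kept_s <- numeric(0); kept_e <- numeric(0)
    need <- params$n_fragments
    acc <- NA_real_
    for (iter in seq_len(1000)) {
      m <- if (is.na(acc)) max(20000L, 4L * need)
           else as.integer(min(5e6, ceiling(1.5 * need / max(acc, 1e-4))))
      ch <- sample(chroms, m, replace = TRUE, prob = lens)
      len <- pmax(2 * bin_size, round(stats::rnorm(m, params$fragment_mean,
                                                   params$fragment_sd)))
      len <- pmin(len, lens[ch])
      start <- floor(stats::runif(m) * (lens[ch] - len + 1))
      ret <- numeric(m)
      for (cc in chroms) {
        i <- which(ch == cc)
        if (!length(i)) next
        pp <- pre[[cc]]
        lo <- findInterval(start[i] - 1, pp$pos)
        hi <- findInterval(start[i] + len[i] - 1, pp$pos)
        ret[i] <- 1 - exp(pp$cum[hi + 1] - pp$cum[lo + 1])
      }
      if (is.na(acc)) {
        acc <- mean(ret)
        if (acc == 0)
          stop("no fragment can be captured: methylome carries no methylated CpGs",
               call. = FALSE)
      }
      keep <- stats::runif(m) < ret
      kept_ch <- c(kept_ch, ch[keep])
      kept_s <- c(kept_s, start[keep])
      kept_e <- c(kept_e, start[keep] + len[keep])
      if (length(kept_ch) >= need) break
    }
    if (length(kept_ch) < need)
      stop("could not retain ", need, " fragments (capture probability too low)",
           call. = FALSE)
    gr <- GenomicRanges::GRanges(kept_ch[seq_len(need)],
                                 IRanges::IRanges(kept_s[seq_len(need)] + 1,
                                                  kept_e[seq_len(need)]))
    S4Vectors::mcols(gr)$name <- sprintf("frag_%06d", seq_len(need))
    GenomicRanges::sort(gr)
  })
}

#' Write a ground-truth methylome table
#'
#' @param truth MethylomeTruth
#' @param path output TSV (chrom, pos, condition, probability)
#' @return `path`, invisibly
#' @export
write_truth_table <- function(truth, path) {
  s <- truth$sites
  long <- rbind(
    data.frame(chrom = s$chrom, pos = s$pos, condition = "untreated",
               probability = s$untreated),
    data.frame(chrom = s$chrom, pos = s$pos, condition = "treated",
               probability = s$treated))
  write_tsv_table(long, path)
}
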