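# brute-force O(n*m) interval/bin overlap oracle used across this file
overlaps0 <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

test_that("bin_coverage counts fragments overlapping each bin", {
  cs <- c(chr1 = 1000)
  # one 150 bp fragment aligned to bin boundaries covers exactly 15 bins
  tr <- bin_coverage(gr0("chr1", 200, 350), cs, 10)
  expect_equal(sum(tr$signal$chr1 > 0), 15L)
  expect_equal(unique(tr$signal$chr1[21:35]), 1)
  # empty fragment set gives an all-zero track
  tr0 <- bin_coverage(GenomicRanges::GRanges(), cs, 10)
  expect_true(all(tr0$signal$chr1 == 0))
  expect_error(bin_coverage(gr0("chr1", 990, 1010), cs, 10), "bounds")
})

test_that("bin_coverage equals the brute-force per-bin overlap oracle", {
  set.seed(41)
  cs <- c(chrA = 2000, chrB = 1500)
  n <- 300
  ch <- sample(names(cs), n, replace = TRUE)
  len <- sample(20:180, n, replace = TRUE)
  s0 <- floor(runif(n) * (cs[ch] - len))
  frags <- gr0(ch, s0, s0 + len)
  tr <- bin_coverage(frags, cs, 10)
  for (cc in names(cs)) {
    nb <- cs[[cc]] / 10
    oracle <- vapply(seq_len(nb) - 1, function(b) {
      i <- ch == cc
      sum(overlaps0(s0[i], s0[i] + len[i], b * 10, (b + 1) * 10))
    }, numeric(1))
    expect_equal(tr$signal[[cc]], oracle)
  }
})

test_that("RPKM normalization follows the formula and its invariances", {
  cs <- c(chr1 = 100)
  raw <- coverage_track(list(chr1 = c(1, rep(0, 9))), 10, cs,
                        total_fragments = 1e6)
  rp <- rpkm_normalize(raw)
  expect_equal(rp$signal$chr1[1], 100)          # 1e9 / (1e6 * 10)
  expect_equal(rp$state, "rpkm")
  # doubling counts and total fragments leaves RPKM unchanged
  raw2 <- coverage_track(list(chr1 = c(2, rep(0, 9))), 10, cs,
                         total_fragments = 2e6)
  expect_equal(rpkm_normalize(raw2)$signal, rp$signal)
  # arbitrary track matches direct bin-by-bin evaluation
  set.seed(2)
  v <- rpois(50, 4)
  raw3 <- coverage_track(list(chr1 = v), 10, c(chr1 = 500),
                         total_fragments = 12345)
  expect_equal(rpkm_normalize(raw3)$signal$chr1, v * 1e9 / (12345 * 10))
  expect_error(rpkm_normalize(rp), "raw")
  expect_error(rpkm_normalize(coverage_track(list(chr1 = v), 10,
                                             c(chr1 = 500))), "zero")
})

test_that("quantify_intervals averages the overlapped bins", {
  trk <- make_track(list(chr1 = c(1, 2, 3, 4, 5, 6, 7, 8)), state = "rpkm")
  expect_equal(quantify_intervals(trk, gr0("chr1", 0, 80)), mean(1:8))
  # interval covering bins 2-4 (values 3,4,5): bins weighted equally
  expect_equal(quantify_intervals(trk, gr0("chr1", 25, 42)), 4)
  cst <- make_track(list(chr1 = rep(7, 20)))
  expect_equal(quantify_intervals(cst, gr0("chr1", c(3, 50), c(40, 199))),
               c(7, 7))
  expect_error(quantify_intervals(trk, gr0("chr1", 10, 10)), "zero-length")
  # random tracks match a per-bin averaging oracle
  set.seed(43)
  v <- runif(200)
  trk2 <- make_track(list(chr1 = v))
  s0 <- sample(0:1900, 25); e0 <- pmin(s0 + sample(10:300, 25, TRUE), 2000)
  got <- quantify_intervals(trk2, gr0("chr1", s0, e0))
  oracle <- mapply(function(s, e) {
    bins <- which(overlaps0((seq_len(200) - 1) * 10, seq_len(200) * 10, s, e))
    mean(v[bins])
  }, s0, e0)
  expect_equal(got, oracle)
})

test_that("recalibration anchors every sample to the reference CGI scale", {
  set.seed(47)
  cgis <- gr0("chr1", seq(0, 990, 50), seq(0, 990, 50) + 30)
  v <- runif(100, 1, 10)
  unt <- make_track(list(chr1 = v), state = "rpkm")
  # identical sample: factor 1, unchanged
  rec <- recalibrate(list(untreated = unt, same = unt), cgis, k = 10)
  expect_equal(unname(rec$scale_factors), c(1, 1))
  expect_equal(rec$tracks$same$signal, unt$signal)
  # doubled sample: factor 0.5, recalibrated equals untreated
  dbl <- make_track(list(chr1 = 2 * v), state = "rpkm")
  rec2 <- recalibrate(list(untreated = unt, dbl = dbl), cgis, k = 10)
  expect_equal(rec2$scale_factors[["dbl"]], 0.5)
  expect_equal(rec2$tracks$dbl$signal$chr1, v)
  # after recalibration the reference-set mean is equal across samples (exact)
  rnd <- make_track(list(chr1 = v * runif(100, 0.2, 5)), state = "rpkm")
  rec3 <- recalibrate(list(untreated = unt, rnd = rnd), cgis, k = 10)
  ref <- rec3$reference_set
  m_ref <- mean(quantify_intervals(rec3$tracks$untreated, cgis)[ref])
  m_rnd <- mean(quantify_intervals(rec3$tracks$rnd, cgis)[ref])
  expect_equal(m_rnd, m_ref)
  # repeated recalibration with the same reference set is idempotent
  rec4 <- recalibrate(rec3$tracks, cgis, k = 10)
  expect_equal(rec4$scale_factors[["rnd"]], 1)
  expect_equal(rec4$tracks$rnd$signal, rec3$tracks$rnd$signal)
  expect_error(recalibrate(list(untreated = unt), cgis, k = 1000), "k must")
  zero <- make_track(list(chr1 = rep(0, 100)), state = "rpkm")
  expect_error(recalibrate(list(untreated = unt, z = zero), cgis, k = 10),
               "zero signal")
})

test_that("CGI two-class split recovers planted partitions", {
  cgis <- gr0("chr1", seq(0, 110, 20), seq(0, 110, 20) + 10)  # 6 one-bin CGIs
  trk <- make_track(list(chr1 = as.numeric(rbind(c(0, 0, 0, 10, 10, 10),
                                                 0))[1:12]), bin_size = 10)
  # signals {0,0,0,10,10,10} -> 3 unmethylated, 3 methylated
  cls <- classify_cgis(trk, cgis)
  expect_equal(as.character(cls$class),
               rep(c("unmethylated", "methylated"), each = 3))
  # a single outlier among equals is isolated into its own class
  trk2 <- make_track(list(chr1 = as.numeric(rbind(c(5, 5, 5, 5, 5, 50),
                                                  0))[1:12]), bin_size = 10)
  cls2 <- classify_cgis(trk2, cgis)
  expect_equal(sum(cls2$class == "methylated"), 1L)
  expect_equal(as.character(cls2$class)[6], "methylated")
  trk3 <- make_track(list(chr1 = rep(3, 12)), bin_size = 10)
  expect_error(classify_cgis(trk3, cgis), "degenerate")
  expect_error(classify_cgis(trk, cgis[1]), "at least 2")
})

test_that("CGI split recovers a planted 40/60 class structure end to end", {
  g <- simulate_genome(n_cgis = 50, frac_methylated = 0.4, seed = 51)
  tr <- simulate_methylome(g, theta = 1, seed = 51)
  fr <- simulate_mbd_fragments(g, tr, "untreated",
                               sim_params(n_fragments = 40000, seed = 51))
  trk <- rpkm_normalize(bin_coverage(fr, g$chrom_sizes, 10))
  cls <- classify_cgis(trk, g$cgis)
  expect_equal(as.character(cls$class), S4Vectors::mcols(g$cgis)$class)
})

test_that("peak calling: null, planted and gap-fusion cases", {
  nb <- 2000
  cgis <- gr0("chr1", 0, 10)      # keep the background definition non-empty
  flat <- make_track(list(chr1 = rep(1, nb)))
  # treated == untreated: zero peaks
  expect_length(call_new_peaks(flat, flat, cgis), 0L)
  # one planted 500 bp gain at 10x amplitude: exactly one matching peak
  v <- rep(1, nb); v[501:550] <- 11
  gain <- make_track(list(chr1 = v))
  pk <- call_new_peaks(gain, flat, cgis)
  expect_length(pk, 1L)
  expect_equal(GenomicRanges::start(pk) - 1L, 5000L)
  expect_equal(GenomicRanges::end(pk), 5500L)
  # two gains separated by less than the merge gap fuse into one peak
  v2 <- rep(1, nb); v2[101:130] <- 11; v2[135:164] <- 11   # 40 bp gap
  pk2 <- call_new_peaks(make_track(list(chr1 = v2)), flat, cgis,
                        merge_gap = 50)
  expect_length(pk2, 1L)
  pk3 <- call_new_peaks(make_track(list(chr1 = v2)), flat, cgis,
                        merge_gap = 30)
  expect_length(pk3, 2L)
  # runs shorter than the minimum width are discarded
  v3 <- rep(1, nb); v3[301:305] <- 11                      # 50 bp < 100 bp
  expect_length(call_new_peaks(make_track(list(chr1 = v3)), flat, cgis), 0L)
  expect_error(call_new_peaks(flat, rpkm_normalize(
    coverage_track(list(chr1 = rep(1, nb)), 10, c(chr1 = nb * 10),
                   total_fragments = 10)), cgis), "recalibrated")
})

test_that("peaks are sorted, disjoint and at least the minimum width", {
  set.seed(53)
  for (rep_i in 1:5) {
    v <- rep(1, 3000)
    n_gain <- sample(3:8, 1)
    starts <- sort(sample(seq(10, 2900, 40), n_gain))
    for (s in starts) v[s:(s + sample(10:60, 1))] <- runif(1, 8, 20)
    pk <- call_new_peaks(make_track(list(chr1 = v)),
                         make_track(list(chr1 = rep(1, 3000))),
                         gr0("chr1", 0, 10))
    if (length(pk) > 1) {
      expect_true(all(diff(GenomicRanges::start(pk)) > 0))
      expect_true(all(GenomicRanges::start(pk)[-1] >
                        GenomicRanges::end(pk)[-length(pk)]))
    }
    expect_true(all(GenomicRanges::width(pk) >= 100))
  }
})

test_that("intersect_counts matches the brute-force overlap oracle", {
  # disjoint sets and exact-equality cases
  p <- gr0("chr1", c(0, 100), c(50, 150))
  cg <- gr0("chr1", c(200, 300), c(250, 350))
  ic <- intersect_counts(p, cg)
  expect_equal(ic$n_in_cgis, 0L)
  expect_equal(intersect_counts(cg, cg)$n_in_cgis, 2L)
  # random sets against O(n*m) enumeration
  set.seed(59)
  ps <- sample(0:5000, 80); pe <- ps + sample(10:400, 80, TRUE)
  cs_ <- sample(0:5000, 60); ce <- cs_ + sample(10:400, 60, TRUE)
  peaks <- GenomicRanges::sort(gr0("chr1", ps, pe))
  cgis <- GenomicRanges::sort(gr0("chr1", cs_, ce))
  sub <- cgis[seq(1, 60, 2)]
  ic2 <- intersect_counts(peaks, cgis, sub)
  ps0 <- GenomicRanges::start(peaks) - 1; pe0 <- GenomicRanges::end(peaks)
  cs0 <- GenomicRanges::start(cgis) - 1; ce0 <- GenomicRanges::end(cgis)
  ss0 <- GenomicRanges::start(sub) - 1; se0 <- GenomicRanges::end(sub)
  n_in <- sum(vapply(seq_along(ps0), function(i)
    any(overlaps0(ps0[i], pe0[i], cs0, ce0)), logical(1)))
  n_sub <- sum(vapply(seq_along(ps0), function(i)
    any(overlaps0(ps0[i], pe0[i], ss0, se0)), logical(1)))
  expect_equal(ic2$n_in_cgis, n_in)
  expect_equal(ic2$n_in_subset, n_sub)
})

test_that("fold_reduction compares background-subtracted gains", {
  expect_equal(fold_reduction(8, 8, 1)$fold, 1.0)
  expect_equal(fold_reduction(8.8, 2, 1)$fold, 7.8)
  fr <- fold_reduction(8, 1, 1)
  expect_true(fr$capped)
  expect_error(fold_reduction(1, 2, 1), "no off-target gain")
})

test_that("cgi_matrix extracts flanks in real coordinates and rescales the body", {
  v <- runif(300)
  trk <- make_track(list(chr1 = v))
  cgis <- gr0("chr1", c(500, 1000), c(700, 1300))
  # constant track gives a constant matrix
  cst <- make_track(list(chr1 = rep(4, 300)))
  m0 <- cgi_matrix(cst, cgis, flank = 100, body_bins = 20)
  expect_true(all(m0 == 4))
  expect_equal(dim(m0), c(2L, 40L))
  # flank 0, one-bin CGI: a repeat of that bin
  m1 <- cgi_matrix(trk, gr0("chr1", 120, 130), flank = 0, body_bins = 10)
  expect_equal(as.numeric(m1), rep(v[13], 10))
  # naive per-row extraction oracle
  m2 <- cgi_matrix(trk, cgis, flank = 100, body_bins = 25)
  for (i in 1:2) {
    s0 <- GenomicRanges::start(cgis)[i] - 1; e0 <- GenomicRanges::end(cgis)[i]
    body <- (s0 / 10 + 1):(e0 / 10)              # 1-based bin ids
    left <- v[(s0 / 10 - 9):(s0 / 10)]
    right <- v[(e0 / 10 + 1):(e0 / 10 + 10)]
    rescaled <- v[body[ceiling((1:25) * length(body) / 25)]]
    expect_equal(unname(m2[i, ]), c(left, rescaled, right))
  }
  # out-of-chromosome flanks become missing values
  m3 <- cgi_matrix(trk, gr0("chr1", 0, 100), flank = 50, body_bins = 5)
  expect_true(all(is.na(m3[1, 1:5])))
  expect_false(anyNA(m3[1, 6:15]))
  expect_error(cgi_matrix(trk, cgis, flank = 15), "multiple")
})

test_that("tracks round-trip through bedGraph", {
  v <- c(rep(0, 5), rep(2.5, 10), rep(0.5, 5))
  trk <- make_track(list(chr1 = v), state = "rpkm")
  path <- tempfile(fileext = ".bedGraph")
  track_to_bedgraph(trk, path)
  back <- bedgraph_to_track(path, c(chr1 = 200), 10, state = "rpkm")
  expect_equal(back$signal$chr1, v)
})
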