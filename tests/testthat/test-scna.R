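tiny_genome <- c(`1` = 10000, `2` = 10000)

test_that("segments rasterize onto windows with length-weighted means", {
  segs <- data.frame(sample_id = "S1", chrom = "1", start = 1L, end = 3000L,
                     log2_ratio = 0.5)
  g <- segments_to_windows(segs, tiny_genome)
  expect_equal(unname(g$values[1:3, 1]), rep(0.5, 3))
  expect_true(all(is.na(g$values[4:10, 1])))      # uncovered: missing, not 0
  expect_true(all(is.na(g$values[g$chrom == "2", 1])))

  # half a window at 1.0, the other half at 0.0 averages to 0.5
  segs2 <- data.frame(sample_id = "S1", chrom = "1",
                      start = c(1L, 501L), end = c(500L, 1000L),
                      log2_ratio = c(1, 0))
  g2 <- segments_to_windows(segs2, tiny_genome)
  expect_equal(unname(g2$values[1, 1]), 0.5)

  out_of_range <- data.frame(sample_id = "S1", chrom = "1", start = 9000L,
                             end = 11000L, log2_ratio = 0)
  expect_error(segments_to_windows(out_of_range, tiny_genome), "beyond")
})

test_that("rasterization conserves the length-weighted chromosome mean", {
  set.seed(55)
  breaks <- sort(sample(seq(500, 9500, by = 500), 6))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, 10000L)
  segs <- data.frame(sample_id = "S1", chrom = "1", start = starts,
                     end = ends, log2_ratio = round(stats::rnorm(7), 3))
  g <- segments_to_windows(segs, tiny_genome)
  chr1 <- g$values[g$chrom == "1", 1]
  want <- sum((ends - starts + 1) * segs$log2_ratio) / 10000
  expect_equal(mean(chr1), want, tolerance = 1e-12)
})

test_that("G-scores average signed parts across samples and flip under negation", {
  v <- cbind(S1 = c(1, 0, -1, NA), S2 = c(0, 0, -0.5, 0.3))
  g <- window_grid(v, c(`1` = 4000))
  gs <- g_scores(g)
  expect_equal(gs$g_amp, c(0.5, 0, 0, 0.3))
  expect_equal(gs$g_del, c(0, 0, 0.75, 0))
  # the NA window uses only the covered sample in its denominator
  expect_equal(gs$n_eff, c(2, 2, 2, 1))

  flipped <- g_scores(window_grid(-v, c(`1` = 4000)))
  expect_equal(flipped$g_amp, gs$g_del)
  expect_equal(flipped$g_del, gs$g_amp)

  zero <- g_scores(window_grid(matrix(0, 4, 3), c(`1` = 4000)))
  expect_true(all(zero$g_amp == 0) && all(zero$g_del == 0))
})

test_that("a planted recurrent amplification is significant; empty grids are not", {
  set.seed(71)
  W <- 500
  S <- 10
  v <- matrix(stats::rnorm(W * S, 0, 0.1), W, S)
  v[101:110, ] <- v[101:110, ] + 1.5
  g <- window_grid(v, c(`1` = W * 1000))
  perm <- permutation_null(g, n_perm = 200, seed = 4)
  expect_true(all(perm$p_amp[101:110] < 0.05))
  regions <- call_regions(perm)
  amp <- regions[regions$direction == "amp", ]
  expect_gte(nrow(amp), 1L)
  expect_true(any(amp$start <= 100001 & amp$end >= 110000))

  flat <- window_grid(matrix(0, 100, 4), c(`1` = 1e5))
  permf <- permutation_null(flat, n_perm = 100, seed = 4)
  expect_equal(nrow(call_regions(permf)), 0L)
  expect_error(permutation_null(flat, n_perm = 50), ">= 100")
})

test_that("regions are maximal significant runs with peaks at the G-score mode", {
  perm <- structure(list(
    g_amp = c(0, 1, 2, 5, 2, 1, 0, 0, 3, 3),
    g_del = rep(0, 10),
    p_amp = c(0.5, 0.01, 0.01, 0.01, 0.01, 0.01, 0.5, 0.5, 0.01, 0.01),
    p_del = rep(0.5, 10),
    sig_amp = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    sig_del = rep(FALSE, 10),
    n_perm = 100L, alpha = 0.05,
    chrom = rep("1", 10), start = (0:9) * 1000, window_size = 1000L
  ), class = "scna_permutation")
  regions <- call_regions(perm)
  expect_equal(nrow(regions), 2L)
  r1 <- regions[1, ]
  expect_equal(r1$start, 1001)
  expect_equal(r1$end, 6000)
  expect_equal(r1$g_score, 5)
  # unimodal G: the peak is the single mode window
  expect_equal(r1$peak_start, 3001)
  expect_equal(r1$peak_end, 4000)
  # two runs separated by a non-significant window stay two regions
  expect_equal(regions$start[2], 8001)

  # a run split across a chromosome boundary is two regions
  perm2 <- perm
  perm2$chrom <- rep(c("1", "2"), each = 5)
  perm2$start <- c((0:4) * 1000, (0:4) * 1000)
  regions2 <- call_regions(perm2)
  expect_true(all(regions2$chrom[1:2] == c("1", "2")))
})

test_that("level classification uses the printed thresholds with boundaries to the milder tier", {
  m <- c(1.2, 0.91, 0.9, 0.5, 0.11, 0.1, 0, -0.1, -0.11, -0.7, -1.3, -1.31, NA)
  expect_equal(level_of(m),
               c(2, 2, 1, 1, 1, 0, 0, 0, -1, -1, -1, -2, NA))

  v <- matrix(c(rep(1.2, 5), rep(0, 5)), ncol = 1)
  colnames(v) <- "S1"
  g <- window_grid(v, c(`1` = 10000))
  regions <- data.frame(region_id = c("r1", "r2"), win_from = c(1, 6),
                        win_to = c(5, 10))
  lv <- classify_levels(regions, g)
  expect_equal(unname(lv[, "S1"]), c(2, 0))
})

test_that("cosine similarity matches hand computations and handles degenerate vectors", {
  lv <- rbind(c(2, 2), c(0, 0), c(-2, -2))
  colnames(lv) <- c("A", "B")
  expect_equal(cosine_similarity(lv, "A", "B"), 1)

  lv2 <- cbind(A = c(2, 0, -2), B = c(-2, 0, 2))
  expect_equal(cosine_similarity(lv2, "A", "B"), -1)

  lv3 <- cbind(A = c(2, 1, 0, 0), B = c(2, 0, 0, -1))
  expect_equal(cosine_similarity(lv3, "A", "B"), 0.8)

  lv4 <- cbind(A = c(0, 0), B = c(1, 2))
  expect_equal(cosine_similarity(lv4, "A", "B"), 0)
  lv5 <- cbind(A = c(NA, NA), B = c(1, 2))
  expect_error(cosine_similarity(lv5, "A", "B"), "no focal region")
})

test_that("cosine similarity is symmetric and unchanged by double-neutral regions", {
  set.seed(61)
  for (i in 1:20) {
    a <- sample(-2:2, 30, replace = TRUE)
    b <- sample(-2:2, 30, replace = TRUE)
    lv <- cbind(A = a, B = b)
    s1 <- cosine_similarity(lv, "A", "B")
    expect_equal(s1, cosine_similarity(lv, "B", "A"))
    lv_pad <- rbind(lv, cbind(A = rep(0, 10), B = rep(0, 10)))
    expect_equal(cosine_similarity(lv_pad, "A", "B"), s1)
    expect_equal(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), s1)
  }
})

test_that("permutation p-values are calibrated on a pure-noise grid", {
  set.seed(91)
  v <- matrix(stats::rnorm(3000 * 4, 0, 0.1), 3000, 4)
  g <- window_grid(v, c(`1` = 1e6, `2` = 1e6, `3` = 1e6))
  perm <- permutation_null(g, n_perm = 200, seed = 8)
  frac <- mean(perm$p_amp < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
  # super-uniformity: P(p <= x) <= x at a few probes
  for (x in c(0.1, 0.25, 0.5)) {
    expect_lte(mean(perm$p_amp <= x), x + 0.05)
  }
})
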