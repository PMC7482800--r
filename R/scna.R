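# GISTIC-like focal SCNA analysis on fixed 1-kb windows: per-window
# G-scores (frequency x amplitude folded into one mean of positive, resp.
# negative, log2 ratios), a circular-shift permutation null, region and
# peak calling, five-tier level classification at the 0.9/0.1/-0.1/-1.3
# thresholds, and cosine similarity of level vectors between samples.

#' Rasterize segments onto a fixed window grid
#'
#' Each window's value is the length-weighted mean of the segments
#' overlapping it; windows with no segment coverage are missing (`NA`),
#' never zero. Window arithmetic is 0-based half-open internally; SEG input
#' is 1-based inclusive.
#'
#' @param segs Validated SEG data.frame (see [read_seg()]); may contain
#'   several samples.
#' @param genome Named vector of chromosome lengths (bp), e.g.
#'   [toy_genome()].
#' @param window_size Window width in bp (default 1000).
#' @return List of class `window_grid`: `genome`, `window_size`, `chrom`
#'   and `start` (0-based) per window, `values` (windows x samples matrix),
#'   `samples`.
#' @export
segments_to_windows <- function(segs, genome, window_size = 1000L) {
  segs <- validate_seg(segs)
  chroms <- names(genome)
  nw <- as.integer(ceiling(genome / window_size))
  offset <- stats::setNames(c(0L, cumsum(nw))[seq_along(nw)], chroms)
  W <- sum(nw)
  win_chrom <- rep(chroms, nw)
  win_start <- unlist(lapply(nw, function(n) (seq_len(n) - 1L) * window_size),
                      use.names = FALSE)
  bad_chrom <- !segs$chrom %in% chroms
  if (any(bad_chrom)) {
    stop("segment chromosome(s) not in genome model: ",
         paste(unique(segs$chrom[bad_chrom]), collapse = ","))
  }
  if (any(segs$end > genome[segs$chrom])) {
    stop("segment(s) extend beyond chromosome length")
  }
  samples <- sort(unique(segs$sample_id))
  values <- matrix(NA_real_, W, length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    num <- numeric(W)
    den <- numeric(W)
    ss <- segs[segs$sample_id == s, , drop = FALSE]
    s0 <- ss$start - 1          # 0-based half-open
    e0 <- as.numeric(ss$end)
    w1 <- floor(s0 / window_size)                  # first window, 0-based
    w2 <- floor((e0 - 1) / window_size)            # last window, 0-based
    n_i <- w2 - w1 + 1
    seg_id <- rep(seq_along(n_i), n_i)
    loc_w <- sequence(n_i, from = w1 + 1)          # 1-based within chrom
    glob_w <- offset[ss$chrom][seg_id] + loc_w
    ov <- pmin(e0[seg_id], loc_w * window_size) -
      pmax(s0[seg_id], (loc_w - 1) * window_size)
    acc <- rowsum(cbind(ov * ss$log2_ratio[seg_id], ov), glob_w)
    idx <- as.integer(rownames(acc))
    num[idx] <- num[idx] + acc[, 1]
    den[idx] <- den[idx] + acc[, 2]
    v <- ifelse(den > 0, num / den, NA_real_)
    values[, s] <- v
  }
  structure(list(genome = genome, window_size = as.integer(window_size),
                 chrom = win_chrom, start = win_start, values = values,
                 samples = samples),
            class = "window_grid")
}

#' Construct a window grid directly from a values matrix
#'
#' Mainly for simulation and calibration studies where per-window copy
#' ratios are generated in memory rather than read from SEG files.
#'
#' @param values Windows x samples numeric matrix (NA = missing).
#' @param genome Named vector of chromosome lengths.
#' @param window_size Window width in bp.
#' @return A `window_grid`.
#' @export
window_grid <- function(values, genome, window_size = 1000L) {
  nw <- as.integer(ceiling(genome / window_size))
  if (nrow(values) != sum(nw)) {
    stop("values has ", nrow(values), " rows; genome implies ", sum(nw), " windows")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  structure(list(genome = genome, window_size = as.integer(window_size),
                 chrom = rep(names(genome), nw),
                 start = unlist(lapply(nw, function(n) (seq_len(n) - 1L) * window_size),
                                use.names = FALSE),
                 values = values, samples = colnames(values)),
            class = "window_grid")
}

#' Per-window amplification and deletion G-scores
#'
#' `g_amp` at a window is the mean over samples of the positive part of the
#' log2 copy ratio (so frequency and amplitude of gain are folded into one
#' number); `g_del` is the mean of the negative part. Samples missing at a
#' window are excluded from that window's denominator; a window missing in
#' every sample gets `NA`.
#'
#' @param grid A `window_grid`.
#' @return List: `g_amp`, `g_del` (per-window vectors), `n_eff` (per-window
#'   non-missing sample count).
#' @export
g_scores <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  v <- grid$values
  present <- !is.na(v)
  pos <- ifelse(present, pmax(v, 0), 0)
  neg <- ifelse(present, pmax(-v, 0), 0)
  n_eff <- rowSums(present)
  g_amp <- ifelse(n_eff > 0, rowSums(pos) / pmax(n_eff, 1), NA_real_)
  g_del <- ifelse(n_eff > 0, rowSums(neg) / pmax(n_eff, 1), NA_real_)
  list(g_amp = g_amp, g_del = g_del, n_eff = n_eff)
}

#' Permutation null for G-scores and per-window significance
#'
#' The null preserves each sample's marginal copy-ratio distribution and
#' spatial autocorrelation: every permutation circularly shifts each
#' sample's window vector by an independent uniform offset within each
#' chromosome, and the per-window G-scores are recomputed. The per-window
#' p-value is `(1 + #null >= observed) / (1 + n_perm)`.
#'
#' @param grid A `window_grid`.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @param alpha Significance threshold recorded in the result (default 0.05).
#' @return List of class `scna_permutation`: observed `g_amp`/`g_del`,
#'   `p_amp`/`p_del`, `sig_amp`/`sig_del` logical vectors, `n_perm`,
#'   `alpha`, and the grid geometry needed by [call_regions()].
#' @export
permutation_null <- function(grid, n_perm = 1000L, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(grid, "window_grid"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  run <- function() {
    v <- grid$values
    W <- nrow(v)
    S <- ncol(v)
    present <- !is.na(v)
    pos <- ifelse(present, pmax(v, 0), 0)
    neg <- ifelse(present, pmax(-v, 0), 0)
    cnt <- present * 1
    obs <- g_scores(grid)
    nw <- as.integer(ceiling(grid$genome / grid$window_size))
    blocks <- split(seq_len(W), rep(seq_along(nw), nw))
    ge_amp <- numeric(W)
    ge_del <- numeric(W)
    for (b in seq_len(n_perm)) {
      sum_pos <- numeric(W); sum_neg <- numeric(W); sum_cnt <- numeric(W)
      for (s in seq_len(S)) {
        idx <- integer(W)
        for (bl in blocks) {
          L <- length(bl)
          off <- sample.int(L, 1L)
          idx[bl] <- bl[((seq_len(L) + off - 1L) %% L) + 1L]
        }
        sum_pos <- sum_pos + pos[idx, s]
        sum_neg <- sum_neg + neg[idx, s]
        sum_cnt <- sum_cnt + cnt[idx, s]
      }
      ok <- sum_cnt > 0
      null_amp <- ifelse(ok, sum_pos / pmax(sum_cnt, 1), 0)
      null_del <- ifelse(ok, sum_neg / pmax(sum_cnt, 1), 0)
      ge_amp <- ge_amp + (null_amp >= obs$g_amp)
      ge_del <- ge_del + (null_del >= obs$g_del)
    }
    p_amp <- ifelse(is.na(obs$g_amp), NA_real_, (1 + ge_amp) / (1 + n_perm))
    p_del <- ifelse(is.na(obs$g_del), NA_real_, (1 + ge_del) / (1 + n_perm))
    structure(list(
      g_amp = obs$g_amp, g_del = obs$g_del,
      p_amp = p_amp, p_del = p_del,
      sig_amp = !is.na(p_amp) & p_amp < alpha,
      sig_del = !is.na(p_del) & p_del < alpha,
      n_perm = as.integer(n_perm), alpha = alpha,
      chrom = grid$chrom, start = grid$start,
      window_size = grid$window_size
    ), class = "scna_permutation")
  }
  if (is.null(seed)) run() else with_private_seed(seed, run())
}

#' Call focal regions and peaks from per-window significance
#'
#' Maximal runs of contiguous significant windows (within one chromosome,
#' per direction) become focal regions. Within each region the peak is the
#' contiguous stretch around the G-score maximum where G stays at or above
#' `peak_frac` of the maximum.
#'
#' @param perm An `scna_permutation` result.
#' @param peak_frac Peak extension fraction of the maximal G (default 0.95).
#' @return data.frame of focal regions: `region_id`, `chrom`, `start`,
#'   `end` (1-based inclusive, window-aligned), `direction` ("amp"/"del"),
#'   `g_score` (region max), `p_value` (region min), `peak_start`,
#'   `peak_end`, `win_from`, `win_to` (global window indices).
#' @export
call_regions <- function(perm, peak_frac = 0.95) {
  stopifnot(inherits(perm, "scna_permutation"))
  ws <- perm$window_size
  one_dir <- function(sig, g, p, direction) {
    sig[is.na(sig)] <- FALSE
    # pasting chrom into the rle key breaks runs at chromosome boundaries
    r <- rle(paste(perm$chrom, sig))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- grepl("TRUE$", r$values)
    out <- list()
    for (k in which(keep)) {
      i1 <- starts[k]; i2 <- ends[k]
      gr <- g[i1:i2]
      gmax <- max(gr, na.rm = TRUE)
      mode_i <- which.max(gr)
      lo <- mode_i
      while (lo > 1L && !is.na(gr[lo - 1L]) && gr[lo - 1L] >= peak_frac * gmax) lo <- lo - 1L
      hi <- mode_i
      while (hi < length(gr) && !is.na(gr[hi + 1L]) && gr[hi + 1L] >= peak_frac * gmax) hi <- hi + 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = perm$chrom[i1],
        start = perm$start[i1] + 1L,
        end = perm$start[i2] + ws,
        direction = direction,
        g_score = gmax,
        p_value = min(p[i1:i2], na.rm = TRUE),
        peak_start = perm$start[i1 + lo - 1L] + 1L,
        peak_end = perm$start[i1 + hi - 1L] + ws,
        win_from = i1, win_to = i2,
        stringsAsFactors = FALSE
      )
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  amp <- one_dir(perm$sig_amp, perm$g_amp, perm$p_amp, "amp")
  del <- one_dir(perm$sig_del, perm$g_del, perm$p_del, "del")
  regions <- rbind(amp, del)
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), direction = character(0),
                          g_score = numeric(0), p_value = numeric(0),
                          peak_start = integer(0), peak_end = integer(0),
                          win_from = integer(0), win_to = integer(0),
                          stringsAsFactors = FALSE)
  }
  if (nrow(regions)) {
    regions <- regions[order(regions$direction, regions$chrom, regions$start), ,
                       drop = FALSE]
    regions$region_id <- paste0(regions$direction, "_", regions$chrom, ":",
                                regions$start, "-", regions$end)
  } else {
    regions$region_id <- character(0)
  }
  rownames(regions) <- NULL
  regions[, c("region_id", "chrom", "start", "end", "direction", "g_score",
              "p_value", "peak_start", "peak_end", "win_from", "win_to")]
}

#' Five-tier copy-aberration level classification per region per sample
#'
#' The level is determined solely by the region's mean log2 copy ratio `m`
#' in that sample: `+2` (high amplification) if `m > 0.9`; `+1` (low) if
#' `0.1 < m <= 0.9`; `0` (neutral) if `-0.1 <= m <= 0.1`; `-1` (low
#' deletion) if `-1.3 <= m < -0.1`; `-2` (high deletion) if `m < -1.3`.
#' The printed thresholds leave the exact boundary values unassigned;
#' boundaries are assigned to the less extreme tier. Regions with no
#' covered window in a sample get `NA`.
#'
#' @param regions Focal-region data.frame from [call_regions()] (or any
#'   data.frame with `region_id`, `win_from`, `win_to`).
#' @param grid The `window_grid` the regions were called on.
#' @return Numeric regions x samples matrix of levels in
#'   `{-2, -1, 0, 1, 2}` with `region_id` rownames.
#' @export
classify_levels <- function(regions, grid) {
  stopifnot(inherits(grid, "window_grid"))
  lv <- matrix(NA_real_, nrow(regions), ncol(grid$values),
               dimnames = list(regions$region_id, grid$samples))
  for (i in seq_len(nrow(regions))) {
    vals <- grid$values[regions$win_from[i]:regions$win_to[i], , drop = FALSE]
    m <- colMeans(vals, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    lv[i, ] <- level_of(m)
  }
  lv
}

#' Map mean log2 ratios to numeric aberration levels
#' @param m Numeric vector of mean log2 copy ratios.
#' @return Numeric levels in `{-2,-1,0,1,2}` (`NA` preserved).
#' @export
level_of <- function(m) {
  out <- rep(NA_real_, length(m))
  ok <- !is.na(m)
  out[ok & m > 0.9] <- 2
  out[ok & m > 0.1 & m <= 0.9] <- 1
  out[ok & m >= -0.1 & m <= 0.1] <- 0
  out[ok & m >= -1.3 & m < -0.1] <- -1
  out[ok & m < -1.3] <- -2
  out
}

#' Cosine similarity of two samples' focal-SCNA level vectors
#'
#' Computed over the regions with non-missing levels in both samples
#' (amplification and deletion regions concatenated, as supplied). If
#' either restricted vector is all zero (no aberration in the compared
#' regions) the similarity is defined as 0.
#'
#' @param levels Regions x samples level matrix from [classify_levels()].
#' @param sample_a,sample_b Column names (or indices) to compare.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(levels, sample_a, sample_b) {
  va <- levels[, sample_a]
  vb <- levels[, sample_b]
  keep <- !is.na(va) & !is.na(vb)
  if (!any(keep)) stop("no focal region with levels in both samples")
  va <- va[keep]; vb <- vb[keep]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}
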