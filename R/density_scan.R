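#' Per-site pileup of covering and unmatched reads
#'
#' For every reference site, `d` counts reads whose aligned span covers the
#' site and `u` counts covering reads carrying an unmatched base there.
#' "Unmatched" covers four kinds of CIGAR evidence: an aligned base differing
#' from the reference, a site spanned by a deletion op, the site immediately
#' before an insertion op, and the single aligned site adjacent to a soft clip
#' (clipped bases themselves contribute to neither `u` nor `d`).
#'
#' @param aln alignment data frame (see [read_alignments()]), position-sorted.
#' @param reference reference sequence (character string).
#' @param region optional `c(start, end)` restricting the output.
#' @return data frame with columns `pos`, `d`, `u` (one row per site).
#' @export
build_pileup <- function(aln, reference, region = NULL) {
  L <- nchar(reference)
  if (is.null(region)) region <- c(1L, L)
  if (is.unsorted(aln$pos)) stop("alignments must be sorted by position", call. = FALSE)
  ref_raw <- charToRaw(reference)
  cov_diff <- integer(L + 1L)
  u_all <- vector("list", nrow(aln))
  cigs <- parse_cigars(aln)
  for (i in seq_len(nrow(aln))) {
    cg <- cigs[[i]]
    if (cg$rend > L) stop("alignment beyond reference end", call. = FALSE)
    s <- aln$pos[i]; e <- cg$rend
    cov_diff[s] <- cov_diff[s] + 1L
    cov_diff[e + 1L] <- cov_diff[e + 1L] - 1L
    u <- integer(0)
    mi <- which(cg$op %in% c("M", "=", "X"))
    if (length(mi)) {
      rp <- sequence(cg$len[mi], from = cg$rstart[mi])
      qp <- sequence(cg$len[mi], from = cg$qstart[mi])
      qraw <- charToRaw(aln$seq[i])
      u <- rp[ref_raw[rp] != qraw[qp]]
    }
    di <- which(cg$op == "D")
    if (length(di)) u <- c(u, sequence(cg$len[di], from = cg$rstart[di]))
    ii <- which(cg$op == "I")
    if (length(ii)) u <- c(u, pmax(cg$rstart[ii] - 1L, s))
    si <- which(cg$op == "S")
    if (length(si)) {
      # left clip -> first aligned site; right clip -> last aligned site
      u <- c(u, ifelse(cg$qstart[si] == 1L, s, e))
    }
    u_all[[i]] <- unique(u)
  }
  d <- cumsum(cov_diff[seq_len(L)])
  u_pos <- unlist(u_all, use.names = FALSE)
  u_pos <- u_pos[u_pos >= 1L & u_pos <= L]
  u <- tabulate(u_pos, L)
  sel <- region[1]:region[2]
  data.frame(pos = sel, d = d[sel], u = pmin(u[sel], d[sel]))
}

#' Unmatched-base proportion at a site
#'
#' Returns `u / d`, and 0 at zero depth (absence of reads is not evidence of
#' variation).
#'
#' @param site a row of [build_pileup()] output (or any list with `u`, `d`).
#' @export
unmatched_proportion <- function(site) {
  ifelse(site$d == 0, 0, site$u / site$d)
}

#' Gaussian window weights
#'
#' Discretized standard-normal weights over offsets
#' `-windows_len .. windows_len`: raw weight at offset t is
#' `(3/windows_len) * dnorm(3 t / windows_len)`, i.e. the kernel truncated at
#' three standard deviations. The raw sum is the Riemann approximation of the
#' normal mass on `[-3, 3]` (about 0.997); by default the vector is
#' renormalized to sum to exactly 1, which makes the all-mutated window score
#' exactly 1.
#'
#' @param windows_len half-window size in sites (>= 1).
#' @param renormalize renormalize to unit sum (default) or keep raw weights.
#' @return object of class `window_weights`: list with `windows_len`,
#'   `weights` (length `2*windows_len+1`) and `raw_sum`.
#' @export
weight_vector <- function(windows_len, renormalize = TRUE) {
  stop_if_not_scalar_count(windows_len, "windows_len")
  if (windows_len < 1) stop("windows_len must be >= 1", call. = FALSE)
  off <- seq.int(-windows_len, windows_len)
  w <- (3 / windows_len) * stats::dnorm(3 * off / windows_len)
  raw_sum <- sum(w)
  if (renormalize) w <- w / raw_sum
  structure(list(windows_len = as.integer(windows_len), weights = w,
                 raw_sum = raw_sum), class = "window_weights")
}

#' Variation score track
#'
#' Per-site Gaussian-weighted average of unmatched-base proportions: the score
#' at site c is the weight dot product of p over the window
#' `c - windows_len .. c + windows_len`. At contig edges the window is
#' truncated and the weights renormalized over the available offsets, so
#' scores stay in `[0, 1]`.
#'
#' @param pileups [build_pileup()] output, contiguous in position.
#' @param weights a [weight_vector()].
#' @param contig contig name stored in the track.
#' @return object of class `score_track`: list with `contig`, `start`,
#'   `scores`, and (after [smooth_track()]) `smooth_scores` and `win`.
#' @export
score_track <- function(pileups, weights, contig = "sim1") {
  stopifnot(inherits(weights, "window_weights"))
  if (nrow(pileups) > 1 && any(diff(pileups$pos) != 1L))
    stop("pileups must be contiguous in position", call. = FALSE)
  p <- unmatched_proportion(pileups)
  n <- length(p)
  w <- weights$weights
  wl <- weights$windows_len
  if (n <= 2L * wl) {
    scores <- vapply(seq_len(n), function(c) {
      k <- max(1L, c - wl):min(n, c + wl)
      ww <- w[k - c + wl + 1L]
      sum(ww * p[k]) / sum(ww)
    }, numeric(1))
  } else {
    num <- stats::filter(p, w, sides = 2)
    scores <- as.numeric(num)
    edge <- c(seq_len(wl), (n - wl + 1L):n)
    for (c in edge) {
      k <- max(1L, c - wl):min(n, c + wl)
      ww <- w[k - c + wl + 1L]
      scores[c] <- sum(ww * p[k]) / sum(ww)
    }
  }
  structure(list(contig = contig, start = pileups$pos[1L],
                 scores = pmin(pmax(scores, 0), 1),
                 smooth_scores = NULL, win = NULL),
            class = "score_track")
}

#' Smooth a score track
#'
#' Centered moving average with half-window `win` and divisor `2*win+1`;
#' truncated windows at the edges use the actual site count as divisor.
#'
#' @param track a [score_track()].
#' @param win smoothing half-window in sites (>= 0); defaults to the scoring
#'   half-window convention of 50 sites.
#' @return the track with `smooth_scores` filled.
#' @export
smooth_track <- function(track, win = 50) {
  stopifnot(inherits(track, "score_track"))
  stop_if_not_scalar_count(win, "win")
  x <- track$scores
  n <- length(x)
  if (win == 0L) {
    track$smooth_scores <- x
  } else {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - win, 1L)
    hi <- pmin(seq_len(n) + win, n)
    track$smooth_scores <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  track$win <- as.integer(win)
  track
}

#' Call candidate regions from a smoothed track
#'
#' Maximal runs of consecutive sites whose smoothed score strictly exceeds
#' `T`; sites scoring exactly `T` break runs. Runs separated by fewer than
#' `merge_gap` sites are merged.
#'
#' @param track a smoothed [score_track()].
#' @param T threshold in (0, 1).
#' @param merge_gap merge regions separated by fewer than this many sites.
#' @return data frame of regions: `contig`, `l`, `r` (1-based inclusive),
#'   `peak_score`, `threshold_used`.
#' @export
call_candidate_regions <- function(track, T = 0.35, merge_gap = 100) {
  stopifnot(inherits(track, "score_track"))
  if (is.null(track$smooth_scores)) stop("track not smoothed yet", call. = FALSE)
  if (!is.numeric(T) || length(T) != 1L || T <= 0 || T >= 1)
    stop("threshold T must lie in (0, 1)", call. = FALSE)
  s <- track$smooth_scores
  above <- s > T
  empty <- data.frame(contig = character(0), l = integer(0), r = integer(0),
                      peak_score = numeric(0), threshold_used = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  l <- starts[r$values]; rr <- ends[r$values]
  if (length(l) > 1L) {
    gap <- l[-1L] - rr[-length(rr)] - 1L
    new_blk <- c(TRUE, gap >= merge_gap)
    blk <- cumsum(new_blk)
    l <- tapply(l, blk, min)
    rr <- tapply(rr, blk, max)
  }
  l <- as.integer(l); rr <- as.integer(rr)
  peak <- vapply(seq_along(l), function(i) max(s[l[i]:rr[i]]), numeric(1))
  off <- track$start - 1L
  data.frame(contig = track$contig, l = l + off, r = rr + off,
             peak_score = peak, threshold_used = T, stringsAsFactors = FALSE)
}
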