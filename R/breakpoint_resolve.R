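#' Collect soft-clip evidence around a candidate region
#'
#' Returns reads whose soft clip of the requested side is strictly longer than
#' `min_clip` bases and whose clip anchor lies within the region extended by
#' `pad` sites. For a right clip the anchor is the reference position of the
#' last aligned base; for a left clip, of the first aligned base.
#'
#' @param aln alignment data frame.
#' @param region list/row with `l`, `r`.
#' @param side `"right_clip"` or `"left_clip"`.
#' @param min_clip minimum clip length (exclusive bound).
#' @param pad extension of the search interval on both sides, in sites.
#' @param cigs optional precomputed [parse_cigars()].
#' @return data frame: `qname`, `side`, `clip_len`, `anchor_pos`, `clipped_seq`.
#' @export
collect_softclips <- function(aln, region, side = c("right_clip", "left_clip"),
                              min_clip = 50, pad = 50, cigs = NULL) {
  side <- match.arg(side)
  if (is.null(cigs)) cigs <- parse_cigars(aln)
  lo <- region$l - pad; hi <- region$r + pad
  out <- list()
  for (i in seq_along(cigs)) {
    cg <- cigs[[i]]
    nop <- length(cg$op)
    if (side == "left_clip") {
      if (cg$op[1L] != "S") next
      clip_len <- cg$len[1L]
      anchor <- aln$pos[i]
      seq_ <- substr(aln$seq[i], 1L, clip_len)
    } else {
      if (cg$op[nop] != "S") next
      clip_len <- cg$len[nop]
      anchor <- cg$rend
      seq_ <- substr(aln$seq[i], nchar(aln$seq[i]) - clip_len + 1L,
                     nchar(aln$seq[i]))
    }
    if (clip_len <= min_clip) next
    if (anchor < lo || anchor > hi) next
    out[[length(out) + 1L]] <- data.frame(
      qname = aln$qname[i], side = side, clip_len = clip_len,
      anchor_pos = anchor, clipped_seq = seq_, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(qname = character(0), side = character(0),
                      clip_len = integer(0), anchor_pos = integer(0),
                      clipped_seq = character(0)))
  do.call(rbind, out)
}

#' Tukey (box-diagram) outlier removal
#'
#' Removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, quartiles by linear
#' interpolation. At least the inter-quartile mass always survives, so the
#' result is never empty.
#'
#' @param values numeric vector (nonempty).
#' @return the retained values, in input order.
#' @export
tukey_filter <- function(values) {
  if (!length(values)) stop("tukey_filter needs at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  values[keep]
}

#' Locate a breakpoint from soft-clip evidence
#'
#' Candidate positions derive from the clip anchors: for the start breakpoint,
#' right-clip anchors + 1 (first deleted base); for the end, left-clip anchors
#' - 1 (last deleted base). Outliers are removed with [tukey_filter()] and the
#' arithmetic mean, rounded half-up, is the estimate. With no evidence the
#' corresponding density-scan region bound is returned flagged low-confidence.
#'
#' @param evidence [collect_softclips()] output for the matching side.
#' @param which `"start"` (uses right clips) or `"end"` (left clips).
#' @param fallback region bound used when evidence is empty.
#' @return list: `position`, `support`, `discarded`, `low_confidence`.
#' @export
locate_breakpoint <- function(evidence, which = c("start", "end"),
                              fallback = NA_integer_) {
  which <- match.arg(which)
  want <- if (which == "start") "right_clip" else "left_clip"
  ev <- evidence[evidence$side == want, , drop = FALSE]
  if (!nrow(ev))
    return(list(position = as.integer(fallback), support = 0L, discarded = 0L,
                low_confidence = TRUE))
  cand <- if (which == "start") ev$anchor_pos + 1L else ev$anchor_pos - 1L
  kept <- tukey_filter(cand)
  list(position = as.integer(round_half_up(mean(kept))),
       support = length(kept), discarded = length(cand) - length(kept),
       low_confidence = FALSE)
}

# ---- exact-anchor alignment -------------------------------------------------

# 2-bit encode every k-mer start position of a sequence; returns integer codes
# (NA where the k-mer would run off the end). k <= 15 keeps codes < 2^31.
kmer_codes <- function(seq, k) {
  b <- seq_to_codes(seq)
  n <- length(b) - k + 1L
  if (n < 1L) return(integer(0))
  code <- numeric(n)
  for (j in 0:(k - 1L)) code <- code + b[(1L + j):(n + j)] * 4^j
  as.integer(code)
}

#' Exact-match anchor alignment
#'
#' Finds maximal exact-match runs between a query and the reference via k-mer
#' seeding: runs are unions of consecutive matching k-mers on a common
#' diagonal, so every maximal exact run of length >= `min_anchor` >= k is
#' recovered. Deterministic; no scoring heuristics.
#'
#' @param query query sequence (character string, length >= `min_anchor`).
#' @param reference reference sequence, or a prebuilt [anchor_index()].
#' @param min_anchor minimum reported run length (>= k).
#' @param k seed k-mer size (<= 15).
#' @return data frame of anchors: `ref_pos`, `query_pos` (1-based run starts),
#'   `run_len`, sorted by `run_len` descending.
#' @export
anchor_align <- function(query, reference, min_anchor = 50, k = 13) {
  if (min_anchor < k) stop("min_anchor must be >= k", call. = FALSE)
  if (nchar(query) < min_anchor)
    stop("query shorter than min_anchor", call. = FALSE)
  idx <- if (inherits(reference, "anchor_index")) reference
         else anchor_index(reference, k)
  k <- idx$k
  qc <- kmer_codes(query, k)
  hit_q <- integer(0); hit_r <- integer(0)
  m <- match(qc, idx$codes_sorted)
  # expand ties: all reference positions sharing the k-mer
  has <- which(!is.na(m))
  for (qi in has) {
    j <- m[qi]
    while (j >= 1L && idx$codes_sorted[j] == qc[qi]) j <- j - 1L
    j <- j + 1L
    while (j <= length(idx$codes_sorted) && idx$codes_sorted[j] == qc[qi]) {
      hit_q <- c(hit_q, qi); hit_r <- c(hit_r, idx$pos_sorted[j])
      j <- j + 1L
    }
  }
  empty <- data.frame(ref_pos = integer(0), query_pos = integer(0),
                      run_len = integer(0))
  if (!length(hit_q)) return(empty)
  diag <- hit_r - hit_q
  o <- order(diag, hit_q)
  dq <- hit_q[o]; dd <- diag[o]
  # consecutive k-mer hits on one diagonal merge into one exact run
  new_run <- c(TRUE, dd[-1L] != dd[-length(dd)] | dq[-1L] != dq[-length(dq)] + 1L)
  run_id <- cumsum(new_run)
  q0 <- dq[new_run]
  r0 <- q0 + dd[new_run]
  len <- tabulate(run_id) + k - 1L
  keep <- len >= min_anchor
  if (!any(keep)) return(empty)
  out <- data.frame(ref_pos = r0[keep], query_pos = q0[keep],
                    run_len = len[keep])
  out[order(-out$run_len), , drop = FALSE]
}

#' Prebuilt k-mer index of a reference for [anchor_align()]
#' @param reference reference sequence.
#' @param k k-mer size (<= 15).
#' @export
anchor_index <- function(reference, k = 13) {
  codes <- kmer_codes(reference, k)
  o <- order(codes)
  structure(list(codes_sorted = codes[o], pos_sorted = o, k = k),
            class = "anchor_index")
}

# chain exact runs within a diagonal band; returns best chain or NULL
chain_anchors <- function(anchors, band = 30L, min_total = 50L) {
  if (!nrow(anchors)) return(NULL)
  d <- anchors$ref_pos - anchors$query_pos
  o <- order(d)
  a <- anchors[o, , drop = FALSE]; d <- d[o]
  grp <- cumsum(c(TRUE, diff(d) > band))
  best <- NULL; best_tot <- -1L
  for (g in unique(grp)) {
    sel <- a[grp == g, , drop = FALSE]
    # merge query overlap: total matched = union of query intervals
    oo <- order(sel$query_pos)
    qs <- sel$query_pos[oo]; qe <- qs + sel$run_len[oo] - 1L
    tot <- 0L; cur_s <- qs[1L]; cur_e <- qe[1L]
    if (length(qs) > 1L) for (i in 2:length(qs)) {
      if (qs[i] <= cur_e + 1L) cur_e <- max(cur_e, qe[i])
      else { tot <- tot + (cur_e - cur_s + 1L); cur_s <- qs[i]; cur_e <- qe[i] }
    }
    tot <- tot + (cur_e - cur_s + 1L)
    if (tot > best_tot) {
      best_tot <- tot
      first <- which.min(sel$query_pos)
      best <- list(query_start = min(sel$query_pos),
                   query_end = max(sel$query_pos + sel$run_len - 1L),
                   ref_start_proj = sel$ref_pos[first] - (sel$query_pos[first] - 1L),
                   matched = tot)
    }
  }
  if (is.null(best) || best$matched < min_total) return(NULL)
  best
}

#' Trace the origin of an inserted fragment
#'
#' Clipped sequences become artificial reads that are mapped back to the
#' reference with the built-in exact-anchor aligner. Per iteration the longest
#' chained matching fragment is placed and masked; the still-unplaced flanks
#' (the artificial reads' own "soft clips") are re-queued for up to
#' `max_iterations`. The reported source is the placement reaching the
#' clip-proximal end of the clipped sequence — the first inserted base for a
#' right clip, the last for a left clip — projected along its diagonal, with
#' the per-read estimates combined by median.
#'
#' @param clips [collect_softclips()] output (either side; both may be mixed).
#' @param reference reference sequence or [anchor_index()].
#' @param min_anchor minimum chained matched length to accept a placement.
#' @param max_iterations re-queue rounds for unmatched flanks.
#' @param k seed size.
#' @param max_reads at most this many clipped reads are traced (longest first).
#' @param max_query clip-proximal bases of each clip used for tracing.
#' @param fastq_path optional path; when given, the artificial reads are also
#'   written there as FASTQ.
#' @return list (`InsertTrace`): `source_locus`, `matched_len`, `iterations`,
#'   `status` ("placed"/"unplaced"), `n_reads_used`.
#' @export
trace_insert_source <- function(clips, reference, min_anchor = 50,
                                max_iterations = 3, k = 13, max_reads = 6,
                                max_query = 2000, fastq_path = NULL) {
  if (!nrow(clips)) stop("need at least one clipped sequence", call. = FALSE)
  idx <- if (inherits(reference, "anchor_index")) reference
         else anchor_index(reference, k)
  # right clips first: their clip-proximal end is the first inserted base
  # exactly, so the diagonal projection is anchored without boundary noise
  o <- order(clips$side != "right_clip", -clips$clip_len)
  clips <- clips[o[seq_len(min(nrow(clips), max_reads))], , drop = FALSE]
  if (!is.null(fastq_path)) {
    arts <- lapply(seq_len(nrow(clips)), function(i)
      list(name = sprintf("clip_%s_%d", clips$qname[i], i),
           seq = clips$clipped_seq[i]))
    write_fastq(arts, fastq_path)
  }
  loci <- integer(0); matched <- integer(0); iters_used <- 0L
  from_right <- logical(0)
  for (i in seq_len(nrow(clips))) {
    side <- clips$side[i]
    s <- clips$clipped_seq[i]
    # keep the clip-proximal portion: the inserted fragment abuts the clip
    if (nchar(s) > max_query)
      s <- if (side == "right_clip") substr(s, 1L, max_query)
           else substr(s, nchar(s) - max_query + 1L, nchar(s))
    qlen <- nchar(s)
    prox <- if (side == "right_clip") 1L else qlen
    segments <- list(c(1L, qlen))
    placements <- list()
    it <- 0L
    while (length(segments) && it < max_iterations) {
      it <- it + 1L
      seg <- segments[[1L]]; segments <- segments[-1L]
      sub <- substr(s, seg[1L], seg[2L])
      if (nchar(sub) < max(min_anchor, k)) next
      anch <- anchor_align(sub, idx, min_anchor = k, k = k)
      ch <- chain_anchors(anch, min_total = min_anchor)
      if (is.null(ch)) next
      # ref_start_proj projects the chain diagonal to the segment start; the
      # segment starts where the previous iteration's placement stopped, i.e.
      # at the boundary of the inserted fragment
      ch$query_start <- ch$query_start + seg[1L] - 1L
      ch$query_end <- ch$query_end + seg[1L] - 1L
      placements[[length(placements) + 1L]] <- ch
      # re-queue unmatched flanks of this segment
      if (ch$query_start - seg[1L] >= min_anchor)
        segments[[length(segments) + 1L]] <- c(seg[1L], ch$query_start - 1L)
      if (seg[2L] - ch$query_end >= min_anchor)
        segments[[length(segments) + 1L]] <- c(ch$query_end + 1L, seg[2L])
    }
    iters_used <- max(iters_used, it)
    if (!length(placements)) next
    # placement nearest the clip-proximal end
    dist <- vapply(placements, function(p)
      min(abs(p$query_start - prox), abs(p$query_end - prox)), numeric(1))
    best <- placements[[which.min(dist)]]
    if (min(dist) > 60) next   # nothing reaches the inserted fragment
    loci <- c(loci, best$ref_start_proj)
    matched <- c(matched, best$matched)
    from_right <- c(from_right, side == "right_clip")
  }
  if (!length(loci))
    return(list(source_locus = NA_integer_, matched_len = 0L,
                iterations = iters_used, status = "unplaced", n_reads_used = 0L))
  use <- if (any(from_right)) from_right else rep(TRUE, length(loci))
  list(source_locus = as.integer(round_half_up(stats::median(loci[use]))),
       matched_len = max(matched), iterations = iters_used,
       status = "placed", n_reads_used = sum(use))
}
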