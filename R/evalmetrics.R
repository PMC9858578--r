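#' Match calls against truth records
#'
#' Greedy one-to-one matching, nearest pairs first: a call matches an
#' unmatched truth record when (optionally) the types agree and both
#' breakpoints lie within `tolerance` bases. Each truth record is matched at
#' most once.
#'
#' @param calls data frame with `vtype`, `start`, `end` (position-sorted).
#' @param truth data frame with `vtype`, `start`, `end` (position-sorted).
#' @param tolerance maximum breakpoint distance in bases.
#' @param require_type require matching variant types.
#' @return list: `tp`, `fp`, `fn`, `call_matched` (truth index per call or
#'   NA), `truth_matched` (logical).
#' @export
match_calls <- function(calls, truth, tolerance = 100, require_type = TRUE) {
  n_c <- nrow(calls); n_t <- nrow(truth)
  call_matched <- rep(NA_integer_, n_c)
  truth_matched <- rep(FALSE, n_t)
  if (n_c && n_t) {
    cand <- list()
    for (i in seq_len(n_c)) for (j in seq_len(n_t)) {
      if (require_type && calls$vtype[i] != truth$vtype[j]) next
      ds <- abs(calls$start[i] - truth$start[j])
      de <- abs(calls$end[i] - truth$end[j])
      if (ds <= tolerance && de <= tolerance)
        cand[[length(cand) + 1L]] <- c(i, j, ds + de)
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand[, 3]), , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (is.na(call_matched[i]) && !truth_matched[j]) {
          call_matched[i] <- j; truth_matched[j] <- TRUE
        }
      }
    }
  }
  tp <- sum(!is.na(call_matched))
  list(tp = tp, fp = n_c - tp, fn = n_t - tp,
       call_matched = call_matched, truth_matched = truth_matched)
}

#' Precision, recall and f-measure of a matching
#'
#' @param matching a [match_calls()] result.
#' @param tolerance recorded in the report.
#' @return data frame (`DetectionReport`): counts plus `precision`, `recall`,
#'   `f_measure` (0 where the denominator is 0).
#' @export
precision_recall_f <- function(matching, tolerance = 100) {
  tp <- matching$tp; fp <- matching$fp; fn <- matching$fn
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  data.frame(true_positives = tp, false_positives = fp, false_negatives = fn,
             precision = precision, recall = recall, f_measure = f,
             match_tolerance = tolerance)
}

#' Switch and mismatch rates of phased blocks against truth
#'
#' Per block the assigned alleles are compared with the truth haplotype under
#' the better global flip. Disagreement runs of length 1 are mismatch errors;
#' longer runs contribute one switch error per run boundary interior to the
#' block (so a flip persisting to the block end is a single switch). Possible
#' switch positions are `sum(n_b - 1)` over blocks with >= 2 variants;
#' possible mismatch positions are all phased variants.
#'
#' @param blocks block list (ids + phase).
#' @param truth_phase named integer vector: truth allele on haplotype 0 for
#'   every phased variant id (1 = alternate allele on haplotype 0).
#' @return list: `switch_rate`, `mismatch_rate`, `switch_errors`,
#'   `mismatch_errors`, `switch_positions`, `mismatch_positions`.
#' @export
switch_mismatch_rates <- function(blocks, truth_phase) {
  sw <- mm <- 0L
  sw_pos <- mm_pos <- 0L
  for (b in blocks) {
    n <- length(b$ids)
    if (n < 1L) next
    if (any(!b$ids %in% names(truth_phase)))
      stop("phased variant missing from truth: ",
           paste(setdiff(b$ids, names(truth_phase)), collapse = ", "),
           call. = FALSE)
    mm_pos <- mm_pos + n
    if (n < 2L) next
    sw_pos <- sw_pos + (n - 1L)
    tr <- truth_phase[b$ids]
    e1 <- b$phase != tr
    e2 <- (1L - b$phase) != tr
    e <- if (sum(e2) < sum(e1)) e2 else e1
    if (!any(e)) next
    r <- rle(as.logical(e))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] == 1L) mm <- mm + 1L
      else {
        interior <- (starts[k] > 1L) + (ends[k] < n)
        sw <- sw + interior
      }
    }
  }
  list(switch_rate = if (sw_pos) sw / sw_pos else 0,
       mismatch_rate = if (mm_pos) mm / mm_pos else 0,
       switch_errors = sw, mismatch_errors = mm,
       switch_positions = sw_pos, mismatch_positions = mm_pos)
}

#' Haplotype-block N50
#'
#' Block spans (last minus first variant position + 1) are sorted descending;
#' N50 is the span at which the cumulative span first reaches half the total.
#'
#' @param blocks block list, or a numeric vector of spans.
#' @return N50 in bases (0 for empty input).
#' @export
block_n50 <- function(blocks) {
  spans <- if (is.numeric(blocks)) blocks
           else vapply(blocks, function(b)
             diff(range(b$pos)) + 1, numeric(1))
  if (!length(spans)) return(0)
  s <- sort(spans, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1L]]
}
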