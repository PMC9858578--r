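#' Emit truth-derived alignments
#'
#' Projects each simulated read onto the reference coordinate system,
#' reconstructing the CIGAR from the planted variants and the read's edit
#' trace. Reads crossing a planted delins are represented the way noisy-read
#' mappers represent them: a mixture of (i) soft-clipping at the nearer
#' breakpoint, (ii) an explicit insertion-plus-deletion at the locus, and
#' (iii) force-aligning the inserted fragment against the deleted span as a
#' mismatch-dense match run. At error rates below 1% the forced representation
#' folds into (ii), since a mapper of clean reads has no reason to accept a
#' ~75%-mismatch segment. Pure insertions are emitted as a long `I` op (or a
#' clip); pure deletions always as `D`. Partial inserted fragments at read
#' ends are always soft-clipped.
#'
#' @param reads list from [simulate_reads()].
#' @param planted result of [plant_variants()] (haplotypes + truth).
#' @param error_rate the simulation error rate (drives the behavior mixture).
#' @param behavior probabilities `c(clip=, id=, forced=)` for delins-crossing
#'   reads.
#' @param ins_clip_frac probability that a pure-insertion-crossing read is
#'   clipped rather than given an `I` op.
#' @param contig reference name used in the records.
#' @param seed integer seed for the per-read behavior draws.
#' @return a data frame of alignment records (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `hp`), sorted by position.
#' @export
emit_truth_alignments <- function(reads, planted, error_rate,
                                  behavior = c(clip = 0.25, id = 0.50, forced = 0.25),
                                  ins_clip_frac = 0.25, contig = "sim1", seed = 1) {
  truth <- planted$truth
  segs <- lapply(planted$haplotypes, `[[`, "segments")
  with_seed(derive_seed(seed, "align"), {
    recs <- vector("list", length(reads))
    for (i in seq_along(reads)) {
      recs[[i]] <- align_one_read(reads[[i]], segs[[reads[[i]]$haplotype + 1L]],
                                  truth, error_rate, behavior, ins_clip_frac,
                                  contig)
    }
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  aln <- data.frame(
    qname = vapply(recs, `[[`, character(1), "qname"),
    flag = 0L,
    rname = contig,
    pos = vapply(recs, `[[`, integer(1), "pos"),
    mapq = 60L,
    cigar = vapply(recs, `[[`, character(1), "cigar"),
    seq = vapply(recs, `[[`, character(1), "seq"),
    hp = vapply(recs, `[[`, integer(1), "hp"),
    stringsAsFactors = FALSE)
  aln <- aln[order(aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

align_one_read <- function(read, segments, truth, error_rate, behavior,
                           ins_clip_frac, contig) {
  L <- read$clean_len
  rs <- read$hap_start; re <- rs + L - 1L
  i0 <- findInterval(rs, segments$hap_start)
  i1 <- findInterval(re, segments$hap_start)
  ops <- character(L)       # per clean base: "M" or "I"
  refpos <- integer(L); refpos[] <- NA_integer_
  # chunk bookkeeping: rel ranges + separator flags at clipped junctions
  n_chunk <- i1 - i0 + 1L
  ch_a <- integer(n_chunk); ch_b <- integer(n_chunk)
  ch_sep <- logical(n_chunk)       # TRUE -> this chunk splits the read (clip)
  ch_ref <- logical(n_chunk)
  sg_kind <- segments$kind; sg_hs <- segments$hap_start; sg_he <- segments$hap_end
  sg_rs <- segments$ref_start; sg_vid <- segments$var_id
  for (j in seq_len(n_chunk)) {
    sg <- i0 + j - 1L
    a <- max(rs, sg_hs[sg]); b <- min(re, sg_he[sg])
    ra <- a - rs + 1L; rb <- b - rs + 1L      # rel clean coords
    ch_a[j] <- ra; ch_b[j] <- rb
    if (sg_kind[sg] == "ref") {
      ch_ref[j] <- TRUE
      off <- a - sg_hs[sg]
      ops[ra:rb] <- "M"
      refpos[ra:rb] <- seq.int(sg_rs[sg] + off, length.out = rb - ra + 1L)
    } else {
      v <- truth[match(sg_vid[sg], truth$id), ]
      partial <- a > sg_hs[sg] || b < sg_he[sg]
      if (v$vtype == "insertion") {
        beh <- if (partial) "clip"
               else if (stats::runif(1) < ins_clip_frac) "clip" else "iop"
      } else {
        beh <- if (partial) "clip"
               else sample(c("clip", "id", "forced"), 1L, prob = behavior)
        if (beh == "forced" && error_rate < 0.01) beh <- "id"
      }
      if (beh == "clip") {
        ch_sep[j] <- TRUE
        ops[ra:rb] <- "I"     # never aligned; lands in a soft clip
      } else if (beh == "forced") {
        span <- v$end - v$start + 1L       # deleted span length
        l1 <- rb - ra + 1L                 # inserted length (full chunk)
        m <- min(l1, span)
        ops[ra:rb] <- "I"
        ops[ra:(ra + m - 1L)] <- "M"
        refpos[ra:(ra + m - 1L)] <- seq.int(v$start, length.out = m)
      } else {
        ops[ra:rb] <- "I"                  # id / iop: explicit insertion op
      }
    }
  }
  # groups: maximal chunk runs not containing a separator chunk
  if (!any(!ch_sep & ch_ref)) return(NULL)
  best <- -1L; ga <- gb <- 0L
  g_start <- 1L
  j <- 1L
  while (j <= n_chunk) {
    if (ch_sep[j]) { j <- j + 1L; next }
    k <- j
    while (k < n_chunk && !ch_sep[k + 1L]) k <- k + 1L
    if (any(ch_ref[j:k])) {
      len <- ch_b[k] - ch_a[j] + 1L
      if (len > best) { best <- len; ga <- ch_a[j]; gb <- ch_b[k] }
    }
    j <- k + 1L
  }
  if (best < 30L) return(NULL)   # no usable anchor

  # error events restricted to the group, expansion mirroring read synthesis
  del <- logical(L); del[read$del_pos] <- TRUE
  ins_after <- tabulate(read$ins_pos, L)
  gi <- ga:gb
  # insertion errors after the last group base belong to the right clip
  ia <- ins_after[gi]; ia[length(ia)] <- 0L
  reps <- (!del[gi]) + ia
  idx <- rep.int(gi, reps)
  if (!length(idx)) return(NULL)
  fop <- ops[idx]
  is_ins_slot <- duplicated(idx) | del[idx]
  fop[is_ins_slot] <- "I"
  fref <- refpos[idx]
  fref[is_ins_slot] <- NA_integer_
  mloc <- which(fop == "M")
  if (!length(mloc)) return(NULL)
  mfirst <- mloc[1L]; mlast <- mloc[length(mloc)]
  # noisy-read clip lengths flanking the aligned block
  n_before <- function(p) if (p < 1L) 0L else
    p - sum(del[seq_len(p)]) + sum(ins_after[seq_len(p)])
  left_s <- n_before(ga - 1L) + (mfirst - 1L)
  total_noisy <- nchar(read$seq)
  fop <- fop[mfirst:mlast]; fref <- fref[mfirst:mlast]
  right_s <- total_noisy - left_s - length(fop)
  # run construction (vectorized): break on op change or reference gap
  mpos <- which(fop == "M")
  pm <- fref[mpos]
  gaps <- c(0L, diff(pm) - 1L)
  gb_q <- integer(length(fop)); gb_q[mpos] <- gaps
  brk <- c(TRUE, fop[-1L] != fop[-length(fop)] | gb_q[-1L] > 0L)
  runid <- cumsum(brk)
  rstart <- which(brk)
  rlen <- tabulate(runid)
  rop <- fop[rstart]
  rgap <- gb_q[rstart]
  pieces <- ifelse(rgap > 0L, paste0(rgap, "D", rlen, rop), paste0(rlen, rop))
  cig <- paste(pieces, collapse = "")
  if (left_s > 0L) cig <- paste0(left_s, "S", cig)
  if (right_s > 0L) cig <- paste0(cig, right_s, "S")
  list(qname = read$name, pos = pm[1L], cigar = cig, seq = read$seq,
       hp = as.integer(read$haplotype))
}
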