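#' Merge SV calls with SNVs into a phasable variant set
#'
#' Takes the union of SNVs (from a VCF or data frame) and SV calls, sorted by
#' position with duplicates (same position and kind) collapsed. The alternate
#' allele frequency `p` of every variant is estimated from the reads via
#' [assign_read_alleles()]; variants with `p` outside
#' `[het_min, 1 - het_min]` are marked non-phasable (homozygous or noise) and
#' excluded from blocks.
#'
#' @param sv_calls data frame of SV calls: `vtype`, `start`, `end`,
#'   `inserted_len` (optional), one row per call; may be empty.
#' @param snvs SNV VCF path or data frame with `pos`, `ref`, `alt`.
#' @param aln alignment data frame.
#' @param reference reference sequence.
#' @param het_min heterozygosity gate on `p`.
#' @return list: `variants` (data frame with `id`, `kind`, `pos`, `end`,
#'   `ref`, `alt`, `p`, `phasable`) and `matrix` (the read-allele matrix).
#' @export
load_and_merge_variants <- function(sv_calls, snvs, aln, reference,
                                    het_min = 0.2) {
  if (is.character(snvs)) snvs <- read_snv_vcf(snvs)
  v <- list()
  if (!is.null(snvs) && nrow(snvs)) {
    v[[1]] <- data.frame(kind = "snv", pos = snvs$pos, end = snvs$pos,
                         ref = snvs$ref, alt = snvs$alt,
                         stringsAsFactors = FALSE)
  }
  if (!is.null(sv_calls) && nrow(sv_calls)) {
    v[[length(v) + 1L]] <- data.frame(
      kind = sv_calls$vtype, pos = sv_calls$start, end = sv_calls$end,
      ref = "N", alt = paste0("<", toupper(sv_calls$vtype), ">"),
      stringsAsFactors = FALSE)
  }
  if (!length(v)) {
    variants <- data.frame(id = character(0), kind = character(0),
                           pos = integer(0), end = integer(0),
                           ref = character(0), alt = character(0),
                           p = numeric(0), phasable = logical(0))
    return(list(variants = variants,
                matrix = matrix(NA_integer_, 0, 0)))
  }
  variants <- do.call(rbind, v)
  variants <- variants[order(variants$pos), , drop = FALSE]
  dup <- duplicated(paste(variants$pos, variants$kind))
  variants <- variants[!dup, , drop = FALSE]
  variants$id <- sprintf("v%05d", seq_len(nrow(variants)))
  rownames(variants) <- NULL
  mat <- assign_read_alleles(variants, aln, reference)
  p <- colMeans(mat == 1L, na.rm = TRUE)
  p[is.nan(p)] <- 0
  variants$p <- p
  variants$phasable <- p >= het_min & p <= 1 - het_min
  list(variants = variants, matrix = mat)
}

# minimal SNV VCF reader (positions + alleles) via vcfR
read_snv_vcf <- function(path) {
  x <- try(vcfR::read.vcfR(path, verbose = FALSE), silent = TRUE)
  if (inherits(x, "try-error"))
    stop("malformed VCF: ", path, " (", attr(x, "condition")$message, ")",
         call. = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(data.frame(pos = integer(0), ref = character(0),
                                    alt = character(0)))
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl("<", fix$ALT)
  data.frame(pos = as.integer(fix$POS[snv]), ref = fix$REF[snv],
             alt = fix$ALT[snv], stringsAsFactors = FALSE)
}

#' Score each read at each variant
#'
#' SNVs are scored by the aligned base: alt allele -> 1, reference base -> 0,
#' anything else (or no aligned base) -> NA. Deletions and delins are scored
#' alt when the read soft-clips at the span, gaps (D ops) across at least half
#' of it, or force-aligns through it with a mismatch-dense span (>= 40%
#' mismatching columns); ref when it aligns contiguously and cleanly through;
#' NA when the read does not span informatively. Insertions are scored alt on
#' a long I op or clip anchored near the site.
#'
#' @param variants variant data frame (see [load_and_merge_variants()]).
#' @param aln alignment data frame.
#' @param reference reference sequence.
#' @return integer matrix reads x variants with entries 1 (alt), 0 (ref), NA.
#' @export
assign_read_alleles <- function(variants, aln, reference) {
  n_r <- nrow(aln); n_v <- nrow(variants)
  mat <- matrix(NA_integer_, n_r, n_v,
                dimnames = list(aln$qname, variants$id))
  if (!n_r || !n_v) return(mat)
  cigs <- parse_cigars(aln)
  ref_raw <- charToRaw(reference)
  margin <- 50L
  vpos <- variants$pos; vend <- variants$end
  for (i in seq_len(n_r)) {
    cg <- cigs[[i]]
    rs <- aln$pos[i]; re <- cg$rend
    ov <- which(vpos <= re + margin & vend >= rs - margin)
    if (!length(ov)) next
    qraw <- NULL
    # per-read op arrays, computed once
    mi <- which(cg$op %in% c("M", "=", "X"))
    m_rs <- cg$rstart[mi]; m_len <- cg$len[mi]; m_qs <- cg$qstart[mi]
    di <- which(cg$op == "D")
    d_rs <- cg$rstart[di]; d_len <- cg$len[di]
    ii <- which(cg$op == "I")
    i_anchor <- cg$rstart[ii] - 1L; i_len <- cg$len[ii]
    si <- which(cg$op == "S")
    s_anchor <- ifelse(cg$qstart[si] == 1L, rs, re)
    s_len <- cg$len[si]
    for (j in ov) {
      kind <- variants$kind[j]
      vp <- vpos[j]; ve <- vend[j]
      if (kind == "snv") {
        if (vp < rs || vp > re) next
        ki <- findInterval(vp, m_rs)
        if (ki < 1L || vp > m_rs[ki] + m_len[ki] - 1L) next  # in a deletion
        if (is.null(qraw)) qraw <- charToRaw(aln$seq[i])
        qb <- rawToChar(qraw[m_qs[ki] + (vp - m_rs[ki])])
        mat[i, j] <- if (qb == variants$alt[j]) 1L
                     else if (qb == variants$ref[j]) 0L else NA_integer_
      } else {
        span <- max(ve - vp + 1L, 1L)
        # soft clip anchored near a breakpoint -> alt
        clip_alt <- length(si) && any(s_anchor >= vp - margin &
                                      s_anchor <= ve + margin &
                                      s_len > margin)
        if (clip_alt) { mat[i, j] <- 1L; next }
        spans <- rs <= vp - margin && re >= ve + margin
        if (!spans) next
        d_cov <- 0L
        if (length(di)) {
          a <- pmax(d_rs, vp); b <- pmin(d_rs + d_len - 1L, ve)
          d_cov <- sum(pmax(b - a + 1L, 0L))
        }
        big_i <- length(ii) && any(i_anchor >= vp - margin &
                                   i_anchor <= ve + margin &
                                   i_len >= 0.5 * max(span, 100L))
        if (kind == "insertion") {
          mat[i, j] <- if (big_i) 1L else 0L
          next
        }
        if (d_cov >= 0.5 * span) { mat[i, j] <- 1L; next }
        # mismatch-dense forced alignment across the span?
        a <- pmax(m_rs, vp); b <- pmin(m_rs + m_len - 1L, ve)
        w <- which(b >= a)
        mm <- 0L; cols <- 0L
        if (length(w)) {
          if (is.null(qraw)) qraw <- charToRaw(aln$seq[i])
          qa <- m_qs[w] + (a[w] - m_rs[w])
          rp <- sequence(b[w] - a[w] + 1L, from = a[w])
          qp <- sequence(b[w] - a[w] + 1L, from = qa)
          mm <- sum(ref_raw[rp] != qraw[qp])
          cols <- length(rp)
        }
        mat[i, j] <- if (cols > 0 && mm / cols >= 0.4) 1L else 0L
      }
    }
  }
  mat
}

#' Read-backed splicing into haplotype blocks
#'
#' Greedy left-to-right merge over position-sorted phasable variants:
#' consecutive variants co-observed on at least `min_shared` reads whose
#' co-allele majority is strict are joined into one block, phase chosen by the
#' majority; conflicting reads are outvoted. Every phasable variant ends up in
#' exactly one block (singletons allowed).
#'
#' @param mat read-allele matrix.
#' @param variants variant data frame (phasable column respected).
#' @param min_shared minimum co-informative reads to join.
#' @return list of blocks: each has `ids`, `pos`, `phase` (allele on haplotype
#'   A per variant), `provenance` (per junction).
#' @export
read_backed_splice <- function(mat, variants, min_shared = 2) {
  ph <- which(variants$phasable)
  if (!length(ph)) return(list())
  blocks <- list()
  cur_ids <- variants$id[ph[1L]]
  cur_pos <- variants$pos[ph[1L]]
  cur_phase <- 1L
  cur_prov <- character(0)
  if (length(ph) > 1L) for (t in 2:length(ph)) {
    a <- ph[t - 1L]; b <- ph[t]
    xa <- mat[, a]; xb <- mat[, b]
    ok <- !is.na(xa) & !is.na(xb)
    cis <- sum(xa[ok] == xb[ok])
    trans <- sum(xa[ok] != xb[ok])
    joined <- (cis + trans) >= min_shared && cis != trans
    if (joined) {
      prev_phase <- cur_phase[length(cur_phase)]
      new_phase <- if (cis > trans) prev_phase else 1L - prev_phase
      cur_ids <- c(cur_ids, variants$id[b])
      cur_pos <- c(cur_pos, variants$pos[b])
      cur_phase <- c(cur_phase, new_phase)
      cur_prov <- c(cur_prov, "read_backed")
    } else {
      blocks[[length(blocks) + 1L]] <- list(ids = cur_ids, pos = cur_pos,
                                            phase = cur_phase,
                                            provenance = cur_prov)
      cur_ids <- variants$id[b]; cur_pos <- variants$pos[b]
      cur_phase <- 1L; cur_prov <- character(0)
    }
  }
  blocks[[length(blocks) + 1L]] <- list(ids = cur_ids, pos = cur_pos,
                                        phase = cur_phase, provenance = cur_prov)
  blocks
}

#' Linkage-disequilibrium correlation between two blocks
#'
#' `L = sum_i sum_j lq(i,j) * p(j)` over cross-block variant pairs, where
#' `lq` is the signed linkage strength `D = p(AB) - p(A) p(B)` computed from
#' reads informative at both sites ("A" meaning the allele on haplotype A of
#' each block under the given orientation; 0 when no co-informative reads)
#' and `p(j)` is the posterior variant's alternate-allele frequency.
#'
#' @param blockA,blockB blocks from [read_backed_splice()] (A anterior).
#' @param mat read-allele matrix.
#' @param variants variant data frame.
#' @param orientation `"same"` (B's haplotype A pairs with A's) or `"flipped"`.
#' @param max_pair_dist skip pairs farther apart than this (no read can span
#'   them, so their `lq` is exactly 0).
#' @return the correlation strength L (numeric scalar).
#' @export
ld_correlation <- function(blockA, blockB, mat, variants,
                           orientation = c("same", "flipped"),
                           max_pair_dist = 30000) {
  orientation <- match.arg(orientation)
  ia <- match(blockA$ids, variants$id)
  ib <- match(blockB$ids, variants$id)
  # pairs farther apart than a read span have lq = 0; restrict to the junction
  keep_a <- variants$pos[ia] >= min(variants$pos[ib]) - max_pair_dist
  keep_b <- variants$pos[ib] <= max(variants$pos[ia]) + max_pair_dist
  phaseA <- blockA$phase[keep_a]; phaseB <- blockB$phase[keep_b]
  ia <- ia[keep_a]; ib <- ib[keep_b]
  blockA <- list(phase = phaseA); blockB <- list(phase = phaseB)
  pj <- variants$p[ib]
  L <- 0
  if (!length(ia) || !length(ib)) return(L)
  for (u in seq_along(ia)) {
    xa <- mat[, ia[u]]
    pa_allele <- blockA$phase[u]
    for (v in seq_along(ib)) {
      if (abs(variants$pos[ia[u]] - variants$pos[ib[v]]) > max_pair_dist) next
      xb <- mat[, ib[v]]
      ok <- !is.na(xa) & !is.na(xb)
      n <- sum(ok)
      if (n == 0L) next
      pb_allele <- if (orientation == "same") blockB$phase[v]
                   else 1L - blockB$phase[v]
      x <- as.numeric(xa[ok] == pa_allele)
      y <- as.numeric(xb[ok] == pb_allele)
      lq <- mean(x * y) - mean(x) * mean(y)
      L <- L + lq * pj[v]
    }
  }
  L
}

#' Secondary splicing of blocks by LD correlation
#'
#' Scans junctions left to right; for each anterior/posterior pair of adjacent
#' blocks, computes L under both orientations and splices with the better one
#' when `max(L) >= min_L`, marking the junction `ld_spliced`. Repeats until no
#' junction changes (at most one pass per block). Within-block phase from
#' read-backed splicing is never altered (a flip relabels the haplotypes of
#' the posterior block globally).
#'
#' @param blocks blocks from [read_backed_splice()].
#' @param mat read-allele matrix.
#' @param variants variant data frame.
#' @param min_L acceptance threshold on the correlation strength.
#' @return spliced block list.
#' @export
secondary_splice <- function(blocks, mat, variants, min_L = 0) {
  if (length(blocks) <= 1L) return(blocks)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    changed <- FALSE
    i <- 1L
    while (i < length(blocks)) {
      A <- blocks[[i]]; B <- blocks[[i + 1L]]
      Ls <- ld_correlation(A, B, mat, variants, "same")
      Lf <- ld_correlation(A, B, mat, variants, "flipped")
      if (max(Ls, Lf) >= min_L) {
        flip <- Lf > Ls
        phB <- if (flip) 1L - B$phase else B$phase
        blocks[[i]] <- list(ids = c(A$ids, B$ids), pos = c(A$pos, B$pos),
                            phase = c(A$phase, phB),
                            provenance = c(A$provenance, "ld_spliced",
                                           B$provenance))
        blocks[[i + 1L]] <- NULL
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed || passes >= length(blocks) + 1L) break
  }
  blocks
}

#' Write a phased VCF
#'
#' Phased genotypes are emitted as `phase|1-phase` with a `PS` phase-set
#' identifier equal to the block's first variant position; singleton blocks
#' and non-phasable variants are emitted unphased (`0/1`, or `1/1` when p >
#' 0.5 beyond the het gate). SVs use symbolic ALT alleles with `SVTYPE`,
#' `END`, and the inserted sequence/source in INFO.
#'
#' @param blocks block list.
#' @param variants variant data frame.
#' @param path output path.
#' @param contig,contig_len header contig line.
#' @param reference optional reference sequence for REF bases.
#' @export
emit_phased_vcf <- function(blocks, variants, path, contig = "sim1",
                            contig_len = NA, reference = NULL) {
  gt <- rep("0/1", nrow(variants))
  ps <- rep(NA_integer_, nrow(variants))
  hom <- !variants$phasable & variants$p > 0.5
  gt[hom] <- "1/1"
  for (b in blocks) {
    if (length(b$ids) < 2L) next
    ix <- match(b$ids, variants$id)
    gt[ix] <- sprintf("%d|%d", b$phase, 1L - b$phase)
    ps[ix] <- b$pos[1L]
  }
  ref_col <- if (!is.null(reference) && nrow(variants))
    substring(reference, variants$pos, variants$pos) else variants$ref
  alt <- variants$alt
  info <- ifelse(variants$kind == "snv", ".",
                 sprintf("SVTYPE=%s;END=%d", toupper(variants$kind),
                         variants$end))
  fmt <- ifelse(is.na(ps), "GT", "GT:PS")
  sample_col <- ifelse(is.na(ps), gt, sprintf("%s:%d", gt, ps))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s%s>", contig,
                   if (is.na(contig_len)) "" else sprintf(",length=%d", as.integer(contig_len))),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\t%s\t%s",
                   contig, variants$pos, variants$id, ref_col, alt, info,
                   fmt, sample_col)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read block membership back from a phased VCF
#'
#' @param path VCF path.
#' @return data frame: `id`, `pos`, `gt`, `ps` (NA when unphased).
#' @export
read_phased_vcf <- function(path) {
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  gtc <- x@gt[, 2]
  fmt <- x@gt[, 1]
  gt <- vapply(strsplit(gtc, ":"), `[`, character(1), 1)
  ps <- rep(NA_integer_, length(gt))
  has_ps <- grepl("PS", fmt, fixed = TRUE)
  ps[has_ps] <- as.integer(vapply(strsplit(gtc[has_ps], ":"), `[`,
                                  character(1), 2))
  data.frame(id = fix$ID, pos = as.integer(fix$POS), gt = gt, ps = ps,
             stringsAsFactors = FALSE)
}
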