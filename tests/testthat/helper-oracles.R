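# Independent brute-force oracles used by the unit tests and the
# oracle-equivalence checks. Deliberately naive implementations sharing no
# code with the package internals.

# per-read character-level CIGAR walk pileup
oracle_pileup <- function(aln, reference) {
  L <- nchar(reference)
  d <- integer(L); u <- integer(L)
  refc <- strsplit(reference, "")[[1]]
  for (i in seq_len(nrow(aln))) {
    ops <- regmatches(aln$cigar[i], gregexpr("[0-9]+[MIDSH=X]", aln$cigar[i]))[[1]]
    n <- as.integer(sub("[A-Z=]", "", ops))
    op <- sub("[0-9]+", "", ops)
    qc <- strsplit(aln$seq[i], "")[[1]]
    rp <- aln$pos[i]; qp <- 1L
    um <- integer(0)
    for (k in seq_along(op)) {
      if (op[k] %in% c("M", "=", "X")) {
        for (t in seq_len(n[k])) {
          if (qc[qp] != refc[rp]) um <- c(um, rp)
          rp <- rp + 1L; qp <- qp + 1L
        }
      } else if (op[k] == "D") {
        um <- c(um, rp:(rp + n[k] - 1L)); rp <- rp + n[k]
      } else if (op[k] == "I") {
        um <- c(um, rp - 1L); qp <- qp + n[k]
      } else if (op[k] == "S") {
        um <- c(um, if (k == 1L) aln$pos[i] else rp - 1L)
        qp <- qp + n[k]
      }
    }
    span <- aln$pos[i]:(rp - 1L)
    d[span] <- d[span] + 1L
    for (x in unique(um)) if (x >= 1 && x <= L) u[x] <- u[x] + 1L
  }
  data.frame(pos = seq_len(L), d = d, u = pmin(u, d))
}

# double-loop weighted window score with edge renormalization
oracle_score <- function(p, w) {
  n <- length(p); wl <- (length(w) - 1L) %/% 2L
  vapply(seq_len(n), function(c) {
    acc <- 0; wsum <- 0
    for (k in max(1, c - wl):min(n, c + wl)) {
      acc <- acc + w[k - c + wl + 1] * p[k]
      wsum <- wsum + w[k - c + wl + 1]
    }
    acc / wsum
  }, numeric(1))
}

# direct O(n * win) moving average with truncated edges
oracle_smooth <- function(x, win) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- max(1, i - win):min(n, i + win)
    sum(x[k]) / length(k)
  }, numeric(1))
}

# linear scan for maximal runs strictly above T
oracle_regions <- function(s, T) {
  above <- s > T
  out <- NULL
  i <- 1L
  while (i <= length(s)) {
    if (above[i]) {
      j <- i
      while (j < length(s) && above[j + 1L]) j <- j + 1L
      out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# hand-rolled type-7 quartiles + Tukey fences
oracle_tukey <- function(v) {
  srt <- sort(v); n <- length(v)
  qat <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    srt[lo] + (h - lo) * (srt[hi] - srt[lo])
  }
  q1 <- qat(0.25); q3 <- qat(0.75); iqr <- q3 - q1
  v[v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr]
}

# cumulative-sum N50 by explicit loop
oracle_n50 <- function(spans) {
  if (!length(spans)) return(0)
  s <- sort(spans, decreasing = TRUE)
  half <- sum(s) / 2; acc <- 0
  for (x in s) { acc <- acc + x; if (acc >= half) return(x) }
}

# direct switch/mismatch classification of one disagreement vector:
# scan runs of disagreement; length-1 runs are mismatches, longer runs add a
# switch at each boundary interior to the block
oracle_switch_mismatch <- function(e) {
  n <- length(e); sw <- 0L; mm <- 0L
  i <- 1L
  while (i <= n) {
    if (e[i]) {
      j <- i
      while (j < n && e[j + 1L]) j <- j + 1L
      if (j == i) mm <- mm + 1L
      else sw <- sw + (i > 1L) + (j < n)
      i <- j + 1L
    } else i <- i + 1L
  }
  c(sw = sw, mm = mm)
}
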