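#' Simulation configuration
#'
#' Parameters of the built-in diploid simulator. The defaults are the study
#' conditions used throughout the package's validation: a 1 Mbp genome with 20
#' heterozygous delins of 500-1000 bp, CLR-like reads of length N(15000, 1500)
#' at 25x depth and a 15% sequencing error rate dominated by spurious
#' insertions and deletions.
#'
#' @param ref_length reference length in bases.
#' @param n_delins,n_ins,n_del number of planted delins / insertions / deletions.
#' @param delins_len_range (min, max) deleted-span length in bases; also used
#'   for pure deletion and insertion lengths.
#' @param snv_rate per-base probability of a planted SNV.
#' @param depth target fold-coverage.
#' @param read_len_mean,read_len_sd read length distribution (normal, truncated
#'   at 200 bases).
#' @param error_rate per-base sequencing error probability in `[0, 0.5)`.
#' @param error_mix length-3 numeric (insertion, deletion, substitution)
#'   fractions of errors; must sum to 1.
#' @param min_sv_gap minimum distance in bases between planted SV breakpoints.
#' @param seed integer seed; every simulator stage is deterministic given it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(ref_length = 1e6, n_delins = 20, n_ins = 0, n_del = 0,
                       delins_len_range = c(500, 1000), snv_rate = 0.001,
                       depth = 25, read_len_mean = 15000, read_len_sd = 1500,
                       error_rate = 0.15,
                       error_mix = c(ins = 0.45, del = 0.40, sub = 0.15),
                       min_sv_gap = 5000, seed = 1) {
  cfg <- list(ref_length = ref_length, n_delins = n_delins, n_ins = n_ins,
              n_del = n_del, delins_len_range = delins_len_range,
              snv_rate = snv_rate, depth = depth,
              read_len_mean = read_len_mean, read_len_sd = read_len_sd,
              error_rate = error_rate, error_mix = unname(error_mix),
              min_sv_gap = min_sv_gap, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$ref_length <= 0) stop("ref_length must be > 0", call. = FALSE)
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)", call. = FALSE)
  if (length(cfg$error_mix) != 3 || any(cfg$error_mix < 0) ||
      abs(sum(cfg$error_mix) - 1) > 1e-9)
    stop("error_mix must be 3 nonnegative fractions summing to 1", call. = FALSE)
  if (cfg$delins_len_range[1] > cfg$delins_len_range[2])
    stop("delins_len_range must satisfy min <= max", call. = FALSE)
  if (cfg$snv_rate < 0 || cfg$snv_rate > 1) stop("snv_rate must be in [0,1]", call. = FALSE)
  if (cfg$depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (cfg$read_len_mean <= 0) stop("read_len_mean must be > 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a random reference sequence
#'
#' I.i.d. uniform A/C/G/T sequence standing in for a sampled genomic region;
#' any user FASTA can be used instead throughout the pipeline.
#'
#' @param length sequence length in bases (> 0).
#' @param seed integer seed.
#' @return a character string of exactly `length` bases.
#' @export
generate_reference <- function(length, seed = 1) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length <= 0)
    stop("reference length must be a positive number", call. = FALSE)
  with_seed(derive_seed(seed, "reference"),
            paste(sample(BASES, as.integer(length), replace = TRUE), collapse = ""))
}

new_truth <- function(id, vtype, haplotype, start, end, inserted_seq,
                      insert_source = rep(NA_integer_, length(id)),
                      alt_base = rep(NA_character_, length(id))) {
  data.frame(id = id, vtype = vtype, haplotype = haplotype,
             start = as.integer(start), end = as.integer(end),
             inserted_seq = inserted_seq,
             insert_source = as.integer(insert_source),
             alt_base = alt_base, stringsAsFactors = FALSE)
}

# Sample n non-overlapping SV placements (deleted spans) separated by at least
# min_gap, within [margin, L - margin]. Errors out after bounded retries.
place_intervals <- function(n, lens, L, min_gap, margin, existing_starts = integer(0),
                            existing_ends = integer(0), max_retry = 2000L) {
  starts <- integer(0); ends <- integer(0)
  s_all <- existing_starts; e_all <- existing_ends
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_retry)
      stop("could not place requested variants without overlap; ",
           "reduce counts or lengths relative to ref_length", call. = FALSE)
    len <- lens[length(starts) + 1L]
    lo <- margin; hi <- L - margin - len
    if (hi < lo) stop("ref_length too small for requested variants", call. = FALSE)
    s <- sample(lo:hi, 1L)
    e <- s + len - 1L
    if (all(s > e_all + min_gap | e < s_all - min_gap)) {
      starts <- c(starts, s); ends <- c(ends, e)
      s_all <- c(s_all, s); e_all <- c(e_all, e)
    }
  }
  list(start = starts, end = ends)
}

#' Plant variants into a reference, producing two haplotypes
#'
#' Delins replace a deleted span with a fragment of approximately equal length
#' (uniform in 0.9-1.1x) copied from a random reference locus; insertions copy
#' a fragment likewise; deletions remove a span. All SVs are heterozygous
#' (assigned to one haplotype); SNVs go to haplotype 0, 1 or both at random.
#'
#' @param reference reference sequence (character string).
#' @param config a [sim_config()].
#' @return list with `haplotypes` (two per-haplotype lists carrying `seq` and a
#'   `segments` coordinate table) and `truth` (data frame of planted variants,
#'   sorted by start).
#' @export
plant_variants <- function(reference, config) {
  L <- nchar(reference)
  cfg <- validate_sim_config(config)
  with_seed(derive_seed(cfg$seed, "plant"), {
    truth <- new_truth(character(0), character(0), character(0), integer(0),
                       integer(0), character(0))
    n_sv <- cfg$n_delins + cfg$n_del + cfg$n_ins
    if (n_sv > 0) {
      lr <- cfg$delins_len_range
      del_lens <- c(
        sample(lr[1]:lr[2], cfg$n_delins, replace = TRUE),   # delins deleted span
        sample(lr[1]:lr[2], cfg$n_del, replace = TRUE),      # pure deletions
        rep(0L, cfg$n_ins))                                  # insertions: empty span
      # an insertion still needs clearance for its inserted length
      clearance <- pmax(del_lens, 1L)
      pl <- place_intervals(n_sv, clearance, L, cfg$min_sv_gap,
                            margin = max(2000L, lr[2]))
      vt <- rep(c("delins", "deletion", "insertion"),
                c(cfg$n_delins, cfg$n_del, cfg$n_ins))
      for (i in seq_len(n_sv)) {
        s <- pl$start[i]
        if (vt[i] == "insertion") {
          start <- s; end <- s - 1L
          ins_len <- sample(lr[1]:lr[2], 1L)
        } else {
          start <- s; end <- s + del_lens[i] - 1L
          ins_len <- if (vt[i] == "delins")
            max(1L, round(stats::runif(1, 0.9, 1.1) * del_lens[i])) else 0L
        }
        if (ins_len > 0) {
          src <- sample.int(L - ins_len, 1L)
          ins_seq <- substr(reference, src, src + ins_len - 1L)
        } else { src <- NA_integer_; ins_seq <- "" }
        truth <- rbind(truth, new_truth(
          sprintf("sv%03d", i), vt[i], sample(c("0", "1"), 1L),
          start, end, ins_seq, src))
      }
    }
    if (cfg$snv_rate > 0) {
      n_snv <- stats::rbinom(1L, L, cfg$snv_rate)
      if (n_snv > 0) {
        blocked <- logical(L)
        if (nrow(truth)) for (i in seq_len(nrow(truth))) {
          lo <- max(1L, truth$start[i] - 50L); hi <- min(L, truth$end[i] + 50L)
          blocked[lo:hi] <- TRUE
        }
        pos <- sample(which(!blocked), min(n_snv, sum(!blocked)))
        refb <- substring(reference, pos, pos)
        altb <- mutate_bases(refb)
        hap <- sample(c("0", "1", "both"), length(pos), replace = TRUE)
        truth <- rbind(truth, new_truth(
          sprintf("snv%05d", seq_along(pos)), "snv", hap, pos, pos, "",
          NA_integer_, altb))
      }
    }
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    haps <- lapply(c("0", "1"), function(h) build_haplotype(reference, truth, h))
    list(haplotypes = haps, truth = truth)
  })
}

# Apply one haplotype's variants to the reference; returns the haplotype
# sequence plus a segment table mapping haplotype coords <-> reference coords.
# Segment kinds: "ref" (aligned stretch) and "ins" (inserted sequence of an SV).
build_haplotype <- function(reference, truth, hap) {
  L <- nchar(reference)
  take <- truth$haplotype == hap | truth$haplotype == "both"
  v <- truth[take, , drop = FALSE]
  pieces <- character(0)
  s_kind <- character(0); s_hs <- integer(0); s_he <- integer(0)
  s_rs <- integer(0); s_re <- integer(0); s_vid <- character(0)
  pos <- 1L      # next reference position to copy
  hpos <- 1L     # next haplotype position to fill
  add_seg <- function(kind, n, rs, re, vid, piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    s_kind[length(s_kind) + 1L] <<- kind
    s_hs[length(s_hs) + 1L] <<- hpos
    s_he[length(s_he) + 1L] <<- hpos + n - 1L
    s_rs[length(s_rs) + 1L] <<- rs
    s_re[length(s_re) + 1L] <<- re
    s_vid[length(s_vid) + 1L] <<- vid
    hpos <<- hpos + n
  }
  add_ref <- function(from, to) {
    if (to >= from)
      add_seg("ref", to - from + 1L, from, to, NA_character_,
              substr(reference, from, to))
  }
  if (nrow(v)) for (i in seq_len(nrow(v))) {
    if (v$vtype[i] == "snv") {
      add_ref(pos, v$start[i] - 1L)
      # SNV: still a reference-aligned segment, carrying the alternate base
      add_seg("ref", 1L, v$start[i], v$start[i], v$id[i], v$alt_base[i])
      pos <- v$start[i] + 1L
    } else {
      add_ref(pos, v$start[i] - 1L)
      if (nchar(v$inserted_seq[i]) > 0L)
        add_seg("ins", nchar(v$inserted_seq[i]), NA_integer_, NA_integer_,
                v$id[i], v$inserted_seq[i])
      pos <- v$end[i] + 1L
    }
  }
  add_ref(pos, L)
  segments <- data.frame(kind = s_kind, hap_start = s_hs, hap_end = s_he,
                         ref_start = s_rs, ref_end = s_re, var_id = s_vid,
                         stringsAsFactors = FALSE)
  list(seq = paste(unlist(pieces), collapse = ""), segments = segments, hap = hap)
}

#' Simulate noisy long reads from two haplotypes
#'
#' Read lengths are normal (truncated at 200 bases), start positions uniform,
#' haplotype of origin fair-coin, and per-base errors injected at `error_rate`
#' with the configured insertion/deletion/substitution mix. Reads are drawn
#' until the total simulated bases reach `depth * ref_length`.
#'
#' @param haplotypes the `haplotypes` element of [plant_variants()].
#' @param config a [sim_config()].
#' @return list of read records: `name`, `haplotype` (0/1), `hap_start`
#'   (1-based clean start on the haplotype), `clean_len`, `seq` (noisy bases),
#'   and the error-event positions `sub_pos`, `ins_pos`, `del_pos` in clean
#'   read coordinates (the per-base edit trace).
#' @export
simulate_reads <- function(haplotypes, config) {
  cfg <- validate_sim_config(config)
  if (cfg$error_rate >= 0.5) stop("error_rate must be < 0.5", call. = FALSE)
  hl <- vapply(haplotypes, function(h) nchar(h$seq), integer(1))
  target <- cfg$depth * cfg$ref_length
  with_seed(derive_seed(cfg$seed, "reads"), {
    reads <- vector("list", ceiling(target / cfg$read_len_mean * 1.5))
    n <- 0L; total <- 0
    while (total < target) {
      len <- 0L
      while (len < 200L) len <- as.integer(round(stats::rnorm(1, cfg$read_len_mean,
                                                              cfg$read_len_sd)))
      hap <- sample(0:1, 1L)
      len <- min(len, hl[hap + 1L])
      start <- sample.int(hl[hap + 1L] - len + 1L, 1L)
      clean <- substr(haplotypes[[hap + 1L]]$seq, start, start + len - 1L)
      k <- stats::rbinom(1L, len, cfg$error_rate)
      if (k > 0) {
        epos <- sort(sample.int(len, k))
        etype <- sample(c("ins", "del", "sub"), k, replace = TRUE,
                        prob = cfg$error_mix)
      } else { epos <- integer(0); etype <- character(0) }
      sub_pos <- epos[etype == "sub"]
      ins_pos <- epos[etype == "ins"]
      del_pos <- epos[etype == "del"]
      chars <- charToRaw(clean)
      if (length(sub_pos)) chars[sub_pos] <- mutate_bases_raw(chars[sub_pos])
      ins_after <- tabulate(ins_pos, len)
      del <- logical(len); del[del_pos] <- TRUE
      reps <- (!del) + ins_after
      idx <- rep.int(seq_len(len), reps)
      out <- chars[idx]
      is_ins_slot <- duplicated(idx) | del[idx]
      if (any(is_ins_slot)) out[is_ins_slot] <- random_bases_raw(sum(is_ins_slot))
      n <- n + 1L
      reads[[n]] <- list(name = sprintf("read%06d", n), haplotype = hap,
                         hap_start = start, clean_len = len,
                         seq = rawToChar(out),
                         sub_pos = sub_pos, ins_pos = ins_pos, del_pos = del_pos)
      total <- total + len
    }
    reads[seq_len(n)]
  })
}

# true reference-projected start of a read (first clean base mapped to the
# reference; bases born in an inserted segment project to the insertion locus)
true_ref_start <- function(read, segments, truth) {
  i <- findInterval(read$hap_start, segments$hap_start)
  if (segments$kind[i] == "ref")
    return(segments$ref_start[i] + (read$hap_start - segments$hap_start[i]))
  truth$start[match(segments$var_id[i], truth$id)]
}
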