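# hand-built read-allele matrices for the splicing/LD primitives
mk_variants <- function(pos, p = rep(0.5, length(pos)),
                        kind = rep("snv", length(pos))) {
  data.frame(id = sprintf("v%05d", seq_along(pos)), kind = kind, pos = pos,
             end = pos, ref = "A", alt = "C", p = p,
             phasable = p >= 0.2 & p <= 0.8, stringsAsFactors = FALSE)
}

test_that("merging unions SNVs and SVs, dedups, and applies the het gate", {
  sm <- fix_noisy()
  snv_df <- sim_snv_df(sm)
  calls <- data.frame(vtype = sm$truth_sv$vtype, start = sm$truth_sv$start,
                      end = sm$truth_sv$end)
  mg <- load_and_merge_variants(calls, snv_df, sm$aln, sm$ref)
  expect_true(!is.unsorted(mg$variants$pos))
  expect_equal(nrow(mg$variants), nrow(snv_df) + nrow(calls))
  # duplicate SNV records collapse
  mg2 <- load_and_merge_variants(calls, rbind(snv_df, snv_df[1, ]),
                                 sm$aln, sm$ref)
  expect_equal(nrow(mg2$variants), nrow(mg$variants))
  # heterozygous SNVs sit near p = 0.5; homozygous near 1 and are gated out
  truth_snv <- sm$pl$truth[sm$pl$truth$vtype == "snv", ]
  het_pos <- truth_snv$start[truth_snv$haplotype != "both"]
  hom_pos <- truth_snv$start[truth_snv$haplotype == "both"]
  central <- het_pos[het_pos > 0.05 * sm$cfg$ref_length &
                     het_pos < 0.95 * sm$cfg$ref_length]
  vh <- mg$variants[mg$variants$pos %in% central & mg$variants$kind == "snv", ]
  # binomial sampling with error contamination: p concentrates near 0.5
  expect_gt(mean(vh$p >= 0.3 & vh$p <= 0.7), 0.95)
  expect_equal(median(vh$p), 0.5, tolerance = 0.05)
  vhom <- mg$variants[mg$variants$pos %in% hom_pos & mg$variants$kind == "snv", ]
  expect_true(all(!vhom$phasable))
  # empty SNV set: SV calls alone survive
  mg3 <- load_and_merge_variants(calls, NULL, sm$aln, sm$ref)
  expect_equal(nrow(mg3$variants), nrow(calls))
})

test_that("read alleles follow the span rules and input order invariance", {
  sm <- fix_clean()
  snv_df <- sim_snv_df(sm)
  truth_snv <- sm$pl$truth[sm$pl$truth$vtype == "snv", ]
  variants <- mk_variants(snv_df$pos)
  variants$ref <- snv_df$ref; variants$alt <- snv_df$alt
  mat <- assign_read_alleles(variants, sm$aln, sm$ref)
  # noise-free: a read's allele equals its haplotype's truth allele
  err <- 0L; checked <- 0L
  for (i in seq_len(nrow(sm$aln))) {
    hap <- as.character(sm$aln$hp[i])
    for (j in which(!is.na(mat[i, ]))) {
      tv <- truth_snv[truth_snv$start == variants$pos[j], ]
      want <- as.integer(tv$haplotype == hap | tv$haplotype == "both")
      checked <- checked + 1L
      if (mat[i, j] != want) err <- err + 1L
    }
  }
  expect_gt(checked, 100)
  expect_equal(err, 0L)
  # a read not spanning a variant is missing there
  far <- which(variants$pos > max(sm$aln$pos + nchar(sm$aln$seq)))
  # order invariance
  perm <- sample(seq_len(nrow(sm$aln)))
  mat2 <- assign_read_alleles(variants, sm$aln[perm, ], sm$ref)
  expect_equal(mat[perm, , drop = FALSE], mat2, ignore_attr = TRUE)
})

test_that("read-backed splicing joins unanimous pairs and splits uncovered ones", {
  v <- mk_variants(c(100, 200, 5000))
  # 10 reads covering v1+v2 concordantly; nothing co-covers v3
  mat <- matrix(NA_integer_, 12, 3)
  mat[1:5, 1] <- 1L; mat[1:5, 2] <- 1L
  mat[6:10, 1] <- 0L; mat[6:10, 2] <- 0L
  mat[11:12, 3] <- 1L
  colnames(mat) <- v$id
  b <- read_backed_splice(mat, v)
  expect_equal(length(b), 2)
  expect_equal(b[[1]]$ids, v$id[1:2])
  expect_equal(b[[1]]$phase[1], b[[1]]$phase[2])   # cis
  expect_equal(b[[2]]$ids, v$id[3])
  # trans signal flips the phase
  mat2 <- mat; mat2[1:5, 2] <- 0L; mat2[6:10, 2] <- 1L
  b2 <- read_backed_splice(mat2, v)
  expect_true(b2[[1]]$phase[1] != b2[[1]]$phase[2])
  # below min_shared: no join
  mat3 <- mat; mat3[2:5, ] <- NA; mat3[6:10, ] <- NA
  b3 <- read_backed_splice(mat3, v, min_shared = 2)
  expect_equal(length(b3), 3)
})

test_that("ld correlation is signed by orientation and zero at independence", {
  v <- mk_variants(c(100, 300), p = c(0.5, 0.5))
  # perfectly linked pair: 6 reads, alleles identical
  mat <- cbind(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  colnames(mat) <- v$id
  A <- list(ids = v$id[1], pos = v$pos[1], phase = 1L)
  B <- list(ids = v$id[2], pos = v$pos[2], phase = 1L)
  Ls <- ld_correlation(A, B, mat, v, "same")
  Lf <- ld_correlation(A, B, mat, v, "flipped")
  expect_gt(Ls, 0)
  expect_equal(Lf, -Ls)            # D flips sign under allele swap
  # independent variants: D = 0
  mat2 <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  colnames(mat2) <- v$id
  expect_equal(ld_correlation(A, B, mat2, v, "same"), 0)
  # no co-informative reads: contribution 0
  mat3 <- cbind(c(1, 1, NA, NA), c(NA, NA, 1, 0))
  colnames(mat3) <- v$id
  expect_equal(ld_correlation(A, B, mat3, v, "same"), 0)
})

test_that("secondary splicing is identity on single blocks and gated by min_L", {
  v <- mk_variants(c(100, 300))
  mat <- cbind(c(1, 1, 0, 0), c(NA, NA, NA, NA))
  colnames(mat) <- v$id
  A <- list(ids = v$id[1], pos = v$pos[1], phase = 1L, provenance = character(0))
  B <- list(ids = v$id[2], pos = v$pos[2], phase = 1L, provenance = character(0))
  expect_equal(secondary_splice(list(A), mat, v), list(A))
  # zero co-informative reads and min_L > 0: not spliced
  out <- secondary_splice(list(A, B), mat, v, min_L = 0.01)
  expect_equal(length(out), 2)
  # with real signal the junction is spliced and marked
  mat2 <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  colnames(mat2) <- v$id
  out2 <- secondary_splice(list(A, B), mat2, v, min_L = 0.01)
  expect_equal(length(out2), 1)
  expect_true("ld_spliced" %in% out2[[1]]$provenance)
  expect_true(out2[[1]]$phase[1] != out2[[1]]$phase[2])  # trans signal honored
})

test_that("noise-free phasing equals planted truth up to a global flip", {
  sm <- fix_clean()
  pcfg <- default_pcfg(sm$cfg)
  calls <- data.frame(vtype = sm$truth_sv$vtype, start = sm$truth_sv$start,
                      end = sm$truth_sv$end)
  ph <- ds_phase(calls, sim_snv_df(sm), sm$aln, sm$ref, pcfg)
  tp <- truth_phase_map(ph$variants, sm$pl$truth)
  expect_gt(length(tp), 50)
  sm_rates <- switch_mismatch_rates(ph$blocks, tp)
  expect_equal(sm_rates$switch_rate, 0)
  expect_equal(sm_rates$mismatch_rate, 0)
  # complement consistency: flipping every allele leaves the rates unchanged
  flipped <- lapply(ph$blocks, function(b) { b$phase <- 1L - b$phase; b })
  sm_f <- switch_mismatch_rates(flipped, tp)
  expect_equal(sm_f$switch_rate, 0)
  expect_equal(sm_f$mismatch_rate, 0)
  # block disjointness and coverage of phasable variants
  ids <- unlist(lapply(ph$blocks, `[[`, "ids"))
  expect_equal(anyDuplicated(ids), 0)
  expect_setequal(ids, ph$variants$id[ph$variants$phasable])
})

test_that("secondary splicing never lowers N50 nor rewires block interiors", {
  sm <- fix_noisy()
  pcfg <- default_pcfg(sm$cfg)
  calls <- data.frame(vtype = sm$truth_sv$vtype, start = sm$truth_sv$start,
                      end = sm$truth_sv$end)
  ph <- ds_phase(calls, sim_snv_df(sm), sm$aln, sm$ref, pcfg)
  expect_gte(ph$n50, ph$n50_read_backed)
  # within-block relative phase of read-backed blocks is preserved
  rel <- function(b) if (length(b$phase) > 1) diff(b$phase) else integer(0)
  final_ids <- lapply(ph$blocks, `[[`, "ids")
  for (b in ph$blocks_read_backed) {
    if (length(b$ids) < 2) next
    host <- which(vapply(final_ids, function(x) all(b$ids %in% x), logical(1)))
    expect_equal(length(host), 1)
    hb <- ph$blocks[[host]]
    ix <- match(b$ids, hb$ids)
    d1 <- abs(diff(b$phase)); d2 <- abs(diff(hb$phase[ix]))
    expect_equal(d1, d2)
  }
})

test_that("phased VCF round-trips block membership and validates", {
  sm <- fix_noisy()
  pcfg <- default_pcfg(sm$cfg)
  calls <- data.frame(vtype = sm$truth_sv$vtype, start = sm$truth_sv$start,
                      end = sm$truth_sv$end)
  vcf <- tempfile(fileext = ".vcf")
  ph <- ds_phase(calls, sim_snv_df(sm), sm$aln, sm$ref, pcfg, vcf_path = vcf)
  back <- read_phased_vcf(vcf)
  expect_equal(nrow(back), nrow(ph$variants))
  # block membership: same PS <=> same block (for phased variants)
  for (b in ph$blocks) {
    if (length(b$ids) < 2) next
    ps <- back$ps[match(b$ids, back$id)]
    expect_equal(length(unique(ps)), 1)
    expect_equal(unique(ps), b$pos[1])
  }
  # singleton blocks come back unphased
  singles <- unlist(lapply(ph$blocks[vapply(ph$blocks, function(b)
    length(b$ids) == 1, logical(1))], `[[`, "ids"))
  if (length(singles))
    expect_true(all(is.na(back$ps[match(singles, back$id)])))
  # minimal VCF v4.2 syntax checks
  lines <- readLines(vcf)
  expect_match(lines[1], "^##fileformat=VCFv4.2$")
  body <- lines[!startsWith(lines, "#")]
  expect_true(all(lengths(strsplit(body, "\t")) == 10))
})
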