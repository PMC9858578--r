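test_that("reference generation is deterministic, uniform and validated", {
  a <- generate_reference(100, seed = 7)
  b <- generate_reference(100, seed = 7)
  expect_identical(a, b)
  expect_equal(nchar(a), 100)
  expect_true(all(strsplit(a, "")[[1]] %in% c("A", "C", "G", "T")))
  # binomial bound: GC fraction of a 1 Mb i.i.d. sequence, p = 0.5, 6 sigma
  big <- generate_reference(1e6, seed = 1)
  gc <- sum(charToRaw(big) %in% charToRaw("GC")) / 1e6
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)
  expect_error(generate_reference(0, 1), "positive")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(ref_length = -1), "ref_length")
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(sim_config(error_mix = c(0.5, 0.5, 0.5)), "error_mix")
  expect_error(sim_config(delins_len_range = c(100, 50)), "min <= max")
})

test_that("plant_variants conserves counts, lengths and identity", {
  cfg <- sim_config(ref_length = 3e6, n_delins = 20, snv_rate = 0, seed = 3)
  ref <- generate_reference(cfg$ref_length, cfg$seed)
  pl <- plant_variants(ref, cfg)
  sv <- pl$truth[pl$truth$vtype == "delins", ]
  expect_equal(nrow(sv), 20)
  # "approximately equal-length": inserted length within +/-10% of deletion
  del_len <- sv$end - sv$start + 1L
  ins_len <- nchar(sv$inserted_seq)
  expect_true(all(ins_len >= floor(0.9 * del_len) - 1 &
                  ins_len <= ceiling(1.1 * del_len) + 1))
  # inserts really are copies of the reference at the recorded source
  for (i in seq_len(nrow(sv)))
    expect_identical(sv$inserted_seq[i],
                     substr(ref, sv$insert_source[i],
                            sv$insert_source[i] + ins_len[i] - 1L))
  expect_true(!is.unsorted(pl$truth$start))
  # identity case: nothing planted -> haplotypes equal the reference
  cfg0 <- sim_config(ref_length = 10000, n_delins = 0, snv_rate = 0, seed = 3)
  pl0 <- plant_variants(generate_reference(10000, 3), cfg0)
  expect_identical(pl0$haplotypes[[1]]$seq, generate_reference(10000, 3))
  expect_identical(pl0$haplotypes[[2]]$seq, generate_reference(10000, 3))
  expect_equal(nrow(pl0$truth), 0)
})

test_that("unplaceable variant requests fail with a clear error", {
  cfg <- sim_config(ref_length = 20000, n_delins = 30, seed = 1)
  ref <- generate_reference(20000, 1)
  expect_error(plant_variants(ref, cfg), "place|small")
})

test_that("simulated reads recover the configured error rate and coverage", {
  sm <- fix_noisy()
  edits <- sum(vapply(sm$reads, function(r)
    length(r$sub_pos) + length(r$ins_pos) + length(r$del_pos), numeric(1)))
  clean <- sum(vapply(sm$reads, `[[`, numeric(1), "clean_len"))
  expect_gt(edits / clean, sm$cfg$error_rate - 0.01)
  expect_lt(edits / clean, sm$cfg$error_rate + 0.01)
  # coverage accounting: total bases ~ depth x genome
  expect_gt(clean, 0.8 * sm$cfg$depth * sm$cfg$ref_length)
  expect_lt(clean, 1.2 * sm$cfg$depth * sm$cfg$ref_length)
  # mean per-site depth within 15% of configured depth over the central 90%
  pu <- build_pileup(sm$aln, sm$ref)
  central <- pu$d[seq(0.05 * sm$cfg$ref_length, 0.95 * sm$cfg$ref_length)]
  expect_gt(mean(central), 0.85 * sm$cfg$depth)
  expect_lt(mean(central), 1.15 * sm$cfg$depth)
})

test_that("zero-noise reads are exact substrings and M-runs match the reference", {
  sm <- fix_clean()
  hseq <- lapply(sm$pl$haplotypes, `[[`, "seq")
  for (r in sm$reads[seq(1, length(sm$reads), by = 7)]) {
    expect_identical(r$seq, substr(hseq[[r$haplotype + 1L]], r$hap_start,
                                   r$hap_start + r$clean_len - 1L))
  }
  # every M run matches the reference exactly, except at planted SNV sites
  # (heterozygous SNVs legitimately align as mismatches)
  snv_sites <- sm$pl$truth$start[sm$pl$truth$vtype == "snv"]
  cigs <- delinscan:::parse_cigars(sm$aln)
  ref_raw <- charToRaw(sm$ref)
  bad <- 0L
  for (i in seq_len(nrow(sm$aln))) {
    cg <- cigs[[i]]
    qraw <- charToRaw(sm$aln$seq[i])
    mi <- which(cg$op == "M")
    rp <- sequence(cg$len[mi], from = cg$rstart[mi])
    qp <- sequence(cg$len[mi], from = cg$qstart[mi])
    mm <- rp[ref_raw[rp] != qraw[qp]]
    bad <- bad + sum(!mm %in% snv_sites)
  }
  expect_equal(bad, 0L)
})

test_that("simulation is deterministic given the seed", {
  a <- make_sim(seed = 19, ref_length = 50000, n_delins = 1, depth = 8,
                read_len_mean = 3000, read_len_sd = 300)
  b <- make_sim(seed = 19, ref_length = 50000, n_delins = 1, depth = 8,
                read_len_mean = 3000, read_len_sd = 300)
  expect_identical(a$ref, b$ref)
  expect_identical(a$pl$truth, b$pl$truth)
  expect_identical(a$aln, b$aln)
})

test_that("emitted CIGARs consume exactly the read length on query ops", {
  sm <- fix_noisy()
  cigs <- delinscan:::parse_cigars(sm$aln)
  qlens <- vapply(cigs, function(cg)
    sum(cg$len[cg$op %in% c("M", "I", "S")]), integer(1))
  expect_identical(qlens, nchar(sm$aln$seq))
})

test_that("reads crossing a delins from the left are clipped at the truth start", {
  sm <- fix_clean()
  sv <- sm$truth_sv[1, ]
  cigs <- delinscan:::parse_cigars(sm$aln)
  rends <- vapply(cigs, `[[`, integer(1), "rend")
  # right-clipped reads anchored at the delins must stop exactly at start - 1
  anchored <- which(vapply(cigs, function(cg) cg$op[length(cg$op)] == "S",
                           logical(1)) &
                    abs(rends - (sv$start - 1L)) <= 0)
  expect_gte(length(anchored), 1)
  for (i in anchored) expect_equal(rends[i], sv$start - 1L)
})

test_that("truth files round-trip and use the documented coordinate conventions", {
  sm <- fix_noisy()
  vcf <- tempfile(fileext = ".vcf"); bed <- tempfile(fileext = ".bed")
  write_truth_files(sm$pl$truth, vcf, bed, reference = sm$ref,
                    contig_len = sm$cfg$ref_length)
  back <- read_truth_vcf(vcf)
  expect_equal(back, sm$pl$truth)
  b <- read_truth_bed(bed)
  expect_equal(nrow(b), nrow(sm$truth_sv))
  expect_equal(b$start, sm$truth_sv$start)
  expect_equal(b$end, pmax(sm$truth_sv$end, sm$truth_sv$start - 1L))
  # raw BED line is 0-based half-open
  line1 <- strsplit(readLines(bed, n = 1), "\t")[[1]]
  expect_equal(as.integer(line1[2]), sm$truth_sv$start[1] - 1L)
  # empty truth -> valid header-only files
  empty <- sm$pl$truth[0, ]
  write_truth_files(empty, vcf, bed)
  expect_equal(nrow(read_truth_vcf(vcf)), 0)
  expect_equal(nrow(read_truth_bed(bed)), 0)
})

test_that("SAM output is readable by the standard BAM machinery", {
  sm <- cached("tiny_sam", make_sim(seed = 23, ref_length = 50000,
                                    n_delins = 1, depth = 10,
                                    read_len_mean = 4000, read_len_sd = 400))
  sam <- tempfile(fileext = ".sam")
  write_sam(sm$aln, sam, "sim1", sm$cfg$ref_length)
  back <- read_alignments(sam)
  expect_equal(nrow(back), nrow(sm$aln))
  expect_equal(back$pos, sm$aln$pos)
  expect_equal(back$cigar, sm$aln$cigar)
  expect_equal(toupper(back$seq), toupper(sm$aln$seq))
})
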