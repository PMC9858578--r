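# One full pipeline replicate at the headline study conditions (1 Mbp genome,
# 20 delins of 500-1000 bp, reads N(15000, 1500)), returning summary metrics
# only so replicates can be shared across test files without holding reads in
# memory.
run_replicate <- function(seed, depth = 25, error_rate = 0.15,
                          delins_len_range = c(500, 1000), ensemble = NULL,
                          with_phasing = TRUE) {
  if (is.null(ensemble)) ensemble <- fix_ensemble()
  scfg <- sim_config(ref_length = 1e6, n_delins = 20, snv_rate = 0.001,
                     depth = depth, error_rate = error_rate,
                     delins_len_range = delins_len_range, seed = seed)
  pcfg <- pipeline_config(seed = seed, sim = scfg)
  ref <- generate_reference(scfg$ref_length, scfg$seed)
  pl <- plant_variants(ref, scfg)
  reads <- simulate_reads(pl$haplotypes, scfg)
  aln <- emit_truth_alignments(reads, pl, scfg$error_rate, seed = scfg$seed)
  calls <- ds_call(aln, ref, ensemble, pcfg)
  ev <- ds_evaluate(calls, pl$truth, pcfg)
  truth_sv <- pl$truth[pl$truth$vtype != "snv", , drop = FALSE]
  m <- match_calls(calls, truth_sv, tolerance = pcfg$match_tolerance)
  trace_diff <- integer(0)
  for (i in which(!is.na(m$call_matched))) {
    if (!is.na(calls$insert_source[i])) {
      j <- m$call_matched[i]
      trace_diff <- c(trace_diff,
                      abs(calls$insert_source[i] - truth_sv$insert_source[j]))
    }
  }
  out <- list(seed = seed, detection = ev$detection,
              f = ev$detection$f_measure, recall = ev$detection$recall,
              precision = ev$detection$precision, trace_diff = trace_diff)
  if (with_phasing) {
    snvs <- pl$truth[pl$truth$vtype == "snv", , drop = FALSE]
    snv_df <- data.frame(pos = snvs$start,
                         ref = substring(ref, snvs$start, snvs$start),
                         alt = snvs$alt_base)
    ph <- ds_phase(calls, snv_df, aln, ref, pcfg)
    ev2 <- ds_evaluate(calls, pl$truth, pcfg, phase = ph)
    out$phasing <- ev2$phasing
  }
  out
}

# the ten seeded replicates of the headline setup, shared by several checks
headline_replicates <- function() cached("headline",
  lapply(1:10, function(s) run_replicate(s)))
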