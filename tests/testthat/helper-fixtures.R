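# session-level fixture cache: simulations and trained ensembles are built
# once and shared across test files
.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) assign(key, expr, envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# one simulated dataset: reference, planted variants, reads, alignments
make_sim <- function(seed = 7, ref_length = 200000, n_delins = 3,
                     n_ins = 0, n_del = 0, snv_rate = 0.001, depth = 25,
                     error_rate = 0.15, read_len_mean = 15000,
                     read_len_sd = 1500, delins_len_range = c(500, 1000)) {
  cfg <- sim_config(ref_length = ref_length, n_delins = n_delins,
                    n_ins = n_ins, n_del = n_del, snv_rate = snv_rate,
                    depth = depth, error_rate = error_rate,
                    read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                    delins_len_range = delins_len_range, seed = seed)
  ref <- generate_reference(cfg$ref_length, cfg$seed)
  pl <- plant_variants(ref, cfg)
  reads <- simulate_reads(pl$haplotypes, cfg)
  aln <- emit_truth_alignments(reads, pl, cfg$error_rate, seed = cfg$seed)
  list(cfg = cfg, ref = ref, pl = pl, reads = reads, aln = aln,
       truth_sv = pl$truth[pl$truth$vtype != "snv", , drop = FALSE])
}

fix_noisy <- function() cached("noisy", make_sim(seed = 7))

# zero-noise runs use 60x: with a quarter of crossing reads clipping and the
# clips split between the two breakpoint sides, that yields ~3-4 exact-anchor
# reads per side, enough for the exactness properties to be well-posed
fix_clean <- function() cached("clean", make_sim(seed = 11, error_rate = 0,
                                                 depth = 60))

# ensemble trained at the default 15%-error conditions
fix_ensemble <- function() cached("ens",
  ds_train(pipeline_config(seed = 400), n_per_class = 24))

# ensemble trained at zero-error conditions (for noise-free runs)
fix_ensemble0 <- function() cached("ens0",
  ds_train(pipeline_config(seed = 401,
                           sim = sim_config(error_rate = 0, seed = 401)),
           n_per_class = 24))

# truth SNVs as the external small-variant set for phasing
sim_snv_df <- function(sm) {
  snv <- sm$pl$truth[sm$pl$truth$vtype == "snv", , drop = FALSE]
  data.frame(pos = snv$start,
             ref = substring(sm$ref, snv$start, snv$start),
             alt = snv$alt_base, stringsAsFactors = FALSE)
}

empty_calls_df <- function() delinscan:::empty_calls()

default_pcfg <- function(sim_cfg) {
  pipeline_config(seed = sim_cfg$seed, sim = sim_cfg)
}
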