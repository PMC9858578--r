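#' Pipeline configuration
#'
#' One validated list holding every stage's tunables plus the simulator block.
#' Unknown keys are rejected.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param windows_len scoring half-window (sites).
#' @param smooth_win smoothing half-window (sites).
#' @param threshold_T candidate-region threshold in (0,1).
#' @param merge_gap merge regions closer than this many sites.
#' @param min_clip soft clips must exceed this length (bases).
#' @param max_iterations insert-tracing re-queue rounds.
#' @param het_min heterozygosity gate on allele frequency.
#' @param min_shared co-informative reads needed for a read-backed join.
#' @param min_L acceptance threshold for LD splicing.
#' @param match_tolerance breakpoint tolerance for evaluation (bases).
#' @param sim a [sim_config()] (or list of its fields).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, windows_len = 50, smooth_win = 50,
                            threshold_T = 0.35, merge_gap = 2 * windows_len,
                            min_clip = 50, max_iterations = 3, het_min = 0.2,
                            min_shared = 2, min_L = 0, match_tolerance = 100,
                            sim = sim_config(seed = seed)) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  cfg <- list(seed = seed, windows_len = windows_len, smooth_win = smooth_win,
              threshold_T = threshold_T, merge_gap = merge_gap,
              min_clip = min_clip, max_iterations = max_iterations,
              het_min = het_min, min_shared = min_shared, min_L = min_L,
              match_tolerance = match_tolerance, sim = sim)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  if (cfg$threshold_T <= 0 || cfg$threshold_T >= 1)
    stop("threshold_T must lie in (0,1)", call. = FALSE)
  if (cfg$windows_len < 1) stop("windows_len must be >= 1", call. = FALSE)
  validate_sim_config(cfg$sim)
  structure(cfg, class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#' @param path YAML file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config_from_list(y)
}

pipeline_config_from_list <- function(y) {
  if (is.null(y)) y <- list()   # empty YAML: all defaults
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  y$sim <- NULL
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  args <- y
  if (!is.null(sim)) args$sim <- sim
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the simulator end to end, writing a fixture set
#'
#' Writes reference FASTA, haplotype FASTAs, reads FASTQ, truth-derived sorted
#' SAM, truth VCF and truth BED to `out_dir`, plus a manifest with MD5
#' checksums.
#'
#' @param config a [pipeline_config()] (its `sim` block drives everything).
#' @param out_dir output directory (created if needed).
#' @param contig contig name.
#' @return invisible list with the in-memory objects and file paths.
#' @export
ds_simulate <- function(config, out_dir, contig = "sim1") {
  cfg <- validate_pipeline_config(config)$sim
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference(cfg$ref_length, cfg$seed)
  pl <- plant_variants(ref, cfg)
  reads <- simulate_reads(pl$haplotypes, cfg)
  aln <- emit_truth_alignments(reads, pl, cfg$error_rate, contig = contig,
                               seed = cfg$seed)
  paths <- list(ref = file.path(out_dir, "reference.fasta"),
                hap0 = file.path(out_dir, "haplotype0.fasta"),
                hap1 = file.path(out_dir, "haplotype1.fasta"),
                fastq = file.path(out_dir, "reads.fastq"),
                sam = file.path(out_dir, "alignments.sam"),
                vcf = file.path(out_dir, "truth.vcf"),
                bed = file.path(out_dir, "truth.bed"))
  write_fasta(stats::setNames(ref, contig), paths$ref)
  write_fasta(stats::setNames(pl$haplotypes[[1]]$seq, paste0(contig, "_h0")), paths$hap0)
  write_fasta(stats::setNames(pl$haplotypes[[2]]$seq, paste0(contig, "_h1")), paths$hap1)
  write_fastq(reads, paths$fastq)
  write_sam(aln, paths$sam, contig, cfg$ref_length)
  write_truth_files(pl$truth, paths$vcf, paths$bed, reference = ref,
                    contig = contig, contig_len = cfg$ref_length)
  files <- unlist(paths)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = unname(file.size(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reference = ref, planted = pl, reads = reads, aln = aln,
                 paths = c(paths, manifest = file.path(out_dir, "manifest.tsv"))))
}

#' Train the default one-vs-one SVM ensemble from seeded simulations
#'
#' @param config a [pipeline_config()]; training simulations inherit its
#'   `sim` error rate, depth and read lengths.
#' @param n_per_class training regions per class.
#' @param model_path optional path to save the ensemble.
#' @return the trained `svm_ensemble`.
#' @export
ds_train <- function(config = pipeline_config(), n_per_class = 40,
                     model_path = NULL) {
  cfg <- validate_pipeline_config(config)
  labeled <- make_training_regions(n_per_class, cfg$sim)
  ens <- train_ensemble(labeled, seed = cfg$seed)
  if (!is.null(model_path)) save_ensemble(ens, model_path)
  ens
}

#' Call structural variants from alignments
#'
#' Chains the density scan (pileup, variation score, smoothing, thresholded
#' candidate regions), the one-vs-one SVM classification, the soft-clip
#' breakpoint resolution and the insert-source tracing. Noise-class regions
#' are dropped.
#'
#' @param aln alignment data frame or SAM/BAM path.
#' @param reference reference sequence or FASTA path.
#' @param ensemble a trained `svm_ensemble` (see [ds_train()]).
#' @param config a [pipeline_config()].
#' @param verbose log per-stage record counts.
#' @return data frame of calls: `contig`, `vtype`, `start`, `end`,
#'   `support_start`, `support_end`, `low_confidence`, `insert_source`,
#'   `trace_status`, `region_l`, `region_r`, `peak_score`.
#' @export
ds_call <- function(aln, reference, ensemble, config = pipeline_config(),
                    verbose = FALSE) {
  cfg <- validate_pipeline_config(config)
  if (is.character(aln)) aln <- read_alignments(aln)
  reference <- resolve_reference(reference)
  if (is.null(ensemble)) stop("no trained ensemble; run ds_train() first",
                              call. = FALSE)
  contig <- if (nrow(aln)) aln$rname[1] else "sim1"
  pu <- build_pileup(aln, reference)
  w <- weight_vector(cfg$windows_len)
  tr <- score_track(pu, w, contig = contig)
  tr <- smooth_track(tr, cfg$smooth_win)
  regs <- call_candidate_regions(tr, cfg$threshold_T, cfg$merge_gap)
  if (verbose) message(sprintf("[call] %d candidate regions", nrow(regs)))
  if (!nrow(regs)) return(empty_calls())
  cigs <- parse_cigars(aln)
  feats <- vector("list", nrow(regs))
  ok <- rep(TRUE, nrow(regs))
  for (i in seq_len(nrow(regs))) {
    f <- try(extract_features(regs[i, ], aln, reference, pileup = pu,
                              cigs = cigs), silent = TRUE)
    if (inherits(f, "try-error")) { ok[i] <- FALSE; next }
    feats[[i]] <- f
  }
  regs <- regs[ok, , drop = FALSE]
  if (!nrow(regs)) return(empty_calls())
  feats <- do.call(rbind, feats[ok])
  cl <- classify_region(feats, ensemble)
  keep <- cl$label != "noise"
  regs <- regs[keep, , drop = FALSE]
  labels <- cl$label[keep]
  if (verbose) message(sprintf("[call] %d regions after noise drop", nrow(regs)))
  if (!nrow(regs)) return(empty_calls())
  aidx <- NULL
  calls <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    rg <- regs[i, ]
    right <- collect_softclips(aln, rg, "right_clip", cfg$min_clip,
                               pad = cfg$windows_len, cigs = cigs)
    left <- collect_softclips(aln, rg, "left_clip", cfg$min_clip,
                              pad = cfg$windows_len, cigs = cigs)
    bs <- locate_breakpoint(right, "start", fallback = rg$l)
    be <- locate_breakpoint(left, "end", fallback = rg$r)
    vt <- labels[i]
    start <- bs$position; end <- be$position
    if (vt == "insertion") end <- start - 1L
    if (vt != "insertion" && end < start) { s2 <- start; start <- min(start, end); end <- max(s2, end) }
    src <- NA_integer_; status <- NA_character_
    if (vt %in% c("delins", "insertion")) {
      clips <- rbind(right, left)
      if (nrow(clips)) {
        if (is.null(aidx)) aidx <- anchor_index(reference)
        trc <- trace_insert_source(clips, aidx,
                                   max_iterations = cfg$max_iterations)
        src <- trc$source_locus; status <- trc$status
      } else status <- "unplaced"
    }
    calls[[i]] <- data.frame(
      contig = rg$contig, vtype = vt, start = start, end = end,
      support_start = bs$support, support_end = be$support,
      low_confidence = bs$low_confidence | be$low_confidence,
      insert_source = src, trace_status = status,
      region_l = rg$l, region_r = rg$r, peak_score = rg$peak_score,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# accept either a raw sequence string or a FASTA path
resolve_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      nchar(reference) < 4096 && file.exists(reference))
    return(read_fasta(reference)[[1]])
  reference
}

empty_calls <- function() {
  data.frame(contig = character(0), vtype = character(0), start = integer(0),
             end = integer(0), support_start = integer(0),
             support_end = integer(0), low_confidence = logical(0),
             insert_source = integer(0), trace_status = character(0),
             region_l = integer(0), region_r = integer(0),
             peak_score = numeric(0))
}

#' Phase calls and SNVs into haplotype blocks
#'
#' @param calls [ds_call()] output (or compatible data frame).
#' @param snvs SNV VCF path or data frame (`pos`, `ref`, `alt`); may be NULL.
#' @param aln alignment data frame or path.
#' @param reference reference sequence or FASTA path.
#' @param config a [pipeline_config()].
#' @param vcf_path optional path for the phased VCF.
#' @return list: `variants`, `matrix`, `blocks_read_backed`, `blocks`,
#'   `n50_read_backed`, `n50`, and the phased VCF path if written.
#' @export
ds_phase <- function(calls, snvs, aln, reference, config = pipeline_config(),
                     vcf_path = NULL) {
  cfg <- validate_pipeline_config(config)
  if (is.character(aln)) aln <- read_alignments(aln)
  reference <- resolve_reference(reference)
  merged <- load_and_merge_variants(calls, snvs, aln, reference,
                                    het_min = cfg$het_min)
  blocks_rb <- read_backed_splice(merged$matrix, merged$variants,
                                  min_shared = cfg$min_shared)
  blocks <- secondary_splice(blocks_rb, merged$matrix, merged$variants,
                             min_L = cfg$min_L)
  if (!is.null(vcf_path))
    emit_phased_vcf(blocks, merged$variants, vcf_path,
                    contig = if (nrow(aln)) aln$rname[1] else "sim1",
                    reference = reference)
  list(variants = merged$variants, matrix = merged$matrix,
       blocks_read_backed = blocks_rb, blocks = blocks,
       n50_read_backed = block_n50(blocks_rb), n50 = block_n50(blocks),
       vcf = vcf_path)
}

#' Evaluate calls (and optionally phasing) against truth
#'
#' @param calls [ds_call()] output.
#' @param truth truth data frame (from [plant_variants()] or
#'   [read_truth_vcf()]).
#' @param config a [pipeline_config()] (supplies the match tolerance).
#' @param phase optional [ds_phase()] result for phasing metrics.
#' @param json_path,tsv_path optional report outputs.
#' @return list: `detection` (data frame), and with `phase` given, `phasing`
#'   (switch/mismatch rates, N50s, block count).
#' @export
ds_evaluate <- function(calls, truth, config = pipeline_config(),
                        phase = NULL, json_path = NULL, tsv_path = NULL) {
  cfg <- validate_pipeline_config(config)
  sv_truth <- truth[truth$vtype != "snv", , drop = FALSE]
  m <- match_calls(calls, sv_truth, tolerance = cfg$match_tolerance)
  det <- precision_recall_f(m, tolerance = cfg$match_tolerance)
  out <- list(detection = det)
  if (!is.null(phase)) {
    tp_map <- truth_phase_map(phase$variants, truth,
                              tolerance = cfg$match_tolerance)
    blocks <- filter_blocks(phase$blocks, names(tp_map))
    blocks_rb <- filter_blocks(phase$blocks_read_backed, names(tp_map))
    sm <- switch_mismatch_rates(blocks, tp_map)
    sm_rb <- switch_mismatch_rates(blocks_rb, tp_map)
    out$phasing <- list(switch_rate = sm$switch_rate,
                        mismatch_rate = sm$mismatch_rate,
                        switch_rate_read_backed = sm_rb$switch_rate,
                        mismatch_rate_read_backed = sm_rb$mismatch_rate,
                        n50 = phase$n50, n50_read_backed = phase$n50_read_backed,
                        blocks = length(phase$blocks))
  }
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(tsv_path))
    utils::write.table(det, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Map phased variant ids to their truth haplotype assignment
#'
#' SNVs match by position; SV calls by breakpoint proximity. Returns the truth
#' allele on haplotype 0 (1 = alternate) for every heterozygous phased variant
#' that has a truth counterpart.
#'
#' @param variants variant data frame from [ds_phase()].
#' @param truth truth data frame.
#' @param tolerance SV breakpoint tolerance.
#' @return named integer vector keyed by variant id.
#' @export
truth_phase_map <- function(variants, truth, tolerance = 100) {
  out <- integer(0)
  het <- truth[truth$haplotype %in% c("0", "1"), , drop = FALSE]
  for (i in seq_len(nrow(variants))) {
    if (!variants$phasable[i]) next
    v <- variants[i, ]
    if (v$kind == "snv") {
      j <- which(het$vtype == "snv" & het$start == v$pos)
    } else {
      j <- which(het$vtype == v$kind &
                 abs(het$start - v$pos) <= tolerance &
                 abs(het$end - v$end) <= tolerance)
    }
    if (length(j) == 1L)
      out[v$id] <- as.integer(het$haplotype[j] == "0")
  }
  out
}

# drop variants without truth counterparts from blocks (evaluation only)
filter_blocks <- function(blocks, keep_ids) {
  out <- list()
  for (b in blocks) {
    sel <- b$ids %in% keep_ids
    if (!any(sel)) next
    out[[length(out) + 1L]] <- list(ids = b$ids[sel], pos = b$pos[sel],
                                    phase = b$phase[sel],
                                    provenance = b$provenance[seq_len(max(sum(sel) - 1L, 0L))])
  }
  out
}
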