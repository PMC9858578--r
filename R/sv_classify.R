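#' Extract classification features for a candidate region
#'
#' Rates are computed over the CIGAR operations of reads overlapping the
#' region, restricted to in-region aligned columns: `ins_rate` is the fraction
#' of region-attributed op-bases that are insertion ops, `del_rate` the
#' deletion fraction, `mismatch_rate` the substitution fraction. Delins
#' regions show elevated mismatch rates (the inserted fragment force-aligned
#' against the deleted span) and poor continuity of unmatched sites, captured
#' by `max_consec_unmatched_ratio`: the longest run of sites with unmatched
#' proportion above `site_min`, divided by the region length.
#'
#' @param region one row of [call_candidate_regions()] output (list with `l`, `r`).
#' @param aln alignment data frame.
#' @param reference reference sequence.
#' @param pileup optional precomputed [build_pileup()] covering the region.
#' @param site_min per-site unmatched proportion above which a site counts as
#'   unmatched for the continuity feature.
#' @param cigs optional precomputed [parse_cigars()] result for `aln`.
#' @return one-row data frame of class features.
#' @export
extract_features <- function(region, aln, reference, pileup = NULL,
                             site_min = 0.3, cigs = NULL) {
  l <- region$l; r <- region$r
  if (is.null(cigs)) cigs <- parse_cigars(aln)
  rends <- vapply(cigs, `[[`, integer(1), "rend")
  keep <- seq_len(nrow(aln))
  ov <- which(aln$pos <= r & rends >= l)
  if (!length(ov)) stop("no reads overlap region ", l, "-", r, call. = FALSE)
  ref_raw <- charToRaw(reference)
  m_cols <- d_cols <- i_bases <- mm_cols <- 0
  for (j in ov) {
    cg <- cigs[[j]]
    mi <- which(cg$op %in% c("M", "=", "X"))
    if (length(mi)) {
      a <- pmax(cg$rstart[mi], l)
      b <- pmin(cg$rstart[mi] + cg$len[mi] - 1L, r)
      w <- which(b >= a)
      if (length(w)) {
        m_cols <- m_cols + sum(b[w] - a[w] + 1L)
        qa <- cg$qstart[mi][w] + (a[w] - cg$rstart[mi][w])
        rp <- sequence(b[w] - a[w] + 1L, from = a[w])
        qp <- sequence(b[w] - a[w] + 1L, from = qa)
        qraw <- charToRaw(aln$seq[keep[j]])
        mm_cols <- mm_cols + sum(ref_raw[rp] != qraw[qp])
      }
    }
    di <- which(cg$op == "D")
    if (length(di)) {
      a <- pmax(cg$rstart[di], l)
      b <- pmin(cg$rstart[di] + cg$len[di] - 1L, r)
      d_cols <- d_cols + sum(pmax(b - a + 1L, 0L))
    }
    ii <- which(cg$op == "I")
    if (length(ii)) {
      # insertions anchor at the base before the op; a variant's insertion can
      # anchor just outside a tightly-called region, so allow a small slack
      anchor <- cg$rstart[ii] - 1L
      i_bases <- i_bases + sum(cg$len[ii][anchor >= l - 50L & anchor <= r + 50L])
    }
  }
  denom <- m_cols + d_cols + i_bases
  if (denom == 0) stop("no aligned columns in region ", l, "-", r, call. = FALSE)
  if (is.null(pileup))
    pileup <- build_pileup(aln, reference, region = c(l, r))
  sel <- pileup$pos >= l & pileup$pos <= r
  p <- unmatched_proportion(pileup[sel, , drop = FALSE])
  run <- rle(p >= site_min)
  max_run <- if (any(run$values)) max(run$lengths[run$values]) else 0L
  region_len <- r - l + 1L
  data.frame(ins_rate = i_bases / denom, del_rate = d_cols / denom,
             mismatch_rate = mm_cols / denom,
             max_consec_unmatched_ratio = max_run / region_len,
             region_len = region_len,
             mean_depth = mean(pileup$d[sel]))
}

FEATURE_NAMES <- c("ins_rate", "del_rate", "mismatch_rate",
                   "max_consec_unmatched_ratio", "region_len", "mean_depth")

# the classifier trains on the rate features only: region length and depth are
# nuisance parameters with respect to the variant class, and a model trained
# at one coverage must generalize to others
SVM_FEATURES <- FEATURE_NAMES[1:4]

#' Train a one-vs-one SVM ensemble
#'
#' One binary radial-basis SVM per unordered pair of classes, each trained on
#' the examples of those two classes only, on standardized features. The
#' standardization parameters are stored with the ensemble.
#'
#' @param labeled data frame containing the feature columns plus a `class`
#'   column.
#' @param classes character vector of class labels (the fixed class order used
#'   for tie-breaking).
#' @param cost,gamma SVM hyperparameters passed to [e1071::svm()]; `gamma`
#'   `NULL` means the e1071 default (1/n_features).
#' @param seed integer seed (SVM training is deterministic, but kept for
#'   reproducibility of any downstream sampling).
#' @return object of class `svm_ensemble`.
#' @export
train_ensemble <- function(labeled,
                           classes = c("deletion", "delins", "insertion", "noise"),
                           cost = 1, gamma = NULL, seed = 1) {
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  missing_cls <- setdiff(classes, unique(labeled$class))
  if (length(missing_cls))
    stop("no training examples for class: ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(labeled[, SVM_FEATURES])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- with_seed(derive_seed(seed, "svm"), lapply(pairs, function(pr) {
    sel <- labeled$class %in% pr
    y <- factor(labeled$class[sel], levels = pr)
    e1071::svm(Xs[sel, , drop = FALSE], y, kernel = "radial", cost = cost,
               gamma = if (is.null(gamma)) 1 / ncol(Xs) else gamma,
               scale = FALSE)
  }))
  names(models) <- vapply(pairs, paste, character(1), collapse = "|")
  structure(list(classes = classes, models = models, center = ctr,
                 scale = scl, features = SVM_FEATURES, version = 1L),
            class = "svm_ensemble")
}

#' @export
print.svm_ensemble <- function(x, ...) {
  cat("One-vs-one SVM ensemble:", length(x$models), "pairwise models over",
      length(x$classes), "classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a region by majority vote of the pairwise SVMs
#'
#' Each of the m(m-1)/2 pairwise classifiers votes; the label with the most
#' votes wins. Ties are broken by summed decision-function margin, then by
#' the fixed class order of the ensemble.
#'
#' @param features one-row data frame from [extract_features()] (or several
#'   rows; one label per row is returned).
#' @param ensemble a trained [train_ensemble()].
#' @return list with `label` (character vector) and `votes` (matrix of vote
#'   counts, rows = inputs, columns = classes).
#' @export
classify_region <- function(features, ensemble) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  X <- as.matrix(features[, ensemble$features, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (any(X[, 1:4] < 0 | X[, 1:4] > 1))
    stop("rate features out of [0, 1]", call. = FALSE)
  Xs <- scale(X, ensemble$center, ensemble$scale)
  n <- nrow(Xs)
  cls <- ensemble$classes
  votes <- matrix(0L, n, length(cls), dimnames = list(NULL, cls))
  margin <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  for (nm in names(ensemble$models)) {
    pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
    pred <- stats::predict(ensemble$models[[nm]], Xs, decision.values = TRUE)
    dv <- attr(pred, "decision.values")[, 1]
    won <- as.character(pred)
    for (i in seq_len(n)) {
      votes[i, won[i]] <- votes[i, won[i]] + 1L
      # decision value is signed toward the first factor level
      margin[i, pr[1]] <- margin[i, pr[1]] + dv[i]
      margin[i, pr[2]] <- margin[i, pr[2]] - dv[i]
    }
  }
  label <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) {
      m <- margin[i, top]
      top <- top[m == max(m)]
    }
    cls[top[1L]]
  }, character(1))
  list(label = label, votes = votes)
}

#' Build a labeled training set from seeded simulations
#'
#' Simulates genomes containing each SV type, extracts features at the truth
#' intervals (labels deletion/insertion/delins) and at random background
#' intervals (label noise).
#'
#' @param n_per_class target number of training regions per class.
#' @param base_config a [sim_config()] used as the template (its seed spawns
#'   per-replicate seeds).
#' @return data frame of features plus `class`.
#' @export
make_training_regions <- function(n_per_class = 40, base_config = sim_config()) {
  per_sim <- 8L
  n_sims <- ceiling(n_per_class / per_sim)
  out <- list()
  for (s in seq_len(n_sims)) {
    cfg <- base_config
    cfg$ref_length <- 400000
    cfg$n_delins <- per_sim; cfg$n_del <- per_sim; cfg$n_ins <- per_sim
    cfg$min_sv_gap <- 5000
    cfg$seed <- derive_seed(base_config$seed, paste0("train", s))
    ref <- generate_reference(cfg$ref_length, cfg$seed)
    pl <- plant_variants(ref, cfg)
    reads <- simulate_reads(pl$haplotypes, cfg)
    aln <- emit_truth_alignments(reads, pl, cfg$error_rate, seed = cfg$seed)
    pu <- build_pileup(aln, ref)
    cigs <- parse_cigars(aln)
    sv <- pl$truth[pl$truth$vtype != "snv", , drop = FALSE]
    noise_pos <- with_seed(derive_seed(cfg$seed, "noise"), {
      ok <- rep(TRUE, cfg$ref_length)
      for (i in seq_len(nrow(sv)))
        ok[max(1, sv$start[i] - 3000):min(cfg$ref_length, sv$end[i] + 3000)] <- FALSE
      ok[1:20000] <- FALSE; ok[(cfg$ref_length - 20000):cfg$ref_length] <- FALSE
      sample(which(ok), per_sim)
    })
    feats <- list()
    for (i in seq_len(nrow(sv))) {
      l <- sv$start[i]
      r <- if (sv$vtype[i] == "insertion") sv$start[i] + 200L else sv$end[i]
      f <- try(extract_features(list(l = l, r = r), aln, ref, pileup = pu,
                                cigs = cigs), silent = TRUE)
      if (!inherits(f, "try-error")) {
        f$class <- sv$vtype[i]; feats[[length(feats) + 1L]] <- f
      }
    }
    for (p in noise_pos) {
      f <- try(extract_features(list(l = p, r = p + 600L), aln, ref, pileup = pu,
                                cigs = cigs), silent = TRUE)
      if (!inherits(f, "try-error")) {
        f$class <- "noise"; feats[[length(feats) + 1L]] <- f
      }
    }
    out[[s]] <- do.call(rbind, feats)
  }
  do.call(rbind, out)
}

#' Save / load an SVM ensemble
#'
#' The ensemble is serialized to a single versioned file (R serialization,
#' ASCII) so a trained model can be shipped alongside calls.
#' @param ensemble a [train_ensemble()] result.
#' @param path file path.
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path, ascii = TRUE)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "svm_ensemble")) stop("not an svm_ensemble file", call. = FALSE)
  x
}
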