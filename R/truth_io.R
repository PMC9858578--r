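#' Write truth variants as VCF and BED
#'
#' The VCF carries SNVs and SVs with phased genotypes on the two simulated
#' haplotypes (`1|0` for haplotype 0, `0|1` for haplotype 1, `1|1` for both);
#' SVs use symbolic ALT alleles with `SVTYPE`, `END`, `INSSEQ` (inserted
#' sequence) and `INSSRC` (1-based source locus of the copied fragment) INFO
#' keys. Insertions follow the `end = start - 1` convention. The BED lists SV
#' intervals 0-based half-open. Both round-trip through [read_truth_vcf()] /
#' [read_truth_bed()].
#'
#' @param truth truth data frame from [plant_variants()], sorted by start.
#' @param vcf_path,bed_path output paths (either may be NULL to skip).
#' @param reference optional reference sequence for proper REF columns.
#' @param contig,contig_len contig header values.
#' @return invisible list of the written paths.
#' @export
write_truth_files <- function(truth, vcf_path, bed_path = NULL,
                              reference = NULL, contig = "sim1",
                              contig_len = NA) {
  if (is.unsorted(truth$start)) stop("truth must be sorted by start", call. = FALSE)
  if (!is.null(vcf_path)) {
    gt <- c("0" = "1|0", "1" = "0|1", "both" = "1|1")[truth$haplotype]
    refb <- if (!is.null(reference))
      substring(reference, truth$start, truth$start) else rep("N", nrow(truth))
    is_snv <- truth$vtype == "snv"
    alt <- ifelse(is_snv, truth$alt_base,
                  paste0("<", toupper(truth$vtype), ">"))
    info <- ifelse(is_snv, ".",
                   sprintf("SVTYPE=%s;END=%d%s%s", toupper(truth$vtype),
                           truth$end,
                           ifelse(truth$inserted_seq != "",
                                  paste0(";INSSEQ=", truth$inserted_seq), ""),
                           ifelse(!is.na(truth$insert_source),
                                  paste0(";INSSRC=", truth$insert_source), "")))
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s%s>", contig,
                     if (is.na(contig_len)) "" else
                       sprintf(",length=%d", as.integer(contig_len))),
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Last deleted base (start-1 for insertions)\">",
             "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
             "##INFO=<ID=INSSRC,Number=1,Type=Integer,Description=\"Source locus of inserted fragment\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSIM")
    lines <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                     contig, truth$start, truth$id, refb, alt, info, gt)
    writeLines(c(hdr, lines), vcf_path)
  }
  if (!is.null(bed_path)) {
    sv <- truth[truth$vtype != "snv", , drop = FALSE]
    con <- file(bed_path, "wt")
    if (nrow(sv))
      writeLines(sprintf("%s\t%d\t%d\t%s", contig, sv$start - 1L,
                         pmax(sv$end, sv$start - 1L), sv$id), con)
    close(con)
  }
  invisible(list(vcf = vcf_path, bed = bed_path))
}

#' Read a truth VCF back into a truth data frame
#' @param path VCF path written by [write_truth_files()].
#' @return truth data frame (same columns as [plant_variants()]'s `truth`).
#' @export
read_truth_vcf <- function(path) {
  x <- try(vcfR::read.vcfR(path, verbose = FALSE), silent = TRUE)
  if (inherits(x, "try-error"))
    stop("malformed VCF: ", path, call. = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(new_truth(character(0), character(0), character(0), integer(0),
                     integer(0), character(0)))
  gt <- if (ncol(x@gt) >= 2) x@gt[, 2] else rep("0/1", nrow(fix))
  hap <- rep(NA_character_, nrow(fix))
  hap[gt == "1|0"] <- "0"; hap[gt == "0|1"] <- "1"; hap[gt == "1|1"] <- "both"
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    out[grepl(paste0(key, "="), info)] <- sub(paste0(key, "="), "", m)
    out
  }
  svtype <- info_get(fix$INFO, "SVTYPE")
  vtype <- ifelse(is.na(svtype), "snv", tolower(svtype))
  end <- as.integer(info_get(fix$INFO, "END"))
  pos <- as.integer(fix$POS)
  end[is.na(end)] <- pos[is.na(end)]
  ins <- info_get(fix$INFO, "INSSEQ"); ins[is.na(ins)] <- ""
  src <- as.integer(info_get(fix$INFO, "INSSRC"))
  alt_base <- ifelse(vtype == "snv", fix$ALT, NA_character_)
  out <- new_truth(fix$ID, vtype, hap, pos, end, ins, src, alt_base)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a truth BED of SV intervals
#' @param path BED path (0-based half-open).
#' @return data frame: `contig`, `start`, `end` (1-based inclusive), `id`.
#' @export
read_truth_bed <- function(path) {
  n <- length(readLines(path))
  if (n == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), id = character(0)))
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(contig = b[[1]], start = b[[2]] + 1L, end = b[[3]],
             id = b[[4]], stringsAsFactors = FALSE)
}
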