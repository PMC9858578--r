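#' Write alignments as a SAM file
#'
#' @param aln alignment data frame (as produced by [emit_truth_alignments()]),
#'   sorted by position.
#' @param path output path.
#' @param ref_name,ref_len reference name and length for the `@SQ` header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref_name, ref_len) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(ref_len))), con)
  if (nrow(aln)) {
    hp <- if ("hp" %in% names(aln)) sprintf("\tHP:i:%d", aln$hp) else ""
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                       aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                       aln$cigar, aln$seq, hp), con)
  }
  invisible(path)
}

#' Read alignments from a SAM or BAM file
#'
#' SAM input is converted with [Rsamtools::asBam()] and records are loaded via
#' [Rsamtools::scanBam()]. Only mapped primary records are returned.
#'
#' @param path SAM or BAM path.
#' @return alignment data frame (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`), sorted by position.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos) & bitwAnd(x$flag, 0x904L) == 0L
  aln <- data.frame(qname = x$qname[keep], flag = x$flag[keep],
                    rname = as.character(x$rname[keep]), pos = x$pos[keep],
                    mapq = x$mapq[keep], cigar = x$cigar[keep],
                    seq = as.character(x$seq[keep]), stringsAsFactors = FALSE)
  aln[order(aln$pos), , drop = FALSE]
}

# Exploded CIGARs plus per-op reference/query offsets for a batch of records.
# Returns a list of per-read lists: op, len, rstart (1-based ref), qstart
# (1-based in SEQ). D consumes ref only; I/S consume query only.
parse_cigars <- function(aln) {
  ops_l <- GenomicAlignments::explodeCigarOps(aln$cigar)
  len_l <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  out <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    op <- ops_l[[i]]; len <- len_l[[i]]
    ref_c <- len * (op %in% c("M", "D", "=", "X", "N"))
    qry_c <- len * (op %in% c("M", "I", "S", "=", "X"))
    rstart <- aln$pos[i] + cumsum(c(0L, ref_c[-length(ref_c)]))
    qstart <- 1L + cumsum(c(0L, qry_c[-length(qry_c)]))
    out[[i]] <- list(op = op, len = len, rstart = rstart, qstart = qstart,
                     rend = aln$pos[i] + sum(ref_c) - 1L)
  }
  out
}

#' Write a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads as FASTQ (constant base quality)
#' @param reads list of read records (needs `name`, `seq`).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in reads)
    writeLines(c(paste0("@", r$name), r$seq, "+",
                 strrep("I", nchar(r$seq))), con)
  invisible(path)
}
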