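#' Write alignment records to a SAM file
#'
#' Emits a minimal single-end SAM file (with `@HD`/`@SQ` headers) from a tibble
#' of alignment records, as produced by [simulate_spliced_reads()]. Sequences
#' and qualities are written as `*`; coordinates are 1-based per the SAM
#' convention.
#'
#' @param reads Tibble with columns `qname`, `flag`, `chrom`, `pos` (1-based
#'   leftmost aligned base), `mapq`, `cigar`.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp), used
#'   for the `@SQ` header lines.
#' @param path Output file path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_sizes, path) {
  stopifnot(is.data.frame(reads), !is.null(names(chrom_sizes)))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), as.integer(chrom_sizes))
  )
  rec <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
    reads$qname, as.integer(reads$flag), reads$chrom,
    as.integer(reads$pos), as.integer(reads$mapq), reads$cigar
  )
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# Read alignments from SAM or BAM, excluding unmapped/secondary/supplementary/
# duplicate records. Returns a GAlignments with a `mapq` metadata column.
read_alignments <- function(path, which = NULL) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE
  )
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = flag, what = "mapq")
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = "mapq", which = which)
  }
  GenomicAlignments::readGAlignments(path, param = param)
}

# Chromosome lengths recorded in a SAM/BAM header, as a named integer vector.
alignment_chrom_sizes <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  }
  tl <- Rsamtools::scanBamHeader(path)[[1]]$targets
  setNames(as.integer(tl), names(tl))
}

# Write a tibble as a plain TSV with a fixed column order; deterministic bytes
# for identical input.
write_tsv_plain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
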