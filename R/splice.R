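#' Construct an exon model for splice-ratio analysis
#'
#' Defines the gene structure the expected-splicing-ratio detector works on:
#' merged exons ordered in transcription direction, the derived introns, and
#' a 200-nt "upstream anchor" pseudo-exon immediately 5' of the transcription
#' start site so promoter-proximal read starts count as expected for the
#' first exon.
#'
#' @param exons Data frame with `start`, `end` (1-based inclusive genomic
#'   coordinates).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param gene_id Gene label.
#' @param read_length Library read length in nt (default 97).
#' @param anchor_length Length of the upstream anchor in nt (default 200).
#' @return An `exon_model` object: exon table (`rank` in transcription order,
#'   `start`, `end`, `length`), intron table, anchor interval, strand,
#'   chromosome and read length.
#' @export
exon_model <- function(exons, chrom = "chr13", strand = "+",
                       gene_id = "GENE", read_length = 97,
                       anchor_length = 200) {
  stopifnot(strand %in% c("+", "-"), read_length >= 1)
  exons <- as_tibble(exons)
  if (any(exons$end < exons$start)) abort("zero- or negative-length exon")
  exons <- arrange(exons, .data$start)
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    abort("exons overlap; merge them first (see build_exon_model)")
  introns <- if (nrow(exons) > 1) {
    tibble(start = exons$end[-nrow(exons)] + 1L, end = exons$start[-1] - 1L)
  } else {
    tibble(start = integer(), end = integer())
  }
  if (strand == "-") exons <- arrange(exons, dplyr::desc(.data$start))
  exons <- mutate(exons, rank = dplyr::row_number(),
                  length = .data$end - .data$start + 1L) %>%
    select("rank", "start", "end", "length")
  tss <- if (strand == "+") exons$start[1] else exons$end[1]
  anchor <- if (strand == "+") {
    c(start = tss - anchor_length, end = tss - 1L)
  } else {
    c(start = tss + 1L, end = tss + anchor_length)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand, exons = exons,
         introns = introns, anchor = anchor, read_length = read_length,
         anchor_length = anchor_length),
    class = "exon_model"
  )
}

#' Build an exon model from a GTF annotation
#'
#' Extracts the annotated exons of one gene, merges overlapping exon variants
#' into single intervals, and orders them 5' to 3' by strand.
#'
#' @param gtf Path to a GTF file (1-based inclusive coordinates).
#' @param gene_id Gene identifier matched against the GTF `gene_id`
#'   attribute.
#' @param read_length Library read length in nt.
#' @param anchor_length Upstream anchor length in nt.
#' @return An [exon_model()] object.
#' @export
build_exon_model <- function(gtf, gene_id, read_length = 97,
                             anchor_length = 200) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  gr <- gr[gr$type == "exon" & gr$gene_id == gene_id]
  if (length(gr) == 0) abort(sprintf("gene '%s' not found in annotation", gene_id))
  strand <- unique(as.character(GenomicRanges::strand(gr)))
  if (length(strand) != 1 || !strand %in% c("+", "-"))
    abort("gene must have a single explicit strand")
  merged <- GenomicRanges::reduce(gr)
  exon_model(
    tibble(start = GenomicRanges::start(merged), end = GenomicRanges::end(merged)),
    chrom = as.character(GenomicRanges::seqnames(merged))[1],
    strand = strand, gene_id = gene_id,
    read_length = read_length, anchor_length = anchor_length
  )
}

#' Expected upstream exon sets for each exon
#'
#' For each exon k, identifies the most 5'-distant exon whose sequence can
#' still be contained in a read of the library's length ending in exon k
#' after canonical splicing: exon j (j < k) is reachable when the summed
#' lengths of the exons strictly between j and k are less than
#' `read_length - 1` (a read whose final base is the first base of exon k
#' extends `read_length - 1` nt upstream in spliced coordinates). Each exon
#' is always a member of its own set; the upstream anchor is included when
#' all exons before k fit the same bound.
#'
#' @param model An [exon_model()].
#' @return Tibble with `rank`, `min_rank` (most distant reachable exon) and
#'   `anchor_included`. The set for exon k is `min_rank:k` (plus the anchor
#'   when flagged) and is always suffix-contiguous.
#' @export
expected_upstream <- function(model) {
  stopifnot(inherits(model, "exon_model"))
  len <- model$exons$length
  K <- length(len)
  rl <- model$read_length
  cl <- c(0, cumsum(len)) # cl[j+1] = total length of exons 1..j
  res <- lapply(seq_len(K), function(k) {
    between <- function(j) cl[k] - cl[j + 1] # exons strictly between j and k
    js <- seq_len(k)
    reachable <- vapply(js, function(j) j == k || between(j) < rl - 1,
                        logical(1))
    tibble(rank = k, min_rank = min(js[reachable]),
           anchor_included = (cl[k] - cl[1]) < rl - 1)
  })
  bind_rows(res)
}

# 5'-most aligned genomic base of each alignment, by gene strand.
read_start_5p <- function(ga, strand) {
  if (strand == "+") GenomicAlignments::start(ga) else GenomicAlignments::end(ga)
}

#' Per-exon expected splicing ratio from RNA-seq alignments
#'
#' For each exon, the informative reads are those with at least one aligned
#' base in the exon; among them, a read is "expected" when its 5' start
#' coordinate falls inside one of the exon's expected upstream exons (or the
#' upstream anchor region). The expected splicing ratio is expected /
#' informative, reported only where at least `min_reads` reads were recorded.
#'
#' @param alignments Path to a SAM/BAM of RNA-seq alignments (spliced reads
#'   carry N CIGAR operations).
#' @param model An [exon_model()].
#' @param min_reads Minimum informative reads for a cell to be reported
#'   (default 10, below which the exon is not informative).
#' @param sample_id Optional sample label attached to the output.
#' @return Tibble with `exon_rank`, `start`, `end`, `informative_reads`,
#'   `expected_reads`, `ratio` (`NA` when not informative) and `sample_id`.
#' @export
compute_splice_ratio <- function(alignments, model, min_reads = 10,
                                 sample_id = NA_character_) {
  stopifnot(inherits(model, "exon_model"))
  span_lo <- min(model$exons$start, model$anchor["start"])
  span_hi <- max(model$exons$end, model$anchor["end"])
  which <- GenomicRanges::GRanges(model$chrom,
                                  IRanges::IRanges(span_lo, span_hi))
  ga <- read_alignments(alignments, which = which)
  sets <- expected_upstream(model)
  K <- nrow(model$exons)
  if (length(ga) == 0) {
    return(tibble(exon_rank = model$exons$rank, start = model$exons$start,
                  end = model$exons$end, informative_reads = 0L,
                  expected_reads = 0L, ratio = NA_real_,
                  sample_id = sample_id))
  }
  blocks <- GenomicAlignments::grglist(ga) # aligned M blocks per read
  exon_gr <- GenomicRanges::GRanges(
    model$chrom, IRanges::IRanges(model$exons$start, model$exons$end))
  ov <- GenomicRanges::findOverlaps(blocks, exon_gr)
  # which exon (rank) or anchor (0) contains each read's 5' start
  s5 <- read_start_5p(ga, model$strand)
  start_rank <- rep(NA_integer_, length(ga))
  for (k in seq_len(K)) {
    inside <- s5 >= model$exons$start[k] & s5 <= model$exons$end[k]
    start_rank[inside] <- k
  }
  in_anchor <- s5 >= model$anchor["start"] & s5 <= model$anchor["end"]
  start_rank[in_anchor] <- 0L
  res <- lapply(seq_len(K), function(k) {
    reads_k <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]
    informative <- length(reads_k)
    sr <- start_rank[reads_k]
    expected <- sum(!is.na(sr) &
                      ((sr == 0L & sets$anchor_included[k]) |
                         (sr >= sets$min_rank[k] & sr <= k)))
    tibble(exon_rank = k, start = model$exons$start[k],
           end = model$exons$end[k],
           informative_reads = informative, expected_reads = expected,
           ratio = if (informative >= min_reads) expected / informative
                   else NA_real_)
  })
  mutate(bind_rows(res), sample_id = sample_id)
}

#' Fraction of noncanonical splice junctions over a gene
#'
#' Every N gap of an alignment within the gene span is compared with the
#' model's annotated introns; a gap is canonical only when both boundaries
#' match an intron exactly. Reads without N operations contribute nothing.
#'
#' @param alignments Path to a SAM/BAM.
#' @param model An [exon_model()].
#' @param sample_id Optional sample label.
#' @return Tibble with `total_gaps`, `noncanonical_gaps`, `fraction`
#'   (`NA` when no gapped reads are present).
#' @export
noncanonical_junction_fraction <- function(alignments, model,
                                           sample_id = NA_character_) {
  stopifnot(inherits(model, "exon_model"))
  span <- GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(min(model$exons$start), max(model$exons$end)))
  ga <- read_alignments(alignments, which = span)
  gaps <- unlist(GenomicAlignments::junctions(ga), use.names = FALSE)
  gaps <- gaps[IRanges::overlapsAny(gaps, span)]
  total <- length(gaps)
  if (total == 0) {
    return(tibble(sample_id = sample_id, total_gaps = 0L,
                  noncanonical_gaps = 0L, fraction = NA_real_))
  }
  key <- paste(GenomicRanges::start(gaps), GenomicRanges::end(gaps))
  canon <- paste(model$introns$start, model$introns$end)
  noncanon <- sum(!key %in% canon)
  tibble(sample_id = sample_id, total_gaps = total,
         noncanonical_gaps = noncanon, fraction = noncanon / total)
}

#' Assemble per-sample splice-ratio columns into the exon x sample matrix
#'
#' @param columns Named list of [compute_splice_ratio()] outputs sharing one
#'   exon model; names are the sample labels (must be unique).
#' @return Wide tibble: one row per exon (`exon_rank`, `start`, `end`), one
#'   ratio column per sample (`NA` marks not-informative cells); the matching
#'   informative read counts are attached as attribute `informative_reads`.
#'   An empty list yields an empty tibble.
#' @export
assemble_splice_matrix <- function(columns) {
  if (length(columns) == 0) return(tibble())
  labels <- names(columns)
  if (is.null(labels) || anyDuplicated(labels))
    abort("columns must be uniquely named by sample")
  base <- select(columns[[1]], "exon_rank", "start", "end")
  for (col in columns) {
    if (!identical(select(col, "exon_rank", "start", "end"), base))
      abort("all columns must share the same exon model")
  }
  ratios <- lapply(columns, function(col) col$ratio)
  counts <- do.call(cbind, lapply(columns, function(col) col$informative_reads))
  out <- bind_cols(base, as_tibble(setNames(ratios, labels)))
  attr(out, "informative_reads") <- counts
  class(out) <- c("splice_matrix", class(out))
  out
}
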