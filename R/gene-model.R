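#' Gene model for pseudoexon analysis
#'
#' A `gene_model` is the coordinate frame for all cDNA (c.), RNA (r.) and
#' protein (p.) arithmetic in this package: an ordered multi-exon structure on
#' one chromosome, a strand, the transcript position of the translation start,
#' and the underlying genomic sequence.
#'
#' Genomic coordinates are 1-based inclusive throughout (HGVS/VCF convention);
#' BED input/output converts to and from 0-based half-open at the boundary and
#' nowhere else. Exons are stored in ascending genomic order; transcript order
#' is ascending for `+` genes and descending for `-` genes. The translation
#' start (`cds_start`) is a transcript position, i.e. c.1 need not fall in the
#' first exon (as for APC, where translation starts in exon 2).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name (must name a sequence in `genome`).
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`: genomic 1-based
#'   inclusive exon intervals, non-overlapping, each intron at least 4 bp.
#' @param cds_start Transcript coordinate (1-based, spliced) of the first base
#'   of the start codon (the base written c.1).
#' @param genome A [Biostrings::DNAStringSet] holding the chromosome sequence,
#'   or a named character vector coerced to one.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, genome) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) stop("exon end < start")
  if (nrow(exons) > 1L) {
    gaps <- exons$start[-1L] - exons$end[-nrow(exons)] - 1L
    if (any(gaps < 4L)) stop("exons overlap or intron shorter than 4 bp")
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!chrom %in% names(genome)) stop("chrom '", chrom, "' not in genome")
  tx_len <- sum(exons$end - exons$start + 1L)
  cds_start <- as.integer(cds_start)
  if (cds_start < 1L || cds_start > tx_len)
    stop("cds_start outside transcript (length ", tx_len, ")")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds_start = cds_start, genome = genome),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exons, transcript %d nt, CDS from t.%d\n",
              x$gene_id, x$chrom, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons), transcript_length(x), x$cds_start))
  invisible(x)
}

#' Transcript length of a gene model
#' @param model A [gene_model].
#' @return Integer: summed exon length.
#' @export
transcript_length <- function(model) {
  sum(model$exons$end - model$exons$start + 1L)
}

n_exons <- function(model) nrow(model$exons)

# exons in transcript (5'->3') order
exons_tx_order <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

# transcript start/end (spliced coords) of each exon, transcript order
exon_tx_bounds <- function(model) {
  ex <- exons_tx_order(model)
  len <- ex$end - ex$start + 1L
  tx_end <- cumsum(len)
  data.frame(tx_start = tx_end - len + 1L, tx_end = tx_end)
}

gene_span <- function(model) c(min(model$exons$start), max(model$exons$end))

#' Extract genomic sequence in transcript orientation
#'
#' @param model A [gene_model].
#' @param start,end Genomic 1-based inclusive interval.
#' @return Character scalar: the genomic bases, reverse-complemented for
#'   minus-strand genes so the string always reads 5'->3' of the transcript.
#' @export
genomic_seq <- function(model, start, end) {
  s <- Biostrings::subseq(model$genome[[model$chrom]], start, end)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Spliced transcript sequence of a gene model
#' @param model A [gene_model].
#' @return Character scalar (5'->3').
#' @export
transcript_seq <- function(model) {
  ex <- exons_tx_order(model)
  paste0(vapply(seq_len(nrow(ex)),
                function(i) genomic_seq(model, ex$start[i], ex$end[i]),
                character(1)), collapse = "")
}

# transcript position -> genomic position
tx_to_genomic <- function(model, t_pos) {
  t_pos <- as.integer(t_pos)
  bounds <- exon_tx_bounds(model)
  ex <- exons_tx_order(model)
  out <- integer(length(t_pos))
  for (k in seq_along(t_pos)) {
    tp <- t_pos[k]
    if (is.na(tp) || tp < 1L || tp > bounds$tx_end[nrow(bounds)])
      stop("transcript position ", tp, " outside transcript")
    i <- which(tp >= bounds$tx_start & tp <= bounds$tx_end)
    off <- tp - bounds$tx_start[i]
    out[k] <- if (model$strand == "+") ex$start[i] + off else ex$end[i] - off
  }
  out
}

# genomic position -> transcript position (exonic only; NA if intronic)
genomic_to_tx <- function(model, g_pos) {
  bounds <- exon_tx_bounds(model)
  ex <- exons_tx_order(model)
  vapply(as.integer(g_pos), function(g) {
    i <- which(g >= ex$start & g <= ex$end)
    if (length(i) == 0L) return(NA_integer_)
    off <- if (model$strand == "+") g - ex$start[i] else ex$end[i] - g
    bounds$tx_start[i] + off
  }, integer(1))
}

# introns in transcript order: genomic first/last intronic base, oriented so
# that `left` is the transcript-5' end of the intron
introns_tx_order <- function(model) {
  ex <- exons_tx_order(model)
  n <- nrow(ex)
  if (n < 2L) return(data.frame(five = integer(0), three = integer(0)))
  if (model$strand == "+") {
    data.frame(five = ex$end[-n] + 1L, three = ex$start[-1L] - 1L)
  } else {
    data.frame(five = ex$start[-n] - 1L, three = ex$end[-1L] + 1L)
  }
}

intron_length <- function(model, intron_index) {
  intr <- introns_tx_order(model)
  abs(intr$three[intron_index] - intr$five[intron_index]) + 1L
}

strand_sign <- function(model) if (model$strand == "+") 1L else -1L
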