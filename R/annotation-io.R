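#' Write a gene model's genome as FASTA
#'
#' @param model A [gene_model].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(model, path) {
  Biostrings::writeXStringSet(model$genome, path)
  invisible(path)
}

#' Write a gene model's annotation as GFF3 or BED12
#'
#' GFF3 emits gene, mRNA, exon and CDS features; BED12 emits one line with
#' exon blocks and the CDS as the thick interval. Genomic coordinates are
#' 1-based inclusive internally; the BED writer converts to 0-based half-open
#' at the boundary.
#'
#' @param model A [gene_model].
#' @param path Output path.
#' @param format `"gff3"` or `"bed12"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(model, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  ex <- model$exons
  span <- gene_span(model)
  cds <- cds_genomic_segments(model)
  if (format == "gff3") {
    tx_id <- paste0(model$gene_id, ".t1")
    gr <- c(
      GenomicRanges::GRanges(model$chrom,
                             IRanges::IRanges(span[1], span[2]),
                             strand = model$strand, type = "gene",
                             ID = model$gene_id, Parent = NA_character_,
                             phase = NA_integer_),
      GenomicRanges::GRanges(model$chrom,
                             IRanges::IRanges(span[1], span[2]),
                             strand = model$strand, type = "mRNA",
                             ID = tx_id, Parent = model$gene_id,
                             phase = NA_integer_),
      GenomicRanges::GRanges(model$chrom,
                             IRanges::IRanges(ex$start, ex$end),
                             strand = model$strand, type = "exon",
                             ID = paste0(tx_id, ".exon", seq_len(nrow(ex))),
                             Parent = tx_id, phase = NA_integer_),
      GenomicRanges::GRanges(model$chrom,
                             IRanges::IRanges(cds$start, cds$end),
                             strand = model$strand, type = "CDS",
                             ID = paste0(tx_id, ".cds", seq_len(nrow(cds))),
                             Parent = tx_id, phase = cds_phases(model, cds)))
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    line <- paste(
      model$chrom, span[1] - 1L, span[2], model$gene_id, 0, model$strand,
      min(cds$start) - 1L, max(cds$end),
      "0", nrow(ex),
      paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
      paste0(paste(ex$start - span[1], collapse = ","), ","),
      sep = "\t")
    writeLines(line, path)
  }
  invisible(path)
}

# GFF3 phase per CDS segment (segments in ascending genomic order)
cds_phases <- function(model, cds) {
  ord <- if (model$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  len <- cds$end - cds$start + 1L
  cum <- cumsum(c(0L, len[ord]))[seq_len(nrow(cds))]
  phase_tx <- (3L - cum %% 3L) %% 3L
  phase <- integer(nrow(cds))
  phase[ord] <- phase_tx
  phase
}

# genomic intervals covered by the CDS (ascending order)
cds_genomic_segments <- function(model) {
  tx_len <- transcript_length(model)
  aa <- translate_from(transcript_seq(model), model$cds_start)
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  cds_end_t <- if (stop_at > 0) model$cds_start + 3L * stop_at - 1L else tx_len
  g <- tx_to_genomic(model, model$cds_start:cds_end_t)
  g <- sort(g)
  breaks <- c(0L, which(diff(g) != 1L), length(g))
  do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(i)
    data.frame(start = g[breaks[i] + 1L], end = g[breaks[i + 1L]])))
}

#' Read a gene model from annotation + FASTA
#'
#' GFF3: exon features define the transcript structure and CDS features the
#' translation start. BED12: blocks define exons and the thick interval the
#' CDS. Multi-gene files are not supported; the file must describe one
#' transcript.
#'
#' @param annotation_path GFF3 or BED12 path.
#' @param fasta_path Genome FASTA path.
#' @param format `"gff3"` or `"bed12"` (default guessed from extension).
#' @param gene_id Optional gene id override.
#' @return A [gene_model].
#' @export
read_gene_model <- function(annotation_path, fasta_path, format = NULL,
                            gene_id = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", annotation_path, ignore.case = TRUE))
      "bed12" else "gff3"
  }
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (format == "gff3") {
    gr <- rtracklayer::import(annotation_path, format = "gff3")
    exon <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    if (length(exon) == 0L) stop("no exon features in ", annotation_path)
    if (length(cds) == 0L) stop("no CDS features in ", annotation_path)
    chrom <- as.character(GenomicRanges::seqnames(exon))[1]
    strand <- as.character(GenomicRanges::strand(exon))[1]
    exons <- data.frame(start = GenomicRanges::start(exon),
                        end = GenomicRanges::end(exon))
    cds_first_g <- if (strand == "+") min(GenomicRanges::start(cds))
                   else max(GenomicRanges::end(cds))
    gid <- gene_id
    if (is.null(gid)) {
      gene <- gr[gr$type == "gene"]
      gid <- if (length(gene) && !is.null(gene$ID)) gene$ID[1] else "GENE1"
    }
  } else {
    f <- strsplit(readLines(annotation_path)[1], "\t")[[1]]
    if (length(f) < 12L) stop("BED12 requires 12 columns")
    chrom <- f[1]; strand <- f[6]
    chrom_start <- as.integer(f[2])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offsets <- as.integer(strsplit(f[12], ",")[[1]])
    exons <- data.frame(start = chrom_start + offsets + 1L,
                        end = chrom_start + offsets + sizes)
    thick_start <- as.integer(f[7]) + 1L
    thick_end <- as.integer(f[8])
    cds_first_g <- if (strand == "+") thick_start else thick_end
    gid <- if (is.null(gene_id)) f[4] else gene_id
  }
  tmp <- gene_model(gid, chrom, strand, exons, cds_start = 1L, genome = genome)
  cds_start_t <- genomic_to_tx(tmp, cds_first_g)
  if (is.na(cds_start_t)) stop("CDS start is not exonic")
  gene_model(gid, chrom, strand, exons, cds_start = cds_start_t,
             genome = genome)
}
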