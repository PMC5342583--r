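#' Read splice junctions from a STAR-style SJ table or BED6
#'
#' `sj_tab` is the 9-column STAR SJ.out.tab dialect (chrom, intron start,
#' intron end, strand code 0/1/2, motif code, annotated flag, unique reads,
#' multi-mapping reads, max overhang), 1-based inclusive on the first and last
#' intronic bases. BED6 intervals are converted from 0-based half-open, with
#' the score column taken as the unique read count. Records are sorted by
#' (chrom, intron_start).
#'
#' @param path File path.
#' @param format `"sj_tab"` or `"bed6"`.
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, the
#'   donor/acceptor motif class of BED6 junctions (which carry none) is derived
#'   from the intron-terminal dinucleotides.
#' @return Data frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand` (`"+"`, `"-"` or `NA`), `motif_class` (`"GT/AG"`, `"GC/AG"`,
#'   `"other"`), `unique_reads`, `annotated`.
#' @export
read_junctions <- function(path, format = c("sj_tab", "bed6"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("junction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty junction file: ", path)
    return(empty_junctions())
  }
  fields <- strsplit(lines, "[\t ]+")
  ncols <- lengths(fields)
  want <- if (format == "sj_tab") 9L else 6L
  bad <- which(ncols != want)
  if (length(bad))
    stop(format, " record with ", ncols[bad[1]], " fields (expected ", want,
         ") at line ", bad[1], " of ", path)
  m <- do.call(rbind, fields)
  if (format == "sj_tab") {
    strand_code <- as.integer(m[, 4])
    motif_code <- as.integer(m[, 5])
    out <- data.frame(
      chrom = m[, 1],
      intron_start = as.integer(m[, 2]),
      intron_end = as.integer(m[, 3]),
      strand = c(NA, "+", "-")[strand_code + 1L],
      motif_class = ifelse(motif_code %in% 1:2, "GT/AG",
                    ifelse(motif_code %in% 3:4, "GC/AG", "other")),
      unique_reads = as.integer(m[, 7]),
      annotated = as.integer(m[, 6]) == 1L)
  } else {
    out <- data.frame(
      chrom = m[, 1],
      intron_start = as.integer(m[, 2]) + 1L,   # 0-based half-open -> 1-based
      intron_end = as.integer(m[, 3]),
      strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], NA),
      motif_class = "other",
      unique_reads = as.integer(m[, 5]),
      annotated = FALSE)
    if (!is.null(genome)) out$motif_class <- junction_motif(out, genome)
  }
  if (any(out$intron_start > out$intron_end)) stop("junction with start > end")
  if (any(out$unique_reads < 0)) stop("negative unique read count")
  out <- out[order(out$chrom, out$intron_start, out$intron_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_junctions <- function() {
  data.frame(chrom = character(0), intron_start = integer(0),
             intron_end = integer(0), strand = character(0),
             motif_class = character(0), unique_reads = integer(0),
             annotated = logical(0))
}

# motif class from the intron-terminal dinucleotides, strand-aware
junction_motif <- function(junctions, genome) {
  vapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    if (!j$chrom %in% names(genome) || is.na(j$strand)) return("other")
    chrseq <- genome[[j$chrom]]
    d5 <- as.character(Biostrings::subseq(chrseq, j$intron_start, j$intron_start + 1L))
    d3 <- as.character(Biostrings::subseq(chrseq, j$intron_end - 1L, j$intron_end))
    if (j$strand == "-") {
      tmp <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(d5)))
      d5 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(d3)))
      d3 <- tmp
    }
    key <- paste0(toupper(d5), "/", toupper(d3))
    if (key == "GT/AG") "GT/AG" else if (key == "GC/AG") "GC/AG" else "other"
  }, character(1))
}

#' Write junctions as a STAR-style SJ table
#'
#' @param junctions Data frame as returned by [read_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sj_tab <- function(junctions, path) {
  strand_code <- match(junctions$strand, c("+", "-"))
  strand_code[is.na(strand_code)] <- 0L
  motif_code <- ifelse(junctions$motif_class == "GT/AG", 1L,
                ifelse(junctions$motif_class == "GC/AG", 3L, 0L))
  m <- cbind(junctions$chrom, junctions$intron_start, junctions$intron_end,
             strand_code, motif_code, as.integer(junctions$annotated),
             junctions$unique_reads, 0L, 30L)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter junctions by per-motif-class minimum unique read support
#'
#' Default minima mirror sensitive splice-junction calling: 2 unique reads for
#' the canonical GT/AG and GC/AG classes, 6 for non-canonical junctions.
#'
#' @param junctions Data frame of junctions.
#' @param min_unique Named vector of per-class minima.
#' @return The surviving junctions.
#' @export
filter_junctions <- function(junctions,
                             min_unique = c("GT/AG" = 2, "GC/AG" = 2, other = 6)) {
  if (nrow(junctions) == 0L) return(junctions)
  minima <- min_unique[junctions$motif_class]
  minima[is.na(minima)] <- min_unique[["other"]]
  junctions[junctions$unique_reads >= minima, , drop = FALSE]
}

#' Detect pseudoexon inclusion events from paired novel junctions
#'
#' A pseudoexon inclusion leaves two unannotated junctions inside one annotated
#' intron: J1 sharing the upstream exon's donor, J2 sharing the downstream
#' exon's acceptor, with a fully intronic internal segment between them whose
#' length falls in `length_range`. Inclusion depth is quantified against the
#' canonical junction: `inclusion_fraction = inclusion_reads /
#' (inclusion_reads + canonical_reads)`, where `inclusion_reads` are those of
#' the transcript-downstream novel junction (or the pair minimum, see
#' `inclusion_stat`). Unpaired novel junctions are returned separately as
#' incomplete candidates, never as events.
#'
#' @param junctions Filtered junction data frame.
#' @param model A [gene_model].
#' @param length_range Allowed internal segment lengths (bp).
#' @param inclusion_stat `"downstream"` (default) or `"min"`.
#' @return List with `events` (one row per pseudoexon event: segment
#'   coordinates, length, read support, inclusion fraction) and `incomplete`
#'   (unpaired novel junctions).
#' @export
detect_pseudoexon_events <- function(junctions, model,
                                     length_range = c(50, 300),
                                     inclusion_stat = c("downstream", "min")) {
  inclusion_stat <- match.arg(inclusion_stat)
  jx <- junctions[junctions$chrom == model$chrom, , drop = FALSE]
  if (nrow(jx) && any(is.na(jx$strand))) {
    warning("unstranded junctions: imputing strand from the gene model")
    jx$strand[is.na(jx$strand)] <- model$strand
  }
  jx <- jx[jx$strand == model$strand, , drop = FALSE]
  ex <- model$exons                       # ascending genomic order
  n <- nrow(ex)
  events <- list(); used <- rep(FALSE, nrow(jx))
  novel <- !jx$annotated
  for (i in seq_len(n - 1L)) {
    can_start <- ex$end[i] + 1L; can_end <- ex$start[i + 1L] - 1L
    canonical <- jx$intron_start == can_start & jx$intron_end == can_end
    can_reads <- sum(jx$unique_reads[canonical])
    used[canonical] <- TRUE
    j1 <- which(novel & jx$intron_start == can_start & jx$intron_end < can_end)
    j2 <- which(novel & jx$intron_end == can_end & jx$intron_start > can_start)
    for (a in j1) for (b in j2) {
      seg_start <- jx$intron_end[a] + 1L
      seg_end <- jx$intron_start[b] - 1L
      seg_len <- seg_end - seg_start + 1L
      if (seg_len < length_range[1] || seg_len > length_range[2]) next
      used[c(a, b)] <- TRUE
      down <- if (model$strand == "+") b else a
      incl <- switch(inclusion_stat,
                     downstream = jx$unique_reads[down],
                     min = min(jx$unique_reads[a], jx$unique_reads[b]))
      events[[length(events) + 1L]] <- data.frame(
        gene_id = model$gene_id, chrom = model$chrom,
        intron_index = if (model$strand == "+") i else n - i,
        segment_start = seg_start, segment_end = seg_end,
        segment_length = seg_len,
        upstream_reads = jx$unique_reads[if (model$strand == "+") a else b],
        downstream_reads = jx$unique_reads[down],
        canonical_reads = can_reads,
        inclusion_reads = incl,
        inclusion_fraction = if (incl + can_reads > 0)
          incl / (incl + can_reads) else NA_real_)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else data.frame(
    gene_id = character(0), chrom = character(0), intron_index = integer(0),
    segment_start = integer(0), segment_end = integer(0),
    segment_length = integer(0), upstream_reads = integer(0),
    downstream_reads = integer(0), canonical_reads = integer(0),
    inclusion_reads = integer(0), inclusion_fraction = numeric(0))
  incomplete <- jx[novel & !used, , drop = FALSE]
  rownames(ev) <- NULL; rownames(incomplete) <- NULL
  list(events = ev, incomplete = incomplete)
}

#' Check variant phasing within pseudoexon-supporting reads
#'
#' Given per-read base observations at the variant position, extracted from
#' reads that support the pseudoexon inclusion and cover the variant (possible
#' when the variant lies inside the pseudoexon), returns the fraction carrying
#' the alternate allele — evidence that the variant is on the
#' pseudoexon-forming haplotype.
#'
#' @param observations Data frame with columns `read_id` and `base`.
#' @param variant A [cdna_variant].
#' @return List with `alt_fraction` (NA when no coverage), `n_alt`, `n_ref`,
#'   `n_other`, `n_total` and `no_coverage`.
#' @export
variant_phase_check <- function(observations, variant) {
  stopifnot(inherits(variant, "cdna_variant"))
  n <- nrow(observations)
  if (is.null(n) || n == 0L)
    return(list(alt_fraction = NA_real_, n_alt = 0L, n_ref = 0L,
                n_other = 0L, n_total = 0L, no_coverage = TRUE))
  base <- toupper(observations$base)
  n_alt <- sum(base == variant$alt)
  n_ref <- sum(base == variant$ref)
  list(alt_fraction = n_alt / n, n_alt = n_alt, n_ref = n_ref,
       n_other = n - n_alt - n_ref, n_total = n, no_coverage = FALSE)
}
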