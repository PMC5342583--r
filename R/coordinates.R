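#' cDNA position with intronic offset
#'
#' HGVS-style coding-sequence position: a positive exonic anchor (c.
#' coordinate) plus an intronic offset. Offset 0 means the position is exonic;
#' `+n` means n bases into the intron downstream (transcript 3') of the anchor
#' exon end, `-n` means n bases upstream (transcript 5') of the anchor exon
#' start, as in c.1408+731 or c.646-1806.
#'
#' @param anchor Positive integer c. coordinate of the nearest exonic base.
#' @param offset Integer intronic offset (0 = exonic).
#' @return An object of class `cdna_pos`.
#' @export
cdna_pos <- function(anchor, offset = 0L) {
  anchor <- as.integer(anchor); offset <- as.integer(offset)
  if (is.na(anchor) || anchor < 1L) stop("anchor must be a positive integer")
  structure(list(anchor = anchor, offset = offset), class = "cdna_pos")
}

#' @export
print.cdna_pos <- function(x, ...) {
  cat("<cdna_pos> c.", format_cdna_pos(x), "\n", sep = "")
  invisible(x)
}

format_cdna_pos <- function(pos) {
  if (pos$offset == 0L) as.character(pos$anchor)
  else paste0(pos$anchor, ifelse(pos$offset > 0L, "+", "-"), abs(pos$offset))
}

#' cDNA substitution variant
#'
#' @param position A [cdna_pos].
#' @param ref,alt Single reference/alternate nucleotides (A/C/G/T, transcript
#'   strand), `ref != alt`.
#' @return An object of class `cdna_variant`.
#' @export
cdna_variant <- function(position, ref, alt) {
  stopifnot(inherits(position, "cdna_pos"))
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% c("A", "C", "G", "T")) stop("ref allele not ACGT: '", ref, "'")
  if (!alt %in% c("A", "C", "G", "T")) stop("alt allele not ACGT: '", alt, "'")
  if (ref == alt) stop("ref and alt alleles are identical")
  structure(list(position = position, ref = ref, alt = alt),
            class = "cdna_variant")
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat("<cdna_variant>", format_hgvs_c(x), "\n")
  invisible(x)
}

#' Parse an HGVS c. substitution string
#'
#' Accepts the substitution grammar `c.<anchor>[(+|-)<offset>]<ref>><alt>`,
#' e.g. `"c.646-1806T>G"` or `"c.100A>T"`.
#'
#' @param text HGVS c. string.
#' @return A [cdna_variant].
#' @export
#' @examples
#' parse_hgvs_c("c.1408+731C>T")
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^c\\.([0-9]+)(([+-])([0-9]+))?([A-Za-z]+)>([A-Za-z]+)$", text))[[1]]
  if (length(m) == 0L) {
    # locate the offending token for a useful message
    if (!grepl("^c\\.", text)) stop("malformed HGVS c. string (missing 'c.' prefix): '", text, "'")
    body <- sub("^c\\.", "", text)
    if (!grepl("^[0-9]+", body)) stop("malformed anchor in '", text, "'")
    rest <- sub("^[0-9]+", "", body)
    if (grepl("^[+-]", rest) && !grepl("^[+-][0-9]+", rest))
      stop("malformed offset token '", rest, "' in '", text, "'")
    stop("malformed HGVS c. substitution: '", text, "'")
  }
  anchor <- as.integer(m[2])
  offset <- if (m[3] == "") 0L else as.integer(m[5]) * ifelse(m[4] == "-", -1L, 1L)
  cdna_variant(cdna_pos(anchor, offset), m[6], m[7])
}

#' Format a cDNA variant as an HGVS c. string
#'
#' Inverse of [parse_hgvs_c()]: `format_hgvs_c(parse_hgvs_c(x)) == x` for every
#' grammar-valid `x`.
#'
#' @param variant A [cdna_variant].
#' @return Character scalar.
#' @export
format_hgvs_c <- function(variant) {
  stopifnot(inherits(variant, "cdna_variant"))
  paste0("c.", format_cdna_pos(variant$position), variant$ref, ">", variant$alt)
}

#' Map a cDNA position to its genomic coordinate
#'
#' Strand-aware: intronic offsets follow transcript orientation, so `+n` moves
#' toward larger genomic coordinates on `+` genes and smaller on `-` genes.
#'
#' @param model A [gene_model].
#' @param pos A [cdna_pos].
#' @return Genomic position (1-based).
#' @export
map_cdna_to_genomic <- function(model, pos) {
  stopifnot(inherits(pos, "cdna_pos"))
  t_pos <- pos$anchor + model$cds_start - 1L
  if (t_pos > transcript_length(model))
    stop("c.", format_cdna_pos(pos), " beyond transcript end")
  g <- tx_to_genomic(model, t_pos)
  if (pos$offset == 0L) return(g)
  bounds <- exon_tx_bounds(model)
  i <- which(t_pos >= bounds$tx_start & t_pos <= bounds$tx_end)
  if (pos$offset > 0L) {
    if (t_pos != bounds$tx_end[i])
      stop("positive offset requires the anchor at an exon 3' end (c.",
           format_cdna_pos(pos), ")")
    if (i == nrow(bounds) || pos$offset >= intron_length(model, i))
      stop("offset exceeds intron (c.", format_cdna_pos(pos), ")")
  } else {
    if (t_pos != bounds$tx_start[i])
      stop("negative offset requires the anchor at an exon 5' start (c.",
           format_cdna_pos(pos), ")")
    if (i == 1L || abs(pos$offset) >= intron_length(model, i - 1L))
      stop("offset exceeds intron (c.", format_cdna_pos(pos), ")")
  }
  g + pos$offset * strand_sign(model)
}

#' Map a genomic position to its cDNA position
#'
#' Exonic positions get offset 0. Intronic positions anchor to the nearer exon
#' in transcript orientation: the 5' half of an intron anchors to the upstream
#' exon end (`+n`), the 3' half to the downstream exon start (`-n`); an
#' equidistant position anchors upstream. Inverse of [map_cdna_to_genomic()]
#' across the whole gene span.
#'
#' @param model A [gene_model].
#' @param g_pos Genomic position within the gene span (first to last exon).
#' @return A [cdna_pos].
#' @export
map_genomic_to_cdna <- function(model, g_pos) {
  g_pos <- as.integer(g_pos)
  span <- gene_span(model)
  if (g_pos < span[1] || g_pos > span[2])
    stop("genomic position ", g_pos, " outside gene span ",
         span[1], "-", span[2])
  t_pos <- genomic_to_tx(model, g_pos)
  if (!is.na(t_pos)) {
    anchor <- t_pos - model$cds_start + 1L
    if (anchor < 1L) stop("position maps 5' of c.1; positions upstream of the ",
                          "start codon are not supported")
    return(cdna_pos(anchor, 0L))
  }
  intr <- introns_tx_order(model)
  bounds <- exon_tx_bounds(model)
  sgn <- strand_sign(model)
  for (i in seq_len(nrow(intr))) {
    lo <- min(intr$five[i], intr$three[i]); hi <- max(intr$five[i], intr$three[i])
    if (g_pos >= lo && g_pos <= hi) {
      d5 <- (g_pos - intr$five[i]) * sgn + 1L   # 1 = first intronic base
      L <- intron_length(model, i)
      d3 <- L - d5 + 1L
      if (d5 <= d3) {
        anchor <- bounds$tx_end[i] - model$cds_start + 1L
        return(cdna_pos(anchor, d5))
      } else {
        anchor <- bounds$tx_start[i + 1L] - model$cds_start + 1L
        return(cdna_pos(anchor, -d3))
      }
    }
  }
  stop("genomic position ", g_pos, " not locatable in gene model")  # nocov
}

#' RNA-level pseudoexon insertion description
#'
#' Records an intronic insertion between two adjacent exonic bases in r.
#' notation, e.g. `r.645_646ins646-1933_646-1807`.
#'
#' @param last_exonic_before,first_exonic_after Adjacent exonic c. positions
#'   flanking the insertion (`first_exonic_after == last_exonic_before + 1`).
#' @param inserted_start,inserted_end [cdna_pos] boundaries (intronic, same
#'   intron, start not 3' of end).
#' @return An object of class `rna_change`.
#' @export
rna_change <- function(last_exonic_before, first_exonic_after,
                       inserted_start, inserted_end) {
  stopifnot(inherits(inserted_start, "cdna_pos"),
            inherits(inserted_end, "cdna_pos"))
  last_exonic_before <- as.integer(last_exonic_before)
  first_exonic_after <- as.integer(first_exonic_after)
  if (first_exonic_after != last_exonic_before + 1L)
    stop("insertion flanks must be adjacent exonic positions")
  if (inserted_start$offset == 0L || inserted_end$offset == 0L)
    stop("inserted boundaries must be intronic (nonzero offset)")
  if (sign(inserted_start$offset) != sign(inserted_end$offset) ||
      inserted_start$anchor != inserted_end$anchor)
    stop("inserted boundaries lie in different introns")
  if (inserted_end$offset < inserted_start$offset)
    stop("inserted_start is 3' of inserted_end")
  structure(list(last_exonic_before = last_exonic_before,
                 first_exonic_after = first_exonic_after,
                 inserted_start = inserted_start,
                 inserted_end = inserted_end),
            class = "rna_change")
}

#' @export
print.rna_change <- function(x, ...) {
  cat("<rna_change>", format_hgvs_r(x), "\n")
  invisible(x)
}

#' Format an rna_change in HGVS r. insertion notation
#' @param change An [rna_change].
#' @return Character scalar like `"r.1408_1409ins1408+647_1408+729"`.
#' @export
format_hgvs_r <- function(change) {
  stopifnot(inherits(change, "rna_change"))
  paste0("r.", change$last_exonic_before, "_", change$first_exonic_after,
         "ins", format_cdna_pos(change$inserted_start), "_",
         format_cdna_pos(change$inserted_end))
}

#' Parse an HGVS r. intronic-insertion string
#'
#' Accepts `r.<a>_<b>ins<start>_<end>` where `<start>`/`<end>` are anchored
#' intronic positions, e.g. `"r.645_646ins646-1933_646-1807"`.
#'
#' @param text HGVS r. string.
#' @return An [rna_change].
#' @export
parse_hgvs_r <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^r\\.([0-9]+)_([0-9]+)ins([0-9]+)([+-][0-9]+)_([0-9]+)([+-][0-9]+)$",
    text))[[1]]
  if (length(m) == 0L) stop("malformed HGVS r. insertion: '", text, "'")
  rna_change(as.integer(m[2]), as.integer(m[3]),
             cdna_pos(as.integer(m[4]), as.integer(m[5])),
             cdna_pos(as.integer(m[6]), as.integer(m[7])))
}

#' Length of the inserted pseudoexon sequence
#'
#' For boundaries in the same intron the inserted length is the signed-offset
#' difference plus one, so `r.1408_1409ins1408+647_1408+729` inserts 83 bp and
#' `r.645_646ins646-1933_646-1807` inserts 127 bp.
#'
#' @param change An [rna_change] (or an HGVS r. string, parsed on the fly).
#' @return Integer insertion length in bp (strictly positive).
#' @export
insertion_length <- function(change) {
  if (is.character(change)) change <- parse_hgvs_r(change)
  stopifnot(inherits(change, "rna_change"))
  change$inserted_end$offset - change$inserted_start$offset + 1L
}

#' Codon index and phase of a coding position
#'
#' @param c_pos Exonic coding c. position (>= 1).
#' @return List with `codon` (1-based codon index, `ceiling(c_pos/3)`) and
#'   `phase` (position within the codon, 1-3).
#' @export
#' @examples
#' codon_of(646)  # codon 216, phase 1
codon_of <- function(c_pos) {
  c_pos <- as.integer(c_pos)
  if (is.na(c_pos) || c_pos < 1L) stop("c_pos must be a positive integer")
  list(codon = as.integer(ceiling(c_pos / 3)),
       phase = as.integer((c_pos - 1L) %% 3L + 1L))
}
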