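AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")

aa3 <- function(aa1) unname(AA_THREE[aa1])
aa1_from_3 <- function(aa3v) {
  names(AA_THREE)[match(aa3v, AA_THREE)]
}

# translate a nucleotide string from `from` to the end (trimmed to codons);
# returns the amino-acid string including any '*'
translate_from <- function(seq, from) {
  if (from > nchar(seq)) stop("cds_start beyond sequence end")
  cds <- substr(seq, from, nchar(seq))
  cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
  if (nchar(cds) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X"))
}

#' Splice a pseudoexon into the mRNA
#'
#' Inserts the genomic pseudoexon segment (transcript strand) between the two
#' exons flanking its intron, and records the event as an HGVS-style r.
#' insertion.
#'
#' @param model A [gene_model].
#' @param call One pseudoexon call: a single-row data frame (as returned by
#'   [predict_pseudoexon()]) or a list with elements `pe_start_g` and
#'   `pe_end_g` (genomic boundaries, both inside one intron).
#' @return List with `wild_mrna`, `mutant_mrna` (character sequences) and
#'   `change` (an [rna_change]). The mutant mRNA is longer than the wild type
#'   by the pseudoexon length.
#' @export
apply_pseudoexon <- function(model, call) {
  pe_start_g <- as.integer(call$pe_start_g)
  pe_end_g <- as.integer(call$pe_end_g)
  sgn <- strand_sign(model)
  intr <- introns_tx_order(model)
  in_intron <- function(g, i) g >= min(intr$five[i], intr$three[i]) &&
    g <= max(intr$five[i], intr$three[i])
  ii <- which(vapply(seq_len(nrow(intr)), function(i)
    in_intron(pe_start_g, i) && in_intron(pe_end_g, i), logical(1)))
  if (length(ii) != 1L)
    stop("pseudoexon boundaries do not lie within a single intron")
  if ((pe_end_g - pe_start_g) * sgn < 0)
    stop("pe_start_g is 3' of pe_end_g in transcript orientation")
  bounds <- exon_tx_bounds(model)
  t_before <- bounds$tx_end[ii]
  c_before <- t_before - model$cds_start + 1L
  if (c_before < 1L)
    stop("pseudoexon insertion upstream of the coding sequence is not supported")
  # both inserted boundaries share the 5' boundary's anchoring frame, so the
  # r. description reads like r.645_646ins646-1933_646-1807 even when the
  # pseudoexon straddles the intron midpoint
  ins_start <- map_genomic_to_cdna(model, pe_start_g)
  pe_len <- abs(pe_end_g - pe_start_g) + 1L
  ins_end <- cdna_pos(ins_start$anchor, ins_start$offset + pe_len - 1L)
  change <- rna_change(c_before, c_before + 1L, ins_start, ins_end)
  pe_seq <- genomic_seq(model, min(pe_start_g, pe_end_g),
                        max(pe_start_g, pe_end_g))
  wild <- transcript_seq(model)
  mutant <- paste0(substr(wild, 1L, t_before), pe_seq,
                   substr(wild, t_before + 1L, nchar(wild)))
  list(wild_mrna = wild, mutant_mrna = mutant, change = change)
}

#' Classify the protein consequence of a pseudoexon insertion
#'
#' Translates the wild-type and mutant coding sequences and compares them
#' residue by residue. An insertion of length divisible by 3 that introduces no
#' stop is an in-frame insertion; a mutant whose first changed codon is a stop
#' is nonsense (e.g. a codon-aligned insertion beginning with TAA, the
#' family-42-type event); otherwise a premature stop yields a frameshift with
#' HGVS fs*N counting — N is the stop position counted with the first changed
#' residue as 1. The first affected codon is the first codon whose amino acid
#' differs from wild type, so a hybrid codon that happens to re-encode its
#' wild-type residue is skipped (the Gly471Serfs*55 rule).
#'
#' @param wild_mrna,mutant_mrna Wild-type and mutant mRNA sequences.
#' @param cds_start Transcript position of the first base of the start codon.
#' @param change The [rna_change] describing the insertion.
#' @return An object of class `protein_change` with fields `category`
#'   (`nonsense`, `frameshift`, `inframe_insertion`, `no_ptc`),
#'   `first_affected_codon`, `ref_aa`, `alt_aa` (1-letter), `stop_offset`
#'   (fs*N count; 0 for direct nonsense; NA when no stop is reached),
#'   `ptc_codon` (mutant codon index of the premature stop, NA if none) and
#'   `notation` (HGVS-style p. string).
#' @export
classify_protein_effect <- function(wild_mrna, mutant_mrna, cds_start, change) {
  stopifnot(inherits(change, "rna_change"))
  wild_aa_full <- translate_from(wild_mrna, cds_start)
  mut_aa_full <- translate_from(mutant_mrna, cds_start)
  # the first stop terminates the wild-type product (any 3' UTR sequence
  # beyond it is untranslated)
  wild_stop <- regexpr("*", wild_aa_full, fixed = TRUE)[1]
  wild_aa <- if (wild_stop > 0) substr(wild_aa_full, 1L, wild_stop - 1L) else wild_aa_full
  mut_stop <- regexpr("*", mut_aa_full, fixed = TRUE)[1]
  mut_aa <- if (mut_stop > 0) substr(mut_aa_full, 1L, mut_stop) else mut_aa_full

  ins_len <- insertion_length(change)
  w <- strsplit(wild_aa, "")[[1]]
  m <- strsplit(mut_aa, "")[[1]]
  has_stop <- mut_stop > 0
  s <- if (has_stop) length(m) else NA_integer_   # mutant stop codon index
  body <- if (has_stop) m[seq_len(s - 1L)] else m # residues before the stop

  # first residue that differs from wild type (terminal stop excluded)
  f <- NA_integer_
  for (i in seq_along(body)) {
    if (i > length(w) || body[i] != w[i]) { f <- i; break }
  }

  # an in-frame insertion whose translation runs to a stop exactly where the
  # full-length product should end has no premature stop
  premature <- has_stop &&
    !(ins_len %% 3L == 0L && (s - 1L) == length(w) + ins_len %/% 3L)

  if (!premature) {
    if (is.na(f))
      return(new_protein_change("no_ptc", NA_integer_, NA_character_,
                                NA_character_, NA_integer_, NA_integer_, "p.(=)"))
    if (ins_len %% 3L == 0L) {
      k <- ins_len %/% 3L
      idx <- f - 1L
      notation <- sprintf("p.%s%d_%s%dins%d",
                          aa3(w[max(idx, 1L)]), idx, aa3(w_at(w, idx + 1L)),
                          idx + 1L, k)
      return(new_protein_change("inframe_insertion", f, w_at(w, f), m[f],
                                NA_integer_, NA_integer_, notation))
    }
    # frame destroyed but translation ran off the transcript without a stop
    notation <- sprintf("p.%s%d%sfs*?", aa3(w_at(w, f)), f, aa3(m[f]))
    return(new_protein_change("frameshift", f, w_at(w, f), m[f],
                              NA_integer_, NA_integer_, notation))
  }
  if (is.na(f) || f >= s) {
    # all residues before the stop match wild type: the stop itself is the
    # first change (family-42-type codon-aligned stop insertion)
    notation <- sprintf("p.%s%d*", aa3(w_at(w, s)), s)
    return(new_protein_change("nonsense", s, w_at(w, s), "*", 0L, s, notation))
  }
  stop_offset <- s - f + 1L
  notation <- sprintf("p.%s%d%sfs*%d", aa3(w_at(w, f)), f, aa3(m[f]), stop_offset)
  new_protein_change("frameshift", f, w_at(w, f), m[f], stop_offset, s, notation)
}

w_at <- function(w, i) if (i <= length(w)) w[i] else NA_character_

new_protein_change <- function(category, first_affected_codon, ref_aa, alt_aa,
                               stop_offset, ptc_codon, notation) {
  structure(list(category = category,
                 first_affected_codon = first_affected_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 stop_offset = stop_offset, ptc_codon = ptc_codon,
                 notation = notation),
            class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat(sprintf("<protein_change> %s  %s\n", x$category, x$notation))
  invisible(x)
}

#' Parse / format HGVS-style p. notation emitted by this package
#'
#' Handles the four forms produced by [classify_protein_effect()]: `p.(=)`,
#' nonsense `p.Arg216*`, frameshift `p.Gly471Serfs*55` (or `fs*?` when no stop
#' is reached) and in-frame insertion `p.Lys215_Arg216ins18`.
#' `format_hgvs_p(parse_hgvs_p(x)) == x` for every such string.
#'
#' @param text A p. notation string.
#' @return `parse_hgvs_p`: a list with `form` and its components.
#' @export
parse_hgvs_p <- function(text) {
  if (text == "p.(=)") return(list(form = "identity"))
  m <- regmatches(text, regexec("^p\\.([A-Za-z]{3})([0-9]+)\\*$", text))[[1]]
  if (length(m)) return(list(form = "nonsense", ref_aa = m[2],
                             codon = as.integer(m[3])))
  m <- regmatches(text, regexec(
    "^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})fs\\*([0-9]+|\\?)$", text))[[1]]
  if (length(m)) return(list(form = "frameshift", ref_aa = m[2],
                             codon = as.integer(m[3]), alt_aa = m[4],
                             stop_offset = if (m[5] == "?") NA_integer_
                                           else as.integer(m[5])))
  m <- regmatches(text, regexec(
    "^p\\.([A-Za-z]{3})([0-9]+)_([A-Za-z]{3})([0-9]+)ins([0-9]+)$", text))[[1]]
  if (length(m)) return(list(form = "inframe_insertion", left_aa = m[2],
                             left_codon = as.integer(m[3]), right_aa = m[4],
                             right_codon = as.integer(m[5]),
                             n_inserted = as.integer(m[6])))
  stop("unrecognized p. notation: '", text, "'")
}

#' @rdname parse_hgvs_p
#' @param parsed A list returned by `parse_hgvs_p`.
#' @export
format_hgvs_p <- function(parsed) {
  switch(parsed$form,
    identity = "p.(=)",
    nonsense = sprintf("p.%s%d*", parsed$ref_aa, parsed$codon),
    frameshift = sprintf("p.%s%d%sfs*%s", parsed$ref_aa, parsed$codon,
                         parsed$alt_aa,
                         if (is.na(parsed$stop_offset)) "?"
                         else as.character(parsed$stop_offset)),
    inframe_insertion = sprintf("p.%s%d_%s%dins%d", parsed$left_aa,
                                parsed$left_codon, parsed$right_aa,
                                parsed$right_codon, parsed$n_inserted),
    stop("unknown p. form"))
}

#' Predict nonsense-mediated decay for a premature stop
#'
#' Applies the standard junction rule: a premature termination codon triggers
#' NMD when it lies at least 55 nt upstream of the final exon-exon junction of
#' the mutant transcript (measured from the 3'-most base of the stop codon to
#' the last base before the final junction).
#'
#' @param protein_change A `protein_change` with a PTC (`ptc_codon` set).
#' @param model The [gene_model].
#' @param change The [rna_change] that produced the mutant transcript (the
#'   pseudoexon counts as an additional internal exon).
#' @return Logical: TRUE if NMD is predicted.
#' @export
nmd_flag <- function(protein_change, model, change) {
  stopifnot(inherits(protein_change, "protein_change"))
  if (is.na(protein_change$ptc_codon))
    stop("nmd_flag requires a premature termination codon")
  exlen <- {
    ex <- exons_tx_order(model)
    ex$end - ex$start + 1L
  }
  ins_len <- insertion_length(change)
  t_before <- change$last_exonic_before + model$cds_start - 1L
  # exon index holding the insertion point (end of that exon)
  i <- which(cumsum(exlen) == t_before)
  if (length(i) != 1L) stop("rna_change insertion point is not an exon boundary")
  mut_exlen <- append(exlen, ins_len, after = i)
  last_junction <- sum(mut_exlen[-length(mut_exlen)])
  ptc_last_base <- model$cds_start + 3L * protein_change$ptc_codon - 1L
  (last_junction - ptc_last_base) >= 55L
}
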