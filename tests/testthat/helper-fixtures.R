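# Toy two-exon gene used across coordinate tests: exon1 at genomic 101-200
# (c.1-100), exon2 at 301-400, translation from transcript base 1.
toy_gene <- function(strand = "+", seed = 101) {
  set.seed(seed)
  genome <- paste0(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = "")
  gene_model("TOY", "chrT", strand,
             data.frame(start = c(101L, 301L), end = c(200L, 400L)),
             cds_start = 1L,
             genome = Biostrings::DNAStringSet(c(chrT = genome)))
}

# ---- independent splice-and-translate oracle --------------------------------
# Builds the mutant mRNA by naive string surgery on the genome and translates
# with seqinr; classification logic is written from scratch against the
# full-sequence translation, independent of the package's implementation.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

oracle_consequence <- function(model, pe_start_g, pe_end_g) {
  chrom_seq <- as.character(model$genome[[model$chrom]])
  ex <- model$exons
  exon_seqs <- vapply(seq_len(nrow(ex)), function(i)
    substr(chrom_seq, ex$start[i], ex$end[i]), character(1))
  if (model$strand == "-")
    exon_seqs <- rev(vapply(exon_seqs, oracle_revcomp, character(1)))
  wild <- paste0(exon_seqs, collapse = "")
  lo <- min(pe_start_g, pe_end_g); hi <- max(pe_start_g, pe_end_g)
  pe <- substr(chrom_seq, lo, hi)
  if (model$strand == "-") pe <- oracle_revcomp(pe)
  # transcript position of the exon end 5' of the pseudoexon
  ex_tx <- if (model$strand == "+") ex else ex[rev(seq_len(nrow(ex))), ]
  lens <- ex_tx$end - ex_tx$start + 1L
  cum <- cumsum(lens)
  intron_after <- which(vapply(seq_len(nrow(ex_tx) - 1L), function(i) {
    if (model$strand == "+") lo > ex_tx$end[i] && hi < ex_tx$start[i + 1L]
    else hi < ex_tx$start[i] && lo > ex_tx$end[i + 1L]
  }, logical(1)))
  t_before <- cum[intron_after]
  mut <- paste0(substr(wild, 1, t_before), pe,
                substr(wild, t_before + 1, nchar(wild)))
  tr <- function(s, from) {
    cds <- substr(s, from, nchar(s))
    cds <- substr(cds, 1, 3 * (nchar(cds) %/% 3))
    paste0(seqinr::translate(strsplit(cds, "")[[1]]), collapse = "")
  }
  waa <- tr(wild, model$cds_start); maa <- tr(mut, model$cds_start)
  wstop <- regexpr("*", waa, fixed = TRUE)[1]
  w <- strsplit(substr(waa, 1, wstop - 1), "")[[1]]
  mstop <- regexpr("*", maa, fixed = TRUE)[1]
  m <- strsplit(if (mstop > 0) substr(maa, 1, mstop) else maa, "")[[1]]
  L <- hi - lo + 1L
  body <- if (mstop > 0) m[seq_len(mstop - 1L)] else m
  f <- NA_integer_
  for (i in seq_along(body)) if (i > length(w) || body[i] != w[i]) { f <- i; break }
  if (mstop > 0 && L %% 3 == 0 && (mstop - 1L) == length(w) + L %/% 3)
    return(list(category = if (is.na(f)) "no_ptc" else "inframe_insertion",
                stop_offset = NA_integer_))
  if (mstop < 1)
    return(list(category = if (is.na(f)) "no_ptc" else "frameshift",
                stop_offset = NA_integer_))
  if (is.na(f) || f >= mstop)
    return(list(category = "nonsense", stop_offset = 0L, stop_codon = mstop))
  list(category = "frameshift", stop_offset = mstop - f + 1L, stop_codon = mstop)
}

# random grammar-valid HGVS c. substitution strings
random_hgvs_c <- function(n) {
  vapply(seq_len(n), function(i) {
    anchor <- sample(1:5000, 1)
    off <- sample(c(0, sample(1:3000, 1) * sample(c(-1, 1), 1)), 1)
    nts <- sample(c("A", "C", "G", "T"), 2)
    paste0("c.", anchor,
           if (off > 0) paste0("+", off) else if (off < 0) off else "",
           nts[1], ">", nts[2])
  }, character(1))
}
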