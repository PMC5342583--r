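STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")), 1, paste0,
                              collapse = ""), STOP_CODONS)

ACCEPTOR_CONSENSUS <- "tttttttttttcag"   # 10 y + n + y + a + g, all pyrimidine-maximal

rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

str_assign <- function(s, at, value) {
  substr(s, at, at + nchar(value) - 1L) <- value
  s
}

#' Generate a synthetic multi-exon coding gene
#'
#' Builds a gene model plus genomic sequence emulating the discovery setting:
#' a stop-free coding sequence (codons drawn from the 61 sense codons, with a
#' terminal stop appended), translation starting inside exon 2 (so c.1 is not
#' transcript base 1, as for APC), canonical splice consensus written at every
#' exon/intron border (`AG/gtaagt` donors, `poly(t)tcag/G` acceptors — every
#' border scores 100 under [score_site()]), and introns long enough for
#' deep-intronic planting. Deterministic given `seed`.
#'
#' @param n_exons Number of exons (>= 3).
#' @param exon_len_range,intron_len_range Length ranges (bp); introns must
#'   allow at least 400 bp.
#' @param strand `"+"` or `"-"`.
#' @param gene_id,chrom Identifiers.
#' @param align_boundary_exon Optional exon index: the 5' UTR length is
#'   adjusted so that the cDNA position of that exon's 3' end is a multiple of
#'   3 (a codon-aligned boundary, needed to plant a family-42-type
#'   stop-leading pseudoexon in the following intron).
#' @param seed Random seed.
#' @return A [gene_model] (genome attached).
#' @export
make_gene <- function(n_exons = 5, exon_len_range = c(90, 180),
                      intron_len_range = c(1500, 2500), strand = "+",
                      gene_id = "GENE1", chrom = "chrS1",
                      align_boundary_exon = NULL, seed = 1) {
  if (n_exons < 3L) stop("n_exons must be >= 3")
  if (intron_len_range[1] < 400L)
    stop("introns must be at least 400 bp for deep-intronic planting")
  if (exon_len_range[1] < 40L) stop("exons must be at least 40 bp")
  set.seed(seed)
  exon_len <- sample(exon_len_range[1]:exon_len_range[2], n_exons, replace = TRUE)
  intron_len <- sample(intron_len_range[1]:intron_len_range[2], n_exons - 1L,
                       replace = TRUE)
  tx_len <- sum(exon_len)
  # translation starts a little inside exon 2
  off <- sample(3:30, 1)
  utr5 <- exon_len[1] + off
  if (!is.null(align_boundary_exon)) {
    tgt <- sum(exon_len[seq_len(align_boundary_exon)])
    utr5 <- utr5 + (tgt - utr5) %% 3L
  }
  cds_len <- 3L * ((tx_len - utr5 - 6L) %/% 3L)
  if (cds_len < 30L) stop("gene too short for a coding sequence")
  codons <- c("ATG", sample(SENSE_CODONS, cds_len / 3L - 2L, replace = TRUE), "TAA")
  tx <- paste0(rand_dna(utr5), paste0(codons, collapse = ""),
               rand_dna(tx_len - utr5 - cds_len))

  # assemble the transcript-sense genome with flanks and introns
  flank <- 200L
  pieces <- character(2L * n_exons + 1L)
  pieces[1] <- rand_dna(flank)
  exon_tx_start <- cumsum(c(1L, exon_len))[seq_len(n_exons)]
  for (i in seq_len(n_exons)) {
    pieces[2L * i] <- substr(tx, exon_tx_start[i], exon_tx_start[i] + exon_len[i] - 1L)
    if (i < n_exons) {
      intr <- rand_dna(intron_len[i])
      intr <- str_assign(intr, 1L, "gtaagt")
      intr <- str_assign(intr, nchar(intr) - 13L, ACCEPTOR_CONSENSUS)
      pieces[2L * i + 1L] <- intr
    }
  }
  pieces[2L * n_exons + 1L] <- rand_dna(flank)

  # exonic consensus at internal borders: AG before each donor, G after each
  # acceptor; track forced transcript positions, then repair any stop codons
  forced <- rep(FALSE, tx_len)
  genome_exonic_fix <- function(tx, forced) {
    for (i in seq_len(n_exons - 1L)) {
      e_end <- sum(exon_len[seq_len(i)])
      substr(tx, e_end - 1L, e_end) <- "AG"
      forced[(e_end - 1L):e_end] <- TRUE
      substr(tx, e_end + 1L, e_end + 1L) <- "G"
      forced[e_end + 1L] <- TRUE
    }
    list(tx = tx, forced = forced)
  }
  fixed <- genome_exonic_fix(tx, forced)
  tx <- fixed$tx; forced <- fixed$forced
  forced[utr5 + seq_len(3L)] <- TRUE   # keep ATG
  # repair internal stops among the forced-sequence CDS
  repeat {
    aa <- translate_from(tx, utr5 + 1L)
    stops <- which(strsplit(aa, "")[[1]] == "*")
    stops <- stops[stops < cds_len / 3L]
    if (length(stops) == 0L) break
    for (s in stops) {
      cpos <- utr5 + 3L * (s - 1L) + 1:3
      free <- cpos[!forced[cpos]]
      if (length(free) == 0L) stop("cannot repair stop codon at fixed positions")  # nocov
      for (p in free) substr(tx, p, p) <- sample(c("A", "C", "G"), 1)
    }
  }
  for (i in seq_len(n_exons))
    pieces[2L * i] <- substr(tx, exon_tx_start[i], exon_tx_start[i] + exon_len[i] - 1L)

  genome_ts <- paste0(pieces, collapse = "")
  # exon coordinates in transcript-sense genome space
  starts_ts <- integer(n_exons)
  pos <- flank + 1L
  for (i in seq_len(n_exons)) {
    starts_ts[i] <- pos
    pos <- pos + exon_len[i] + if (i < n_exons) intron_len[i] else 0L
  }
  exons_ts <- data.frame(start = starts_ts, end = starts_ts + exon_len - 1L)
  Lg <- nchar(genome_ts)
  if (strand == "+") {
    genome <- genome_ts
    exons <- exons_ts
  } else {
    genome <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genome_ts)))
    exons <- data.frame(start = Lg - exons_ts$end + 1L,
                        end = Lg - exons_ts$start + 1L)
  }
  genome_set <- Biostrings::DNAStringSet(stats::setNames(genome, chrom))
  gene_model(gene_id, chrom, strand, exons, cds_start = utr5 + 1L,
             genome = genome_set)
}

# transcript-sense genome string and coordinate converters
ts_genome <- function(model) {
  g <- model$genome[[model$chrom]]
  if (model$strand == "-") g <- Biostrings::reverseComplement(g)
  as.character(g)
}

ts_to_genomic <- function(model, p) {
  if (model$strand == "+") p
  else length(model$genome[[model$chrom]]) - p + 1L
}

with_genome <- function(model, genome_ts_str) {
  g <- genome_ts_str
  if (model$strand == "-")
    g <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  gene_model(model$gene_id, model$chrom, model$strand, model$exons,
             model$cds_start,
             Biostrings::DNAStringSet(stats::setNames(g, model$chrom)))
}

#' Apply a cDNA substitution to a gene model's genome
#'
#' @param model A [gene_model].
#' @param variant A [cdna_variant] whose ref matches the genome.
#' @return A new [gene_model] carrying the alternate allele.
#' @export
apply_variant_to_model <- function(model, variant) {
  g <- map_cdna_to_genomic(model, variant$position)
  ts <- ts_genome(model)
  p <- if (model$strand == "+") g else nchar(ts) - g + 1L
  if (toupper(substr(ts, p, p)) != variant$ref)
    stop("variant ref does not match genome")
  ts <- str_assign(ts, p, variant$alt)
  with_genome(model, ts)
}

#' Plant a pseudoexon-activating variant in an intron
#'
#' Writes a cryptic acceptor (polypyrimidine tract + `ag`) at the 5' boundary
#' of a latent pseudoexon and a near-donor at its 3' boundary that becomes
#' viable only under a single substitution:
#'
#' * `gt_gain` — the reference donor context is `AG/gc aagt`; the planted
#'   variant converts the `g·c` dinucleotide to `g·t` (the family-42/85
#'   geometry: a deep-intronic C>T two bases past the latent exon end).
#' * `exonic_ag_gain_gc_donor` — the reference context is `AA/gc aagt`; the
#'   planted variant is on the exonic side of the latent donor, changing the
#'   last pseudoexon base A>G to complete `AG/` before a `g·c` dinucleotide
#'   (the family-163 geometry: a GC-class donor that a GT-only motif scan
#'   cannot see, and a variant that is carried inside the pseudoexon reads).
#'
#' The generator verifies that, for the planted variant, exactly one
#' motif-visible (donor, acceptor) pair passes thresholds in the allowed
#' length range, resampling the intron background a bounded number of times if
#' an accidental competing site appears.
#'
#' @param model A reference [gene_model] from [make_gene()].
#' @param intron_index Intron (transcript order) to plant into.
#' @param pe_length Pseudoexon length in bp (50-300).
#' @param scenario `"gt_gain"` or `"exonic_ag_gain_gc_donor"`.
#' @param consequence Desired protein consequence: `"any"`, `"nonsense"`
#'   (first three pseudoexon bases TAA; requires a codon-aligned boundary),
#'   `"frameshift"` (requires `pe_length` not divisible by 3) or `"inframe"`
#'   (requires divisibility and a stop-free insert, enforced by resampling).
#' @param splice_model [splice_site_model] used for the uniqueness check.
#' @param seed Random seed.
#' @param max_retries Background resampling attempts before giving up.
#' @return List with `model_ref`, `model_alt` (the variant applied),
#'   `variant` (a [cdna_variant]) and `truth` (planted boundaries, length,
#'   scenario, consequence and bookkeeping).
#' @export
plant_pseudoexon_variant <- function(model, intron_index = 2, pe_length = 83,
                                     scenario = c("gt_gain",
                                                  "exonic_ag_gain_gc_donor"),
                                     consequence = "any",
                                     splice_model = splice_site_model(),
                                     seed = 1, max_retries = 20) {
  scenario <- match.arg(scenario)
  stopifnot(pe_length >= 50, pe_length <= 300)
  if (consequence == "frameshift" && pe_length %% 3L == 0L)
    stop("frameshift consequence requires pe_length not divisible by 3")
  if (consequence == "inframe" && pe_length %% 3L != 0L)
    stop("inframe consequence requires pe_length divisible by 3")
  set.seed(seed)
  intr <- introns_tx_order(model)
  if (intron_index > nrow(intr)) stop("intron_index out of range")
  five_ts <- if (model$strand == "+") intr$five[intron_index] else
    nchar(ts_genome(model)) - intr$five[intron_index] + 1L
  three_ts <- if (model$strand == "+") intr$three[intron_index] else
    nchar(ts_genome(model)) - intr$three[intron_index] + 1L
  guard <- 40L
  lo <- five_ts + guard + 14L + pe_length       # min pe_end
  hi <- three_ts - guard - 6L                   # max pe_end
  if (lo > hi) stop("intron too short for requested pseudoexon")
  bounds <- exon_tx_bounds(model)
  c_before <- bounds$tx_end[intron_index] - model$cds_start + 1L
  if (consequence == "nonsense" && c_before %% 3L != 0L)
    stop("nonsense consequence needs a codon-aligned exon boundary; ",
         "regenerate the gene with align_boundary_exon = ", intron_index)

  ts0 <- ts_genome(model)
  for (attempt in seq_len(max_retries)) {
    ts <- ts0
    pe_end <- sample(lo:hi, 1)
    pe_start <- pe_end - pe_length + 1L
    # resample the intron interior to control accidental motifs
    if (attempt > 1L) {
      ts <- str_assign(ts, five_ts + 6L,
                       rand_dna(three_ts - 14L - (five_ts + 6L) + 1L))
    }
    # cryptic acceptor 5' of the pseudoexon
    ts <- str_assign(ts, pe_start - 14L, ACCEPTOR_CONSENSUS)
    # pseudoexon body
    body <- rand_dna(pe_length)
    if (consequence == "nonsense") body <- str_assign(body, 1L, "TAA")
    else body <- str_assign(body, 1L, "G")   # acceptor-consensus first base
    ts <- str_assign(ts, pe_start, body)
    # latent donor context
    if (scenario == "gt_gain") {
      ts <- str_assign(ts, pe_end - 1L, "AG")
      ts <- str_assign(ts, pe_end + 1L, "GCAAGT")
      var_ts <- pe_end + 2L; ref <- "C"; alt <- "T"
    } else {
      ts <- str_assign(ts, pe_end - 1L, "AA")
      ts <- str_assign(ts, pe_end + 1L, "GCAAGT")
      var_ts <- pe_end; ref <- "A"; alt <- "G"
    }
    cand_ref <- with_genome(model, ts)
    variant <- cdna_variant(
      map_genomic_to_cdna(cand_ref, ts_to_genomic(cand_ref, var_ts)), ref, alt)
    pe_start_g <- ts_to_genomic(cand_ref, pe_start)
    pe_end_g <- ts_to_genomic(cand_ref, pe_end)
    eff_ok <- function(m_alt) {
      sp <- apply_pseudoexon(m_alt, list(pe_start_g = pe_start_g,
                                         pe_end_g = pe_end_g))
      eff <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                     m_alt$cds_start, sp$change)
      switch(consequence,
             any = TRUE,
             nonsense = eff$category == "nonsense",
             frameshift = eff$category == "frameshift" && !is.na(eff$ptc_codon),
             inframe = eff$category == "inframe_insertion")
    }
    Lg <- nchar(ts)
    to_ts <- function(g) if (model$strand == "+") g else Lg - g + 1L

    # iterate: (a) resample the pseudoexon interior until the requested
    # protein consequence holds; (b) reject-and-resample accidental competing
    # acceptors by breaking their obligatory ag dinucleotide
    ok <- FALSE
    for (iter in seq_len(60L)) {
      cand_ref <- with_genome(model, ts)
      cand_alt <- apply_variant_to_model(cand_ref, variant)
      if (!eff_ok(cand_alt)) {
        interior <- rand_dna(pe_length - 4L)
        ts <- str_assign(ts, pe_start + 1L, interior)
        if (consequence == "nonsense") ts <- str_assign(ts, pe_start, "TAA")
        ts <- str_assign(ts, pe_end - 1L,
                         if (scenario == "gt_gain") "AG" else "AA")
        next
      }
      calls <- predict_pseudoexon(cand_ref, variant, splice_model)
      hits <- calls[calls$motif_supported, , drop = FALSE]
      planted_row <- hits$pe_start_g == pe_start_g & hits$pe_end_g == pe_end_g
      if (!any(planted_row)) break            # planted site not viable; replant
      if (all(planted_row)) { ok <- TRUE; break }
      for (r in which(!planted_row)) {        # break the accidental ag
        g_pos <- to_ts(hits$pe_start_g[r]) - 1L
        ts <- str_assign(ts, g_pos, "C")
      }
    }
    if (ok) {
      truth <- list(gene_id = model$gene_id, intron_index = intron_index,
                    pe_start_g = pe_start_g, pe_end_g = pe_end_g,
                    length = pe_length, scenario = scenario,
                    consequence = consequence,
                    hgvs_c = format_hgvs_c(variant),
                    c_before = c_before,
                    variant_g = ts_to_genomic(cand_ref, var_ts),
                    variant_in_pseudoexon = scenario == "exonic_ag_gain_gc_donor")
      return(list(model_ref = cand_ref, model_alt = cand_alt,
                  variant = variant, truth = truth))
    }
  }
  stop("could not plant a unique pseudoexon after ", max_retries,
       " attempts; try another seed")
}

#' Simulate splice-junction tables for a carrier and a control sample
#'
#' The canonical junction of the affected intron draws
#' `Binomial(depth, 1 - psi)` unique reads; each pseudoexon-flanking novel
#' junction draws `Binomial(depth, psi)` independently; all other canonical
#' junctions are at full depth. The control sample has `psi = 0` (novel
#' junctions absent).
#'
#' @param truth Truth record from [plant_pseudoexon_variant()].
#' @param model The reference [gene_model].
#' @param psi Inclusion level in \[0, 1\].
#' @param depth Junction read depth (>= 1).
#' @param seed Random seed.
#' @return List of junction data frames `carrier` and `control` in the
#'   [read_junctions()] layout.
#' @export
simulate_junctions <- function(truth, model, psi = 0.3, depth = 60, seed = 1) {
  stopifnot(depth >= 1, psi >= 0, psi <= 1)
  set.seed(seed)
  intr <- introns_tx_order(model)
  canon <- data.frame(
    chrom = model$chrom,
    intron_start = pmin(intr$five, intr$three),
    intron_end = pmax(intr$five, intr$three),
    strand = model$strand, motif_class = "GT/AG",
    unique_reads = depth, annotated = TRUE)
  make_sample <- function(p) {
    jx <- canon
    i <- truth$intron_index
    # transcript intron index -> genomic-order row
    row <- if (model$strand == "+") i else nrow(canon) - i + 1L
    jx$unique_reads[row] <- stats::rbinom(1, depth, 1 - p)
    if (p > 0) {
      pe_lo <- min(truth$pe_start_g, truth$pe_end_g)
      pe_hi <- max(truth$pe_start_g, truth$pe_end_g)
      donor_motif <- if (truth$scenario == "gt_gain") "GT/AG" else "GC/AG"
      up <- data.frame(chrom = model$chrom,
                       intron_start = jx$intron_start[row],
                       intron_end = pe_lo - 1L,
                       strand = model$strand, motif_class = "GT/AG",
                       unique_reads = stats::rbinom(1, depth, p),
                       annotated = FALSE)
      dn <- data.frame(chrom = model$chrom,
                       intron_start = pe_hi + 1L,
                       intron_end = jx$intron_end[row],
                       strand = model$strand, motif_class = donor_motif,
                       unique_reads = stats::rbinom(1, depth, p),
                       annotated = FALSE)
      if (model$strand == "-") { # novel junction motifs swap genomic sides
        up$motif_class <- donor_motif; dn$motif_class <- "GT/AG"
      }
      jx <- rbind(jx, up, dn)
    }
    jx <- jx[jx$unique_reads > 0, , drop = FALSE]
    jx <- jx[order(jx$chrom, jx$intron_start), , drop = FALSE]
    rownames(jx) <- NULL
    jx
  }
  list(carrier = make_sample(psi), control = make_sample(0))
}

#' Simulate a SNuPE/RNA allelic count table
#'
#' gDNA allele-1 counts are `Binomial(depth, 0.5)`; cDNA allele-1 counts are
#' `Binomial(depth, R_true / (1 + R_true))`, so the expected SNuPE ratio is
#' `R_true`.
#'
#' @param R_true True allelic expression ratio (> 0).
#' @param n_snps Number of heterozygous SNPs (>= 1).
#' @param depth Count depth per SNP (0 gives uninformative records).
#' @param sample,gene_id Identifiers.
#' @param seed Random seed.
#' @return Allelic count data frame (columns as in [gene_ase_test()]).
#' @export
simulate_allelic_counts <- function(R_true = 1, n_snps = 4, depth = 500,
                                    sample = "S1", gene_id = "GENE1",
                                    seed = 1) {
  stopifnot(R_true > 0, n_snps >= 1)
  set.seed(seed)
  g1 <- stats::rbinom(n_snps, depth, 0.5)
  c1 <- stats::rbinom(n_snps, depth, R_true / (1 + R_true))
  data.frame(sample = sample, snp_id = paste0("snp", seq_len(n_snps)),
             gene_id = gene_id, gdna_a1 = g1, gdna_a2 = depth - g1,
             cdna_a1 = c1, cdna_a2 = depth - c1)
}

#' Simulate a pedigree and carrier genotypes
#'
#' Dominant mode: all affected individuals are heterozygous carriers and all
#' unaffected individuals non-carriers (full penetrance). Sporadic mode: a
#' single affected carrier.
#'
#' @param n_affected Number of affected individuals (>= 1; forced to 1 in
#'   sporadic mode).
#' @param n_unaffected Number of unaffected individuals.
#' @param mode `"dominant"` or `"sporadic"`.
#' @param id_prefix Prefix for individual ids.
#' @param seed Random seed.
#' @return List with `pedigree` (a `pedigree_df`) and `genotypes` (named
#'   vector id -> genotype for the causal variant).
#' @export
simulate_pedigree <- function(n_affected = 4, n_unaffected = 2,
                              mode = c("dominant", "sporadic"),
                              id_prefix = "IND", seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_affected >= 1)
  if (mode == "sporadic") n_affected <- 1L
  set.seed(seed)
  aff_ids <- paste0(id_prefix, "_A", seq_len(n_affected))
  una_ids <- if (n_unaffected > 0) paste0(id_prefix, "_U", seq_len(n_unaffected))
             else character(0)
  founder_mother <- if (n_unaffected > 0) una_ids[1] else "0"
  d <- data.frame(
    id = c(aff_ids, una_ids),
    father = c("0", rep(aff_ids[1], n_affected - 1L),
               if (n_unaffected > 0) c("0", rep(aff_ids[1], n_unaffected - 1L))),
    mother = c("0", rep(founder_mother, n_affected - 1L),
               if (n_unaffected > 0) c("0", rep(founder_mother, n_unaffected - 1L))),
    sex = c("M", sample(c("M", "F"), n_affected - 1L, replace = TRUE),
            if (n_unaffected > 0) c("F", sample(c("M", "F"), n_unaffected - 1L,
                                                replace = TRUE))),
    affected = c(rep(TRUE, n_affected), rep(FALSE, n_unaffected)),
    available = TRUE)
  gt <- stats::setNames(ifelse(d$affected, "het", "hom_ref"), d$id)
  list(pedigree = validate_pedigree(d), genotypes = gt)
}
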