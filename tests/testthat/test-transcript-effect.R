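test_that("splicing in a pseudoexon lengthens the mRNA and records the r. change", {
  p <- plant_pseudoexon_variant(make_gene(seed = 31), intron_index = 2,
                                pe_length = 83, seed = 31)
  sp <- apply_pseudoexon(p$model_alt, list(pe_start_g = p$truth$pe_start_g,
                                           pe_end_g = p$truth$pe_end_g))
  expect_equal(nchar(sp$mutant_mrna), nchar(sp$wild_mrna) + 83L)
  expect_equal(sp$change$last_exonic_before + 1L,
               sp$change$first_exonic_after)
  expect_equal(insertion_length(sp$change), 83L)
  expect_identical(parse_hgvs_r(format_hgvs_r(sp$change))$inserted_start,
                   sp$change$inserted_start)
  # boundaries outside one intron are rejected
  expect_error(apply_pseudoexon(p$model_alt,
                                list(pe_start_g = p$truth$pe_start_g,
                                     pe_end_g = p$truth$pe_end_g + 5000L)),
               "single intron")
})

test_that("a codon-aligned stop-leading pseudoexon is nonsense at the next codon", {
  g <- make_gene(seed = 32, align_boundary_exon = 2)
  p <- plant_pseudoexon_variant(g, intron_index = 2, pe_length = 127,
                                scenario = "gt_gain",
                                consequence = "nonsense", seed = 32)
  sp <- apply_pseudoexon(p$model_alt, list(pe_start_g = p$truth$pe_start_g,
                                           pe_end_g = p$truth$pe_end_g))
  eff <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                 p$model_alt$cds_start, sp$change)
  expect_equal(eff$category, "nonsense")
  expect_equal(eff$stop_offset, 0L)
  expect_equal(eff$first_affected_codon, p$truth$c_before %/% 3L + 1L)
  expect_match(eff$notation, "\\*$")
})

test_that("a non-triplet pseudoexon frameshifts with fs*N counted from the first changed residue", {
  p <- plant_pseudoexon_variant(make_gene(seed = 33), intron_index = 3,
                                pe_length = 83, consequence = "frameshift",
                                seed = 33)
  sp <- apply_pseudoexon(p$model_alt, list(pe_start_g = p$truth$pe_start_g,
                                           pe_end_g = p$truth$pe_end_g))
  eff <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                 p$model_alt$cds_start, sp$change)
  expect_equal(eff$category, "frameshift")
  expect_gte(eff$stop_offset, 1L)
  expect_match(eff$notation, "fs\\*[0-9]+$")
  orc <- oracle_consequence(p$model_alt, p$truth$pe_start_g, p$truth$pe_end_g)
  expect_equal(eff$stop_offset, orc$stop_offset)
})

test_that("a triplet-length stop-free pseudoexon is an in-frame insertion", {
  p <- plant_pseudoexon_variant(make_gene(seed = 34), intron_index = 2,
                                pe_length = 54, consequence = "inframe",
                                seed = 34)
  sp <- apply_pseudoexon(p$model_alt, list(pe_start_g = p$truth$pe_start_g,
                                           pe_end_g = p$truth$pe_end_g))
  eff <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                 p$model_alt$cds_start, sp$change)
  expect_equal(eff$category, "inframe_insertion")
  expect_true(is.na(eff$ptc_codon))
  expect_match(eff$notation, "ins")
})

test_that("consequence classification matches the independent splice-and-translate oracle", {
  set.seed(35)
  n_cases <- 0L
  for (gs in 1:10) {
    g <- make_gene(seed = 350 + gs)
    intr <- pseudoexonr:::introns_tx_order(g)
    for (r in 1:10) {
      i <- sample(2:nrow(intr), 1)
      five <- intr$five[i]; three <- intr$three[i]
      L <- sample(50:300, 1)
      lo <- min(five, three) + 20L
      hi <- max(five, three) - 20L - L
      s <- sample(lo:hi, 1)
      pe <- if (g$strand == "+") c(s, s + L - 1L) else c(s + L - 1L, s)
      sp <- apply_pseudoexon(g, list(pe_start_g = pe[1], pe_end_g = pe[2]))
      eff <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                     g$cds_start, sp$change)
      orc <- oracle_consequence(g, pe[1], pe[2])
      expect_equal(eff$category, orc$category,
                   info = sprintf("gene %d case %d", gs, r))
      expect_equal(eff$stop_offset, orc$stop_offset,
                   info = sprintf("gene %d case %d", gs, r))
      n_cases <- n_cases + 1L
    }
  }
  expect_equal(n_cases, 100L)
})

test_that("frame preservation is equivalent to triplet insertion length", {
  set.seed(36)
  g <- make_gene(seed = 36)
  intr <- pseudoexonr:::introns_tx_order(g)
  for (r in 1:20) {
    i <- sample(2:nrow(intr), 1)
    L <- sample(50:120, 1)
    lo <- min(intr$five[i], intr$three[i]) + 20L
    s <- sample(lo:(lo + 500L), 1)
    sp <- apply_pseudoexon(g, list(pe_start_g = s, pe_end_g = s + L - 1L))
    eff <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                   g$cds_start, sp$change)
    if (L %% 3L != 0L) {
      # a non-triplet insert can never preserve the downstream frame
      expect_true(eff$category %in% c("frameshift", "nonsense"))
    }
  }
})

test_that("p. notation round-trips through its parser", {
  for (s in c("p.Arg216*", "p.Gly471Serfs*55", "p.Lys10Metfs*?",
              "p.Lys215_Arg216ins18", "p.(=)")) {
    expect_identical(format_hgvs_p(parse_hgvs_p(s)), s)
  }
  expect_error(parse_hgvs_p("p.R216X"), "unrecognized")
})

test_that("the NMD junction rule uses the 55 nt boundary strictly", {
  # toy 3-exon gene built by hand: exon lengths 120/120/120
  set.seed(37)
  genome <- paste0(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  exons <- data.frame(start = c(101L, 721L, 1341L),
                      end = c(220L, 840L, 1460L))
  g <- gene_model("NMD", "chrN", "+", exons, cds_start = 1L,
                  genome = Biostrings::DNAStringSet(c(chrN = genome)))
  change <- rna_change(120, 121, cdna_pos(121, -61), cdna_pos(121, -1))
  # mutant exon layout: 120 | 61 | 120 | 120; last junction at position 301
  mk_pc <- function(ptc_codon) {
    structure(list(category = "nonsense", first_affected_codon = ptc_codon,
                   ref_aa = "K", alt_aa = "*", stop_offset = 0L,
                   ptc_codon = ptc_codon, notation = "p.Lys1*"),
              class = "protein_change")
  }
  # PTC last base sits at 3*codon (cds_start = 1)
  expect_true(nmd_flag(mk_pc(81L), g, change))    # distance 58 -> NMD
  expect_true(nmd_flag(mk_pc(82L), g, change))    # distance exactly 55 -> NMD
  expect_false(nmd_flag(mk_pc(83L), g, change))   # distance 52 -> escapes
  # PTC in the last exon escapes
  expect_false(nmd_flag(mk_pc(120L), g, change))
  expect_error(nmd_flag(mk_pc(NA_integer_), g, change), "termination codon")
})
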