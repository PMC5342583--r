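test_that("gene generation is deterministic and writes canonical borders", {
  g1 <- make_gene(seed = 71)
  g2 <- make_gene(seed = 71)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$exons, g2$exons)
  expect_equal(nrow(g1$exons), 5L)
  # every internal border scores 100 for donor and acceptor
  intr <- pseudoexonr:::introns_tx_order(g1)
  sgn <- pseudoexonr:::strand_sign(g1)
  for (i in seq_len(nrow(intr))) {
    dwin <- genomic_seq(g1, min(intr$five[i] - 2L * sgn, intr$five[i] + 5L * sgn),
                        max(intr$five[i] - 2L * sgn, intr$five[i] + 5L * sgn))
    expect_equal(score_site(dwin, "donor"), 100)
    awin <- genomic_seq(g1, min(intr$three[i] - 13L * sgn, intr$three[i] + 1L * sgn),
                        max(intr$three[i] - 13L * sgn, intr$three[i] + 1L * sgn))
    expect_equal(score_site(awin, "acceptor"), 100)
  }
})

test_that("the wild-type coding sequence is stop-free and starts with ATG", {
  for (seed in c(72, 73)) {
    g <- make_gene(seed = seed)
    tx <- transcript_seq(g)
    expect_equal(substr(tx, g$cds_start, g$cds_start + 2L), "ATG")
    aa <- pseudoexonr:::translate_from(tx, g$cds_start)
    first_stop <- regexpr("*", aa, fixed = TRUE)[1]
    expect_gt(first_stop, 10)  # a real ORF, stop only at its end
  }
})

test_that("minus-strand gene models mirror the plus strand consistently", {
  g <- make_gene(seed = 74, strand = "-")
  expect_equal(g$strand, "-")
  tx <- transcript_seq(g)
  expect_equal(substr(tx, g$cds_start, g$cds_start + 2L), "ATG")
  p <- plant_pseudoexon_variant(g, intron_index = 2, pe_length = 83, seed = 74)
  calls <- predict_pseudoexon(p$model_ref, p$variant)
  hits <- calls[calls$motif_supported, , drop = FALSE]
  expect_equal(hits$pe_start_g[1], p$truth$pe_start_g)
  expect_equal(hits$pe_end_g[1], p$truth$pe_end_g)
})

test_that("planting is deterministic and the reference genome stays call-free", {
  p1 <- plant_pseudoexon_variant(make_gene(seed = 75), intron_index = 2,
                                 pe_length = 83, seed = 75)
  p2 <- plant_pseudoexon_variant(make_gene(seed = 75), intron_index = 2,
                                 pe_length = 83, seed = 75)
  expect_identical(as.character(p1$model_ref$genome),
                   as.character(p2$model_ref$genome))
  expect_identical(p1$truth, p2$truth)
  # a benign substitution elsewhere yields no donor gain on the same genome
  b <- pseudoexonr:::benign_variant(p1$model_ref,
                                    forbidden = c(p1$truth$pe_start_g,
                                                  p1$truth$pe_end_g,
                                                  p1$truth$variant_g))
  expect_equal(nrow(donor_gain_scan(p1$model_ref, b$variant)), 0L)
})

test_that("junction simulation is seed-deterministic and respects psi", {
  p <- plant_pseudoexon_variant(make_gene(seed = 76), intron_index = 2,
                                pe_length = 83, seed = 76)
  j1 <- simulate_junctions(p$truth, p$model_ref, psi = 0.3, depth = 200,
                           seed = 10)
  j2 <- simulate_junctions(p$truth, p$model_ref, psi = 0.3, depth = 200,
                           seed = 10)
  expect_identical(j1, j2)
  # psi = 0: no novel junctions
  expect_true(all(j1$control$annotated))
  # mean inclusion fraction approaches psi
  fr <- vapply(1:100, function(s) {
    jj <- simulate_junctions(p$truth, p$model_ref, psi = 0.3, depth = 200,
                             seed = s)
    ev <- detect_pseudoexon_events(jj$carrier, p$model_ref)$events
    ev$inclusion_fraction[1]
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 3 * sd(fr) / sqrt(length(fr)) + 0.02)
})

test_that("inclusion fraction increases with the simulated inclusion level", {
  p <- plant_pseudoexon_variant(make_gene(seed = 77), intron_index = 2,
                                pe_length = 83, seed = 77)
  psis <- seq(0.1, 0.8, by = 0.1)
  fr <- vapply(seq_along(psis), function(i) {
    jj <- simulate_junctions(p$truth, p$model_ref, psi = psis[i], depth = 300,
                             seed = 100 + i)
    detect_pseudoexon_events(jj$carrier, p$model_ref)$events$inclusion_fraction[1]
  }, numeric(1))
  expect_gt(cor(psis, fr, method = "spearman"), 0)
})

test_that("allelic count simulation hits degenerate depths gracefully", {
  d0 <- simulate_allelic_counts(0.6, n_snps = 2, depth = 0, seed = 1)
  expect_true(all(d0$cdna_a1 + d0$cdna_a2 == 0))
  expect_true(is.na(snupe_ratio(d0$gdna_a1[1], d0$gdna_a2[1],
                                d0$cdna_a1[1], d0$cdna_a2[1])))
  expect_equal(gene_ase_test(d0)$rnaseq_class, "uninformative")
})

test_that("pedigree simulation is deterministic and matches its mode", {
  p1 <- simulate_pedigree(4, 2, "dominant", seed = 78)
  p2 <- simulate_pedigree(4, 2, "dominant", seed = 78)
  expect_identical(p1, p2)
  expect_equal(sum(p1$pedigree$affected), 4L)
  expect_true(all(p1$genotypes[p1$pedigree$id[p1$pedigree$affected]] == "het"))
  sp <- simulate_pedigree(5, 2, "sporadic", seed = 78)
  expect_equal(sum(sp$pedigree$affected), 1L)  # sporadic forces one affected
})

test_that("cohort simulation embeds the planted truth", {
  co <- suppressMessages(simulate_cohort(n_families = 6, n_carriers = 2,
                                         seed = 79))
  expect_equal(length(co$truth), 2L)
  expect_equal(sort(names(co$truth)), sort(co$carrier_families))
  for (fam in co$carrier_families) {
    tr <- co$truth[[fam]]
    fd <- co$families[[fam]]
    expect_true(tr$causal_id %in% fd$variants$variant_id)
    # the causal variant recreates the planted call on the shared reference
    v <- parse_hgvs_c(tr$hgvs_c)
    calls <- predict_pseudoexon(co$model, v)
    hits <- calls[calls$motif_supported, , drop = FALSE]
    expect_equal(hits$pe_start_g[1], tr$pe_start_g)
    expect_equal(hits$pe_end_g[1], tr$pe_end_g)
  }
})
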