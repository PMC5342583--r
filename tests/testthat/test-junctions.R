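sj_line <- function(chrom, start, end, strand, motif, annot, uniq) {
  paste(chrom, start, end, strand, motif, annot, uniq, 3, 40, sep = "\t")
}

test_that("STAR SJ tables are read 1-based with motif and annotation decoding", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(sj_line("chr5", 1000, 1100, 1, 1, 0, 12),
               sj_line("chr5", 2000, 2200, 1, 3, 1, 8),
               sj_line("chr5", 3000, 3300, 0, 0, 0, 6)), path)
  j <- read_junctions(path, "sj_tab")
  expect_equal(j$intron_start, c(1000L, 2000L, 3000L))
  expect_equal(j$intron_end, c(1100L, 2200L, 3300L))
  expect_equal(j$motif_class, c("GT/AG", "GC/AG", "other"))
  expect_equal(j$unique_reads, c(12L, 8L, 6L))
  expect_equal(j$annotated, c(FALSE, TRUE, FALSE))
  expect_true(is.na(j$strand[3]))
})

test_that("BED6 junctions convert from 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr5\t999\t1100\tj1\t12\t+", path)
  j <- read_junctions(path, "bed6")
  expect_equal(j$intron_start, 1000L)
  expect_equal(j$intron_end, 1100L)
  expect_equal(j$unique_reads, 12L)
})

test_that("the same junctions read via sj_tab and BED6 give identical records", {
  g <- make_gene(seed = 41)
  intr <- pseudoexonr:::introns_tx_order(g)
  jx <- data.frame(chrom = g$chrom,
                   intron_start = pmin(intr$five, intr$three),
                   intron_end = pmax(intr$five, intr$three),
                   strand = g$strand, motif_class = "GT/AG",
                   unique_reads = c(12L, 7L, 20L, 5L), annotated = FALSE)
  sj <- withr::local_tempfile(fileext = ".tab")
  b6 <- withr::local_tempfile(fileext = ".bed")
  write_sj_tab(jx, sj)
  writeLines(sprintf("%s\t%d\t%d\tj%d\t%d\t%s", jx$chrom, jx$intron_start - 1L,
                     jx$intron_end, seq_len(nrow(jx)), jx$unique_reads,
                     jx$strand), b6)
  a <- read_junctions(sj, "sj_tab")
  b <- read_junctions(b6, "bed6", genome = g$genome)
  expect_equal(a[, c("chrom", "intron_start", "intron_end", "strand",
                     "motif_class", "unique_reads")],
               b[, c("chrom", "intron_start", "intron_end", "strand",
                     "motif_class", "unique_reads")])
})

test_that("malformed and empty junction files are handled", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines("chr5\t1\t2\t3", path)
  expect_error(read_junctions(path, "sj_tab"), "line 1")
  writeLines(character(0), path)
  expect_warning(j <- read_junctions(path, "sj_tab"), "empty")
  expect_equal(nrow(j), 0L)
})

test_that("junction filtering applies per-motif-class minima at the boundary", {
  jx <- data.frame(chrom = "c", intron_start = 1:6 * 100L,
                   intron_end = 1:6 * 100L + 50L, strand = "+",
                   motif_class = c("GT/AG", "GT/AG", "GC/AG", "other",
                                   "other", "other"),
                   unique_reads = c(1L, 2L, 2L, 5L, 6L, 100L),
                   annotated = FALSE)
  kept <- filter_junctions(jx)
  expect_equal(kept$unique_reads, c(2L, 2L, 6L, 100L))
  # hand-count on a mixed list of ten
  set.seed(42)
  jx10 <- data.frame(chrom = "c", intron_start = 1:10 * 10L,
                     intron_end = 1:10 * 10L + 5L, strand = "+",
                     motif_class = sample(c("GT/AG", "GC/AG", "other"), 10,
                                          replace = TRUE),
                     unique_reads = sample(0:8, 10, replace = TRUE),
                     annotated = FALSE)
  minima <- c("GT/AG" = 2, "GC/AG" = 2, other = 6)
  expect_equal(nrow(filter_junctions(jx10)),
               sum(jx10$unique_reads >= minima[jx10$motif_class]))
})

test_that("paired novel junctions define a pseudoexon event with its inclusion fraction", {
  g <- make_gene(seed = 43)
  intr <- pseudoexonr:::introns_tx_order(g)
  can_start <- min(intr$five[2], intr$three[2])
  can_end <- max(intr$five[2], intr$three[2])
  seg_start <- can_start + 400L
  seg_end <- seg_start + 82L          # 83 bp segment
  jx <- data.frame(
    chrom = g$chrom,
    intron_start = c(can_start, can_start, seg_end + 1L),
    intron_end = c(can_end, seg_start - 1L, can_end),
    strand = "+", motif_class = "GT/AG",
    unique_reads = c(60L, 28L, 25L),
    annotated = c(TRUE, FALSE, FALSE))
  det <- detect_pseudoexon_events(jx, g)
  expect_equal(nrow(det$events), 1L)
  ev <- det$events
  expect_equal(ev$segment_start, seg_start)
  expect_equal(ev$segment_end, seg_end)
  expect_equal(ev$segment_length, 83L)
  expect_equal(ev$inclusion_fraction, 25 / (25 + 60))
  expect_equal(nrow(det$incomplete), 0L)
  # min-of-pair alternative
  det2 <- detect_pseudoexon_events(jx, g, inclusion_stat = "min")
  expect_equal(det2$events$inclusion_fraction, 25 / (25 + 60))
})

test_that("events require fully intronic segments in range; singles are incomplete", {
  g <- make_gene(seed = 44)
  intr <- pseudoexonr:::introns_tx_order(g)
  can_start <- min(intr$five[2], intr$three[2])
  can_end <- max(intr$five[2], intr$three[2])
  # only the upstream novel junction present -> incomplete, no event
  jx <- data.frame(chrom = g$chrom,
                   intron_start = c(can_start, can_start),
                   intron_end = c(can_end, can_start + 399L),
                   strand = "+", motif_class = "GT/AG",
                   unique_reads = c(60L, 20L), annotated = c(TRUE, FALSE))
  det <- detect_pseudoexon_events(jx, g)
  expect_equal(nrow(det$events), 0L)
  expect_equal(nrow(det$incomplete), 1L)
  # a paired segment of 400 bp is out of range
  jx2 <- rbind(jx, data.frame(chrom = g$chrom,
                              intron_start = can_start + 800L,
                              intron_end = can_end, strand = "+",
                              motif_class = "GT/AG", unique_reads = 22L,
                              annotated = FALSE))
  det2 <- detect_pseudoexon_events(jx2, g)
  expect_equal(nrow(det2$events), 0L)
  # control sample with only canonical junctions
  det3 <- detect_pseudoexon_events(jx[1, ], g)
  expect_equal(nrow(det3$events), 0L)
  expect_equal(nrow(det3$incomplete), 0L)
})

test_that("unstranded junctions are imputed with a warning", {
  g <- make_gene(seed = 45)
  intr <- pseudoexonr:::introns_tx_order(g)
  jx <- data.frame(chrom = g$chrom, intron_start = intr$five[1],
                   intron_end = intr$three[1], strand = NA,
                   motif_class = "GT/AG", unique_reads = 10L, annotated = TRUE)
  expect_warning(det <- detect_pseudoexon_events(jx, g), "imputing")
  expect_equal(nrow(det$events), 0L)
})

test_that("variant phasing within pseudoexon reads returns the alt fraction", {
  v <- parse_hgvs_c("c.100+75A>G")
  obs <- data.frame(read_id = paste0("r", 1:20), base = "G")
  pc <- variant_phase_check(obs, v)
  expect_equal(pc$alt_fraction, 1)
  expect_equal(pc$n_alt, 20L)
  half <- data.frame(read_id = paste0("r", 1:20),
                     base = rep(c("G", "A"), each = 10))
  expect_equal(variant_phase_check(half, v)$alt_fraction, 0.5)
  none <- variant_phase_check(data.frame(read_id = character(0),
                                         base = character(0)), v)
  expect_true(none$no_coverage)
  expect_true(is.na(none$alt_fraction))
})
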