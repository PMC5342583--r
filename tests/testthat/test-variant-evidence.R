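mk_var <- function(id, af = NA_real_) {
  data.frame(variant_id = id, chrom = "chr5", pos = nchar(id) * 100L,
             ref = "A", alt = "T", population_af = af)
}
mk_gt <- function(id, sample = "S1", gt = "het", dp = 30L, gq = 99L) {
  data.frame(variant_id = id, sample = sample, gt = gt, dp = dp, gq = gq)
}

test_that("WGS filters apply the depth, quality, frequency and zygosity boundaries", {
  vars <- do.call(rbind, list(
    mk_var("a"), mk_var("bb"), mk_var("ccc", 0.001), mk_var("dddd", 0.0009),
    mk_var("eeeee"), mk_var("ffffff")))
  gts <- rbind(mk_gt("a", dp = 7L, gq = 70L),    # boundary pass
               mk_gt("bb", dp = 6L),             # DP 6 removed
               mk_gt("ccc"),                     # MAF 0.001 removed (>= rule)
               mk_gt("dddd"),                    # MAF 0.0009 kept
               mk_gt("eeeee", gq = 69L),         # GQ 69 removed
               mk_gt("ffffff", gt = "hom_alt"))  # heterozygote-only
  out <- suppressMessages(filter_variants(vars, gts, "S1"))
  expect_setequal(out$variant_id, c("a", "dddd"))
})

test_that("the filter has set semantics: idempotent and order-independent", {
  set.seed(61)
  ids <- paste0("v", 1:12)
  vars <- do.call(rbind, lapply(ids, function(i)
    mk_var(i, af = sample(c(NA, 0, 0.0005, 0.002), 1))))
  gts <- do.call(rbind, lapply(ids, function(i)
    mk_gt(i, gt = sample(c("het", "hom_ref", "hom_alt"), 1),
          dp = sample(4:40, 1), gq = sample(c(60L, 75L, 99L), 1))))
  once <- suppressMessages(filter_variants(vars, gts, "S1"))
  twice <- suppressMessages(filter_variants(once, gts, "S1"))
  expect_equal(once, twice)
  shuffled <- vars[sample(nrow(vars)), ]
  out2 <- suppressMessages(filter_variants(shuffled, gts, "S1"))
  expect_setequal(once$variant_id, out2$variant_id)
  # hand enumeration
  keep <- vapply(ids, function(i) {
    g <- gts[gts$variant_id == i, ]
    v <- vars[vars$variant_id == i, ]
    g$dp >= 7 && g$gq >= 70 && g$gt == "het" &&
      (is.na(v$population_af) || v$population_af < 0.001)
  }, logical(1))
  expect_setequal(once$variant_id, ids[keep])
})

test_that("dominant-shared mode requires the het genotype in all affected samples", {
  vars <- rbind(mk_var("a"), mk_var("bb"))
  gts <- rbind(mk_gt("a", "S1"), mk_gt("a", "S2"), mk_gt("a", "S3"),
               mk_gt("bb", "S1"), mk_gt("bb", "S2", gt = "hom_ref"),
               mk_gt("bb", "S3"))
  out <- suppressMessages(
    filter_variants(vars, gts, "S1", dominant_shared = TRUE,
                    affected_samples = c("S1", "S2", "S3")))
  expect_equal(out$variant_id, "a")
  expect_error(filter_variants(vars, gts, "S1", dominant_shared = TRUE),
               "affected_samples")
})

test_that("variants and genotypes survive a VCF round trip", {
  vars <- rbind(mk_var("chr5:100:A:T"), mk_var("chr5:200:A:T"))
  vars$pos <- c(100L, 200L)
  gts <- rbind(mk_gt("chr5:100:A:T", "S1"), mk_gt("chr5:100:A:T", "S2",
                                                  gt = "hom_ref", dp = 22L),
               mk_gt("chr5:200:A:T", "S1", gt = "hom_alt"),
               mk_gt("chr5:200:A:T", "S2", gt = "missing"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_variants(vars, gts, path)
  back <- read_vcf_variants(path)
  expect_equal(back$variants$pos, vars$pos)
  m <- merge(gts, back$genotypes, by = c("variant_id", "sample"))
  expect_equal(m$gt.x, m$gt.y)
  expect_equal(m$dp.x[m$gt.x != "missing"], m$dp.y[m$gt.x != "missing"])
})

test_that("co-segregation classifies complete, incomplete and not assessable", {
  ped <- simulate_pedigree(4, 2, "dominant", id_prefix = "F85", seed = 62)
  expect_equal(cosegregation_check(ped$pedigree, ped$genotypes), "complete")
  broken <- ped$genotypes
  broken[names(broken)[ped$pedigree$affected][2]] <- "hom_ref"
  expect_equal(cosegregation_check(ped$pedigree, broken), "incomplete")
  spor <- simulate_pedigree(1, 2, "sporadic", id_prefix = "F42", seed = 62)
  expect_equal(cosegregation_check(spor$pedigree, spor$genotypes),
               "not_assessable")
  # unaffected carrier breaks completeness unless penetrance is reduced
  carrier_unaff <- ped$genotypes
  carrier_unaff[names(carrier_unaff)[!ped$pedigree$affected][1]] <- "het"
  expect_equal(cosegregation_check(ped$pedigree, carrier_unaff), "incomplete")
  expect_equal(cosegregation_check(ped$pedigree, carrier_unaff,
                                   reduced_penetrance = TRUE), "complete")
  expect_error(cosegregation_check(ped$pedigree, c(GHOST = "het")), "unknown")
})

test_that("pedigrees survive a TSV round trip and are validated", {
  ped <- simulate_pedigree(3, 2, "dominant", id_prefix = "P", seed = 63)
  path <- withr::local_tempfile(fileext = ".ped")
  write_pedigree(ped$pedigree, path)
  back <- read_pedigree(path)
  expect_equal(back$id, ped$pedigree$id)
  expect_equal(back$affected, ped$pedigree$affected)
  bad <- ped$pedigree; bad$father[2] <- "NOBODY"
  expect_error(validate_pedigree <- pseudoexonr:::validate_pedigree(bad),
               "do not resolve")
})

mk_call <- function(motif = TRUE, junction = TRUE) {
  data.frame(gene_id = "G", hgvs_c = "c.100+50C>T", pe_start_g = 500L,
             pe_end_g = 582L, pe_start_c = "100+50", pe_end_c = "100+132",
             length = 83L, donor_class = "GT", donor_score = 100,
             acceptor_score = 100, motif_supported = motif,
             junction_supported = junction)
}
mk_pc2 <- function(category = "frameshift", ptc = 120L) {
  structure(list(category = category, first_affected_codon = 100L,
                 ref_aa = "G", alt_aa = "S", stop_offset = 21L,
                 ptc_codon = ptc, notation = "p.Gly100Serfs*21"),
            class = "protein_change")
}

test_that("evidence aggregation reproduces the three family profiles", {
  # family-85 profile: motif call, truncating, complete co-segregation
  r85 <- aggregate_evidence(mk_call(TRUE, TRUE), mk_pc2(), "complete",
                            population_af = NA, ase_class = "unequivocal")
  expect_equal(r85$tier, "supported")
  # family-163 profile: motif failed, junction rescue, sporadic pedigree
  r163 <- aggregate_evidence(mk_call(FALSE, TRUE), mk_pc2(), "not_assessable",
                             population_af = 0, ase_class = "putative")
  expect_equal(r163$tier, "supported")
  # in-frame insertion present also in controls
  inframe <- mk_pc2("inframe_insertion", NA_integer_)
  rctrl <- aggregate_evidence(mk_call(TRUE, TRUE), inframe, "not_assessable",
                              also_in_control = TRUE)
  expect_equal(rctrl$tier, "unsupported")
  # non-truncating but well-supported call is uncertain
  runc <- aggregate_evidence(mk_call(TRUE, TRUE), inframe, "complete")
  expect_equal(runc$tier, "uncertain")
  # common variant cannot be supported
  rcommon <- aggregate_evidence(mk_call(TRUE, TRUE), mk_pc2(), "complete",
                                population_af = 0.01)
  expect_equal(rcommon$tier, "uncertain")
})

test_that("switching any single evidence flag off never raises the tier", {
  rank <- c(unsupported = 1L, uncertain = 2L, supported = 3L)
  base_tier <- rank[[aggregate_evidence(mk_call(TRUE, TRUE), mk_pc2(),
                                        "complete", NA, "ASE")$tier]]
  weaker <- list(
    aggregate_evidence(NULL, mk_pc2(), "complete", NA, "ASE"),
    aggregate_evidence(mk_call(FALSE, FALSE), mk_pc2(), "complete", NA, "ASE"),
    aggregate_evidence(mk_call(TRUE, TRUE), NULL, "complete", NA, "ASE"),
    aggregate_evidence(mk_call(TRUE, TRUE), mk_pc2(), "incomplete", NA, "ASE"),
    aggregate_evidence(mk_call(TRUE, TRUE), mk_pc2(), "complete", 0.5, "ASE"),
    aggregate_evidence(mk_call(TRUE, TRUE), mk_pc2(), "complete", NA, "ASE",
                       also_in_control = TRUE))
  for (w in weaker) expect_lte(rank[[w$tier]], base_tier)
})
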