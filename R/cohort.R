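sub_seed <- function(seed, k) (as.integer(seed) %% 100000L) * 20011L + k

# canonical junction rows (full depth) for every intron of the model
canonical_junction_table <- function(model, depth) {
  intr <- introns_tx_order(model)
  data.frame(chrom = model$chrom,
             intron_start = pmin(intr$five, intr$three),
             intron_end = pmax(intr$five, intr$three),
             strand = model$strand, motif_class = "GT/AG",
             unique_reads = depth, annotated = TRUE)
}

# overlay an inclusion event (pseudoexon or constitutive insert) on a table
overlay_inclusion <- function(jx, model, intron_index, seg_lo, seg_hi, psi,
                              depth, donor_motif = "GT/AG") {
  row <- if (model$strand == "+") intron_index else
    (nrow(jx[jx$annotated, ]) - intron_index + 1L)
  ann <- which(jx$annotated)
  r <- ann[row]
  jx$unique_reads[r] <- stats::rbinom(1, depth, 1 - psi)
  if (psi > 0) {
    up <- data.frame(chrom = model$chrom, intron_start = jx$intron_start[r],
                     intron_end = seg_lo - 1L, strand = model$strand,
                     motif_class = if (model$strand == "+") "GT/AG" else donor_motif,
                     unique_reads = stats::rbinom(1, depth, psi),
                     annotated = FALSE)
    dn <- data.frame(chrom = model$chrom, intron_start = seg_hi + 1L,
                     intron_end = jx$intron_end[r], strand = model$strand,
                     motif_class = if (model$strand == "+") donor_motif else "GT/AG",
                     unique_reads = stats::rbinom(1, depth, psi),
                     annotated = FALSE)
    jx <- rbind(jx, up, dn)
  }
  jx
}

# a background (benign) variant guaranteed to create no donor gain
benign_variant <- function(model, forbidden, max_tries = 50) {
  intr <- introns_tx_order(model)
  lo <- pmin(intr$five, intr$three) + 30L
  hi <- pmax(intr$five, intr$three) - 30L
  for (i in seq_len(max_tries)) {
    ii <- sample(nrow(intr), 1)
    g <- sample(lo[ii]:hi[ii], 1)
    if (any(abs(g - forbidden) < 60L)) next
    # positions 5' of c.1 (e.g. the 5' UTR intron) have no c. coordinate here
    cd <- tryCatch(map_genomic_to_cdna(model, g), error = function(e) NULL)
    if (is.null(cd)) next
    ref <- toupper(genomic_seq(model, g, g))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- cdna_variant(cd, ref, alt)
    if (nrow(donor_gain_scan(model, v)) == 0L) return(list(variant = v, g = g))
  }
  stop("could not place a benign background variant")  # nocov
}

# plus-strand VCF-style alleles for a transcript-strand cdna_variant
variant_vcf_alleles <- function(model, variant) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (model$strand == "+") c(variant$ref, variant$alt)
  else unname(comp[c(variant$ref, variant$alt)])
}

#' Simulate a polyposis-style study cohort
#'
#' Generates a cohort of families screened for pseudoexon mutations in one
#' shared gene: a synthetic multi-exon gene whose reference carries latent
#' cryptic splice sites in three introns, carrier families bearing activating
#' deep-intronic substitutions (a stop-leading 127-bp pseudoexon, a
#' frameshifting 83-bp pseudoexon with a dominant multiplex pedigree, and a
#' GC-donor 83-bp pseudoexon whose variant sits inside the pseudoexon), and
#' non-carrier families. Every sample also shows a constitutive 54-bp
#' in-frame inclusion, present in healthy controls too, which the pipeline
#' must flag as non-causal. Per family the generator emits WGS-style variants
#' (with depth/quality/frequency structure exercising each filter), junction
#' tables, allelic counts and a pedigree; ground truth is recorded for every
#' carrier.
#'
#' @param n_families Number of families (default 54).
#' @param n_carriers Number of carrier families (default 3; at most 3
#'   scenarios are distinct).
#' @param psi Pseudoexon inclusion level in carrier RNA (default 0.3).
#' @param junction_depth Junction read depth (default 60).
#' @param ase_depth Allelic count depth (default 500).
#' @param n_snps Heterozygous SNPs per sample for ASE (default 4).
#' @param R_carrier True allelic ratio in carriers (default 0.6, the
#'   unequivocal-ASE boundary corresponding to a 40% reduction of one allele).
#' @param seed Random seed.
#' @return A `pseudoexon_cohort` list: shared reference `model`, `families`
#'   (each with variant, genotype, junction, count and pedigree tables),
#'   `af_table`, `control_junctions`, and `truth` records per carrier.
#' @export
simulate_cohort <- function(n_families = 54, n_carriers = 3, psi = 0.3,
                            junction_depth = 60, ase_depth = 500, n_snps = 4,
                            R_carrier = 0.6, seed = 1) {
  stopifnot(n_carriers <= n_families)
  gene <- make_gene(n_exons = 5, align_boundary_exon = 2,
                    seed = sub_seed(seed, 0))
  scenarios <- list(
    list(scenario = "gt_gain", consequence = "nonsense", pe_length = 127,
         intron = 2, mode = "sporadic"),
    list(scenario = "gt_gain", consequence = "frameshift", pe_length = 83,
         intron = 3, mode = "dominant"),
    list(scenario = "exonic_ag_gain_gc_donor", consequence = "frameshift",
         pe_length = 83, intron = 4, mode = "sporadic"))
  if (n_carriers > length(scenarios))
    stop("at most ", length(scenarios), " carrier scenarios are available")

  # plant all latent sites into one shared reference (distinct introns)
  ref <- gene
  plants <- list()
  for (k in seq_len(n_carriers)) {
    sc <- scenarios[[k]]
    p <- plant_pseudoexon_variant(ref, intron_index = sc$intron,
                                  pe_length = sc$pe_length,
                                  scenario = sc$scenario,
                                  consequence = sc$consequence,
                                  seed = sub_seed(seed, k))
    ref <- p$model_ref
    plants[[k]] <- p
  }
  # re-bind planted models to the final shared reference
  for (k in seq_along(plants)) plants[[k]]$model_ref <- ref

  # constitutive 54-bp in-frame inclusion in intron 1, present in everyone
  set.seed(sub_seed(seed, 900))
  intr <- introns_tx_order(ref)
  c_lo <- min(intr$five[1], intr$three[1]) + 400L
  common_seg <- c(c_lo, c_lo + 53L)
  common_psi <- 0.15

  set.seed(sub_seed(seed, 901))
  carrier_fams <- sort(sample(n_families, n_carriers))
  fam_ids <- sprintf("F%02d", seq_len(n_families))
  forbidden <- unlist(lapply(plants, function(p)
    c(p$truth$pe_start_g, p$truth$pe_end_g, p$truth$variant_g)))

  af_rows <- list()
  families <- vector("list", n_families)
  names(families) <- fam_ids
  truth <- list()
  for (f in seq_len(n_families)) {
    fam <- fam_ids[f]
    k <- match(f, carrier_fams)
    carrier <- !is.na(k)
    sc <- if (carrier) scenarios[[k]] else list(mode = "sporadic")
    ped <- simulate_pedigree(
      n_affected = if (identical(sc$mode, "dominant")) 4 else 1,
      n_unaffected = 2, mode = sc$mode, id_prefix = fam,
      seed = sub_seed(seed, 1000 + f))
    index <- paste0(fam, "_A1")

    set.seed(sub_seed(seed, 2000 + f))
    vs <- list(); gts <- list()
    add_variant <- function(variant_g, ref_alt, gt_by_id, dp, gq, vid = NULL) {
      if (is.null(vid))
        vid <- paste(ref$chrom, variant_g, ref_alt[1], ref_alt[2], sep = ":")
      vs[[length(vs) + 1L]] <<- data.frame(
        variant_id = vid, chrom = ref$chrom, pos = variant_g,
        ref = ref_alt[1], alt = ref_alt[2])
      gts[[length(gts) + 1L]] <<- data.frame(
        variant_id = vid, sample = names(gt_by_id), gt = unname(gt_by_id),
        dp = dp, gq = gq)
      vid
    }
    all_ids <- ped$pedigree$id
    base_gt <- stats::setNames(rep("hom_ref", length(all_ids)), all_ids)
    het_index <- base_gt; het_index[index] <- "het"
    hom_index <- base_gt; hom_index[index] <- "hom_alt"

    # background variants exercising every WGS filter
    b1 <- benign_variant(ref, forbidden)   # common SNP, removed by MAF
    vid1 <- add_variant(b1$g, variant_vcf_alleles(ref, b1$variant),
                        het_index, dp = 35L, gq = 99L)
    af_rows[[length(af_rows) + 1L]] <-
      data.frame(chrom = ref$chrom, pos = b1$g,
                 ref = variant_vcf_alleles(ref, b1$variant)[1],
                 alt = variant_vcf_alleles(ref, b1$variant)[2], af = 0.01)
    b2 <- benign_variant(ref, forbidden)   # low depth
    add_variant(b2$g, variant_vcf_alleles(ref, b2$variant), het_index,
                dp = 5L, gq = 99L)
    b3 <- benign_variant(ref, forbidden)   # low genotype quality
    add_variant(b3$g, variant_vcf_alleles(ref, b3$variant), het_index,
                dp = 30L, gq = 65L)
    b4 <- benign_variant(ref, forbidden)   # rare, passes filters, no donor gain
    add_variant(b4$g, variant_vcf_alleles(ref, b4$variant), het_index,
                dp = 28L, gq = 95L)
    b5 <- benign_variant(ref, forbidden)   # homozygous, removed
    add_variant(b5$g, variant_vcf_alleles(ref, b5$variant), hom_index,
                dp = 30L, gq = 99L)
    causal_id <- NULL
    if (carrier) {
      p <- plants[[k]]
      causal_id <- add_variant(
        p$truth$variant_g, variant_vcf_alleles(ref, p$variant),
        ped$genotypes, dp = 31L, gq = 99L)
      truth[[fam]] <- c(p$truth, list(family = fam, causal_id = causal_id))
    }
    variants <- do.call(rbind, vs)
    genotypes <- do.call(rbind, gts)

    # junction table: canonical + the constitutive 54-bp event (+ pe if carrier)
    set.seed(sub_seed(seed, 3000 + f))
    jx <- canonical_junction_table(ref, junction_depth)
    jx <- overlay_inclusion(jx, ref, 1L, common_seg[1], common_seg[2],
                            common_psi, junction_depth)
    if (carrier) {
      p <- plants[[k]]
      jx <- overlay_inclusion(
        jx, ref, p$truth$intron_index,
        min(p$truth$pe_start_g, p$truth$pe_end_g),
        max(p$truth$pe_start_g, p$truth$pe_end_g), psi, junction_depth,
        donor_motif = if (p$truth$scenario == "gt_gain") "GT/AG" else "GC/AG")
    }
    jx <- jx[jx$unique_reads > 0, , drop = FALSE]
    rownames(jx) <- NULL

    counts <- simulate_allelic_counts(
      R_true = if (carrier) R_carrier else 1, n_snps = n_snps,
      depth = ase_depth, sample = index, gene_id = ref$gene_id,
      seed = sub_seed(seed, 4000 + f))

    families[[fam]] <- list(
      family = fam, carrier = carrier, index_sample = index,
      pedigree = ped$pedigree, variants = variants, genotypes = genotypes,
      junctions = jx, counts = counts, causal_id = causal_id)
  }

  control_junctions <- lapply(1:3, function(i) {
    set.seed(sub_seed(seed, 5000 + i))
    jx <- canonical_junction_table(ref, junction_depth)
    jx <- overlay_inclusion(jx, ref, 1L, common_seg[1], common_seg[2],
                            common_psi, junction_depth)
    jx[jx$unique_reads > 0, , drop = FALSE]
  })

  structure(list(model = ref, families = families,
                 af_table = {
                   a <- do.call(rbind, af_rows)
                   a$variant_id <- paste(a$chrom, a$pos, a$ref, a$alt, sep = ":")
                   a
                 },
                 control_junctions = control_junctions,
                 truth = truth, carrier_families = fam_ids[carrier_fams]),
            class = "pseudoexon_cohort")
}

#' @export
print.pseudoexon_cohort <- function(x, ...) {
  cat(sprintf("<pseudoexon_cohort> %d families, %d carriers (%s)\n",
              length(x$families), length(x$truth),
              paste(x$carrier_families, collapse = ", ")))
  invisible(x)
}
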