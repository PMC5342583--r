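#' Read substitution variants and per-sample genotypes from a VCF
#'
#' Single-nucleotide substitutions only. Genotypes are decoded to
#' `hom_ref`/`het`/`hom_alt`/`missing`; per-sample DP and GQ are taken from the
#' FORMAT fields (NA where absent).
#'
#' @param path VCF path (plain text or bgzipped).
#' @return List with `variants` (data frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `genotypes` (long data frame: `variant_id`, `sample`,
#'   `gt`, `dp`, `gq`).
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  variants <- data.frame(
    variant_id = paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT)[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))[keep, , drop = FALSE]
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))[keep, , drop = FALSE]
  decode <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(is.na(g) | g %in% c("./.", "."), "missing",
    ifelse(g == "0/0", "hom_ref",
    ifelse(g %in% c("0/1", "1/0"), "het",
    ifelse(g == "1/1", "hom_alt", "missing"))))
  }
  samples <- colnames(gt)
  genotypes <- do.call(rbind, lapply(samples, function(s) data.frame(
    variant_id = variants$variant_id, sample = s,
    gt = decode(gt[, s]), dp = as.integer(dp[, s]), gq = as.integer(gq[, s]))))
  rownames(variants) <- rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Write variants and genotypes as a minimal VCF
#'
#' @param variants,genotypes Data frames in the layout returned by
#'   [read_vcf_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_variants <- function(variants, genotypes, path) {
  samples <- unique(genotypes$sample)
  enc <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    vid <- variants$variant_id[i]
    cells <- vapply(samples, function(s) {
      g <- genotypes[genotypes$variant_id == vid & genotypes$sample == s, ]
      if (nrow(g) == 0L) "./.:.:."
      else sprintf("%s:%s:%s", enc[[g$gt[1]]],
                   ifelse(is.na(g$dp[1]), ".", g$dp[1]),
                   ifelse(is.na(g$gq[1]), ".", g$gq[1]))
    }, character(1))
    paste(c(variants$chrom[i], variants$pos[i], vid, variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT:DP:GQ", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a local population allele-frequency table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `af`. This stands in for
#' live population-database lookups: a variant absent from the table is
#' treated as having unknown (effectively zero) population frequency.
#'
#' @param path TSV path.
#' @return Data frame with a `variant_id` key column added.
#' @export
read_population_af <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(d)))
  d$variant_id <- paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  d
}

#' Annotate variants with population allele frequency
#'
#' @param variants Variant data frame (with `variant_id`).
#' @param af_table Table from [read_population_af()], or NULL.
#' @return `variants` with a `population_af` column (NA where unknown).
#' @export
annotate_population_af <- function(variants, af_table = NULL) {
  variants$population_af <- if (is.null(af_table)) NA_real_
    else af_table$af[match(variants$variant_id, af_table$variant_id)]
  variants
}

#' WGS-style candidate variant filtering
#'
#' Retains variants with read depth >= `min_dp` and genotype quality >=
#' `min_gq` in every analyzed sample, population minor allele frequency below
#' `max_af` (the >= boundary is removed; unknown frequency passes and is
#' logged), heterozygous genotype in the index sample, optionally restricted
#' to a genomic region, and optionally — dominant-inheritance mode —
#' heterozygous in all affected genotyped samples.
#'
#' The filter has set semantics: it is idempotent and order-independent.
#'
#' @param variants Variant data frame with `population_af` (see
#'   [annotate_population_af()]).
#' @param genotypes Long genotype data frame (`variant_id`, `sample`, `gt`,
#'   `dp`, `gq`).
#' @param index_sample Sample whose heterozygosity is required.
#' @param samples Samples whose DP/GQ must pass (default: all in `genotypes`).
#' @param min_dp Minimum read depth (default 7).
#' @param min_gq Minimum genotype quality (default 70; GQ < 70 excluded).
#' @param max_af Population-frequency cutoff (default 0.001; MAF >= 0.001
#'   removed).
#' @param dominant_shared If TRUE, require het in all `affected_samples`.
#' @param affected_samples Samples that must share the het genotype under
#'   `dominant_shared`.
#' @param region Optional list/data frame with `chrom`, `start`, `end`.
#' @return The surviving rows of `variants`.
#' @export
filter_variants <- function(variants, genotypes, index_sample,
                            samples = NULL, min_dp = 7, min_gq = 70,
                            max_af = 0.001, dominant_shared = FALSE,
                            affected_samples = NULL, region = NULL) {
  if (is.null(samples)) samples <- unique(genotypes$sample)
  if (is.null(variants$population_af)) variants$population_af <- NA_real_
  g <- genotypes[genotypes$sample %in% samples, , drop = FALSE]
  qual_ok <- tapply(g$dp >= min_dp & g$gq >= min_gq, g$variant_id, all)
  keep <- variants$variant_id %in% names(qual_ok)[qual_ok %in% TRUE]
  af <- variants$population_af
  if (any(is.na(af) & keep))
    message(sum(is.na(af) & keep),
            " variant(s) with unknown population frequency treated as rare")
  keep <- keep & (is.na(af) | af < max_af)
  idx <- genotypes[genotypes$sample == index_sample, , drop = FALSE]
  het_idx <- idx$variant_id[idx$gt == "het"]
  keep <- keep & variants$variant_id %in% het_idx
  if (dominant_shared) {
    if (is.null(affected_samples)) stop("dominant_shared requires affected_samples")
    ga <- genotypes[genotypes$sample %in% affected_samples, , drop = FALSE]
    shared <- tapply(ga$gt == "het", ga$variant_id, all)
    keep <- keep & variants$variant_id %in% names(shared)[shared %in% TRUE]
  }
  if (!is.null(region)) {
    keep <- keep & variants$chrom == region$chrom &
      variants$pos >= region$start & variants$pos <= region$end
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a 6-column pedigree table
#'
#' Tab-separated with columns `id`, `father`, `mother`, `sex` (`M`/`F`/`U`),
#' `affected` (0/1) and `available` (0/1, sample availability); founders use
#' `"0"` for missing parents.
#'
#' @param path File path.
#' @return `read_pedigree`: a data frame of class `pedigree_df`.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.delim(path, colClasses = c(id = "character",
                                              father = "character",
                                              mother = "character"))
  validate_pedigree(d)
}

#' @rdname read_pedigree
#' @param pedigree Pedigree data frame.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_pedigree <- function(d) {
  stopifnot(all(c("id", "father", "mother", "sex", "affected", "available")
                %in% names(d)))
  d$affected <- as.logical(d$affected); d$available <- as.logical(d$available)
  parents <- setdiff(c(d$father, d$mother), c("0", NA))
  if (!all(parents %in% d$id))
    stop("pedigree parent reference(s) do not resolve: ",
         paste(setdiff(parents, d$id), collapse = ", "))
  if (!any(d$affected)) stop("pedigree has no affected individual")
  class(d) <- c("pedigree_df", class(d))
  d
}

#' Co-segregation of a variant with disease in a pedigree
#'
#' `complete`: every genotyped affected individual carries the variant and
#' (unless `reduced_penetrance`) every genotyped unaffected individual does
#' not. `not_assessable`: fewer than two genotyped affected individuals (e.g.
#' a sporadic case). `incomplete` otherwise.
#'
#' @param pedigree Data frame from [read_pedigree()] or
#'   [simulate_pedigree()].
#' @param genotypes Named character vector (individual id ->
#'   `hom_ref`/`het`/`hom_alt`/`missing`) for one variant.
#' @param reduced_penetrance If TRUE, unaffected carriers do not break
#'   completeness.
#' @return `"complete"`, `"incomplete"` or `"not_assessable"`.
#' @export
cosegregation_check <- function(pedigree, genotypes,
                                reduced_penetrance = FALSE) {
  unknown <- setdiff(names(genotypes), pedigree$id)
  if (length(unknown))
    stop("genotypes reference unknown individuals: ",
         paste(unknown, collapse = ", "))
  gt <- genotypes[genotypes != "missing"]
  carrier <- gt %in% c("het", "hom_alt")
  names(carrier) <- names(gt)
  aff <- pedigree$affected[match(names(gt), pedigree$id)]
  if (sum(aff) < 2L) return("not_assessable")
  ok <- all(carrier[aff])
  if (!reduced_penetrance) ok <- ok && all(!carrier[!aff])
  if (ok) "complete" else "incomplete"
}

#' Aggregate pathogenicity evidence for a pseudoexon variant
#'
#' Formalizes the evidence checklist used to support pseudoexon pathogenicity:
#' a predicted truncating consequence, absence from the population, disease
#' co-segregation (or a pedigree too small to assess), and pseudoexon support
#' from either the splice-motif model or RNA junction evidence. ASE
#' consistency is reported but advisory — it is not required for the
#' `supported` tier, since genuine pseudoexon alleles may fall short of
#' statistical significance in small RNA data.
#'
#' Tiers: `supported` requires truncating AND population-absent AND
#' co-segregation in `{complete, not_assessable}` AND motif or junction
#' support; an event seen also in control samples, or lacking any pseudoexon
#' support, is `unsupported`; everything else is `uncertain`. Turning any
#' single evidence flag off never raises the tier.
#'
#' @param pseudoexon_call One pseudoexon call (single-row data frame), or NULL.
#' @param protein_change A `protein_change`, or NULL.
#' @param coseg Co-segregation status (default `"not_assessable"`).
#' @param population_af Population allele frequency (NA = unknown/absent).
#' @param ase_class ASE classification for the sample's gene (SNuPE or RNA
#'   class), or NA.
#' @param also_in_control TRUE when the same event occurs in control samples.
#' @return An `evidence_report` list with all flags and the `tier`.
#' @export
aggregate_evidence <- function(pseudoexon_call = NULL, protein_change = NULL,
                               coseg = "not_assessable", population_af = NA,
                               ase_class = NA, also_in_control = FALSE) {
  pe_present <- !is.null(pseudoexon_call) && NROW(pseudoexon_call) > 0L
  motif <- pe_present && isTRUE(pseudoexon_call$motif_supported[1])
  junction <- pe_present && isTRUE(pseudoexon_call$junction_supported[1])
  truncating <- !is.null(protein_change) &&
    protein_change$category %in% c("nonsense", "frameshift") &&
    !is.na(protein_change$ptc_codon)
  population_absent <- is.na(population_af) || population_af == 0
  ase_consistent <- !is.na(ase_class) &&
    ase_class %in% c("ASE", "borderline", "unequivocal", "putative")
  tier <- if (!pe_present || also_in_control || !(motif || junction)) {
    "unsupported"
  } else if (truncating && population_absent &&
             coseg %in% c("complete", "not_assessable")) {
    "supported"
  } else "uncertain"
  structure(list(
    variant = if (pe_present) pseudoexon_call$hgvs_c[1] else NA_character_,
    pseudoexon_present = pe_present,
    motif_supported = motif, junction_supported = junction,
    truncating = truncating,
    protein_notation = if (!is.null(protein_change)) protein_change$notation
                       else NA_character_,
    cosegregation = coseg, population_absent = population_absent,
    ase_consistent = ase_consistent, also_in_control = also_in_control,
    tier = tier), class = "evidence_report")
}

#' @export
print.evidence_report <- function(x, ...) {
  cat("<evidence_report>", if (is.na(x$variant)) "(no call)" else x$variant,
      "->", toupper(x$tier), "\n")
  cat(sprintf("  pseudoexon: %s (motif %s, junction %s, in controls %s)\n",
              x$pseudoexon_present, x$motif_supported, x$junction_supported,
              x$also_in_control))
  cat(sprintf("  protein: %s (truncating %s)\n",
              ifelse(is.na(x$protein_notation), "-", x$protein_notation),
              x$truncating))
  cat(sprintf("  co-segregation: %s | population absent: %s | ASE consistent: %s\n",
              x$cosegregation, x$population_absent, x$ase_consistent))
  invisible(x)
}

evidence_report_row <- function(report, family = NA_character_) {
  data.frame(family = family, variant = report$variant,
             tier = report$tier, truncating = report$truncating,
             protein = report$protein_notation,
             motif_supported = report$motif_supported,
             junction_supported = report$junction_supported,
             cosegregation = report$cosegregation,
             population_absent = report$population_absent,
             ase_consistent = report$ase_consistent,
             also_in_control = report$also_in_control)
}
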