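#' SNuPE allelic expression ratio
#'
#' Ratio of allelic signal in cDNA relative to genomic DNA:
#' `R = (cdna_a1/cdna_a2) / (gdna_a1/gdna_a2)`. Allele labels are fixed by the
#' SNP definition, so R may fall on either side of 1; swapping the labels maps
#' R to 1/R. An optional per-SNP normalization factor (calibrated on
#' mutation-negative controls) divides the raw ratio.
#'
#' @param gdna_a1,gdna_a2,cdna_a1,cdna_a2 Allele counts or peak areas.
#' @param normalization Per-SNP normalization factor (default 1).
#' @return R (positive), or `NA` (uninformative) when any denominator is zero.
#' @export
snupe_ratio <- function(gdna_a1, gdna_a2, cdna_a1, cdna_a2, normalization = 1) {
  if (any(c(gdna_a1, gdna_a2, cdna_a1, cdna_a2) < 0))
    stop("allelic counts must be non-negative")
  if (gdna_a2 == 0 || cdna_a2 == 0 || gdna_a1 == 0 || cdna_a1 == 0)
    return(NA_real_)
  ((cdna_a1 / cdna_a2) / (gdna_a1 / gdna_a2)) / normalization
}

#' Classify a SNuPE ratio into ASE bands
#'
#' `R <= 0.6` or `R >= 1/0.6` (1.67 at the usual printed precision) is
#' unequivocal ASE — a 40% or greater reduction of one allele relative to the
#' other; `0.6 < R < 0.8` or `1.25 < R < 1/0.6` is putative ASE; the closed
#' band `[0.8, 1.25]` is no ASE. The upper thresholds are the exact
#' reciprocals of the lower ones (1/0.8 = 1.25, 1/0.6 = 1.6667), which makes
#' the classification symmetric under allele relabeling:
#' `classify_snupe(R) == classify_snupe(1/R)` for every R.
#'
#' @param R SNuPE ratio (positive; `NA` returns `"uninformative"`).
#' @return One of `"unequivocal"`, `"putative"`, `"none"`, `"uninformative"`.
#' @export
classify_snupe <- function(R) {
  if (is.na(R)) return("uninformative")
  if (R <= 0) stop("SNuPE ratio must be positive")
  if (R <= 0.6 || R >= 1 / 0.6) "unequivocal"
  else if (R < 0.8 || R > 1.25) "putative"
  else "none"
}

#' Gene-level SNuPE status from several SNPs
#'
#' The gene's status is assigned from the SNP with the largest allelic
#' deviation, i.e. maximal `max(R, 1/R)`.
#'
#' @param R Vector of SNuPE ratios (NAs ignored).
#' @return List with `R` (the most deviant ratio) and `class`.
#' @export
snupe_gene_status <- function(R) {
  R <- R[!is.na(R)]
  if (length(R) == 0L) return(list(R = NA_real_, class = "uninformative"))
  dev <- pmax(R, 1 / R)
  best <- R[which.max(dev)]
  list(R = best, class = classify_snupe(best))
}

# ---- gene-level allelic-imbalance test -------------------------------------

# mid-p upper-tail binomial probability at the major allele count
midp_major <- function(x_major, n) {
  stats::pbinom(x_major, n, 0.5, lower.tail = FALSE) +
    0.5 * stats::dbinom(x_major, n, 0.5)
}

# aligned per-SNV z-score: the major-allele mid-p mapped through the normal
# quantile (non-negative by construction)
aligned_z <- function(x_major, n) {
  p <- pmin(pmax(midp_major(x_major, n), 1e-300), 1)
  pmax(stats::qnorm(p, lower.tail = FALSE), 0)
}

# Exact null distribution of the summed aligned z-scores for SNV depths
# `n_vec` under balanced binomial sampling: each SNV's z is a discrete
# variable (folded over the two alleles); the sum's distribution is obtained
# by FFT convolution on a fine grid. Cached per depth profile.
.aligned_null_cache <- new.env(parent = emptyenv())

aligned_sum_sf <- function(s_obs, n_vec, dx = 0.005) {
  key <- paste(sort(n_vec), collapse = ",")
  if (is.null(.aligned_null_cache[[key]])) {
    per_snv <- lapply(n_vec, function(n) {
      x_hi <- ceiling(n / 2):n
      z <- aligned_z(x_hi, n)
      pr <- stats::dbinom(x_hi, n, 0.5) + stats::dbinom(n - x_hi, n, 0.5)
      if (n %% 2L == 0L) pr[1] <- stats::dbinom(n / 2L, n, 0.5)
      list(z = z, pr = pr)
    })
    upper <- sum(vapply(per_snv, function(d) max(d$z), numeric(1))) + 1
    nbin <- ceiling(upper / dx) + 1L
    to_bins <- function(d) {
      v <- numeric(nbin)
      idx <- pmin(floor(d$z / dx) + 1L, nbin)
      for (j in seq_along(idx)) v[idx[j]] <- v[idx[j]] + d$pr[j]
      v
    }
    dist <- to_bins(per_snv[[1]])
    for (i in seq_along(per_snv)[-1]) {
      dist <- convolve(dist, rev(to_bins(per_snv[[i]])), type = "open")
      dist <- dist[seq_len(nbin)]
    }
    dist <- pmax(dist, 0)
    # tail probability from each bin upward
    .aligned_null_cache[[key]] <- list(
      sf = rev(cumsum(rev(dist))), dx = dx, nbin = nbin)
  }
  g <- .aligned_null_cache[[key]]
  bin <- min(floor((s_obs + 1e-9) / g$dx) + 1L, g$nbin)
  min(max(g$sf[bin], 0), 1)
}

#' Gene-level allelic-imbalance test from RNA allele counts
#'
#' A simplified gene-level test of allele-specific expression: per
#' heterozygous SNV, a two-sided exact binomial test of the cDNA major-allele
#' fraction against 0.5 is reported; per gene, the SNVs' one-sided evidence is
#' combined after aligning each SNV to its sample-major allele — Stouffer's
#' sum of `z = qnorm(1 - p)` with equal weights, using mid-p one-sided tails —
#' and the sum is referred to its exact null distribution under balanced
#' binomial sampling (computed by convolution over the SNV depths). Referring
#' the aligned sum to the folded null is the two-sided correction required by
#' the major-allele alignment; using the exact discrete null keeps the test
#' calibrated at realistic coverages.
#' Across genes, Benjamini-Hochberg q-values are computed and classes
#' assigned: `ASE` (q < 0.05), `borderline` (0.05 < q <= 0.15), `none`
#' otherwise. Genes with fewer than two informative SNVs are `uninformative`.
#'
#' This is not a reimplementation of the MBASED meta-analytic model; it is a
#' transparent substitute producing the same class structure.
#'
#' @param counts Data frame of allelic counts for one sample: columns
#'   `sample`, `snp_id`, `gene_id`, `gdna_a1`, `gdna_a2`, `cdna_a1`,
#'   `cdna_a2`.
#' @param min_cdna_coverage Minimum cDNA depth per SNV (default 10).
#' @param min_het_fraction Minimum gDNA minor-allele fraction asserting
#'   heterozygosity (default 0.2).
#' @param q_ase,q_borderline Class boundaries on the q-value (defaults 0.05 and
#'   0.15).
#' @return Data frame with one row per gene: `sample`, `gene_id`, `n_snps`,
#'   `p_value`, `q_value`, `rnaseq_class`.
#' @export
gene_ase_test <- function(counts, min_cdna_coverage = 10,
                          min_het_fraction = 0.2,
                          q_ase = 0.05, q_borderline = 0.15) {
  stopifnot(all(c("sample", "snp_id", "gene_id", "gdna_a1", "gdna_a2",
                  "cdna_a1", "cdna_a2") %in% names(counts)))
  if (length(unique(counts$sample)) > 1L)
    stop("gene_ase_test expects counts from a single sample")
  gtot <- counts$gdna_a1 + counts$gdna_a2
  ctot <- counts$cdna_a1 + counts$cdna_a2
  het <- gtot > 0 & pmin(counts$gdna_a1, counts$gdna_a2) / gtot >= min_het_fraction
  informative <- het & ctot >= min_cdna_coverage
  res <- lapply(split(seq_len(nrow(counts)), counts$gene_id), function(idx) {
    ok <- idx[informative[idx]]
    gene <- counts$gene_id[idx[1]]
    if (length(ok) < 2L)
      return(data.frame(sample = counts$sample[idx[1]], gene_id = gene,
                        n_snps = length(ok), p_value = NA_real_))
    x_major <- pmax(counts$cdna_a1[ok], counts$cdna_a2[ok])
    n <- ctot[ok]
    p <- aligned_sum_sf(sum(aligned_z(x_major, n)), n)
    data.frame(sample = counts$sample[idx[1]], gene_id = gene,
               n_snps = length(ok), p_value = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$rnaseq_class <- ifelse(!tested, "uninformative",
                      ifelse(out$q_value < q_ase, "ASE",
                      ifelse(out$q_value > q_ase & out$q_value <= q_borderline,
                             "borderline", "none")))
  out
}

#' Per-SNV exact binomial allelic-imbalance p-value
#'
#' Two-sided exact binomial test of the cDNA allele-1 count against an equal
#' allelic ratio.
#'
#' @param cdna_a1,cdna_a2 cDNA allele counts.
#' @return Two-sided p-value (`NA` when coverage is zero).
#' @export
snv_binomial_test <- function(cdna_a1, cdna_a2) {
  n <- cdna_a1 + cdna_a2
  if (n == 0) return(NA_real_)
  stats::binom.test(cdna_a1, n, p = 0.5)$p.value
}

#' Read / write an allelic count table
#'
#' Tab-separated with columns `sample`, `snp_id`, `gene_id`, `gdna_a1`,
#' `gdna_a2`, `cdna_a1`, `cdna_a2`.
#'
#' @param path File path.
#' @return `read_allelic_counts`: the counts data frame.
#' @export
read_allelic_counts <- function(path) {
  d <- utils::read.delim(path)
  need <- c("sample", "snp_id", "gene_id", "gdna_a1", "gdna_a2",
            "cdna_a1", "cdna_a2")
  if (!all(need %in% names(d)))
    stop("allelic count table must have columns ", paste(need, collapse = ", "))
  d
}

#' @rdname read_allelic_counts
#' @param counts Allelic count data frame.
#' @export
write_allelic_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
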