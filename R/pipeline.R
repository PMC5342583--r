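#' Default pipeline configuration
#'
#' All tunable thresholds of the analysis in one flat list: splice-model
#' thresholds, pseudoexon length bounds, junction support minima, WGS filter
#' cutoffs (depth, genotype quality, population frequency), ASE settings and
#' q-value class boundaries. Every value can be overridden by name in
#' [run_pipeline()].
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    length_range = c(50, 300),
    donor_threshold_gt = 70,
    donor_threshold_gc = 85,
    acceptor_threshold = 65,
    gc_donors = TRUE,
    junction_min = c("GT/AG" = 2, "GC/AG" = 2, other = 6),
    inclusion_stat = "downstream",
    min_dp = 7,
    min_gq = 70,
    max_af = 0.001,
    min_cdna_coverage = 10,
    min_het_fraction = 0.2,
    q_ase = 0.05,
    q_borderline = 0.15,
    reduced_penetrance = FALSE,
    rescue_window = 10
  )
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  bad <- setdiff(names(config), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base[names(config)] <- config
  base
}

# cdna_variant from plus-strand VCF-style alleles
genomic_variant_to_cdna <- function(model, pos, ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (model$strand == "-") { ref <- comp[[ref]]; alt <- comp[[alt]] }
  cdna_variant(map_genomic_to_cdna(model, pos), ref, alt)
}

segment_key <- function(ev) paste(ev$segment_start, ev$segment_end, sep = "-")

#' Run the full pseudoexon discovery pipeline on a cohort
#'
#' Per family: (1) allele-specific expression — SNuPE ratios and the
#' gene-level allelic-imbalance test; (2) junction evidence — filtering,
#' paired-novel-junction event detection, and flagging of events also present
#' in control samples; (3) WGS-style variant filtering (dominant-shared mode
#' when the pedigree has two or more genotyped affected members); (4) for each
#' surviving variant, splice-motif pseudoexon prediction with RNA-evidence
#' rescue (a junction event covering the variant can assert the donor when the
#' motif scan fails), transcript and protein consequence, NMD prediction; (5)
#' pedigree co-segregation and evidence aggregation into a tier.
#'
#' @param cohort A `pseudoexon_cohort` from [simulate_cohort()] (or an object
#'   of the same shape built from files).
#' @param config Named list overriding entries of [default_config()].
#' @param out_dir Optional directory: per-stage TSVs and a summary are written
#'   there.
#' @return List of data frames: `reports` (one row per evaluated variant with
#'   evidence flags and tier), `supported` (the tier = supported subset),
#'   `ase`, `events`, `calls`, plus `config`.
#' @export
run_pipeline <- function(cohort, config = NULL, out_dir = NULL) {
  cfg <- merge_config(config)
  model <- cohort$model
  sm <- splice_site_model(donor_threshold_gt = cfg$donor_threshold_gt,
                          donor_threshold_gc = cfg$donor_threshold_gc,
                          acceptor_threshold = cfg$acceptor_threshold,
                          allow_gc = cfg$gc_donors)

  control_keys <- unique(unlist(lapply(cohort$control_junctions, function(jx) {
    ev <- detect_pseudoexon_events(filter_junctions(jx, cfg$junction_min),
                                   model, cfg$length_range,
                                   cfg$inclusion_stat)$events
    segment_key(ev)
  })))

  reports <- list(); ase_rows <- list(); event_rows <- list(); call_rows <- list()
  for (fam in names(cohort$families)) {
    fd <- cohort$families[[fam]]

    ase <- gene_ase_test(fd$counts, min_cdna_coverage = cfg$min_cdna_coverage,
                         min_het_fraction = cfg$min_het_fraction,
                         q_ase = cfg$q_ase, q_borderline = cfg$q_borderline)
    snupe <- snupe_gene_status(vapply(seq_len(nrow(fd$counts)), function(i)
      snupe_ratio(fd$counts$gdna_a1[i], fd$counts$gdna_a2[i],
                  fd$counts$cdna_a1[i], fd$counts$cdna_a2[i]), numeric(1)))
    ase$snupe_R <- snupe$R
    ase$snupe_class <- snupe$class
    ase$family <- fam
    ase_rows[[fam]] <- ase
    ase_class <- if (snupe$class != "uninformative") snupe$class
                 else ase$rnaseq_class[1]

    det <- detect_pseudoexon_events(
      filter_junctions(fd$junctions, cfg$junction_min), model,
      cfg$length_range, cfg$inclusion_stat)
    ev <- det$events
    if (nrow(ev)) {
      ev$also_in_control <- segment_key(ev) %in% control_keys
      ev$family <- fam
      event_rows[[fam]] <- ev
    }
    candidate_ev <- if (nrow(ev)) ev[!ev$also_in_control, , drop = FALSE]
                    else ev

    vars <- annotate_population_af(fd$variants, cohort$af_table)
    genotyped_aff <- intersect(
      fd$pedigree$id[fd$pedigree$affected & fd$pedigree$available],
      unique(fd$genotypes$sample))
    dominant <- length(genotyped_aff) >= 2L
    surv <- filter_variants(vars, fd$genotypes, fd$index_sample,
                            min_dp = cfg$min_dp, min_gq = cfg$min_gq,
                            max_af = cfg$max_af,
                            dominant_shared = dominant,
                            affected_samples = if (dominant) genotyped_aff)

    for (i in seq_len(nrow(surv))) {
      variant <- genomic_variant_to_cdna(model, surv$pos[i], surv$ref[i],
                                         surv$alt[i])
      calls <- predict_pseudoexon(model, variant, sm, cfg$length_range)
      best <- calls[calls$motif_supported, , drop = FALSE]
      call <- if (nrow(best)) best[1, , drop = FALSE] else NULL
      # RNA-evidence rescue: a junction event covering the variant asserts
      # the donor when the motif scan finds nothing
      if (is.null(call) && nrow(candidate_ev)) {
        near <- candidate_ev[
          surv$pos[i] >= candidate_ev$segment_start - cfg$rescue_window &
          surv$pos[i] <= candidate_ev$segment_end + cfg$rescue_window, ,
          drop = FALSE]
        if (nrow(near)) {
          donor_g <- if (model$strand == "+") near$segment_end[1] else
            near$segment_start[1]
          resc <- predict_pseudoexon(model, variant, sm, cfg$length_range,
                                     asserted_donor = donor_g)
          hit <- resc[pmin(resc$pe_start_g, resc$pe_end_g) == near$segment_start[1] &
                      pmax(resc$pe_start_g, resc$pe_end_g) == near$segment_end[1], ,
                      drop = FALSE]
          if (nrow(hit)) call <- hit[1, , drop = FALSE]
        }
      }
      protein <- NULL; in_control <- FALSE
      if (!is.null(call)) {
        lo <- min(call$pe_start_g, call$pe_end_g)
        hi <- max(call$pe_start_g, call$pe_end_g)
        if (nrow(ev)) {
          matching <- ev[ev$segment_start == lo & ev$segment_end == hi, ,
                         drop = FALSE]
          if (nrow(matching)) {
            call$junction_supported <- !all(matching$also_in_control)
            in_control <- any(matching$also_in_control)
          }
        }
        model_alt <- apply_variant_to_model(model, variant)
        sp <- apply_pseudoexon(model_alt, call)
        protein <- classify_protein_effect(sp$wild_mrna, sp$mutant_mrna,
                                           model_alt$cds_start, sp$change)
        call$hgvs_r <- format_hgvs_r(sp$change)
        call$protein <- protein$notation
        call$nmd <- if (!is.na(protein$ptc_codon))
          nmd_flag(protein, model, sp$change) else FALSE
        call$family <- fam
        call_rows[[length(call_rows) + 1L]] <- call
      }
      ped_gt <- stats::setNames(
        fd$genotypes$gt[fd$genotypes$variant_id == surv$variant_id[i]],
        fd$genotypes$sample[fd$genotypes$variant_id == surv$variant_id[i]])
      coseg <- cosegregation_check(fd$pedigree, ped_gt,
                                   reduced_penetrance = cfg$reduced_penetrance)
      rep <- aggregate_evidence(call, protein, coseg,
                                population_af = surv$population_af[i],
                                ase_class = ase_class,
                                also_in_control = in_control)
      row <- evidence_report_row(rep, family = fam)
      row$variant_id <- surv$variant_id[i]
      reports[[length(reports) + 1L]] <- row
    }
  }
  out <- list(
    reports = if (length(reports)) do.call(rbind, reports) else NULL,
    ase = do.call(rbind, ase_rows),
    events = if (length(event_rows)) do.call(rbind, event_rows) else NULL,
    calls = if (length(call_rows)) do.call(rbind, call_rows) else NULL,
    config = cfg)
  out$supported <- if (!is.null(out$reports))
    out$reports[out$reports$tier == "supported", , drop = FALSE] else NULL
  rownames(out$reports) <- rownames(out$supported) <- NULL
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, name) if (!is.null(d))
    utils::write.table(d, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(result$reports, "evidence_reports.tsv")
  wr(result$ase, "ase.tsv")
  wr(result$events, "junction_events.tsv")
  wr(result$calls, "pseudoexon_calls.tsv")
  summary <- c(
    sprintf("families analyzed: %d", length(unique(result$ase$family))),
    sprintf("variants evaluated: %d",
            if (is.null(result$reports)) 0L else nrow(result$reports)),
    sprintf("tier=supported: %d",
            if (is.null(result$supported)) 0L else nrow(result$supported)))
  writeLines(summary, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' Write a consequence report table
#'
#' One row per pseudoexon call with its RNA and protein consequence, as a TSV.
#'
#' @param calls The `calls` data frame from [run_pipeline()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_consequence_report <- function(calls, path) {
  cols <- c("family", "gene_id", "hgvs_c", "hgvs_r", "length", "protein", "nmd")
  utils::write.table(calls[, intersect(cols, names(calls)), drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
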