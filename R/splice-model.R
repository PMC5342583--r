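#' Position-weight splice-site model
#'
#' Transparent per-position weight model of the canonical splice consensus:
#' donor `AG/gtragt` (2 exonic + 6 intronic positions) and acceptor
#' `poly(y)nyag/G` (14 intronic + 1 exonic positions, with a 10-base
#' polypyrimidine tract). At each position the consensus base carries weight
#' 0.79 and the remaining mass 0.21 is spread over the other bases; degenerate
#' IUPAC symbols (r, y, n) share 0.79 equally among their member bases (n is
#' therefore uniform). Each position's weights sum to 1.
#'
#' Scores are Shapiro-Senapathy-style min-max normalized percentages: 100 iff
#' every position carries its maximal-weight base, 0 iff every position carries
#' a minimal-weight base.
#'
#' @param donor_weights,acceptor_weights Optional weight matrices (rows =
#'   window positions, columns A/C/G/T, rows summing to 1); defaults built from
#'   the consensus above.
#' @param donor_threshold_gt Percent score a GT-class donor must reach
#'   (default 70, full 8-position window).
#' @param donor_threshold_gc Percent score a GC-class donor must reach
#'   (default 85, computed over the 6 non-dinucleotide positions since the +2
#'   base is fixed by the class).
#' @param acceptor_threshold Percent score an acceptor must reach (default 65).
#' @param allow_gc If FALSE, GC-class donors are not recognized at all (the
#'   behavior of classic GT-only splice predictors); gains at `g·c`
#'   dinucleotides are then reported only as logged near-misses.
#' @return An object of class `splice_site_model`.
#' @export
splice_site_model <- function(donor_weights = NULL, acceptor_weights = NULL,
                              donor_threshold_gt = 70, donor_threshold_gc = 85,
                              acceptor_threshold = 65, allow_gc = TRUE) {
  if (is.null(donor_weights))
    donor_weights <- consensus_weights(c("A", "G", "g", "t", "r", "a", "g", "t"))
  if (is.null(acceptor_weights))
    acceptor_weights <- consensus_weights(c(rep("y", 10), "n", "y", "a", "g", "G"))
  for (w in list(donor_weights, acceptor_weights)) {
    stopifnot(identical(colnames(w), c("A", "C", "G", "T")))
    if (any(abs(rowSums(w) - 1) > 1e-9)) stop("weights per position must sum to 1")
  }
  stopifnot(donor_threshold_gt >= 0, donor_threshold_gt <= 100,
            donor_threshold_gc >= 0, donor_threshold_gc <= 100,
            acceptor_threshold >= 0, acceptor_threshold <= 100)
  structure(list(donor_weights = donor_weights,
                 acceptor_weights = acceptor_weights,
                 donor_threshold_gt = donor_threshold_gt,
                 donor_threshold_gc = donor_threshold_gc,
                 acceptor_threshold = acceptor_threshold,
                 allow_gc = isTRUE(allow_gc)),
            class = "splice_site_model")
}

# weight rows from IUPAC consensus symbols; members of the symbol share 0.79,
# non-members share the remaining 0.21 (n: uniform 0.25)
consensus_weights <- function(symbols) {
  members <- list(a = "A", c = "C", g = "G", t = "T",
                  r = c("A", "G"), y = c("C", "T"), n = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  w <- t(vapply(tolower(symbols), function(s) {
    mem <- members[[s]]
    if (is.null(mem)) stop("unsupported consensus symbol '", s, "'")
    row <- stats::setNames(numeric(4), bases)
    row[mem] <- 0.79 / length(mem)
    if (length(mem) < 4L) row[setdiff(bases, mem)] <- 0.21 / (4 - length(mem))
    else row[] <- 0.25
    row
  }, numeric(4)))
  rownames(w) <- NULL
  w
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("<splice_site_model> donor %d nt (GT >= %g, GC >= %g), acceptor %d nt (>= %g)\n",
              nrow(x$donor_weights), x$donor_threshold_gt, x$donor_threshold_gc,
              nrow(x$acceptor_weights), x$acceptor_threshold))
  invisible(x)
}

#' Read / write a splice-site weight table
#'
#' TSV with columns `position`, `A`, `C`, `G`, `T`; one row per window
#' position.
#'
#' @param path File path.
#' @return `read_weight_table`: a weight matrix usable in
#'   [splice_site_model()].
#' @export
read_weight_table <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(d))) stop("weight table must have columns ",
                                     paste(need, collapse = ", "))
  d <- d[order(d$position), ]
  as.matrix(d[, c("A", "C", "G", "T")])
}

#' @rdname read_weight_table
#' @param weights Weight matrix (rows = positions, columns A/C/G/T).
#' @export
write_weight_table <- function(weights, path) {
  d <- data.frame(position = seq_len(nrow(weights)), weights,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# raw min-max normalized percent over a subset of window positions
pwm_score <- function(weights, window, positions = seq_len(nrow(weights))) {
  bases <- strsplit(toupper(window), "")[[1]]
  idx <- match(bases[positions], c("A", "C", "G", "T"))
  w <- weights[positions, , drop = FALSE]
  got <- sum(w[cbind(seq_along(positions), idx)])
  lo <- sum(apply(w, 1, min)); hi <- sum(apply(w, 1, max))
  100 * (got - lo) / (hi - lo)
}

#' Score a splice-site window
#'
#' @param window Window sequence: 8 nt for donors (2 exonic + 6 intronic), 15
#'   nt for acceptors (14 intronic + 1 exonic), ACGT only (case-insensitive).
#' @param kind `"donor"` or `"acceptor"`.
#' @param model A [splice_site_model].
#' @return Percent score in \[0, 100\].
#' @export
#' @examples
#' score_site("AGgtaagt", "donor", splice_site_model())      # 100
#' score_site("tttttttttttcagG", "acceptor", splice_site_model())
score_site <- function(window, kind = c("donor", "acceptor"),
                       model = splice_site_model()) {
  kind <- match.arg(kind)
  stopifnot(is.character(window), length(window) == 1L)
  weights <- if (kind == "donor") model$donor_weights else model$acceptor_weights
  if (nchar(window) != nrow(weights))
    stop(kind, " window must be ", nrow(weights), " nt, got ", nchar(window))
  if (grepl("[^ACGTacgt]", window))
    stop("window contains non-ACGT characters: '", window, "'")
  pwm_score(weights, window)
}

# donor score under the class-appropriate scheme: GT = full window vs the GT
# threshold; GC = the 6 non-dinucleotide positions vs the GC threshold
donor_class_score <- function(window, class, model) {
  if (class == "GT") pwm_score(model$donor_weights, window)
  else pwm_score(model$donor_weights, window, positions = c(1, 2, 5, 6, 7, 8))
}

donor_class_threshold <- function(class, model) {
  if (class == "GT") model$donor_threshold_gt else model$donor_threshold_gc
}

#' Scan a substitution for gained splice-donor sites
#'
#' Evaluates every donor window overlapping the variant (at most 8 placements)
#' under the reference and alternate alleles. A gain is reported where the
#' alternate window passes its class-appropriate threshold (class read from the
#' +1/+2 intronic dinucleotide: GT or GC) while the reference window is not a
#' passing donor of that class. GC-class near-misses (right dinucleotide,
#' sub-threshold context) are reported via `message()` so that RNA-evidence
#' rescue can be considered.
#'
#' @param model A [gene_model].
#' @param variant A [cdna_variant] (intronic or exonic substitution).
#' @param splice_model A [splice_site_model].
#' @return Data frame of gains ordered by `alt_score` descending, with columns
#'   `pe_end_g` (genomic position of the last base retained 5' of the new
#'   donor), `donor_class`, `ref_score`, `alt_score`.
#' @export
donor_gain_scan <- function(model, variant, splice_model = splice_site_model()) {
  stopifnot(inherits(variant, "cdna_variant"))
  g_var <- map_cdna_to_genomic(model, variant$position)
  ref_base <- genomic_seq(model, g_var, g_var)
  if (toupper(ref_base) != variant$ref)
    stop("variant ref allele '", variant$ref, "' does not match genome ('",
         toupper(ref_base), "') at mapped position ", g_var)
  sgn <- strand_sign(model)
  span <- gene_span(model)
  gains <- list()
  for (k in 1:8) {
    g1 <- g_var - (k - 1L) * sgn                 # window position 1 (tx sense)
    g8 <- g1 + 7L * sgn
    if (min(g1, g8) < span[1] || max(g1, g8) > span[2]) next
    refwin <- genomic_seq(model, min(g1, g8), max(g1, g8))
    altwin <- refwin
    substr(altwin, k, k) <- variant$alt
    dinuc_alt <- toupper(substr(altwin, 3, 4))
    if (!dinuc_alt %in% c("GT", "GC")) next
    class <- dinuc_alt
    if (class == "GC" && !splice_model$allow_gc) {
      message(sprintf(
        "GC dinucleotide gain at window starting %d ignored (GT-only model)",
        g1))
      next
    }
    thr <- donor_class_threshold(class, splice_model)
    alt_score <- donor_class_score(altwin, class, splice_model)
    ref_is_donor <- toupper(substr(refwin, 3, 4)) == class &&
      donor_class_score(refwin, class, splice_model) >= thr
    ref_score <- donor_class_score(refwin, class, splice_model)
    if (alt_score >= thr && !ref_is_donor) {
      gains[[length(gains) + 1L]] <- data.frame(
        pe_end_g = g1 + 1L * sgn, donor_class = class,
        ref_score = ref_score, alt_score = alt_score)
    } else if (class == "GC" && alt_score < thr && alt_score >= thr - 25) {
      message(sprintf(
        "near-miss GC donor at window starting %d (alt score %.1f < %g)",
        g1, alt_score, thr))
    }
  }
  out <- if (length(gains)) do.call(rbind, gains) else
    data.frame(pe_end_g = integer(0), donor_class = character(0),
               ref_score = numeric(0), alt_score = numeric(0))
  out[order(-out$alt_score), , drop = FALSE]
}

#' Predict pseudoexon boundaries from a donor-gain variant
#'
#' For each gained donor (from [donor_gain_scan()], or one asserted externally
#' from RNA junction evidence), scans upstream within the same intron for
#' acceptor positions — an obligatory `ag` dinucleotide immediately 5' of the
#' candidate first pseudoexon base — whose implied pseudoexon length falls in
#' `length_range`. One call is emitted per (donor, acceptor) pair, ranked by
#' acceptor score, best first. `motif_supported` is TRUE when both the donor
#' and the acceptor pass their thresholds.
#'
#' @param model A [gene_model].
#' @param variant A [cdna_variant], the candidate causal substitution.
#' @param splice_model A [splice_site_model].
#' @param length_range Allowed pseudoexon lengths in bp (default 50-300, the
#'   usual working definition of a pseudoexon).
#' @param asserted_donor Optional genomic position of the last pseudoexon base
#'   (transcript sense) asserted from junction evidence when the motif scan
#'   fails; used for RNA-evidence rescue.
#' @return Data frame of pseudoexon calls (possibly empty): genomic and c.
#'   boundaries, length, donor class and scores, `motif_supported`,
#'   `junction_supported` (initialized FALSE; set by the pipeline when a
#'   junction event corroborates the call).
#' @export
predict_pseudoexon <- function(model, variant,
                               splice_model = splice_site_model(),
                               length_range = c(50, 300),
                               asserted_donor = NULL) {
  gains <- donor_gain_scan(model, variant, splice_model)
  donor_passed <- rep(TRUE, nrow(gains))
  if (!is.null(asserted_donor)) {
    gains <- rbind(gains, data.frame(pe_end_g = as.integer(asserted_donor),
                                     donor_class = "asserted",
                                     ref_score = NA_real_, alt_score = NA_real_))
    donor_passed <- c(donor_passed, FALSE)
  }
  if (nrow(gains) == 0L) return(empty_pseudoexon_calls())
  sgn <- strand_sign(model)
  intr <- introns_tx_order(model)
  calls <- list()
  for (j in seq_len(nrow(gains))) {
    pe_end_g <- gains$pe_end_g[j]
    # locate the intron holding the pseudoexon 3' end
    ii <- which(pe_end_g >= pmin(intr$five, intr$three) &
                pe_end_g <= pmax(intr$five, intr$three))
    if (length(ii) != 1L) next                 # donor end not intronic
    five_g <- intr$five[ii]                    # transcript-5' first intronic base
    for (L in seq(length_range[1], length_range[2])) {
      pe_start_g <- pe_end_g - (L - 1L) * sgn
      # acceptor window: 14 intronic bases 5' of pe_start + pe_start itself
      win_start_g <- pe_start_g - 14L * sgn
      if ((win_start_g - five_g) * sgn < 0) next      # window leaves the intron
      win <- genomic_seq(model, min(win_start_g, pe_start_g),
                         max(win_start_g, pe_start_g))
      if (toupper(substr(win, 13, 14)) != "AG") next  # obligatory ag at -2/-1
      acc_score <- pwm_score(splice_model$acceptor_weights, win)
      calls[[length(calls) + 1L]] <- data.frame(
        gene_id = model$gene_id,
        hgvs_c = format_hgvs_c(variant),
        pe_start_g = pe_start_g, pe_end_g = pe_end_g,
        pe_start_c = format_cdna_pos(map_genomic_to_cdna(model, pe_start_g)),
        pe_end_c = format_cdna_pos(map_genomic_to_cdna(model, pe_end_g)),
        length = L,
        donor_class = gains$donor_class[j],
        donor_score = gains$alt_score[j],
        acceptor_score = acc_score,
        motif_supported = donor_passed[j] &&
          acc_score >= splice_model$acceptor_threshold,
        junction_supported = FALSE)
    }
  }
  if (length(calls) == 0L) return(empty_pseudoexon_calls())
  out <- do.call(rbind, calls)
  out <- out[order(-out$acceptor_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pseudoexon_calls <- function() {
  data.frame(gene_id = character(0), hgvs_c = character(0),
             pe_start_g = integer(0), pe_end_g = integer(0),
             pe_start_c = character(0), pe_end_c = character(0),
             length = integer(0), donor_class = character(0),
             donor_score = numeric(0), acceptor_score = numeric(0),
             motif_supported = logical(0), junction_supported = logical(0))
}
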