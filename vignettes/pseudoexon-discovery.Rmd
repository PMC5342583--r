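---
title: "Discovering pseudoexons from deep-intronic variants: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering pseudoexons from deep-intronic variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A pseudoexon is an intronic segment — typically 50–300 bp — flanked by latent
splice sites that the spliceosome normally ignores. A single deep-intronic
substitution can complete a viable splice donor (`/gt` or, rarely, `/gc`) next
to a pre-existing cryptic acceptor, so that the segment is spliced into the
mature mRNA. In a disease gene such as *APC*, the inserted sequence usually
truncates the protein (a direct stop or a frameshift), the transcript is
degraded by nonsense-mediated decay (NMD), and the mutation manifests as
allele-specific expression (ASE) while remaining invisible to exon-focused
screens.

`pseudoexonr` implements the full analysis chain for this situation: HGVS-style
coordinate arithmetic on a gene model, splice-site scoring and pseudoexon
boundary prediction from candidate variants, RNA splice-junction evidence,
transcript/protein consequence prediction, ASE quantification, WGS-style
variant filtering, pedigree co-segregation, and a deterministic evidence tier.
Because studies of this kind rarely deposit raw patient data, the package also
ships seeded generators that produce complete synthetic cohorts with ground
truth, and the test suite validates the pipeline against that truth.

## Coordinate model

Genomic coordinates are 1-based inclusive everywhere (HGVS/VCF convention); BED
I/O converts to 0-based half-open at the file boundary only. A `gene_model`
stores exons in genomic order, the strand, and the transcript position of the
translation start — c.1 is a model parameter, not transcript base 1, mirroring
genes like *APC* whose start codon sits in exon 2. All c./r./p. arithmetic is
performed in transcript orientation, so minus-strand genes are fully
supported.

Intronic positions use anchor/offset notation (`c.1408+731`, `c.646-1806`).
Mapping a genomic position back to a cDNA position must choose an anchor: we
anchor to the nearer exon in transcript orientation — the 5' half of an intron
anchors to the upstream exon end (`+n`), the 3' half to the downstream exon
start (`-n`) — and an exactly equidistant base (possible only in odd-length
introns) anchors upstream. This matches the usual reading of deep-intronic
positions such as `+731` (early in a long intron) and `-1806` (late in one),
and makes the genomic↔cDNA maps mutually inverse across the whole gene span,
which a property test verifies position by position.

For r. insertion descriptions both inserted boundaries share the 5' boundary's
anchoring frame (`r.645_646ins646-1933_646-1807`), so a pseudoexon that
straddles the intron midpoint still gets a single consistent description.

## Splice-site model

Donor sites are scored over an 8-nt window (2 exonic + 6 intronic bases,
consensus `AG/gtragt`) and acceptors over a 15-nt window (a 10-base
polypyrimidine tract, then `n`, `y`, the invariant `ag`, and the first exonic
base, consensus `poly(y)nyag/G`). The weight table is transparent by design: at
each position the consensus base carries weight 0.79 and the remaining 0.21 is
spread over the other bases; degenerate symbols (`r`, `y`, `n`) share the 0.79
equally among member bases, so every column still sums to 1. Scores are
min–max-normalized to percent (Shapiro–Senapathy style): 100 means every
position carries a maximal-weight base. This replaces the opaque
neural-network splice predictors often used in the field with a scheme that
can be hand-summed in a test.

Defaults (all configurable): GT donors must reach 70; GC donors 85, scored
over the six non-dinucleotide positions since `+1/+2` is fixed by the class —
GC donors are a rare legitimate class, so they must show stronger context;
acceptors must reach 65 and always require the invariant `ag` at −2/−1.
`donor_gain_scan()` slides all eight windows over a substitution and reports
placements where the alternate allele passes its class threshold while the
reference allele is not a passing donor of that class.

Two geometries deserve note. A `g·c → g·t` substitution two bases past a
latent exon end is the classic activating event. But an exonic-side
substitution that completes `AG/` in front of an existing `g·c` dinucleotide
creates a GC-class donor that GT-only predictors cannot see; for this case the
pipeline provides RNA-evidence rescue — a paired-novel-junction event covering
the variant may assert the donor position, and the resulting call is
`junction_supported` rather than `motif_supported`. This reproduces the
situation where motif predictors fail and RNA sequencing carries the call.

## Junction evidence

Junction tables come in STAR `SJ.out.tab` (read 1-based inclusive) or BED6
(converted at the boundary). Filtering uses per-motif-class minimum unique
read counts, defaulting to 2 for GT/AG and GC/AG and 6 for non-canonical
junctions, mirroring sensitive splice-junction discovery settings. A
pseudoexon event requires a *pair* of unannotated junctions inside one
annotated intron — one sharing the upstream exon's donor, one sharing the
downstream exon's acceptor — with a fully intronic internal segment of 50–300
bp. Single novel junctions are reported as incomplete candidates, never as
events.

Inclusion depth is `inclusion_reads / (inclusion_reads + canonical_reads)`
with the transcript-downstream novel junction supplying `inclusion_reads` (the
pair minimum is available via `inclusion_stat = "min"`). The definition is
explicit here because junction depth figures in published work are typically
shown without a formal ratio. Events whose segment also appears in control
samples — such as a constitutive in-frame insertion present in healthy
reference RNA — are annotated `also_in_control` and excluded from causal
pairing.

## Transcript and protein consequence

`apply_pseudoexon()` splices the genomic segment between its flanking exons
and records the r. description. Classification compares the translated mutant
against the wild type residue by residue: an insertion divisible by 3 that
introduces no stop is an in-frame insertion; if the first changed codon is
itself a stop the call is nonsense (this subsumes the codon-aligned
stop-leading insertion, where translation terminates before frame can matter);
otherwise a premature stop yields a frameshift, written `fs*N` with the stop
counted from the first changed residue as position 1. The first *changed*
residue rule matters: a hybrid codon at the insertion point that still encodes
its wild-type amino acid is skipped, so an 83-bp insertion after c.1408 names
codon 471, not 470. The standard genetic code is used; translation continues
past the wild-type stop position into downstream sequence for frameshifts, and
a frameshift that never reaches a stop is reported `fs*?`.

NMD is predicted by the standard junction rule with the 55-nt variant of the
50–55-nt boundary: a premature stop whose 3'-most base lies at least 55 nt
upstream of the final exon–exon junction of the *mutant* transcript (the
pseudoexon counts as an internal exon) is flagged for decay. The tests pin the
boundary exactly (distance 55 decays, 52 escapes).

## Allele-specific expression

The SNuPE ratio is `R = (cDNA a1/a2) / (gDNA a1/a2)`; genomic DNA serves as
the heterozygous 50:50 calibrator. Bands: unequivocal ASE at `R <= 0.6` or
`R >= 1/0.6` (a 40% reduction of one allele; 1/0.6 prints as 1.67), putative
at `0.6 < R < 0.8` or `1.25 < R < 1/0.6`, and no ASE on the closed interval
`[0.8, 1.25]`. Implementing the upper thresholds as exact reciprocals keeps
the classification invariant under allele relabeling (`R -> 1/R`), which the
printed two-decimal value 1.67 would break by 0.003. Gene-level SNuPE status
takes the SNP with the largest deviation `max(R, 1/R)`. Per-SNP normalization
factors (calibrated on mutation-negative controls) can divide the raw ratio;
the default is 1.

The gene-level RNA test is a deliberately transparent substitute for
meta-analytic ASE callers (it is *not* MBASED): per heterozygous SNV with cDNA
coverage ≥ 10, evidence is aligned to the sample-major allele and converted to
`z = qnorm(1 - p)` using the mid-p one-sided binomial tail; the per-gene sum of
these z-scores is then referred to its exact null distribution under balanced
binomial sampling, computed once per depth profile by FFT convolution of the
per-SNV discrete z distributions. Aligning to the major allele folds each z to
the non-negative half-line, so naive doubling of a Stouffer p-value is
anti-conservative; referring the sum to the folded *exact* null is the correct
two-sided adjustment and keeps the test calibrated at realistic coverages
(≥ 30×; at very low depths the discreteness of the binomial makes any exact
test conservative). Genes need at least two informative SNVs, otherwise they
are reported uninformative. Across genes, Benjamini–Hochberg q-values define
the classes: ASE (q < 0.05), borderline (0.05 < q ≤ 0.15), none otherwise.

## Variant filtering and evidence aggregation

WGS-style filtering keeps variants with read depth ≥ 7 and genotype quality
≥ 70 in every analyzed sample, population minor allele frequency < 0.001
(unknown frequency passes and is logged; population lookups are served by a
local frequency table rather than live databases), and a heterozygous index
genotype; dominant-shared mode additionally requires the heterozygote in all
affected genotyped samples. All cutoffs sit at the stated boundaries: DP 6
fails, DP 7 passes; GQ 69 fails; MAF exactly 0.001 is removed.

Co-segregation is `complete` when every genotyped affected individual carries
the variant and every genotyped unaffected individual does not (the unaffected
check can be relaxed under a reduced-penetrance setting), `not_assessable`
with fewer than two genotyped affected members (sporadic cases), and
`incomplete` otherwise.

The evidence tier formalizes a checklist that published analyses apply
narratively: `supported` requires a truncating consequence AND absence from
the population AND co-segregation in {complete, not_assessable} AND pseudoexon
support from motif or junction evidence; calls absent or seen also in controls
are `unsupported`; everything else is `uncertain`. ASE consistency is reported
but advisory — a genuine pseudoexon allele may miss statistical significance
in small RNA data, so it must not gate the tier. The aggregation is monotone:
turning any single evidence flag off never raises the tier (a unit test
enumerates the single-flag perturbations).

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` reproduces the structure of a mutation-negative polyposis
study: 54 families, three of them carriers — a sporadic family with a 127-bp
stop-leading pseudoexon, a dominant four-affected family with a frameshifting
83-bp pseudoexon, and a sporadic family with a GC-donor 83-bp pseudoexon whose
variant lies inside the pseudoexon. The shared reference genome carries all
latent cryptic sites (as a real population reference would); each carrier's
single substitution activates one. Every sample additionally shows a
constitutive 54-bp in-frame inclusion that is also present in the three
control samples, exercising the also-in-control exclusion. Per family the
generator emits background variants that each trip exactly one WGS filter
(common, low-DP, low-GQ, homozygous) plus one rare passing benign variant that
is verified to create no donor gain.

Generator defaults are fixed study conditions, not tuning knobs: five exons,
introns of 1.5–2.5 kb (long enough for deep-intronic planting with the
acceptor window and guard margins), junction depth 60 with carrier inclusion
ψ = 0.3 (heterozygous inclusion attenuated by NMD), allelic counts at depth
500 with carrier ratio R = 0.6 (the unequivocal boundary), four SNPs per
sample. Background intronic sequence is uniform over ACGT; accidental
competing acceptors that pass thresholds within the allowed length range are
rejected and resampled (their `ag` dinucleotide is broken), guaranteeing a
unique planted truth, and the generator re-verifies that the planted call is
the unique motif-supported prediction before returning.

What the generator does not emulate: sequencing reads and their error
structure (junction counts are drawn directly as binomials), alignment
artifacts, overdispersion of allelic counts (an option exists for the null
only in concept — counts are pure binomial), expression idiosyncrasies of
transformed cell lines, multi-transcript genes, and genomic rearrangements.
Passing tests therefore demonstrate correctness of the analysis logic under
idealized counts, not robustness to alignment or library artifacts.

## Numerical and interface choices

* Problem sizes in the checks: 50 seeded genes for boundary recovery, 100
  random pseudoexons for the consequence oracle, 1000 null genes at depth 50
  for calibration, 200 seeds at depth 500 for ratio recovery, and one
  54-family cohort end to end. These run in a few minutes on one CPU.
* Degenerate inputs: zero allelic denominators give `NA` (uninformative), not
  errors; an empty junction file warns and returns an empty table; a variant
  whose reference allele disagrees with the genome is a hard consistency
  error.
* Ties: competing acceptor calls are ranked by acceptor score; the intron
  anchoring tie goes upstream; the no-ASE band is closed on both ends (the
  strict inequalities of the putative bands force this).
* The command-line entry point (`inst/scripts/pseudoexonr.R`) is a thin
  wrapper over `simulate_cohort()`/`run_pipeline()`; the R API is the primary
  interface, and `scripts/acceptance.R` reproduces the headline numbers.

## Known limitations

Only single-nucleotide substitutions are handled (no indels or delins in the
HGVS grammar); positions 5' of c.1 have no cDNA coordinate, so 5'-UTR introns
cannot host planted variants; branch-point strength and exonic splicing
enhancers are not modeled, so the motif model will miss pseudoexons activated
through those mechanisms (the junction-rescue path is the intended fallback);
and the gene-level ASE test assumes independent SNVs within a gene, which real
haplotype structure violates — with few SNPs per gene the practical effect is
small, but it is an assumption, not a theorem.
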