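---
title: "Methods: long-read proteogenomic isoform characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read proteogenomic isoform characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protiso)
```

# The procedure and its assumptions

`protiso` implements a long-read proteogenomics workflow: long-read
transcript models define a sample-specific protein search space, and peptide
identifications from an external search engine are interpreted against that
space. Three assumptions underlie the design. First, observed exon chains are
taken at face value — the package classifies and translates the models it is
given and does not correct alignment or clustering artifacts. Second, the
transcript-to-protein step assumes one AUG-initiated reading frame per
transcript is biologically operative; non-AUG starts, selenocysteine
recoding and ribosomal frameshifting are out of scope. Third, transcript
abundance is treated as a usable (moderately correlated) proxy for protein
abundance, which is exactly the assumption the nomination tier makes
explicit rather than hides.

Peptides arrive pre-scored (sequence, q-value, PSM count). Spectral
processing, target-decoy FDR estimation and protein-level inference are the
search engine's job; the package deliberately works at the peptide level
because protein inference adds ambiguity the isoform question does not need.

# Coordinates, junctions, and classification

All intervals are held 0-based half-open; GTF input/output converts to and
from the 1-based inclusive convention at the boundary, so interval arithmetic
(`length = end - start`) never needs special cases. A junction is identified
by `(chrom, strand, lower, upper)`; the donor/acceptor roles are derived
strand-awarely (on the minus strand the donor is the upper bound). Junction
chains are canonical strings of genomic-ascending intron bounds, which makes
chain comparison an exact string match.

Transcript classification follows a strict decision order for multi-exonic
models: (1) any donor or acceptor absent from the catalog's per-(chrom,
strand) site sets makes the transcript NNC, (2) an exact chain match to a
reference transcript makes it FSM, (3) otherwise NIC. Consequences worth
knowing: a retained intron removes a junction but introduces no new site, so
it classifies NIC; an exon skip likewise. Mono-exonic models are FSM only
when fully contained within a mono-exonic reference transcript of the same
gene, and OTHER otherwise — the finer mono-exonic subcategories (ISM, genic,
antisense) are collapsed into OTHER, and OTHER-class transcripts never reach
the protein database. Gene assignment uses the largest same-strand exonic
overlap, with ties broken toward the gene sharing more splice sites; this
makes the pipeline robust to transcript GTFs that carry no usable gene ids.

The CPM denominator is the total full-length read count over the loaded
transcript models, which makes CPM self-contained and reproducible from the
counts file alone (the alternative — raw instrument reads — would leave CPM
dependent on information the pipeline never sees).

# ORF selection

Candidate ORFs run from each AUG to the first in-frame stop (or the
transcript end when none is reached; codons containing non-ACGT bases
truncate the candidate rather than invent amino acids). The 50-nt minimum
counts start through stop codon inclusive. Candidates are ranked by a strict
lexicographic rule:

1. start codon at an annotated reference start position,
2. fewer upstream AUGs skipped,
3. higher coding potential,
4. longer ORF,
5. smaller start position.

The field's practice combines these criteria without publishing the exact
rule; the lexicographic order was chosen because it is deterministic,
auditable (the winning tier is recorded per transcript), and encodes the
clear intent of preferring annotated starts. Stop-less candidates are kept at
this stage so the later truncation filter's removal count is observable.

The coding-potential score is a deliberately simple logistic stand-in for a
trained model such as CPAT: `plogis(-4 + 3·coverage + 2.5·min(codons/100, 1)
+ 2·composition)`, where coverage is ORF length over transcript length and
composition is a Fickett-style codon-position asymmetry in [0, 1). It is
monotone in coverage, needs no training data, and sits third in the ranking
where it only breaks ties among unannotated starts with equal AUG skips. The
scorer is pluggable: an external score table keyed by (transcript, start)
replaces it entry-wise, so a trained model can be dropped in without touching
the selection rule.

# SQANTI-Protein reconstruction

The protein-level classes are decided on three elements: the N-terminus
(start codon genomic position against the gene's annotated start set), the
CDS-internal splice chain (every CDS junction site against the gene's
annotated CDS site sets; the full chain against annotated CDS chains), and
the C-terminus (stop codon position against annotated stops). pFSM requires
start + CDS chain + stop to match one reference coding transcript; any
novel element gives pNNC; otherwise pNIC. The published description names
the categories and elements but not the full decision table; this
three-element evaluation is the package's concrete reconstruction and is
evaluated on the CDS only — UTR-region novelty does not change the protein
class, because the classification is about the protein sequence's relation
to reference proteins. Annotated stop sets are derived from reference CDS
ends. Every pNNC call records which element was novel, so calls are
auditable one by one.

# Filtering and the hybrid database

Removals are applied in order with one recorded reason per isoform:
truncation (no stop codon), class (not pFSM/pNIC/pNNC), then NMD. The NMD
rule — more than two junctions after the stop codon — is scoped to pNNC
isoforms only, following the source description's sentence order; pFSM and
pNIC isoforms with long 3' UTR junction chains are annotated biology, not
suspects. Identical proteins within a gene are grouped with summed CPM; the
representative accession is the highest-CPM member (ties to the smaller
accession suffix), a choice the field leaves open.

A gene is "high-confidence" when its aggregated abundance is at least 3 CPM
and its mean annotated transcript length lies in 1–4 kb, both bounds
inclusive ("at least three", and "between" read inclusively). The mean
length averages the spliced lengths of **all** annotated transcripts of the
gene, coding and non-coding alike — the most literal reading of "average
reference transcript length"; restricting to coding transcripts would shift
genes near the window edges, which is why the choice is centralized in one
catalog field and flagged for sensitivity testing. High-confidence genes
contribute their PacBio entries, every other catalog gene its grouped
reference entries, contaminants pass through verbatim. One edge the source
leaves open: a high-confidence gene whose predicted proteins were all
filtered out would otherwise vanish from the database; such genes fall back
to reference entries so the gene-source map stays a total partition.

# Peptide evidence

Peptide-to-entry matching requires digest-legal termini (fully tryptic,
cleavage after K/R except before P, up to two missed cleavages, 7–50 aa) —
the same rule that produced and scored the peptides — rather than free
substring matching (available as an option). Peptides hitting more than one
gene are excluded from isoform evidence and from PSM sums. Isoleucine and
leucine are distinct by default; an I/L-equivalence switch exists for the
novelty check, where collapsing them is the conservative choice. Novel
peptides must pass the strict tier (q strictly below 0.001), map to the
sample database, and be absent from both reference digests; novelty is
therefore sound by construction and every call can be re-verified by string
lookup. Event annotation projects the peptide's genomic footprint through
the CDS map and tests, in order: unannotated sequence contiguous with
annotated exons (intron retention) or not (novel exon), junctions with
unannotated sites (novel acceptor/donor), and reading-frame disagreement
with every covering reference CDS (frameshift).

The RNA–protein relation is fit by ordinary least squares on
log10(CPM + 1) versus log10(PSM + 1) — both distributions are heavy-tailed,
and the pseudocount of 1 keeps zero-PSM genes finite (the transform is a
package choice; the source states only the quantities).

Report percentages round to the nearest integer, half away from zero, which
is consistent with every checkable published percentage.

# What the synthetic generator emulates — and what it does not

The generator builds genes with seven codon-aligned exons (a G-free 5' UTR
so the annotated AUG is the first AUG, codon-safe designated introns so
retention and novel-exon events preserve frame), annotates skip isoforms and
a UTR-only duplicate-protein isoform, and then plants novelty events with
known labels: annotated-skip combinations (NIC), retention of the codon-safe
intron (NIC), 9-nt (frame-preserving) or 8-nt (frame-shifting)
acceptor/donor shifts (NNC), and a 36-nt inserted exon (NNC). Abundances use
the study-scale library of 3,608,972 full-length reads with planted CPM
levels kept clear of the 1, 3 and 25 CPM decision boundaries; designated
genes sit below 3 CPM total or below 1 CPM per transcript to exercise the
filters. Peptides are drawn from the entry digests under a per-gene scenario
plan, novel peptides only from event footprints verified absent from both
reference digests, and PSM counts follow a log-log abundance model
(slope 0.8, noise 0.58 in `simulate_expression_pairs()`, giving an expected
coefficient of determination near 0.66).

Passing on this generator demonstrates that every decision rule — class
boundaries, filter order, label formats, tier thresholds — is implemented
exactly, because each label is recoverable only if the whole chain is right.
It does **not** demonstrate robustness to what real data adds: alignment
noise and truncated reads, non-canonical splice sites, paralog crosstalk in
gene assignment, chimeric models, search-engine score miscalibration, or
abundance distributions with the long tails of a real transcriptome.
Boundary-straddling inputs are tested separately with handcrafted cases
rather than generated randomness, so a near-threshold real-world value still
deserves manual scrutiny.

All generator randomness flows from a single seed through a scoped RNG
(caller state is restored), so identical configurations produce byte-
identical bundles.

# Numerical and degenerate-input choices

* Ties in major-isoform calls: larger full-length count, then smaller PB
  accession numeric suffix. APPRIS ties: lowest principal rank, then
  transcript id.
* A zero total read count is a hard error ("empty dataset"), not a silent
  NaN; a gene list with no detected members is an empty table, not an error.
* Fewer than three genes shared between the RNA and protein tables refuses
  the correlation; a constant PSM response reports a coefficient of
  determination of zero.
* Stop-less ORFs have undefined junctions-after-stop (NA) and are removed as
  truncations before the NMD rule could read the NA.
* Duplicate database labels are a hard error — labels are the join key for
  every downstream table.

# Problem sizes

The test suite and the acceptance script run the full pipeline on the
30-gene smoke preset (~130 transcript models, ~120 database entries, ~90
peptides), the oracle-equivalence sweeps on 500 randomized instances per
operation, and the statistical-recovery check on 2,000 simulated gene pairs.
These sizes were chosen so every label-recovery property is exercised with
all event types present while a complete run stays in the tens of seconds;
the pipeline itself has no size-dependent logic, so larger inputs change
only runtime.

# Known limitations

Mono-exonic novelty is collapsed into OTHER; genetic variation is invisible
(the database is genome-derived, so transcriptional but not genotypic
variation is captured); quantitation stops at PSM counting; the
coding-potential stand-in is not a trained model and should be replaced via
the score-table interface when CPAT-style output is available; and
protein-level FDR/parsimony is intentionally not reimplemented.
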