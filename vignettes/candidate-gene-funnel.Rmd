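---
title: "Mapping a causal gene through a cross-lineage variant funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a causal gene through a cross-lineage variant funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A heterothallic fungus's standard laboratory strain is female-sterile: it
can fertilize a partner but cannot form fruiting bodies itself. To map the
lesion, the strain is crossed to a fertile wild isolate and the progeny
are backcrossed to the sterile recurrent parent for several generations in
two independent lines, selecting for fertility each round. Each inbred
line ends up nearly identical to the recurrent parent, carrying only a
small residue of donor genome — and, necessarily, the functional allele of
whatever gene rescues fertility. Sequencing both lines against the
recurrent parent's genome and keeping only the variants the two lines
share concentrates the signal: private variants are backcross noise, while
the shared set must contain the causal locus (plus whatever donor sequence
hitchhiked with it, typically clustered around the selected mating-type
region).

`variantfunnel` implements the downstream inference as a reusable,
testable pipeline: variant ingestion and normalization, cross-lineage
intersection, codon-level consequence prediction, a fixed gene-level
exclusion funnel, splice-disruption modeling by intron retention, protein
characterization, and scaffold-bias summarization — plus a synthetic
backcross generator that provides a complete ground-truthed universe for
validation.

## Variant model and normalization

Variants are atomic: single-nucleotide variants (SNVs) and short
insertion/deletion polymorphisms (DIPs) keyed by
`(scaffold, pos, ref, alt)`. Multi-allelic records are decomposed,
multi-base substitutions split into SNVs, and indels left-aligned with one
anchor base. Left-alignment matters because the cross-lineage intersection
is a set operation on keys: two callers (or two lines) may place the same
homopolymer deletion at different equivalent positions, and only a
canonical representation makes the intersection
representation-independent. Normalization is idempotent, and records whose
reference allele disagrees with the genome are rejected and reported,
never silently dropped.

All internal coordinates are 1-based inclusive, the convention of the
surrounding R/Bioconductor ecosystem; GFF3 (1-based) and VCF (1-based,
anchored) are converted only at the I/O boundary so no off-by-one
arithmetic leaks into the middle of the pipeline.

## Consequence prediction

`classify()` assigns exactly one consequence per (variant, gene) pair with
a fixed priority:

1. **Splice windows first.** The first and last two bases of every intron
   (the near-invariant `GT`/`AG` dinucleotides) outrank any coding
   interpretation: a substitution at a donor `+1` acts through splicing
   even if it would also change a codon. Deletions that span an
   exon/intron junction land here too.
2. **Coding effects by re-translation, never heuristics.** The variant is
   applied to the scaffold, exon boundaries are shifted (an exon start
   erased by a deletion resumes at the first surviving base; an erased
   exon end stops at the replacement's last base), the coding sequence is
   re-extracted, and both alleles are translated. The protein diff yields
   synonymous, missense (conservative or non-conservative), nonsense,
   frameshift, or in-frame indel; truncation lengths always come from the
   mutant translation itself. Minus-strand genes are handled by operating
   on the coding-strand sequence, and the test suite asserts full strand
   symmetry.
3. Intronic, then intergenic, for everything else.

Splice disruption is modeled mechanistically as **retention of the
affected intron**: `retained_intron_protein()` builds the transcript with
that intron left in, applies the variant, and translates to the first
stop. This is the observed mechanism for the motivating case — a donor
`G>T` turns the site into sense `TTAAGT`, whose `TAA` falls in frame and
truncates the protein. Donor and acceptor disruption are treated
symmetrically, the simplest model consistent with that observation; branch
points, cryptic splice sites and exon skipping are deliberately out of
scope.

Because variants are called *inbred vs. reference*, a splice-window hit
has an orientation: the classifier compares the `GT`/`AG` dinucleotide
under both alleles. `allele_disrupted = "inbred"` means the inbred allele
breaks a canonical site; `"reference"` means the shared variant *repairs*
a site that is broken in the reference genome — precisely the signature of
a causal allele rescued by the backcross. The funnel treats the two
orientations oppositely (below).

**Conservative exchanges** are operationalized as BLOSUM62 score ≥ 0,
which classifies the canonical examples A>V (0), I>L (2) and K>E (1) as
conservative and dissimilar pairs (W>G, −2) as not. The threshold is a
config knob (`substitution_policy()`), since the underlying field practice
is a judgment call with only examples to anchor it.

**The conservation filter** stands in for a manual homolog search: for a
missense effect it maps the protein position to its column in a
user-supplied homolog alignment and asks what fraction of non-gap homolog
rows carry the focal residue (default threshold 0.5). A missing alignment
passes the effect through (fail-open), because genes should be excluded
only on positive evidence that the changed residue is unconstrained. This
column-identity surrogate is a reasoned stand-in, not a reimplementation
of any particular database search.

## The exclusion funnel

`run_funnel()` applies a fixed step order at the **gene** level (a gene is
excluded as a whole, matching how such screens are actually conducted):

| step | keeps |
|------|-------|
| 1 | variants with a coding consequence |
| 2 | non-synonymous effects |
| 3 | genes with ≥ 1 amino-acid-changing effect |
| 4 | genes whose *inbred* allele is not truncated (stop / frameshift / inbred-side splice loss) |
| 5 | genes with ≥ 1 non-conservative effect |
| 6 | genes with ≥ 1 effect in a conserved alignment region |

Step 1 includes splice-window variants even though they sit in intron
positions: they alter the coding product, and excluding them would discard
the causal donor-site variant the design exists to find. Step 4 encodes
the design's logic: a gene already broken in the fertile inbred lines
cannot explain the reference strain's sterility. The mirrored orientation
— the inbred allele *repairing* a reference-broken site — is not excluded
but reported separately (`reference_lesions`), since the screen's own
rules say nothing about it and it is exactly where a causal allele shows
up. Per-step variant and gene counts are reported so the reduction is
auditable, and survivor sets are monotone and invariant to input order by
construction (both properties are tested).

Percent shares of the common pool are reported as integer percent with
halves rounded away from zero — the only convention that reproduces all
four headline shares (56/36 for SNVs, 53/31 for indels) of the motivating
tables simultaneously. Two cells of those tables (70/136 printed as 52,
151/512 printed as 30) disagree with this convention by one point; the
acceptance suite flags them as apparent errata rather than asserting them.

`scaffold_bias()` summarizes candidate clustering per scaffold: observed
count, length-proportional expectation, their fold ratio, and an
upper-tail probability (hypergeometric over a supplied gene universe,
binomial under the length-proportional null otherwise). The original
screen performed no formal test, so the statistic is labeled descriptive:
it orders scaffolds, it does not calibrate error rates.

## Protein features

`translate_cds()` uses the standard code, stops at the first stop codon
and renders ambiguous codons as `X`. `molecular_weight()` sums *average*
residue masses plus one water (average, not monoisotopic, is what
reproduces the ~178 kDa scale of a ~1600-residue protein) and satisfies
additivity to 1e−9 kDa. `residue_rich_windows()` finds the densest
fixed-width window of a residue (leftmost on ties) — the natural
operationalization of "35 glutamines within 38 residues", whose exact
window placement no text defines. `proline_rich_regions()` merges
overlapping qualifying windows (default 20 residues, ≥ 30% proline) into
maximal regions. Window defaults are knobs that express observations, not
claims.

## The synthetic generator

`simulate_backcross()` produces the entire test universe from one seed: a
four-scaffold 150 kb genome, 24 intron-containing genes (1–3 `GT..AG`
introns at arbitrary coding offsets, ATG…stop, no internal stops), two
lineage variant sets, per-gene homolog alignments, and a truth table. Key
design choices:

* **Sharing is constructed, not sampled.** Lineage sets are built from an
  explicit common pool (252 SNVs, 62 DIPs) plus private pools sized so the
  shares are exactly 56%/36% and 53%/31%. The pipeline consumes variant
  sets, not pedigrees, so the eight-generation backcross is emulated only
  at the level of its observable consequence.
* **Planted lesions, one per funnel rule**: a causal gene whose reference
  allele carries a broken donor (sense `TTAAGT`, placed 2 mod 3 into the
  CDS so retention yields an immediate in-frame `TAA`) repaired by a
  shared variant; two non-conservative missense survivors; and decoys for
  the silent, inbred-truncation, conservative-exchange and
  non-conserved-region rules. Survivors sit on scaffold 1 to emulate
  clustering around a selected locus. Expected fates are recorded in the
  truth table and recovered end-to-end for 20 seeds in the acceptance
  suite.
* **Background shared variants are neutral by construction** (intergenic
  or intron-interior), so the truth table is exact: candidate recovery is
  a sharp equality, not a statistical tendency.
* Homolog rows mutate the reference protein at 5% per column (2% gaps);
  planted missense columns are forced conserved — or non-conserved for the
  step-6 decoy.

What the generator does **not** emulate: recombination and linkage,
sequencing error and coverage, UTRs and isoforms, phase-split codons,
non-canonical splice sites, and real annotation noise. Passing tests
therefore demonstrate the inference logic is correct under clean inputs,
not that any particular caller or annotation is reliable.

Problem sizes (150 kb, 24 genes, ~1,400 variants across lineages, 20-seed
end-to-end replication, 1,000 random oracle comparisons) were chosen so
the whole suite runs in about a minute while every code path is exercised;
all of them scale up through `sim_config()`.

## Numerical and degenerate-input choices

* Indels are left-aligned with one anchor base; normalization is
  idempotent and applied at ingestion.
* Variants with `N` in the reference allele are rejected; `N` inside a
  codon translates to `X`, and an `X`-producing change is treated as
  non-conservative (no matrix row exists for it).
* A stop-loss substitution is classified non-conservative rather than
  given a class of its own; it does not occur in the generated universe.
* Exon boundaries erased by a deletion clamp to the replacement's edges
  (start → first surviving base, end → last replacement base), so a
  clipped exon stays clipped instead of absorbing neighboring sequence.
* Ties in window searches resolve leftmost; all output tables have fixed
  column order and radix-sorted rows, so reruns are byte-identical.
* Degenerate inputs are defined, not special-cased: empty variant sets
  yield all-zero reports, a single-scaffold genome yields fold 1 and
  p = 1, an empty candidate list yields a header-only table.

## Known limitations

The funnel is only as good as its inputs: it ingests already-called
variants and annotated gene models, and systematic caller or annotation
errors pass straight through. The conservation filter depends entirely on
the homolog alignments supplied and fails open without them. Splice
modeling covers only canonical-site disruption with full retention. The
scaffold-bias probabilities are descriptive. And the screen's logic finds
genes whose *shared* variants change proteins — a causal lesion acting
through regulation, copy number, or a variant private to one line is
invisible to it by design.
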