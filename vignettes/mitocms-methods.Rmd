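---
title: "Screening mitochondrial genomes for CMS candidate genes with mitocms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mitochondrial genomes for CMS candidate genes with mitocms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocms)
```

## The screening problem

Cytoplasmic male sterility (CMS) in plants is usually caused by novel
mitochondrial open reading frames born from genome rearrangement: fragments
of conserved genes and anonymous sequence are fused into chimeric ORFs
that, when expressed, poison pollen development. Because a CMS line and
its isonuclear maintainer share a nuclear genome but differ in cytoplasm,
comparing their mitochondrial genomes isolates the sterility-associated
differences. The classic screen asks three questions about every ORF of
the CMS mitogenome:

* **AS** -- is the ORF absent from the maintainer mitogenome
  (line-specific)?
* **TM** -- does its predicted protein carry at least one transmembrane
  segment (membrane-damaging CMS proteins are the norm)?
* **CH** -- is it chimeric, i.e. does it overlap a conserved
  mitochondrial protein-coding gene or sit within 500 bp of one, so that
  it can be co-transcribed with a functional gene?

An ORF satisfying all three is the archetypal candidate: a line-specific
transmembrane ORF whose 3' end overlaps the 5' end of a ribosomal-protein
gene by a few tens of bases and which sits a couple of hundred bases from
the next conserved gene, co-transcribed with both. `mitocms` implements
this screen end to end, together with a synthetic mitogenome-pair
generator that makes every stage testable without sequencing data.

## ORF calling on a circle

`find_orfs()` scans all six reading frames. On a circular genome the scan
runs across the origin (internally the strand text is tripled and each
ORF is represented by its canonical start position), so origin-crossing
ORFs are found at their true coordinates and the result is invariant
under `rotate_origin()`. Conventions:

* **Minimum length.** Plant mitogenome annotations restrict to proteins
  of more than 100 amino acids; the default `min_aa = 101` reads that
  strictly, so a 100-residue protein is rejected and a 101-residue one is
  kept.
* **Start codons.** ATG, plus ACG and ATT, which conserved plant mt genes
  use at the DNA level (C-to-U RNA editing restores AUG on the
  transcript); a leading ACG/ATT is translated as methionine. The set is
  configurable down to `{ATG}`.
* **Maximality.** Within one stop-bounded segment only the most upstream
  permitted start defines the ORF; nested internal starts are not
  reported separately. On a circle a segment must be bounded by an
  upstream in-frame stop within one genome length.
* Coordinates are 0-based half-open and include the stop codon;
  `nt_length = 3 * (aa_length + 1)`.

ORF ids follow the field's `orf<aa-length>` convention with `a`, `b`, ...
suffixes in positional order when lengths tie, which is how names like
*orf116b* arise.

## Transmembrane prediction

The TM axis uses a deterministic Kyte-Doolittle sliding-window scan
(`hydropathy_profile()`, `predict_tm_segments()`), not an HMM topology
model: window 19, calling threshold 1.6 (the classic membrane-spanning
criterion), maximal runs of above-threshold window centres expanded to
full windows, runs closer than 5 residues merged, segments shorter than
18 residues dropped. All four numbers are arguments. The embedded
20-value hydropathy table is unit-tested against the published scale.

This predictor is reproducible and dependency-free, and it separates the
generator's planted hydrophobic-stretch proteins from hydrophilic ones
perfectly, but it is *not* an HMM and will not reproduce HMM predictions
residue-for-residue on arbitrary real proteins; on real data treat the TM
flag as a hydropathy screen, not a topology call.

One subtlety: as the threshold rises the set of above-threshold window
centres can only shrink, but the *number* of segments is not monotone in
general -- a single hydrophobic run with an interior dip can split into
two runs at a higher threshold. The test suite therefore asserts
centre-set shrinkage on random proteins and count monotonicity on
dip-free run-structured proteins, where it genuinely holds.

## The AS/TM/CH classification

* `find_specific_orfs()` declares an ORF line-specific when its protein
  has no counterpart in the other genome. The default criterion is exact
  protein-string equality -- fully reproducible, and the right notion for
  the generator's planted truth. An `identity` mode (global alignment,
  match 1 / mismatch -1 / gap -2; counterpart when identity >= 0.95 at
  length coverage >= 0.9) is provided for real data where SNP-carrying
  homologs should not count as novel. The uniqueness criterion used in
  published screens is rarely stated; both interpretations are exposed.
* `classify_chimeric()` measures proximity on the circle
  (`circular_distance()`), strand-agnostically, between the ORF's genomic
  span and each conserved protein-coding gene's full span (introns
  included); tRNA/rRNA genes do not anchor chimerism. The flag is true on
  overlap or on a gap of at most `window` (default 500 bp, a hard
  boundary: 500 is chimeric, 501 is not). Both the gap and the overlap
  toward every gene are reported, so a locus like the candidate fixture
  yields its two printed numbers -- 41 bp of overlap with *rpl2* and a
  187 bp gap to *rpl5* -- from one call.
* `venn_counts()` and `rank_candidates()` summarize the screen. Ranking
  is a deterministic total order: AS+TM+CH, then AS+CH, then AS+TM, then
  AS, with ties broken by larger overlap, then smaller gap, then id.

## In-silico co-transcription

`predict_amplicon()` models the junction-spanning RT-PCR readout as
presence/absence of a product: the forward primer must match the
transcript sense strand, the reverse complement of the reverse primer
must match downstream, the leftmost forward site and its nearest
downstream reverse site define the product, and the 3'-terminal base of a
primer must always match exactly (extension cannot start from a 3'
mismatch). By default no other mismatches are tolerated; there is no
melting-temperature model, because the experiment being mirrored is a gel
band, not hybridization physics. Templates are built with
`make_transcript()`: the maintainer transcript carries the conserved gene
alone, the CMS co-transcript carries ORF, intergenic spacer and neighbor
gene in one molecule, so a junction-spanning pair is positive only on the
latter.

## Composition statistics and expression

`summarize_genome()` reports genome length, GC, per-category gene counts
(with and without copy multiplicity, since published totals rarely say
which they use), intron-bearing gene count, start-codon usage, the
protein-coding length extremes, and a protein-length class histogram in
100-aa bins. Bins are left-closed right-open -- a 200-aa protein falls in
[200,300) -- a convention that published bin labels leave ambiguous;
proteins under 100 aa land in an `underflow` bucket. `rel_expression()`
implements the 2^-ddCt estimator against a reference gene (default the
cotton *18S* rRNA) and a calibrator sample; the calibrator's fold change
is 1 by construction and the estimator is invariant to adding a constant
to one sample's two Ct values.

## The synthetic mitogenome pair

`simulate_pair()` is first-class, tested code, not a fixture dump. The
maintainer genome places the packaged 36-gene conserved table
(`conserved_gene_table()`) in random order and orientation on a circle of
200 kb (default), with random intergenic spacers at GC 0.45. The table's
documented anchors are the eight intron-bearing genes (nad1/nad2/nad5/
nad7 with four introns each, cox2/ccmFC/rps3/rps10 with one), the
303 bp (*nad4L*) to 2013 bp (*nad5*) coding-length extremes, ACG starts
for nad1/nad4L/rps10 and the ATT start of mttB; the remaining lengths are
plausible in-range values for each gene family and are flagged as
non-authoritative. 200 kb (rather than the several-hundred-kb scale of
real cotton mitogenomes) keeps a simulate-and-screen cycle at a couple of
seconds while leaving realistic multi-kb spacers; full-scale generation
is just slower.

`derive_cms()` applies seeded rearrangements: neutral translocations of
intergenic segments, plus insertion of novel-ORF cassettes. Default event
counts are 15 line-specific ORFs (matching the scale of a real screen's
AS set), of which 6 carry a planted transmembrane stretch and 4 are
placed chimerically; the overlap range (10-60 bp) brackets the 41 bp
archetype and the gap range (20-450 bp) brackets the 187 bp archetype
within the 500 bp window. TM status is dialled by codon sampling: a
21-residue run from {L,I,V,F} guarantees a segment under the default
predictor, while restricting every other residue to the hydrophilic set
(all indices <= -0.4) guarantees none.

Making the planted set *exactly* the line-specific set takes care,
because rearrangement loves to create reading frames by accident:

* Every engineered junction carries a palindromic 38-bp **dual guard**
  containing stop codons in all six frames; every start codon inside it
  (the stop repeat is full of ATT triplets, which the caller accepts as
  starts) reaches an in-frame stop before leaving it on either strand,
  and its terminal bases cannot combine with flanking sequence into a
  start codon spanning the junction.
* Cassette ORF bodies are salted every ~25 residues with a 5-codon
  **frame-breaker** block (Leu-Thr-Lys-Leu-His) that stops both shifted
  forward frames and all three reverse frames locally, so no unplanned
  frame can run through a cassette.
* Insertion points never fall strictly inside a background ORF of the
  maintainer: truncating one would otherwise leave a shorter remainder
  ORF with a novel protein -- a spurious line-specific call. All edit
  positions are chosen up front in maintainer coordinates with pairwise
  disjoint zones and applied from the highest position down.
* Chimeric-overlap cassettes share their last bases with the neighbor
  gene's untouched 5' end. The maintainer builds those genes with a
  "dockable" prefix: a stop codon in the future ORF's frame exactly at
  the overlap boundary, none earlier, while the gene's own codons remain
  sense. Overlap sizes that are multiples of 3 are excluded (they would
  put the ORF in frame with the gene); the derivation also plants a
  gene-frame stop immediately before the gene start inside the ORF body,
  so the gene's own ORF still begins at its annotated start codon.
  Conserved CDS sequence is never mutated.

After construction the derivation verifies itself against the package's
own caller -- planted coordinates recovered, line-specific set equal to
the planted set, planted TM status reproduced -- and retries with a
different derived sub-seed if a rare chance configuration slips through.
The emitted truth table (`SyntheticTruth` rows) records the planted
class flags, coordinates, neighbor gene and gap/overlap; the `ch_expected`
flag is computed honestly from the planted geometry and the 500 bp
window, so an ORF deliberately planted at 501 bp is recorded as
*not* chimeric.

What the generator does **not** model: recombination-repeat structure and
substoichiometric shifting, RNA editing, tRNA/rRNA genes, multi-copy
genes (the table carries a `copies` field but the default is single
copy), and sequencing error. Passing the planted-truth properties
therefore shows the pipeline's logic is correct on clean rearrangements,
not that it is robust to assembly artifacts in real data.

## The packaged candidate-locus fixture

`make_orf116b_fixture()` (shipped pre-generated under
`inst/extdata/orf116b/`, byte-identical to what the function regenerates)
is a hand-constructed miniature of the candidate architecture: a 116-aa
ORF with leucine runs at residues 20-40 and 70-90 (two predicted TM
segments) whose last 41 bases are the first 41 bases of an rpl2-labelled
gene -- read in the ORF's frame they are twelve aspartates and a stop,
read in rpl2's frame they are sense codons -- with a 187 bp non-coding
gap to an rpl5-labelled gene; plus a 103-aa one-TM-segment ORF more than
500 bp from every gene, and a maintainer genome with identical conserved
CDS and neither ORF. A junction-spanning primer table (pairs `2O` and
`5O`) reproduces the co-transcription gel logic: both pairs are positive
on the CMS co-transcript and negative on the maintainer transcript. The
fixture is synthetic throughout; only the locus geometry and the
segment-count archetypes are modelled on the real candidate.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; GFF3 I/O converts to the
  standard's 1-based inclusive coordinates. Origin-crossing features are
  written as single lines with `end` beyond the sequence length on an
  `Is_circular` landmark -- the GFF3 specification's own convention --
  which round-trips exactly.
* `circular_distance()` returns the pair (gap, overlap); exactly one is
  positive except for abutting features (both 0). Distance is measured in
  either direction around the circle and is symmetric in its arguments.
* A genome shorter than 3 bp yields an empty ORF set, not an error; a
  protein shorter than the hydropathy window yields zero segments flagged
  `too_short`; an empty primer list is rejected, a primer outside
  15-35 nt is rejected.
* Determinism: a single seeded RNG stream per generator run (the
  derivation and the event plan use fixed offsets of the configured
  seed); identical configuration gives byte-identical FASTA/GFF3/TSV
  output. `make_orf116b_fixture()` saves and restores the caller's RNG
  state.

## Problem sizes used by the checks

The shipped test-and-acceptance material runs the screen at the
generator's default scale: 200 kb genomes, 36 conserved genes, 15 planted
ORFs, 25 seeds for the planted-truth recovery property; brute-force
oracle comparisons (codon-walk ORF calling, membership-set circular
distances, sliding-mean hydropathy, substring-scan amplicons) run on
instances up to 5 kb, where exhaustive enumeration is exact and fast.
These sizes were chosen so that a full simulate-screen-verify cycle is a
few seconds and the entire property suite a few minutes on one core.

## Known limitations

* The TM proxy diverges from HMM predictors on real proteins (see above).
* Exact-protein AS matching treats any single substitution as novelty;
  use `identity` mode on real assemblies.
* The conserved-gene table's non-extreme lengths are plausible, not
  measured; composition summaries of synthetic genomes should be read as
  self-consistency checks, not as reference values for cotton.
* Genome-scale published counts (total ORF numbers, AS/TM/CH totals of a
  real screen) depend on the deposited assemblies and the original TM
  predictor and are deliberately not targets of the synthetic pipeline.
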