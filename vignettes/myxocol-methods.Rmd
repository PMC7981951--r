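---
title: "myxocol: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{myxocol: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myxocol)
```

## The problem

De novo transcriptome assemblies of endoparasites are routinely mixed
material. Two contamination layers matter here: reads from the host, and
reads from a second, closely related parasite co-infecting the same
organ. Host contamination is easy — almost any alignment to the host
genome disqualifies a contig. Contamination by a congener is not: the two
parasites share substantial sequence identity, so presence/absence of a
hit cannot separate them; a graded similarity measure can. `myxocol`
implements that two-stage cleaning, plus a downstream toolkit for mining
and characterising minicollagens — the short nematocyst collagens of
cnidarians (including myxozoans) whose domain architecture (cysteine-rich
domains, a central Gly-X-Y triple-helix, flanking linkers) is diagnostic
of gene family membership.

## Identity-weighted hit coverage

For one contig of length $L$ with a set of HSPs against the contaminant
reference, every base covered by at least one HSP is assigned the
maximum fractional identity among HSPs covering it ($id_b$, 0 for
uncovered bases), and

$$ s \;=\; \frac{1}{L}\sum_{b=1}^{L} id_b \;\in\; [0,1]. $$

A contig is discarded when $s$ strictly exceeds the threshold
(default 0.90, i.e. "more than 90% similar"; equality keeps the contig).
Properties that make this a good decontamination statistic:

* it pools HSPs across all subjects and both strands — chimeric or
  fragmented reference transcripts still accumulate evidence;
* partial hits degrade the score proportionally — a 50 bp hit at 80%
  identity on a 1000 bp contig contributes only 0.04;
* when all identities are equal it reduces to plain hit coverage.

The original decontamination script organises its computation around hit
coverage but does not publish the exact formula. We expose two modes:
`weighted` (the default above) and `coverage_only` (fraction of bases
covered by segments with identity at or above a floor, default 0.90).
The default is our design choice, declared rather than asserted to match
the original; both modes sit behind one flag and one contract. Whether
the original pooled subjects or applied the rule per subject is likewise
unrecorded; we pool, because contamination is a property of the contig,
not of any single reference transcript.

The host stage is deliberately cruder: *any* hit removes the contig, with
no E-value gate by default (an optional `max_evalue` exists). Stage
order matters for bookkeeping only — a contig hit by both references is
counted once, as host-removed.

## Assembly statistics

N50 uses the dominant convention: sort lengths descending and report the
length at which the cumulative sum first reaches half the total
(inclusive at ties). GC is pooled over all contigs and excludes
ambiguity codes (including N) from numerator and denominator, so
assembler N-padding cannot bias it.

## Minicollagen scanning

**CRD matching.** A cysteine-rich domain is modelled as six cysteines
with constrained inter-cysteine gap lengths. The canonical motif uses
3-residue internal gaps and a terminal adjacent `CC`; the noncanonical
C-terminal motif of the Ncol-4/Ncol-5 type widens the C2–C3 gap to 9–10
residues. Dot notation in the literature is typographic, not a rigorous
count, so every gap range is widened by a tolerance (default ±1, floored
at 0) and all ranges are configuration-overridable. Matching scans
windows of six *consecutive* cysteine occurrences — a cysteine inside a
gap would by definition split the window — and reports all matches left
to right, overlaps allowed.

**Interrupted C-CRDs.** The Ncol-4 hallmark is a C-terminal CRD split by
a polyproline stretch. We flag a window as interrupted when exactly one
gap exceeds its allowed range (by 3–60 residues) and that oversized gap
is proline-rich (fraction ≥ 0.5). The window still counts as a C-CRD.

**Gly-X-Y counting.** The repeat count is the longest run of consecutive
triplets each beginning with glycine; trailing partial triplets never
count; ties go to the leftmost run. The strict default (no broken
triplets) keeps counting unambiguous and testable; `max_gxy_gaps = 1`
tolerates one non-G-led triplet inside a run without counting it, for
the residue replacements seen in some Ncol-4 repeats.

**Linkers and propeptide.** Segments between located domains are
classified by composition: `polyP` when the proline fraction is ≥ 0.30
(checked first), else `SG_rich` when Ser+Gly ≥ 0.50, else `other`.
Signal-peptide prediction is out of scope; absent external annotations,
the whole span upstream of the N-CRD is treated as propeptide and the KR
cleavage dipeptide is required at its terminal two residues (an
`anywhere` mode exists, since the literature does not fully pin the
position down).

**Typing.** Each candidate class carries a small rule set; confidence is
the fraction of rules satisfied, and the call is the best class reaching
0.8, else `unclassified`:

* **Ncol-5** — canonical N-CRD, noncanonical (uninterrupted) C-CRD,
  16–24 repeats, at least one SG-rich linker, no KR;
* **Ncol-4** — 4–7 repeats, no polyproline linker after the collagen
  domain, interrupted C-CRD;
* **Ncol-1/2/3-group** — canonical CRDs, 12–16 repeats, at least one
  polyproline linker. The three classical types are distinguished
  phylogenetically, not architecturally, so the scanner reports them as
  one group by design.

The 0.8 threshold means an architecture missing more than one rule of a
3–5 rule set stays unclassified — deliberate: the scanner should flag
borderline architectures for human eyes, not force a label. Note that
repeat count 16 satisfies both the Ncol-5 and the group range; the other
rules (C-CRD type, linker class, KR) separate the classes, and the
maximum-confidence winner is taken with ties broken in rule-table order.

One reported Ncol-4 peculiarity — a glycine replacing alanine in the
fifth repeat — is ambiguous as written and is encoded in no rule.

## Intron mapping

Introns are located by exact comparison of a genomic amplicon with its
transcript: anchor the longest common prefix and suffix, treat the
remainder recursively, and open deletion blocks where the transcript and
genomic diverge. Candidate block ends are ranked by the length of the
exon match that resumes there (ties: leftmost), which keeps the block
set minimal whenever exon anchors are unique; with repeats at a
junction the leftmost placement is reported, the convention of common
spliced aligners. Matching is mismatch-free by default because the
method targets Sanger-verified amplicon/transcript pairs; reconstruction
(splicing reported blocks out of the genomic sequence must reproduce the
transcript byte-exactly) is asserted inside the function, not just in
tests. Splice-site content (`GT..AG`) is reported but never required.

## Gene-cluster geometry

Intergenic distance between two genes on one scaffold is the number of
bases strictly between them on 1-based inclusive bounds
($start_2 - end_1 - 1$ after coordinate sorting), clamped to 0 for
adjacent or overlapping genes. Whether published IGR values count from
CDS or full gene bounds is unstated; we use the bounds the caller
provides. Orientation after coordinate sorting: equal strands are
co-directional, $(-,+)$ is head-to-head (divergent), $(+,-)$ is
tail-to-tail (convergent).

## Alignment preparation

For phylogenetic work the polyproline linkers are excised (they are
length-variable, compositionally biased, and alignable only by luck);
SG-rich linkers are retained by default because excluding them would
also delete the very signal that distinguishes the derived myxozoan
types. A coordinate map from trimmed to original positions accompanies
every record, and excision is exactly invertible. Whether internal
proline-rich stretches were excised in published alignments is unstated;
we excise exactly the segments classified `polyP`, wherever they fall,
with a flag to excise all linkers.

## The synthetic world

The generator states one fixed world rather than tunable difficulty:

* **Transcriptome** — contig lengths uniform in 300–3000 bp, GC 0.31
  (the GC of the real filtered assemblies this models), contaminant
  contigs derived from a related source pool by substitution-only
  mutation at rate 0.02 (binomial per base, count recorded exactly, so
  truth identity is analytic), target noise hits at identity 0.85
  (≥ 15% divergence), host contigs at fish-like GC 0.41. Substitution-
  only derivation is deliberate: full-length HSP coordinates and
  identities are then exact, so filter acceptance is analytic instead of
  aligner-dependent; an indel mode is future work.
* **Hit tables** — emitted from the truth table, standing in for an
  external BLAST run: one full-length HSP per contaminant contig at its
  true identity; one host hit per host contig; optional noise HSPs on
  targets.
* **Minicollagens** — proteins assembled domain-by-domain from disjoint
  residue alphabets (the neutral alphabet contains no C, G, P, S, K or
  R), so a planted motif is provably the only match: glycine occurs
  only in the collagen domain and in SG linkers, where placement rules
  (no glycine three residues apart, none at segment edges) cap stray
  triplet runs at one. An independent regex-based run counter *asserts*
  (never repairs) the planted truth at generation time.
* **Gene fixtures** — a transcript with introns inserted after stated
  positions (`GT…AG` boundaries by default; the published intron lengths
  32 and 40 bp are the default plantings) and a two-gene locus table at
  a planted IGR and strand pair.

All generators pin the RNG (Mersenne-Twister / Inversion / Rejection),
derive everything from one integer seed, and restore the caller's RNG
state; identical seeds give byte-identical files.

What a green test does **not** establish: real contamination involves
indels, fragmented and chimeric contigs, uneven coverage and
misassembly; real minicollagens carry noisier compositions than the
planted alphabets; real amplicons contain PCR and assembly mismatches
that the exact intron mapper refuses by design. The synthetic results
validate the algorithms' contracts, not field performance on arbitrary
assemblies.

## Numerical and degenerate-input choices

* Threshold comparisons are strict (`score > threshold`) to encode
  "more than 90%"; boundary equality keeps the contig.
* The E-value gate in mining is inclusive (`evalue <= 1e-5`); the
  literature gives no boundary semantics, and inclusive is the common
  BLAST convention.
* Reciprocal best hits break ties by bitscore (desc), then E-value
  (asc), then subject id — fully deterministic across platforms.
* Empty assemblies: N50 is 0 with a warning; GC on zero unambiguous
  bases is an error (no defensible value exists).
* Contig lengths always come from the FASTA, never from hits, so
  uncovered tails count against the similarity score.
* Proteins shorter than 30 residues are rejected by the scanner; a
  protein with no CRD and no collagen domain yields an empty
  architecture typed `unclassified`.

## Known limitations

* The default `weighted` score is a declared reconstruction of an
  unpublished formula; `coverage_only` covers the main alternative.
* The intron mapper's block set is guaranteed minimal only when exon
  anchors are unique (in practice: anchors of ≥ 10 bp); adversarial
  repeat structures can split a block without breaking reconstruction.
* Ncol-1/2/3 are not separated; signal peptides are consumed, not
  predicted; BLAST itself, assembly, read trimming, 3D structure
  comparison and tree inference are all upstream/downstream of this
  package by design.
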