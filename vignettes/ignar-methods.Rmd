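---
title: "Methods: characterizing IgNAR loci, isoforms and VNAR domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing IgNAR loci, isoforms and VNAR domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignarkit)
```

# Scope and model

IgNAR is the heavy-chain-only antibody isotype of cartilaginous fish; its
single variable domain (VNAR) is the antigen-binding unit, followed in the
full-length chain by five immunoglobulin constant domains (C1–C5). `ignarkit`
implements a desk-scale version of the complete characterization workflow for
IgNAR-like genes:

1. **Locus discovery** — translated (six-frame) local-alignment search of a
   protein query against genome scaffolds, with hit clustering into loci.
2. **Gap resolution** — reconstruction of assembly N-gaps from read pairs
   mapped around them, by overlap-consensus extension.
3. **Isoform reconstruction** — junction-chain extraction from spliced
   alignments, collapse into isoforms, exon-to-domain assignment, and FPKM
   quantification.
4. **VNAR annotation** — positional region delimitation (FR1, CDR1, FR2, HV2,
   FR3a, HV4, FR3b, CDR3, FR4), cysteine census, and type I/II classification
   with predicted disulfide bonds.
5. **Structure checking** — geometric disulfide detection on coordinate files
   and classification into intra-domain, inter-domain and inter-chain bonds.
6. **Synthetic data** — a first-class generator for every input the pipeline
   consumes, so each step can be validated against planted truth without any
   external download.

All internal coordinates are 0-based half-open; conversion to 1-based happens
only at the SAM/GTF/PDB boundaries, in the writers and readers.

# The synthetic locus generator

`build_locus()` plants a complete IgNAR-like gene inside a random scaffold.
The two packaged architectures mirror the figure-level organisation of the
two expressed nurse-shark loci:

* `ignar1_architecture()` — 10 exons; leader at exon 1, VNAR at exon 2,
  constant domains C1–C5 at exons 4–8, two tail exons. Exon 3 sits between
  the VNAR and C1; no published source fixes its content, so it carries an
  `NA` domain label (a "spacer" in the documentation) and is treated as an
  ordinary coding exon.
* `ignar2_architecture()` — 9 exons; VNAR at exon 2, C1–C5 at exons 3–7, two
  tail exons.

Cysteine placement encodes everything the downstream modules test for: the
canonical FR1/FR3b pair in the VNAR; a type-I-like FR2 (+FR4) cysteine in the
GcIgNAR1-like locus versus a type-II-like CDR1 cysteine in the GcIgNAR2-like
locus; three cysteines in C1 (positions 25/50/75 of the domain, the middle
one deliberately unpaired); two in each of C2–C5 (25/75); and one extra
cysteine in the last six residues of the C3 exon, reported as the C3–C4
linker.

Numbers not fixed by any published description are declared defaults, chosen
once as realistic for a compact vertebrate Ig locus and recorded in the
architecture object: constant domains of 100 aa (300 bp exons), a leader of
20 aa, tail exons of 30 and 12 aa, introns of 300–600 bp, 500 bp flanks, a
14-aa CDR3 in the genomic VNAR exon. Every exon is a whole number of codons
and every exon peptide is stop-free, so the concatenation of any subset of
exons stays in frame — this is what makes the exon-skipping isoform models
translate cleanly, and it is asserted by the frame-closure property test.
Architectures given explicit exon lengths in bp are rejected when a
constant-domain exon is not a multiple of three.

The packaged loci are built from one shared set of ancestral domain peptides
(fixed master seed), each locus diverging from it at rate 0.08 per position
with all planted cysteines protected. This makes the loci homologous — one
query protein (`ignar_query_protein()`, the undiverged VNAR+C1 peptide) finds
all of them — without hand-crafting sequence similarity.

## Isoform models

`ignar1_isoforms()` carries 11 exon chains and `ignar2_isoforms()` 4,
matching the isoform counts reported for the two loci. Exactly one chain per
locus is the short form lacking C4 and C5 while retaining C1–C3 (the 6th and
3rd models, mirroring the published numbering of the short isoforms); two
further GcIgNAR1-like chains skip only C4 or only C5 and are deliberately
*not* short-form under the rule, exercising its boundary. Every exon of each
locus appears in at least one chain, so full recovery of the exon catalogue
is testable.

# Read simulators

`simulate_genomic_reads()` draws `coverage × L / (2 × read_len)` fragments
with normally distributed insert sizes (default sd = insert/20, a typical
tight library), sequencing inward from both fragment ends; mate 2 is emitted
reverse-complemented in FASTQ and in reference orientation in SAM, as the
formats require. Base qualities are constant maximum quality: quality
modelling is out of scope, and the gap assembler treats all bases equally.
Substitution errors are optional; indel errors are not modelled.

`simulate_spliced_reads()` assigns fragments to isoforms multinomially in
their abundances. **By default each fragment is emitted as one full-length
spliced alignment** whose blocks are exactly its isoform's exons — a
full-cDNA (long-read-like) emulation in which every fragment carries its
isoform's complete junction chain. This is a deliberate design choice: the
isoform-collapse step groups fragments by identical junction chain, and only
complete chains make "number of distinct recovered chains" equal the number
of planted isoforms; with partial reads the same collapse would enumerate
sub-chains instead. A short-read mode (`read_len` set) generates uniform
windows along the transcript for workflows that want partial chains; it
errors when `read_len` exceeds the shortest transcript.

# Gap resolution

`find_gaps()` reports maximal N-runs of at least `min_run` (default 10) bp.
`collect_flanking_reads()` keeps pairs with at least one mate overlapping the
gap ± `flank_window` (default 500 bp, several read lengths). `assemble_gap()`
then:

1. seeds a contig on the positional majority-vote consensus of reads whose
   mapped start precedes the gap (positions in non-N sequence are trusted;
   ties go to the alphabetically smaller base);
2. greedily extends with the read whose prefix overlaps the contig suffix by
   ≥ `min_overlap` (default 30 bp) with ≤ `max_mismatch` (default 1)
   mismatches — longest overlap wins, ties broken by lexicographically
   smaller read name for determinism;
3. stops when the right-flank consensus (reads starting at or after the gap
   end) is reached by the same overlap criterion, or when no admissible
   extension exists (`"unjoined"`), or when no flank is covered at all
   (`"unfillable"`).

Candidate overlaps are located by an exact seed of `min_overlap` bases with
a full mismatch-tolerant scan as fallback, so the documented contract is
preserved while the error-free common case stays fast. The extension is
abandoned once the implied fill exceeds `3 × gap width + 500` bp, which
bounds runaway joins through repeats. Defaults scale with the simulated
100 bp reads; they are parameters, not constants. Per-base read support is
tracked along the contig and reported for the fill; `patch_scaffold()`
splices the fill in and emits a coordinate-offset table. The resolver is not
a general assembler: gaps whose fill is repetitive at the read length, or
longer than a few inserts, are out of scope.

# Translated locus search

`six_frame_translate()` uses the standard code; codons containing N become
`X`, stops are kept as `*`. `local_align()` is optimal local alignment under
BLOSUM62 with affine gaps (open 11, extend 1 — customary translated-search
settings; a gap of length *k* costs `open + k·ext`). It is backed by
`Biostrings::pairwiseAlignment()`; the test suite verifies it against an
independently written quadratic Gotoh dynamic program on hundreds of random
pairs, and scores are clamped at zero (the empty local alignment), so an
empty target scores 0.

`call_loci()` aligns the query against every stop-free segment of every
frame — segments shorter than `min_score / 11` residues (the best possible
per-residue score) are skipped as incapable of reaching the threshold — and
single-linkage clusters hits within `max_cluster_gap`. Intron stop codons
naturally fragment a locus into one hit per exon-scale segment; clustering,
not spliced alignment, reassembles the locus. Defaults `min_score = 60` and
`max_cluster_gap = 50` kb suit loci that cluster on one scaffold;
the packaged multi-locus fixture is analysed with a smaller gap matched to
its spacing. E-value statistics and seeded heuristics are not implemented:
the search is exhaustive at desk scale.

# Isoform reconstruction

`blocks_from_alignment()` is standard CIGAR arithmetic (M/D consume
reference, N splits blocks, S/I consume none; anything else errors naming
the token). `collapse_isoforms()` groups fragments by identical junction
chain, drops chains below `min_support` (default 2, filtering singleton
chimeras), and classes junction-free fragments as unspliced.
`assign_domains()` matches junctions to exon boundaries exactly (0 bp
tolerance — exactness is testable on synthetic data and the tolerance is a
parameter for noisy data), flags unmatched junctions as novel, and applies
the short-form rule: C4 and C5 both absent while C1–C3 are present. Chains
skipping only one of C4/C5 are therefore full-length but atypical. FPKM uses
fragment-level counting (`fragments × 1e9 / (total_fragments ×
exonic_length)`); junctions internal to the VNAR exon are outside the
isoform definition, consistent with treating the variable coding region as
one exon.

# VNAR annotation and typing

The positional scheme (`vnar_scheme()`) fixes FR1 = 25, CDR1 = 8, FR2 = 10,
HV2 = 8, FR3a = 16, HV4 = 6, FR3b = 15 aa — 88 aa from FR1 through FR3b,
reflecting the constant total length of that block across a repertoire; the
per-region lengths themselves are configurable defaults, since only the
constancy of the total is established. Canonical cysteines sit at FR1
offset 22 and FR3b offset 11. CDR3 is variable-length, delimited by the FR4
anchor motif (default pattern `[YW]G.G`, the conserved FR4 start); when the
anchor is absent CDR3 runs to the terminus and the annotation is flagged
rather than guessed. A positional scheme was chosen over alignment-based
(IMGT-like) numbering deliberately: it matches the fixed-frame structure of
the data, needs no embedded multiple alignment, and makes planted-truth
comparison exact.

Typing is a pure function of cysteine placement: type I = noncanonical FR2
cysteine + ≥ 2 CDR3 cysteines, predicting bonds FR1–FR3b, FR2–CDR3 (first
CDR3 cysteine) and CDR3–FR4 (last CDR3 cysteine); type II = CDR1 cysteine +
≥ 1 CDR3 cysteine, predicting FR1–FR3b and CDR1–CDR3; exactly the two
canonical cysteines is canonical-only (one bond). Sequences with cysteines
in both FR2 and CDR1 are unclassified with both candidates listed. Although
four IgNAR types are named in the literature, only types I and II have
explicit bond definitions, so no III/IV call is computed — guessing a
definition would be worse than abstaining. The census reports both exact-k
and at-least-k fractions because published repertoire counts are sometimes
stated in the one form and sometimes the other (and occasionally
inconsistently); both readings are recoverable from the histogram.

## Repertoire generator

`generate_repertoire()` mutates only CDR1/HV2/HV4 (per-position rate
`hv_mut_rate`, default 0.2 — strong diversification without erasing the
template), drawing from the 19 non-identical residues excluding cysteine so
the cysteine census remains fully controlled by the configured
distributions. CDR3 lengths default to uniform 12–18 aa; CDR3 cysteine-count
defaults emulate a type-I-like locus (majority two cysteines) or
type-II-like locus (majority one). Sampled CDR3 residues exclude cysteine
(planted separately at the drawn count) and glycine; excluding glycine makes
a chance FR4-anchor match inside CDR3 impossible, so planted and annotated
region spans agree exactly. Real CDR3s contain glycine — this is a
limitation of the emulation, traded for exact truth-table comparison, and it
does not affect the annotator itself, which handles arbitrary sequences.

# Structure checking

`detect_disulfides()` reads fixed-column PDB ATOM records (via bio3d),
extracts cysteine SG atoms (insertion codes kept in the residue key), and
pairs them greedily by nearest SG–SG distance under the threshold (default
2.5 Å; a genuine disulfide is ≈ 2.05 Å, and the margin absorbs modelling
noise in predicted structures). Greedy nearest-pair matching with
lower-residue-number tie-breaks makes the output deterministic and
independent of atom order; the suite checks it against an all-pairs
brute-force oracle. `classify_bonds()` labels bonds intra-domain,
inter-domain or inter-chain from user-supplied per-chain residue ranges, and
raises flags when a constant domain lacks an internal bond or a linker
cysteine is bonded but not between chains — the two structural expectations
for a homodimeric IgNAR. Structure prediction, energies and mmCIF parsing
are out of scope; published model-specific residue numbers (e.g. the linker
cysteines of particular predicted homodimers) are expected values for users
who supply those coordinate files, not packaged fixtures.

# Problem sizes, seeds and what the tests show

The suite exercises: isoform recovery on 10,000 full-length fragments per
locus (recovering 10/9 exons and 11/4 chains); gap recovery of a planted
200 bp gap at 30× error-free coverage over 20 seeds (exact fill each time);
the alignment oracle on 200 random pairs of ≤ 25 aa; the census on a
2,000-sequence repertoire (fractions within ±0.03 of the generator
probabilities, a ≈ 3-standard-deviation band at that size); and bond
detection against brute force on sets of up to 50 sulfurs. These sizes were
chosen so the full suite runs in minutes on one core while keeping each
check statistically meaningful.

Passing these tests shows the machinery is correct on data satisfying the
generator's assumptions: substitution-only errors, exact splice boundaries,
tight insert sizes, non-repetitive gap neighbourhoods, fixed-length
frameworks. Real genomes and repertoires violate several of these (indels,
soft-clipped mappings at N boundaries, repeat-rich gaps, length-variant
frameworks), so results on real data should be read with the corresponding
module limitations in mind.
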