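---
title: "Annotating totivirus-like genomes and their -1 frameshift signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating totivirus-like genomes and their -1 frameshift signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(totiscan)
```

## The biological problem

Members of the genus *Totivirus* (family *Totiviridae*) carry a single
linear dsRNA genome of roughly 4.6-7 kb whose plus strand encodes two
large proteins: a coat protein (CP, ORF1) and an RNA-dependent RNA
polymerase (RdRp, ORF2). In the yeast-totivirus expression strategy the
RdRp is produced as a CP-RdRp fusion by **-1 programmed ribosomal
frameshifting (-1 PRF)**: just upstream of the ORF1 stop codon the
ribosome encounters three genetic elements --

1. a **slippery heptamer** of the general form XXXYYYZ,
2. a short **spacer**, and
3. an **H-type pseudoknot** that pauses the ribosome,

and a fraction of elongating ribosomes slip one nucleotide backwards,
read through the ORF1 stop in the -1 frame, and continue into ORF2.
Characterizing a new totivirus-like genome therefore means: finding the
plus-strand ORFs and the UTR/intergenic layout, locating the three PRF
elements, computing the implied fusion product, and -- when near-identical
genomes turn up in different hosts, the signature of recent horizontal
transfer -- tabulating the point substitutions and classifying them as
silent or amino-acid-changing. `totiscan` packages exactly that analysis,
together with a synthetic-genome generator so every stage can be
exercised and tested without downloading any sequence record.

## Coordinate and alphabet conventions

All public coordinates are 1-based and inclusive, the convention of
GenBank feature tables and GFF3; the length of a region is always
`end - start + 1`. Sequences are held internally in the RNA alphabet
(A/C/G/U) because the objects of interest -- slippery heptamers, wobble
pairs, stop codons -- are RNA elements; DNA input is converted on read
and can be written back with `write_genome_fasta(..., alphabet = "dna")`.
IUPAC ambiguity codes are rejected by default (the analysis assumes a
finished, resequenced genome); `allow_iupac = TRUE` keeps them but masks
them from every pattern and pairing test. Reading frames on the plus
strand are numbered `frame = ((start - 1) mod 3) + 1`, which is the only
numbering that reproduces the conventional "ORF1 in frame 2, ORF2 in
frame 1" description from coordinates like 98 and 2410.

## ORF discovery and architecture

`find_orfs()` reports AUG-initiated, stop-terminated ORFs on the three
plus-strand frames, with maximality: an ORF's AUG is the 5'-most AUG
after the previous in-frame stop, so internal methionines never spawn
nested calls. The default minimum length of 300 nt is deliberately
conservative for viral genomes whose real ORFs are kilobases long; it is
a parameter, not a claim. Translation uses the standard genetic code
(stop codons UAA, UAG, UGA; no alternative tables, since an ochre-
terminated ORF implies the standard code) and molecular weights are sums
of Expasy *average* residue masses plus one water (18.01528 Da), the
convention of common protein-parameter tools, reported in kDa to three
decimals. `derive_architecture()` computes UTRs and intergenic regions
purely by complementation, so region lengths always sum to the genome
length -- a conservation law the tests exploit.

## The -1 PRF scanner

`scan_slippery()` implements two dialects of the XXXYYYZ grammar. The
*strict* dialect demands three identical X (any base), three identical Y
from {A, U}, and Z from {A, C, U}. Naturally occurring sites, however,
include heptamers such as UGUUUUC whose X triplet is not homogeneous, so
the *relaxed* dialect (the default in `detect_prf()`) drops the X
identity constraint and keeps the Y and Z requirements, which carry the
mechanistic load (the P- and A-site tRNAs re-pair on the Y run).

`find_pseudoknot()` enumerates H-type pseudoknots exhaustively: every
pair of helices (stem 1 a hairpin; stem 2 pairing stem 1's loop with
sequence downstream of the hairpin) with at least `min_stem = 3`
contiguous AU/GC/GU pairs per stem, loops of at most `max_loop = 20` nt,
and the crossing topology that defines an H-type knot. Plain hairpins
are never reported. Candidates are scored by an *estimated free energy*
that is simply a sum of per-pair terms (GC -3, AU -2, GU -1 kcal/mol).
This is intentionally not a full thermodynamic model: over windows of a
few tens of nucleotides, exhaustive enumeration plus a monotone
pair-count surrogate is enough to rank candidates, is exactly
reproducible, and is trivial to verify against a brute-force oracle. The
ranking is EFE ascending, ties broken by smaller extent, then 5'-most
start, so output is deterministic.

`detect_prf()` composes the two scanners: it scans the `window = 150` nt
upstream of the ORF1 stop for heptamers, searches downstream of each for
pseudoknots at an admissible spacer (4-20 nt), and returns the best
complete signal. Signals are compared by pseudoknot EFE first, then by
spacer length, then by 5' position. The spacer tie-break matters in a
subtle way: a heptamer whose Y run extends past position 6 (UGUUUUC has
a run of four U) also matches one position to its left, where the same
pseudoknot sits one nucleotide further away; preferring the shorter
spacer selects the mechanistically sensible, pseudoknot-proximal
register. The window and spacer defaults were chosen once to bracket the
geometry reported for yeast-like totiviruses (slippery site ending ~50
nt before the ORF1 stop, spacers up to ~20 nt) with margin; all are
arguments.

## Fusion-product arithmetic

`build_fusion()` models tandem slippage as a net single-nucleotide
re-read: translation runs in the zero (ORF1) frame through the codon
containing heptamer nucleotide 6, slips back one nucleotide, and
continues in the -1 frame to the first stop. The translated length is
therefore the spanned nucleotide count plus one, and the junction falls
at a fixed, reproducible codon boundary. Where exactly within the
heptamer the slip is applied is a convention, not an observable: the
product *length* is invariant to moving the anchor by a codon, a
property the test suite asserts via the `slip_offset` argument. The
ORF1/ORF2 overlap is computed by walking the -1 frame backwards from the
slip codon to the first in-frame stop; the stop-free stretch is the
overlap between ORF1 and the extended -1 reading of ORF2, and its first
position is where a stop-free "extended ORF2" could begin.

## Comparing near-identical genomes

`compare_genomes()` handles the same-length, collinear case only --
appropriate for isolates separated by a handful of point mutations; an
alignment mode would add failure modes without serving the intended
use, so unequal lengths are an explicit error. Effects are classified
one substitution at a time against the reference codon (multiple hits in
one codon trigger a warning), and percent identity is rounded half-even
to two decimals, so e.g. five differences over 4712 sites print as
99.89%.

## Residue mapping and motif scanning

`align_pair()` performs global affine-gap alignment (BLOSUM62, gap open
10, extend 1, a gap of length L costing `open + L * ext`) and exposes a
column-wise coordinate map; `map_residue()` uses it to transfer residue
numbering, e.g. locating the conserved CP histidine of a new virus
relative to a reference coat protein. This pairwise mapping is the
desk-scale stand-in for the structure-aware multiple alignments used in
comparative virology; it is honest for near-homologs with planted,
unambiguous correspondence, which is what the tests construct.
`scan_motifs()` matches user-supplied consensus patterns (letters,
`[..]`, `x`, `{n,m}`); the shipped RdRp motif set I-VIII is curated
configuration approximating the eight conserved dsRNA-virus RdRp motifs
(motif VI carrying the classic (S/G)DD core) -- it is replaceable via
YAML, and no quantitative result in the package depends on it.

## The synthetic generator: what it emulates, and what not

`generate_genome()` realizes a declarative architecture (the bundled
`tktv1_architecture()` encodes a 4712 nt yeast-totivirus-like layout:
UTRs of 97/59 nt, ORFs at 98-2161 and 2410-4653, heptamer UGUUUUC at
2104, a 19 nt spacer, a 25 nt pseudoknot at 2130-2154, a -1 frame
stop-free from position 1990, and five planted mutations) by
plant-fill-repair: planted elements are written verbatim, the rest is
filled with uniform random bases, and a repair loop redraws only free
positions until every constraint holds -- no internal stops in the ORF
frames, a stop-free and AUG-free -1 frame through the intergenic region,
realizable silent-mutation codons, no unplanted ORF of 300 nt or more,
and unique recovery of the planted PRF cassette by the detector itself
(chance background competitors are redrawn). The loop is capped at 1000
iterations and is a deterministic function of (architecture, seed);
in practice it converges in well under a hundred.

Two fixed sequence choices are part of the planted cassette rather than
background: the 19 nt spacer and the pseudoknot stems are written
U-free/GC-only so the cassette cannot contain a stop codon in any frame,
and the pseudoknot is flanked by short A guards so its stems cannot be
extended by chance complementarity. The neutral background is uniform
over A/C/G/U; no tested quantity depends on base composition.

What the generator does *not* emulate: sequencing error, assembly
artifacts, codon-usage or GC bias, homology to any real virus protein,
and biologically plausible pseudoknot thermodynamics beyond pair counts.
Passing the recovery tests therefore demonstrates that the annotation
arithmetic is internally consistent and that the detectors find what the
architecture says is there -- not that the detectors would outperform
thermodynamic folding on arbitrary natural sequence.

## Numerical and size choices

Tests compare the ORF finder with a per-AUG brute-force oracle on 200
random genomes up to 10 kb, the pseudoknot enumerator with a
nested-loop oracle on 100 windows up to 80 nt, and the aligner with a
cubic-time affine-gap oracle on 100 pairs up to 30 residues; the
full-pipeline recovery property runs 20 generator seeds. These sizes
keep the whole suite within a few minutes on one CPU while covering the
combinatorial space densely; all oracles live in the test helpers, never
in the package.

## Known limitations

Only plus-strand, AUG-initiated ORFs are modeled; there is no
minus-strand feature model, no stop/restart (victorivirus-style)
expression model, no kinetic estimate of frameshifting efficiency, no
alignment-based comparison of diverged genomes, and no profile-HMM or
database search. The pseudoknot EFE is a ranking surrogate, not a
physical free energy; users wanting thermodynamic values should fold
the reported region with a dedicated RNA-structure package.
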