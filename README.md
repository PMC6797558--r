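# totiscan

Annotation of totivirus-like dsRNA genomes and their −1 ribosomal
frameshifting signals.

## What problem this solves, and for whom

Totiviruses (family *Totiviridae*) carry a single dsRNA genome whose plus
strand encodes a coat protein (CP, ORF1) and an RNA-dependent RNA
polymerase (RdRp, ORF2). In the yeast-totivirus expression strategy the
RdRp is made as a CP–RdRp fusion via **−1 programmed ribosomal
frameshifting (−1 PRF)**: upstream of the ORF1 stop codon sit a slippery
heptamer `XXXYYYZ`, a short spacer, and an H-type pseudoknot; a fraction
of ribosomes slip one nucleotide backwards at the heptamer and read into
ORF2 in the −1 frame.

`totiscan` is for virologists and mycovirus hunters characterizing a new
totivirus-like sequence. It provides, as plain R functions:

- plus-strand **ORF discovery** (`find_orfs`) and **UTR/intergenic
  architecture** (`derive_architecture`), with standard-code translation
  and average-mass protein molecular weights;
- detection of the three **−1 PRF elements** (`scan_slippery`,
  `find_pseudoknot`, `detect_prf`) and construction of the predicted
  **CP–RdRp fusion product** (`build_fusion`): for a slip at the codon
  containing heptamer nt 6, the fusion translates `span + 1` nucleotides
  (one nt read twice), and the ORF1/ORF2 overlap is the stop-free
  stretch of the −1 frame ending at the ORF1 stop;
- **comparison of near-identical genomes** (`compare_genomes`):
  positional differences, percent identity
  `100 × (n_sites − n_diff) / n_sites`, and per-substitution
  silent/nonsynonymous classification from codon arithmetic
  (`codon_index = ⌊(pos − orf_start)/3⌋ + 1`);
- **residue mapping and RdRp motif scanning** (`align_pair`,
  `map_residue`, `scan_motifs`) via global affine-gap alignment;
- a **synthetic genome generator** (`generate_genome`,
  `generate_mutant`) that realizes a declarative architecture by
  plant–fill–repair constraint satisfaction, so the entire pipeline is
  testable offline.

Outputs go to GFF3 (`write_gff3`; ORFs as `CDS`, PRF elements with type
strings `slippery_site` / `spacer` / `pseudoknot`), JSON
(`write_report`), FASTA (`write_genome_fasta`), and a VCF-like TSV of
substitutions. All coordinates are 1-based inclusive, plus strand only;
sequences are held as RNA (T converted to U on input).

## Worked example

```r
library(totiscan)

arch   <- tktv1_architecture()            # bundled 4712 nt totivirus-like layout
genome <- generate_genome(arch, seed = 1) # deterministic synthetic genome

orfs <- find_orfs(genome)
derive_architecture(genome, orfs)
#> <architecture> TkTV1-like-synthetic (4712 nt)
#>   5'-UTR: 97 nt; 3'-UTR: 59 nt; intergenic: 248 nt
#> <orf> ORF1 [98, 2161] frame 2, 2064 nt, 687 aa, 78.302 kDa
#> <orf> ORF2 [2410, 4653] frame 1, 2244 nt, 747 aa, 83.290 kDa

detect_prf(genome, orfs[[1]], orfs[[2]])
#> <prf_signal> complete
#> <slippery_site> UGUUUUC [2104, 2110] (relaxed dialect)
#>   spacer: [2111, 2129] (19 nt)
#> <pseudoknot> [2130, 2154] EFE -33 kcal/mol; stem1 2130-2135/2142-2147, stem2 2136-2140/2150-2154
#>   fusion: 1518 aa, overlap 172 nt

mutant <- generate_mutant(genome, arch$mutations, seed = 2)
compare_genomes(genome, mutant)
#> <comparison> TkTV1-like-synthetic vs TkTV1-like-synthetic-mut: 5 substitution(s) over 4712 nt (99.89% identity)
#>   effects: utr=1, intergenic=0, silent=3, nonsynonymous=1
```

Reading the output: the genome carries a 97 nt 5′-UTR, ORF1 at 98–2161
(frame 2, 687 aa), a 248 nt intergenic region, ORF2 at 2410–4653
(frame 1, 747 aa) and a 59 nt 3′-UTR. The −1 PRF cassette — heptamer
UGUUUUC at 2104–2110 (a site that satisfies only the *relaxed* XXXYYYZ
dialect, since its X triplet is not homogeneous), a 19 nt spacer, and an
H-type pseudoknot at 2130–2154 — implies a 1518 aa CP–RdRp fusion whose
−1 frame overlaps ORF1 by 172 nt. The companion isolate differs at five
positions: one in the 5′-UTR, three silent, one amino-acid-changing.
Protein molecular weights are sequence-dependent (the synthetic
background is random), so they vary with the seed while all coordinate
and length arithmetic does not.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/totiscan.R` (subcommands `annotate`, `prf`, `compare`,
`protein`, `simulate`).

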