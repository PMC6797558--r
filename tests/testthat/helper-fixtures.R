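# Shared fixture: one generated totivirus-like genome (seed 1) with its
# annotation, cached for the whole test run.
tk_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arch <- tktv1_architecture()
      genome <- generate_genome(arch, seed = 1)
      orfs <- find_orfs(genome)
      cache <<- list(
        arch = arch,
        genome = genome,
        orfs = orfs,
        annotation = derive_architecture(genome, orfs)
      )
    }
    cache
  }
})

# Small hand-built ORF carrying a -1 frameshift cassette with two
# candidate heptamers; only the second has a pseudoknot in range.
# Layout (1-based): AUG, 20x GCA, heptamer GGGUUUA, AA, 20x GCA, heptamer
# GGGUUUA, 5 nt spacer, 25 nt pseudoknot (6 bp stem1 + 5 bp stem2, all
# GC), padding, UAA.
two_site_prf_genome <- function() {
  pk <- "GGCGGCGCGCGAGCCGCCAACGCGC"
  seqstr <- paste0(
    "AUG", strrep("GCA", 20), "GGGUUUA", "AA", strrep("GCA", 20),
    "GGGUUUA", "CAGCA", pk, "AA", strrep("AAA", 2), "UAA",
    "GCUAA" # supplies the -1-frame stop the fusion reads into
  )
  genome_record("two-site", seqstr)
}
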