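test_that("the fixture's two large ORFs are recovered with frames and proteins", {
  fx <- tk_fixture()
  expect_length(fx$orfs, 2)
  o1 <- fx$orfs[[1]]
  o2 <- fx$orfs[[2]]
  expect_equal(c(o1$region$start, o1$region$end), c(98, 2161))
  expect_equal(c(o2$region$start, o2$region$end), c(2410, 4653))
  expect_equal(o1$frame, 2)
  expect_equal(o2$frame, 1)
  expect_equal(o1$start_codon, "AUG")
  expect_equal(o1$stop_codon, "UAA")
  expect_equal(o1$protein_length, 687)
  expect_equal(o2$protein_length, 747)
  # stop codon translated but excluded
  for (o in fx$orfs) {
    expect_equal(o$protein_length * 3 + 3, region_length(o$region))
    expect_equal(o$frame, ((o$region$start - 1) %% 3) + 1)
  }
})

test_that("a minimal AUG-stop ORF is annotated", {
  g <- genome_record("mini", "AUGUAA")
  orfs <- find_orfs(g, min_length_nt = 6)
  expect_length(orfs, 1)
  expect_equal(orfs[[1]]$protein_length, 1)
  expect_equal(orfs[[1]]$protein, "M")
})

test_that("ORF finding matches the brute-force per-AUG oracle on random genomes", {
  withr::local_seed(101)
  for (rep in 1:40) {
    n <- sample(300:3000, 1)
    min_len <- sample(c(30L, 60L, 150L, 300L), 1)
    s <- random_rna(n)
    g <- genome_record(paste0("rand", rep), s)
    got <- t(vapply(
      find_orfs(g, min_length_nt = min_len),
      function(o) c(o$region$start, o$region$end), integer(2)
    ))
    want <- oracle_orfs(s, min_len)
    expect_equal(unname(got), unname(want), ignore_attr = TRUE)
  }
})

test_that("translation follows the standard code with strict error semantics", {
  expect_equal(translate_cds("AUGAAAUAA"), "MK")
  expect_equal(translate_cds("AUGAAA"), "MK") # no trailing stop required
  fx <- tk_fixture()
  cds1 <- genome_subseq(fx$genome, 98, 2161)
  cds2 <- genome_subseq(fx$genome, 2410, 4653)
  expect_equal(nchar(translate_cds(cds1)), 687)
  expect_equal(nchar(translate_cds(cds2)), 747)
  expect_error(translate_cds("AUGUAAAAA"), "codon index 2")
  expect_error(translate_cds("AUGA"), "not divisible by 3")
})

test_that("molecular weights use average residue masses plus one water", {
  expect_equal(protein_mw("G"), 0.075)
  expect_equal(protein_mw(""), 0.018)
  expect_error(protein_mw("GXZ"), "non-standard")
  # additivity of the unrounded value
  withr::local_seed(5)
  a <- random_protein(25)
  b <- random_protein(40)
  expect_equal(
    protein_mw(paste0(a, b), digits = NULL),
    protein_mw(a, digits = NULL) + protein_mw(b, digits = NULL) -
      18.01528 / 1000
  )
})

test_that("molecular weights agree with an independent implementation", {
  skip_if_not_installed("seqinr")
  withr::local_seed(6)
  for (i in 1:10) {
    p <- random_protein(sample(10:400, 1))
    expect_equal(
      protein_mw(p, digits = NULL) * 1000,
      seqinr::pmw(strsplit(p, "")[[1]]),
      tolerance = 1e-4
    )
  }
})

test_that("architecture complementation reproduces UTR and intergenic lengths", {
  fx <- tk_fixture()
  a <- fx$annotation
  expect_equal(region_length(a$five_prime_utr), 97)
  expect_equal(region_length(a$three_prime_utr), 59)
  expect_length(a$intergenic, 1)
  expect_equal(region_length(a$intergenic[[1]]), 248)
  regs <- architecture_regions(a)
  expect_equal(sum(vapply(regs, region_length, integer(1))), 4712)
  # no gaps, no overlaps
  starts <- vapply(regs, `[[`, integer(1), "start")
  ends <- vapply(regs, `[[`, integer(1), "end")
  expect_equal(starts[1], 1L)
  expect_equal(ends[length(ends)], 4712L)
  expect_equal(starts[-1], ends[-length(ends)] + 1L)
})

test_that("degenerate architectures are handled", {
  g <- genome_record("full", "AUGGCAGCAUAA")
  orfs <- find_orfs(g, min_length_nt = 12)
  a <- derive_architecture(g, orfs)
  expect_null(a$five_prime_utr)
  expect_null(a$three_prime_utr)
  expect_length(a$intergenic, 0)
  expect_warning(a0 <- derive_architecture(g, list()), "no ORFs")
  expect_equal(region_length(a0$intergenic[[1]]), g$length)
})

test_that("region lengths always sum to the genome length on random genomes", {
  withr::local_seed(77)
  for (i in 1:15) {
    g <- genome_record("r", random_rna(sample(500:3000, 1)))
    orfs <- find_orfs(g, 90)
    # keep a greedy non-overlapping subset (different frames may overlap)
    keep <- list()
    last_end <- 0L
    for (o in orfs) {
      if (o$region$start > last_end) {
        keep[[length(keep) + 1L]] <- o
        last_end <- o$region$end
      }
    }
    a <- suppressWarnings(derive_architecture(g, keep))
    regs <- architecture_regions(a)
    expect_equal(sum(vapply(regs, region_length, integer(1))), g$length)
  }
})

test_that("overlapping ORFs are refused with a pointer to frameshift analysis", {
  g <- genome_record("ovl", paste0("AUG", strrep("GCA", 30), "UAA"))
  o1 <- find_orfs(g, min_length_nt = 10)[[1]]
  fake <- o1
  fake$region <- region(o1$region$start + 3, o1$region$end, "orf")
  expect_error(derive_architecture(g, list(o1, fake)), "detect_prf")
})
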