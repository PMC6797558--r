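test_that("identical genomes compare at 100.00% with no substitutions", {
  g <- genome_record("a", strrep("ACGU", 25))
  h <- genome_record("b", strrep("ACGU", 25))
  expect_equal(nrow(diff_genomes(g, h)), 0)
  rep <- suppressWarnings(compare_genomes(g, h))
  expect_equal(rep$percent_identity, 100.00)
  expect_equal(rep$n_diff, 0)
})

test_that("unequal lengths are refused explicitly", {
  g <- genome_record("a", "ACGUACGU")
  h <- genome_record("b", "ACGUACG")
  expect_error(diff_genomes(g, h), "differ in length")
})

test_that("fixture vs mutant differs at exactly the five planted positions", {
  fx <- tk_fixture()
  mut <- generate_mutant(fx$genome, fx$arch$mutations, seed = 2)
  d <- diff_genomes(fx$genome, mut)
  expect_equal(d$position, c(84, 1003, 1336, 1952, 3507))
})

test_that("positional diffing matches a per-position loop oracle", {
  withr::local_seed(41)
  for (i in 1:20) {
    n <- sample(50:4000, 1)
    a <- random_rna(n)
    b_chars <- strsplit(a, "")[[1]]
    nmut <- sample(0:12, 1)
    at <- sample(n, nmut)
    for (p in at) b_chars[p] <- sample(setdiff(c("A", "C", "G", "U"), b_chars[p]), 1)
    b <- paste(b_chars, collapse = "")
    d <- diff_genomes(genome_record("a", a), genome_record("b", b))
    # oracle: literal per-position comparison
    ac <- strsplit(a, "")[[1]]
    bc <- strsplit(b, "")[[1]]
    want <- which(vapply(seq_len(n), function(p) ac[p] != bc[p], logical(1)))
    expect_equal(d$position, want)
    expect_equal(d$ref_base, ac[want])
    expect_equal(d$alt_base, bc[want])
  }
})

test_that("substitutions map to regions, codons, and coding effects", {
  fx <- tk_fixture()
  mut <- generate_mutant(fx$genome, fx$arch$mutations, seed = 2)
  subs <- classify_substitutions(
    diff_genomes(fx$genome, mut), fx$annotation, fx$genome
  )
  expect_equal(subs$region_label, c("five_prime_utr", "ORF1", "ORF1", "ORF1", "ORF2"))
  expect_equal(subs$effect, c("utr", "silent", "silent", "nonsynonymous", "silent"))
  # codon arithmetic: (1952 - 98) = 1854 = 618 codons -> codon 619, position 1
  r1952 <- subs[subs$position == 1952, ]
  expect_equal(r1952$codon_index, 619)
  expect_equal(r1952$codon_position, 1)
  expect_false(r1952$ref_aa == r1952$alt_aa)
  # third-position changes at 1003, 1336 (ORF1) and 3507 (ORF2)
  expect_equal(subs$codon_position[subs$position %in% c(1003, 1336, 3507)],
    rep(3L, 3))
  utr_row <- subs[subs$position == 84, ]
  expect_true(is.na(utr_row$codon_index))
})

test_that("mutation classification recovers planted effect labels across seeds", {
  arch <- tktv1_architecture()
  for (s in c(11, 12, 13, 14, 15)) {
    g <- generate_genome(arch, seed = s)
    m <- generate_mutant(g, arch$mutations, seed = s + 500)
    rep <- compare_genomes(g, m)
    expect_equal(rep$n_diff, 5)
    expect_equal(rep$percent_identity, 99.89)
    expect_equal(
      rep$effect_counts,
      c(utr = 1L, intergenic = 0L, silent = 3L, nonsynonymous = 1L)
    )
    expect_equal(sum(rep$effect_counts), rep$n_diff)
  }
})

test_that("percent identity rounds half-even to two decimals", {
  expect_equal(percent_identity(4712, 5), 99.89)
  expect_equal(percent_identity(100, 0), 100.00)
  expect_equal(percent_identity(3, 3), 0.00)
  expect_error(percent_identity(0, 0), "positive")
  expect_error(percent_identity(10, 11), "n_diff")
  # monotonically decreasing in the number of differences
  vals <- vapply(0:50, function(k) percent_identity(100, k), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 100.00)
})

test_that("multiple hits in one codon raise a warning", {
  g <- genome_record("a", paste0(strrep("C", 6), "AUG", strrep("GCA", 30), "UAA"))
  orfs <- find_orfs(g, min_length_nt = 30)
  arch <- derive_architecture(g, orfs)
  chars <- strsplit(g$sequence, "")[[1]]
  chars[13] <- "U" # codon 2, position 1 (GCA -> UCA, both -> Ser? no: Ala -> Ser)
  chars[14] <- "G" # codon 2, position 2
  h <- genome_record("b", paste(chars, collapse = ""))
  expect_warning(
    classify_substitutions(diff_genomes(g, h), arch, g),
    "same codon"
  )
})

test_that("substitution TSV carries both alphabets", {
  fx <- tk_fixture()
  mut <- generate_mutant(fx$genome, fx$arch$mutations, seed = 2)
  rep <- compare_genomes(fx$genome, mut)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_substitution_tsv(rep, f)
  tsv <- read.delim(f)
  expect_equal(nrow(tsv), 5)
  expect_equal(tsv$POS, c(84, 1003, 1336, 1952, 3507))
  expect_false(any(grepl("U", tsv$REF)))
  expect_false(any(grepl("T", tsv$REF_RNA)))
})
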