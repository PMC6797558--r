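test_that("slippery dialects implement the XXXYYYZ grammar", {
  pad <- function(s) genome_record("p", paste0("GCGC", s, "GCGC"))
  hit_starts <- function(g, dialect) {
    vapply(scan_slippery(g, dialect = dialect), function(s) s$region$start,
      integer(1)
    )
  }
  # canonical yeast-totivirus heptamer: strict
  expect_equal(hit_starts(pad("GGGUUUA"), "strict"), 5)
  expect_equal(hit_starts(pad("GGGUUUA"), "relaxed"), 5)
  # UGUUUUC: X positions not identical, so relaxed-only
  expect_length(scan_slippery(pad("UGUUUUC"), dialect = "strict"), 0)
  bare <- genome_record("b", "UGUUUUC")
  expect_length(scan_slippery(bare, dialect = "strict"), 0)
  expect_equal(hit_starts(bare, "relaxed"), 1)
  # in context, the 4-U run also licenses the register one nt to the left
  expect_equal(hit_starts(pad("UGUUUUC"), "relaxed"), c(4, 5))
  # GGAUUUU (X. dendrorhous viruses): relaxed
  expect_equal(hit_starts(pad("GGAUUUU"), "relaxed"), 5)
  # G at Z position is disallowed in both dialects
  expect_length(scan_slippery(pad("GGGUUUG"), dialect = "relaxed"), 0)
})

test_that("strict hits are a subset of relaxed hits on random sequences", {
  withr::local_seed(21)
  for (i in 1:25) {
    g <- genome_record("r", random_rna(300))
    strict <- vapply(
      scan_slippery(g, dialect = "strict"),
      function(s) s$region$start, integer(1)
    )
    relaxed <- vapply(
      scan_slippery(g, dialect = "relaxed"),
      function(s) s$region$start, integer(1)
    )
    expect_true(all(strict %in% relaxed))
  }
})

test_that("short windows yield an empty scan with a warning", {
  g <- genome_record("s", "GGGUUUAGC")
  expect_warning(out <- scan_slippery(g, window = region(1, 5, "orf")), "shorter")
  expect_length(out, 0)
})

test_that("a planted two-stem insert is recovered as the top pseudoknot", {
  # stem1: 5 GC pairs; stem2: 4 GC pairs crossing the hairpin loop
  s1a <- "GCGCG"
  s2a <- "GGGG"
  insert <- paste0(s1a, s2a, "A", "CGCGC", "AA", "CCCC")
  g <- genome_record("pk", paste0(strrep("A", 6), insert, strrep("A", 6)))
  pks <- find_pseudoknot(g, search_start = 2, max_extent = 40)
  expect_gt(length(pks), 0)
  top <- pks[[1]]
  expect_equal(top$efe, 9 * -3)
  expect_equal(c(top$region$start, top$region$end), c(7, 27))
  expect_equal(c(top$stem1[[1]]$start, top$stem1[[1]]$end), c(7, 11))
  expect_equal(c(top$stem1[[2]]$start, top$stem1[[2]]$end), c(17, 21))
  expect_equal(c(top$stem2[[1]]$start, top$stem2[[1]]$end), c(12, 15))
  expect_equal(c(top$stem2[[2]]$start, top$stem2[[2]]$end), c(24, 27))
})

test_that("pseudoknot enumeration requires crossing stems and pairing", {
  g_polyA <- genome_record("a", strrep("A", 60))
  expect_length(find_pseudoknot(g_polyA, 1), 0)
  # a clean hairpin with no downstream partner for its loop: no H-type
  hairpin <- genome_record("h", paste0("GGGGG", "AAAAA", "CCCCC", strrep("A", 20)))
  expect_length(find_pseudoknot(hairpin, 1), 0)
})

test_that("pseudoknot enumeration matches the nested-loop oracle", {
  withr::local_seed(31)
  for (i in 1:30) {
    n <- sample(20:55, 1)
    s <- random_rna(n)
    got <- pk_canonical(totiscan:::enumerate_pseudoknots(strsplit(s, "")[[1]]))
    want <- pk_canonical(oracle_pseudoknots(s))
    expect_equal(got, want)
  }
})

test_that("the fixture's frameshift signal matches the planted cassette", {
  fx <- tk_fixture()
  sig <- detect_prf(fx$genome, fx$orfs[[1]], fx$orfs[[2]])
  expect_true(sig$complete)
  expect_equal(c(sig$slippery$region$start, sig$slippery$region$end), c(2104, 2110))
  expect_equal(sig$slippery$heptamer, "UGUUUUC")
  expect_equal(region_length(sig$spacer), 19)
  expect_equal(c(sig$pseudoknot$region$start, sig$pseudoknot$region$end), c(2130, 2154))
  expect_equal(
    region_length(sig$spacer),
    sig$pseudoknot$region$start - sig$slippery$region$end - 1
  )
})

test_that("a slippery site without downstream structure yields a partial signal", {
  # ORF whose tail after the heptamer is unpairable poly-A
  seqstr <- paste0(
    "AUG", strrep("GCA", 30), "GGGUUUA", "AA", strrep("AAA", 15), "UAA"
  )
  g <- genome_record("partial", seqstr)
  orf <- find_orfs(g, min_length_nt = 30)[[1]]
  expect_warning(sig <- detect_prf(g, orf), "no admissible pseudoknot")
  expect_false(sig$complete)
  expect_null(sig$pseudoknot)
  expect_false(is.null(sig$slippery))
})

test_that("of two candidate heptamers the one completing a signal wins", {
  g <- two_site_prf_genome()
  orf <- find_orfs(g, min_length_nt = 60)[[1]]
  expect_equal(c(orf$region$start, orf$region$end), c(1, 180))
  sig <- detect_prf(g, orf)
  expect_true(sig$complete)
  expect_equal(sig$slippery$region$start, 133)
  expect_equal(sig$pseudoknot$region$start, 145)
  expect_equal(region_length(sig$spacer), 5)
})

test_that("the fusion product reproduces hand-computed toy arithmetic", {
  # AUG GGG UUU | slip re-reads nt 9 | UAC -> Y | UAA
  g <- genome_record("toy", "AUGGGGUUUACUAAGUAA")
  orf <- find_orfs(g, min_length_nt = 18)[[1]]
  slip <- scan_slippery(g, dialect = "strict")[[1]]
  expect_equal(slip$region$start, 4)
  fus <- build_fusion(g, orf, slip)
  expect_equal(fus$protein, "MGFY")
  expect_equal(fus$protein_length, 4)
  expect_equal(fus$slip_position, 9)
  expect_equal(c(fus$cds_span$start, fus$cds_span$end), c(1, 14))
})

test_that("fusion construction errors on degenerate -1 frames", {
  # -1 frame stop immediately after the slip
  g_stop <- genome_record("s", "AUGGGGUUUAAGCUAUAA")
  orf <- find_orfs(g_stop, min_length_nt = 18)[[1]]
  slip <- scan_slippery(g_stop, dialect = "strict")[[1]]
  expect_error(build_fusion(g_stop, orf, slip), "immediately after the slip")
  # no -1-frame stop before the genome end
  g_run <- genome_record("r", "AUGGGGUUUCACUAA")
  orf <- find_orfs(g_run, min_length_nt = 15)[[1]]
  slip <- scan_slippery(g_run, dialect = "strict")[[1]]
  expect_error(build_fusion(g_run, orf, slip), "runaway")
})

test_that("fixture fusion arithmetic matches the printed genome arithmetic", {
  fx <- tk_fixture()
  sig <- detect_prf(fx$genome, fx$orfs[[1]], fx$orfs[[2]])
  fus <- sig$fusion
  expect_equal(fus$protein_length, 1518)
  expect_equal(fus$overlap_nt, 172)
  expect_equal(fus$minus_frame_start, 1990)
  expect_equal(c(fus$cds_span$start, fus$cds_span$end), c(98, 4653))
  # spanned nt + 1 re-read nt = translated codons * 3
  expect_equal(
    region_length(fus$cds_span) + 1L,
    (fus$protein_length + 1L) * 3L
  )
})

test_that("fusion length is invariant to the within-heptamer slip convention", {
  fx <- tk_fixture()
  sig <- detect_prf(fx$genome, fx$orfs[[1]], fx$orfs[[2]])
  lens <- vapply(c(-1L, 0L, 1L), function(off) {
    build_fusion(fx$genome, fx$orfs[[1]], sig$slippery,
      slip_offset = off
    )$protein_length
  }, integer(1))
  expect_equal(lens, rep(1518L, 3))
})
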