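# Standard genetic code keyed by RNA codons, derived once from the table
# shipped with Biostrings (DNA-keyed).
rna_codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      names(gc) <- chartr("T", "U", names(gc))
      tab <<- gc
    }
    tab
  }
})

# Expasy average residue masses (Da); a free chain adds one water.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds RNA (or DNA) coding sequence whose length is a multiple of 3.
#'   A trailing stop codon is translated but removed from the returned
#'   protein; a stop codon anywhere else is an error.
#' @return Amino-acid string.
#' @examples
#' translate_cds("AUGAAAUAA") # "MK"
#' @export
translate_cds <- function(cds) {
  s <- toupper(chartr("T", "U", gsub("[[:space:]]", "", cds)))
  n <- nchar(s)
  if (n == 0L) stop("empty coding sequence")
  if (n %% 3L != 0L) stop("coding sequence length ", n, " is not divisible by 3")
  starts <- seq.int(1L, n - 2L, 3L)
  codons <- substring(s, starts, starts + 2L)
  tab <- rna_codon_table()
  aa <- unname(tab[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1]
    stop("untranslatable codon '", codons[bad], "' at codon index ", bad)
  }
  internal_stop <- which(aa == "*")
  if (length(internal_stop)) {
    if (length(internal_stop) > 1L || internal_stop[1] != length(aa)) {
      stop("internal stop codon at codon index ", internal_stop[1])
    }
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

#' Protein molecular weight from average residue masses
#'
#' Sum of Expasy average residue masses plus one water (18.01528 Da),
#' reported in kDa.
#'
#' @param protein Amino-acid string over the standard 20-letter alphabet
#'   (may be empty: the result is then the mass of water alone).
#' @param digits Decimal places for the kDa value (default 3, the
#'   convention used throughout the annotation objects); `NULL` for the
#'   unrounded value.
#' @return Molecular weight in kDa.
#' @examples
#' protein_mw("G") # 0.075
#' @export
protein_mw <- function(protein, digits = 3L) {
  stopifnot(is.character(protein), length(protein) == 1L)
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% names(AA_AVG_MASS))
  if (length(bad)) {
    stop(
      "non-standard residue(s) ",
      paste0("'", res[bad], "' at position ", bad, collapse = ", ")
    )
  }
  kda <- (sum(AA_AVG_MASS[res]) + WATER_MASS) / 1000
  if (is.null(digits)) kda else round(kda, digits)
}

# Build one ORF annotation from coordinates (internal).
new_orf_annotation <- function(genome, start, end, name = NA_character_) {
  cds <- genome_subseq(genome, start, end)
  protein <- translate_cds(cds)
  structure(
    list(
      name = name,
      region = region(start, end, "orf"),
      frame = ((start - 1L) %% 3L) + 1L,
      start_codon = substr(cds, 1L, 3L),
      stop_codon = substr(cds, nchar(cds) - 2L, nchar(cds)),
      protein = protein,
      protein_length = nchar(protein),
      molecular_weight = protein_mw(protein)
    ),
    class = "orf_annotation"
  )
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat("<orf> ", x$name, " [", x$region$start, ", ", x$region$end, "] frame ",
    x$frame, ", ", region_length(x$region), " nt, ", x$protein_length,
    " aa, ", format(x$molecular_weight, nsmall = 3), " kDa\n",
    sep = ""
  )
  invisible(x)
}

#' Find plus-strand open reading frames
#'
#' Scans the three plus-strand reading frames for AUG-initiated ORFs ending
#' at the first in-frame stop codon. Each reported ORF is maximal: its AUG
#' is the 5'-most AUG after the previous in-frame stop, so internal
#' methionines never spawn nested ORFs. ORFs are sorted by start and named
#' ORF1, ORF2, ... in genome order.
#'
#' @param genome A [genome_record()].
#' @param min_length_nt Minimum ORF length in nucleotides, stop codon
#'   included (default 300).
#' @return List of `orf_annotation` objects (possibly empty).
#' @export
find_orfs <- function(genome, min_length_nt = 300L) {
  stopifnot(inherits(genome, "genome_record"))
  hits <- orf_coords(genome_chars(genome), min_length_nt)
  lapply(seq_along(hits), function(i) {
    new_orf_annotation(genome, hits[[i]][1], hits[[i]][2],
      name = paste0("ORF", i)
    )
  })
}

# Coordinate-level ORF scan on a character vector: list of c(start, end),
# sorted by start. Shared by find_orfs() and the synthetic generator's
# no-spurious-ORF constraint.
orf_coords <- function(chars, min_length_nt) {
  n <- length(chars)
  hits <- list()
  for (f in 1:3) {
    if (n - f + 1L < 3L) next
    starts <- seq.int(f, n - 2L, 3L)
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    stop_idx <- which(codons %in% STOP_CODONS)
    aug_idx <- which(codons == START_CODON)
    if (!length(stop_idx) || !length(aug_idx)) next
    # assign every AUG to the first stop after it, keep the 5'-most AUG
    # per stop
    nxt <- stop_idx[findInterval(aug_idx, stop_idx + 1L) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    first_aug <- tapply(aug_idx[ok], nxt[ok], min)
    for (k in seq_along(first_aug)) {
      orf_start <- starts[first_aug[[k]]]
      orf_end <- starts[as.integer(names(first_aug))[k]] + 2L
      if (orf_end - orf_start + 1L >= min_length_nt) {
        hits[[length(hits) + 1L]] <- c(orf_start, orf_end)
      }
    }
  }
  if (!length(hits)) return(list())
  ord <- order(
    vapply(hits, `[`, integer(1), 1L),
    vapply(hits, `[`, integer(1), 2L)
  )
  hits[ord]
}

#' Derive the UTR/intergenic architecture around a set of ORFs
#'
#' Computes the 5'/3' untranslated regions and intergenic regions by
#' complementation of non-overlapping ORFs; region lengths always sum to
#' the genome length. Overlapping ORFs are refused (overlap between
#' adjacent frames is the signature of ribosomal frameshifting and is
#' handled by [detect_prf()] instead).
#'
#' @param genome A [genome_record()].
#' @param orfs List of `orf_annotation` objects from [find_orfs()].
#' @return An object of class `architecture_annotation` with fields
#'   `genome_id`, `genome_length`, `five_prime_utr` (a [region()] or `NULL`
#'   when length 0), `orfs`, `intergenic` (list of regions), and
#'   `three_prime_utr` (or `NULL`).
#' @export
derive_architecture <- function(genome, orfs) {
  stopifnot(inherits(genome, "genome_record"))
  n <- genome$length
  if (!length(orfs)) {
    warning("no ORFs: architecture is a single intergenic region")
    return(structure(
      list(
        genome_id = genome$id, genome_length = n,
        five_prime_utr = NULL, orfs = list(),
        intergenic = list(region(1L, n, "intergenic")),
        three_prime_utr = NULL
      ),
      class = "architecture_annotation"
    ))
  }
  orfs <- orfs[order(vapply(orfs, function(o) o$region$start, integer(1)))]
  starts <- vapply(orfs, function(o) o$region$start, integer(1))
  ends <- vapply(orfs, function(o) o$region$end, integer(1))
  if (any(ends > n) || any(starts < 1L)) stop("ORF outside genome bounds")
  if (length(orfs) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    stop(
      "overlapping ORFs: architecture derivation requires non-overlapping ",
      "ORFs; overlapping reading frames are analyzed with detect_prf()"
    )
  }
  utr5 <- if (starts[1] > 1L) region(1L, starts[1] - 1L, "five_prime_utr") else NULL
  utr3 <- if (ends[length(ends)] < n) {
    region(ends[length(ends)] + 1L, n, "three_prime_utr")
  } else {
    NULL
  }
  intergenic <- list()
  if (length(orfs) > 1L) {
    for (i in seq_len(length(orfs) - 1L)) {
      if (starts[i + 1L] > ends[i] + 1L) {
        intergenic[[length(intergenic) + 1L]] <-
          region(ends[i] + 1L, starts[i + 1L] - 1L, "intergenic")
      }
    }
  }
  structure(
    list(
      genome_id = genome$id, genome_length = n,
      five_prime_utr = utr5, orfs = orfs,
      intergenic = intergenic, three_prime_utr = utr3
    ),
    class = "architecture_annotation"
  )
}

#' Ordered regions of an architecture
#'
#' All regions of an [derive_architecture()] result (UTRs, ORFs,
#' intergenic), sorted by start. For a complete annotation these partition
#' `[1, genome_length]` with no gaps or overlaps.
#'
#' @param arch An `architecture_annotation`.
#' @return List of [region()] objects.
#' @export
architecture_regions <- function(arch) {
  stopifnot(inherits(arch, "architecture_annotation"))
  regs <- c(
    if (!is.null(arch$five_prime_utr)) list(arch$five_prime_utr),
    lapply(arch$orfs, `[[`, "region"),
    arch$intergenic,
    if (!is.null(arch$three_prime_utr)) list(arch$three_prime_utr)
  )
  regs[order(vapply(regs, `[[`, integer(1), "start"))]
}

#' @export
print.architecture_annotation <- function(x, ...) {
  cat("<architecture> ", x$genome_id, " (", x$genome_length, " nt)\n", sep = "")
  cat("  5'-UTR: ", if (is.null(x$five_prime_utr)) 0 else region_length(x$five_prime_utr),
    " nt; 3'-UTR: ", if (is.null(x$three_prime_utr)) 0 else region_length(x$three_prime_utr),
    " nt; intergenic: ",
    paste(vapply(x$intergenic, region_length, integer(1)), collapse = ", "),
    " nt\n",
    sep = ""
  )
  for (o in x$orfs) print(o)
  invisible(x)
}
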