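#' Create a genome record
#'
#' A `genome_record` is a single named plus-strand nucleotide sequence with
#' 1-based inclusive coordinate semantics. Sequences are normalized to the
#' RNA alphabet (A, C, G, U); `T` on input is converted to `U`. Characters
#' outside the unambiguous alphabet are rejected unless `allow_iupac = TRUE`,
#' in which case IUPAC ambiguity codes are kept but flagged: their positions
#' are recorded in the `masked` attribute and they never match any pattern,
#' codon, or base-pair test downstream.
#'
#' @param id Sequence identifier (FASTA header text).
#' @param sequence Nucleotide string; case-insensitive; `T` converted to `U`.
#' @param allow_iupac Keep IUPAC ambiguity codes instead of erroring.
#' @return An object of class `genome_record` with fields `id`, `sequence`
#'   (character string), `length`, `topology` (always `"linear"`), and
#'   `masked` (integer positions holding ambiguity codes).
#' @examples
#' g <- genome_record("x", "ACGT")
#' g$sequence   # "ACGU"
#' @export
genome_record <- function(id, sequence, allow_iupac = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  seq <- chartr("T", "U", seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% RNA_BASES)
  masked <- integer(0)
  if (length(bad)) {
    amb <- bad[chars[bad] %in% IUPAC_AMBIG]
    other <- setdiff(bad, amb)
    if (length(other)) {
      stop(
        "record '", id, "': non-nucleotide character(s) ",
        paste0("'", chars[other], "' at position ", other, collapse = ", ")
      )
    }
    if (!allow_iupac) {
      stop(
        "record '", id, "': IUPAC ambiguity code(s) ",
        paste0("'", chars[amb], "' at position ", amb, collapse = ", "),
        " (use allow_iupac = TRUE to keep them masked)"
      )
    }
    masked <- amb
  }
  structure(
    list(
      id = id, sequence = seq, length = nchar(seq),
      topology = "linear", masked = masked
    ),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", x$length, " nt (",
    x$topology, ")", sep = ""
  )
  if (length(x$masked)) cat(", ", length(x$masked), " masked position(s)", sep = "")
  cat("\n  5' ", substr(x$sequence, 1, min(60, x$length)),
    if (x$length > 60) "..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.genome_record <- function(x) x$length

# Character vector view of a record (or a plain string), used internally.
genome_chars <- function(genome) {
  if (inherits(genome, "genome_record")) {
    strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  } else {
    strsplit(toupper(chartr("T", "U", genome)), "", fixed = TRUE)[[1]]
  }
}

#' Extract a subsequence by 1-based inclusive coordinates
#'
#' @param genome A [genome_record()].
#' @param start,end 1-based inclusive bounds.
#' @return Character string.
#' @export
genome_subseq <- function(genome, start, end) {
  stopifnot(inherits(genome, "genome_record"))
  if (start < 1L || end > genome$length || start > end) {
    stop("subsequence [", start, ", ", end, "] outside genome [1, ", genome$length, "]")
  }
  substr(genome$sequence, start, end)
}

#' Create a genome region
#'
#' A contiguous 1-based inclusive interval with a structural label. Region
#' length is always `end - start + 1`.
#'
#' @param start,end 1-based inclusive nucleotide positions, `start <= end`.
#' @param label One of `five_prime_utr`, `orf`, `intergenic`,
#'   `three_prime_utr`, `slippery_site`, `spacer`, `pseudoknot`.
#' @return An object of class `region`.
#' @export
region <- function(start, end, label = "orf") {
  labels <- c(
    "five_prime_utr", "orf", "intergenic", "three_prime_utr",
    "slippery_site", "spacer", "pseudoknot"
  )
  label <- match.arg(label, labels)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid region: need 1 <= start <= end, got [", start, ", ", end, "]")
  }
  structure(list(start = start, end = end, label = label), class = "region")
}

#' Length of a region in nucleotides
#' @param x A [region()].
#' @return Integer, `end - start + 1`.
#' @export
region_length <- function(x) {
  stopifnot(inherits(x, "region"))
  x$end - x$start + 1L
}

#' @export
print.region <- function(x, ...) {
  cat("<region> ", x$label, " [", x$start, ", ", x$end, "] (",
    region_length(x), " nt)\n",
    sep = ""
  )
  invisible(x)
}

# Reverse complement of an RNA string (internal helper).
revcomp_rna <- function(s) {
  paste(rev(unname(RNA_COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]])),
    collapse = ""
  )
}
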