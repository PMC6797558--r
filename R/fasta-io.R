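#' Read nucleotide FASTA into genome records
#'
#' Reads a (possibly multi-entry) nucleotide FASTA file. DNA and RNA inputs
#' are both accepted; sequences are normalized to the internal RNA alphabet
#' (T converted to U). The full header line (minus `>`) is preserved as the
#' record id.
#'
#' @param path Path to a FASTA file.
#' @param allow_iupac Keep IUPAC ambiguity codes (masked) instead of
#'   erroring; see [genome_record()].
#' @return A list of [genome_record()] objects.
#' @export
read_genome_fasta <- function(path, allow_iupac = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  recs <- lapply(seq_along(set), function(i) {
    genome_record(names(set)[i], as.character(set[[i]]), allow_iupac = allow_iupac)
  })
  recs
}

#' Write genome records to FASTA
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path.
#' @param alphabet `"rna"` (default, sequences written with U) or `"dna"`
#'   (U converted back to T).
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(records, path, alphabet = c("rna", "dna"),
                               width = 70L) {
  alphabet <- match.arg(alphabet)
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- vapply(records, function(r) {
    stopifnot(inherits(r, "genome_record"))
    if (alphabet == "dna") chartr("U", "T", r$sequence) else r$sequence
  }, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
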