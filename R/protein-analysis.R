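#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), scored with a standard
#' substitution matrix. Used to transfer residue numbering between
#' homologous proteins, e.g. locating the conserved coat-protein histidine
#' of a new totivirus relative to a reference CP.
#'
#' @param query,reference Non-empty amino-acid strings (standard alphabet).
#' @param substitution_matrix Matrix name shipped with Biostrings
#'   (default `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap parameters (positive costs;
#'   defaults 10 and 1).
#' @return An `alignment_result` with fields `aligned_query`,
#'   `aligned_reference` (gapped strings), `score`, `identity` (% of
#'   aligned columns with identical residues), and `coordinate_map`
#'   (data.frame `query_pos`/`reference_pos` over columns where both
#'   sequences have a residue).
#' @export
align_pair <- function(query, reference, substitution_matrix = "BLOSUM62",
                       gap_open = 10, gap_extend = 1) {
  stopifnot(is.character(query), nzchar(query),
            is.character(reference), nzchar(reference))
  if (is.character(substitution_matrix)) {
    mat <- get(
      data(list = substitution_matrix, package = "Biostrings",
           envir = environment())
    )
  } else {
    mat <- substitution_matrix
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global"
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(aq, "", fixed = TRUE)[[1]]
  rc <- strsplit(ar, "", fixed = TRUE)[[1]]
  qpos <- cumsum(qc != "-")
  rpos <- cumsum(rc != "-")
  both <- qc != "-" & rc != "-"
  cmap <- data.frame(query_pos = qpos[both], reference_pos = rpos[both])
  ident <- if (any(both)) 100 * sum(qc[both] == rc[both]) / sum(both) else 0
  structure(
    list(
      aligned_query = aq, aligned_reference = ar,
      score = Biostrings::score(pa),
      identity = round(ident, 2),
      coordinate_map = cmap
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment> score ", x$score, ", identity ", x$identity, "%\n",
    "  Q: ", substr(x$aligned_query, 1, 60),
    if (nchar(x$aligned_query) > 60) "..." else "", "\n",
    "  R: ", substr(x$aligned_reference, 1, 60),
    if (nchar(x$aligned_reference) > 60) "..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Map a reference residue position onto the query
#'
#' @param alignment An `alignment_result` from [align_pair()].
#' @param reference_position 1-based residue index in the reference.
#' @return The query residue index aligned to that reference column, or
#'   `NA` when the column is a gap in the query.
#' @export
map_residue <- function(alignment, reference_position) {
  stopifnot(inherits(alignment, "alignment_result"))
  rc <- strsplit(alignment$aligned_reference, "", fixed = TRUE)[[1]]
  nref <- sum(rc != "-")
  if (reference_position < 1L || reference_position > nref) {
    stop("reference position ", reference_position, " outside [1, ", nref, "]")
  }
  cm <- alignment$coordinate_map
  hit <- cm$query_pos[cm$reference_pos == reference_position]
  if (length(hit)) hit[1] else NA_integer_
}

# Consensus pattern -> regular expression. Syntax: exact residue letters,
# [..] alternatives, 'x' wildcard, {n} / {n,m} repetition of the previous
# element.
consensus_to_regex <- function(pattern) {
  if (!grepl("^([A-WYZ]|x|\\[[A-WYZ]+\\]|\\{[0-9]+(,[0-9]+)?\\})+$", pattern)) {
    stop("malformed consensus pattern: '", pattern, "'")
  }
  gsub("x", ".", pattern, fixed = TRUE)
}

#' Scan a protein for consensus motifs
#'
#' Finds all non-overlapping leftmost matches of each motif. The consensus
#' syntax is: exact residue letters, `[..]` alternatives, `x` for any
#' residue, `{n,m}` repetition. The shipped default set
#' ([default_rdrp_motifs()]) approximates the eight conserved RdRp motifs
#' (I-VIII) of dsRNA viruses; it is curated configuration, replaceable via
#' YAML ([read_motifs()]).
#'
#' @param protein Amino-acid string.
#' @param motif_set Named character vector or named list of consensus
#'   patterns (names are the motif ids, e.g. `"I"` ... `"VIII"`).
#' @return List with `hits` (data.frame: `motif_id`, `start`, `end`,
#'   `matched_subsequence`, `pattern`) and `ordered_complete` (TRUE when
#'   every motif in the set matched and the first hits occur in the order
#'   the set lists them).
#' @export
scan_motifs <- function(protein, motif_set) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (is.list(motif_set)) motif_set <- unlist(motif_set)
  if (is.null(names(motif_set)) || any(!nzchar(names(motif_set)))) {
    stop("motif_set must be named")
  }
  rows <- list()
  first_hit <- rep(NA_integer_, length(motif_set))
  for (i in seq_along(motif_set)) {
    rx <- consensus_to_regex(motif_set[[i]])
    m <- gregexpr(rx, protein, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      first_hit[i] <- starts[1]
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = names(motif_set)[i],
        start = starts, end = starts + lens - 1L,
        matched_subsequence = substring(protein, starts, starts + lens - 1L),
        pattern = unname(motif_set[[i]]),
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
    motif_id = character(0), start = integer(0), end = integer(0),
    matched_subsequence = character(0), pattern = character(0),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$start, hits$motif_id), , drop = FALSE]
  rownames(hits) <- NULL
  ordered_complete <- !anyNA(first_hit) && !is.unsorted(first_hit, strictly = TRUE)
  list(hits = hits, ordered_complete = ordered_complete)
}

#' Default RdRp motif consensus set
#'
#' A curated approximation of the eight conserved RdRp sequence motifs
#' (I-VIII) of dsRNA viruses, usable with [scan_motifs()]. These consensus
#' strings are configuration distilled from the mycovirus literature, not
#' data computed by this package; motif VI carries the classic (S/G)DD
#' polymerase core. Replace with [read_motifs()] for a custom set.
#'
#' @return Named character vector of consensus patterns.
#' @export
default_rdrp_motifs <- function() {
  path <- system.file("extdata", "rdrp_motifs.yaml", package = "totiscan")
  read_motifs(path)
}

#' Read a motif set from YAML
#'
#' The YAML file maps motif ids to consensus strings (see [scan_motifs()]
#' for the syntax).
#'
#' @param path YAML file path.
#' @return Named character vector of consensus patterns.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.list(y) || is.null(names(y))) stop("motif YAML must be a named map")
  out <- vapply(y, as.character, character(1))
  for (p in out) consensus_to_regex(p) # validate early
  out
}
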