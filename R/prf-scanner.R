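# Per-pair stacking scores (kcal/mol) used for the pseudoknot estimated
# free energy. Deliberately simple: exhaustive enumeration over short
# windows needs only a ranking, not a full thermodynamic model.
DEFAULT_PAIR_SCORES <- c(GC = -3, AU = -2, GU = -1)

pair_score <- function(a, b, scores = DEFAULT_PAIR_SCORES) {
  key <- paste0(a, b)
  out <- rep(0, length(key))
  out[key %in% c("GC", "CG")] <- scores[["GC"]]
  out[key %in% c("AU", "UA")] <- scores[["AU"]]
  out[key %in% c("GU", "UG")] <- scores[["GU"]]
  out
}

#' Scan for -1 frameshift slippery heptamers
#'
#' Finds heptamers of the general form XXXYYYZ. In the `strict` dialect the
#' X triplet must be three identical bases, Y three identical A/U, and Z
#' one of A/C/U. The `relaxed` dialect (default in [detect_prf()]) drops
#' the X-identity requirement and is needed for naturally occurring sites
#' such as UGUUUUC, whose first three bases are not identical.
#'
#' @param genome A [genome_record()].
#' @param window Optional [region()] restricting the scan (default: whole
#'   genome). Heptamers must lie entirely inside the window.
#' @param dialect `"relaxed"` or `"strict"`.
#' @return List of `slippery_site` objects (fields `region`, `heptamer`,
#'   `dialect`), ordered by start; empty list (with a warning) when the
#'   window is shorter than 7 nt.
#' @export
scan_slippery <- function(genome, window = NULL,
                          dialect = c("relaxed", "strict")) {
  stopifnot(inherits(genome, "genome_record"))
  dialect <- match.arg(dialect)
  if (is.null(window)) window <- region(1L, genome$length, "orf")
  if (window$start < 1L || window$end > genome$length) {
    stop("scan window outside genome bounds")
  }
  if (region_length(window) < 7L) {
    warning("scan window shorter than 7 nt; no slippery site possible")
    return(list())
  }
  chars <- genome_chars(genome)
  starts <- window$start:(window$end - 6L)
  x1 <- chars[starts]; x2 <- chars[starts + 1L]; x3 <- chars[starts + 2L]
  y1 <- chars[starts + 3L]; y2 <- chars[starts + 4L]; y3 <- chars[starts + 5L]
  z <- chars[starts + 6L]
  ok <- y1 == y2 & y2 == y3 & y1 %in% c("A", "U") & z %in% c("A", "C", "U")
  if (dialect == "strict") {
    ok <- ok & x1 == x2 & x2 == x3 & x1 %in% RNA_BASES
  }
  hit_starts <- starts[ok]
  lapply(hit_starts, function(s) {
    structure(
      list(
        region = region(s, s + 6L, "slippery_site"),
        heptamer = substr(genome$sequence, s, s + 6L),
        dialect = dialect
      ),
      class = "slippery_site"
    )
  })
}

#' @export
print.slippery_site <- function(x, ...) {
  cat("<slippery_site> ", x$heptamer, " [", x$region$start, ", ",
    x$region$end, "] (", x$dialect, " dialect)\n",
    sep = ""
  )
  invisible(x)
}

# Inward-extension run lengths for all (i, j) anchors of a character
# window: run[i, j] = number of consecutive pairs (i, j), (i+1, j-1), ...
# that can form Watson-Crick or GU wobble pairs. Computed over
# anti-diagonals so run[i, j] only needs run[i+1, j-1].
pair_run_matrix <- function(chars, scores = DEFAULT_PAIR_SCORES) {
  n <- length(chars)
  psc <- outer(chars, chars, function(a, b) pair_score(a, b, scores))
  paired <- psc < 0
  run <- matrix(0L, n, n)
  sc <- matrix(0, n, n)
  for (span in seq_len(n - 1L)) { # span = j - i
    i <- seq_len(n - span)
    j <- i + span
    idx <- cbind(i, j)
    inner <- cbind(i + 1L, j - 1L)
    inner_run <- if (span >= 3L) run[inner] else rep(0L, length(i))
    inner_sc <- if (span >= 3L) sc[inner] else rep(0, length(i))
    run[idx] <- ifelse(paired[idx], inner_run + 1L, 0L)
    sc[idx] <- ifelse(paired[idx], inner_sc + psc[idx], 0)
  }
  list(run = run, score = sc)
}

# All helices (outer pair (i, j), k consecutive pairs) with k >= min_stem,
# as a data.frame with the summed pair score of the outermost k pairs.
helix_table <- function(mat, min_stem) {
  run <- mat$run
  sc <- mat$score
  anc <- which(run >= min_stem, arr.ind = TRUE)
  anc <- anc[anc[, 1] < anc[, 2], , drop = FALSE]
  if (!nrow(anc)) {
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      score = numeric(0)))
  }
  reps <- run[anc] - min_stem + 1L
  i <- rep.int(anc[, 1], reps)
  j <- rep.int(anc[, 2], reps)
  k <- unlist(lapply(seq_len(nrow(anc)), function(r) {
    min_stem:run[anc[r, 1], anc[r, 2]]
  }), use.names = FALSE)
  # arms must not touch: outermost k pairs need i + k - 1 < j - k + 1
  keep <- (i + k - 1L) < (j - k + 1L)
  i <- i[keep]; j <- j[keep]; k <- k[keep]
  rest <- run[cbind(i, j)] - k
  tail_sc <- numeric(length(i))
  has_tail <- rest > 0L
  tail_sc[has_tail] <- sc[cbind(i[has_tail] + k[has_tail], j[has_tail] - k[has_tail])]
  data.frame(i = i, j = j, k = k, score = sc[cbind(i, j)] - tail_sc)
}

# Tuple-level exhaustive enumeration of H-type pseudoknots on a character
# window. Returns a data.frame (i1, j1, k1, i2, j2, k2, l1, l2, l3, efe),
# ranked by efe ascending, then extent, then i1. Coordinates are window-
# relative.
enumerate_pseudoknots <- function(chars, min_stem = 3L, max_loop = 20L,
                                  pair_scores = DEFAULT_PAIR_SCORES) {
  n <- length(chars)
  empty <- data.frame(
    i1 = integer(0), j1 = integer(0), k1 = integer(0),
    i2 = integer(0), j2 = integer(0), k2 = integer(0),
    l1 = integer(0), l2 = integer(0), l3 = integer(0), efe = numeric(0)
  )
  if (n < 4L * min_stem + 1L) return(empty)
  mat <- pair_run_matrix(chars, pair_scores)
  hx <- helix_table(mat, min_stem)
  if (!nrow(hx)) return(empty)
  out <- vector("list", nrow(hx))
  for (a in seq_len(nrow(hx))) {
    i1 <- hx$i[a]; j1 <- hx$j[a]; k1 <- hx$k[a]
    loop1_lo <- i1 + k1
    loop1_hi <- j1 - k1
    if (loop1_hi - loop1_lo + 1L < min_stem) next
    # stem2 candidates: 5' arm inside loop1, 3' arm entirely downstream of j1
    s2 <- hx[hx$i >= loop1_lo & hx$i <= loop1_hi - min_stem + 1L &
      hx$j > j1, , drop = FALSE]
    if (!nrow(s2)) next
    # trim k2 so the 5' arm stays inside loop1 and the 3' arm past j1;
    # trimming k pairs off a helix keeps its outermost pairs, so the
    # trimmed helices are already rows of hx - only keep rows that fit
    fits <- (s2$i + s2$k - 1L) <= loop1_hi & (s2$j - s2$k + 1L) > j1
    s2 <- s2[fits, , drop = FALSE]
    if (!nrow(s2)) next
    l1 <- s2$i - loop1_lo
    l2 <- loop1_hi - (s2$i + s2$k - 1L)
    l3 <- (s2$j - s2$k + 1L) - j1 - 1L
    ok <- l1 >= 0L & l1 <= max_loop & l2 >= 0L & l2 <= max_loop &
      l3 >= 0L & l3 <= max_loop
    if (!any(ok)) next
    s2 <- s2[ok, , drop = FALSE]
    out[[a]] <- data.frame(
      i1 = i1, j1 = j1, k1 = k1,
      i2 = s2$i, j2 = s2$j, k2 = s2$k,
      l1 = l1[ok], l2 = l2[ok], l3 = l3[ok],
      efe = hx$score[a] + s2$score
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$efe, res$j2 - res$i1, res$i1, res$i2, res$k1, res$k2), ,
      drop = FALSE]
}

#' Enumerate H-type pseudoknot candidates
#'
#' Exhaustively enumerates H-type pseudoknots in a window downstream of
#' `search_start`: a hairpin (stem 1) whose loop pairs with sequence
#' downstream of the hairpin's 3' arm (stem 2), giving two crossing
#' helices. Plain hairpins (no crossing stem) are never reported. Every
#' base pair is one of AU, GC, or GU. Candidates are ranked by estimated
#' free energy (EFE, sum of per-pair scores) ascending, ties broken by
#' smaller total extent, then 5'-most start.
#'
#' @param genome A [genome_record()] (or plain nucleotide string).
#' @param search_start 1-based position where the search window begins.
#' @param max_extent Window size in nt; candidates must lie within
#'   `[search_start, search_start + max_extent]`.
#' @param min_stem Minimum pairs per stem (default 3).
#' @param max_loop Maximum length of each of the three loops (default 20).
#' @param pair_scores Named vector of pair scores in kcal/mol,
#'   `c(GC = -3, AU = -2, GU = -1)` by default.
#' @return List of `pseudoknot` objects, ranked; fields: `region`, `stem1`
#'   and `stem2` (each a list of two [region()] arms), `loops`, `efe`.
#' @export
find_pseudoknot <- function(genome, search_start, max_extent = 60L,
                            min_stem = 3L, max_loop = 20L,
                            pair_scores = DEFAULT_PAIR_SCORES) {
  if (inherits(genome, "genome_record")) {
    n_genome <- genome$length
    seq_chars <- genome_chars(genome)
  } else {
    seq_chars <- genome_chars(genome)
    n_genome <- length(seq_chars)
  }
  if (search_start < 1L || search_start > n_genome) {
    stop("search_start outside genome")
  }
  win_end <- min(n_genome, search_start + max_extent)
  chars <- seq_chars[search_start:win_end]
  tuples <- enumerate_pseudoknots(chars,
    min_stem = min_stem,
    max_loop = max_loop, pair_scores = pair_scores
  )
  off <- search_start - 1L
  lapply(seq_len(nrow(tuples)), function(r) {
    pseudoknot_from_tuple(tuples[r, ], off)
  })
}

# Build a pseudoknot S3 object from one tuple row of
# enumerate_pseudoknots(), shifting window-relative coordinates by off.
pseudoknot_from_tuple <- function(tp, off) {
  structure(
    list(
      region = region(tp$i1 + off, tp$j2 + off, "pseudoknot"),
      stem1 = list(
        region(tp$i1 + off, tp$i1 + tp$k1 - 1L + off, "pseudoknot"),
        region(tp$j1 - tp$k1 + 1L + off, tp$j1 + off, "pseudoknot")
      ),
      stem2 = list(
        region(tp$i2 + off, tp$i2 + tp$k2 - 1L + off, "pseudoknot"),
        region(tp$j2 - tp$k2 + 1L + off, tp$j2 + off, "pseudoknot")
      ),
      loops = list(l1 = tp$l1, l2 = tp$l2, l3 = tp$l3),
      n_pairs = tp$k1 + tp$k2,
      efe = tp$efe
    ),
    class = "pseudoknot"
  )
}

#' @export
print.pseudoknot <- function(x, ...) {
  cat("<pseudoknot> [", x$region$start, ", ", x$region$end, "] EFE ",
    x$efe, " kcal/mol; stem1 ",
    x$stem1[[1]]$start, "-", x$stem1[[1]]$end, "/",
    x$stem1[[2]]$start, "-", x$stem1[[2]]$end, ", stem2 ",
    x$stem2[[1]]$start, "-", x$stem2[[1]]$end, "/",
    x$stem2[[2]]$start, "-", x$stem2[[2]]$end, "\n",
    sep = ""
  )
  invisible(x)
}

#' Detect a complete -1 ribosomal frameshifting signal
#'
#' Scans a window upstream of the first ORF's stop codon for slippery
#' heptamers; for each hit, searches for an H-type pseudoknot separated
#' from the heptamer by an admissible spacer. Complete signals (slippery +
#' spacer + pseudoknot) are ranked by pseudoknot EFE ascending, then spacer
#' length ascending, then slippery start; the best is returned, with the
#' predicted ORF1-ORF2 fusion product attached when it can be built. If no
#' complete signal exists, a partial signal with the missing elements set
#' to `NULL` is returned together with a diagnostic warning.
#'
#' @param genome A [genome_record()].
#' @param orf1 The upstream `orf_annotation` (CP ORF).
#' @param downstream_orf Optional downstream `orf_annotation` (RdRp ORF);
#'   only used for a sanity check that `orf1` lies upstream of it.
#' @param dialect Slippery-site dialect, `"relaxed"` (default) or
#'   `"strict"`.
#' @param window Length (nt) of the scan window ending at the ORF1 stop
#'   (default 150).
#' @param min_spacer,max_spacer Admissible spacer lengths between heptamer
#'   and pseudoknot (defaults 4 and 20 nt).
#' @param max_extent,min_stem,max_loop,pair_scores Passed to
#'   [find_pseudoknot()].
#' @return A `prf_signal` object with fields `slippery`, `spacer` (a
#'   [region()]), `pseudoknot`, `fusion` (a `fusion_product` or `NULL`),
#'   and `complete` (logical).
#' @export
detect_prf <- function(genome, orf1, downstream_orf = NULL,
                       dialect = c("relaxed", "strict"), window = 150L,
                       min_spacer = 4L, max_spacer = 20L, max_extent = 60L,
                       min_stem = 3L, max_loop = 20L,
                       pair_scores = DEFAULT_PAIR_SCORES) {
  stopifnot(inherits(genome, "genome_record"), inherits(orf1, "orf_annotation"))
  dialect <- match.arg(dialect)
  if (!is.null(downstream_orf) &&
    downstream_orf$region$start <= orf1$region$end) {
    stop("orf1 must lie upstream of downstream_orf")
  }
  win <- region(
    max(orf1$region$start, orf1$region$end - window + 1L),
    orf1$region$end, "orf"
  )
  sites <- scan_slippery(genome, win, dialect)
  # the heptamer must sit upstream of the stop codon
  sites <- Filter(function(s) s$region$end <= orf1$region$end - 3L, sites)
  if (!length(sites)) {
    warning("no slippery heptamer in the ", window, " nt upstream of the ORF1 stop")
    return(structure(
      list(slippery = NULL, spacer = NULL, pseudoknot = NULL, fusion = NULL,
           complete = FALSE),
      class = "prf_signal"
    ))
  }
  chars <- genome_chars(genome)
  best <- NULL
  for (site in sites) {
    off <- site$region$end
    win_end <- min(genome$length, off + 1L + max_spacer + max_extent)
    tuples <- enumerate_pseudoknots(chars[(off + 1L):win_end],
      min_stem = min_stem, max_loop = max_loop, pair_scores = pair_scores
    )
    # spacer admissibility: pseudoknot starts i1 window positions after
    # the heptamer, so the spacer is i1 - 1 nt long
    tuples <- tuples[tuples$i1 - 1L >= min_spacer &
      tuples$i1 - 1L <= max_spacer, , drop = FALSE]
    if (!nrow(tuples)) next
    tp <- tuples[1L, ]
    key <- c(tp$efe, tp$i1 - 1L, site$region$start)
    if (is.null(best) ||
      key[1] < best$key[1] ||
      (key[1] == best$key[1] && key[2] < best$key[2]) ||
      (key[1] == best$key[1] && key[2] == best$key[2] && key[3] < best$key[3])) {
      best <- list(site = site, pk = pseudoknot_from_tuple(tp, off), key = key)
    }
  }
  if (is.null(best)) {
    warning("slippery heptamer(s) found but no admissible pseudoknot downstream")
    return(structure(
      list(slippery = sites[[1]], spacer = NULL, pseudoknot = NULL,
           fusion = NULL, complete = FALSE),
      class = "prf_signal"
    ))
  }
  spacer <- region(best$site$region$end + 1L, best$pk$region$start - 1L, "spacer")
  fusion <- tryCatch(
    build_fusion(genome, orf1, best$site),
    error = function(e) {
      warning("fusion product could not be built: ", conditionMessage(e))
      NULL
    }
  )
  structure(
    list(
      slippery = best$site, spacer = spacer, pseudoknot = best$pk,
      fusion = fusion, complete = TRUE
    ),
    class = "prf_signal"
  )
}

#' @export
print.prf_signal <- function(x, ...) {
  cat("<prf_signal>", if (x$complete) "complete" else "partial", "\n")
  if (!is.null(x$slippery)) print(x$slippery) else cat("  slippery: absent\n")
  if (!is.null(x$spacer)) {
    cat("  spacer: [", x$spacer$start, ", ", x$spacer$end, "] (",
      region_length(x$spacer), " nt)\n",
      sep = ""
    )
  }
  if (!is.null(x$pseudoknot)) print(x$pseudoknot) else cat("  pseudoknot: absent\n")
  if (!is.null(x$fusion)) {
    cat("  fusion: ", x$fusion$protein_length, " aa, overlap ",
      x$fusion$overlap_nt, " nt\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Build the predicted -1 frameshift fusion product
#'
#' Models tandem-slippage -1 frameshifting: translation proceeds in the
#' zero (ORF1) frame through the codon containing the heptamer's 6th
#' nucleotide, the ribosome slips one nucleotide backward (net effect: one
#' nucleotide is read twice), and translation continues in the -1 frame to
#' the first stop codon. The translated nucleotide count is therefore the
#' spanned length plus one. The fusion length is invariant to moving the
#' slip point by a codon within the heptamer (`slip_offset`), which only
#' changes junction residues.
#'
#' @param genome A [genome_record()].
#' @param orf1 The `orf_annotation` containing the slippery site.
#' @param slippery A `slippery_site` from [scan_slippery()]/[detect_prf()].
#' @param slip_offset Shift (in nt) applied to the nominal slip anchor
#'   (heptamer nt 6) before snapping to the enclosing zero-frame codon;
#'   default 0. Exposed to allow checking the invariance of the product
#'   length to the within-heptamer slip convention.
#' @return A `fusion_product` with fields `cds_span` (ORF1 start to the
#'   last nt of the -1-frame stop), `slip_position` (last zero-frame
#'   position, read twice), `protein`, `protein_length`,
#'   `molecular_weight`, and `overlap_nt` (length of the overlap between
#'   ORF1 and the stop-free extended -1 frame).
#' @export
build_fusion <- function(genome, orf1, slippery, slip_offset = 0L) {
  stopifnot(
    inherits(genome, "genome_record"),
    inherits(orf1, "orf_annotation"),
    inherits(slippery, "slippery_site")
  )
  hept_end <- slippery$region$end
  if (slippery$region$start <= orf1$region$start ||
    hept_end > orf1$region$end - 3L) {
    stop("slippery site must lie inside ORF1, upstream of its stop codon")
  }
  anchor <- slippery$region$start + 5L + as.integer(slip_offset)
  # last position of the zero-frame codon containing the anchor
  b <- orf1$region$start +
    3L * ((anchor - orf1$region$start) %/% 3L) + 2L
  chars <- genome_chars(genome)
  n <- genome$length
  # -1 frame resumes by re-reading position b
  minus_starts <- seq.int(b, n - 2L, 3L)
  codons <- paste0(chars[minus_starts], chars[minus_starts + 1L], chars[minus_starts + 2L])
  stop_at <- which(codons %in% STOP_CODONS)
  if (!length(stop_at)) stop("runaway fusion frame: no -1-frame stop before genome end")
  if (stop_at[1] == 1L) {
    stop("stop codon immediately after the slip at position ", b)
  }
  stop_end <- minus_starts[stop_at[1]] + 2L
  fusion_nt <- paste0(
    genome_subseq(genome, orf1$region$start, b),
    genome_subseq(genome, b, stop_end)
  )
  protein <- translate_cds(fusion_nt)
  # walk the -1 frame backwards from the slip codon to the first in-frame
  # stop; the stop-free stretch defines the ORF1/ORF2 overlap
  p <- b
  repeat {
    q <- p - 3L
    if (q < 1L) break
    cod <- paste0(chars[q], chars[q + 1L], chars[q + 2L])
    if (cod %in% STOP_CODONS) break
    p <- q
  }
  overlap_nt <- orf1$region$end - p + 1L
  structure(
    list(
      cds_span = region(orf1$region$start, stop_end, "orf"),
      slip_position = b,
      protein = protein,
      protein_length = nchar(protein),
      molecular_weight = protein_mw(protein),
      overlap_nt = overlap_nt,
      minus_frame_start = p
    ),
    class = "fusion_product"
  )
}

#' @export
print.fusion_product <- function(x, ...) {
  cat("<fusion_product> span [", x$cds_span$start, ", ", x$cds_span$end,
    "], slip at ", x$slip_position, ": ", x$protein_length, " aa, ",
    format(x$molecular_weight, nsmall = 3), " kDa, overlap ",
    x$overlap_nt, " nt\n",
    sep = ""
  )
  invisible(x)
}
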