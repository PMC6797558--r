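#' Positional differences between two same-length genomes
#'
#' Assumes the genomes are collinear (no indels); unequal lengths are an
#' error rather than silently aligned.
#'
#' @param a,b [genome_record()] objects of equal length.
#' @return A data.frame with columns `position`, `ref_base`, `alt_base`
#'   (RNA alphabet), one row per mismatch, ascending by position.
#' @export
diff_genomes <- function(a, b) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  if (a$length != b$length) {
    stop(
      "genomes differ in length (", a$length, " vs ", b$length,
      " nt); same-length collinear comparison only - align the sequences ",
      "first (alignment mode is not provided)"
    )
  }
  ca <- genome_chars(a)
  cb <- genome_chars(b)
  pos <- which(ca != cb)
  data.frame(
    position = pos, ref_base = ca[pos], alt_base = cb[pos],
    stringsAsFactors = FALSE
  )
}

#' Percent identity of a pairwise comparison
#'
#' `100 * (n_sites - n_diff) / n_sites`, rounded (half-even) to 2 decimals.
#'
#' @param n_sites Number of compared sites (> 0).
#' @param n_diff Number of differing sites.
#' @return Percentage with 2 decimal places.
#' @examples
#' percent_identity(4712, 5) # 99.89
#' @export
percent_identity <- function(n_sites, n_diff) {
  if (n_sites <= 0L) stop("n_sites must be positive")
  if (n_diff < 0L || n_diff > n_sites) stop("need 0 <= n_diff <= n_sites")
  round(100 * (n_sites - n_diff) / n_sites, 2)
}

# Region label for one position given an architecture (internal).
locate_position <- function(pos, arch) {
  for (o in arch$orfs) {
    if (pos >= o$region$start && pos <= o$region$end) {
      return(list(label = o$name, orf = o))
    }
  }
  if (!is.null(arch$five_prime_utr) && pos <= arch$five_prime_utr$end) {
    return(list(label = "five_prime_utr", orf = NULL))
  }
  if (!is.null(arch$three_prime_utr) && pos >= arch$three_prime_utr$start) {
    return(list(label = "three_prime_utr", orf = NULL))
  }
  for (r in arch$intergenic) {
    if (pos >= r$start && pos <= r$end) {
      return(list(label = "intergenic", orf = NULL))
    }
  }
  stop("position ", pos, " outside genome [1, ", arch$genome_length, "]")
}

#' Classify point substitutions by region and coding effect
#'
#' Maps each difference to the architecture region it falls in. Inside an
#' ORF the codon index and codon position are computed, the alternative
#' codon is built by substituting the single base in the reference codon,
#' and the effect is `silent` when the encoded amino acid is unchanged,
#' `nonsynonymous` otherwise. Substitutions outside ORFs are labelled
#' `utr` or `intergenic`. Each substitution is evaluated independently;
#' two or more hits in the same codon trigger a warning because the
#' single-substitution codon logic then underestimates the joint effect.
#'
#' @param diffs Data.frame from [diff_genomes()].
#' @param architecture An `architecture_annotation` derived from the
#'   reference genome.
#' @param genome The reference [genome_record()] the architecture was
#'   derived from.
#' @return A data.frame of substitution records: `position`, `ref_base`,
#'   `alt_base`, `region_label`, `codon_index`, `codon_position`,
#'   `ref_aa`, `alt_aa`, `effect`.
#' @export
classify_substitutions <- function(diffs, architecture, genome) {
  stopifnot(
    inherits(architecture, "architecture_annotation"),
    inherits(genome, "genome_record")
  )
  n <- nrow(diffs)
  out <- data.frame(
    position = integer(n), ref_base = character(n), alt_base = character(n),
    region_label = character(n), codon_index = rep(NA_integer_, n),
    codon_position = rep(NA_integer_, n), ref_aa = rep(NA_character_, n),
    alt_aa = rep(NA_character_, n), effect = character(n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  tab <- rna_codon_table()
  for (i in seq_len(n)) {
    pos <- diffs$position[i]
    if (pos < 1L || pos > genome$length) {
      stop("position ", pos, " outside genome [1, ", genome$length, "]")
    }
    loc <- locate_position(pos, architecture)
    out$position[i] <- pos
    out$ref_base[i] <- diffs$ref_base[i]
    out$alt_base[i] <- diffs$alt_base[i]
    out$region_label[i] <- loc$label
    if (is.null(loc$orf)) {
      out$effect[i] <- if (loc$label == "intergenic") "intergenic" else "utr"
    } else {
      orf_start <- loc$orf$region$start
      off <- pos - orf_start
      out$codon_index[i] <- off %/% 3L + 1L
      out$codon_position[i] <- off %% 3L + 1L
      cstart <- orf_start + 3L * (off %/% 3L)
      ref_codon <- genome_subseq(genome, cstart, cstart + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, off %% 3L + 1L, off %% 3L + 1L) <- diffs$alt_base[i]
      ref_aa <- unname(tab[ref_codon])
      alt_aa <- unname(tab[alt_codon])
      out$ref_aa[i] <- ref_aa
      out$alt_aa[i] <- alt_aa
      out$effect[i] <- if (identical(ref_aa, alt_aa)) "silent" else "nonsynonymous"
    }
  }
  in_orf <- !is.na(out$codon_index)
  codon_key <- paste(out$region_label[in_orf], out$codon_index[in_orf])
  if (anyDuplicated(codon_key)) {
    warning(
      "multiple substitutions hit the same codon; effects are classified ",
      "one substitution at a time"
    )
  }
  out
}

#' Compare two near-identical genomes
#'
#' Full comparison driver: positional diff, percent identity, and
#' silent/nonsynonymous classification against an architecture derived
#' from the reference genome (computed with [find_orfs()] +
#' [derive_architecture()] unless supplied).
#'
#' @param a Reference [genome_record()] (annotation source).
#' @param b Second [genome_record()], same length.
#' @param architecture Optional precomputed `architecture_annotation` of
#'   `a`.
#' @param min_length_nt Passed to [find_orfs()] when the architecture is
#'   derived internally.
#' @return A `comparison_report`: `n_sites`, `n_diff`, `percent_identity`,
#'   `substitutions` (classified data.frame), `effect_counts`.
#' @export
compare_genomes <- function(a, b, architecture = NULL, min_length_nt = 300L) {
  if (is.null(architecture)) {
    architecture <- derive_architecture(a, find_orfs(a, min_length_nt))
  }
  diffs <- diff_genomes(a, b)
  subs <- classify_substitutions(diffs, architecture, a)
  counts <- c(utr = 0L, intergenic = 0L, silent = 0L, nonsynonymous = 0L)
  if (nrow(subs)) {
    tb <- table(subs$effect)
    counts[names(tb)] <- as.integer(tb)
  }
  structure(
    list(
      ref_id = a$id, alt_id = b$id,
      n_sites = a$length, n_diff = nrow(subs),
      percent_identity = percent_identity(a$length, nrow(subs)),
      substitutions = subs, effect_counts = counts
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison> ", x$ref_id, " vs ", x$alt_id, ": ", x$n_diff,
    " substitution(s) over ", x$n_sites, " nt (",
    format(x$percent_identity, nsmall = 2), "% identity)\n",
    sep = ""
  )
  cat("  effects:", paste(names(x$effect_counts), x$effect_counts,
    sep = "=", collapse = ", "
  ), "\n")
  if (x$n_diff) print(x$substitutions, row.names = FALSE)
  invisible(x)
}

#' Write substitutions as a VCF-like TSV
#'
#' Columns CHROM, POS, REF, ALT (DNA alphabet, as deposited sequence
#' records use), REF_RNA, ALT_RNA, REGION, EFFECT.
#'
#' @param report A `comparison_report` from [compare_genomes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_tsv <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  s <- report$substitutions
  df <- data.frame(
    CHROM = rep(report$ref_id, nrow(s)),
    POS = s$position,
    REF = chartr("U", "T", s$ref_base),
    ALT = chartr("U", "T", s$alt_base),
    REF_RNA = s$ref_base,
    ALT_RNA = s$alt_base,
    REGION = s$region_label,
    EFFECT = s$effect,
    stringsAsFactors = FALSE
  )
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
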