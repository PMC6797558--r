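# Flatten annotation objects (regions, ORFs, PRF signals, architectures)
# into a feature table used by the GFF3 writer.
features_from_records <- function(records) {
  rows <- list()
  add <- function(start, end, type, id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start = start, end = end, type = type, id = id,
      stringsAsFactors = FALSE
    )
  }
  walk <- function(x) {
    if (inherits(x, "region")) {
      type <- if (x$label == "orf") "CDS" else x$label
      add(x$start, x$end, type, type)
    } else if (inherits(x, "orf_annotation")) {
      add(x$region$start, x$region$end, "CDS", x$name %||% "CDS")
    } else if (inherits(x, "architecture_annotation")) {
      if (!is.null(x$five_prime_utr)) walk(x$five_prime_utr)
      lapply(x$orfs, walk)
      lapply(x$intergenic, walk)
      if (!is.null(x$three_prime_utr)) walk(x$three_prime_utr)
      invisible(NULL)
    } else if (inherits(x, "prf_signal")) {
      if (!is.null(x$slippery)) walk(x$slippery$region)
      if (!is.null(x$spacer)) walk(x$spacer)
      if (!is.null(x$pseudoknot)) walk(x$pseudoknot$region)
    } else if (inherits(x, "pseudoknot")) {
      walk(x$region)
    } else if (inherits(x, "slippery_site")) {
      walk(x$region)
    } else if (is.list(x)) {
      lapply(x, walk)
      invisible(NULL)
    } else {
      stop("cannot write object of class '", class(x)[1], "' to GFF3")
    }
  }
  walk(records)
  if (!length(rows)) {
    return(data.frame(
      start = integer(0), end = integer(0), type = character(0),
      id = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Write annotations to GFF3
#'
#' Writes regions, ORFs (as `CDS`), and frameshift elements (type strings
#' `slippery_site`, `spacer`, `pseudoknot`) to a GFF3 file via
#' rtracklayer. Coordinates are 1-based inclusive on the plus strand;
#' features are sorted by start, so output is deterministic for fixed
#' input. Bounds are checked before anything is written.
#'
#' @param records A list mixing [region()], `orf_annotation`,
#'   `architecture_annotation`, and/or `prf_signal` objects.
#' @param genome The [genome_record()] the coordinates refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  feats <- features_from_records(records)
  if (nrow(feats)) {
    if (any(feats$start < 1L) || any(feats$end > genome$length)) {
      bad <- which(feats$start < 1L | feats$end > genome$length)[1]
      stop(
        "feature [", feats$start[bad], ", ", feats$end[bad],
        "] outside genome [1, ", genome$length, "]; nothing written"
      )
    }
    feats <- feats[order(feats$start, feats$end, feats$type), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = feats$start, end = feats$end),
      strand = "+",
      type = feats$type,
      phase = ifelse(feats$type == "CDS", 0L, NA_integer_),
      ID = paste0(feats$id, ".", seq_len(nrow(feats)))
    )
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, path, format = "gff3")
  # drop the run-date pragma so fixed input gives byte-identical output
  lines <- readLines(path)
  writeLines(lines[!grepl("^##date", lines)], path)
  invisible(path)
}

region_json <- function(r) {
  list(label = r$label, start = r$start, end = r$end, length = region_length(r))
}

orf_json <- function(o) {
  list(
    name = o$name, start = o$region$start, end = o$region$end,
    length_nt = region_length(o$region), frame = o$frame,
    start_codon = o$start_codon, stop_codon = o$stop_codon,
    protein_length = o$protein_length,
    molecular_weight_kda = o$molecular_weight,
    protein = o$protein
  )
}

prf_json <- function(p) {
  out <- list(complete = p$complete)
  out$slippery <- if (is.null(p$slippery)) NULL else list(
    start = p$slippery$region$start, end = p$slippery$region$end,
    heptamer = p$slippery$heptamer, dialect = p$slippery$dialect
  )
  out$spacer <- if (is.null(p$spacer)) NULL else list(
    start = p$spacer$start, end = p$spacer$end,
    length = region_length(p$spacer)
  )
  out$pseudoknot <- if (is.null(p$pseudoknot)) NULL else list(
    start = p$pseudoknot$region$start, end = p$pseudoknot$region$end,
    stem1 = lapply(p$pseudoknot$stem1, region_json),
    stem2 = lapply(p$pseudoknot$stem2, region_json),
    loops = p$pseudoknot$loops,
    efe_kcal_mol = p$pseudoknot$efe
  )
  out$fusion <- if (is.null(p$fusion)) NULL else list(
    cds_start = p$fusion$cds_span$start, cds_end = p$fusion$cds_span$end,
    slip_position = p$fusion$slip_position,
    protein_length = p$fusion$protein_length,
    molecular_weight_kda = p$fusion$molecular_weight,
    overlap_nt = p$fusion$overlap_nt,
    minus_frame_start = p$fusion$minus_frame_start
  )
  out
}

#' Build a machine-readable annotation report
#'
#' Assembles genome, architecture, frameshift-signal, and comparison
#' results into one stable-keyed list, the in-memory form of the JSON
#' report written by [write_report()].
#'
#' @param genome A [genome_record()].
#' @param architecture Optional `architecture_annotation`.
#' @param prf Optional `prf_signal`.
#' @param comparison Optional `comparison_report`.
#' @return Nested list with stable keys.
#' @export
build_report <- function(genome, architecture = NULL, prf = NULL,
                         comparison = NULL) {
  rep <- list(
    genome = list(id = genome$id, length = genome$length)
  )
  if (!is.null(architecture)) {
    regs <- architecture_regions(architecture)
    rep$regions <- lapply(regs, region_json)
    rep$orfs <- lapply(architecture$orfs, orf_json)
  }
  if (!is.null(prf)) rep$prf <- prf_json(prf)
  if (!is.null(comparison)) {
    rep$comparison <- list(
      ref_id = comparison$ref_id, alt_id = comparison$alt_id,
      n_sites = comparison$n_sites, n_diff = comparison$n_diff,
      percent_identity = comparison$percent_identity,
      effect_counts = as.list(comparison$effect_counts),
      substitutions = comparison$substitutions
    )
  }
  rep
}

#' Write the annotation report as JSON
#'
#' Serializes [build_report()] output deterministically (fixed key order,
#' full precision), so identical input yields byte-identical files.
#'
#' @param report A list from [build_report()] (or the individual objects
#'   via `...` passed to it).
#' @param path Output path.
#' @return The report list, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    report, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    dataframe = "rows"
  )
  invisible(report)
}
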