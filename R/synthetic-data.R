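# Run an expression with a private, seeded RNG stream, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Read a genome architecture from YAML
#'
#' A genome architecture declaratively describes the layout the synthetic
#' generator must realize: total length, UTR lengths, ORF coordinates,
#' the planted frameshift cassette (slippery heptamer, spacer sequence,
#' pseudoknot geometry), the 5'-most stop-free -1-frame position, and the
#' list of planted point mutations for the companion isolate.
#'
#' @param path YAML file path.
#' @return A validated `genome_architecture` object.
#' @export
read_architecture <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_architecture(yaml::read_yaml(path))
}

#' The bundled totivirus-like reference architecture
#'
#' Encodes the printed genome arithmetic of a 4712 nt yeast-totivirus-like
#' dsRNA: 97 nt 5'-UTR; ORF1 at 98-2161 (frame 2); a 248 nt intergenic
#' region; ORF2 at 2410-4653 (frame 1); 59 nt 3'-UTR; slippery heptamer
#' UGUUUUC at 2104-2110; 19 nt spacer; H-type pseudoknot at 2130-2154;
#' -1 frame stop-free from 1990 (giving a 172 nt ORF1/ORF2 overlap and a
#' 1518 aa fusion product); and five planted point mutations at 84, 1003,
#' 1336, 1952, 3507 (1 UTR, 3 silent, 1 nonsynonymous).
#'
#' @return A `genome_architecture` object.
#' @export
tktv1_architecture <- function() {
  read_architecture(system.file("extdata", "tktv1.yaml", package = "totiscan"))
}

#' Validate a genome architecture
#'
#' Checks mutual consistency of the declared regions: ORFs inside the
#' genome with lengths divisible by 3, UTR lengths matching the ORF
#' coordinates, the slippery site inside ORF1 upstream of its stop, the
#' pseudoknot downstream of the spacer, and the -1 fusion frame congruent
#' with the slippery site and the downstream ORF.
#'
#' @param arch A list as produced by [read_architecture()].
#' @return The architecture, classed `genome_architecture`; errors name
#'   the first violated constraint.
#' @export
validate_architecture <- function(arch) {
  need <- c("total_length", "utr5_length", "utr3_length", "orfs")
  miss <- setdiff(need, names(arch))
  if (length(miss)) stop("architecture missing field(s): ", paste(miss, collapse = ", "))
  n <- as.integer(arch$total_length)
  for (o in arch$orfs) {
    len <- o$end - o$start + 1L
    if (len %% 3L != 0L) {
      stop("ORF [", o$start, ", ", o$end, "] length ", len, " not divisible by 3")
    }
    if (o$start < 1L || o$end > n) stop("ORF outside genome bounds")
  }
  starts <- vapply(arch$orfs, function(o) as.integer(o$start), integer(1))
  ends <- vapply(arch$orfs, function(o) as.integer(o$end), integer(1))
  if (is.unsorted(starts, strictly = TRUE) ||
    any(starts[-1L] <= ends[-length(ends)])) {
    stop("ORFs must be sorted and non-overlapping")
  }
  if (starts[1] != arch$utr5_length + 1L) {
    stop("utr5_length inconsistent with first ORF start")
  }
  if (ends[length(ends)] != n - arch$utr3_length) {
    stop("utr3_length inconsistent with last ORF end")
  }
  if (is.null(arch$stop_codon)) arch$stop_codon <- "UAA"
  if (!arch$stop_codon %in% STOP_CODONS) stop("invalid stop_codon")
  if (!is.null(arch$slippery)) {
    sp <- as.integer(arch$slippery$position)
    hept <- arch$slippery$heptamer
    if (nchar(hept) != 7L) stop("slippery heptamer must be 7 nt")
    if (sp <= starts[1] || sp + 6L > ends[1] - 3L) {
      stop("slippery site must lie inside ORF1, upstream of its stop")
    }
    if (is.null(arch$pseudoknot)) stop("slippery site declared without pseudoknot")
    pk <- arch$pseudoknot
    pk_len <- 2L * pk$stem1_len + 2L * pk$stem2_len +
      pk$loop1_extra + pk$loop2_len
    pk_end <- pk$start + pk_len - 1L
    if (pk$start <= sp + 6L) stop("pseudoknot must start downstream of the slippery site")
    if (pk_end > ends[1]) stop("pseudoknot must lie inside ORF1")
    spacer_len <- pk$start - (sp + 7L)
    if (!is.null(arch$spacer)) {
      if (nchar(arch$spacer) != spacer_len) {
        stop("spacer sequence length must equal pseudoknot start - slippery end - 1")
      }
      if (grepl("U|T", toupper(arch$spacer))) {
        stop("spacer sequence must avoid U so the planted cassette is stop-free in every frame")
      }
    }
    if (!is.null(arch$fusion)) {
      mfs <- as.integer(arch$fusion$minus_frame_start)
      if ((sp - mfs) %% 3L != 0L) {
        stop("minus_frame_start not congruent with the slippery site (-1 frame)")
      }
      if (length(arch$orfs) >= 2L && (starts[2] - mfs) %% 3L != 0L) {
        stop("minus_frame_start not congruent with the downstream ORF frame")
      }
      if (mfs >= sp) stop("minus_frame_start must precede the slippery site")
    }
  }
  if (is.null(arch$min_orf_length)) arch$min_orf_length <- 300L
  for (m in arch$mutations) {
    if (m$position < 1L || m$position > n) stop("mutation position outside genome")
    if (!m$effect %in% c("utr", "intergenic", "silent", "nonsynonymous")) {
      stop("unknown mutation effect class '", m$effect, "'")
    }
  }
  structure(arch, class = "genome_architecture")
}

# Planted base assignments implied by an architecture: named integer
# positions -> bases. These are never touched by the repair loop.
planted_bases <- function(arch) {
  plant <- character(0)
  put <- function(plant, pos, seqstr) {
    bases <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    plant[as.character(seq(pos, length.out = length(bases)))] <- bases
    plant
  }
  stop_c <- arch$stop_codon
  for (o in arch$orfs) {
    plant <- put(plant, o$start, START_CODON)
    plant <- put(plant, o$end - 2L, stop_c)
  }
  # fence stop upstream of the first ORF in its own frame, so the planted
  # AUG is the 5'-most start after an in-frame stop
  o1 <- arch$orfs[[1]]
  if (o1$start > 3L) plant <- put(plant, o1$start - 3L, "UAA")
  if (!is.null(arch$slippery)) {
    sp <- as.integer(arch$slippery$position)
    plant <- put(plant, sp, toupper(chartr("T", "U", arch$slippery$heptamer)))
    pk <- arch$pseudoknot
    if (!is.null(arch$spacer)) plant <- put(plant, sp + 7L, toupper(arch$spacer))
    s1a <- paste(rep(c("G", "G", "C"), length.out = pk$stem1_len), collapse = "")
    s2a <- paste(rep(c("G", "C"), length.out = pk$stem2_len), collapse = "")
    pk_seq <- paste0(
      s1a, s2a, strrep("A", pk$loop1_extra),
      revcomp_rna(s1a), strrep("A", pk$loop2_len), revcomp_rna(s2a)
    )
    plant <- put(plant, pk$start, pk_seq)
    # short A guard after the pseudoknot so planted stems cannot be
    # extended by chance complementarity in the background
    pk_end <- pk$start + nchar(pk_seq) - 1L
    if (pk_end + 2L <= arch$total_length) plant <- put(plant, pk_end + 1L, "AA")
    if (!is.null(arch$fusion)) {
      mfs <- as.integer(arch$fusion$minus_frame_start)
      # -1-frame fence stop immediately upstream of the declared stop-free
      # stretch
      if (mfs > 3L) plant <- put(plant, mfs - 3L, "UAA")
    }
  }
  plant
}

#' Generate a genome realizing an architecture
#'
#' Constraint satisfaction works by plant-fill-repair: all declared
#' elements (start/stop codons, frame fences, the frameshift cassette) are
#' planted verbatim; the remaining positions are filled with uniform
#' random bases; then a repair loop rechecks every constraint and redraws
#' only free (unplanted) positions until the genome is clean or a retry
#' cap is hit. Constraints: no internal stop in either ORF frame; the -1
#' fusion frame stop-free (and AUG-free) from `minus_frame_start` to the
#' downstream ORF; codons carrying planted silent mutations must admit a
#' synonymous change; no unplanted ORF of `min_orf_length` or more in any
#' plus-strand frame; and the frameshift detector must recover the planted
#' cassette uniquely (chance competitor elements in the background are
#' redrawn).
#'
#' @param arch A `genome_architecture` (see [tktv1_architecture()],
#'   [read_architecture()]).
#' @param seed Integer seed; output is a deterministic function of
#'   (architecture, seed).
#' @param max_retries Repair iteration cap (default 1000).
#' @param id Record id of the generated genome.
#' @return A [genome_record()].
#' @export
generate_genome <- function(arch, seed, max_retries = 1000L,
                            id = NULL) {
  arch <- validate_architecture(unclass(arch))
  if (is.null(id)) id <- if (!is.null(arch$name)) arch$name else "synthetic-genome"
  n <- as.integer(arch$total_length)
  plant <- planted_bases(arch)
  plant_pos <- as.integer(names(plant))
  is_planted <- rep(FALSE, n)
  is_planted[plant_pos] <- TRUE
  seq_str <- with_seed(seed, {
    chars <- sample(RNA_BASES, n, replace = TRUE)
    chars[plant_pos] <- unname(plant)
    clean <- FALSE
    for (iter in seq_len(max_retries)) {
      v <- first_violation(chars, arch)
      if (is.null(v)) {
        clean <- TRUE
        break
      }
      free <- v$positions[!is_planted[v$positions]]
      if (!length(free)) {
        stop(
          "unsatisfiable architecture: constraint '", v$what,
          "' involves only planted positions (",
          paste(v$positions, collapse = ","), ")"
        )
      }
      if (!is.null(v$force)) {
        # targeted edit (e.g. insert a stop to break a spurious ORF)
        chars[v$positions] <- v$force
      } else {
        chars[free] <- sample(RNA_BASES, length(free), replace = TRUE)
      }
    }
    if (!clean) {
      stop(
        "constraint satisfaction failed after ", max_retries,
        " repair iterations; last violated constraint: '",
        first_violation(chars, arch)$what, "'"
      )
    }
    paste(chars, collapse = "")
  })
  genome_record(id, seq_str)
}

# Find the first violated constraint, returning NULL when clean or a list
# (what, positions [, force]) describing what to redraw.
first_violation <- function(chars, arch) {
  n <- length(chars)
  codon_at <- function(p) paste0(chars[p], chars[p + 1L], chars[p + 2L])
  # 1. no internal stop inside any declared ORF frame
  for (o in arch$orfs) {
    starts <- seq.int(o$start, o$end - 5L, 3L)
    cods <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    bad <- which(cods %in% STOP_CODONS)
    if (length(bad)) {
      p <- starts[bad[1]]
      return(list(what = paste0("internal stop in ", o$name %||% "ORF"),
                  positions = p:(p + 2L)))
    }
  }
  # 2. -1 fusion frame: stop-free and AUG-free between minus_frame_start
  #    and the downstream ORF start
  if (!is.null(arch$fusion) && length(arch$orfs) >= 2L) {
    mfs <- as.integer(arch$fusion$minus_frame_start)
    o2s <- as.integer(arch$orfs[[2]]$start)
    starts <- seq.int(mfs, o2s - 3L, 3L)
    cods <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    bad <- which(cods %in% c(STOP_CODONS, START_CODON))
    if (length(bad)) {
      p <- starts[bad[1]]
      return(list(
        what = "stop or AUG in the stop-free -1 fusion frame",
        positions = p:(p + 2L)
      ))
    }
  }
  # 3. planted silent mutations must be realizable (codon not AUG/UGG)
  for (m in arch$mutations) {
    if (!identical(m$effect, "silent")) next
    o <- Filter(function(o) m$position >= o$start && m$position <= o$end, arch$orfs)
    if (!length(o)) next
    o <- o[[1]]
    cstart <- o$start + 3L * ((m$position - o$start) %/% 3L)
    if (codon_at(cstart) %in% c("AUG", "UGG")) {
      return(list(
        what = paste0("no synonymous change possible at position ", m$position),
        positions = cstart:(cstart + 2L)
      ))
    }
  }
  # 4. no spurious ORF of min_orf_length or more
  planted_orfs <- lapply(arch$orfs, function(o) c(o$start, o$end))
  found <- orf_coords(chars, as.integer(arch$min_orf_length))
  extra <- Filter(
    function(h) !any(vapply(planted_orfs, function(p) all(p == h), logical(1))),
    found
  )
  if (length(extra)) {
    h <- extra[[1]]
    fix <- break_orf_edit(chars, h, arch)
    if (is.null(fix)) {
      return(list(
        what = paste0("unbreakable spurious ORF [", h[1], ", ", h[2], "]"),
        positions = h[1]:(h[1] + 2L)
      ))
    }
    return(fix)
  }
  # 5. the frameshift cassette must be recovered uniquely by the detector
  if (!is.null(arch$slippery)) {
    v <- prf_recovery_violation(chars, arch)
    if (!is.null(v)) return(v)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Choose an edit that breaks a spurious ORF: turn a free in-frame codon in
# its interior into a stop codon without violating the local frame
# constraints of the architecture. Returns a violation-style list with a
# forced replacement, or NULL when no safe edit exists.
break_orf_edit <- function(chars, hit, arch) {
  plant <- planted_bases(arch)
  plant_pos <- as.integer(names(plant))
  cand_starts <- seq.int(hit[1] + 3L, hit[2] - 5L, 3L)
  cand_starts <- sample(cand_starts) # randomized but seeded by caller
  for (p in cand_starts) {
    pos <- p:(p + 2L)
    if (any(pos %in% plant_pos)) next
    for (sc in sample(STOP_CODONS)) {
      trial <- chars
      trial[pos] <- strsplit(sc, "", fixed = TRUE)[[1]]
      if (edit_frame_safe(trial, pos, arch)) {
        return(list(
          what = paste0("spurious ORF [", hit[1], ", ", hit[2], "]"),
          positions = pos, force = strsplit(sc, "", fixed = TRUE)[[1]]
        ))
      }
    }
  }
  NULL
}

# Check only the frame constraints local to an edited window (fast guard
# used when breaking spurious ORFs).
edit_frame_safe <- function(chars, pos, arch) {
  lo <- min(pos) - 2L
  hi <- max(pos) + 2L
  for (o in arch$orfs) {
    if (hi < o$start || lo > o$end) next
    starts <- seq.int(o$start, o$end - 5L, 3L)
    starts <- starts[starts + 2L >= lo & starts <= hi]
    for (p in starts) {
      if (paste0(chars[p], chars[p + 1L], chars[p + 2L]) %in% STOP_CODONS) {
        return(FALSE)
      }
    }
  }
  if (!is.null(arch$fusion) && length(arch$orfs) >= 2L) {
    mfs <- as.integer(arch$fusion$minus_frame_start)
    o2s <- as.integer(arch$orfs[[2]]$start)
    starts <- seq.int(mfs, o2s - 3L, 3L)
    starts <- starts[starts + 2L >= lo & starts <= hi]
    for (p in starts) {
      if (paste0(chars[p], chars[p + 1L], chars[p + 2L]) %in%
        c(STOP_CODONS, START_CODON)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Verify that detect_prf() on the current sequence recovers the planted
# cassette; when a background competitor wins, return its free positions
# for redrawing.
prf_recovery_violation <- function(chars, arch) {
  g <- genome_record("candidate", paste(chars, collapse = ""))
  o1 <- arch$orfs[[1]]
  orf1 <- new_orf_annotation(g, o1$start, o1$end, name = "ORF1")
  sig <- suppressWarnings(detect_prf(g, orf1))
  sp <- as.integer(arch$slippery$position)
  pk <- arch$pseudoknot
  pk_end <- pk$start + 2L * pk$stem1_len + 2L * pk$stem2_len +
    pk$loop1_extra + pk$loop2_len - 1L
  ok <- sig$complete &&
    sig$slippery$region$start == sp &&
    sig$pseudoknot$region$start == pk$start &&
    sig$pseudoknot$region$end == pk_end
  if (ok) return(NULL)
  pos <- integer(0)
  if (!is.null(sig$slippery)) {
    pos <- c(pos, sig$slippery$region$start:sig$slippery$region$end)
  }
  if (!is.null(sig$pseudoknot)) {
    for (arm in c(sig$pseudoknot$stem1, sig$pseudoknot$stem2)) {
      pos <- c(pos, arm$start:arm$end)
    }
  }
  if (!length(pos)) {
    # nothing to redraw here: the cassette itself failed, which planted
    # bases should make impossible
    return(list(what = "planted frameshift cassette not detected",
                positions = sp:(sp + 6L)))
  }
  list(what = "background competitor outranks the planted cassette",
       positions = sort(unique(pos)))
}

#' Mutate a genome at planted positions with declared coding effects
#'
#' Applies one substitution per specification. `silent` specs pick a
#' seeded random base keeping the codon's amino acid; `nonsynonymous`
#' specs pick a base changing it (never into a stop codon); `utr` /
#' `intergenic` specs pick any different base. The coding frame is taken
#' from the genome's own annotation ([find_orfs()]).
#'
#' @param genome A [genome_record()].
#' @param mutation_specs List of `list(position =, effect =)` entries;
#'   effects in `utr`, `intergenic`, `silent`, `nonsynonymous`.
#' @param seed Integer seed for the (deterministic) base draws.
#' @param min_length_nt Passed to [find_orfs()].
#' @param id Id for the mutant record (default: reference id + "-mut").
#' @return A [genome_record()] differing from `genome` at exactly the
#'   specified positions.
#' @export
generate_mutant <- function(genome, mutation_specs, seed,
                            min_length_nt = 300L, id = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(id)) id <- paste0(genome$id, "-mut")
  arch <- derive_architecture(genome, find_orfs(genome, min_length_nt))
  chars <- genome_chars(genome)
  tab <- rna_codon_table()
  with_seed(seed, {
    for (m in mutation_specs) {
      pos <- as.integer(m$position)
      if (pos < 1L || pos > genome$length) stop("mutation position ", pos, " outside genome")
      loc <- locate_position(pos, arch)
      ref <- chars[pos]
      if (m$effect %in% c("utr", "intergenic")) {
        if (!is.null(loc$orf)) {
          stop("position ", pos, " lies in ", loc$label, ", not a non-coding region")
        }
        alt <- sample(setdiff(RNA_BASES, ref), 1L)
      } else {
        if (is.null(loc$orf)) {
          stop("position ", pos, " is non-coding; cannot apply a ", m$effect, " change")
        }
        ostart <- loc$orf$region$start
        off <- pos - ostart
        cstart <- ostart + 3L * (off %/% 3L)
        cpos <- off %% 3L + 1L
        codon <- paste0(chars[cstart], chars[cstart + 1L], chars[cstart + 2L])
        cands <- setdiff(RNA_BASES, ref)
        aa_of <- vapply(cands, function(b) {
          alt_codon <- codon
          substr(alt_codon, cpos, cpos) <- b
          unname(tab[alt_codon])
        }, character(1))
        ref_aa <- unname(tab[codon])
        keep <- if (identical(m$effect, "silent")) {
          cands[aa_of == ref_aa]
        } else {
          cands[aa_of != ref_aa & aa_of != "*"]
        }
        if (!length(keep)) {
          stop(
            "no ", m$effect, " substitution exists at position ", pos,
            " (codon ", codon, ", position ", cpos, ")"
          )
        }
        alt <- if (length(keep) == 1L) keep else sample(keep, 1L)
      }
      chars[pos] <- alt
    }
    genome_record(id, paste(chars, collapse = ""))
  })
}

#' Generate a synthetic coat-protein homolog pair
#'
#' Builds a reference protein carrying a single conserved histidine at a
#' given position and a query that is identical except for an N-terminal
#' insertion, so the conserved residue shifts by a known offset. Used to
#' exercise [align_pair()] + [map_residue()] the way conserved catalytic
#' residues are located across totivirus coat proteins.
#'
#' @param seed Integer seed.
#' @param ref_length Reference protein length (default 300 aa).
#' @param his_position Position of the conserved His in the reference
#'   (default 154).
#' @param insertion_length Length of the query's extra N-terminal segment
#'   (default 5).
#' @return List with `reference`, `query` (amino-acid strings) and
#'   `query_his` (expected His position in the query).
#' @export
generate_cp_pair <- function(seed, ref_length = 300L, his_position = 154L,
                             insertion_length = 5L) {
  stopifnot(his_position >= 1L, his_position <= ref_length)
  alphabet <- setdiff(names(AA_AVG_MASS), "H")
  with_seed(seed, {
    ref <- sample(alphabet, ref_length, replace = TRUE)
    ref[his_position] <- "H"
    ins <- sample(alphabet, insertion_length, replace = TRUE)
    list(
      reference = paste(ref, collapse = ""),
      query = paste(c(ins, ref), collapse = ""),
      query_his = his_position + insertion_length
    )
  })
}
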