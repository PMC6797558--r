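# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Deliberately naive: per-position walks and
# nested loops, no shared code with R/.

ORACLE_STOPS <- c("UAA", "UAG", "UGA")

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
  collapse = ""
)

# Enumerate every AUG in every plus-strand frame, walk codon by codon to
# the next in-frame stop, then keep the 5'-most AUG per (frame, stop).
oracle_orfs <- function(sequence, min_length_nt) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  found <- list()
  p <- 1L
  while (p <= n - 2L) {
    if (chars[p] == "A" && chars[p + 1L] == "U" && chars[p + 2L] == "G") {
      q <- p + 3L
      while (q <= n - 2L) {
        cod <- paste0(chars[q], chars[q + 1L], chars[q + 2L])
        if (cod %in% ORACLE_STOPS) {
          found[[length(found) + 1L]] <- c(start = p, end = q + 2L)
          break
        }
        q <- q + 3L
      }
    }
    p <- p + 1L
  }
  if (!length(found)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, found)
  # maximality: smallest start per (frame, stop end)
  key <- paste(m[, 1] %% 3L, m[, 2])
  keep <- !duplicated(key) # first occurrence has smallest start (scan order)
  m <- m[keep, , drop = FALSE]
  m <- m[m[, 2] - m[, 1] + 1L >= min_length_nt, , drop = FALSE]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

oracle_pair_score <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AU", "UA")) return(-2)
  if (key %in% c("GU", "UG")) return(-1)
  0
}

# Naive nested-loop enumeration of H-type pseudoknots on a window string.
# Returns a data.frame of tuples (window-relative coordinates) comparable
# with the package enumeration after sorting.
oracle_pseudoknots <- function(sequence, min_stem = 3L, max_loop = 20L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  helix_run <- function(i, j) {
    k <- 0L
    while (i + k < j - k && oracle_pair_score(chars[i + k], chars[j - k]) < 0) {
      k <- k + 1L
    }
    k
  }
  helix_efe <- function(i, j, k) {
    s <- 0
    for (t in 0:(k - 1L)) s <- s + oracle_pair_score(chars[i + t], chars[j - t])
    s
  }
  rows <- list()
  for (i1 in seq_len(n)) {
    for (j1 in seq_len(n)) {
      if (j1 <= i1) next
      r1 <- helix_run(i1, j1)
      if (r1 < min_stem) next
      for (k1 in min_stem:r1) {
        lo <- i1 + k1
        hi <- j1 - k1
        if (hi < lo) next
        for (i2 in lo:hi) {
          if (i2 - lo > max_loop) next
          j2hi <- min(n, j1 + 1L + max_loop + (hi - i2 + 1L))
          if (j1 + 1L > j2hi) next
          for (j2 in (j1 + 1L):j2hi) {
            r2 <- helix_run(i2, j2)
            if (r2 < min_stem) next
            for (k2 in min_stem:r2) {
              if (i2 + k2 - 1L > hi) next # 5' arm must stay in loop1
              if (j2 - k2 + 1L <= j1) next # 3' arm must clear stem1
              l1 <- i2 - lo
              l2 <- hi - (i2 + k2 - 1L)
              l3 <- (j2 - k2 + 1L) - j1 - 1L
              if (l1 < 0L || l1 > max_loop) next
              if (l2 < 0L || l2 > max_loop) next
              if (l3 < 0L || l3 > max_loop) next
              rows[[length(rows) + 1L]] <- data.frame(
                i1 = i1, j1 = j1, k1 = k1, i2 = i2, j2 = j2, k2 = k2,
                l1 = l1, l2 = l2, l3 = l3,
                efe = helix_efe(i1, j1, k1) + helix_efe(i2, j2, k2)
              )
            }
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      i1 = integer(0), j1 = integer(0), k1 = integer(0), i2 = integer(0),
      j2 = integer(0), k2 = integer(0), l1 = integer(0), l2 = integer(0),
      l3 = integer(0), efe = numeric(0)
    ))
  }
  do.call(rbind, rows)
}

# Canonical form for comparing candidate sets from the two enumerators.
pk_canonical <- function(df) {
  df <- df[order(df$i1, df$j1, df$k1, df$i2, df$j2, df$k2), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("i1", "j1", "k1", "i2", "j2", "k2", "l1", "l2", "l3", "efe")]
}

# Cubic-time global affine-gap alignment score: a gap of length L costs
# open + L * ext, matches scored with the given matrix.
oracle_align_score <- function(q, r, mat, open, ext) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  rc <- strsplit(r, "", fixed = TRUE)[[1]]
  n <- length(qc)
  m <- length(rc)
  S <- matrix(-Inf, n + 1L, m + 1L)
  S[1, 1] <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0L && j == 0L) next
      best <- -Inf
      if (i > 0L && j > 0L) best <- S[i, j] + mat[qc[i], rc[j]]
      if (i > 0L) {
        best <- max(best, max(S[seq_len(i), j + 1L] - (open + ext * (i:1))))
      }
      if (j > 0L) {
        best <- max(best, max(S[i + 1L, seq_len(j)] - (open + ext * (j:1))))
      }
      S[i + 1L, j + 1L] <- best
    }
  }
  S[n + 1L, m + 1L]
}

random_protein <- function(n) {
  aa <- c(
    "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
    "F", "P", "S", "T", "W", "Y", "V"
  )
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
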