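# Independent oracles used across the suite. These deliberately take
# different algorithmic routes than the package code they check.

# Exhaustive global alignment score by recursive enumeration of all
# alignments with affine gap runs (open + extend * run_length). Only for
# tiny strings.
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 4, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {  # gap in b
      open <- if (state == "gb") 0 else gap_open
      best <- max(best, -(open + gap_extend) + rec(i + 1, j, "gb"))
    }
    if (j <= length(bv)) {  # gap in a
      open <- if (state == "ga") 0 else gap_open
      best <- max(best, -(open + gap_extend) + rec(i, j + 1, "ga"))
    }
    best
  }
  rec(1, 1, "m")
}

# SSR oracle by plain position-by-position scanning: at every start, count
# repeat units by direct block comparison, keeping only left-maximal tracts
# at their leftmost phase. Deliberately loop-based and unoptimized -- a
# different route than the package's vectorized comparison-shift scan.
brute_ssr_scan <- function(sequence, min_mono = 8, min_multi = 5, max_unit = 6) {
  x <- strsplit(toupper(sequence), "")[[1]]
  L <- length(x)
  period_of <- function(motif) {
    k <- nchar(motif)
    for (p in seq_len(k)) {
      if (k %% p == 0 &&
          motif == paste(rep(substr(motif, 1, p), k / p), collapse = "")) {
        return(p)
      }
    }
    k
  }
  block <- function(s, k) if (s < 1 || s + k - 1 > L) NULL else x[s:(s + k - 1)]
  cands <- list()
  for (k in seq_len(max_unit)) {
    if (L < 2 * k) break
    s <- 1L
    while (s + 2L * k - 1L <= L) {
      unit <- block(s, k)
      if (!identical(unit, block(s + k, k))) { s <- s + 1L; next }
      # tract start must be left-maximal: the base before must break period
      if (s > 1L && x[s - 1L] == x[s - 1L + k]) { s <- s + 1L; next }
      u <- 2L
      while (identical(unit, block(s + u * k, k))) u <- u + 1L
      motif <- paste(unit, collapse = "")
      min_units <- if (k == 1) min_mono else min_multi
      if (period_of(motif) == k && u >= min_units) {
        cands[[length(cands) + 1]] <- data.frame(
          motif = motif, unit_length = k, start = s - 1L,
          units = u, length = u * k, stringsAsFactors = FALSE
        )
      }
      s <- s + 1L  # overlapping tracts of the same period can share bases
    }
  }
  if (length(cands) == 0) {
    return(data.frame(motif = character(), unit_length = integer(),
                      start = integer(), units = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, cands)
  out <- out[order(-out$length, out$start, out$unit_length), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1):nrow(out)) {
        if (!keep[j]) next
        if (out$start[j] < out$start[i] + out$length[i] &&
            out$start[i] < out$start[j] + out$length[j]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Mann-Whitney U by direct pair counting: wins + half ties.
pair_count_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

random_dna_str <- function(n, at = 0.6) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
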