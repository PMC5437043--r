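# Lexicographically smallest rotation of a motif ("TA" -> "AT").
canonical_rotation <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(motif)
  rots <- vapply(seq_len(n), function(i) {
    paste0(substr(motif, i, n), substr(motif, 1, i - 1))
  }, character(1))
  min(rots)
}

# TRUE if the motif is primitive (its minimal period equals its length),
# so e.g. "AA" and "ATAT" are rejected in favor of their shorter unit.
is_primitive_motif <- function(motif) {
  n <- nchar(motif)
  if (n == 1) return(TRUE)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 && motif == strrep(substr(motif, 1, p), n / p)) return(FALSE)
  }
  TRUE
}

#' Detect simple sequence repeats (SSRs)
#'
#' Finds maximal perfect tandem repeats of 1..`max_unit` bp motifs. A repeat
#' qualifies if it has at least `min_mono` units (mononucleotide) or
#' `min_multi` units (2..`max_unit` bp motifs). Non-primitive motifs (e.g.
#' "AA", "ATAT") are never reported, and overlapping reports are collapsed
#' to the longest span, so a mononucleotide run inside a reported
#' dinucleotide repeat is not re-reported.
#'
#' @param sequence An A/C/G/T string.
#' @param min_mono Minimum units for mononucleotide SSRs (default 8).
#' @param min_multi Minimum units for multi-nucleotide SSRs (default 5).
#' @param max_unit Longest motif considered, default 6 bp.
#' @return A tibble: `motif` (as observed), `motif_class` (canonical
#'   rotation), `unit_length`, `start` (0-based), `units`, `length` (bp).
#' @export
find_ssrs <- function(sequence, min_mono = 8, min_multi = 5, max_unit = 6) {
  sequence <- toupper(sequence)
  x <- seq_chars(sequence)
  L <- length(x)
  cands <- list()
  for (k in seq_len(max_unit)) {
    if (L < 2 * k) break
    # comparison-shift scan: x[i] == x[i + k] marks period-k tracts; a
    # maximal TRUE run of length m starting at i is a tract of m + k bases,
    # reported at its leftmost phase
    eq <- x[seq_len(L - k)] == x[seq_len(L - k) + k]
    runs <- true_runs(eq)
    for (ri in seq_len(nrow(runs))) {
      s <- runs$start[ri] + 1L              # 1-based tract start
      tract_len <- (runs$end[ri] - runs$start[ri]) + k
      units <- tract_len %/% k
      if (units < 2) next
      motif <- paste(x[s:(s + k - 1)], collapse = "")
      if (!is_primitive_motif(motif)) next
      min_units <- if (k == 1) min_mono else min_multi
      if (units < min_units) next
      cands[[length(cands) + 1]] <- tibble::tibble(
        motif = motif, motif_class = canonical_rotation(motif),
        unit_length = k, start = s - 1L, units = as.integer(units),
        length = as.integer(units * k)
      )
    }
  }
  if (length(cands) == 0) {
    return(tibble::tibble(motif = character(), motif_class = character(),
                          unit_length = integer(), start = integer(),
                          units = integer(), length = integer()))
  }
  out <- dplyr::bind_rows(cands)
  # collapse overlaps: keep longer spans first (ties: leftmost, shorter unit)
  out <- dplyr::arrange(out, dplyr::desc(.data$length), .data$start,
                        .data$unit_length)
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
  dplyr::arrange(out[keep, , drop = FALSE], .data$start)
}

# Locate a flank (allowing mismatches) in a sequence; returns the 0-based
# start of the best (fewest-mismatch, leftmost) hit or NA.
locate_flank <- function(flank, sequence, max_mismatch) {
  if (!nzchar(flank) || nchar(sequence) < nchar(flank)) return(NA_integer_)
  hits <- Biostrings::matchPattern(flank, Biostrings::DNAString(sequence),
                                   max.mismatch = max_mismatch)
  # drop hits whose view extends past the subject (possible with mismatches)
  st <- Biostrings::start(hits); en <- Biostrings::end(hits)
  keep <- st >= 1L & en <= nchar(sequence)
  if (!any(keep)) return(NA_integer_)
  st <- st[keep]
  fl <- seq_chars(flank)
  mm <- vapply(st, function(s) {
    sum(seq_chars(substr(sequence, s, s + length(fl) - 1L)) != fl)
  }, double(1))
  as.integer(st[which.min(mm)] - 1L)
}

# Maximal run of `motif` units starting at or shortly after `from`
# (0-based); returns c(start, units) or NULL.
motif_run_at <- function(sequence, motif, from, slop = 5L) {
  k <- nchar(motif)
  n <- nchar(sequence)
  best <- NULL
  for (s in from:min(from + slop, n - k)) {
    u <- 0L
    while (s + (u + 1L) * k <= n &&
           substr(sequence, s + u * k + 1L, s + (u + 1L) * k) == motif) {
      u <- u + 1L
    }
    if (u > 0L) { best <- c(s, u); break }
  }
  best
}

#' Cross-species SSR records from syntenic loci
#'
#' Detects SSRs in the reference taxon's sequence of each locus, then
#' matches each site across taxa by its 20-bp flanking context (allowing a
#' few mismatches per flank) and counts repeat units per taxon. A record is
#' kept iff the SSR is present (units at or above the class minimum) in at
#' least `min_species` taxa; it is polymorphic iff present taxa disagree on
#' the repeat count.
#'
#' @param loci Tibble from [extract_syntenic_loci()].
#' @param min_species Presence threshold (default 15).
#' @param reference_id Taxon providing the reference sites and flanks;
#'   default first taxon seen in the loci.
#' @param min_mono,min_multi,max_unit As in [find_ssrs()].
#' @param flank Flank length in bp (default 20).
#' @param max_mismatch Mismatches tolerated per flank (default 2).
#' @return A tibble: `locus`, `region`, `location`, `motif`, `motif_class`,
#'   `unit_length`, `ref_start`, `flank_left`, `flank_right`, `n_present`,
#'   `polymorphic`, `units_min`, `units_max`, and list-column
#'   `units_by_taxon`.
#' @export
cross_species_ssrs <- function(loci, min_species = 15, reference_id = NULL,
                               min_mono = 8, min_multi = 5, max_unit = 6,
                               flank = 20L, max_mismatch = 2L) {
  all_taxa <- unique(unlist(lapply(loci$seqs, names)))
  if (is.null(reference_id)) reference_id <- all_taxa[1]
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    seqs <- loci$seqs[[i]]
    ref_seq <- seqs[[reference_id]]
    if (is.null(ref_seq)) return(NULL)
    ssrs <- find_ssrs(ref_seq, min_mono, min_multi, max_unit)
    if (nrow(ssrs) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(ssrs)), function(j) {
      s <- ssrs$start[j]; e <- s + ssrs$length[j]
      fl <- seq_slice(ref_seq, max(0L, s - flank), s)
      fr <- seq_slice(ref_seq, e, min(nchar(ref_seq), e + flank))
      if (nchar(fl) < 8) return(NULL)  # too little context to anchor
      min_units <- if (ssrs$unit_length[j] == 1) min_mono else min_multi
      units <- purrr::map_int(seqs, function(sq) {
        pos <- locate_flank(fl, sq, max_mismatch)
        if (is.na(pos)) return(NA_integer_)
        run <- motif_run_at(sq, ssrs$motif[j], pos + nchar(fl))
        if (is.null(run)) return(0L)
        # verify the right flank sits after the run
        if (nchar(fr) >= 8) {
          tail_at <- run[1] + run[2] * ssrs$unit_length[j]
          window <- seq_slice(sq, tail_at, min(nchar(sq), tail_at + nchar(fr) + 10L))
          if (is.na(locate_flank(fr, window, max_mismatch))) return(NA_integer_)
        }
        run[2]
      })
      present <- !is.na(units) & units >= min_units
      if (sum(present) < min_species) return(NULL)
      tibble::tibble(
        locus = loci$locus[i], region = loci$region[i],
        location = loci$type[i],
        motif = ssrs$motif[j], motif_class = ssrs$motif_class[j],
        unit_length = ssrs$unit_length[j], ref_start = s,
        flank_left = fl, flank_right = fr,
        n_present = sum(present),
        polymorphic = length(unique(units[present])) > 1,
        units_min = min(units[present]), units_max = max(units[present]),
        units_by_taxon = list(units[present])
      )
    })
  })
}

#' Tally SSR records by motif class, region, and location
#'
#' Motif classes are mono A/T, mono C/G, di, and higher. Works on
#' [cross_species_ssrs()] output and on the printed-table fixture loaded by
#' [read_ssr_table()] (any tibble with `motif`, `unit_length`, `region`,
#'   `location`).
#'
#' @param records SSR record tibble.
#' @return A list of three tibbles: `motif` (`class`, `n`), `region`, and
#'   `location`, each tallying to `nrow(records)`.
#' @export
ssr_summary <- function(records) {
  cls <- with(records, ifelse(
    unit_length == 1,
    ifelse(substr(motif, 1, 1) %in% c("A", "T"), "mono A/T", "mono C/G"),
    ifelse(unit_length == 2, "di", "higher")
  ))
  lvl_m <- c("mono A/T", "mono C/G", "di", "higher")
  tally <- function(x, levels) {
    tibble::tibble(value = factor(x, levels = levels)) |>
      dplyr::count(.data$value, .drop = FALSE) |>
      dplyr::rename(class = "value")
  }
  list(
    motif = tally(cls, lvl_m),
    region = tally(records$region, c("LSC", "SSC", "IR")),
    location = tally(records$location, c("spacer", "intron"))
  )
}

#' Read a printed polymorphic-SSR table
#'
#' Loads the transcription of a published SSR table (shipped at
#' `system.file("extdata", "table3_ssrs.tsv", package = "plastohotspot")`)
#' and parses each "SSR Type" string such as `"T × (8–14)"` or
#' `"AT × 6"` into motif, unit length, and the printed unit range.
#'
#' @param path Path to the TSV (defaults to the shipped fixture).
#' @return A tibble with the printed columns plus `motif`, `unit_length`,
#'   `units_min`, `units_max`.
#' @export
read_ssr_table <- function(path = system.file("extdata", "table3_ssrs.tsv",
                                              package = "plastohotspot")) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ty <- gsub("×", "x", tbl$ssr_type)
  m <- stringr::str_match(ty, "^\\s*([ACGT]+)\\s*x\\s*\\(?(\\d+)(?:[-–](\\d+))?\\)?\\s*$")
  if (anyNA(m[, 1])) {
    abort(sprintf("unparseable SSR type string: '%s'",
                  tbl$ssr_type[which(is.na(m[, 1]))[1]]))
  }
  tbl$motif <- m[, 2]
  tbl$unit_length <- nchar(m[, 2])
  tbl$units_min <- as.integer(m[, 3])
  tbl$units_max <- as.integer(ifelse(is.na(m[, 4]), m[, 3], m[, 4]))
  tbl
}
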