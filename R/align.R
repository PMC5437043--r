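#' Alignment scoring scheme
#'
#' Defaults for the global aligner: match +1, mismatch -1, gap open -4,
#' gap extend -0.5. `N` scores as a mismatch against every base.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   given as positive magnitudes for the gap terms).
#' @return A list used by [global_align()].
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = 4, gap_extend = 0.5) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  list(matrix = m, gap_open = gap_open, gap_extend = gap_extend)
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch global alignment (affine gaps) of two nucleotide
#' sequences, computed by `Biostrings::pairwiseAlignment`. Traceback is
#' deterministic, so identical inputs always give identical alignments.
#'
#' @param seq_a,seq_b Non-empty A/C/G/T/N strings.
#' @param scoring An [align_scoring()] list.
#' @param id_a,id_b Optional sequence labels carried on the result.
#' @return An object of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `id_a`, `id_b`. Removing the
#'   gaps recovers the inputs exactly.
#' @export
global_align <- function(seq_a, seq_b, scoring = align_scoring(),
                         id_a = "a", id_b = "b") {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("cannot align an empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend
  )
  rows <- finish_global_rows(al, seq_a, seq_b)
  res <- structure(
    list(
      aligned_a = rows$a, aligned_b = rows$b,
      score = Biostrings::score(al),
      id_a = id_a, id_b = id_b
    ),
    class = "pairwise_alignment"
  )
  stopifnot(nchar(res$aligned_a) == nchar(res$aligned_b))
  res
}

# pattern()/subject() drop terminal overhangs (a terminal indel in a global
# alignment); re-attach them so degapping each row recovers the full input.
finish_global_rows <- function(al, seqs_a, seq_b, i = 1L) {
  pa <- unname(as.character(Biostrings::pattern(al)))[i]
  sa <- unname(as.character(Biostrings::subject(al)))[i]
  ps <- Biostrings::start(Biostrings::pattern(al))[i]
  pe <- Biostrings::end(Biostrings::pattern(al))[i]
  ss <- Biostrings::start(Biostrings::subject(al))[i]
  se <- Biostrings::end(Biostrings::subject(al))[i]
  a <- if (length(seqs_a) > 1L) seqs_a[[i]] else seqs_a[[1]]
  b <- seq_b
  na <- nchar(a); nb <- nchar(b)
  list(
    a = paste0(substr(a, 1, ps - 1), strrep("-", ss - 1), pa,
               substr(a, pe + 1, na), strrep("-", nb - se)),
    b = paste0(strrep("-", ps - 1), substr(b, 1, ss - 1), sa,
               strrep("-", na - pe), substr(b, se + 1, nb))
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: %d columns, score %.1f\n",
              x$id_a, x$id_b, nchar(x$aligned_a), x$score))
  invisible(x)
}

# Vectorized global alignment of many patterns against one subject.
# Returns a list of pairwise_alignment objects in input order.
global_align_batch <- function(patterns, subject, scoring = align_scoring(),
                               id_subject = "b") {
  if (length(patterns) == 0) return(list())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unlist(patterns, use.names = FALSE)),
    Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend
  )
  sc <- Biostrings::score(al)
  ids <- names(patterns) %||% rep("a", length(patterns))
  pvec <- unlist(patterns, use.names = FALSE)
  pa <- unname(as.character(Biostrings::pattern(al)))
  sa <- unname(as.character(Biostrings::subject(al)))
  ps <- Biostrings::start(Biostrings::pattern(al))
  pe <- Biostrings::end(Biostrings::pattern(al))
  ss <- Biostrings::start(Biostrings::subject(al))
  se <- Biostrings::end(Biostrings::subject(al))
  na <- nchar(pvec); nb <- nchar(subject)
  lapply(seq_along(patterns), function(i) {
    structure(
      list(
        aligned_a = paste0(substr(pvec[i], 1, ps[i] - 1), strrep("-", ss[i] - 1),
                           pa[i], substr(pvec[i], pe[i] + 1, na[i]),
                           strrep("-", nb - se[i])),
        aligned_b = paste0(strrep("-", ps[i] - 1), substr(subject, 1, ss[i] - 1),
                           sa[i], strrep("-", na[i] - pe[i]),
                           substr(subject, se[i] + 1, nb)),
        score = sc[i], id_a = ids[i], id_b = id_subject
      ),
      class = "pairwise_alignment"
    )
  })
}

# Character-vector view of the two rows.
aln_rows <- function(aln) {
  list(a = seq_chars(aln$aligned_a), b = seq_chars(aln$aligned_b))
}

# Column range [first, last] (1-based) after trimming terminal gap runs:
# from the first column where both rows have a base to the last such column.
# Returns NULL if no column survives.
aln_core_range <- function(a, b) {
  both <- a != "-" & b != "-"
  if (!any(both)) return(NULL)
  c(min(which(both)), max(which(both)))
}

#' Extract InDel events from a pairwise alignment against a reference
#'
#' Each maximal run of gap characters in one row is one event: a gap in the
#' reference row is an insertion (the taxon has extra sequence), a gap in the
#' taxon row a deletion. Terminal gap runs at either end of the alignment are
#' excluded. `ref_position` is the 0-based position of the event's left edge
#' in the ungapped reference (for insertions, the reference base just right
#' of the inserted block).
#'
#' @param aln A `pairwise_alignment` with the taxon as row a and the
#'   reference as row b.
#' @param reference Optional `plastome_record` of the reference: when given,
#'   events gain a `region` column (LSC/SSC/IR, from the left edge) and an
#'   `ndh_related` flag (event interval intersects an annotated ndh* feature
#'   extended by `ndh_window` bp on each side; zero-width insertions use the
#'   two flanking bases).
#' @param ref_offset 0-based offset of the aligned reference slice within the
#'   full reference sequence (used when aligning region by region).
#' @param ndh_window Flank in bp for NDH-relatedness, default 50.
#' @return A tibble: `kind` (insertion/deletion), `ref_position`, `length`,
#'   and optionally `region`, `ndh_related`.
#' @export
extract_indel_events <- function(aln, reference = NULL, ref_offset = 0L,
                                 ndh_window = 50L) {
  rows <- aln_rows(aln)
  a <- rows$a; b <- rows$b
  core <- aln_core_range(a, b)
  out <- tibble::tibble(kind = character(), ref_position = integer(),
                        length = integer())
  if (!is.null(core)) {
    keep <- seq(core[1], core[2])
    a <- a[keep]; b <- b[keep]
    # cumulative count of reference bases before each column
    ref_before <- cumsum(b != "-") - (b != "-")
    ins <- true_runs(b == "-")   # gap in reference row
    del <- true_runs(a == "-")   # gap in taxon row
    out <- dplyr::bind_rows(
      tibble::tibble(kind = "insertion",
                     ref_position = as.integer(ref_before[ins$start + 1L]),
                     length = as.integer(ins$end - ins$start)),
      tibble::tibble(kind = "deletion",
                     ref_position = as.integer(ref_before[del$start + 1L]),
                     length = as.integer(del$end - del$start))
    )
    out <- dplyr::arrange(out, .data$ref_position, .data$kind)
  }
  out$ref_position <- out$ref_position + as.integer(ref_offset)
  if (!is.null(reference)) {
    out$region <- region_class(vapply(out$ref_position, function(p) {
      region_of_position(reference, p)
    }, character(1)))
    out$ndh_related <- event_ndh_related(out, reference, ndh_window)
  }
  out
}

# TRUE where the event interval (deletions: [pos, pos+len); insertions:
# flanking bases [pos-1, pos+1)) intersects an ndh* feature +/- window bp.
event_ndh_related <- function(events, reference, ndh_window = 50L) {
  ndh <- reference$features[grepl("^ndh", reference$features$name, ignore.case = TRUE), ]
  if (nrow(events) == 0) return(logical(0))
  if (nrow(ndh) == 0) return(rep(FALSE, nrow(events)))
  ev_start <- ifelse(events$kind == "insertion",
                     pmax(events$ref_position - 1L, 0L), events$ref_position)
  ev_end <- ifelse(events$kind == "insertion",
                   events$ref_position + 1L,
                   events$ref_position + events$length)
  vapply(seq_len(nrow(events)), function(i) {
    any(ev_start[i] < ndh$end + ndh_window & ev_end[i] > ndh$start - ndh_window)
  }, logical(1))
}
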