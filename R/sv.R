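# Ordered "anchor" features of a record: exons of multi-exon genes plus
# genes/tRNAs/rRNAs without exons, sorted by start. Adjacent anchor pairs
# define intergenic spacers; same-name adjacent exons define introns.
anchor_features <- function(rec) {
  ft <- rec$features
  exon_names <- unique(ft$name[ft$kind == "exon"])
  keep <- ft$kind == "exon" |
    (ft$kind %in% c("gene", "tRNA", "rRNA") & !(ft$name %in% exon_names))
  dplyr::arrange(ft[keep, , drop = FALSE], .data$start, .data$end)
}

# Adjacent-pair table for one record: locus key, display name, type,
# interval of the intervening sequence, strand rule.
candidate_loci <- function(rec) {
  an <- anchor_features(rec)
  n <- nrow(an)
  if (n < 2) {
    return(tibble::tibble(key = character(), locus = character(),
                          type = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  left <- an[-n, ]; right <- an[-1, ]
  intron <- left$name == right$name
  # number repeated introns of the same gene
  display <- ifelse(intron, paste(left$name, "intron"),
                    paste0(left$name, "-", right$name))
  dup <- stats::ave(seq_len(n - 1), display, FUN = seq_along)
  display <- ifelse(intron & dup > 1, paste0(display, dup), display)
  strand <- ifelse(intron, left$strand,
                   ifelse(left$strand == "-" & right$strand == "-", "-", "+"))
  tibble::tibble(
    key = paste0(pmin(left$name, right$name), "|", pmax(left$name, right$name),
                 "|", ifelse(intron, dup, 0L)),
    locus = display,
    type = ifelse(intron, "intron", "spacer"),
    start = left$end, end = right$start, strand = strand
  )
}

#' Extract syntenic intergenic and intronic loci
#'
#' For every adjacent gene/exon pair in the reference gene order the
#' intervening spacer is taken per taxon, and for every multi-exon gene each
#' intron. A locus is kept iff its reference sequence is at least
#' `min_length` bp and it is present (same flanks, same order) in at least
#' two taxa. Sequences are normalized to the reference orientation
#' (minus-strand loci are reverse complemented). Loci duplicated by the two
#' IR copies are reported once, from the lower-coordinate copy.
#'
#' @param records Named list of `plastome_record`s.
#' @param reference_id Taxon whose gene order and sequence define the locus
#'   catalogue; defaults to the first record.
#' @param min_length Minimum reference length in bp (default 150).
#' @return A tibble: `locus`, `type` (spacer/intron), `region` (LSC/SSC/IR),
#'   `ref_length`, `gc_percent` (reference sequence), `n_taxa` present, and
#'   a list-column `seqs` of named per-taxon sequences.
#' @export
extract_syntenic_loci <- function(records, reference_id = names(records)[1],
                                  min_length = 150L) {
  ref <- records[[reference_id]]
  if (is.null(ref)) abort(sprintf("reference taxon '%s' not found", reference_id))
  cand <- candidate_loci(ref)
  cand <- cand[cand$end - cand$start >= min_length, , drop = FALSE]
  cand <- cand[!duplicated(cand$key), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(locus = character(), type = character(),
                          region = character(), ref_length = integer(),
                          gc_percent = double(), n_taxa = integer(),
                          seqs = list()))
  }
  per_taxon <- lapply(records, function(rec) {
    ct <- candidate_loci(rec)
    ct <- ct[!duplicated(ct$key), , drop = FALSE]
    ct
  })
  rows <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    key <- cand$key[i]
    seqs <- list()
    for (tx in names(records)) {
      ct <- per_taxon[[tx]]
      j <- match(key, ct$key)
      if (is.na(j)) next
      s <- feature_sequence(records[[tx]], ct$start[j], ct$end[j], ct$strand[j])
      if (nzchar(s)) seqs[[tx]] <- s
    }
    ref_seq <- seqs[[reference_id]]
    tibble::tibble(
      locus = cand$locus[i], type = cand$type[i],
      region = region_class(region_of_position(ref, cand$start[i])),
      ref_length = cand$end[i] - cand$start[i],
      gc_percent = if (is.null(ref_seq)) NA_real_ else gc_percent(ref_seq),
      n_taxa = length(seqs),
      seqs = list(seqs)
    )
  })
  dropped <- rows$n_taxa < 2
  if (any(dropped)) {
    warn(sprintf("dropping %d locus/loci present in fewer than 2 taxa: %s",
                 sum(dropped), paste(rows$locus[dropped], collapse = ", ")))
  }
  rows[!dropped, , drop = FALSE]
}

#' Pairwise sequence variability (SV)
#'
#' Globally aligns the two sequences, trims terminal gap runs, and computes
#' SV = (mutations + InDel events) / (conserved sites + mutations + InDel
#' events) x 100, where conserved/mutated sites are identical/mismatching
#' non-gap columns and an InDel event is a maximal internal gap run in
#' either row.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @param scoring An [align_scoring()] list.
#' @return SV in percent, or NA (with a warning) if nothing remains after
#'   trimming.
#' @export
pairwise_sv <- function(seq_a, seq_b, scoring = align_scoring()) {
  # canonical argument order: SV is symmetric, but gap placement in a
  # tie-broken traceback need not be; fix the orientation once
  if (seq_a > seq_b) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  aln <- global_align(seq_a, seq_b, scoring = scoring)
  sv_from_alignment(aln$aligned_a, aln$aligned_b)
}

# SV from an already-aligned pair of gapped rows.
sv_from_alignment <- function(row_a, row_b) {
  a <- seq_chars(row_a); b <- seq_chars(row_b)
  core <- aln_core_range(a, b)
  if (is.null(core)) {
    warn("alignment empty after terminal-gap trimming; SV undefined")
    return(NA_real_)
  }
  keep <- seq(core[1], core[2])
  a <- a[keep]; b <- b[keep]
  non_gap <- a != "-" & b != "-"
  conserved <- sum(non_gap & a == b)
  mutations <- sum(non_gap & a != b)
  events <- nrow(true_runs(a == "-")) + nrow(true_runs(b == "-"))
  denom <- conserved + mutations + events
  if (denom == 0) {
    warn("no scorable columns after trimming; SV undefined")
    return(NA_real_)
  }
  100 * (mutations + events) / denom
}

#' Mean SV per locus over all taxon pairs
#'
#' Averages pairwise SV over all unordered distinct pairs of the taxon
#' subset in which both sequences are present, ranks loci by mean SV
#' (descending, ties broken by locus name), and carries GC content of the
#' reference sequence.
#'
#' @param loci Tibble from [extract_syntenic_loci()].
#' @param taxa_subset Character vector of taxa to use; default all taxa
#'   appearing in the loci.
#' @param scoring An [align_scoring()] list.
#' @return A tibble: `locus`, `type`, `region`, `mean_sv`, `gc_percent`,
#'   `n_pairs`, `rank`, sorted by rank.
#' @export
mean_sv_table <- function(loci, taxa_subset = NULL, scoring = align_scoring()) {
  all_taxa <- unique(unlist(lapply(loci$seqs, names)))
  if (is.null(taxa_subset)) taxa_subset <- all_taxa
  if (length(taxa_subset) < 2) abort("need at least 2 taxa")
  rows <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    seqs <- loci$seqs[[i]]
    present <- intersect(taxa_subset, names(seqs))
    if (length(present) < 2) {
      return(tibble::tibble(locus = loci$locus[i], mean_sv = NA_real_,
                            n_pairs = 0L))
    }
    svs <- unlist(lapply(seq_along(present)[-1], function(j) {
      alns <- global_align_batch(seqs[present[seq_len(j - 1)]],
                                 seqs[[present[j]]], scoring = scoring)
      vapply(alns, function(al) sv_from_alignment(al$aligned_a, al$aligned_b),
             double(1))
    }))
    tibble::tibble(locus = loci$locus[i],
                   mean_sv = mean(svs, na.rm = TRUE),
                   n_pairs = sum(!is.na(svs)))
  })
  excluded <- rows$n_pairs == 0
  if (any(excluded)) {
    warn(sprintf("excluding %d locus/loci present in <2 taxa of the subset",
                 sum(excluded)))
  }
  out <- loci |>
    dplyr::select("locus", "type", "region", "gc_percent") |>
    dplyr::inner_join(rows[!excluded, ], by = "locus") |>
    dplyr::arrange(dplyr::desc(.data$mean_sv), .data$locus) |>
    dplyr::mutate(rank = dplyr::row_number())
  dplyr::select(out, "locus", "type", "region", "mean_sv", "gc_percent",
                "n_pairs", "rank")
}

#' Correlation of SV with GC content
#'
#' Spearman correlation of per-locus mean SV against GC content.
#'
#' @param sv_records Tibble from [mean_sv_table()].
#' @return One-row tibble (`statistic`, `p_value`, `method`, `n`).
#' @export
sv_gc_correlation <- function(sv_records) {
  if (nrow(sv_records) < 3) abort("need at least 3 loci")
  spearman(sv_records$mean_sv, sv_records$gc_percent)
}

#' Rank stability of top hotspots under taxon subsampling
#'
#' Draws nested random taxon subsets of the given sizes (each group extends
#' the previous one), recomputes the mean-SV ranking within each group, and
#' reports the rank of each reference top locus, or NA when it falls outside
#' the top `n_reference_top`.
#'
#' @param loci Tibble from [extract_syntenic_loci()].
#' @param group_sizes Integer vector of subset sizes (default
#'   c(2, 5, 10, 15, 20, 25), truncated to the available taxa).
#' @param n_reference_top How many top loci (from the full taxon set) to
#'   track, default 10.
#' @param seed Optional RNG seed for the nested draw.
#' @param scoring An [align_scoring()] list.
#' @return A tibble: `locus`, `reference_rank`, `group_size`, `rank`
#'   (NA when outside the top `n_reference_top`).
#' @export
rank_stability <- function(loci, group_sizes = c(2, 5, 10, 15, 20, 25),
                           n_reference_top = 10, seed = NULL,
                           scoring = align_scoring()) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- sort(unique(unlist(lapply(loci$seqs, names))))
  if (any(group_sizes > length(taxa))) {
    abort(sprintf("group size %d exceeds the %d available taxa",
                  max(group_sizes), length(taxa)))
  }
  full <- mean_sv_table(loci, taxa, scoring = scoring)
  top <- head(full, n_reference_top)
  perm <- sample(taxa)
  purrr::map_dfr(sort(group_sizes), function(g) {
    sub <- perm[seq_len(g)]
    tab <- mean_sv_table(loci, sub, scoring = scoring)
    ranks <- tab$rank[match(top$locus, tab$locus)]
    ranks[!is.na(ranks) & ranks > n_reference_top] <- NA_integer_
    tibble::tibble(locus = top$locus, reference_rank = top$rank,
                   group_size = g, rank = as.integer(ranks))
  })
}

#' Write a rank-stability table in wide (printed-table) form
#'
#' One row per tracked locus, one column per group size; ranks outside the
#' tracked top are written as the sentinel "-".
#'
#' @param stability Tibble from [rank_stability()].
#' @param path Output TSV path.
#' @return The wide tibble, invisibly.
#' @export
write_rank_stability <- function(stability, path) {
  wide <- stability |>
    dplyr::mutate(rank = ifelse(is.na(.data$rank), "-", as.character(.data$rank))) |>
    tidyr::pivot_wider(names_from = "group_size", values_from = "rank",
                       names_prefix = "n") |>
    dplyr::arrange(.data$reference_rank)
  write_table(wide, path)
  invisible(wide)
}
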