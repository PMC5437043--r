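#' Multiple alignment of one locus by center-star progressive merging
#'
#' The center sequence is the taxon minimizing the summed pairwise alignment
#' cost (negative score) against all others; every other sequence is aligned
#' pairwise to the center and the pairwise alignments are merged
#' column-wise under the "once a gap, always a gap" rule.
#'
#' @param seqs Named list/vector of sequences (one per taxon); at least 3.
#' @param locus Locus name carried on the result.
#' @param scoring An [align_scoring()] list.
#' @param all_taxa Optional taxon universe: taxa listed here but missing
#'   from `seqs` get all-gap rows.
#' @return A `locus_msa`: list with `locus`, `taxa`, `rows` (named character
#'   vector of equal-length gapped strings), `length`. Degapping any row
#'   recovers that taxon's input sequence.
#' @export
build_locus_msa <- function(seqs, locus = "locus", scoring = align_scoring(),
                            all_taxa = NULL) {
  seqs <- as.list(seqs)
  seqs <- seqs[vapply(seqs, nzchar, logical(1))]
  if (length(seqs) < 3) abort("need the locus present in at least 3 taxa")
  taxa <- names(seqs)
  n <- length(taxa)
  # choose the center: taxon with maximal summed pairwise score
  total <- setNames(numeric(n), taxa)
  alns <- list()
  for (j in 2:n) {
    batch <- global_align_batch(seqs[seq_len(j - 1)], seqs[[j]],
                                scoring = scoring, id_subject = taxa[j])
    for (i in seq_len(j - 1)) {
      al <- batch[[i]]
      total[i] <- total[i] + al$score
      total[j] <- total[j] + al$score
      alns[[paste(taxa[i], taxa[j])]] <- al
    }
  }
  center <- taxa[which.max(total)]
  others <- setdiff(taxa, center)
  master_center <- seq_chars(seqs[[center]])
  rows <- list()
  rows[[center]] <- master_center
  for (tx in others) {
    key_ab <- paste(center, tx); key_ba <- paste(tx, center)
    al <- alns[[key_ab]]
    if (!is.null(al)) {
      c_row <- seq_chars(al$aligned_a); t_row <- seq_chars(al$aligned_b)
    } else {
      al <- alns[[key_ba]]
      c_row <- seq_chars(al$aligned_b); t_row <- seq_chars(al$aligned_a)
    }
    merged <- merge_into_master(rows, master_center, c_row, t_row, tx)
    rows <- merged$rows
    master_center <- merged$master_center
  }
  width <- length(master_center)
  if (!is.null(all_taxa)) {
    for (tx in setdiff(all_taxa, names(rows))) {
      rows[[tx]] <- rep("-", width)
    }
    rows <- rows[intersect(all_taxa, names(rows))]
  }
  structure(
    list(
      locus = locus,
      taxa = names(rows),
      rows = vapply(rows, paste, character(1), collapse = ""),
      length = width
    ),
    class = "locus_msa"
  )
}

# Merge one pairwise alignment (center row c_row / taxon row t_row) into the
# running master alignment, inserting all-gap columns where the two gapped
# center strings disagree ("once a gap, always a gap").
merge_into_master <- function(rows, master_center, c_row, t_row, taxon) {
  i <- 1L; j <- 1L
  out_master <- list()
  out_new <- character(0)
  cols_master <- integer(0)  # for each output column: master col index or NA
  nm <- length(master_center); nc <- length(c_row)
  res_master_cols <- integer(0)
  new_row <- character(0)
  while (i <= nm || j <= nc) {
    mi <- if (i <= nm) master_center[i] else NULL
    cj <- if (j <= nc) c_row[j] else NULL
    if (!is.null(mi) && !is.null(cj) && ((mi != "-") == (cj != "-"))) {
      res_master_cols <- c(res_master_cols, i)
      new_row <- c(new_row, t_row[j])
      i <- i + 1L; j <- j + 1L
    } else if (!is.null(mi) && (is.null(cj) || mi == "-")) {
      # master has a gap column the new alignment lacks
      res_master_cols <- c(res_master_cols, i)
      new_row <- c(new_row, "-")
      i <- i + 1L
    } else {
      # new alignment has a gap in the center the master lacks
      res_master_cols <- c(res_master_cols, NA_integer_)
      new_row <- c(new_row, t_row[j])
      j <- j + 1L
    }
  }
  width <- length(res_master_cols)
  new_rows <- lapply(rows, function(r) {
    out <- rep("-", width)
    keep <- !is.na(res_master_cols)
    out[keep] <- r[res_master_cols[keep]]
    out
  })
  new_master <- rep("-", width)
  keep <- !is.na(res_master_cols)
  new_master[keep] <- master_center[res_master_cols[keep]]
  # center positions introduced by the new alignment stay gaps in the master
  new_rows[[taxon]] <- new_row
  list(rows = new_rows, master_center = new_master)
}

#' @export
print.locus_msa <- function(x, ...) {
  cat(sprintf("<locus_msa> %s: %d taxa x %d columns\n",
              x$locus, length(x$taxa), x$length))
  invisible(x)
}

# Gapped rows as a character matrix (taxa x columns).
msa_matrix <- function(msa) {
  do.call(rbind, lapply(msa$rows, seq_chars))
}

#' Concatenate locus alignments into a supermatrix
#'
#' Column-wise concatenation over the union of taxa (or an explicit taxon
#' order); taxa absent from a member locus are padded with all-gap blocks.
#' The partition table (1-based column ranges per locus) is attached as the
#' `"partitions"` attribute.
#'
#' @param msas List of `locus_msa` objects.
#' @param taxa_order Optional character vector fixing row order.
#' @return A `locus_msa` whose `locus` is the joined member names.
#' @export
concatenate_msas <- function(msas, taxa_order = NULL) {
  if (length(msas) == 0) abort("no alignments to concatenate")
  if (is.null(taxa_order)) {
    taxa_order <- unique(unlist(lapply(msas, function(m) m$taxa)))
  }
  parts <- list()
  pos <- 0L
  rows <- setNames(rep("", length(taxa_order)), taxa_order)
  for (m in msas) {
    block <- setNames(rep(strrep("-", m$length), length(taxa_order)), taxa_order)
    common <- intersect(taxa_order, names(m$rows))
    block[common] <- m$rows[common]
    rows <- paste0(rows, block)
    parts[[length(parts) + 1]] <- tibble::tibble(
      locus = m$locus, start = pos + 1L, end = pos + m$length
    )
    pos <- pos + m$length
  }
  out <- structure(
    list(
      locus = paste(vapply(msas, function(m) m$locus, character(1)), collapse = "+"),
      taxa = taxa_order,
      rows = setNames(rows, taxa_order),
      length = pos
    ),
    class = "locus_msa"
  )
  attr(out, "partitions") <- dplyr::bind_rows(parts)
  out
}
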