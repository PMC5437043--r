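#' Construct a plastome record
#'
#' A plastome record bundles one taxon's forward-strand sequence with its
#' feature annotations and quadripartite region boundaries. Coordinates are
#' 0-based half-open internally; GFF3 input/output converts from/to the
#' standard 1-based closed convention.
#'
#' @param taxon_id Single string.
#' @param sequence Uppercase A/C/G/T/N string.
#' @param features Tibble with columns `name`, `kind` (gene, exon, intron,
#'   tRNA, rRNA), `start`, `end` (0-based half-open), `strand` (+/-),
#'   `pseudo` (logical; truncated/pseudogenized, used for NDH residues).
#' @param region_bounds Tibble with columns `region` (LSC, IRb, SSC, IRa),
#'   `start`, `end`; the four intervals must be disjoint, ordered
#'   LSC, IRb, SSC, IRa, tile the full sequence, and the two IRs must have
#'   equal length.
#' @return An object of class `plastome_record`.
#' @export
plastome_record <- function(taxon_id, sequence, features, region_bounds) {
  rec <- structure(
    list(
      taxon_id = taxon_id,
      sequence = toupper(sequence),
      features = tibble::as_tibble(features),
      region_bounds = tibble::as_tibble(region_bounds)
    ),
    class = "plastome_record"
  )
  validate_plastome_record(rec)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf(
    "<plastome_record> %s: %d bp, %d features, regions %s\n",
    x$taxon_id, nchar(x$sequence), nrow(x$features),
    paste(sprintf("%s=%d", x$region_bounds$region,
                  x$region_bounds$end - x$region_bounds$start), collapse = " ")
  ))
  invisible(x)
}

#' Validate a plastome record's invariants
#'
#' Checks that region intervals are disjoint, ordered LSC, IRb, SSC, IRa,
#' tile the sequence, that IRb and IRa have equal length, and that every
#' feature lies within the sequence bounds.
#'
#' @param rec A `plastome_record`.
#' @return The record, invisibly usable in a pipe; errors on violation.
#' @export
validate_plastome_record <- function(rec) {
  len <- nchar(rec$sequence)
  if (!grepl("^[ACGTN]*$", rec$sequence)) {
    abort(sprintf("taxon %s: sequence contains characters outside A/C/G/T/N", rec$taxon_id))
  }
  rb <- rec$region_bounds
  if (!identical(rb$region, c("LSC", "IRb", "SSC", "IRa"))) {
    abort(sprintf("taxon %s: regions must be ordered LSC, IRb, SSC, IRa", rec$taxon_id))
  }
  if (rb$start[1] != 0 || rb$end[4] != len ||
      any(rb$start[-1] != rb$end[-4]) || any(rb$end <= rb$start)) {
    abort(sprintf("taxon %s: region intervals do not tile the sequence (length %d)", rec$taxon_id, len))
  }
  ir_b <- rb$end[2] - rb$start[2]
  ir_a <- rb$end[4] - rb$start[4]
  if (ir_b != ir_a) {
    abort(sprintf("taxon %s: IRb length %d != IRa length %d", rec$taxon_id, ir_b, ir_a))
  }
  ft <- rec$features
  if (nrow(ft) > 0) {
    bad <- which(ft$start < 0 | ft$end > len | ft$end <= ft$start)
    if (length(bad) > 0) {
      abort(sprintf("taxon %s: feature '%s' out of sequence bounds [0, %d)",
                    rec$taxon_id, ft$name[bad[1]], len))
    }
    if (!all(ft$kind %in% c("gene", "exon", "intron", "tRNA", "rRNA"))) {
      abort(sprintf("taxon %s: unknown feature kind", rec$taxon_id))
    }
  }
  rec
}

# Which region (LSC/IRb/SSC/IRa) contains a 0-based position.
region_of_position <- function(rec, pos) {
  rb <- rec$region_bounds
  i <- which(pos >= rb$start & pos < rb$end)
  if (length(i) == 0) return(NA_character_)
  rb$region[i[1]]
}

# Collapse IRb/IRa to the single class "IR" used in result tables.
region_class <- function(region) replace(region, region %in% c("IRa", "IRb"), "IR")

empty_features <- function() {
  tibble::tibble(name = character(), kind = character(),
                 start = integer(), end = integer(),
                 strand = character(), pseudo = logical())
}

#' Read annotated plastomes from FASTA + GFF3
#'
#' Sequences come from a FASTA file, features and region boundaries from a
#' GFF3 file whose `seqid` column matches the FASTA ids. Region boundaries
#' are carried as four features of type `region` named LSC, IRb, SSC, IRa.
#' All record invariants are checked.
#'
#' @param fasta_path Path to a FASTA file, one sequence per taxon.
#' @param annotation_path Path to a GFF3 file covering every FASTA id.
#' @return A named list of `plastome_record`s, in FASTA order.
#' @export
read_genomes <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  gff <- read_gff3(annotation_path)
  recs <- lapply(seq_along(seqs), function(i) {
    id <- ids[i]
    g <- gff[gff$seqid == id, , drop = FALSE]
    if (nrow(g) == 0) {
      abort(sprintf("no annotation found for taxon '%s'", id))
    }
    reg <- g[g$type == "region", , drop = FALSE]
    if (nrow(reg) != 4) {
      abort(sprintf("taxon %s: expected 4 region features, found %d", id, nrow(reg)))
    }
    reg <- reg[match(c("LSC", "IRb", "SSC", "IRa"), reg$name), , drop = FALSE]
    if (anyNA(reg$name)) abort(sprintf("taxon %s: region features must be named LSC/IRb/SSC/IRa", id))
    ft <- g[g$type != "region", , drop = FALSE]
    plastome_record(
      taxon_id = id,
      sequence = as.character(seqs[[i]]),
      features = tibble::tibble(
        name = ft$name, kind = ft$type,
        start = ft$start - 1L, end = ft$end,
        strand = ft$strand, pseudo = ft$pseudo
      ),
      region_bounds = tibble::tibble(
        region = reg$name, start = reg$start - 1L, end = reg$end
      )
    )
  })
  names(recs) <- ids
  recs
}

#' Write annotated plastomes to FASTA + GFF3
#'
#' Inverse of [read_genomes()]: 0-based half-open internal coordinates are
#' converted back to 1-based closed GFF3 coordinates.
#'
#' @param records List of `plastome_record`s.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the list of records.
#' @export
write_genomes <- function(records, fasta_path, gff3_path) {
  seqs <- Biostrings::DNAStringSet(vapply(records, function(r) r$sequence, character(1)))
  names(seqs) <- vapply(records, function(r) r$taxon_id, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- purrr::map_dfr(records, function(r) {
    dplyr::bind_rows(
      tibble::tibble(
        seqid = r$taxon_id, type = "region",
        start = r$region_bounds$start + 1L, end = r$region_bounds$end,
        strand = "+", name = r$region_bounds$region, pseudo = FALSE
      ),
      tibble::tibble(
        seqid = r$taxon_id, type = r$features$kind,
        start = r$features$start + 1L, end = r$features$end,
        strand = r$features$strand, name = r$features$name,
        pseudo = r$features$pseudo
      )
    )
  })
  write_gff3(rows, gff3_path)
  invisible(records)
}

# Minimal GFF3 reader for the subset this package emits: standard 9 columns,
# attributes Name= and pseudo=. Returns a tibble with 1-based coordinates.
read_gff3 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(seqid = character(), type = character(),
                          start = integer(), end = integer(),
                          strand = character(), name = character(),
                          pseudo = logical()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad) > 0) abort(sprintf("malformed GFF3 line %d in %s", bad[1], path))
  m <- do.call(rbind, parts)
  attr_field <- function(attrs, key) {
    v <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    v
  }
  tibble::tibble(
    seqid = m[, 1], type = m[, 3],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
    strand = m[, 7],
    name = attr_field(m[, 9], "Name"),
    pseudo = !is.na(attr_field(m[, 9], "pseudo")) &
      attr_field(m[, 9], "pseudo") == "true"
  )
}

write_gff3 <- function(rows, path) {
  attrs <- paste0("ID=", rows$seqid, ":", rows$name, ":", rows$start,
                  ";Name=", rows$name,
                  ifelse(rows$pseudo, ";pseudo=true", ""))
  body <- paste(rows$seqid, "plastohotspot", rows$type, rows$start, rows$end,
                ".", rows$strand, ".", attrs, sep = "\t")
  readr::write_lines(c("##gff-version 3", body), path)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Tab-separated UTF-8 with a header line; [read_table_tsv()] reproduces the
#' tibble exactly (column types are re-inferred, so keep types primitive).
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @return `tbl`, invisibly (pipe-friendly).
#' @export
write_table <- function(tbl, path) {
  readr::write_tsv(tibble::as_tibble(tbl), path, na = "NA")
  invisible(tbl)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Extract a feature's sequence from a record, honoring strand.
feature_sequence <- function(rec, start, end, strand = "+") {
  s <- seq_slice(rec$sequence, start, end)
  if (strand == "-") revcomp(s) else s
}
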