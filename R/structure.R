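#' Quadripartite structure summary
#'
#' Region lengths from the record's boundaries, AT content over the whole
#' sequence (Ns ignored), and the total length of retained NDH gene
#' annotations. Truncated (pseudo) NDH residues count with their annotated
#' extents; the IR-duplicated ndhB is counted from one IR copy only.
#'
#' @param records A `plastome_record` or list of them.
#' @return A tibble: `taxon_id`, `total_bp`, `lsc_bp`, `ssc_bp`, `ir_bp`
#'   (one copy), `at_percent`, `ndh_retained_bp`.
#' @export
summarize_structure <- function(records) {
  if (inherits(records, "plastome_record")) records <- list(records)
  purrr::map_dfr(records, function(rec) {
    rb <- rec$region_bounds
    len <- function(region) rb$end[rb$region == region] - rb$start[rb$region == region]
    ndh <- rec$features[grepl("^ndh", rec$features$name, ignore.case = TRUE) &
                        rec$features$kind %in% c("gene", "tRNA", "rRNA"), , drop = FALSE]
    if (nrow(ndh) > 0) {
      # count each IR-duplicated gene once: keep the lower-coordinate copy
      ndh <- ndh |>
        dplyr::group_by(.data$name) |>
        dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
    }
    tibble::tibble(
      taxon_id = rec$taxon_id,
      total_bp = nchar(rec$sequence),
      lsc_bp = len("LSC"),
      ssc_bp = len("SSC"),
      ir_bp = len("IRb"),
      at_percent = at_percent(rec$sequence),
      ndh_retained_bp = if (nrow(ndh) == 0) 0L else sum(ndh$end - ndh$start)
    )
  })
}

#' Changed lengths versus a reference plastome
#'
#' Signed bp differences of total, LSC, SSC, and IR lengths between each
#' taxon and the reference taxon; the reference itself is excluded.
#'
#' @param summaries Tibble from [summarize_structure()] (or a list of
#'   records, summarized on the fly).
#' @param reference_id Taxon id of the reference.
#' @return A tibble: `taxon_id`, `delta_total`, `delta_lsc`, `delta_ssc`,
#'   `delta_ir`.
#' @export
changed_lengths <- function(summaries, reference_id) {
  if (!is.data.frame(summaries)) summaries <- summarize_structure(summaries)
  if (!reference_id %in% summaries$taxon_id) {
    abort(sprintf("reference taxon '%s' not found", reference_id))
  }
  ref <- summaries[summaries$taxon_id == reference_id, ]
  summaries |>
    dplyr::filter(.data$taxon_id != reference_id) |>
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      delta_total = .data$total_bp - ref$total_bp,
      delta_lsc = .data$lsc_bp - ref$lsc_bp,
      delta_ssc = .data$ssc_bp - ref$ssc_bp,
      delta_ir = .data$ir_bp - ref$ir_bp
    )
}

#' Read a printed quadripartite structure table
#'
#' Loads the transcription of a published genome-characteristics table
#' (shipped at `system.file("extdata", "table1_structure.tsv",
#' package = "plastohotspot")`): per species the total, LSC, SSC and IR
#' (one copy) lengths in bp, AT content and accession.
#'
#' @param path Path to the TSV (defaults to the shipped fixture).
#' @return A tibble with columns `species`, `total_bp`, `lsc_bp`, `ssc_bp`,
#'   `ir_bp`, `at_percent`, `accession`.
#' @export
read_structure_table <- function(path = system.file("extdata", "table1_structure.tsv",
                                                    package = "plastohotspot")) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Structure correlations
#'
#' Spearman correlations of each region's changed length against the
#' changed total length, plus retained-NDH length against total plastome
#' length.
#'
#' @param changed Tibble from [changed_lengths()].
#' @param summaries Tibble from [summarize_structure()] covering the same
#'   taxa (the reference may be present; it is used for the NDH test only).
#' @return A tibble with one row per test: `test`, `statistic`, `p_value`,
#'   `method`, `n`.
#' @export
structure_correlations <- function(changed, summaries) {
  if (nrow(changed) < 3) abort("need at least 3 non-reference taxa")
  res <- dplyr::bind_rows(
    dplyr::mutate(spearman(changed$delta_lsc, changed$delta_total),
                  test = "delta_lsc_vs_delta_total"),
    dplyr::mutate(spearman(changed$delta_ssc, changed$delta_total),
                  test = "delta_ssc_vs_delta_total"),
    dplyr::mutate(spearman(changed$delta_ir, changed$delta_total),
                  test = "delta_ir_vs_delta_total"),
    dplyr::mutate(spearman(summaries$ndh_retained_bp, summaries$total_bp),
                  test = "ndh_retained_vs_total")
  )
  dplyr::select(res, "test", "statistic", "p_value", "method", "n")
}
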