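# Region sequence of a record (one IR copy only, the IRb).
region_sequence <- function(rec, region) {
  rb <- rec$region_bounds
  key <- if (region == "IR") "IRb" else region
  i <- match(key, rb$region)
  seq_slice(rec$sequence, rb$start[i], rb$end[i])
}

#' InDel events of each taxon versus a reference plastome
#'
#' Aligns region by region (LSC with LSC, SSC with SSC, one IR copy with one
#' IR copy) using [global_align()] and extracts maximal-gap-run events with
#' [extract_indel_events()]; events carry region and NDH-relatedness labels
#' taken from the reference annotation.
#'
#' @param records Named list of `plastome_record`s including the reference.
#' @param reference_id Taxon id of the reference.
#' @param scoring An [align_scoring()] list.
#' @param ndh_window NDH-relatedness window in bp.
#' @return A tibble: `taxon_id`, `kind`, `region`, `ref_position`, `length`,
#'   `ndh_related`.
#' @export
indel_events <- function(records, reference_id, scoring = align_scoring(),
                         ndh_window = 50L) {
  if (!reference_id %in% names(records)) {
    abort(sprintf("reference taxon '%s' not found", reference_id))
  }
  ref <- records[[reference_id]]
  rb <- ref$region_bounds
  offsets <- c(LSC = rb$start[rb$region == "LSC"],
               SSC = rb$start[rb$region == "SSC"],
               IR = rb$start[rb$region == "IRb"])
  others <- records[setdiff(names(records), reference_id)]
  purrr::map_dfr(others, function(rec) {
    purrr::map_dfr(c("LSC", "SSC", "IR"), function(region) {
      aln <- global_align(region_sequence(rec, region),
                          region_sequence(ref, region),
                          scoring = scoring,
                          id_a = rec$taxon_id, id_b = reference_id)
      ev <- extract_indel_events(aln, reference = ref,
                                 ref_offset = offsets[[region]],
                                 ndh_window = ndh_window)
      # the aligned slice is a single region; label accordingly
      if (nrow(ev) > 0) ev$region <- region
      ev$taxon_id <- rec$taxon_id
      ev
    })
  }) |>
    dplyr::select("taxon_id", "kind", "region", "ref_position", "length",
                  "ndh_related")
}

#' Per-taxon InDel profile
#'
#' Event counts by region plus the LSC percentage, for each taxon compared
#' against the reference.
#'
#' @param records Named list of records (or a precomputed event tibble via
#'   `events`).
#' @param reference_id Reference taxon id.
#' @param events Optional precomputed result of [indel_events()].
#' @param ... Passed to [indel_events()].
#' @return A tibble: `taxon_id`, `n_total`, `n_lsc`, `n_ssc`, `n_ir`,
#'   `pct_lsc`.
#' @export
indel_profile <- function(records, reference_id, events = NULL, ...) {
  if (is.null(events)) events <- indel_events(records, reference_id, ...)
  taxa <- if (is.list(records) && !is.data.frame(records)) {
    setdiff(names(records), reference_id)
  } else {
    unique(events$taxon_id)
  }
  base <- tibble::tibble(taxon_id = sort(taxa))
  counts <- events |>
    dplyr::count(.data$taxon_id, .data$region) |>
    tidyr::pivot_wider(names_from = "region", values_from = "n", values_fill = 0L)
  for (col in c("LSC", "SSC", "IR")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  base |>
    dplyr::left_join(counts, by = "taxon_id") |>
    dplyr::mutate(dplyr::across(c("LSC", "SSC", "IR"), ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      n_total = .data$LSC + .data$SSC + .data$IR,
      n_lsc = .data$LSC, n_ssc = .data$SSC, n_ir = .data$IR,
      pct_lsc = ifelse(.data$n_total > 0, 100 * .data$n_lsc / .data$n_total, NA_real_)
    )
}

#' Changed length carried by InDels, split by NDH relatedness
#'
#' For each taxon's events, the signed bp difference carried by insertions
#' minus deletions, within the NDH-related and NDH-unrelated classes.
#'
#' @param events Tibble from [indel_events()] (a `taxon_id` column is
#'   optional; without it a single row is returned).
#' @return A tibble: `taxon_id` (if present), `ndh_related_delta`,
#'   `ndh_unrelated_delta`.
#' @export
indel_changed_length <- function(events) {
  signed <- function(ev) {
    sum(ifelse(ev$kind == "insertion", ev$length, -ev$length))
  }
  one <- function(ev) {
    tibble::tibble(
      ndh_related_delta = signed(ev[ev$ndh_related, , drop = FALSE]),
      ndh_unrelated_delta = signed(ev[!ev$ndh_related, , drop = FALSE])
    )
  }
  if (!"taxon_id" %in% names(events)) return(one(events))
  events |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Distribution and correlation tests on InDel profiles
#'
#' Three tests: Mann-Whitney of the LSC event proportion against the pooled
#' SSC and IR proportions; Mann-Whitney of |NDH-unrelated| versus
#' |NDH-related| changed lengths; Spearman of the NDH-unrelated changed
#' length against the changed total plastome length.
#'
#' @param profiles Tibble from [indel_profile()].
#' @param indel_deltas Tibble from [indel_changed_length()] (per taxon).
#' @param changed Tibble from [changed_lengths()] (per taxon, `delta_total`).
#' @return A tibble with one row per test.
#' @export
indel_tests <- function(profiles, indel_deltas, changed) {
  pct_ssc <- 100 * profiles$n_ssc / profiles$n_total
  pct_ir <- 100 * profiles$n_ir / profiles$n_total
  joined <- dplyr::inner_join(indel_deltas, changed, by = "taxon_id")
  res <- dplyr::bind_rows(
    dplyr::mutate(
      mann_whitney_two_sided(profiles$pct_lsc, c(pct_ssc, pct_ir)),
      test = "lsc_pct_vs_ssc_ir_pct"),
    dplyr::mutate(
      mann_whitney_two_sided(abs(joined$ndh_unrelated_delta),
                             abs(joined$ndh_related_delta)),
      test = "abs_unrelated_vs_abs_related_delta"),
    dplyr::mutate(
      spearman(joined$ndh_unrelated_delta, joined$delta_total),
      test = "unrelated_delta_vs_delta_total")
  )
  dplyr::select(res, "test", "statistic", "p_value", "method", "n")
}
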