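#' Enumerate all non-empty hotspot subsets
#'
#' Deterministic order: by subset size, then lexicographically within a
#' size. Guarded at 16 names (65,535 subsets).
#'
#' @param hotspot_names Character vector, 1..16 names.
#' @return A list of character vectors.
#' @export
enumerate_combinations <- function(hotspot_names) {
  k <- length(hotspot_names)
  if (k < 1) abort("need at least one hotspot name")
  if (k > 16) abort("refusing to enumerate subsets of more than 16 hotspots")
  nm <- sort(hotspot_names)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- combn(nm, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Score every hotspot combination by mean bootstrap support
#'
#' Builds one multiple alignment per hotspot locus, then, for every
#' non-empty subset of the hotspots, concatenates the member alignments,
#' infers a bootstrapped NJ tree and records the mean ingroup bootstrap
#' support, the concatenated length and the mean SV of the member loci.
#'
#' @param loci Tibble from [extract_syntenic_loci()].
#' @param sv_table Tibble from [mean_sv_table()] (provides per-locus mean
#'   SV; loci missing from it get NA combo_sv).
#' @param hotspots Character vector of locus names to combine (<= 16);
#'   default the top 10 of `sv_table`.
#' @param outgroups Taxa used to root trees and excluded from the mean BS.
#' @param n_replicates Bootstrap replicates per combination.
#' @param seed Base RNG seed; combination i uses `seed + i`.
#' @param scope Passed to [mean_bs()].
#' @param keep_trees If TRUE, a `tree` list-column of `phylo` objects is
#'   kept (memory-heavy for many combinations).
#' @param scoring An [align_scoring()] list.
#' @return A tibble: `combo` (loci collapsed with "+"), `loci` (list-col),
#'   `k`, `concat_length`, `combo_sv`, `mean_bs` (+ optional `tree`).
#' @export
hotspot_combinations <- function(loci, sv_table,
                                 hotspots = head(sv_table$locus, 10),
                                 outgroups = character(0),
                                 n_replicates = 1000, seed = NULL,
                                 scope = "ingroup", keep_trees = FALSE,
                                 scoring = align_scoring()) {
  if (is.null(seed)) seed <- 0L
  missing <- setdiff(hotspots, loci$locus)
  if (length(missing) > 0) {
    abort(sprintf("hotspot loci not in the locus table: %s",
                  paste(missing, collapse = ", ")))
  }
  taxa <- unique(unlist(lapply(loci$seqs, names)))
  msas <- lapply(hotspots, function(h) {
    build_locus_msa(loci$seqs[[match(h, loci$locus)]], locus = h,
                    scoring = scoring, all_taxa = taxa)
  })
  names(msas) <- hotspots
  sv_of <- setNames(sv_table$mean_sv, sv_table$locus)
  subsets <- enumerate_combinations(hotspots)
  rows <- vector("list", length(subsets))
  trees <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    members <- subsets[[i]]
    concat <- concatenate_msas(msas[members], taxa_order = taxa)
    tree <- bootstrap_tree(concat, n_replicates = n_replicates,
                           seed = seed + i, outgroups = outgroups)
    rows[[i]] <- tibble::tibble(
      combo = paste(members, collapse = "+"),
      loci = list(members),
      k = length(members),
      concat_length = concat$length,
      combo_sv = mean(unname(sv_of[members])),
      mean_bs = mean_bs(tree, outgroups = outgroups, scope = scope)
    )
    if (keep_trees) trees[[i]] <- tree
  }
  out <- dplyr::bind_rows(rows)
  if (keep_trees) out$tree <- trees
  out
}

#' Plateau analysis of mean BS against combination size
#'
#' Per-size mean and SD of the combinations' mean BS, an OLS line of mean
#' BS on combination size fitted over all combinations, and the plateau
#' size: the smallest k whose per-k mean is within `tol` BS points of the
#' maximum per-k mean.
#'
#' @param results Tibble from [hotspot_combinations()].
#' @param tol Plateau tolerance in BS points (default 2).
#' @return A `plateau_analysis` object; see [tidy.plateau_analysis()] and
#'   [glance.plateau_analysis()].
#' @export
plateau_analysis <- function(results, tol = 2) {
  per_k <- results |>
    dplyr::group_by(k = .data$k) |>
    dplyr::summarise(n = dplyr::n(),
                     sd_bs = sd(.data$mean_bs),
                     mean_bs = mean(.data$mean_bs), .groups = "drop") |>
    dplyr::select("k", "n", "mean_bs", "sd_bs") |>
    dplyr::arrange(.data$k)
  fit <- ols_line(results$k, results$mean_bs)
  plateau_k <- min(per_k$k[per_k$mean_bs >= max(per_k$mean_bs) - tol])
  structure(
    list(per_k = per_k, fit = fit, plateau_k = plateau_k, tol = tol,
         n_combinations = nrow(results)),
    class = "plateau_analysis"
  )
}

#' @export
print.plateau_analysis <- function(x, ...) {
  cat(sprintf(
    "<plateau_analysis> %d combinations, k = %d..%d\n  mean BS = %.2f k + %.2f (R^2 = %.3f)\n  plateau at k = %d (mean BS %.1f, tolerance %g)\n",
    x$n_combinations, min(x$per_k$k), max(x$per_k$k),
    x$fit$slope, x$fit$intercept, x$fit$r_squared,
    x$plateau_k, x$per_k$mean_bs[x$per_k$k == x$plateau_k], x$tol
  ))
  invisible(x)
}

#' Correlations of mean BS with combination SV and length
#'
#' Spearman correlations of mean BS against the combination's mean SV and
#' its concatenated length. A constant predictor (e.g. a single-k subset
#' with fixed length) is reported as an NA row rather than an error.
#'
#' @param results Tibble from [hotspot_combinations()].
#' @return A tibble with one row per test.
#' @export
combo_correlations <- function(results) {
  if (nrow(results) < 3) abort("need at least 3 combinations")
  safe <- function(x, y, label) {
    tryCatch(
      dplyr::mutate(spearman(x, y), test = label),
      error = function(e) tibble::tibble(
        statistic = NA_real_, p_value = NA_real_,
        method = "spearman", n = length(x), test = label
      )
    )
  }
  res <- dplyr::bind_rows(
    safe(results$mean_bs, results$combo_sv, "mean_bs_vs_combo_sv"),
    safe(results$mean_bs, results$concat_length, "mean_bs_vs_concat_length")
  )
  dplyr::select(res, "test", "statistic", "p_value", "method", "n")
}

#' Top combinations and the minimal-marker recommendation
#'
#' Sorts by mean BS (descending; ties broken by smaller size then by the
#' loci string) and flags, within the top `n`, the entry with the smallest
#' number of hotspots -- the cost-effective recommendation.
#'
#' @param results Tibble from [hotspot_combinations()].
#' @param n How many top combinations to return (default 10).
#' @return The top rows with an added `recommended` logical column; the
#'   recommended row is also attached as the `"recommendation"` attribute.
#' @export
top_combinations <- function(results, n = 10) {
  ranked <- results |>
    dplyr::arrange(dplyr::desc(.data$mean_bs), .data$k, .data$combo) |>
    head(n)
  min_k <- min(ranked$k)
  rec_idx <- which(ranked$k == min_k)[1]
  ranked$recommended <- seq_len(nrow(ranked)) == rec_idx
  attr(ranked, "recommendation") <- ranked[rec_idx, ]
  ranked
}
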