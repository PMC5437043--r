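test_that("printed structure-table rows satisfy total = LSC + SSC + 2xIR", {
  tab <- read_structure_table()
  expect_equal(nrow(tab), 25)
  resid <- tab$total_bp - (tab$lsc_bp + tab$ssc_bp + 2 * tab$ir_bp)
  # the D. crepidatum row is internally inconsistent as printed: its region
  # lengths sum to one bp more than its printed total (the accession length)
  misprint <- tab$species == "Dendrobium crepidatum"
  expect_equal(resid[!misprint], rep(0L, 24))
  expect_equal(resid[misprint], -1L)
  expect_true(all(tab$at_percent > 62 & tab$at_percent < 63))
})

test_that("structure summaries report lengths, AT content, and NDH retention", {
  rec <- make_toy_record()
  s <- summarize_structure(rec)
  expect_equal(s$total_bp, 400L)
  expect_equal(s$lsc_bp, 200L)
  expect_equal(s$ssc_bp, 40L)
  expect_equal(s$ir_bp, 80L)
  expect_equal(s$total_bp, s$lsc_bp + s$ssc_bp + 2 * s$ir_bp)
  expect_equal(s$ndh_retained_bp, 30L)

  at_rec <- plastome_record(
    taxon_id = "at", sequence = strrep("AT", 200),
    features = plastohotspot:::empty_features(),
    region_bounds = make_toy_record()$region_bounds
  )
  expect_equal(summarize_structure(at_rec)$at_percent, 100)

  # two ndh features of 500 and 250 bp sum; IR-duplicated ndhB counts once
  sim <- shared_sim()
  anc <- sim$ancestor
  ndh <- anc$features[grepl("^ndh", anc$features$name) &
                      anc$features$kind %in% c("gene", "tRNA", "rRNA"), ]
  ndh_once <- ndh[!duplicated(ndh$name), ]
  expect_equal(summarize_structure(anc)$ndh_retained_bp,
               sum(ndh_once$end - ndh_once$start))
})

test_that("changed lengths are exact signed differences versus the reference", {
  sim <- shared_sim()
  summaries <- summarize_structure(sim$records)
  ch <- changed_lengths(summaries, "t01")
  expect_false("t01" %in% ch$taxon_id)
  ref <- summaries[summaries$taxon_id == "t01", ]
  for (i in seq_len(nrow(ch))) {
    s <- summaries[summaries$taxon_id == ch$taxon_id[i], ]
    expect_equal(ch$delta_total[i], s$total_bp - ref$total_bp)
    expect_equal(ch$delta_lsc[i], s$lsc_bp - ref$lsc_bp)
    expect_equal(ch$delta_ssc[i], s$ssc_bp - ref$ssc_bp)
    expect_equal(ch$delta_ir[i], s$ir_bp - ref$ir_bp)
  }
  # a taxon identical to the reference has all-zero deltas
  twin <- summaries[1, ]
  twin$taxon_id <- "twin"
  ch2 <- changed_lengths(dplyr::bind_rows(summaries, twin), "t01")
  expect_equal(unlist(ch2[ch2$taxon_id == "twin", -1]),
               c(delta_total = 0L, delta_lsc = 0L, delta_ssc = 0L, delta_ir = 0L))
  expect_error(changed_lengths(summaries, "nope"), "not found")
})

test_that("structure correlations behave under controlled variation", {
  # only the LSC varies: delta_lsc vs delta_total is a perfect rank match
  lsc <- 8000L + 20L * (0:7)
  ssc <- 1500L + c(0L, 3L, 1L, 5L, 2L, 7L, 4L, 6L)
  ir <- 2750L + c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L)
  base <- tibble::tibble(
    taxon_id = paste0("s", 1:8),
    total_bp = lsc + ssc + 2L * ir,
    lsc_bp = lsc, ssc_bp = ssc, ir_bp = ir,
    at_percent = 62,
    ndh_retained_bp = c(900L, 880L, 910L, 890L, 905L, 895L, 885L, 915L)
  )
  ch <- changed_lengths(base, "s1")
  out <- structure_correlations(ch, base)
  expect_equal(out$statistic[out$test == "delta_lsc_vs_delta_total"], 1)

  # rank invariance: shifting all totals by a constant changes nothing
  base2 <- dplyr::mutate(base, total_bp = total_bp + 5000L)
  out2 <- structure_correlations(changed_lengths(base2, "s1"), base2)
  expect_equal(out$statistic, out2$statistic)

  # ndh lengths shuffled independently of totals: |r| stays small on average
  set.seed(31)
  rs <- replicate(20, {
    b <- dplyr::mutate(base, ndh_retained_bp = sample(ndh_retained_bp))
    structure_correlations(changed_lengths(b, "s1"), b) |>
      dplyr::filter(test == "ndh_retained_vs_total") |>
      dplyr::pull(statistic)
  })
  expect_lt(abs(mean(rs)), 0.3)
})
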