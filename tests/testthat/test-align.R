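test_that("global alignment matches the exhaustive-search oracle on tiny strings", {
  al <- global_align("ACGTACGT", "ACGACGT")
  expect_equal(al$score, brute_align_score("ACGTACGT", "ACGACGT"))
  expect_equal(nchar(al$aligned_a), 8)  # one 1-bp gap in the shorter row
  expect_equal(sum(strsplit(al$aligned_b, "")[[1]] == "-"), 1)

  set.seed(20)
  for (i in 1:10) {
    a <- random_dna_str(sample(4:7, 1))
    b <- random_dna_str(sample(4:7, 1))
    expect_equal(global_align(a, b)$score, brute_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("aligning identical sequences is gap-free at full match score", {
  s <- random_dna_str(50)
  al <- global_align(s, s)
  expect_identical(al$aligned_a, s)
  expect_identical(al$aligned_b, s)
  expect_equal(al$score, 50)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment is symmetric and degapping recovers the inputs", {
  set.seed(21)
  for (i in 1:5) {
    a <- random_dna_str(40); b <- random_dna_str(35)
    ab <- global_align(a, b); ba <- global_align(b, a)
    expect_equal(ab$score, ba$score)
    expect_identical(gsub("-", "", ab$aligned_a), a)
    expect_identical(gsub("-", "", ab$aligned_b), b)
  }
})

test_that("indel events are maximal gap runs with terminal runs excluded", {
  mk <- function(a, b) structure(list(aligned_a = a, aligned_b = b,
                                      id_a = "t", id_b = "ref"),
                                 class = "pairwise_alignment")
  ev <- extract_indel_events(mk("AC---GT", "ACTTAGT"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length, 3L)
  expect_equal(ev$ref_position, 2L)

  # leading overhang in the taxon row is not an event
  ev <- extract_indel_events(mk("----------ACGTACGT", "CCCCCCCCCCACGTACGT"))
  expect_equal(nrow(ev), 0)

  # insertion position points at the reference base right of the block
  ev <- extract_indel_events(mk("ACGTTTACG", "ACG---ACG"))
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$ref_position, 3L)
  expect_equal(ev$length, 3L)

  # adjacent gaps in opposite rows are distinct events
  ev <- extract_indel_events(mk("AC--TTGG", "ACGG--GG"))
  expect_equal(sort(ev$kind), c("deletion", "insertion"))

  # gap-free alignment yields an empty list
  ev <- extract_indel_events(mk("ACGT", "ACGA"))
  expect_equal(nrow(ev), 0)
})

test_that("event extraction recovers planted InDels from ground truth", {
  sim <- shared_sim()
  records <- c(list(ancestor = sim$ancestor), sim$records["t01"])
  ev <- indel_events(records, "ancestor")
  truth <- sim$truth$indels[sim$truth$indels$taxon_id == "t01", ]
  # well-separated planted events of >= 3 bp should reappear
  iso <- truth[truth$length >= 3, ]
  found <- vapply(seq_len(nrow(iso)), function(i) {
    any(ev$kind == iso$kind[i] & ev$region == iso$region[i] &
          abs(ev$ref_position - iso$ref_position[i]) <= 15 &
          abs(ev$length - iso$length[i]) <= 1)
  }, logical(1))
  expect_gt(mean(found), 0.8)
})

test_that("indel profiles count by region and are order-invariant", {
  sim <- shared_sim()
  recs <- c(list(ancestor = sim$ancestor), sim$records[c("t01", "t02")])
  ev <- indel_events(recs, "ancestor")
  prof <- indel_profile(recs, "ancestor", events = ev)
  expect_equal(prof$n_total, prof$n_lsc + prof$n_ssc + prof$n_ir)
  expect_equal(prof$pct_lsc, 100 * prof$n_lsc / prof$n_total)

  recs2 <- recs[c("t02", "ancestor", "t01")]
  prof2 <- indel_profile(recs2, "ancestor")
  expect_equal(as.data.frame(prof2), as.data.frame(prof))

  # a taxon identical to the reference has all-zero counts
  recs3 <- list(ancestor = sim$ancestor, clone = local({
    r <- sim$ancestor; r$taxon_id <- "clone"; r
  }))
  prof3 <- indel_profile(recs3, "ancestor")
  expect_equal(prof3$n_total, 0L)
})

test_that("net event lengths equal the region length differences", {
  sim <- shared_sim()
  recs <- c(list(ancestor = sim$ancestor), sim$records[c("t03", "t07")])
  ev <- indel_events(recs, "ancestor")
  for (tx in c("t03", "t07")) {
    for (r in c("LSC", "SSC", "IR")) {
      sub <- ev[ev$taxon_id == tx & ev$region == r, ]
      net <- sum(sub$length[sub$kind == "insertion"]) -
        sum(sub$length[sub$kind == "deletion"])
      len_tax <- nchar(plastohotspot:::region_sequence(sim$records[[tx]], r))
      len_ref <- nchar(plastohotspot:::region_sequence(sim$ancestor, r))
      expect_equal(net, len_tax - len_ref, info = paste(tx, r))
    }
  }
})

test_that("changed lengths split by NDH relatedness and sum signed", {
  ev <- tibble::tibble(
    kind = c("insertion", "deletion"),
    ref_position = c(10L, 50L), length = c(5L, 2L),
    region = c("LSC", "LSC"), ndh_related = c(FALSE, FALSE)
  )
  out <- indel_changed_length(ev)
  expect_equal(out$ndh_unrelated_delta, 3)
  expect_equal(out$ndh_related_delta, 0)

  out0 <- indel_changed_length(ev[0, ])
  expect_equal(out0$ndh_unrelated_delta, 0)
  expect_equal(out0$ndh_related_delta, 0)

  ev2 <- tibble::tibble(kind = "deletion", ref_position = 1L, length = 10L,
                        region = "SSC", ndh_related = TRUE)
  out2 <- indel_changed_length(ev2)
  expect_equal(out2$ndh_related_delta, -10)
  expect_equal(out2$ndh_unrelated_delta, 0)
})

test_that("indel_tests returns the three tests and p near 1 for identical data", {
  profiles <- tibble::tibble(
    taxon_id = paste0("t", 1:6),
    n_total = rep(10L, 6), n_lsc = c(7L, 8L, 6L, 7L, 8L, 6L),
    n_ssc = c(2L, 1L, 3L, 2L, 1L, 3L), n_ir = rep(1L, 6),
    pct_lsc = c(70, 80, 60, 70, 80, 60)
  )
  deltas <- tibble::tibble(
    taxon_id = paste0("t", 1:6),
    ndh_related_delta = c(-5, -8, -2, -6, -9, -1),
    ndh_unrelated_delta = c(40, 80, 20, 60, 90, 10)
  )
  changed <- tibble::tibble(taxon_id = paste0("t", 1:6),
                            delta_total = c(35, 72, 18, 54, 81, 9))
  out <- indel_tests(profiles, deltas, changed)
  expect_equal(nrow(out), 3)
  expect_equal(out$statistic[out$test == "unrelated_delta_vs_delta_total"], 1)

  # identical samples in the Mann-Whitney: p close to 1
  prof_same <- dplyr::mutate(profiles, pct_lsc = 50,
                             n_lsc = 5L, n_ssc = 3L, n_ir = 2L)
  p <- mann_whitney_two_sided(prof_same$pct_lsc / 10,
                              prof_same$pct_lsc / 10)$p_value
  expect_equal(p, 1)
})
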