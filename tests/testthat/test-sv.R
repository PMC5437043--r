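test_that("syntenic locus extraction applies the length filter and finds introns", {
  loci <- shared_loci()
  anc_loci <- attr(shared_sim()$ancestor, "loci")
  # the two decoy loci (< 150 bp) are discarded
  expect_equal(nrow(loci), sum(!anc_loci$decoy))
  expect_false(any(anc_loci$locus[anc_loci$decoy] %in% loci$locus))
  expect_true(all(loci$ref_length >= 150))
  # introns of two-exon genes come out as intron-type loci
  expect_true(any(loci$type == "intron"))
  expect_true("rps16 intron" %in% loci$locus)
  # regions are inherited from the reference coordinates
  expect_setequal(unique(loci$region), c("LSC", "SSC", "IR"))
})

test_that("a locus flanked by minus-strand genes is extracted as reverse complement", {
  mk <- function(id) {
    set.seed(7)
    s <- random_dna_str(600)
    plastome_record(
      taxon_id = id, sequence = paste0(s, random_dna_str(100), random_dna_str(50),
                                       plastohotspot:::revcomp(random_dna_str(100))),
      features = tibble::tibble(
        name = c("gA", "gB", "gC"),
        kind = "gene",
        start = c(0L, 100L, 400L),
        end = c(50L, 150L, 450L),
        strand = c("+", "-", "-"),
        pseudo = FALSE
      ),
      region_bounds = tibble::tibble(
        region = c("LSC", "IRb", "SSC", "IRa"),
        start = c(0L, 600L, 700L, 750L),
        end = c(600L, 700L, 750L, 850L)
      )
    )
  }
  recs <- list(x = mk("x"), y = mk("y"))
  loci <- extract_syntenic_loci(recs, reference_id = "x")
  # gB-gC spacer: both flanks minus -> reverse complement of the raw slice
  raw <- substr(recs$x$sequence, 151, 400)
  expect_identical(loci$seqs[[match("gB-gC", loci$locus)]]$x,
                   plastohotspot:::revcomp(raw))
  # gA-gB spacer: mixed strands -> forward slice
  raw2 <- substr(recs$x$sequence, 51, 100)
  expect_false("gA-gB" %in% loci$locus)  # only 50 bp, filtered
})

test_that("pairwise SV follows the counting formula", {
  s <- random_dna_str(300)
  expect_equal(pairwise_sv(s, s), 0)

  # 7 conserved columns, 0 mismatches, 1 internal gap run -> 1/8 x 100
  expect_equal(plastohotspot:::sv_from_alignment("ACGTTACG", "ACG-TACG"), 12.5)
  # 10 conserved, 2 mismatches, 1 event -> 3/13 x 100
  expect_equal(
    plastohotspot:::sv_from_alignment("ACGTACGTACTTG", "ACGAACGTACG-G"),
    100 * 3 / 13
  )
  # terminal gap runs are trimmed before counting
  expect_equal(plastohotspot:::sv_from_alignment("--GTAC", "ACGTAC"), 0)
  expect_equal(plastohotspot:::sv_from_alignment("ACGTAC--", "ACGTACGT"), 0)
  # nothing but terminal gaps: undefined, with a warning
  expect_warning(v <- plastohotspot:::sv_from_alignment("AC----", "--ACGT"),
                 "undefined")
  expect_true(is.na(v))
})

test_that("pairwise SV is symmetric and bounded", {
  set.seed(40)
  for (i in 1:8) {
    a <- random_dna_str(200)
    b <- random_dna_str(sample(180:220, 1))
    v1 <- pairwise_sv(a, b); v2 <- pairwise_sv(b, a)
    expect_equal(v1, v2)
    expect_gte(v1, 0); expect_lte(v1, 100)
  }
})

test_that("mean SV ranks planted hotspots on top and counts pairs", {
  sim <- shared_sim()
  loci <- shared_loci()
  svt <- mean_sv_table(loci)
  k <- length(sim$truth$hotspots)
  expect_setequal(head(svt$locus, k), sim$truth$hotspots)
  # all unordered distinct pairs of the 13 present taxa
  expect_equal(unique(svt$n_pairs), choose(13, 2))
  expect_equal(svt$rank, seq_len(nrow(svt)))

  # two taxa: exactly one pair
  svt2 <- mean_sv_table(loci, taxa_subset = c("t01", "t02"))
  expect_equal(unique(svt2$n_pairs), 1L)
})

test_that("SV-GC correlation is negative when hotspots are AT-biased", {
  loci <- shared_loci()
  svt <- mean_sv_table(loci)
  out <- sv_gc_correlation(svt)
  expect_lt(out$statistic, 0)
  expect_error(sv_gc_correlation(svt[1:2, ]), "at least 3")
})

test_that("rank stability uses nested seeded subsets and flags drop-outs", {
  loci <- shared_loci()
  st1 <- rank_stability(loci, group_sizes = c(2, 5, 10), n_reference_top = 5,
                        seed = 9)
  st2 <- rank_stability(loci, group_sizes = c(2, 5, 10), n_reference_top = 5,
                        seed = 9)
  expect_identical(as.data.frame(st1), as.data.frame(st2))
  expect_setequal(unique(st1$group_size), c(2, 5, 10))
  # the full taxon set reproduces the global ranks
  full <- rank_stability(loci, group_sizes = 13, n_reference_top = 5, seed = 1)
  svt <- mean_sv_table(loci)
  expect_equal(full$rank, svt$rank[match(full$locus, svt$locus)])
  # ranks outside the tracked top are NA, written as the "-" sentinel
  td <- withr::local_tempdir()
  wide <- write_rank_stability(st1, file.path(td, "rs.tsv"))
  expect_true(all(c("n2", "n5", "n10") %in% names(wide)))
  expect_error(rank_stability(loci, group_sizes = 99), "exceeds")
})
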