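test_that("yule trees are rooted, bifurcating, and seed-deterministic", {
  tr <- simulate_tree(4, seed = 5)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))

  expect_identical(ape::write.tree(simulate_tree(12, seed = 8)),
                   ape::write.tree(simulate_tree(12, seed = 8)))
  expect_false(identical(ape::write.tree(simulate_tree(12, seed = 8)),
                         ape::write.tree(simulate_tree(12, seed = 9))))
  expect_equal(length(simulate_tree(30, seed = 1)$tip.label), 30)
  expect_error(simulate_tree(3), "at least 4")
})

test_that("ancestral genome hosts the requested loci, decoys, and NDH layout", {
  cfg <- sim_config(n_taxa = 6, genome_scale = 15000, n_loci = 12,
                    hotspot_loci = 3, seed = 21)
  anc <- build_ancestral_plastome(cfg)
  loci <- attr(anc, "loci")
  expect_equal(nrow(loci), 12)
  expect_equal(sum(loci$decoy), 2)
  expect_true(all(loci$end[loci$decoy] - loci$start[loci$decoy] < 150))
  expect_true(all(loci$end[!loci$decoy] - loci$start[!loci$decoy] >= 150))
  # every locus sequence is extractable by name through its coordinates
  lens <- vapply(seq_len(nrow(loci)), function(i) {
    nchar(plastohotspot:::seq_slice(anc$sequence, loci$start[i], loci$end[i]))
  }, integer(1))
  expect_equal(lens, as.integer(loci$end - loci$start))
  # ndhB sits in the IR, most other NDH genes in the SSC
  ndh <- anc$features[grepl("^ndh", anc$features$name), ]
  ndhB_regions <- vapply(ndh$start[ndh$name == "ndhB"],
                         function(p) plastohotspot:::region_of_position(anc, p),
                         character(1))
  expect_setequal(ndhB_regions, c("IRb", "IRa"))
  # IRb is the reverse complement of IRa
  rb <- anc$region_bounds
  irb <- substr(anc$sequence, rb$start[2] + 1, rb$end[2])
  ira <- substr(anc$sequence, rb$start[4] + 1, rb$end[4])
  expect_identical(plastohotspot:::revcomp(irb), ira)

  expect_error(build_ancestral_plastome(
    sim_config(n_taxa = 6, genome_scale = 5000, n_loci = 40, seed = 1)
  ), "too small")
})

test_that("zero-rate evolution reproduces the ancestor with empty truth", {
  cfg <- sim_config(n_taxa = 5, genome_scale = 15000, n_loci = 12,
                    hotspot_loci = 3, seed = 30,
                    substitution_rate = 0,
                    indel_rate_per_region = c(LSC = 0, SSC = 0, IR = 0),
                    slippage_rate = 0, ndh_loss_lineages = list())
  sim <- simulate_plastome_set(cfg)
  anc <- sim$ancestor
  for (rec in sim$records) {
    expect_identical(rec$sequence, anc$sequence)
  }
  expect_equal(nrow(sim$truth$indels), 0)
  expect_equal(nrow(sim$truth$ndh_status), 0)
})

test_that("evolution keeps the IR mirrored and truth replayable", {
  sim <- shared_sim()
  anc_lens <- c(LSC = 8370L, IR = 2604L, SSC = 1422L)
  rb_anc <- sim$ancestor$region_bounds
  expect_equal(unname(anc_lens[["LSC"]]), rb_anc$end[1] - rb_anc$start[1])
  for (rec in sim$records) {
    rb <- rec$region_bounds
    irb <- substr(rec$sequence, rb$start[2] + 1, rb$end[2])
    ira <- substr(rec$sequence, rb$start[4] + 1, rb$end[4])
    expect_identical(plastohotspot:::revcomp(irb), ira)
    # replay: region length = ancestral length + net signed truth InDels
    ti <- sim$truth$indels[sim$truth$indels$taxon_id == rec$taxon_id, ]
    for (r in c("LSC", "SSC", "IR")) {
      net <- with(ti[ti$region == r, ],
                  sum(length[kind == "insertion"]) - sum(length[kind == "deletion"]))
      key <- if (r == "IR") "IRb" else r
      i <- match(key, rb$region)
      expect_equal(rb$end[i] - rb$start[i], unname(anc_lens[[r]]) + net)
    }
  }
})

test_that("same seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_taxa = 5, genome_scale = 15000, n_loci = 12,
                    hotspot_loci = 3, seed = 77)
  s1 <- simulate_plastome_set(cfg)
  s2 <- simulate_plastome_set(cfg)
  expect_identical(lapply(s1$records, `[[`, "sequence"),
                   lapply(s2$records, `[[`, "sequence"))
  expect_identical(as.data.frame(s1$truth$indels), as.data.frame(s2$truth$indels))
})

test_that("hotspot loci accumulate more substitutions than background loci", {
  diffs <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- min(length(av), length(bv))
    sum(av[1:n] != bv[1:n])
  }
  hot_excess <- replicate(3, {
    cfg <- sim_config(n_taxa = 6, genome_scale = 15000, n_loci = 12,
                      hotspot_loci = 3, hotspot_multiplier = 5,
                      indel_rate_per_region = c(LSC = 0, SSC = 0, IR = 0),
                      slippage_rate = 0, ndh_loss_lineages = list(),
                      seed = sample.int(1e6, 1))
    sim <- simulate_plastome_set(cfg)
    loci <- attr(sim$ancestor, "loci")
    per_locus <- vapply(seq_len(nrow(loci)), function(i) {
      s <- loci$start[i]; e <- loci$end[i]
      mean(vapply(sim$records, function(rec) {
        diffs(substr(rec$sequence, s + 1, e), substr(sim$ancestor$sequence, s + 1, e))
      }, double(1))) / (e - s)
    }, double(1))
    mean(per_locus[loci$hotspot]) - mean(per_locus[!loci$hotspot & !loci$decoy])
  })
  expect_true(all(hot_excess > 0))
})

test_that("NDH truncation marks pseudo flags and deletions drop the gene", {
  sim <- shared_sim()
  marks <- sim$truth$ndh_status
  expect_true(nrow(marks) > 0)
  trunc <- marks[marks$status == "truncated", ][1, ]
  rec <- sim$records[[trunc$taxon_id]]
  ft <- rec$features[rec$features$name == trunc$gene, ]
  expect_true(all(ft$pseudo))
  del <- marks[marks$status == "deleted", ]
  if (nrow(del) > 0) {
    rec <- sim$records[[del$taxon_id[1]]]
    expect_false(del$gene[1] %in% rec$features$name)
  }
})
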