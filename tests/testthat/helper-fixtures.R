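# Small hand-built plastome record: 400 bp, two genes per region flank a
# central spacer, an ndh gene in the SSC, regions 200/80/40/80.
make_toy_record <- function(taxon_id = "toy") {
  set.seed(99)
  lsc <- random_dna_str(200)
  ir <- random_dna_str(80)
  ssc <- random_dna_str(40)
  seqs <- paste0(lsc, ir, ssc, plastohotspot:::revcomp(ir))
  plastome_record(
    taxon_id = taxon_id,
    sequence = seqs,
    features = tibble::tibble(
      name = c("geneA", "geneB", "rrnX", "ndhF"),
      kind = c("gene", "gene", "rRNA", "gene"),
      start = c(0L, 150L, 210L, 285L),
      end = c(40L, 200L, 260L, 315L),
      strand = c("+", "+", "+", "-"),
      pseudo = c(FALSE, FALSE, FALSE, FALSE)
    ),
    region_bounds = tibble::tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(0L, 200L, 280L, 320L),
      end = c(200L, 280L, 320L, 400L)
    )
  )
}

# One simulated set shared across tests (memoized; ~3 s to build).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_taxa = 10, genome_scale = 15000, n_loci = 12,
                        hotspot_loci = 3, seed = 42)
      cache <<- simulate_plastome_set(cfg)
    }
    cache
  }
})

shared_loci <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- extract_syntenic_loci(shared_sim()$records, reference_id = "t01")
    }
    cache
  }
})
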