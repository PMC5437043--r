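#' Simulation configuration for synthetic plastome sets
#'
#' Bundles every knob of the generator. Defaults emulate a genus-scale
#' comparative study: ~28 quadripartite genomes of ~150 kb with shared gene
#' order, a handful of fast-evolving loci, LSC-biased InDel rates, seeded
#' SSR tracts with slippage, and lineage-specific NDH gene truncation.
#' Tests use the same machinery scaled down (e.g. 15 kb, 12 loci).
#'
#' @param n_taxa Number of ingroup taxa (>= 4 including outgroups overall).
#' @param genome_scale Target total genome length in bp.
#' @param n_loci Number of named intergenic/intronic loci to lay out
#'   (decoys included).
#' @param n_decoys How many of the loci are short decoys (< 150 bp) that the
#'   length filter must discard.
#' @param decoy_len Length of decoy loci in bp (must be < 150).
#' @param hotspot_loci Either a count (loci picked by the builder, spread
#'   over the LSC) or a character vector of locus names.
#' @param hotspot_multiplier Substitution-rate multiplier m > 1 inside
#'   hotspot loci.
#' @param hotspot_at AT fraction used when drawing hotspot locus sequence
#'   (hotspots are AT-biased, as plastome hotspots are).
#' @param substitution_rate Expected substitutions/site from root to tip.
#' @param indel_rate_per_region Named vector (LSC, SSC, IR): expected InDel
#'   events per site from root to tip; LSC highest by default.
#' @param indel_length_p Geometric length parameter for InDel lengths.
#' @param indel_max_len Cap on InDel length in bp.
#' @param ssr_seeds Tibble (`locus`, `motif`, `units`) of SSR tracts to plant,
#'   or NULL for two default mononucleotide/dinucleotide tracts.
#' @param slippage_rate Per-branch probability that a seeded tract gains or
#'   loses one repeat unit.
#' @param ndh_loss_lineages List of `list(taxa=, genes=, mode=)` entries,
#'   mode "truncate" (3' half removed, pseudo flag) or "delete".
#'   NULL plants a default truncation of ndhF/ndhD on two ingroup taxa.
#' @param outgroup_taxa Names of >= 3 outgroup taxa (disjoint from ingroup).
#' @param at_content Background AT fraction of generated sequence.
#' @param seed RNG seed for the whole simulation.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_taxa = 25,
                       genome_scale = 150000,
                       n_loci = 92,
                       n_decoys = 2,
                       decoy_len = 120,
                       hotspot_loci = 10,
                       hotspot_multiplier = 5,
                       hotspot_at = 0.72,
                       substitution_rate = 0.02,
                       indel_rate_per_region = c(LSC = 0.002, SSC = 0.001, IR = 0.0003),
                       indel_length_p = 0.3,
                       indel_max_len = 30,
                       ssr_seeds = NULL,
                       slippage_rate = 0.2,
                       ndh_loss_lineages = NULL,
                       outgroup_taxa = c("og1", "og2", "og3"),
                       at_content = 0.62,
                       seed = 1L) {
  cfg <- list(
    n_taxa = n_taxa, genome_scale = genome_scale, n_loci = n_loci,
    n_decoys = n_decoys, decoy_len = decoy_len,
    hotspot_loci = hotspot_loci, hotspot_multiplier = hotspot_multiplier,
    hotspot_at = hotspot_at,
    substitution_rate = substitution_rate,
    indel_rate_per_region = indel_rate_per_region,
    indel_length_p = indel_length_p, indel_max_len = indel_max_len,
    ssr_seeds = ssr_seeds, slippage_rate = slippage_rate,
    ndh_loss_lineages = ndh_loss_lineages,
    outgroup_taxa = outgroup_taxa,
    at_content = at_content, seed = seed
  )
  stopifnot(
    n_taxa >= 1, genome_scale >= 5000, n_loci >= 1,
    n_decoys >= 0, n_decoys <= n_loci, decoy_len < 150,
    substitution_rate >= 0, all(indel_rate_per_region >= 0),
    slippage_rate >= 0, slippage_rate <= 1,
    hotspot_multiplier > 1,
    all(c("LSC", "SSC", "IR") %in% names(indel_rate_per_region))
  )
  ingroup <- sprintf("t%02d", seq_len(n_taxa))
  if (length(intersect(ingroup, outgroup_taxa)) > 0) {
    abort("outgroup taxa must be disjoint from ingroup names t01, t02, ...")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a rooted Yule tree
#'
#' Pure-birth process: at k lineages the waiting time to the next split is
#' exponential with rate k, and a uniformly chosen lineage splits. Returns a
#' rooted, bifurcating `phylo` with positive branch lengths.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param seed Optional RNG seed (same seed, identical newick).
#' @param labels Optional tip labels (defaults t01, t02, ...).
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, labels = NULL) {
  if (n_taxa < 4) abort("need at least 4 taxa for a useful tree")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  nwk <- yule_newick(n_taxa, labels)
  ape::read.tree(text = nwk)
}

# Yule simulation producing a newick string. Internal.
yule_newick <- function(n, labels) {
  birth <- c(0)          # birth time of each node
  split_time <- c(NA)    # time the node split (NA while a live lineage)
  children <- list(NULL)
  active <- 1L
  t_now <- 0
  while (length(active) < n) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k)
    pick <- active[sample.int(k, 1)]
    id1 <- length(birth) + 1L; id2 <- id1 + 1L
    birth <- c(birth, t_now, t_now)
    split_time[pick] <- t_now
    split_time <- c(split_time, NA, NA)
    children[[pick]] <- c(id1, id2)
    children[id1] <- list(NULL); children[id2] <- list(NULL)
    active <- c(setdiff(active, pick), id1, id2)
  }
  t_end <- t_now + stats::rexp(1, rate = n)
  labs <- character(length(birth))
  labs[sort(active)] <- labels
  build <- function(i) {
    end_t <- if (is.null(children[[i]])) t_end else split_time[i]
    bl <- end_t - birth[i]
    if (is.null(children[[i]])) {
      sprintf("%s:%.8f", labs[i], bl)
    } else {
      sprintf("(%s,%s):%.8f", build(children[[i]][1]), build(children[[i]][2]), bl)
    }
  }
  paste0(sub(":[0-9.]+$", "", build(1L)), ";")
}

# Join an ingroup tree and an outgroup clade at a common root. The outgroup
# stem is long relative to tree height so rooting is unambiguous.
join_outgroups <- function(ingroup_tree, outgroups, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- max(ape::node.depth.edgelength(ingroup_tree))
  in_nwk <- sub(";$", "", ape::write.tree(ingroup_tree))
  og_nwk <- if (length(outgroups) == 1) {
    sprintf("%s:%.8f", outgroups, 0.5 * h)
  } else {
    og_tree <- simulate_tree(max(length(outgroups), 4), labels = c(outgroups, sprintf("ogpad%d", seq_len(max(0, 4 - length(outgroups)))))[seq_len(max(length(outgroups), 4))])
    og_tree <- if (length(outgroups) >= 4) og_tree else {
      ape::keep.tip(og_tree, outgroups)
    }
    # rescale outgroup clade height to half the ingroup height
    hh <- max(ape::node.depth.edgelength(og_tree))
    og_tree$edge.length <- og_tree$edge.length * (0.5 * h / hh)
    sub(";$", "", ape::write.tree(og_tree))
  }
  nwk <- sprintf("(%s:%.8f,%s:%.8f);", in_nwk, 0.5 * h, og_nwk, 1.2 * h)
  ape::read.tree(text = nwk)
}

# ---------------------------------------------------------------------------
# Ancestral genome layout

plastid_gene_pools <- function(small) {
  lsc <- c("psbA", "trnH", "trnK", "matK", "rps16", "trnQ", "psbK", "psbI",
           "atpA", "atpF", "atpH", "atpI", "rps2", "rpoC2", "rpoC1", "rpoB",
           "trnC", "petN", "psbM", "trnD", "trnY", "trnE", "trnT", "psbD",
           "psbC", "trnS", "psbZ", "trnG", "trnfM", "rps14", "psaB", "psaA",
           "ycf3", "trnL", "trnF", "ndhJ", "ndhK", "ndhC", "trnV", "trnM",
           "atpB", "rbcL", "accD", "psaI", "ycf4", "cemA", "petA", "psbJ",
           "psbL", "psbF", "psbE", "petL", "petG", "trnW", "trnP", "psaJ",
           "rpl33", "rps18", "rpl20", "rps12b", "clpP", "psbB", "psbT",
           "psbN", "psbH", "petB", "petD", "rpoA", "rps11", "rpl36", "rps8",
           "rpl14", "rpl16", "rps3", "rpl22", "rps19")
  ssc <- c("ndhF", "rpl32", "ccsA", "ndhD", "psaC", "ndhE", "ndhG", "ndhI",
           "ndhA", "ndhH", "rps15", "ycf1")
  ir <- c("rpl2", "rpl23", "ycf2", "ndhB", "rps7", "rps12", "rrn16", "trnI",
          "trnA", "rrn23", "rrn5", "trnN")
  if (small) {
    ssc <- c("ndhF", "rpl32", "ndhD", "ndhE", "ndhG", "ycf1")
    ir <- c("rpl2", "ndhB", "rrn16", "trnI", "rrn23")
  }
  list(LSC = lsc, SSC = ssc, IR = ir)
}

gene_length_for <- function(name, scale_small) {
  if (startsWith(name, "trn")) 75L
  else if (startsWith(name, "rrn")) if (scale_small) 300L else 1200L
  else if (scale_small) 150L else 500L
}

#' Build the ancestral synthetic plastome
#'
#' Lays out a quadripartite genome (LSC, IRb, SSC, IRa with IRa the reverse
#' complement of IRb) carrying a realistic plastid gene order, `n_loci`
#' named intergenic spacers and introns (a few of them short decoys below
#' the 150 bp filter), the 11-gene NDH family with ndhB in the IRs and most
#' others in the SSC, and seeded SSR tracts. Genes not separated by a named
#' locus abut directly, so the named loci are exactly the extractable ones.
#'
#' @param config A [sim_config()].
#' @return A `plastome_record` for taxon "ancestor" with attributes `loci`
#'   (tibble: locus, type, region, start, end, hotspot), `ssr_tracts`
#'   (tibble: locus, motif, units, start) in ancestor coordinates.
#' @export
build_ancestral_plastome <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$genome_scale
  small <- G < 60000
  lsc_len <- round(0.558 * G)
  ir_len <- round(0.1736 * G)
  ssc_len <- G - lsc_len - 2L * ir_len
  pools <- plastid_gene_pools(small)

  # allocate loci: ~1 in 6 is an intron (always at least one); spacers go
  # mostly to the LSC, with a small share in SSC and IR when there is room
  n_introns <- max(1L, round(config$n_loci * 0.18))
  n_spacers <- config$n_loci - n_introns
  host_candidates <- intersect(c("rps16", "trnL", "clpP", "petB", "rpoC1",
                                 "ycf3", "atpF", "rpl16", "trnG", "trnK",
                                 "petD", "trnV", "ndhA", "rpl2", "trnI",
                                 "trnA", "rps12", "ndhB"),
                               unlist(pools))
  intron_hosts <- head(host_candidates, n_introns)
  if (length(intron_hosts) < n_introns) {
    abort("too many intron loci requested for the available host genes")
  }
  cap <- vapply(pools, length, integer(1)) - 1L
  ssc_spacers <- if (n_spacers >= 4) min(max(1L, round(0.12 * n_spacers)), cap[["SSC"]]) else 0L
  ir_spacers <- if (n_spacers >= 5) min(max(1L, round(0.05 * n_spacers)), cap[["IR"]]) else 0L
  lsc_spacers <- n_spacers - ssc_spacers - ir_spacers
  if (lsc_spacers > cap[["LSC"]]) abort("genome_scale too small to host n_loci")

  layout_region <- function(region, genes, n_reg_spacers, region_len) {
    # element list: genes with loci interleaved between chosen adjacent pairs
    k <- length(genes)
    need <- n_reg_spacers + 1L
    if (k < need) abort(sprintf("genome_scale too small to host n_loci (%s needs %d flank genes, has %d)", region, need, k))
    # spacer slots spread evenly over the gene adjacencies
    slots <- if (n_reg_spacers > 0) unique(round(seq(1, k - 1, length.out = n_reg_spacers))) else integer(0)
    while (length(slots) < n_reg_spacers) {
      cand <- setdiff(seq_len(k - 1), slots)
      slots <- sort(c(slots, cand[1]))
    }
    elements <- list()
    for (i in seq_len(k)) {
      g <- genes[i]
      glen <- gene_length_for(g, small)
      if (g %in% intron_hosts) {
        elements <- c(elements, list(
          list(what = "exon", name = g, len = max(40L, glen %/% 3L)),
          list(what = "intron", name = g, len = 0L),  # locus, sized later
          list(what = "exon", name = g, len = max(60L, glen %/% 2L))
        ))
      } else {
        elements <- c(elements, list(list(what = "gene", name = g, len = glen)))
      }
      if (i %in% slots) {
        nxt <- genes[i + 1]
        elements <- c(elements, list(
          list(what = "spacer", name = paste0(g, "-", nxt), len = 0L)
        ))
      }
    }
    elements
  }

  lsc_genes <- pools$LSC
  if (small) {
    keep_n <- min(length(pools$LSC), max(lsc_spacers + 2L, 16L))
    lsc_genes <- pools$LSC[seq_len(keep_n)]
    lsc_genes <- pools$LSC[pools$LSC %in%
                             union(lsc_genes, intersect(intron_hosts, pools$LSC))]
  }
  ssc_genes <- pools$SSC
  ir_genes <- pools$IR

  elems <- list(
    LSC = layout_region("LSC", lsc_genes, lsc_spacers, lsc_len),
    SSC = layout_region("SSC", ssc_genes, ssc_spacers, ssc_len),
    IR = layout_region("IR", ir_genes, ir_spacers, ir_len)
  )

  # name the loci, mark decoys and hotspots, then size them
  locus_names <- unlist(lapply(names(elems), function(r) {
    vapply(Filter(function(e) e$what %in% c("spacer", "intron"), elems[[r]]),
           function(e) if (e$what == "intron") paste(e$name, "intron") else e$name,
           character(1))
  }))
  locus_names <- unique(locus_names)
  if (length(locus_names) < config$n_loci) {
    abort("genome_scale too small to host n_loci")
  }
  decoys <- if (config$n_decoys > 0) {
    # decoys are LSC spacers, taken from the end of that region's list
    lsc_sp <- vapply(Filter(function(e) e$what == "spacer", elems$LSC),
                     function(e) e$name, character(1))
    if (length(lsc_sp) < config$n_decoys) abort("not enough LSC spacers for the requested decoys")
    tail(lsc_sp, config$n_decoys)
  } else character(0)
  hotspots <- config$hotspot_loci
  if (is.numeric(hotspots)) {
    cand <- setdiff(locus_names, decoys)
    if (hotspots > length(cand)) abort("more hotspots requested than loci available")
    hotspots <- cand[unique(round(seq(1, length(cand), length.out = hotspots)))]
  }
  if (!all(hotspots %in% setdiff(locus_names, decoys))) {
    abort("hotspot_loci must name non-decoy loci")
  }

  # size loci: base length plus a share of the regional slack
  base_locus <- 300L
  region_lengths <- c(LSC = lsc_len, SSC = ssc_len, IR = ir_len)
  seqs <- list(); feats <- list(); loci_tab <- list(); ssr_tab <- list()
  ssr_seeds <- config$ssr_seeds
  if (is.null(ssr_seeds)) {
    sp <- setdiff(grep(" intron$", locus_names, invert = TRUE, value = TRUE), decoys)
    ssr_seeds <- tibble::tibble(
      locus = sp[seq_len(min(2, length(sp)))],
      motif = c("A", "AT")[seq_len(min(2, length(sp)))],
      units = c(10L, 6L)[seq_len(min(2, length(sp)))]
    )
  }
  ssr_seeds <- tibble::as_tibble(ssr_seeds)

  for (r in names(elems)) {
    el <- elems[[r]]
    is_locus <- vapply(el, function(e) e$what %in% c("spacer", "intron"), logical(1))
    lnames <- vapply(el, function(e) {
      if (e$what == "intron") paste(e$name, "intron") else e$name
    }, character(1))
    # assign lengths to loci
    for (i in which(is_locus)) {
      el[[i]]$len <- if (lnames[i] %in% decoys) config$decoy_len else base_locus
    }
    used <- sum(vapply(el, function(e) e$len, numeric(1)))
    slack <- region_lengths[[r]] - used
    if (slack < 0) abort("genome_scale too small to host n_loci")
    growable <- which(is_locus & !(lnames %in% decoys))
    if (length(growable) > 0 && slack > 0) {
      extra <- min(900L, floor(slack * 0.6 / length(growable)))
      for (i in growable) el[[i]]$len <- el[[i]]$len + extra
      slack <- region_lengths[[r]] - sum(vapply(el, function(e) e$len, numeric(1)))
    }
    if (slack > 0) {
      el <- c(el, list(list(what = "gene", name = paste0("orf", r), len = as.integer(slack))))
    }
    # emit sequence + features
    pos <- 0L
    parts <- character(length(el))
    for (i in seq_along(el)) {
      e <- el[[i]]
      at <- if (isTRUE(is_locus[i]) && lnames[i] %in% hotspots) config$hotspot_at else config$at_content
      s <- random_dna(e$len, at = at)
      if (e$what %in% c("spacer", "intron") && lnames[i] %in% ssr_seeds$locus && e$len >= 150) {
        seed_row <- ssr_seeds[match(lnames[i], ssr_seeds$locus), ]
        tract <- strrep(seed_row$motif, seed_row$units)
        ins_at <- max(30L, e$len %/% 3L)
        # avoid the tract bleeding into adjacent identical bases
        s <- paste0(substr(s, 1, ins_at), "C", tract, "C",
                    substr(s, ins_at + nchar(tract) + 3L, e$len))
        s <- substr(s, 1, e$len)
        ssr_tab[[length(ssr_tab) + 1]] <- tibble::tibble(
          locus = lnames[i], motif = seed_row$motif, units = seed_row$units,
          region = r, start_local = pos + ins_at + 1L
        )
      }
      parts[i] <- s
      if (e$what != "filler") {
        kind <- switch(e$what,
          gene = if (startsWith(e$name, "trn")) "tRNA" else if (startsWith(e$name, "rrn")) "rRNA" else "gene",
          exon = "exon", intron = "intron", spacer = NA_character_
        )
        if (!is.na(kind)) {
          feats[[length(feats) + 1]] <- tibble::tibble(
            region = r, name = e$name, kind = kind,
            start_local = pos, end_local = pos + e$len,
            strand = "+", pseudo = FALSE
          )
        }
        if (e$what %in% c("spacer", "intron")) {
          loci_tab[[length(loci_tab) + 1]] <- tibble::tibble(
            locus = lnames[i],
            type = if (e$what == "intron") "intron" else "spacer",
            region = r, start_local = pos, end_local = pos + e$len,
            hotspot = lnames[i] %in% hotspots,
            decoy = lnames[i] %in% decoys
          )
        }
      }
      pos <- pos + e$len
    }
    seqs[[r]] <- paste(parts, collapse = "")
    stopifnot(nchar(seqs[[r]]) == region_lengths[[r]])
  }

  # assemble genome: LSC | IRb | SSC | IRa(revcomp IRb)
  offsets <- c(LSC = 0L, IRb = lsc_len, SSC = lsc_len + ir_len,
               IRa = lsc_len + ir_len + ssc_len)
  genome <- paste0(seqs$LSC, seqs$IR, seqs$SSC, revcomp(seqs$IR))

  feats <- dplyr::bind_rows(feats)
  glob <- function(region, s, e) {
    off <- switch(region, LSC = offsets[["LSC"]], SSC = offsets[["SSC"]], IR = offsets[["IRb"]])
    c(off + s, off + e)
  }
  gstart <- integer(nrow(feats)); gend <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    ge <- glob(feats$region[i], feats$start_local[i], feats$end_local[i])
    gstart[i] <- ge[1]; gend[i] <- ge[2]
  }
  features <- tibble::tibble(name = feats$name, kind = feats$kind,
                             start = gstart, end = gend,
                             strand = feats$strand, pseudo = feats$pseudo)
  # gene umbrella features for intron hosts (span exon1..exon2)
  hosts <- unique(feats$name[feats$kind == "exon"])
  for (h in hosts) {
    idx <- which(features$name == h & features$kind %in% c("exon"))
    features <- dplyr::bind_rows(features, tibble::tibble(
      name = h, kind = if (startsWith(h, "trn")) "tRNA" else "gene",
      start = min(features$start[idx]), end = max(features$end[idx]),
      strand = "+", pseudo = FALSE
    ))
  }
  # mirror IRb features into IRa (reverse complement coordinates)
  irb <- features[features$start >= offsets[["IRb"]] & features$end <= offsets[["IRb"]] + ir_len, ]
  ira <- irb
  ira$start <- offsets[["IRa"]] + (ir_len - (irb$end - offsets[["IRb"]]))
  ira$end <- offsets[["IRa"]] + (ir_len - (irb$start - offsets[["IRb"]]))
  ira$strand <- ifelse(irb$strand == "+", "-", "+")
  features <- dplyr::bind_rows(features, ira)
  features <- dplyr::arrange(features, .data$start, .data$end, .data$name)

  loci_tab <- dplyr::bind_rows(loci_tab)
  loci <- tibble::tibble(
    locus = loci_tab$locus, type = loci_tab$type, region = loci_tab$region,
    start = NA_integer_, end = NA_integer_,
    hotspot = loci_tab$hotspot, decoy = loci_tab$decoy
  )
  for (i in seq_len(nrow(loci))) {
    ge <- glob(loci_tab$region[i], loci_tab$start_local[i], loci_tab$end_local[i])
    loci$start[i] <- ge[1]; loci$end[i] <- ge[2]
  }
  ssr_tab <- if (length(ssr_tab)) dplyr::bind_rows(ssr_tab) else
    tibble::tibble(locus = character(), motif = character(), units = integer(),
                   region = character(), start_local = integer())
  if (nrow(ssr_tab) > 0) {
    ssr_tab$start <- NA_integer_
    for (i in seq_len(nrow(ssr_tab))) {
      ssr_tab$start[i] <- glob(ssr_tab$region[i], ssr_tab$start_local[i], ssr_tab$start_local[i])[1]
    }
  } else {
    ssr_tab$start <- integer(0)
  }

  rec <- plastome_record(
    taxon_id = "ancestor", sequence = genome, features = features,
    region_bounds = tibble::tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = as.integer(unname(offsets)),
      end = as.integer(c(offsets[-1], nchar(genome)))
    )
  )
  attr(rec, "loci") <- loci
  attr(rec, "ssr_tracts") <- ssr_tab[, c("locus", "motif", "units", "region", "start")]
  rec
}
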