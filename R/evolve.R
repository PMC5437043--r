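# Branch-wise evolution of the synthetic plastome. Each node carries, per
# region (LSC, SSC, one IR copy), the current sequence as a character vector
# plus a parallel map giving each base's 1-based position in the ancestral
# region (NA for inserted bases). Ground-truth InDels and annotation lifting
# are both read off that map, so the emitted truth is replayable by
# construction.

anc_region_state <- function(ancestor) {
  rb <- ancestor$region_bounds
  get <- function(region) {
    i <- match(region, rb$region)
    s <- seq_chars(seq_slice(ancestor$sequence, rb$start[i], rb$end[i]))
    list(seq = s, map = seq_along(s))
  }
  list(LSC = get("LSC"), IR = get("IRb"), SSC = get("SSC"))
}

anc_region_offsets <- function(ancestor) {
  rb <- ancestor$region_bounds
  c(LSC = rb$start[rb$region == "LSC"],
    IR = rb$start[rb$region == "IRb"],
    SSC = rb$start[rb$region == "SSC"])
}

# logical mask over ancestral region coordinates flagging hotspot loci
hotspot_masks <- function(ancestor, hotspot_names) {
  loci <- attr(ancestor, "loci")
  offs <- anc_region_offsets(ancestor)
  lens <- vapply(anc_region_state(ancestor), function(r) length(r$seq), integer(1))
  masks <- lapply(lens, function(L) rep(FALSE, L))
  if (is.null(loci)) return(masks)
  hot <- loci[loci$locus %in% hotspot_names, , drop = FALSE]
  for (i in seq_len(nrow(hot))) {
    r <- hot$region[i]
    s <- hot$start[i] - offs[[r]]
    e <- hot$end[i] - offs[[r]]
    masks[[r]][(s + 1):e] <- TRUE
  }
  masks
}

draw_base <- function(n, at) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))
}

# Apply substitutions, InDels and SSR slippage for one branch to one region.
mutate_region <- function(st, region, bl, depth, config, hot_mask, tracts) {
  L <- length(st$seq)
  if (L == 0) return(st)
  # substitutions (Jukes-Cantor events at small rates; hotspot sites x m)
  p_base <- config$substitution_rate / depth * bl
  if (p_base > 0) {
    mult <- rep(1, L)
    inh <- !is.na(st$map)
    mult[inh][hot_mask[st$map[inh]]] <- config$hotspot_multiplier
    p <- pmin(p_base * mult, 0.75)
    hit <- which(stats::runif(L) < p)
    if (length(hit) > 0) {
      for (i in hit) {
        st$seq[i] <- sample(setdiff(c("A", "C", "G", "T"), st$seq[i]), 1)
      }
    }
  }
  # InDel events, region-biased rate, geometric lengths
  rate <- config$indel_rate_per_region[[region]]
  n_ev <- if (rate > 0) stats::rpois(1, rate / depth * bl * L) else 0L
  if (n_ev > 0) {
    for (k in seq_len(n_ev)) {
      len <- min(1L + stats::rgeom(1, config$indel_length_p), config$indel_max_len)
      Lc <- length(st$seq)
      if (Lc <= len + 2L) next
      if (stats::runif(1) < 0.5) {  # deletion
        pos <- sample.int(Lc - len, 1)
        keep <- setdiff(seq_len(Lc), pos:(pos + len - 1L))
        st$seq <- st$seq[keep]; st$map <- st$map[keep]
      } else {                      # insertion after position pos
        pos <- sample.int(Lc - 1L, 1)
        ins <- draw_base(len, config$at_content)
        st$seq <- c(st$seq[seq_len(pos)], ins, st$seq[(pos + 1L):Lc])
        st$map <- c(st$map[seq_len(pos)], rep(NA_integer_, len), st$map[(pos + 1L):Lc])
      }
    }
  }
  # SSR slippage at seeded tracts in this region
  if (nrow(tracts) > 0 && config$slippage_rate > 0) {
    for (k in seq_len(nrow(tracts))) {
      if (stats::runif(1) >= config$slippage_rate) next
      motif <- tracts$motif[k]; ulen <- nchar(motif)
      s0 <- tracts$start_local[k]; e0 <- s0 + ulen * tracts$units[k]
      idx <- which(!is.na(st$map) & st$map > s0 & st$map <= e0)
      if (length(idx) < 2L * ulen) next
      at <- idx[1]
      Lc <- length(st$seq)
      if (stats::runif(1) < 0.5) {  # gain one unit
        ins <- seq_chars(motif)
        st$seq <- c(st$seq[seq_len(at)], ins, st$seq[(at + 1L):Lc])
        st$map <- c(st$map[seq_len(at)], rep(NA_integer_, ulen), st$map[(at + 1L):Lc])
      } else {                      # lose one unit
        drop <- idx[seq_len(ulen)]
        keep <- setdiff(seq_len(Lc), drop)
        st$seq <- st$seq[keep]; st$map <- st$map[keep]
      }
    }
  }
  st
}

# NDH truncation/loss on a terminal branch: remove the 3' half (truncate)
# or the full current extent (delete) of the gene, in the region state.
apply_ndh_loss <- function(states, taxon, config, anc_features_local) {
  losses <- config$ndh_loss_lineages
  marks <- tibble::tibble(taxon_id = character(), gene = character(), status = character())
  if (is.null(losses)) return(list(states = states, marks = marks))
  for (spec in losses) {
    if (!(taxon %in% spec$taxa)) next
    for (g in spec$genes) {
      f <- anc_features_local[anc_features_local$name == g &
                              anc_features_local$kind %in% c("gene", "tRNA", "rRNA"), ]
      if (nrow(f) == 0) next
      f <- f[1, ]
      st <- states[[f$region]]
      s0 <- f$start_local; e0 <- f$end_local
      cut_from <- if (identical(spec$mode, "delete")) s0 else (s0 + e0) %/% 2L
      idx <- which(!is.na(st$map) & st$map > cut_from & st$map <= e0)
      if (length(idx) > 0) {
        keep <- setdiff(seq_along(st$seq), idx)
        st$seq <- st$seq[keep]; st$map <- st$map[keep]
        states[[f$region]] <- st
      }
      marks <- dplyr::bind_rows(marks, tibble::tibble(
        taxon_id = taxon, gene = g,
        status = if (identical(spec$mode, "delete")) "deleted" else "truncated"
      ))
    }
  }
  list(states = states, marks = marks)
}

# Ancestor features in region-local coordinates (IRa copies excluded; they
# are re-mirrored from the lifted IRb copies at assembly time).
anc_features_local <- function(ancestor) {
  rb <- ancestor$region_bounds
  ira_start <- rb$start[rb$region == "IRa"]
  ft <- ancestor$features[ancestor$features$start < ira_start, , drop = FALSE]
  offs <- anc_region_offsets(ancestor)
  region <- character(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    r <- region_of_position(ancestor, ft$start[i])
    region[i] <- if (r == "IRb") "IR" else r
  }
  tibble::tibble(
    name = ft$name, kind = ft$kind, strand = ft$strand, pseudo = ft$pseudo,
    region = region,
    start_local = ft$start - offs[region],
    end_local = ft$end - offs[region]
  )
}

# Lift a set of local intervals through a state's map. Returns start/end
# (0-based half-open, current coordinates) or NA if fully deleted.
lift_intervals <- function(st, starts, ends) {
  nn <- which(!is.na(st$map))
  vals <- st$map[nn]
  lo <- findInterval(starts, vals) + 1L       # first val > start
  hi <- findInterval(ends, vals)              # last val <= end
  out_s <- ifelse(hi >= lo, nn[pmin(lo, length(nn))] - 1L, NA_integer_)
  out_e <- ifelse(hi >= lo, nn[pmax(hi, 1L)], NA_integer_)
  list(start = as.integer(out_s), end = as.integer(out_e))
}

# Ground-truth InDel events of one leaf versus the ancestor, from the map.
truth_indels_from_state <- function(st, region, anc_offset, La) {
  vals <- st$map[!is.na(st$map)]
  miss <- rep(TRUE, La); miss[vals] <- FALSE
  del <- true_runs(miss)
  dels <- tibble::tibble(kind = "deletion",
                         ref_position = as.integer(del$start),
                         length = as.integer(del$end - del$start))
  na_runs <- true_runs(is.na(st$map))
  ins_pos <- integer(0); ins_len <- integer(0)
  if (nrow(na_runs) > 0) {
    for (i in seq_len(nrow(na_runs))) {
      j <- na_runs$end[i] + 1L  # next column right of the run (1-based)
      pos <- if (j <= length(st$map)) st$map[j] - 1L else La
      ins_pos <- c(ins_pos, pos); ins_len <- c(ins_len, na_runs$end[i] - na_runs$start[i])
    }
  }
  ev <- dplyr::bind_rows(
    dels,
    tibble::tibble(kind = "insertion", ref_position = as.integer(ins_pos),
                   length = as.integer(ins_len))
  )
  if (nrow(ev) == 0) {
    return(tibble::tibble(kind = character(), ref_position = integer(),
                          length = integer(), region = character()))
  }
  ev$region <- if (region == "IR") "IR" else region
  ev$ref_position <- ev$ref_position + as.integer(anc_offset)
  dplyr::arrange(ev, .data$ref_position)
}

max_motif_run <- function(x, motif) {
  m <- gregexpr(paste0("(?:", motif, ")+"), x)[[1]]
  if (m[1] == -1) return(0L)
  as.integer(max(attr(m, "match.length")) %/% nchar(motif))
}

#' Evolve a synthetic plastome set along a tree
#'
#' Starting from the ancestral genome, applies per-branch Jukes-Cantor
#' substitutions (rate multiplied inside hotspot loci), region-biased InDel
#' events with geometric lengths, SSR slippage at seeded tracts, and NDH
#' truncation/loss on designated terminal lineages. Edits to the IR are made
#' once and mirrored, so IRa stays the reverse complement of IRb.
#' Annotations are lifted through every edit, and ground truth (InDels per
#' taxon versus the ancestor, SSR repeat units, hotspot names) is recorded.
#'
#' @param tree Rooted `phylo` whose tips name the taxa.
#' @param ancestor Record from [build_ancestral_plastome()].
#' @param config The [sim_config()] used to build the ancestor.
#' @param seed Optional RNG seed.
#' @return A list: `records` (named list of `plastome_record`),
#'   `truth` (list: `tree`, `indels`, `ssr_units`, `hotspots`, `ndh_status`).
#' @export
evolve_plastomes <- function(tree, ancestor, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- attr(ancestor, "loci")
  hot_names <- loci$locus[loci$hotspot]
  masks <- hotspot_masks(ancestor, hot_names)
  offs <- anc_region_offsets(ancestor)
  tracts <- attr(ancestor, "ssr_tracts")
  tracts$start_local <- tracts$start - offs[tracts$region]
  feats_local <- anc_features_local(ancestor)
  depth <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  if (depth <= 0) depth <- 1

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  leaf_states <- vector("list", ntip)
  marks_all <- list()
  walk <- function(node, st) {
    for (ei in kids[[as.character(node)]] %||% integer(0)) {
      child <- tree$edge[ei, 2]
      bl <- tree$edge.length[ei]
      st_c <- st
      for (r in c("LSC", "SSC", "IR")) {
        st_c[[r]] <- mutate_region(st_c[[r]], r, bl, depth, config,
                                   masks[[r]], tracts[tracts$region == r, , drop = FALSE])
      }
      if (child <= ntip) {
        taxon <- tree$tip.label[child]
        res <- apply_ndh_loss(st_c, taxon, config, feats_local)
        leaf_states[[child]] <<- res$states
        marks_all[[length(marks_all) + 1L]] <<- res$marks
      } else {
        walk(child, st_c)
      }
    }
  }
  walk(root, anc_region_state(ancestor))

  marks <- if (length(marks_all)) dplyr::bind_rows(marks_all) else
    tibble::tibble(taxon_id = character(), gene = character(), status = character())

  anc_lens <- vapply(anc_region_state(ancestor), function(r) length(r$seq), integer(1))
  records <- list(); truth_indels <- list(); truth_ssr <- list()
  for (i in seq_len(ntip)) {
    taxon <- tree$tip.label[i]
    st <- leaf_states[[i]]
    rec <- assemble_leaf_record(taxon, st, feats_local, marks[marks$taxon_id == taxon, , drop = FALSE])
    records[[taxon]] <- rec
    for (r in c("LSC", "IR", "SSC")) {
      ti <- truth_indels_from_state(st[[r]], r, offs[[r]], anc_lens[[r]])
      if (nrow(ti) > 0) {
        ti$taxon_id <- taxon
        truth_indels[[length(truth_indels) + 1L]] <- ti
      }
    }
    if (nrow(tracts) > 0) {
      for (k in seq_len(nrow(tracts))) {
        stt <- st[[tracts$region[k]]]
        ulen <- nchar(tracts$motif[k])
        s0 <- tracts$start_local[k]; e0 <- s0 + ulen * tracts$units[k]
        idx <- which(!is.na(stt$map) & stt$map > s0 & stt$map <= e0)
        units <- if (length(idx) == 0) 0L else {
          w_s <- max(1L, idx[1] - 5L)
          w_e <- min(length(stt$seq), idx[length(idx)] + 5L + 3L * ulen)
          max_motif_run(paste(stt$seq[w_s:w_e], collapse = ""), tracts$motif[k])
        }
        truth_ssr[[length(truth_ssr) + 1L]] <- tibble::tibble(
          taxon_id = taxon, locus = tracts$locus[k], motif = tracts$motif[k],
          units = units
        )
      }
    }
  }
  truth_indels <- if (length(truth_indels)) {
    dplyr::bind_rows(truth_indels) |>
      dplyr::mutate(ndh_related = event_ndh_related(
        dplyr::pick(dplyr::everything()), ancestor)) |>
      dplyr::select("taxon_id", "kind", "region", "ref_position", "length", "ndh_related")
  } else {
    tibble::tibble(taxon_id = character(), kind = character(), region = character(),
                   ref_position = integer(), length = integer(), ndh_related = logical())
  }
  truth_ssr <- if (length(truth_ssr)) dplyr::bind_rows(truth_ssr) else
    tibble::tibble(taxon_id = character(), locus = character(),
                   motif = character(), units = integer())

  list(
    records = records,
    truth = list(tree = tree, indels = truth_indels, ssr_units = truth_ssr,
                 hotspots = hot_names, ndh_status = marks)
  )
}

# Build a leaf plastome_record from its three region states.
assemble_leaf_record <- function(taxon, st, feats_local, marks) {
  lsc <- paste(st$LSC$seq, collapse = "")
  irb <- paste(st$IR$seq, collapse = "")
  ssc <- paste(st$SSC$seq, collapse = "")
  l_lsc <- nchar(lsc); l_ir <- nchar(irb); l_ssc <- nchar(ssc)
  offs <- c(LSC = 0L, IR = l_lsc, SSC = l_lsc + l_ir)
  lift <- lift_intervals_by_region(st, feats_local)
  ok <- !is.na(lift$start)
  ft <- feats_local[ok, , drop = FALSE]
  fs <- lift$start[ok] + offs[ft$region]
  fe <- lift$end[ok] + offs[ft$region]
  pseudo <- ft$pseudo
  if (nrow(marks) > 0) {
    pseudo <- pseudo | (ft$name %in% marks$gene[marks$status == "truncated"])
  }
  features <- tibble::tibble(name = ft$name, kind = ft$kind,
                             start = as.integer(fs), end = as.integer(fe),
                             strand = ft$strand, pseudo = pseudo)
  # mirror lifted IR features into IRa
  in_ir <- ft$region == "IR"
  if (any(in_ir)) {
    s_loc <- fs[in_ir] - l_lsc; e_loc <- fe[in_ir] - l_lsc
    ira_off <- l_lsc + l_ir + l_ssc
    features <- dplyr::bind_rows(features, tibble::tibble(
      name = ft$name[in_ir], kind = ft$kind[in_ir],
      start = as.integer(ira_off + (l_ir - e_loc)),
      end = as.integer(ira_off + (l_ir - s_loc)),
      strand = ifelse(ft$strand[in_ir] == "+", "-", "+"),
      pseudo = pseudo[in_ir]
    ))
  }
  features <- dplyr::arrange(features, .data$start, .data$end, .data$name)
  plastome_record(
    taxon_id = taxon,
    sequence = paste0(lsc, irb, ssc, revcomp(irb)),
    features = features,
    region_bounds = tibble::tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(0L, l_lsc, l_lsc + l_ir, l_lsc + l_ir + l_ssc),
      end = c(l_lsc, l_lsc + l_ir, l_lsc + l_ir + l_ssc, l_lsc + 2L * l_ir + l_ssc)
    )
  )
}

lift_intervals_by_region <- function(st, feats_local) {
  out_s <- rep(NA_integer_, nrow(feats_local))
  out_e <- rep(NA_integer_, nrow(feats_local))
  for (r in c("LSC", "SSC", "IR")) {
    sel <- which(feats_local$region == r)
    if (length(sel) == 0) next
    lifted <- lift_intervals(st[[r]], feats_local$start_local[sel],
                             feats_local$end_local[sel])
    out_s[sel] <- lifted$start; out_e[sel] <- lifted$end
  }
  list(start = out_s, end = out_e)
}

#' Simulate a full annotated plastome set with ground truth
#'
#' Convenience wrapper: draws the tree (ingroup Yule tree joined to an
#' outgroup clade on a long stem), builds the ancestral genome, evolves it,
#' and returns records plus ground truth. Fully determined by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `records`, `truth`, `ancestor`, `tree`, `config`.
#' @export
simulate_plastome_set <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ingroup <- sprintf("t%02d", seq_len(config$n_taxa))
  tree_in <- simulate_tree(config$n_taxa, labels = ingroup)
  tree <- if (length(config$outgroup_taxa) > 0) {
    join_outgroups(tree_in, config$outgroup_taxa)
  } else {
    tree_in
  }
  config2 <- config
  if (is.null(config$ndh_loss_lineages) && config$n_taxa >= 3) {
    config2$ndh_loss_lineages <- list(
      list(taxa = ingroup[config$n_taxa - (1:0)], genes = c("ndhF", "ndhD"),
           mode = "truncate"),
      list(taxa = ingroup[config$n_taxa], genes = "ndhG", mode = "delete")
    )
  }
  ancestor <- build_ancestral_plastome(config)
  evo <- evolve_plastomes(tree, ancestor, config2)
  c(evo, list(ancestor = ancestor, tree = tree, config = config2))
}

#' Write a simulated set to FASTA + GFF3 + ground-truth JSON
#'
#' @param sim Result of [simulate_plastome_set()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "genomes.fasta")
  gff <- file.path(dir, "genomes.gff3")
  js <- file.path(dir, "truth.json")
  write_genomes(sim$records, fa, gff)
  truth <- sim$truth
  truth$tree <- ape::write.tree(truth$tree)
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(fasta = fa, gff3 = gff, truth = js))
}
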