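# Jukes-Cantor distance matrix from a gapped character matrix with pairwise
# deletion of gap/N sites. Saturated pairs (mismatch fraction >= 0.75) are
# capped at `cap` with a warning; pairs sharing no scorable column are an
# error naming the pair.
jc_distance_matrix <- function(m, cap = 3) {
  taxa <- rownames(m)
  n <- nrow(m)
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns == 0) {
        abort(sprintf("taxa '%s' and '%s' share no scorable alignment column",
                      taxa[i], taxa[j]))
      }
      p <- sum(m[i, shared] != m[j, shared]) / ns
      if (p >= 0.75) {
        warn(sprintf("JC distance saturated for '%s' vs '%s'; capped at %g",
                     taxa[i], taxa[j], cap))
        dij <- cap
      } else {
        dij <- min(-0.75 * log(1 - 4 * p / 3), cap)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

nj_from_matrix <- function(m, cap = 3) {
  ape::nj(jc_distance_matrix(m, cap = cap))
}

#' Neighbor-joining tree with nonparametric bootstrap supports
#'
#' The point tree is neighbor joining on Jukes-Cantor distances (pairwise
#' deletion of gap/N sites). Supports are the percentage of replicate NJ
#' trees -- alignment columns resampled with replacement -- that contain
#' each internal bipartition of the point tree. The tree is finally rooted
#' on the outgroup clade.
#'
#' @param msa A `locus_msa` with at least 4 taxa.
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed; identical seeds give identical supports.
#' @param outgroups Taxa to root on (must be present in the alignment).
#' @param cap Saturation cap for JC distances.
#' @return A rooted `phylo` whose `node.label` carries integer supports
#'   (0-100; NA on the root).
#' @export
bootstrap_tree <- function(msa, n_replicates = 1000, seed = NULL,
                           outgroups = character(0), cap = 3) {
  if (length(msa$taxa) < 4) abort("need at least 4 taxa")
  missing_og <- setdiff(outgroups, msa$taxa)
  if (length(missing_og) > 0) {
    abort(sprintf("outgroup(s) not in alignment: %s",
                  paste(missing_og, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  m <- msa_matrix(msa)
  phy <- nj_from_matrix(m, cap = cap)
  counts <- suppressWarnings(ape::boot.phylo(
    phy, m,
    FUN = function(xx) {
      tryCatch(nj_from_matrix(xx, cap = cap), error = function(e) phy)
    },
    B = n_replicates, rooted = FALSE, quiet = TRUE
  ))
  support <- as.integer(round(100 * counts / n_replicates))
  phy$node.label <- support
  if (length(outgroups) > 0) {
    rooted <- tryCatch(
      ape::root(phy, outgroup = outgroups, resolve.root = TRUE, edgelabel = TRUE),
      error = function(e) {
        warn(sprintf("outgroups not monophyletic; rooting on '%s'", outgroups[1]))
        ape::root(phy, outgroup = outgroups[1], resolve.root = TRUE, edgelabel = TRUE)
      }
    )
    phy <- rooted
  }
  phy
}

# Tip sets per internal node (node ids ntip+1 .. ntip+Nnode).
node_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(idx) labs[idx])
}

#' Mean bootstrap support over ingroup internal edges
#'
#' Arithmetic mean of the support values carried on the tree's internal
#' nodes, restricted by default to the ingroup: the root, the ingroup crown
#' node (whose edge is the ingroup/outgroup split) and every node inside the
#' outgroup clade are excluded. `scope = "all"` averages every internal
#' node except the root.
#'
#' @param tree Rooted `phylo` from [bootstrap_tree()] with `node.label`
#'   supports.
#' @param outgroups Outgroup tip labels (ignored for `scope = "all"`).
#' @param scope "ingroup" (default) or "all".
#' @return Mean support (numeric scalar in 0..100).
#' @export
mean_bs <- function(tree, outgroups = character(0), scope = c("ingroup", "all")) {
  scope <- match.arg(scope)
  if (is.null(tree$node.label)) abort("tree carries no support values")
  ntip <- length(tree$tip.label)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  tip_sets <- node_tip_sets(tree)
  ingroup <- setdiff(tree$tip.label, outgroups)
  use <- logical(tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    tips <- tip_sets[[k]]
    if (length(tips) == ntip) next  # root
    if (scope == "all") {
      use[k] <- TRUE
    } else {
      all_in <- all(tips %in% ingroup)
      crown <- all_in && setequal(tips, ingroup)
      use[k] <- all_in && !crown
    }
  }
  use <- use & !is.na(supports)
  if (!any(use)) abort("no internal ingroup edges with support values")
  mean(supports[use])
}
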