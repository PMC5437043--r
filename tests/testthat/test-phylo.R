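# Build a locus_msa directly from gapped rows.
msa_from_rows <- function(rows, locus = "toy") {
  structure(list(locus = locus, taxa = names(rows),
                 rows = unlist(rows), length = nchar(rows[[1]])),
            class = "locus_msa")
}

test_that("JC distances match ape::dist.dna under pairwise deletion", {
  set.seed(60)
  taxa <- paste0("t", 1:5)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 300, TRUE), nrow = 5,
              dimnames = list(taxa, NULL))
  # plant close pairs so distances are in the JC-defined range
  m[2, ] <- m[1, ]; flip <- sample(300, 30); m[2, flip] <- sample(c("A", "C", "G", "T"), 30, TRUE)
  m[4, ] <- m[3, ]
  d_pkg <- suppressWarnings(plastohotspot:::jc_distance_matrix(m))
  d_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "JC69",
                                   pairwise.deletion = TRUE))
  ok <- is.finite(d_ape)
  expect_equal(d_pkg[ok], d_ape[ok], tolerance = 1e-12)
})

test_that("saturated or unscorable pairs are handled explicitly", {
  rows <- list(a = "AAAAAAAAAA", b = "CCCCCCCCCC", c = "AAAAAAAAAC",
               d = "AAAAAAAACC")
  m <- do.call(rbind, lapply(rows, function(x) strsplit(x, "")[[1]]))
  w <- capture_warnings(d <- plastohotspot:::jc_distance_matrix(m, cap = 3))
  expect_match(w, "saturated", all = TRUE)
  expect_equal(d["a", "b"], 3)

  rows2 <- list(a = "ACGT----", b = "----ACGT", c = "ACGTACGT", d = "ACGTACGT")
  m2 <- do.call(rbind, lapply(rows2, function(x) strsplit(x, "")[[1]]))
  expect_error(plastohotspot:::jc_distance_matrix(m2), "a.*b")
})

test_that("NJ recovers the generating topology from additive signal", {
  # 60 diagnostic columns split (a,b) from (c,d); NJ must find that split
  base <- strsplit(random_dna_str(200), "")[[1]]
  a <- base; b <- base; c <- base; d <- base
  idx_ab <- 1:30; idx_cd <- 101:130
  b[idx_ab] <- "A"; a[idx_ab] <- "A"
  c[idx_cd] <- "C"; d[idx_cd] <- "C"
  a[51:60] <- "G"  # private noise
  rows <- lapply(list(a = a, b = b, c = c, d = d), paste, collapse = "")
  msa <- msa_from_rows(rows)
  tree <- bootstrap_tree(msa, n_replicates = 50, seed = 4)
  expect_true(ape::is.monophyletic(tree, c("a", "b")) ||
                ape::is.monophyletic(tree, c("c", "d")))
})

test_that("unanimous signal earns 100% support and seeds reproduce exactly", {
  base <- strsplit(random_dna_str(300), "")[[1]]
  mk <- function(mut_at, ch) {
    x <- base; x[mut_at] <- ch; paste(x, collapse = "")
  }
  rows <- list(
    a = mk(1:50, "A"), b = mk(1:50, "A"),
    c = mk(151:160, "C"), d = mk(161:170, "G"), og = mk(251:300, "T")
  )
  msa <- msa_from_rows(rows)
  t1 <- bootstrap_tree(msa, n_replicates = 100, seed = 11, outgroups = "og")
  t2 <- bootstrap_tree(msa, n_replicates = 100, seed = 11, outgroups = "og")
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the (a,b) clade has 50 diagnostic columns: support 100
  sets <- plastohotspot:::node_tip_sets(t1)
  lab <- suppressWarnings(as.numeric(t1$node.label))
  ab <- which(vapply(sets, function(s) setequal(s, c("a", "b")), logical(1)))
  expect_equal(lab[ab], 100)
  t3 <- bootstrap_tree(msa, n_replicates = 100, seed = 12, outgroups = "og")
  expect_true(all(suppressWarnings(as.numeric(t3$node.label)) >= 0, na.rm = TRUE))
})

test_that("mean_bs averages ingroup internal edges only", {
  tree <- ape::read.tree(text = "((((a:1,b:1)60:1,(c:1,d:1)100:1)80:1,e:1)crown:1,og:1)root;")
  expect_equal(mean_bs(tree, outgroups = "og"), mean(c(60, 100, 80)))
  expect_equal(mean_bs(tree, outgroups = "og", scope = "all"),
               mean(c(60, 100, 80)))
  # trivially: single support value
  t2 <- ape::read.tree(text = "(((a:1,b:1)90:1,c:1)crown:1,og:1)root;")
  expect_equal(mean_bs(t2, outgroups = "og"), 90)
  t3 <- ape::read.tree(text = "((a:1,b:1)crown:1,og:1)root;")
  expect_error(mean_bs(t3, outgroups = "og"), "no internal")
})

test_that("combination enumeration is complete, ordered, and guarded", {
  expect_equal(length(enumerate_combinations(paste0("h", 1:10))), 1023)
  combos3 <- enumerate_combinations(c("b", "a", "c"))
  expect_equal(length(combos3), 7)
  expect_equal(combos3[[1]], "a")
  expect_equal(combos3[[7]], c("a", "b", "c"))
  expect_equal(enumerate_combinations("solo"), list("solo"))
  expect_error(enumerate_combinations(paste0("h", 1:17)), "16")
})

test_that("plateau analysis flags flat curves and fits the regression", {
  res <- tibble::tibble(
    combo = paste0("c", 1:7), loci = as.list(paste0("c", 1:7)),
    k = c(1, 1, 2, 2, 3, 3, 3), concat_length = 100 * (1:7),
    combo_sv = 10, mean_bs = 70
  )
  pa <- plateau_analysis(res)
  expect_equal(pa$fit$slope, 0)
  expect_equal(pa$plateau_k, 1)
  expect_equal(glance(pa)$plateau_mean_bs, 70)
  expect_equal(tidy(pa)$n, c(2L, 2L, 3L))

  res2 <- dplyr::mutate(res, mean_bs = c(50, 54, 70, 72, 80, 80, 81))
  pa2 <- plateau_analysis(res2, tol = 2)
  expect_equal(pa2$plateau_k, 3)
  ref <- lm(mean_bs ~ k, data = res2)
  expect_equal(pa2$fit$slope, unname(coef(ref)[2]), tolerance = 1e-9)
  p <- autoplot(pa2)
  expect_s3_class(p, "ggplot")
})

test_that("combo correlations report NA rows for constant predictors", {
  res <- tibble::tibble(
    combo = paste0("c", 1:4), k = 1L,
    concat_length = rep(500L, 4), combo_sv = c(5, 8, 2, 9),
    mean_bs = c(60, 75, 50, 80)
  )
  out <- combo_correlations(res)
  expect_equal(out$statistic[out$test == "mean_bs_vs_combo_sv"], 1)
  expect_true(is.na(out$statistic[out$test == "mean_bs_vs_concat_length"]))
})

test_that("top combinations rank by mean BS with the minimal-k tie rule", {
  res <- tibble::tibble(
    combo = c("a+b+c+d+e+f+g", "a+b+c+d+e", "x", "y+z"),
    k = c(7L, 5L, 1L, 2L),
    concat_length = c(3500L, 2500L, 500L, 1000L),
    combo_sv = c(9, 9, 4, 6),
    mean_bs = c(90, 90, 60, 80)
  )
  top <- top_combinations(res, n = 10)
  expect_equal(top$combo[1], "a+b+c+d+e")  # equal BS, smaller k first
  rec <- attr(top, "recommendation")
  expect_equal(rec$combo, "x")  # minimal k within the returned top set
  expect_true(top$recommended[top$combo == "x"])
  expect_equal(nrow(top_combinations(res, n = 2)), 2)
})
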