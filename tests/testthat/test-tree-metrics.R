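test_that("edge overlap is 100% for identical resolved trees", {
  set.seed(41)
  tr <- ape::rtree(8)
  ov <- edge_overlap(tr, tr)
  expect_identical(ov$n_source, 5L)  # 8 leaves -> n-3 internal edges
  expect_equal(ov$pct_source_in_ref, 100)
  expect_equal(ov$pct_ref_in_source, 100)
  expect_equal(ov$mean_pct, 100)
})

test_that("star trees have no bipartitions and report the undefined sentinel", {
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  ref <- ape::read.tree(text = "((a,b),(c,d),e);")
  ov <- edge_overlap(star, ref)
  expect_identical(ov$n_source, 0L)
  expect_true(is.na(ov$pct_source_in_ref))
  expect_equal(ov$pct_ref_in_source, 0)
  expect_error(edge_overlap(ape::rtree(3), ape::rtree(3)), "fewer than 4")
})

test_that("overlap equals the brute-force bipartition oracle on random trees", {
  set.seed(17)
  for (i in 1:10) {
    t1 <- ape::rtree(6)
    t2 <- ape::rtree(6)
    t2$tip.label <- sample(t1$tip.label)  # same leaf set, different topology
    b1 <- oracle_bipartitions(t1)
    b2 <- oracle_bipartitions(t2)
    ov <- edge_overlap(t1, t2)
    expect_identical(ov$shared_bipartitions, length(intersect(b1, b2)))
    expect_identical(ov$n_source, length(b1))
    expect_identical(ov$n_reference, length(b2))
    # symmetry under argument swap
    ov2 <- edge_overlap(t2, t1)
    expect_identical(ov2$pct_source_in_ref, ov$pct_ref_in_source)
  }
})

test_that("overlap agrees with the Robinson-Foulds relation", {
  skip_if_not_installed("phangorn")
  set.seed(19)
  for (i in 1:5) {
    t1 <- ape::unroot(ape::rtree(10))
    t2 <- ape::unroot(ape::rtree(10))
    t2$tip.label <- sample(t1$tip.label)
    ov <- edge_overlap(t1, t2)
    rf <- phangorn::RF.dist(t1, t2)
    expect_identical(2L * ov$shared_bipartitions,
                     ov$n_source + ov$n_reference - as.integer(rf))
  }
})

test_that("trees are pruned to the shared leaf set before comparison", {
  t1 <- ape::read.tree(text = "((a,b),((c,d),(e,x1)));")
  t2 <- ape::read.tree(text = "((a,b),((c,d),(e,x2)));")
  ov <- edge_overlap(t1, t2)   # shared leaves a..e
  expect_equal(ov$mean_pct, 100)
})

test_that("fitch length matches minimal-change intuition and the oracle", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  synapo <- stats::setNames(c(1, 1, 1, 1, 0, 0, 0, 0), letters[1:8])
  expect_identical(fitch_length(tr, synapo), 1L)
  constant <- stats::setNames(rep(1, 8), letters[1:8])
  expect_identical(fitch_length(tr, constant), 0L)
  allq <- stats::setNames(rep(NA_integer_, 8), letters[1:8])
  expect_identical(fitch_length(tr, allq), 0L)

  set.seed(23)
  for (i in 1:40) {
    tree <- ape::rtree(8)
    states <- stats::setNames(sample(c(0L, 1L, NA), 8, replace = TRUE,
                                     prob = c(0.4, 0.4, 0.2)), tree$tip.label)
    expect_identical(fitch_length(tree, states), oracle_fitch(tree, states))
  }
  # polytomies are scored exactly too
  poly <- ape::read.tree(text = "((a,b,c),(d,e),(f,g,h));")
  states <- stats::setNames(c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 1L), letters[1:8])
  expect_identical(fitch_length(poly, states), oracle_fitch(poly, states))
})

test_that("retention index follows (g - s) / (g - m) with skipping", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  # clean 4/4 synapomorphy: s = 1, g = 4, m = 1 -> RI = 1
  m <- codonpair:::new_pairing_matrix(
    letters[1:8], "og1", "K",
    matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 8, 1))
  ri <- retention_index(tr, m)
  expect_equal(ri$per_character, 1)
  expect_equal(ri$mean_ri, 1)

  # maximal homoplasy on a 4-taxon tree: s = g = 2 -> RI = 0
  tr4 <- ape::read.tree(text = "((a,b),(c,d));")
  m4 <- codonpair:::new_pairing_matrix(
    letters[1:4], "og1", "K", matrix(c(1L, 0L, 1L, 0L), 4, 1))
  expect_equal(retention_index(tr4, m4)$per_character, 0)

  # autapomorphy: g = 1 = m -> undefined, skipped
  mu <- codonpair:::new_pairing_matrix(
    letters[1:4], "og1", "K", matrix(c(1L, 0L, 0L, 0L), 4, 1))
  riu <- retention_index(tr4, mu)
  expect_identical(riu$n_skipped, 1L)
  expect_true(is.na(riu$mean_ri))

  expect_error(retention_index(tr4, codonpair:::new_pairing_matrix(
    letters[1:4], character(0), character(0),
    matrix(integer(0), 4, 0))), "empty")
})

test_that("per-character RI matches the brute-force Fitch oracle", {
  set.seed(29)
  tree <- ape::rtree(10)
  n_char <- 50L
  cells <- matrix(sample(c(0L, 1L, NA), 10 * n_char, replace = TRUE,
                         prob = c(0.42, 0.42, 0.16)), 10, n_char,
                  dimnames = list(tree$tip.label, NULL))
  m <- codonpair:::new_pairing_matrix(tree$tip.label,
                                      sprintf("og%02d", 1:n_char),
                                      rep("K", n_char), cells)
  ri <- retention_index(tree, m)
  for (j in seq_len(n_char)) {
    s <- oracle_fitch(tree, cells[, j])
    n1 <- sum(cells[, j] == 1L, na.rm = TRUE)
    n0 <- sum(cells[, j] == 0L, na.rm = TRUE)
    g <- min(n0, n1); mm <- as.integer(n0 > 0 && n1 > 0)
    if (g > mm) {
      expect_equal(ri$per_character[j], (g - s) / (g - mm))
      expect_gte(ri$per_character[j], 0)
      expect_lte(ri$per_character[j], 1)
    } else {
      expect_true(is.na(ri$per_character[j]))
    }
  }
})

test_that("the RI permutation test detects clean signal and is reproducible", {
  # caterpillar topology: its label automorphism group is tiny, so random
  # permutations essentially never reproduce a perfect fit
  tr <- ape::read.tree(text = "((((((a,b),c),d),e),f),(g,h));")
  # characters that are all clean synapomorphies of the true tree
  clade1 <- function(taxa) as.integer(letters[1:8] %in% taxa)
  cols <- cbind(clade1(c("a", "b")), clade1(c("a", "b", "c")),
                clade1(c("a", "b", "c", "d")), clade1(letters[1:5]),
                clade1(letters[1:6]), clade1(c("g", "h")))
  rownames(cols) <- letters[1:8]
  m <- codonpair:::new_pairing_matrix(letters[1:8],
                                      sprintf("og%d", 1:6), rep("K", 6), cols)
  res <- ri_permutation_test(tr, m, n_perm = 200, seed = 42)
  expect_equal(res$observed_mean_ri, 1)
  expect_true(all(res$null_mean_ri < 1))
  expect_equal(res$p_value, 1 / 201)
  res2 <- ri_permutation_test(tr, m, n_perm = 200, seed = 42)
  expect_identical(res$null_mean_ri, res2$null_mean_ri)
  expect_error(ri_permutation_test(tr, m, n_perm = 0, seed = 1), "n_perm")
})

test_that("saturation profile reports ceiling fraction and excludes strangers", {
  set.seed(37)
  tr <- ape::rtree(6)
  ids <- tr$tip.label
  ones <- matrix(1, 6, 6, dimnames = list(ids, ids)); diag(ones) <- 0
  sp <- saturation_profile(ones, tr)
  expect_equal(sp$saturation_fraction, 1)
  zeros <- matrix(0, 6, 6, dimnames = list(ids, ids))
  expect_equal(saturation_profile(zeros, tr)$saturation_fraction, 0)
  # taxonomic distance is the topological path length in edges
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  dm <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  spb <- saturation_profile(dm, bal)
  ab <- spb$pairs$taxonomic_distance[spb$pairs$species_a == "a" &
                                       spb$pairs$species_b == "b" |
                                       spb$pairs$species_a == "b" &
                                       spb$pairs$species_b == "a"]
  expect_equal(ab, 2)
  # species missing from the reference are excluded with a warning
  dm2 <- rbind(cbind(ones, zz = 1), zz = c(rep(1, 6), 0))
  colnames(dm2)[7] <- rownames(dm2)[7] <- "zz"
  expect_warning(sp2 <- saturation_profile(dm2, tr), "zz")
  expect_identical(sp2$excluded_species, "zz")
  expect_identical(nrow(sp2$pairs), 15L)
})
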