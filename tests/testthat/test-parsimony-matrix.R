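code <- genetic_code(1)

# Four species sharing ortholog G; AAA pairs (adjacent duplicates) in the
# first two only. sp3/sp4 carry AAA once, so the symbol exists but cannot pair.
fixture_sets <- function() {
  pairing <- "AAAAAACCCGGG"      # AAA AAA CCC GGG -> AAA pairs at w=2
  nonpairing <- "AAACCCGGGTGG"   # AAA once -> no pairing
  list(make_gene_set("sp1", c(G = pairing,    H = "CTTCTTAAACCC")),
       make_gene_set("sp2", c(G = pairing,    H = "AAACCCGGGTGG")),
       make_gene_set("sp3", c(G = nonpairing, H = "AAACCCGGGTGG")),
       make_gene_set("sp4", c(G = nonpairing)))
}

test_that("raw matrix encodes 1/0/? from pairing, presence and absence", {
  m <- assemble_raw_matrix(fixture_sets(), "identical", 2, code)
  expect_s3_class(m, "pairing_matrix")
  col_g <- which(m$ortholog == "G" & m$symbol == "AAA")
  expect_length(col_g, 1L)
  expect_identical(unname(m$cells[, col_g]), c(1L, 1L, 0L, 0L))
  # sp4 lacks ortholog H -> '?' in all H columns
  col_h <- which(m$ortholog == "H")
  expect_true(length(col_h) >= 1L)
  expect_true(all(is.na(m$cells["sp4", col_h])))
  # CCC never pairs in G for any species -> no (G, CCC) column
  expect_false(any(m$ortholog == "G" & m$symbol == "CCC"))
  expect_error(assemble_raw_matrix(fixture_sets()[1:3], "identical", 2, code),
               "at least 4")
})

test_that("the informative filter enforces the three conditions", {
  sp <- sprintf("sp%d", 1:5)
  og <- c("a", "a", "b", "c")
  sym <- c("K", "L", "K", "K")
  cells <- rbind(c(1L, 1L, 1L, 1L),
                 c(1L, 0L, 0L, NA),
                 c(1L, NA, NA, NA),
                 c(0L, 1L, 1L, NA),
                 c(NA, 0L, 0L, NA))
  m <- codonpair:::new_pairing_matrix(sp, og, sym, cells)
  f <- filter_informative(m)
  # cols 1-3 are called in >= 4 species and show both states: retained.
  # col 4: ortholog c called in fewer than 4 species: dropped.
  expect_identical(f$ortholog, c("a", "a", "b"))
  # a column lacking the 0 state is dropped
  m2 <- codonpair:::new_pairing_matrix(sp[1:4], "a", "K",
                                       matrix(c(1L, 1L, 1L, NA), 4, 1))
  expect_error(filter_informative(m2), "no parsimony-informative")
  # strict mode requires two taxa per state (drops autapomorphies)
  m3 <- codonpair:::new_pairing_matrix(sp, c("a", "a"), c("K", "L"),
                                       cbind(c(1L, 0L, 0L, 0L, 0L),
                                             c(1L, 0L, 0L, 0L, NA)))
  expect_error(filter_informative(m3, strict = TRUE), "no parsimony")
  f3 <- filter_informative(m3)
  expect_identical(ncol(f3$cells), 2L)
})

test_that("species coverage filter removes sparse species and flags dead groups", {
  n_char <- 100L
  sp <- sprintf("sp%03d", 1:20)
  cells <- matrix(1L, 20, n_char)
  cells[20, seq_len(97)] <- NA  # 3% coverage -> removed
  m <- codonpair:::new_pairing_matrix(sp, rep("og1", n_char),
                                      sprintf("s%03d", 1:n_char), cells)
  f <- filter_species_coverage(m)
  expect_identical(f$species, sp[1:19])
  # full coverage -> unchanged
  m2 <- codonpair:::new_pairing_matrix(sp, m$ortholog, m$symbol,
                                       matrix(1L, 20, n_char))
  expect_identical(filter_species_coverage(m2)$species, sp)
  # 100 species, only 4 qualify -> group not analyzable (4% < 5%)
  cells3 <- matrix(NA_integer_, 100, n_char)
  cells3[1:4, ] <- 1L
  cells3[5:100, 1:2] <- 1L  # 2% coverage each
  m3 <- codonpair:::new_pairing_matrix(sprintf("t%03d", 1:100),
                                       m$ortholog, m$symbol, cells3)
  expect_error(filter_species_coverage(m3), class = "codonpair_skipped_group")
  # 5 of 100 passing is exactly 5% -> analyzable
  cells3[5, ] <- 1L
  m4 <- codonpair:::new_pairing_matrix(sprintf("t%03d", 1:100),
                                       m$ortholog, m$symbol, cells3)
  expect_identical(length(filter_species_coverage(m4)$species), 5L)
})

test_that("filtering is invariant to species input order", {
  set.seed(31)
  sets <- fixture_sets()
  m1 <- filter_informative(assemble_raw_matrix(sets, "identical", 2, code))
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- filter_informative(assemble_raw_matrix(sets[perm], "identical", 2, code))
  expect_identical(m1$ortholog, m2$ortholog)
  expect_identical(m1$symbol, m2$symbol)
  expect_identical(m1$cells[m2$species, , drop = FALSE], m2$cells)
})

test_that("matrix cells agree with direct pairing recomputation", {
  set.seed(77)
  tr <- ape::rtree(6)
  cfg <- simulation_config(tr, n_orthologs = 20, flip_rate = 0.5, seed = 9,
                           missingness = 0.2)
  sets <- realize_sequences(evolve_states(cfg), cfg)
  m <- assemble_raw_matrix(sets, "combined", 9, code)
  for (k in 1:100) {
    i <- sample(length(m$species), 1)
    j <- sample(ncol(m$cells), 1)
    gs <- sets[[m$species[i]]]
    og <- m$ortholog[j]
    if (!og %in% names(gs$genes)) {
      expect_true(is.na(m$cells[i, j]))
    } else {
      ps <- gene_pairing_set(gs$genes[[og]], "combined", 9, code)
      expect_identical(unname(m$cells[i, j]), as.integer(m$symbol[j] %in% ps))
    }
  }
})

test_that("TNT export writes the xread block, key order and name map", {
  m <- codonpair:::new_pairing_matrix(
    c("sp 1", "sp2"), c("og1", "og2"), c("AAA", "K"),
    rbind(c(1L, 0L), c(NA, 1L)))
  mp <- tempfile(); kp <- tempfile(); np <- tempfile()
  write_tnt(m, mp, kp, np)
  lines <- readLines(mp)
  expect_identical(lines[1], "xread")
  expect_identical(lines[2], "2 2")
  expect_identical(lines[3], "sp_1 10")
  expect_identical(lines[4], "sp2 ?1")
  expect_identical(lines[5], ";")
  keys <- readLines(kp)
  expect_identical(keys, c("og1\tAAA", "og2\tK"))
  nm <- utils::read.delim(np)
  expect_identical(nm$species_id, c("sp 1", "sp2"))
})

test_that("TNT write/read/write round trips bit-exactly", {
  set.seed(13)
  for (i in 1:50) {
    m <- random_pairing_matrix(n_species = sample(4:10, 1),
                               n_orth = sample(2:6, 1),
                               n_sym = sample(1:4, 1))
    p1 <- tempfile(); k1 <- tempfile()
    write_tnt(m, p1, k1)
    m2 <- read_tnt(p1, k1)
    expect_identical(unname(m2$cells), unname(m$cells))
    expect_identical(m2$ortholog, m$ortholog)
    expect_identical(m2$symbol, m$symbol)
    p2 <- tempfile(); k2 <- tempfile()
    write_tnt(m2, p2, k2)
    expect_identical(readLines(p1), readLines(p2))
    expect_identical(readLines(k1), readLines(k2))
  }
})
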