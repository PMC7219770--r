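#' @title Tree evaluation metrics
#' @description Bipartition edge overlap between trees, Fitch parsimony steps,
#'   retention index with a leaf-label permutation null, and distance
#'   saturation diagnostics.
#' @name tree_metrics
NULL

# Canonical non-trivial bipartitions of an unrooted tree, encoded as sorted
# label strings of the side not containing the alphabetically first leaf.
tree_bipartitions <- function(tree) {
  labels <- tree$tip.label
  n <- length(labels)
  if (n < 4L) return(character(0))
  tree <- ape::unroot(tree)
  anchor <- sort(labels)[1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (s in pp) {
    side <- labels[s]
    if (anchor %in% side) side <- setdiff(labels, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Percent edge (bipartition) overlap between two trees
#'
#' Both trees are pruned to their shared leaf set and compared unrooted: the
#' non-trivial bipartitions (internal edges) are enumerated and the shared
#' count is expressed as a percentage of each tree's bipartitions, plus their
#' mean (the headline number). Polytomies contribute only the bipartitions
#' they actually resolve, so a star tree has none and its directional
#' percentage is reported as `NA`.
#'
#' @param source,reference `phylo` trees sharing at least 4 leaves.
#' @return object of class `edge_overlap` with `shared_bipartitions`,
#'   `n_source`, `n_reference`, `pct_source_in_ref`, `pct_ref_in_source`,
#'   `mean_pct`.
#' @export
edge_overlap <- function(source, reference) {
  shared <- intersect(source$tip.label, reference$tip.label)
  if (length(shared) < 4L) stop("trees share fewer than 4 leaves", call. = FALSE)
  s <- if (length(shared) < length(source$tip.label))
    ape::keep.tip(source, shared) else source
  r <- if (length(shared) < length(reference$tip.label))
    ape::keep.tip(reference, shared) else reference
  bs <- tree_bipartitions(s)
  br <- tree_bipartitions(r)
  k <- length(intersect(bs, br))
  pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  p1 <- pct(k, length(bs))
  p2 <- pct(k, length(br))
  mean_pct <- if (all(is.na(c(p1, p2)))) NA_real_ else mean(c(p1, p2), na.rm = TRUE)
  structure(list(shared_bipartitions = k, n_source = length(bs),
                 n_reference = length(br), pct_source_in_ref = p1,
                 pct_ref_in_source = p2, mean_pct = mean_pct),
            class = "edge_overlap")
}

#' @export
print.edge_overlap <- function(x, ...) {
  cat(sprintf("Edge overlap: %d shared bipartitions (source %d, reference %d); mean %.1f%%\n",
              x$shared_bipartitions, x$n_source, x$n_reference, x$mean_pct))
  invisible(x)
}

#' Average edge overlap of several source trees against one reference
#'
#' For analyses that return multiple equally parsimonious trees, each tree is
#' compared to the reference and the mean of the per-tree mean percentages is
#' reported.
#'
#' @param sources list of `phylo` trees.
#' @param reference `phylo` tree.
#' @return average `mean_pct` across comparisons.
#' @export
edge_overlap_avg <- function(sources, reference) {
  mean(vapply(sources, function(t) edge_overlap(t, reference)$mean_pct, 0))
}

# Minimum parsimony steps for each binary character column on a tree
# (Sankoff dynamic program with unit costs; exact on polytomies, '?' = {0,1}).
# cells: species x characters matrix over {0L, 1L, NA}; rownames = species,
# all of which must be tree leaves. Returns an integer vector per column.
parsimony_steps <- function(tree, cells) {
  sp <- rownames(cells)
  extra <- setdiff(tree$tip.label, sp)
  if (length(extra)) tree <- ape::keep.tip(tree, sp)
  if (!all(sp %in% tree$tip.label)) {
    stop("tree does not cover all matrix species", call. = FALSE)
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  total <- ntip + tree$Nnode
  k <- ncol(cells)
  if (k == 0L) return(integer(0))
  BIG <- 1e9
  states <- cells[match(tree$tip.label, sp), , drop = FALSE]
  C0 <- matrix(0, total, k)
  C1 <- matrix(0, total, k)
  C0[seq_len(ntip), ] <- ifelse(is.na(states) | states == 0L, 0, BIG)
  C1[seq_len(ntip), ] <- ifelse(is.na(states) | states == 1L, 0, BIG)
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    C0[p, ] <- C0[p, ] + pmin(C0[ch, ], C1[ch, ] + 1)
    C1[p, ] <- C1[p, ] + pmin(C1[ch, ], C0[ch, ] + 1)
  }
  root <- edge[nrow(edge), 1L]
  steps <- pmin(C0[root, ], C1[root, ])
  as.integer(round(steps))
}

#' Fitch parsimony length of one binary character
#'
#' Minimum number of state changes of a 0/1 character on a tree; `?` (`NA`)
#' cells are fully ambiguous. Exact also for multifurcating trees. An all-`?`
#' character costs 0 steps.
#'
#' @param tree `phylo` covering the scored taxa.
#' @param column named vector over `{0, 1, NA}`; names are taxa.
#' @return integer step count.
#' @export
fitch_length <- function(tree, column) {
  cells <- matrix(as.integer(column), ncol = 1L,
                  dimnames = list(names(column), NULL))
  parsimony_steps(tree, cells)[1L]
}

ri_components <- function(m) {
  n1 <- colSums(m$cells == 1L, na.rm = TRUE)
  n0 <- colSums(m$cells == 0L, na.rm = TRUE)
  g <- pmin(n0, n1)                       # max steps (star-tree bound)
  m_min <- as.integer(n0 > 0L & n1 > 0L)  # min steps: 1 if both states present
  list(g = g, m_min = m_min)
}

#' Retention index of a character matrix on a tree
#'
#' Per character with observed steps `s`, minimum steps `m` (1 if both states
#' occur, else 0) and maximum steps `g = min(#0, #1)` over scored taxa:
#' `RI = (g - s) / (g - m)`. An RI of 1 means the character fits the tree with
#' no reversals or parallel gains/losses; 0 means maximal homoplasy.
#' Characters with `g <= m` have an undefined RI and are skipped from the
#' per-character mean (the headline statistic); the ensemble RI
#' `(sum g - sum s) / (sum g - sum m)` pools all characters.
#'
#' @param tree `phylo` covering the matrix species.
#' @param m a `pairing_matrix`.
#' @return object of class `ri_report`: `per_character` (NA where undefined),
#'   `mean_ri`, `ensemble_ri`, `n_skipped`.
#' @export
retention_index <- function(tree, m) {
  if (ncol(m$cells) == 0L) stop("empty character matrix", call. = FALSE)
  comp <- ri_components(m)
  s <- parsimony_steps(tree, m$cells)
  defined <- comp$g > comp$m_min
  ri <- rep(NA_real_, length(s))
  ri[defined] <- (comp$g[defined] - s[defined]) / (comp$g[defined] - comp$m_min[defined])
  den <- sum(comp$g) - sum(comp$m_min)
  structure(list(
    per_character = ri,
    mean_ri = if (any(defined)) mean(ri[defined]) else NA_real_,
    ensemble_ri = if (den > 0) (sum(comp$g) - sum(s)) / den else NA_real_,
    n_skipped = sum(!defined)
  ), class = "ri_report")
}

#' @export
print.ri_report <- function(x, ...) {
  cat(sprintf("Retention index: mean %.4f over %d characters (%d undefined skipped); ensemble %.4f\n",
              x$mean_ri, sum(!is.na(x$per_character)), x$n_skipped, x$ensemble_ri))
  invisible(x)
}

#' Permutation test for phylogenetic signal in the retention index
#'
#' Shuffles species placement on the reference topology (leaf labels only;
#' topology and branch lengths fixed) `n_perm` times, recomputes the mean
#' retention index for each shuffle, and reports the empirical p-value
#' `(1 + #{null >= observed}) / (1 + n_perm)`. A strong phylogenetic signal
#' puts the observed mean above the whole null distribution.
#'
#' @inheritParams retention_index
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (required for reproducible published runs).
#' @return object of class `ri_permutation`: `observed_mean_ri`,
#'   `null_mean_ri`, `p_value`, `n_perm`, `seed`.
#' @export
ri_permutation_test <- function(tree, m, n_perm = 1000L, seed) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs <- retention_index(tree, m)
  comp <- ri_components(m)
  defined <- comp$g > comp$m_min
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    cells <- m$cells
    rownames(cells) <- sample(m$species)
    s <- parsimony_steps(tree, cells)
    mean((comp$g[defined] - s[defined]) / (comp$g[defined] - comp$m_min[defined]))
  }, 0)
  structure(list(
    observed_mean_ri = obs$mean_ri,
    null_mean_ri = null,
    p_value = (1 + sum(null >= obs$mean_ri)) / (1 + n_perm),
    n_perm = n_perm,
    seed = seed
  ), class = "ri_permutation")
}

#' @export
print.ri_permutation <- function(x, ...) {
  cat(sprintf("RI permutation test: observed mean RI %.4f vs null mean %.4f (%d perms), p = %.4g\n",
              x$observed_mean_ri, mean(x$null_mean_ri), x$n_perm, x$p_value))
  invisible(x)
}

#' Distance saturation diagnostic
#'
#' Pairs each computed alignment-free distance with the taxonomic distance of
#' the two species on a reference tree (topological path length in edges).
#' Computed distances of exactly 1.0 mean the metric is fully saturated for
#' that pair and cannot separate deeper divergences; the saturation fraction
#' is the share of such pairs. A Spearman rank correlation between the two
#' distances is also reported.
#'
#' @param dm distance matrix with species ids as dimnames.
#' @param reference `phylo` reference tree.
#' @return object of class `saturation_profile`: `pairs` (data frame with
#'   `species_a`, `species_b`, `taxonomic_distance`, `computed_distance`),
#'   `saturation_fraction`, `spearman_rho`, `excluded_species`.
#' @export
saturation_profile <- function(dm, reference) {
  ids <- rownames(dm)
  missing <- setdiff(ids, reference$tip.label)
  if (length(missing)) {
    warning("species absent from reference tree excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
    ids <- setdiff(ids, missing)
  }
  if (length(ids) < 2L) stop("fewer than 2 species shared with the reference", call. = FALSE)
  tr <- ape::keep.tip(reference, ids)
  tr$edge.length <- rep(1, nrow(tr$edge))
  td <- stats::cophenetic(tr)[ids, ids]
  dm <- dm[ids, ids]
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  pairs <- data.frame(
    species_a = ids[ut[, 1L]],
    species_b = ids[ut[, 2L]],
    taxonomic_distance = td[ut],
    computed_distance = dm[ut]
  )
  rho <- if (stats::sd(pairs$taxonomic_distance) > 0 && stats::sd(pairs$computed_distance) > 0)
    stats::cor(pairs$taxonomic_distance, pairs$computed_distance, method = "spearman")
  else NA_real_
  structure(list(pairs = pairs,
                 saturation_fraction = mean(pairs$computed_distance == 1),
                 spearman_rho = rho,
                 excluded_species = missing),
            class = "saturation_profile")
}

#' @export
print.saturation_profile <- function(x, ...) {
  cat(sprintf("Saturation: %.1f%% of %d pairs at the distance ceiling (1.0); Spearman rho %.3f\n",
              100 * x$saturation_fraction, nrow(x$pairs), x$spearman_rho))
  invisible(x)
}
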