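# Independent brute-force oracles used to check the fast implementations.

# Literal contiguous-window scan: slide every w-codon window over the gene and
# collect duplicated symbols, per mode. Deliberately dumb and independent of
# the lag-based implementation in the package.
oracle_pairing_all <- function(codons, w, code = genetic_code()) {
  aa <- unname(code$codon_to_aa[codons])
  valid <- !is.na(aa) & aa != "*"
  n <- length(codons)
  idc <- character(0); cot <- character(0); comb <- character(0)
  for (i in seq_len(max(n - w + 1L, 1L))) {
    sel <- i:min(i + w - 1L, n)
    v <- sel[valid[sel]]
    cs <- codons[v]
    as <- aa[v]
    idc <- union(idc, cs[duplicated(cs)])
    dup_a <- unique(as[duplicated(as)])
    comb <- union(comb, dup_a)
    for (r in dup_a) {
      if (length(unique(cs[as == r])) >= 2L) cot <- union(cot, r)
    }
  }
  list(identical = sort(idc), cotrna = sort(cot), combined = sort(comb))
}

# Random gene as a codon vector; draws from a per-gene codon pool so that
# pairings of all three kinds actually occur.
random_gene <- function(len, code = genetic_code(), pool_size = 25L) {
  pool <- sample(code$sense_codons, pool_size)
  sample(pool, len, replace = TRUE)
}

random_gene_corpus <- function(n_genes, len_range = c(50L, 500L),
                               code = genetic_code()) {
  lapply(seq_len(n_genes), function(i)
    random_gene(sample(len_range[1]:len_range[2], 1L), code))
}

# Exhaustive-minimization Fitch oracle: enumerate all 0/1 assignments of
# internal nodes (and fully ambiguous leaves) and count changed edges.
oracle_fitch <- function(tree, states) {
  ntip <- length(tree$tip.label)
  tipst <- as.integer(states[tree$tip.label])
  amb <- which(is.na(tipst))
  free_nodes <- c(ntip + seq_len(tree$Nnode), amb)
  stopifnot(length(free_nodes) <= 16L)
  assign_ <- integer(ntip + tree$Nnode)
  assign_[seq_len(ntip)] <- ifelse(is.na(tipst), 0L, tipst)
  best <- Inf
  for (mask in 0:(2^length(free_nodes) - 1L)) {
    assign_[free_nodes] <- as.integer(intToBits(mask))[seq_along(free_nodes)]
    cost <- sum(assign_[tree$edge[, 1]] != assign_[tree$edge[, 2]])
    if (cost < best) best <- cost
  }
  as.integer(best)
}

# Bipartition oracle: a leaf subset S is a split of the unrooted tree iff S is
# monophyletic after rooting at any leaf outside S. Enumerates all subsets.
oracle_bipartitions <- function(tree) {
  labels <- sort(tree$tip.label)
  n <- length(labels)
  anchor <- labels[1]
  out <- character(0)
  others <- setdiff(labels, anchor)
  for (mask in 1:(2^length(others) - 1L)) {
    side <- others[as.logical(intToBits(mask))[seq_along(others)]]
    if (length(side) < 2L || length(side) > n - 2L) next
    rooted <- ape::root(tree, outgroup = anchor, resolve.root = TRUE)
    if (ape::is.monophyletic(rooted, side)) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

# Build a species_gene_set directly from named CDS strings.
make_gene_set <- function(species_id, genes) {
  codonpair:::new_species_gene_set(species_id, genes)
}

make_profile <- function(id, motifs) {
  structure(list(species_id = id, motifs = motifs), class = "species_profile")
}

# Random pairing_matrix for serialization tests.
random_pairing_matrix <- function(n_species = 6L, n_orth = 4L, n_sym = 3L) {
  species <- sprintf("sp%02d", seq_len(n_species))
  og <- rep(sprintf("og%02d", seq_len(n_orth)), each = n_sym)
  sym <- rep(LETTERS[seq_len(n_sym)], n_orth)
  cells <- matrix(sample(c(0L, 1L, NA_integer_), n_species * length(og),
                         replace = TRUE, prob = c(0.4, 0.4, 0.2)),
                  n_species, length(og))
  codonpair:::new_pairing_matrix(species, og, sym, cells)
}

# FASTA fixture writer.
write_fasta_fixture <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(h) c(paste0(">", h), records[[h]])))
  writeLines(lines, path)
  path
}
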