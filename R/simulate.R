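#' @title Simulation of codon-pairing evolution
#' @description Evolves binary pairing states along a known tree under a
#'   symmetric two-state Markov model and realizes each species' states as
#'   coding sequences whose pairing sets recover the states exactly, so the
#'   whole pipeline (pairing -> distances -> NJ, matrix -> RI) is testable
#'   end to end without any downloads.
#' @name simulate
NULL

#' Simulation configuration
#'
#' @param tree `phylo` with branch lengths (the true species tree).
#' @param n_orthologs number of simulated genes per species.
#' @param root_pairing_prob Bernoulli probability that a (gene, symbol) pairs
#'   at the root.
#' @param flip_rate rate of the symmetric two-state Markov chain along
#'   branches; a child's state flips with probability
#'   `(1 - exp(-2 * flip_rate * branch_length)) / 2`, so disagreement
#'   saturates at 1/2 on long branches.
#' @param window ribosome window for realization/recovery.
#' @param mode pairing mode (`"combined"`, `"identical"`, `"cotrna"`).
#' @param gene_length target gene length in codons (`NULL` = as short as the
#'   construction allows; auto-extended with a warning if too short).
#' @param seed mandatory RNG seed.
#' @param n_symbols candidate symbols per ortholog (default 6): residues for
#'   residue modes (for cotrna, only multi-codon families), codons for
#'   identical mode.
#' @param missingness probability that a species lacks an ortholog call
#'   (exercises `?` handling downstream).
#' @param code a [genetic_code()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_orthologs, root_pairing_prob = 0.5,
                              flip_rate = 0.3, window = 9L,
                              mode = c("combined", "identical", "cotrna"),
                              gene_length = NULL, seed, n_symbols = 6L,
                              missingness = 0, code = genetic_code()) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(tree, "phylo"), n_orthologs >= 1L,
            root_pairing_prob >= 0, root_pairing_prob <= 1,
            flip_rate >= 0, missingness >= 0, missingness < 1)
  window <- assert_window(window)
  structure(list(tree = tree, n_orthologs = as.integer(n_orthologs),
                 root_pairing_prob = root_pairing_prob, flip_rate = flip_rate,
                 window = window, mode = mode, gene_length = gene_length,
                 seed = as.integer(seed), n_symbols = as.integer(n_symbols),
                 missingness = missingness, code = code),
            class = "simulation_config")
}

# Symbol alphabet the simulator draws candidate symbols from.
simulation_alphabet <- function(mode, code) {
  if (mode == "identical") return(code$sense_codons)
  res <- sort(unique(code$codon_to_aa[code$sense_codons]))
  if (mode == "cotrna") {
    fam <- table(code$codon_to_aa[code$sense_codons])
    res <- res[fam[res] >= 2L]  # single-codon families can never co-tRNA pair
  }
  res
}

#' Evolve binary pairing states along the tree
#'
#' Each ortholog gets `n_symbols` candidate symbols; each (ortholog, symbol)
#' state starts Bernoulli(`root_pairing_prob`) at the root and evolves down
#' the tree as a symmetric two-state Markov chain. With `missingness > 0`,
#' whole orthologs are dropped per species uniformly at random.
#'
#' @param cfg a [simulation_config()].
#' @return object of class `profile_state_table`: `species`, `ortholog`,
#'   `symbol` (parallel to columns), binary `states` matrix (species x
#'   columns) and logical `presence` matrix (species x orthologs).
#' @export
evolve_states <- function(cfg) {
  tree <- cfg$tree
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  alphabet <- simulation_alphabet(cfg$mode, cfg$code)
  if (cfg$n_symbols > length(alphabet)) {
    stop("n_symbols exceeds the available symbol alphabet (", length(alphabet), ")",
         call. = FALSE)
  }
  orthologs <- sprintf("og%04d", seq_len(cfg$n_orthologs))
  col_og <- rep(orthologs, each = cfg$n_symbols)
  col_sym <- unlist(lapply(orthologs, function(og)
    sort(sample(alphabet, cfg$n_symbols))), use.names = FALSE)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  k <- length(col_og)
  node_states <- matrix(NA_integer_, nnode, k)
  root <- ntip + 1L
  node_states[root, ] <- stats::rbinom(k, 1L, cfg$root_pairing_prob)
  # parent-before-child edge order
  edge <- stats::reorder(tree, "postorder")$edge
  el <- stats::reorder(tree, "postorder")$edge.length
  p_flip <- (1 - exp(-2 * cfg$flip_rate * el)) / 2
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    flips <- stats::rbinom(k, 1L, p_flip[e])
    node_states[ch, ] <- (node_states[par, ] + flips) %% 2L
  }
  states <- node_states[seq_len(ntip), , drop = FALSE]
  rownames(states) <- tree$tip.label
  presence <- matrix(stats::runif(ntip * cfg$n_orthologs) >= cfg$missingness,
                     ntip, cfg$n_orthologs,
                     dimnames = list(tree$tip.label, orthologs))
  # every species keeps at least one ortholog
  for (i in which(rowSums(presence) == 0L)) presence[i, 1L] <- TRUE
  structure(list(species = tree$tip.label, ortholog = col_og,
                 symbol = col_sym, states = states, presence = presence),
            class = "profile_state_table")
}

# Rotating filler supply: never emits the same codon (identical mode) or two
# codons from the same synonymous family (residue modes) within `window`
# positions, provided the pool has >= window elements or fewer fillers than
# pool elements are drawn.
make_filler_pool <- function(targets, mode, code) {
  if (mode == "identical") {
    sort(setdiff(code$sense_codons, targets))
  } else {
    aa <- code$codon_to_aa[code$sense_codons]
    free <- sort(setdiff(unique(aa), targets))
    vapply(free, function(r) sort(code$sense_codons[aa[code$sense_codons] == r])[1L], "")
  }
}

#' Realize a target pairing set as a coding sequence
#'
#' Builds a CDS whose [gene_pairing_set()] under (`mode`, `window`) equals
#' `target` exactly. Each target symbol is placed as a block of two adjacent
#' codons (identical duplicates for identical/combined mode; two distinct
#' synonymous codons for cotrna), blocks are separated by `window - 1` filler
#' codons, and fillers rotate through a pool of codons disjoint from the
#' target symbols (disjoint synonymous families for residue modes) so no
#' unintended pairing can arise within the window. A terminal stop codon is
#' appended.
#'
#' @param target character vector of symbols (codons or residues per `mode`).
#' @inheritParams gene_pairing_set
#' @param gene_length desired length in codons excluding the terminal stop;
#'   padded with fillers if longer than the construction, auto-extended with a
#'   warning if shorter.
#' @return CDS string (including terminal stop codon).
#' @export
realize_cds <- function(target, mode = c("combined", "identical", "cotrna"),
                        window = 9L, code = genetic_code(), gene_length = NULL) {
  mode <- match.arg(mode)
  window <- assert_window(window)
  target <- sort(unique(target))
  aa_of <- code$codon_to_aa
  fam <- function(r) sort(code$sense_codons[aa_of[code$sense_codons] == r])
  blocks <- lapply(target, function(s) {
    if (mode == "identical") {
      if (!s %in% code$sense_codons) stop("target is not a sense codon: ", s, call. = FALSE)
      c(s, s)
    } else {
      codons <- fam(s)
      if (length(codons) == 0L) stop("target is not an encoded residue: ", s, call. = FALSE)
      if (mode == "cotrna") {
        if (length(codons) < 2L) {
          stop("residue ", s, " has a single codon and cannot co-tRNA pair", call. = FALSE)
        }
        codons[1:2]
      } else {
        c(codons[1L], codons[1L])
      }
    }
  })
  pool <- make_filler_pool(target, mode, code)
  nb <- length(blocks)
  base_len <- 2L * nb + nb * (window - 1L)
  len <- max(base_len, window + 1L)
  if (!is.null(gene_length)) {
    if (gene_length < base_len) {
      warning("gene_length ", gene_length, " too short for ", nb,
              " target blocks at window ", window, "; extended to ", base_len,
              call. = FALSE)
    }
    len <- max(len, gene_length)
  }
  n_fillers <- len - 2L * nb
  if (length(pool) == 0L ||
      (length(pool) < window && n_fillers > length(pool))) {
    stop("target set leaves too few filler symbol families to avoid spurious pairing",
         call. = FALSE)
  }
  t <- 0L
  next_filler <- function(m) {
    idx <- ((t + seq_len(m) - 1L) %% length(pool)) + 1L
    t <<- t + m
    pool[idx]
  }
  out <- character(0)
  for (b in blocks) {
    out <- c(out, b, next_filler(window - 1L))
  }
  if (length(out) < len) out <- c(out, next_filler(len - length(out)))
  paste(c(out, code$stop_codons[1L]), collapse = "")
}

#' Realize an evolved state table as per-species gene sets
#'
#' @param states a `profile_state_table` from [evolve_states()].
#' @param cfg the [simulation_config()] used to evolve it.
#' @return named list of `species_gene_set` (genes keep their terminal stop;
#'   pairing is unaffected since stop codons never pair).
#' @export
realize_sequences <- function(states, cfg) {
  orthologs <- colnames(states$presence)
  sets <- lapply(states$species, function(sp) {
    present <- orthologs[states$presence[sp, ]]
    genes <- vapply(present, function(og) {
      sel <- states$ortholog == og & states$states[sp, ] == 1L
      realize_cds(states$symbol[sel], cfg$mode, cfg$window, cfg$code,
                  cfg$gene_length)
    }, "")
    new_species_gene_set(sp, genes)
  })
  names(sets) <- states$species
  sets
}

#' Simulate a complete dataset on disk
#'
#' Writes one FASTA per species (the expected input layout: a directory of
#' per-species CDS files), the true tree in newick, the true state table as
#' TSV, and a flat key=value manifest sufficient for exact replay.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir writable output directory (created if needed).
#' @return invisibly, a list with the gene `sets`, the `states` table and all
#'   output `paths`.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  states <- evolve_states(cfg)
  sets <- realize_sequences(states, cfg)
  fasta <- vapply(sets, function(gs) {
    p <- file.path(out_dir, paste0(gs$species_id, ".fasta"))
    write_species_fasta(gs, p)
    p
  }, "")
  tree_path <- file.path(out_dir, "true_tree.nwk")
  ape::write.tree(cfg$tree, tree_path)
  states_path <- file.path(out_dir, "true_states.tsv")
  st <- data.frame(ortholog = states$ortholog, symbol = states$symbol,
                   t(states$states), check.names = FALSE)
  utils::write.table(st, states_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(c(
    paste0("seed=", cfg$seed),
    paste0("n_orthologs=", cfg$n_orthologs),
    paste0("n_symbols=", cfg$n_symbols),
    paste0("mode=", cfg$mode),
    paste0("window=", cfg$window),
    paste0("flip_rate=", cfg$flip_rate),
    paste0("root_pairing_prob=", cfg$root_pairing_prob),
    paste0("missingness=", cfg$missingness),
    paste0("gene_length=", if (is.null(cfg$gene_length)) "auto" else cfg$gene_length),
    paste0("genetic_code_table=", cfg$code$table_id),
    paste0("n_species=", length(states$species))
  ), manifest_path)
  invisible(list(sets = sets, states = states,
                 paths = list(fasta = fasta, tree = tree_path,
                              states = states_path, manifest = manifest_path)))
}
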