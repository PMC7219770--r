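#' Census of pairing motifs across species
#'
#' Tallies, for every distinct motif, how many species contain it and how many
#' genes use it in total (occurrences across genes, so the occurrence count is
#' always at least the species count). Empty motifs are excluded.
#'
#' @param sets list of `species_gene_set`.
#' @inheritParams gene_pairing_set
#' @return object of class `motif_census`: data frame `table` with columns
#'   `motif`, `n_species`, `n_occurrences`, plus `mode` and `window`.
#' @export
motif_census <- function(sets, mode = c("combined", "identical", "cotrna"),
                         window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  per_species <- lapply(sets, function(gs) {
    m <- vapply(gs$genes, function(g)
      motif_key(gene_pairing_set(g, mode, window, code)), "", USE.NAMES = FALSE)
    m[nzchar(m)]
  })
  all_motifs <- unlist(per_species, use.names = FALSE)
  if (length(all_motifs) == 0L) {
    tab <- data.frame(motif = character(0), n_species = integer(0),
                      n_occurrences = integer(0))
  } else {
    occ <- table(all_motifs)
    nsp <- table(unlist(lapply(per_species, unique), use.names = FALSE))
    motifs <- sort(names(occ))
    tab <- data.frame(motif = motifs,
                      n_species = as.integer(nsp[motifs]),
                      n_occurrences = as.integer(occ[motifs]),
                      row.names = NULL)
  }
  structure(list(table = tab, mode = mode, window = as.integer(window)),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("Motif census (", x$mode, ", window ", x$window, "): ",
      nrow(x$table), " distinct motifs\n", sep = "")
  invisible(x)
}

#' Fraction of motifs found in more than one species
#'
#' The share of distinct motifs identified in at least two species — the
#' cross-species motif repetition rate.
#'
#' @param census a `motif_census`.
#' @return fraction in `[0, 1]`.
#' @export
shared_motif_fraction <- function(census) {
  if (nrow(census$table) == 0L) stop("empty motif census", call. = FALSE)
  mean(census$table$n_species >= 2L)
}

#' Distribution of motif sizes
#'
#' Counts distinct motifs by cardinality (number of symbols in the motif).
#' Codon motifs can span 1..61 symbols, residue motifs 1..20.
#'
#' @param census a `motif_census`.
#' @return named integer vector: size -> number of distinct motifs.
#' @export
motif_size_distribution <- function(census) {
  sizes <- lengths(strsplit(census$table$motif, ",", fixed = TRUE))
  tab <- table(factor(sizes, levels = seq_len(max(sizes, 1L))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Distribution of motif repeat counts
#'
#' Histogram of how many times each distinct motif occurs across genes (the
#' repeated-motif frequency distribution).
#'
#' @param census a `motif_census`.
#' @return named integer vector: occurrence count -> number of distinct motifs.
#' @export
motif_repeat_distribution <- function(census) {
  occ <- census$table$n_occurrences
  tab <- table(factor(occ, levels = seq_len(max(occ, 1L))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-symbol pairing frequency within a species
#'
#' For each codon (or residue) symbol, the fraction of the species' genes
#' whose pairing set contains it.
#'
#' @param gs a `species_gene_set`.
#' @inheritParams gene_pairing_set
#' @return named numeric vector over all symbols observed pairing (plus zeros
#'   for never-pairing sense codons/residues are omitted).
#' @export
codon_pairing_frequency <- function(gs, mode = c("combined", "identical", "cotrna"),
                                    window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  if (length(gs$genes) == 0L) stop("empty gene set", call. = FALSE)
  sets <- lapply(gs$genes, gene_pairing_set, mode = mode, window = window, code = code)
  symbols <- sort(unique(unlist(sets, use.names = FALSE)))
  counts <- vapply(symbols, function(s)
    sum(vapply(sets, function(x) s %in% x, NA)), 0L)
  counts / length(gs$genes)
}

#' Gene-length correlations of pairing counts
#'
#' Ordinary least-squares R-squared of (a) the total number of pairing events
#' (all in-window position pairs) and (b) the number of distinct paired
#' symbols, each against gene length in codons. The binary encoding is only
#' defensible if (a) tracks length while (b) does not.
#'
#' @param gs a `species_gene_set` with at least 3 genes.
#' @inheritParams gene_pairing_set
#' @return list with `r2_events`, `r2_distinct` (NA when the response is
#'   degenerate) and the underlying per-gene data frame.
#' @export
length_correlations <- function(gs, mode = c("combined", "identical", "cotrna"),
                                window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  if (length(gs$genes) < 3L) stop("need at least 3 genes", call. = FALSE)
  len <- vapply(gs$genes, function(g) length(as_codons(g)), 0L)
  events <- vapply(gs$genes, gene_pairing_events, 0L,
                   mode = mode, window = window, code = code)
  distinct <- vapply(gs$genes, function(g)
    length(gene_pairing_set(g, mode, window, code)), 0L)
  r2 <- function(y) {
    if (stats::sd(y) == 0 || stats::sd(len) == 0) return(NA_real_)
    stats::cor(len, y)^2
  }
  list(r2_events = r2(events), r2_distinct = r2(distinct),
       data = data.frame(ortholog_key = names(gs$genes), length_codons = len,
                         n_events = events, n_distinct = distinct,
                         row.names = NULL))
}
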