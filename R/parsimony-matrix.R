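#' @title Parsimony character matrix from codon pairing
#' @description Species x (ortholog, symbol) binary matrix over {0, 1, ?}
#'   built from sliding-window pairing, filtered to the informative columns
#'   and exported for TNT.
#' @name parsimony_matrix
NULL

new_pairing_matrix <- function(species, ortholog, symbol, cells) {
  stopifnot(nrow(cells) == length(species), ncol(cells) == length(ortholog),
            length(ortholog) == length(symbol))
  rownames(cells) <- species
  structure(list(species = species, ortholog = ortholog, symbol = symbol,
                 cells = cells),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat("Pairing character matrix:", length(x$species), "species x",
      ncol(x$cells), "characters;",
      sum(is.na(x$cells)), "missing ('?') cells\n")
  invisible(x)
}

#' @export
dim.pairing_matrix <- function(x) dim(x$cells)

#' Assemble the raw (unfiltered) pairing character matrix
#'
#' One column per (ortholog, symbol) combination where the symbol pairs in at
#' least one species carrying the ortholog. Cells are 1 if the symbol pairs
#' within the ribosomal window in that species' copy of the ortholog, 0 if it
#' does not, and `?` (stored as `NA`) when the ortholog call is unavailable
#' for the species. Columns are ordered by ortholog key then symbol, so the
#' matrix is invariant to species input order (up to row order).
#'
#' @param sets list of `species_gene_set` (at least 4 species).
#' @inheritParams gene_pairing_set
#' @return a `pairing_matrix`.
#' @export
assemble_raw_matrix <- function(sets, mode = c("combined", "identical", "cotrna"),
                                window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  if (length(sets) < 4L) stop("parsimony analysis needs at least 4 species", call. = FALSE)
  species <- vapply(sets, `[[`, "", "species_id")
  if (anyDuplicated(species)) stop("duplicate species ids", call. = FALSE)

  # per species: ortholog -> pairing set
  persp <- lapply(sets, function(gs) {
    ps <- lapply(gs$genes, gene_pairing_set, mode = mode, window = window, code = code)
    names(ps) <- names(gs$genes)
    ps
  })
  orthologs <- sort(unique(unlist(lapply(persp, names), use.names = FALSE)))

  col_og <- character(0); col_sym <- character(0)
  cols <- list()
  for (og in orthologs) {
    have <- vapply(persp, function(p) og %in% names(p), NA)
    syms <- sort(unique(unlist(lapply(persp[have], `[[`, og), use.names = FALSE)))
    if (length(syms) == 0L) next  # symbol must pair somewhere to get a column
    block <- matrix(NA_integer_, length(species), length(syms))
    for (s in which(have)) {
      block[s, ] <- as.integer(syms %in% persp[[s]][[og]])
    }
    cols[[length(cols) + 1L]] <- block
    col_og <- c(col_og, rep(og, length(syms)))
    col_sym <- c(col_sym, syms)
  }
  cells <- if (length(cols)) do.call(cbind, cols) else
    matrix(NA_integer_, length(species), 0L)
  new_pairing_matrix(species, col_og, col_sym, cells)
}

#' Keep only parsimony-informative columns
#'
#' A column is retained when its ortholog is present (non-`?`) in at least
#' four species, its symbol paired in at least one species, and failed to
#' pair in at least one species. `strict = TRUE` tightens the variability
#' requirement to the classical parsimony-informative rule of at least two
#' taxa per state, which excludes autapomorphic columns.
#'
#' @param m a `pairing_matrix`.
#' @param min_species minimum species with the ortholog called (default 4).
#' @param strict require >= 2 taxa in each state instead of >= 1.
#' @return filtered `pairing_matrix`, column order preserved.
#' @export
filter_informative <- function(m, min_species = 4L, strict = FALSE) {
  need <- if (strict) 2L else 1L
  n_called <- colSums(!is.na(m$cells))
  n1 <- colSums(m$cells == 1L, na.rm = TRUE)
  n0 <- colSums(m$cells == 0L, na.rm = TRUE)
  keep <- n_called >= min_species & n1 >= need & n0 >= need
  if (!any(keep)) stop("no parsimony-informative characters survive filtering", call. = FALSE)
  new_pairing_matrix(m$species, m$ortholog[keep], m$symbol[keep],
                     m$cells[, keep, drop = FALSE])
}

#' Remove species with insufficient character coverage
#'
#' Drops species whose fraction of non-`?` cells over the informative columns
#' is below `min_char_frac` (5 percent), limiting the effect of missing data.
#' If fewer than `min_species_frac` of the input species survive, the whole
#' group is not analyzable and a condition of class `codonpair_skipped_group`
#' is signalled (distinct from I/O failure, so callers can map it to its own
#' exit status).
#'
#' @param m a filtered `pairing_matrix`.
#' @param min_char_frac minimum fraction of called cells per species.
#' @param min_species_frac minimum surviving fraction of the input species.
#' @return `pairing_matrix` restricted to surviving species.
#' @export
filter_species_coverage <- function(m, min_char_frac = 0.05,
                                    min_species_frac = 0.05) {
  frac <- rowSums(!is.na(m$cells)) / ncol(m$cells)
  keep <- frac >= min_char_frac
  if (sum(keep) / length(m$species) < min_species_frac) {
    stop(structure(
      class = c("codonpair_skipped_group", "error", "condition"),
      list(message = sprintf(
             "group not analyzable: %d of %d species (%.1f%%) pass the %.0f%% character-coverage filter",
             sum(keep), length(m$species), 100 * sum(keep) / length(m$species),
             100 * min_species_frac),
           call = NULL)))
  }
  new_pairing_matrix(m$species[keep], m$ortholog, m$symbol,
                     m$cells[keep, , drop = FALSE])
}

sanitize_taxon <- function(x, width = 32L) {
  x <- gsub("[^A-Za-z0-9_.]", "_", x)
  substr(x, 1L, width)
}

#' Export a character matrix for TNT
#'
#' Writes a TNT `xread` block (dimensions line `nchar ntax`, one row per
#' species: sanitized taxon name then the contiguous 0/1/? string) plus a key
#' file listing `ortholog<TAB>symbol` in column order, and optionally a
#' taxon-name map guaranteeing reversibility of the sanitization.
#'
#' @param m a `pairing_matrix`.
#' @param matrix_path output TNT file.
#' @param key_path output key TSV.
#' @param name_map_path optional TSV mapping sanitized to original taxon names.
#' @export
write_tnt <- function(m, matrix_path, key_path, name_map_path = NULL) {
  if (ncol(m$cells) == 0L) stop("refusing to write an empty matrix", call. = FALSE)
  taxa <- sanitize_taxon(m$species)
  if (anyDuplicated(taxa)) {
    taxa <- make.unique(taxa, sep = "_")
  }
  ch <- m$cells
  rows <- apply(ch, 1L, function(r) {
    r <- as.character(r)
    r[is.na(r)] <- "?"
    paste(r, collapse = "")
  })
  lines <- c("xread",
             paste(ncol(ch), nrow(ch)),
             paste(taxa, rows),
             ";")
  writeLines(lines, matrix_path)
  writeLines(paste(m$ortholog, m$symbol, sep = "\t"), key_path)
  if (!is.null(name_map_path)) {
    utils::write.table(data.frame(taxon = taxa, species_id = m$species),
                       name_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Read back a TNT matrix written by [write_tnt()]
#'
#' @param matrix_path TNT `xread` file.
#' @param key_path key TSV (`ortholog<TAB>symbol` per line, column order).
#' @return a `pairing_matrix`.
#' @export
read_tnt <- function(matrix_path, key_path) {
  lines <- readLines(matrix_path)
  if (trimws(lines[1]) != "xread") stop("not a TNT xread file: ", matrix_path, call. = FALSE)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nchar_ <- dims[1]; ntax <- dims[2]
  body <- lines[3:(2L + ntax)]
  tok <- strsplit(body, "\\s+")
  taxa <- vapply(tok, `[[`, "", 1L)
  cells <- matrix(NA_integer_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    states <- strsplit(tok[[i]][2], "")[[1]]
    stopifnot(length(states) == nchar_)
    known <- states != "?"
    cells[i, known] <- as.integer(states[known])
  }
  keys <- utils::read.table(key_path, sep = "\t", header = FALSE,
                            col.names = c("ortholog", "symbol"),
                            colClasses = "character")
  stopifnot(nrow(keys) == nchar_)
  new_pairing_matrix(taxa, keys$ortholog, keys$symbol, cells)
}
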