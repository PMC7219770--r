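#' @title Codon pairing detection
#' @description Core sliding-window pairing scan shared by the alignment-free
#'   and parsimony pipelines.
#' @name pairing
NULL

pairing_modes <- c("combined", "identical", "cotrna")

assert_window <- function(window) {
  window <- as.integer(window)
  if (is.na(window) || window < 2L || window > 15L) {
    stop("window must be an integer between 2 and 15 codons (pairing needs at least two codons)",
         call. = FALSE)
  }
  window
}

# Accept a CDS string or a codon character vector; return the codon vector.
as_codons <- function(gene) {
  if (length(gene) == 1L && (nchar(gene) > 3L || nchar(gene) %% 3L == 0L)) {
    split_codons(gene)
  } else {
    toupper(gene)
  }
}

#' Which symbols pair within a gene
#'
#' A codon *pairs* when two occurrences fall within one ribosome-footprint
#' window, i.e. their codon positions i < j satisfy j - i <= window - 1
#' (equivalently, both lie in some contiguous run of `window` codons). The
#' three modes encode the tRNA-reuse hypothesis at different granularity:
#'
#' * `"identical"`: the two codons are the same trinucleotide; the codon
#'   symbol is reported.
#' * `"cotrna"`: two *non-identical* codons encoding the same amino acid; the
#'   residue symbol is reported. Two identical codons alone never trigger it.
#' * `"combined"`: any two synonymous codons (identical or not); the residue
#'   symbol is reported.
#'
#' Encoding is binary: a symbol is in the set whether it paired once or a
#' hundred times. Stop codons never pair; codons containing letters other
#' than A/C/G/T never pair but still occupy their position (they do not
#' shrink distances between flanking codons).
#'
#' @param gene CDS string (length divisible by 3) or codon character vector.
#'   Terminal stop codons should already be stripped (see
#'   [load_species_fasta()]); if present they are simply inert.
#' @param mode one of `"combined"`, `"identical"`, `"cotrna"`.
#' @param window ribosome footprint in codons (2-15; 9 approximates the
#'   commonly accepted 28-nt footprint).
#' @param code a [genetic_code()].
#' @return sorted character vector of codon symbols (`identical`) or
#'   one-letter residues (other modes); empty vector when nothing pairs.
#' @examples
#' gene_pairing_set(c("AAA", "AAA"), "identical", 2)        # "AAA"
#' gene_pairing_set(c("AAA", "AAG"), "cotrna", 2)           # "K"
#' gene_pairing_set(c("AAA", "TTT", "AAA"), "identical", 2) # empty
#' @export
gene_pairing_set <- function(gene, mode = c("combined", "identical", "cotrna"),
                             window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  window <- assert_window(window)
  codons <- as_codons(gene)
  n <- length(codons)
  if (n < 2L) return(character(0))
  aa <- codon_residues(codons, code)
  valid <- !is.na(aa) & aa != "*"
  hits <- vector("list", window - 1L)
  for (d in seq_len(window - 1L)) {
    if (d >= n) break
    i <- seq_len(n - d)
    j <- i + d
    ok <- valid[i] & valid[j]
    hits[[d]] <- switch(mode,
      identical = codons[i][ok & codons[i] == codons[j]],
      cotrna    = aa[i][ok & aa[i] == aa[j] & codons[i] != codons[j]],
      combined  = aa[i][ok & aa[i] == aa[j]]
    )
  }
  sort(unique(unlist(hits)))
}

#' Count pairing events within a gene
#'
#' Number of unordered codon-position pairs (i < j, j - i <= window - 1) whose
#' symbols match under `mode`. This is the event count whose total is expected
#' to scale with gene length, unlike the binary pairing set.
#'
#' @inheritParams gene_pairing_set
#' @return integer count.
#' @export
gene_pairing_events <- function(gene, mode = c("combined", "identical", "cotrna"),
                                window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  window <- assert_window(window)
  codons <- as_codons(gene)
  n <- length(codons)
  if (n < 2L) return(0L)
  aa <- codon_residues(codons, code)
  valid <- !is.na(aa) & aa != "*"
  total <- 0L
  for (d in seq_len(window - 1L)) {
    if (d >= n) break
    i <- seq_len(n - d)
    j <- i + d
    ok <- valid[i] & valid[j]
    total <- total + switch(mode,
      identical = sum(ok & codons[i] == codons[j]),
      cotrna    = sum(ok & aa[i] == aa[j] & codons[i] != codons[j]),
      combined  = sum(ok & aa[i] == aa[j])
    )
  }
  as.integer(total)
}

#' Pairing motif of a gene
#'
#' The alphabetized tuple of all symbols that pair anywhere in the gene,
#' recorded without multiplicity. A gene with identical pairing for AAA and
#' AAT has motif `c("AAA", "AAT")` however many times each paired. Genes with
#' no pairing have an empty motif and are excluded from species profiles.
#'
#' @inheritParams gene_pairing_set
#' @return sorted character vector (possibly empty).
#' @export
gene_motif <- function(gene, mode = c("combined", "identical", "cotrna"),
                       window = 9L, code = genetic_code()) {
  gene_pairing_set(gene, mode, window, code)
}

# Collapse a motif to its canonical single-string form used in profiles.
motif_key <- function(symbols) paste(symbols, collapse = ",")

#' Write per-gene pairing motifs to TSV
#'
#' One row per gene: species_id, ortholog_key, mode, window, comma-joined
#' motif (empty string for genes with no pairing). All downstream motif
#' statistics are recomputable from this file alone.
#'
#' @param sets list of `species_gene_set`.
#' @inheritParams gene_pairing_set
#' @param path output TSV path.
#' @export
write_pairing_report <- function(sets, mode = "combined", window = 9L,
                                 code = genetic_code(), path) {
  rows <- lapply(sets, function(gs) {
    motifs <- vapply(gs$genes, function(g)
      motif_key(gene_pairing_set(g, mode, window, code)), "")
    data.frame(species_id = gs$species_id, ortholog_key = names(gs$genes),
               mode = mode, window = as.integer(window), motif = motifs,
               row.names = NULL)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
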