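#' Extract an ortholog key from a FASTA header
#'
#' Default rule: a `gene=` tag (`[gene=COX1]` or `gene=COX1`) if present,
#' otherwise the first whitespace-delimited token. Header dialects vary across
#' annotation pipelines, so the rule is pluggable: pass any function mapping a
#' header string to a key (return `NA_character_` or `""` to drop the record).
#'
#' @param header FASTA description line (without the leading `>`).
#' @return ortholog key, or `NA_character_` if none can be extracted.
#' @export
default_header_rule <- function(header) {
  m <- regmatches(header, regexpr("gene=([^]\\s]+)", header, perl = TRUE))
  if (length(m) == 1L) {
    return(sub("^gene=", "", m))
  }
  tok <- strsplit(trimws(header), "\\s+")[[1]]
  if (length(tok) == 0L || !nzchar(tok[1])) NA_character_ else tok[1]
}

new_species_gene_set <- function(species_id, genes, qc = NULL) {
  structure(list(species_id = species_id, genes = genes, qc = qc),
            class = "species_gene_set")
}

#' @export
print.species_gene_set <- function(x, ...) {
  cat("Species gene set:", x$species_id, "-", length(x$genes), "genes\n")
  if (!is.null(x$qc) && x$qc$n_dropped > 0) {
    cat("  dropped", x$qc$n_dropped, "records (",
        paste(names(x$qc$reasons), x$qc$reasons, sep = "=", collapse = ", "),
        ")\n")
  }
  invisible(x)
}

#' Load one species' coding sequences from FASTA
#'
#' Reads a per-species CDS FASTA (one record per gene), extracts an ortholog
#' key from each header, validates each CDS and keeps, for every ortholog key,
#' only the longest CDS (the "longest isoform"; ties keep the record first in
#' file order). Terminal stop codons are stripped. Records are dropped (and
#' counted in the QC report) when: the header yields no key, the header
#' contains one of `drop_keywords` (annotated exceptions such as partial
#' genes), the length is not divisible by 3, or an internal stop codon is
#' present under the default `internal_stop = "drop"` policy
#' (`"keep"` retains the gene; stop codons can never pair anyway).
#'
#' @param path FASTA file path.
#' @param species_id species identifier; default the file name without
#'   extension.
#' @param code a [genetic_code()].
#' @param header_rule function mapping a header to an ortholog key; see
#'   [default_header_rule()].
#' @param internal_stop `"drop"` (drop genes with internal stops) or `"keep"`.
#' @param drop_keywords character vector; records whose header contains any of
#'   these (case-insensitive) are dropped.
#' @return A `species_gene_set`: `species_id`, `genes` (named character vector
#'   of uppercase CDS, names = ortholog keys, terminal stops stripped) and a
#'   `qc` list with drop counts by reason.
#' @export
load_species_fasta <- function(path, species_id = NULL, code = genetic_code(),
                               header_rule = default_header_rule,
                               internal_stop = c("drop", "keep"),
                               drop_keywords = c("exception", "partial")) {
  internal_stop <- match.arg(internal_stop)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  if (is.null(species_id)) {
    species_id <- sub("\\.(fa|fasta|fna|ffn)$", "", basename(path), ignore.case = TRUE)
  }
  dss <- Biostrings::readDNAStringSet(path)
  headers <- names(dss)
  seqs <- toupper(as.character(dss))

  reasons <- c(no_key = 0L, keyword = 0L, bad_length = 0L, internal_stop = 0L)
  keys <- character(length(seqs))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    h <- headers[i]
    if (length(drop_keywords) &&
        any(vapply(drop_keywords, grepl, logical(1), x = h, ignore.case = TRUE))) {
      reasons["keyword"] <- reasons["keyword"] + 1L
      next
    }
    k <- header_rule(h)
    if (is.na(k) || !nzchar(k)) {
      reasons["no_key"] <- reasons["no_key"] + 1L
      next
    }
    s <- seqs[i]
    if (nchar(s) %% 3L != 0L) {
      reasons["bad_length"] <- reasons["bad_length"] + 1L
      next
    }
    codons <- split_codons(s)
    aa <- codon_residues(codons, code)
    # strip terminal stop
    n <- length(codons)
    if (n > 0L && !is.na(aa[n]) && aa[n] == "*") {
      codons <- codons[-n]
      aa <- aa[-n]
    }
    if (internal_stop == "drop" && any(!is.na(aa) & aa == "*")) {
      reasons["internal_stop"] <- reasons["internal_stop"] + 1L
      next
    }
    keys[i] <- k
    seqs[i] <- paste(codons, collapse = "")
    keep[i] <- TRUE
  }
  n_dropped_validation <- sum(reasons)
  if (reasons["no_key"] > 0L) {
    warning(sprintf("%s: %d record(s) without an extractable ortholog key dropped",
                    species_id, reasons["no_key"]), call. = FALSE)
  }

  keys <- keys[keep]
  seqs <- seqs[keep]
  # longest isoform per key; ties keep first occurrence in file order
  if (length(keys)) {
    ord <- order(-nchar(seqs), seq_along(seqs))
    first <- !duplicated(keys[ord])
    sel <- sort(ord[first])
    genes <- seqs[sel]
    names(genes) <- keys[sel]
  } else {
    genes <- stats::setNames(character(0), character(0))
  }
  if (length(genes) == 0L) {
    stop("no valid gene records in ", path, " (species ", species_id, ")",
         call. = FALSE)
  }
  qc <- list(
    n_input = length(dss),
    n_genes = length(genes),
    n_dropped = n_dropped_validation + (length(keys) - length(genes)),
    reasons = c(reasons, isoform = length(keys) - length(genes))
  )
  new_species_gene_set(species_id, genes, qc)
}

#' Write a species gene set back to FASTA
#'
#' Headers carry the ortholog key only, so a reload with the default header
#' rule round-trips the records exactly.
#'
#' @param gs a `species_gene_set`.
#' @param path output FASTA path.
#' @export
write_species_fasta <- function(gs, path) {
  dss <- Biostrings::DNAStringSet(gs$genes)
  names(dss) <- names(gs$genes)
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' Load every species FASTA in a directory
#'
#' One FASTA file per species (`*.fa`, `*.fasta`, `*.fna`, `*.ffn`); the file
#' name (without extension) is the species id.
#'
#' @inheritParams load_species_fasta
#' @param dir directory of per-species FASTA files.
#' @return named list of `species_gene_set` objects.
#' @export
load_species_dir <- function(dir, code = genetic_code(), ...) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|fna|ffn)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files found in ", dir, call. = FALSE)
  sets <- lapply(sort(files), load_species_fasta, code = code, ...)
  names(sets) <- vapply(sets, `[[`, "", "species_id")
  if (anyDuplicated(names(sets))) stop("duplicate species ids in ", dir, call. = FALSE)
  sets
}

#' Write a QC report for loaded species
#'
#' @param sets list of `species_gene_set`.
#' @param path output TSV path.
#' @export
write_qc_report <- function(sets, path) {
  rows <- lapply(sets, function(gs) {
    data.frame(species_id = gs$species_id, n_genes = gs$qc$n_genes,
               n_dropped = gs$qc$n_dropped, t(gs$qc$reasons),
               check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
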