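#' NCBI genetic code table
#'
#' Wraps the standard NCBI translation tables as a lookup object used by all
#' pairing computations. Table 1 is the standard code (61 sense codons, stop
#' codons TAA/TAG/TGA); table 11 is the bacterial/archaeal/plastid code, etc.
#'
#' @param table_id integer NCBI translation-table id (default 1).
#' @return An object of class `genetic_code` with components `table_id`,
#'   `codon_to_aa` (named character vector over all 64 codons, `"*"` for
#'   stops), `stop_codons` and `sense_codons`.
#' @examples
#' code <- genetic_code(1)
#' length(code$sense_codons)  # 61
#' @export
genetic_code <- function(table_id = 1L) {
  table_id <- as.integer(table_id)
  tbl <- Biostrings::getGeneticCode(as.character(table_id))
  tbl <- tbl[order(names(tbl))]
  structure(
    list(
      table_id     = table_id,
      codon_to_aa  = tbl,
      stop_codons  = names(tbl)[tbl == "*"],
      sense_codons = names(tbl)[tbl != "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("NCBI genetic code table", x$table_id, "-", length(x$sense_codons),
      "sense codons, stops:", paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

# Split a CDS string into its codon vector. Length must be divisible by 3.
split_codons <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# Residues for a codon vector; NA for codons not in the table (ambiguity
# letters etc.), "*" for stops.
codon_residues <- function(codons, code) {
  unname(code$codon_to_aa[codons])
}

#' Translate a coding sequence
#'
#' One residue per sense codon. A terminal stop codon yields no residue.
#' Internal stop codons are an error under the default policy (genes carrying
#' them are normally dropped at load time) or skipped with `internal_stop =
#' "skip"`. Codons containing letters other than A/C/G/T translate to `"X"`.
#'
#' @param cds DNA string, length divisible by 3.
#' @param code a [genetic_code()].
#' @param internal_stop `"error"` (default) or `"skip"`.
#' @return Single amino-acid string.
#' @examples
#' translate_cds("ATGTAA", genetic_code(1))  # "M"
#' @export
translate_cds <- function(cds, code = genetic_code(), internal_stop = c("error", "skip")) {
  internal_stop <- match.arg(internal_stop)
  codons <- split_codons(cds)
  if (length(codons) == 0L) return("")
  aa <- codon_residues(codons, code)
  # terminal stop yields no residue
  if (!is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  if (any(!is.na(aa) & aa == "*")) {
    if (internal_stop == "error") {
      stop("internal stop codon in CDS", call. = FALSE)
    }
    aa <- aa[is.na(aa) | aa != "*"]
  }
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
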