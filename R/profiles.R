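#' Build a species codon-pairing profile
#'
#' The profile of a species is the *set* of distinct nonempty gene motifs
#' across all its genes: each gene's pairing set is alphabetized into a tuple
#' and the tuples are pooled; two genes with identical motifs contribute one
#' element. Profiles are the operands of the alignment-free distance.
#'
#' @param gs a `species_gene_set`.
#' @inheritParams gene_pairing_set
#' @return object of class `species_profile`: `species_id` plus `motifs`, a
#'   character vector of canonical comma-joined motif strings.
#' @export
build_profile <- function(gs, mode = c("combined", "identical", "cotrna"),
                          window = 9L, code = genetic_code()) {
  mode <- match.arg(mode)
  motifs <- vapply(gs$genes, function(g)
    motif_key(gene_pairing_set(g, mode, window, code)), "", USE.NAMES = FALSE)
  motifs <- unique(motifs[nzchar(motifs)])
  structure(list(species_id = gs$species_id, motifs = motifs),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("Species profile:", x$species_id, "-", length(x$motifs), "distinct motifs\n")
  invisible(x)
}

#' Alignment-free pairwise distance between two species profiles
#'
#' One minus the relative similarity of the two motif sets *a* and *b*:
#' `1 - |a intersect b| / min(|a|, |b|)`. When the smaller profile does not
#' exceed `ratio_floor` (5 percent) of the larger one, the species get the
#' maximum distance 1.0 outright; this guards against small-genome bias (a
#' two-gene virus sharing one motif with a 20 000-gene vertebrate should not
#' land at distance 0.5). Empty profiles also take the guard path. Note this
#' containment-normalized quantity is not a metric (no triangle inequality).
#'
#' @param a,b `species_profile` objects.
#' @param ratio_floor inclusive ratio threshold (default 0.05) below or at
#'   which the distance snaps to 1.
#' @return distance in `[0, 1]`.
#' @examples
#' p <- function(id, m) structure(list(species_id = id, motifs = m),
#'                                class = "species_profile")
#' pair_distance(p("A", c("K", "K,L")), p("B", c("K", "L")))
#' @export
pair_distance <- function(a, b, ratio_floor = 0.05) {
  na <- length(a$motifs); nb <- length(b$motifs)
  lo <- min(na, nb); hi <- max(na, nb)
  if (lo == 0L || lo / hi <= ratio_floor) return(1.0)
  1 - length(intersect(a$motifs, b$motifs)) / lo
}

#' Pairwise distance matrix over species profiles
#'
#' @param profiles list of `species_profile` with unique species ids.
#' @inheritParams pair_distance
#' @return symmetric numeric matrix with zero diagonal, dimnames = species ids.
#' @export
distance_matrix <- function(profiles, ratio_floor = 0.05) {
  if (length(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  ids <- vapply(profiles, `[[`, "", "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids", call. = FALSE)
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pair_distance(profiles[[i]], profiles[[j]], ratio_floor)
      dm[i, j] <- d
      dm[j, i] <- d
    }
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch lengths,
#' an NJ artifact, are clamped to zero. The result is an unrooted tree over
#' all species in the matrix.
#'
#' @param dm symmetric distance matrix with species ids as dimnames.
#' @return an \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor-joining needs at least 3 species", call. = FALSE)
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write / read a square PHYLIP distance matrix
#'
#' Square (full) PHYLIP format, values printed with six decimals.
#'
#' @param dm distance matrix.
#' @param path file path.
#' @export
write_phylip_dist <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  ids <- rownames(dm)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(formatC(ids[i], width = -10),
                     paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  ids <- character(n)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    ids[i] <- tok[1]
    dm[i, ] <- as.numeric(tok[-1])
  }
  dimnames(dm) <- list(ids, ids)
  dm
}
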