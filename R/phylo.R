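# Phylogenetic prior: pairwise species similarity from marker sequences,
# genus-level aggregation, and the graph Laplacian used by the regularizer.

#' Read marker sequences from FASTA
#'
#' Headers encode `kingdom|genus|species`. Bacteria/archaea markers are 16S
#' rRNA, eukaryote markers 5S rRNA, viral markers whole genomes; the
#' similarity contract is the same for all of them.
#'
#' @param path FASTA file.
#' @return data.frame with columns kingdom, genus, species, sequence.
#' @export
read_marker_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) stop("FASTA header not of form kingdom|genus|species: ",
                        names(seqs)[bad[1]])
  data.frame(kingdom = vapply(parts, `[[`, "", 1),
             genus   = vapply(parts, `[[`, "", 2),
             species = vapply(parts, `[[`, "", 3),
             sequence = as.character(seqs),
             stringsAsFactors = FALSE)
}

# Global (Needleman-Wunsch) alignment identity: matches / alignment columns.
# `a` may be a character vector (aligned elementwise against the single
# subject `b` in one vectorized call).
alignment_identity <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 2, gap_ext = 0.5) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(a),
                                       Biostrings::DNAString(b),
                                       type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_ext)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Pairwise species similarity matrix from marker sequences
#'
#' Within each kingdom, similarity is global pairwise alignment identity
#' (matches / alignment columns), then min-max normalized to \[0, 1\] over
#' that kingdom's off-diagonal entries. Cross-kingdom pairs get similarity 0
#' and the diagonal is forced to 1.
#'
#' @param markers data.frame as returned by [read_marker_fasta()]; one
#'   sequence per species.
#' @param match,mismatch,gap_open,gap_ext alignment scoring (recorded in the
#'   result's attributes).
#' @return object of class `species_similarity`: list with `species`,
#'   `genus`, `kingdom` vectors and symmetric matrix `S`.
#' @export
pairwise_species_similarity <- function(markers, match = 1, mismatch = -1,
                                        gap_open = 2, gap_ext = 0.5) {
  stopifnot(nrow(markers) >= 1)
  if (any(!nzchar(markers$sequence))) stop("empty marker sequence")
  if (anyDuplicated(markers$species))
    stop("one sequence per species expected; duplicated species name")
  ns <- nrow(markers)
  S <- matrix(0, ns, ns, dimnames = list(markers$species, markers$species))
  for (kd in unique(markers$kingdom)) {
    idx <- which(markers$kingdom == kd)
    if (length(idx) == 1) { S[idx, idx] <- 1; next }
    raw <- matrix(1, length(idx), length(idx))
    for (b in 2:length(idx)) {
      ids <- tryCatch(
        alignment_identity(markers$sequence[idx[seq_len(b - 1)]],
                           markers$sequence[idx[b]],
                           match, mismatch, gap_open, gap_ext),
        error = function(e) { warning("alignment failed; similarity 0: ",
                                      conditionMessage(e))
                              numeric(b - 1) })
      raw[seq_len(b - 1), b] <- raw[b, seq_len(b - 1)] <- ids
    }
    off <- raw[upper.tri(raw)]
    rng <- range(off)
    norm <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw
    diag(norm) <- 1
    S[idx, idx] <- norm
  }
  structure(list(species = markers$species, genus = markers$genus,
                 kingdom = markers$kingdom, S = S,
                 scoring = c(match = match, mismatch = mismatch,
                             gap_open = gap_open, gap_ext = gap_ext)),
            class = "species_similarity")
}

#' Aggregate species similarities to the genus level
#'
#' The similarity of two genera is the mean over all cross-genus species
#' pairs: `sim(g_a, g_b) = (1 / (|g_a| |g_b|)) * sum over species pairs`.
#' The genus self-similarity is the same mean over the genus's own species
#' pairs (not forced to 1), so the Laplacian degree uses it as computed.
#'
#' @param sp a `species_similarity`.
#' @param genus_map optional named character vector species -> genus
#'   (defaults to the genus column carried by `sp`).
#' @return object of class `genus_similarity`: list with alphabetical genus
#'   `index` and symmetric matrix `P`.
#' @export
aggregate_to_genus <- function(sp, genus_map = NULL) {
  stopifnot(inherits(sp, "species_similarity"))
  genus <- if (is.null(genus_map)) sp$genus else unname(genus_map[sp$species])
  if (any(is.na(genus))) stop("species missing from genus map")
  index <- sort(unique(genus))
  m <- length(index)
  P <- matrix(0, m, m, dimnames = list(index, index))
  groups <- split(seq_along(genus), genus)
  for (a in seq_len(m)) for (b in a:m) {
    ia <- groups[[index[a]]]; ib <- groups[[index[b]]]
    P[a, b] <- P[b, a] <- mean(sp$S[ia, ib, drop = FALSE])
  }
  structure(list(index = index, P = P), class = "genus_similarity")
}

#' Graph Laplacian of a genus similarity matrix
#'
#' `L = D - P` with `D[j, j] = sum_j' P[j, j']` (row sums, diagonal of P
#' included). Row sums of L are 0 and L is positive semidefinite.
#'
#' @param P a `genus_similarity` or a symmetric nonnegative matrix.
#' @return object of class `laplacian`: list with `L`, `D` and the genus
#'   `index`.
#' @export
build_laplacian <- function(P) {
  index <- NULL
  if (inherits(P, "genus_similarity")) { index <- P$index; P <- P$P }
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(P - t(P))) > 1e-9) stop("similarity matrix is not symmetric")
  if (any(P < 0)) stop("similarity matrix has negative entries")
  D <- diag(rowSums(P), nrow(P))
  L <- D - P
  dimnames(L) <- dimnames(P)
  structure(list(L = L, D = D, index = index %||% rownames(P)),
            class = "laplacian")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Laplacian quadratic form
#'
#' Returns `beta' L beta`, the smoothness penalty of a score vector over the
#' similarity graph; equals the half-sum `0.5 * sum P[i,j] (beta_i-beta_j)^2`.
#'
#' @param lap a `laplacian` (or a plain m x m matrix).
#' @param beta numeric vector of length m.
#' @return scalar penalty, always `>= 0` up to round-off.
#' @export
laplacian_quadratic_form <- function(lap, beta) {
  L <- if (inherits(lap, "laplacian")) lap$L else lap
  if (length(beta) != nrow(L)) stop("beta length does not match Laplacian size")
  drop(crossprod(beta, L %*% beta))
}

#' Write a genus similarity matrix or Laplacian as TSV
#' @param x `genus_similarity` or `laplacian`.
#' @param path output path.
#' @export
write_similarity_tsv <- function(x, path) {
  m <- if (inherits(x, "genus_similarity")) x$P else x$L
  write_matrix_tsv(m, path, id_col = "genus")
}
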