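# Parsing of MetaPhlAn-style relative-abundance profiles and construction of
# the binary microbial distribution matrix Y.

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Parse one pipe-delimited taxon path
#'
#' Taxon paths look like `k__Bacteria|p__Proteobacteria|...|g__Pseudomonas`.
#' The path must start at kingdom, ranks must appear in taxonomic order
#' (intermediate ranks may be omitted), and every name must be non-empty.
#'
#' @param path character scalar, pipe-delimited with rank prefixes.
#' @return named character vector of rank -> name.
#' @export
parse_taxon_path <- function(path) {
  parts <- strsplit(path, "|", fixed = TRUE)[[1]]
  if (length(parts) == 0 || length(parts) > length(RANKS)) {
    stop(sprintf("malformed taxon path: '%s'", path), call. = FALSE)
  }
  prefs <- substring(parts, 1, 3)
  ranks <- match(prefs, RANK_PREFIXES)
  names_ <- substring(parts, 4)
  if (any(is.na(ranks)) || any(nchar(names_) == 0)) {
    bad <- which(is.na(ranks) | nchar(names_) == 0)[1]
    stop(sprintf("malformed taxon path: '%s' (bad segment '%s')",
                 path, parts[bad]), call. = FALSE)
  }
  if (ranks[1] != 1L || any(diff(ranks) <= 0)) {
    stop(sprintf("malformed taxon path: '%s' (ranks out of order)", path),
         call. = FALSE)
  }
  setNames(names_, RANKS[ranks])
}

new_abundance_profile <- function(sample_id, abundances, rank,
                                  flagged_empty = FALSE) {
  stopifnot(is.numeric(abundances))
  structure(list(sample_id = sample_id,
                 abundances = abundances,
                 rank = rank,
                 flagged_empty = flagged_empty),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> sample %s, rank %s, %d taxa%s\n",
              x$sample_id, x$rank, length(x$abundances),
              if (isTRUE(x$flagged_empty)) " [flagged empty]" else ""))
  invisible(x)
}

#' Parse a MetaPhlAn-style profile table at one taxonomic rank
#'
#' The table has a taxon-path column (pipe-delimited rank prefixes) and one
#' numeric column per sample holding relative abundances as percentages in
#' \[0, 100\]. Rows whose path terminates exactly at `rank` are kept and
#' percentages are converted to fractions.
#'
#' @param path path to the TSV file (first column: taxon path).
#' @param rank taxonomic rank to extract ("kingdom" ... "species").
#' @return list of `abundance_profile`, one per sample column.
#' @export
parse_profile_table <- function(path, rank = "genus") {
  rank <- match.arg(rank, RANKS)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "")
  if (ncol(df) < 2) stop("profile table needs a taxon column and >=1 sample column")
  sample_ids <- colnames(df)[-1]
  paths <- as.character(df[[1]])
  keep <- logical(length(paths))
  taxa <- character(length(paths))
  for (i in seq_along(paths)) {
    tp <- parse_taxon_path(paths[i])   # errors name the offending row
    if (names(tp)[length(tp)] == rank) {
      keep[i] <- TRUE
      taxa[i] <- tp[[length(tp)]]
    }
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (any(!is.finite(vals))) stop("non-numeric abundance in profile table")
  if (any(vals < 0)) stop("negative abundance in profile table")
  lapply(seq_along(sample_ids), function(j) {
    ab <- vals[keep, j] / 100
    names(ab) <- taxa[keep]
    new_abundance_profile(sample_ids[j], ab, rank)
  })
}

#' Remove unknown taxa and renormalize a profile
#'
#' Taxa not in `known` are dropped and the remaining relative abundances are
#' rescaled to sum to one. If no known taxon with positive mass remains the
#' profile comes back empty and flagged.
#'
#' @param profile an `abundance_profile`.
#' @param known character vector of retained taxon names.
#' @return an `abundance_profile`.
#' @export
drop_unknown_and_renormalize <- function(profile, known) {
  stopifnot(inherits(profile, "abundance_profile"))
  ab <- profile$abundances[names(profile$abundances) %in% known]
  total <- sum(ab)
  if (length(ab) == 0 || total <= 0) {
    return(new_abundance_profile(profile$sample_id,
                                 setNames(numeric(0), character(0)),
                                 profile$rank, flagged_empty = TRUE))
  }
  new_abundance_profile(profile$sample_id, ab / total, profile$rank)
}

#' Build the binary microbial distribution matrix Y
#'
#' The microbe index is the alphabetically ordered union of taxa across
#' profiles; `Y[i, j] = 1` iff sample i's relative abundance of taxon j meets
#' the threshold `gamma`. A missing taxon counts as abundance 0. With
#' `gamma = 0` presence means strictly positive abundance (a literal `>= 0`
#' would mark every absent taxon present); for `gamma > 0` the comparison is
#' `>= gamma`, with equality counting as present.
#'
#' @param profiles list of `abundance_profile` at a common rank.
#' @param gamma abundance threshold (fraction), `>= 0`.
#' @return object of class `microbial_distribution`: list with `index`
#'   (ordered taxon names), `sample_ids`, binary matrix `Y` (n x m) and
#'   `gamma`.
#' @export
build_distribution_matrix <- function(profiles, gamma = 0) {
  if (length(profiles) == 0) stop("no profiles supplied")
  stopifnot(gamma >= 0)
  ranks <- unique(vapply(profiles, `[[`, "", "rank"))
  if (length(ranks) != 1) stop("profiles span multiple ranks: ",
                               paste(ranks, collapse = ", "))
  index <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  n <- length(profiles); m <- length(index)
  sample_ids <- vapply(profiles, `[[`, "", "sample_id")
  A <- matrix(0, n, m, dimnames = list(sample_ids, index))
  for (i in seq_len(n)) {
    ab <- profiles[[i]]$abundances
    if (length(ab)) A[i, names(ab)] <- ab
  }
  Y <- if (gamma > 0) (A >= gamma) else (A > 0)
  storage.mode(Y) <- "integer"
  structure(list(index = index, sample_ids = unname(sample_ids),
                 Y = Y, gamma = gamma),
            class = "microbial_distribution")
}

#' @export
print.microbial_distribution <- function(x, ...) {
  cat(sprintf("<microbial_distribution> %d samples x %d taxa, gamma = %g, density %.3f\n",
              nrow(x$Y), ncol(x$Y), x$gamma, mean(x$Y)))
  invisible(x)
}

#' Write a microbial distribution matrix as TSV
#'
#' Header row of taxon names, first column of sample ids.
#' @param dist a `microbial_distribution`.
#' @param path output path.
#' @export
write_distribution_matrix <- function(dist, path) {
  write_matrix_tsv(dist$Y, path, id_col = "sample_id")
}

#' Write abundance profiles in the MetaPhlAn percentage dialect
#'
#' One taxon-path row per taxon (kingdom prefix + rank-level name), one
#' percentage column per sample. The inverse of [parse_profile_table()] for
#' tables at a single rank.
#'
#' @param profiles list of `abundance_profile` (common rank).
#' @param path output TSV path.
#' @param kingdom_of named character vector taxon -> kingdom name used to
#'   build the path prefix (defaults to "Bacteria" for all).
#' @export
write_profile_table <- function(profiles, path, kingdom_of = NULL) {
  rank <- profiles[[1]]$rank
  taxa <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  if (is.null(kingdom_of)) kingdom_of <- setNames(rep("Bacteria", length(taxa)), taxa)
  pref <- RANK_PREFIXES[[rank]]
  paths <- sprintf("k__%s|%s%s", kingdom_of[taxa], pref, taxa)
  M <- matrix(0, length(taxa), length(profiles),
              dimnames = list(NULL, vapply(profiles, `[[`, "", "sample_id")))
  for (j in seq_along(profiles)) {
    ab <- profiles[[j]]$abundances
    if (length(ab)) M[match(names(ab), taxa), j] <- ab * 100
  }
  df <- data.frame(clade_name = paths, M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
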