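#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm rbinom plogis setNames predict
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

# Great-circle distance in miles between lon/lat points.
# geosphere expects (lon, lat) and returns metres.
METERS_PER_MILE <- 1609.344

haversine_miles <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / METERS_PER_MILE
}

check_coords <- function(lat, lon, what = "point") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    stop(sprintf("invalid coordinates for %s: lat must be in [-90,90], lon in [-180,180]",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

# Derive a stream of reproducible sub-seeds from one top-level seed, so each
# module draws from its own stream (kept below 2^31).
fanout_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

clip01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Write a numeric matrix as TSV with row and column names
#'
#' Helper used for similarity matrices, Laplacians, score tables and
#' embeddings: first column holds row names, header row holds column names.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file path.
#' @param id_col name for the first (row-id) column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path; first column is taken as row names.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
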