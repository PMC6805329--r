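# Station/line features F_s, transit-graph construction for the embedding
# features F_c, surface-material one-hots F_m, and feature assembly.

#' Read station, turnstile and sample-metadata CSVs
#'
#' Station CSV: `station_id,name,lat,lon,lines` (lines semicolon-delimited).
#' Turnstile CSV: `station_id,date,entries,exits`.
#' Sample metadata CSV: `sample_id,lat,lon,material,date`.
#'
#' @param path CSV file.
#' @return data.frame; station `lines` come back as a list column of
#'   character vectors.
#' @export
read_stations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "name", "lat", "lon", "lines")
  if (!all(need %in% colnames(df)))
    stop("station CSV must have columns ", paste(need, collapse = ","))
  check_coords(df$lat, df$lon, "station")
  df$lines <- strsplit(df$lines, ";", fixed = TRUE)
  if (any(lengths(df$lines) == 0)) stop("station with empty line set")
  df
}

#' @rdname read_stations_csv
#' @export
read_turnstile_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "entries", "exits")
  if (!all(need %in% colnames(df)))
    stop("turnstile CSV must have columns ", paste(need, collapse = ","))
  if (any(df$entries < 0 | df$exits < 0)) stop("negative turnstile count")
  df
}

#' @rdname read_stations_csv
#' @export
read_samples_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "lat", "lon", "material", "date")
  if (!all(need %in% colnames(df)))
    stop("sample CSV must have columns ", paste(need, collapse = ","))
  check_coords(df$lat, df$lon, "sample")
  df
}

#' Associate a sampling location with a station or a line segment
#'
#' Returns the nearest station within `radius` miles (great-circle). When no
#' station is that close the two nearest stations overall are examined: if
#' their line sets intersect the location is taken to lie between them on
#' the shared line(s); otherwise no association is made and the sample is
#' dropped upstream.
#'
#' @param lat,lon sample coordinates.
#' @param stations data.frame from [read_stations_csv()].
#' @param radius association radius in miles (default 0.01).
#' @return list with `type` (`"station"`, `"between"`, `"none"`),
#'   `station_ids` (1 or 2 ids, or none), `lines` and `distance` (miles to
#'   the nearest station).
#' @export
associate_station <- function(lat, lon, stations, radius = 0.01) {
  stopifnot(radius > 0, nrow(stations) >= 1)
  if (!is.list(stations$lines))
    stations$lines <- strsplit(stations$lines, ";", fixed = TRUE)
  check_coords(lat, lon, "sample")
  d <- haversine_miles(stations$lon, stations$lat, lon, lat)
  nearest <- order(d)
  if (d[nearest[1]] <= radius) {
    i <- nearest[1]
    return(list(type = "station", station_ids = stations$station_id[i],
                lines = stations$lines[[i]], distance = d[i]))
  }
  if (nrow(stations) >= 2) {
    i <- nearest[1]; j <- nearest[2]
    shared <- intersect(stations$lines[[i]], stations$lines[[j]])
    if (length(shared)) {
      return(list(type = "between",
                  station_ids = stations$station_id[c(i, j)],
                  lines = shared, distance = d[i]))
    }
  }
  list(type = "none", station_ids = character(0), lines = character(0),
       distance = d[nearest[1]])
}

#' Station busyness weights from turnstile data
#'
#' Mean daily (entries + exits) per station over the collection window,
#' divided by the maximum over stations so weights lie in (0, 1];
#' `normalize = FALSE` keeps raw mean counts. Stations without turnstile
#' rows get weight 1 (no information).
#'
#' @param turnstiles data.frame from [read_turnstile_csv()] (or NULL: all
#'   weights 1).
#' @param station_ids ids to produce weights for.
#' @param dates optional date window (character vector); rows outside it are
#'   ignored.
#' @param normalize divide by the max over stations (default TRUE).
#' @return named numeric vector of weights.
#' @export
busyness_weights <- function(turnstiles, station_ids, dates = NULL,
                             normalize = TRUE) {
  w <- setNames(rep(1, length(station_ids)), station_ids)
  if (is.null(turnstiles) || nrow(turnstiles) == 0) return(w)
  tt <- turnstiles
  if (!is.null(dates)) tt <- tt[tt$date %in% dates, , drop = FALSE]
  if (nrow(tt) == 0) return(w)
  daily <- tt$entries + tt$exits
  agg <- tapply(daily, tt$station_id, mean)
  hit <- intersect(names(agg), station_ids)
  w[hit] <- agg[hit]
  if (normalize) w <- w / max(w)
  w
}

#' Line feature vector F_s
#'
#' Binary indicator over the line catalogue of the lines through the
#' associated station(s), scaled by the station's busyness weight (the mean
#' of the two stations' weights for a between-stations association).
#'
#' @param association result of [associate_station()] (type != "none").
#' @param all_lines ordered catalogue of line labels.
#' @param weights named busyness weights per station id (default: all 1).
#' @return numeric vector of length `length(all_lines)`.
#' @export
line_feature <- function(association, all_lines, weights = NULL) {
  if (association$type == "none")
    stop("cannot build a line feature for an unassociated sample")
  unknown <- setdiff(association$lines, all_lines)
  if (length(unknown))
    stop("line label(s) not in catalogue: ", paste(unknown, collapse = ","))
  v <- as.numeric(all_lines %in% association$lines)
  w <- 1
  if (!is.null(weights)) {
    ids <- intersect(association$station_ids, names(weights))
    if (length(ids)) w <- mean(weights[ids])
  }
  v * w
}

#' Surface-material one-hot F_m
#'
#' @param material material label.
#' @param catalogue ordered material labels (as printed for the city:
#'   NY `concrete, metal, plastic, water, wood`; Boston `glass, polyester,
#'   PVC, steel`).
#' @return one-hot vector of length `length(catalogue)`; an unknown material
#'   yields all zeros with a warning.
#' @export
material_feature <- function(material, catalogue) {
  stopifnot(length(catalogue) >= 1)
  v <- as.numeric(catalogue == material)
  if (sum(v) == 0 && !is.na(material))
    warning("unknown material '", material, "': zero vector")
  v
}

#' Build the weighted station network
#'
#' One node per station; every pair of stations sharing at least one line is
#' joined by an edge weighted by the minimum number of stops between them
#' along shared lines. Station order along a line is the order of
#' appearance in the stations table (track order). Express pairs are edges
#' of weight exactly 1. With `adjacent_only = TRUE` only consecutive
#' stations are joined (weight 1).
#'
#' @param stations data.frame from [read_stations_csv()].
#' @param express_pairs optional 2-column matrix / data.frame of station-id
#'   pairs directly connected by express service.
#' @param adjacent_only restrict edges to consecutive stations.
#' @return object of class `transit_graph`: list with `nodes`, an `edges`
#'   data.frame (from, to, weight, express) and a weighted igraph `graph`.
#' @export
build_transit_graph <- function(stations, express_pairs = NULL,
                                adjacent_only = FALSE) {
  if (!is.list(stations$lines))
    stations$lines <- strsplit(stations$lines, ";", fixed = TRUE)
  zero_line <- lengths(stations$lines) == 0
  if (any(zero_line)) {
    warning("excluding ", sum(zero_line), " station(s) on zero lines")
    stations <- stations[!zero_line, , drop = FALSE]
  }
  ids <- stations$station_id
  all_lines <- unique(unlist(stations$lines))
  best <- new.env(parent = emptyenv())
  put <- function(a, b, wt) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    cur <- best[[key]]
    if (is.null(cur) || wt < cur) best[[key]] <- wt
  }
  for (ln in all_lines) {
    on_line <- ids[vapply(stations$lines, function(ls) ln %in% ls, TRUE)]
    s <- length(on_line)
    if (s < 2) next
    for (a in seq_len(s - 1)) {
      bmax <- if (adjacent_only) a + 1 else s
      for (b in (a + 1):bmax) put(on_line[a], on_line[b], b - a)
    }
  }
  if (!is.null(express_pairs)) {
    ep <- as.matrix(express_pairs)
    for (r in seq_len(nrow(ep))) put(ep[r, 1], ep[r, 2], 1)
  }
  keys <- ls(best)
  pairs <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  edges <- if (length(keys)) {
    data.frame(from = pairs[, 1], to = pairs[, 2],
               weight = vapply(keys, function(k) best[[k]], 1),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(from = character(0), to = character(0), weight = numeric(0))
  edges$express <- rep(FALSE, nrow(edges))
  if (!is.null(express_pairs) && nrow(edges)) {
    ep <- as.matrix(express_pairs)
    epk <- apply(ep, 1, function(r) paste(sort(r), collapse = "\r"))
    edges$express <- keys %in% epk & edges$weight == 1
  }
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = ids))
  structure(list(nodes = ids, edges = edges, graph = gr,
                 stations = stations), class = "transit_graph")
}

#' @export
print.transit_graph <- function(x, ...) {
  cat(sprintf("<transit_graph> %d stations, %d edges (%d express)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$express)))
  invisible(x)
}

#' Assemble the feature matrix X = [F_s | F_c | F_m]
#'
#' Builds, per retained sample, the ridership-weighted line vector, the
#' station embedding (for a between-stations association, the mean of the
#' two stations' vectors) and the material one-hot, and concatenates them.
#' Samples with no line association are dropped with a message. Feature
#' blocks can be toggled for ablations.
#'
#' @param samples data.frame from [read_samples_csv()].
#' @param stations data.frame from [read_stations_csv()].
#' @param embedding named list / matrix rows of station embedding vectors
#'   (e.g. from [embed_stations()]); NULL disables the F_c block.
#' @param turnstiles optional turnstile data.frame for busyness weights.
#' @param materials ordered material catalogue; NULL disables F_m.
#' @param all_lines ordered line catalogue (default: union over stations in
#'   first-appearance order); NULL disables F_s.
#' @param radius association radius in miles.
#' @param blocks character subset of `c("Fs", "Fc", "Fm")` to include.
#' @return object of class `feature_matrix`: list with `sample_ids`, matrix
#'   `X`, `blocks` (named list of column index vectors), `coords` (lat/lon
#'   of retained samples) and `dropped` (ids of unassociated samples).
#' @export
assemble_features <- function(samples, stations, embedding = NULL,
                              turnstiles = NULL, materials = NULL,
                              all_lines = NULL, radius = 0.01,
                              blocks = c("Fs", "Fc", "Fm")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (!is.list(stations$lines))
    stations$lines <- strsplit(stations$lines, ";", fixed = TRUE)
  if (is.null(all_lines)) all_lines <- unique(unlist(stations$lines))
  use_fs <- "Fs" %in% blocks
  use_fc <- "Fc" %in% blocks && !is.null(embedding)
  use_fm <- "Fm" %in% blocks && !is.null(materials)
  if (!use_fs && !use_fc && !use_fm) stop("no feature blocks selected")
  wts <- busyness_weights(turnstiles, stations$station_id,
                          dates = unique(samples$date))
  emb_vec <- function(ids) {
    if (is.matrix(embedding)) vs <- embedding[ids, , drop = FALSE]
    else vs <- do.call(rbind, embedding[ids])
    colMeans(vs)
  }
  rows <- list(); kept <- character(0); dropped <- character(0)
  coords <- list()
  for (i in seq_len(nrow(samples))) {
    assoc <- associate_station(samples$lat[i], samples$lon[i], stations, radius)
    if (assoc$type == "none") {
      dropped <- c(dropped, samples$sample_id[i]); next
    }
    parts <- list()
    if (use_fs) parts$Fs <- line_feature(assoc, all_lines, wts)
    if (use_fc) parts$Fc <- emb_vec(assoc$station_ids)
    if (use_fm) parts$Fm <- material_feature(samples$material[i], materials)
    rows[[length(rows) + 1L]] <- unlist(parts, use.names = FALSE)
    kept <- c(kept, samples$sample_id[i])
    coords[[length(coords) + 1L]] <- c(samples$lat[i], samples$lon[i])
  }
  if (length(rows) == 0) stop("no samples retained after station association")
  if (length(dropped))
    message(length(dropped), " sample(s) dropped: no line association")
  X <- do.call(rbind, rows)
  widths <- c(Fs = if (use_fs) length(all_lines) else 0,
              Fc = if (use_fc) ncol(if (is.matrix(embedding)) embedding
                                    else do.call(rbind, embedding)) else 0,
              Fm = if (use_fm) length(materials) else 0)
  cn <- c(if (use_fs) paste0("Fs_", all_lines),
          if (use_fc) paste0("Fc_", seq_len(widths[["Fc"]])),
          if (use_fm) paste0("Fm_", materials))
  dimnames(X) <- list(kept, cn)
  ends <- cumsum(widths); starts <- ends - widths + 1
  block_idx <- lapply(which(widths > 0), function(i) seq(starts[i], ends[i]))
  names(block_idx) <- names(widths)[widths > 0]
  structure(list(sample_ids = kept, X = X, blocks = block_idx,
                 coords = do.call(rbind, coords), dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features [%s]\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(x$blocks), lengths(x$blocks)),
                    collapse = " ")))
  invisible(x)
}
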