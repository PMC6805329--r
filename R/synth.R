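# Synthetic-data generator: emits the station/turnstile/sample CSVs, the
# MetaPhlAn-style profile TSV and the marker FASTA with planted, recoverable
# structure, at the dialects the other modules consume.

#' Synthetic scenario configuration
#'
#' Defaults describe a desk-scale system: 2 lines of 8 stations crossing at
#' a shared hub, 120 samples, 20 genera with 3 species each, and the New
#' York surface-material catalogue. Label presence follows a logistic model
#' on line membership, surface material and proximity (in stops) to a
#' genus-specific home station, with residual co-occurrence drawn from the
#' planted phylogenetic similarity. Present-taxon abundances are drawn
#' uniform(gamma, 3 gamma) and renormalized per sample, so thresholding at
#' gamma recovers the planted presence exactly.
#'
#' @param n_lines,stations_per_line transit layout; lines cross at one hub.
#' @param n_samples number of samples n.
#' @param m number of genera (labels).
#' @param species_per_genus marker sequences per genus.
#' @param materials surface-material catalogue.
#' @param kingdoms kingdom names; genera are assigned round-robin.
#' @param within_rate,between_rate per-site substitution rates from genus
#'   seed to species, and from kingdom seed to genus seed.
#' @param marker_length marker sequence length (nt).
#' @param line_effect,material_effect,spatial_effect effect sizes on the
#'   logit scale (set all to 0 with `coupling = 0` for a null scenario).
#' @param spatial_decay decay rate of the spatial effect per stop.
#' @param base_logit range of per-genus baseline logits; the default skews
#'   negative so most genera are present at a minority of locations.
#' @param coupling scale of the correlated (similarity-driven) logit noise.
#' @param ridership_meanlog,ridership_sdlog lognormal daily rider counts.
#' @param n_days turnstile collection window length.
#' @param station_spacing miles between consecutive stations.
#' @param gamma presence threshold (fraction).
#' @param seed top-level seed; fanned out per generator.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_lines = 2, stations_per_line = 8,
                            n_samples = 120, m = 20, species_per_genus = 3,
                            materials = c("concrete", "metal", "plastic",
                                          "water", "wood"),
                            kingdoms = "Bacteria",
                            within_rate = 0.05, between_rate = 0.3,
                            marker_length = 200,
                            line_effect = 4, material_effect = 4,
                            spatial_effect = 4, spatial_decay = 0.5,
                            base_logit = c(-3, -1), coupling = 0.25,
                            ridership_meanlog = log(5000),
                            ridership_sdlog = 0.5, n_days = 14,
                            station_spacing = 0.3, gamma = 0.001,
                            seed = 1) {
  stopifnot(n_lines >= 1, stations_per_line >= 1, n_samples >= 1, m >= 1,
            species_per_genus >= 1, within_rate >= 0, between_rate >= 0,
            spatial_decay >= 0, coupling >= 0, gamma >= 0)
  if (3 * gamma * m > 1)
    stop("gamma too large: present-taxon mass 3*gamma*m must be <= 1")
  structure(as.list(environment()), class = "scenario_config")
}

#' Null-scenario configuration
#'
#' Same shapes as [scenario_config()] but with all planted effects and the
#' co-occurrence coupling zeroed: labels are independent of geography,
#' lines and materials.
#' @param ... overrides passed to [scenario_config()].
#' @export
scenario_null <- function(...) {
  scenario_config(line_effect = 0, material_effect = 0, spatial_effect = 0,
                  coupling = 0, ...)
}

MILES_PER_DEG_LAT <- 69.054

#' Generate the synthetic transit system
#'
#' Lines are geographic polylines with stations every `station_spacing`
#' miles, all crossing at a single shared hub station (so `n_lines *
#' stations_per_line - (n_lines - 1)` unique stations); per-station daily
#' riders are lognormal.
#'
#' @param config a `scenario_config`.
#' @param express_pairs optional station-id pairs with express service.
#' @return list with `stations`, `turnstiles` data.frames, `express_pairs`,
#'   the `lines` catalogue and the collection `dates`.
#' @export
generate_transit <- function(config, express_pairs = NULL) {
  seeds <- fanout_seeds(config$seed, 4)
  set.seed(seeds[1])
  s <- config$stations_per_line; nl <- config$n_lines
  hub_lat <- 40.75; hub_lon <- -73.98
  mid <- ceiling(s / 2)
  share_hub <- nl > 1 && s >= 1
  rows <- list()
  for (l in seq_len(nl)) {
    ang <- pi * (l - 1) / nl
    for (j in seq_len(s)) {
      if (share_hub && j == mid) {
        id <- "HUB"
      } else {
        id <- sprintf("L%dS%02d", l, j)
      }
      dmi <- (j - mid) * config$station_spacing
      lat <- hub_lat + dmi * cos(ang) / MILES_PER_DEG_LAT
      lon <- hub_lon + dmi * sin(ang) /
        (MILES_PER_DEG_LAT * cos(hub_lat * pi / 180))
      rows[[length(rows) + 1L]] <-
        data.frame(station_id = id, name = id, lat = lat, lon = lon,
                   line = sprintf("L%d", l), stringsAsFactors = FALSE)
    }
  }
  all_rows <- do.call(rbind, rows)
  # collapse the hub: one station on all its lines, placed at the hub
  lines_of <- tapply(all_rows$line, all_rows$station_id, function(x)
    paste(unique(x), collapse = ";"))
  first <- !duplicated(all_rows$station_id)
  stations <- all_rows[first, c("station_id", "name", "lat", "lon")]
  stations$lines <- unname(lines_of[stations$station_id])
  rownames(stations) <- NULL
  dates <- format(as.Date("2017-06-01") + seq_len(config$n_days) - 1)
  set.seed(seeds[2])
  turnstiles <- expand.grid(station_id = stations$station_id, date = dates,
                            stringsAsFactors = FALSE)
  nt <- nrow(turnstiles)
  turnstiles$entries <- round(stats::rlnorm(nt, config$ridership_meanlog,
                                            config$ridership_sdlog))
  turnstiles$exits <- round(stats::rlnorm(nt, config$ridership_meanlog,
                                          config$ridership_sdlog))
  list(stations = stations, turnstiles = turnstiles,
       express_pairs = express_pairs,
       lines = sprintf("L%d", seq_len(nl)), dates = dates)
}

mutate_sequence <- function(seq, rate) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1)
  paste(x, collapse = "")
}

genus_names <- function(m) sprintf("Genus%03d", seq_len(m))

#' Generate marker sequences with a planted hierarchy
#'
#' Each kingdom gets a random seed sequence; each genus seed is the kingdom
#' seed mutated at `between_rate`; each species is the genus seed mutated at
#' `within_rate`. Within-genus identity therefore exceeds between-genus
#' identity, which exceeds cross-kingdom (fixed at 0 downstream).
#'
#' @param config a `scenario_config`.
#' @return data.frame with kingdom, genus, species, sequence (the layout of
#'   [read_marker_fasta()]).
#' @export
generate_marker_fasta <- function(config) {
  seeds <- fanout_seeds(config$seed, 4)
  set.seed(seeds[3])
  bases <- c("A", "C", "G", "T")
  kseeds <- lapply(config$kingdoms, function(.)
    paste(sample(bases, config$marker_length, replace = TRUE), collapse = ""))
  names(kseeds) <- config$kingdoms
  gnames <- genus_names(config$m)
  gking <- config$kingdoms[(seq_len(config$m) - 1) %% length(config$kingdoms) + 1]
  out <- list()
  for (g in seq_len(config$m)) {
    gseed <- mutate_sequence(kseeds[[gking[g]]], config$between_rate)
    for (sp in seq_len(config$species_per_genus)) {
      out[[length(out) + 1L]] <- data.frame(
        kingdom = gking[g], genus = gnames[g],
        species = sprintf("%s_sp%d", gnames[g], sp),
        sequence = mutate_sequence(gseed, config$within_rate),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write marker sequences as FASTA with kingdom|genus|species headers
#' @param markers data.frame from [generate_marker_fasta()].
#' @param path FASTA path.
#' @export
write_marker_fasta <- function(markers, path) {
  seqs <- Biostrings::DNAStringSet(markers$sequence)
  names(seqs) <- sprintf("%s|%s|%s", markers$kingdom, markers$genus,
                         markers$species)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Project a symmetric matrix onto the PSD cone (clamp negative eigenvalues)
# so it can serve as a covariance for the correlated logit noise.
psd_project <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

#' Generate samples, abundance profiles and the planted label matrix
#'
#' Samples are placed at stations (jittered within the association radius)
#' with a material label and a collection date. Each genus j's presence
#' logit at sample i is
#' `intercept_j + line effects + material effect + spatial_effect *
#' exp(-spatial_decay * stops(station_i, home_j)) + coupling * eps_ij`,
#' where `eps_i` is Gaussian with covariance proportional to the planted
#' genus similarity `P_true` (phylogenetically similar genera co-occur).
#' Present-taxon abundances are uniform(gamma, 3 gamma) renormalized per
#' sample, so thresholding at gamma reproduces the planted Y exactly.
#'
#' @param config a `scenario_config`.
#' @param transit result of [generate_transit()].
#' @param P_true m x m planted genus similarity (e.g. from
#'   [aggregate_to_genus()] on the generated markers); NULL means no
#'   correlated noise.
#' @return list with `samples` (metadata data.frame), `profiles` (list of
#'   `abundance_profile`), `Y` (n x m planted binary matrix, genus columns),
#'   and `truth` (the generative effect parameters).
#' @export
generate_samples_and_labels <- function(config, transit, P_true = NULL) {
  seeds <- fanout_seeds(config$seed, 4)
  set.seed(seeds[4])
  st <- transit$stations
  st$lines <- strsplit(st$lines, ";", fixed = TRUE)
  n <- config$n_samples; m <- config$m
  gnames <- genus_names(m)
  nl <- length(transit$lines); nmat <- length(config$materials)

  tg <- build_transit_graph(st)
  stopdist <- igraph::distances(tg$graph, weights = igraph::E(tg$graph)$weight)
  stopdist[!is.finite(stopdist)] <- max(stopdist[is.finite(stopdist)]) + 1

  truth <- list(
    intercept = runif(m, config$base_logit[1], config$base_logit[2]),
    line_w = matrix(config$line_effect *
                      sample(c(-1, 1), m * nl, replace = TRUE), m, nl,
                    dimnames = list(gnames, transit$lines)),
    material_w = matrix(config$material_effect *
                          sample(c(-1, 1), m * nmat, replace = TRUE), m, nmat,
                        dimnames = list(gnames, config$materials)),
    home = sample(st$station_id, m, replace = TRUE))
  chol_fac <- NULL
  if (!is.null(P_true) && config$coupling > 0) {
    Sig <- psd_project(as.matrix(P_true)) + diag(1e-8, m)
    chol_fac <- chol(Sig)
  }

  pick_station <- sample.int(nrow(st), n, replace = TRUE)
  jitter_mi <- config$radius_jitter %||% 0.003
  ang <- runif(n, 0, 2 * pi); r <- runif(n, 0, jitter_mi)
  lat <- st$lat[pick_station] + r * cos(ang) / MILES_PER_DEG_LAT
  lon <- st$lon[pick_station] + r * sin(ang) /
    (MILES_PER_DEG_LAT * cos(st$lat[pick_station] * pi / 180))
  material <- sample(config$materials, n, replace = TRUE)
  date <- sample(transit$dates, n, replace = TRUE)
  sample_ids <- sprintf("S%04d", seq_len(n))

  eta <- matrix(rep(truth$intercept, each = n), n, m)
  line_ind <- t(vapply(st$lines[pick_station],
                       function(ls) as.numeric(transit$lines %in% ls),
                       numeric(nl)))                       # n x nl
  eta <- eta + line_ind %*% t(truth$line_w)
  eta <- eta + t(truth$material_w[, material])             # m x n -> n x m
  home_idx <- match(truth$home, st$station_id)
  ddist <- stopdist[pick_station, home_idx, drop = FALSE]  # n x m
  eta <- eta + config$spatial_effect * exp(-config$spatial_decay * ddist)
  if (!is.null(chol_fac)) {
    eps <- matrix(rnorm(n * m), n, m) %*% chol_fac
    eta <- eta + config$coupling * eps
  }
  Y <- matrix(rbinom(n * m, 1, plogis(eta)), n, m,
              dimnames = list(sample_ids, gnames))

  profiles <- lapply(seq_len(n), function(i) {
    ab <- setNames(numeric(m), gnames)
    pres <- which(Y[i, ] == 1)
    if (length(pres)) {
      raw <- runif(length(pres), config$gamma, 3 * config$gamma)
      ab[pres] <- raw / sum(raw)
    }
    new_abundance_profile(sample_ids[i], ab, "genus",
                          flagged_empty = length(pres) == 0)
  })
  samples <- data.frame(sample_id = sample_ids, lat = lat, lon = lon,
                        material = material, date = date,
                        stringsAsFactors = FALSE)
  list(samples = samples, profiles = profiles, Y = Y, truth = truth,
       station = st$station_id[pick_station])
}

#' Generate a full scenario end to end
#'
#' Transit system, marker FASTA, planted genus similarity + Laplacian,
#' samples/profiles/labels, and (optionally) all files on disk in the
#' dialects the parsers consume, plus a JSON manifest of config and seed.
#'
#' @param config a `scenario_config`.
#' @param out_dir optional directory to write stations.csv, turnstile.csv,
#'   samples.csv, profiles.tsv, markers.fasta, P.tsv, L.tsv, Y.tsv and
#'   manifest.json.
#' @return list with `config`, `transit`, `markers`, `species_sim`,
#'   `genus_sim`, `laplacian`, `samples`, `profiles`, `Y`, `truth`.
#' @export
generate_scenario <- function(config = scenario_config(), out_dir = NULL) {
  transit <- generate_transit(config)
  markers <- generate_marker_fasta(config)
  ssim <- pairwise_species_similarity(markers)
  gsim <- aggregate_to_genus(ssim)
  lap <- build_laplacian(gsim)
  sl <- generate_samples_and_labels(config, transit, P_true = gsim$P)
  out <- list(config = config, transit = transit, markers = markers,
              species_sim = ssim, genus_sim = gsim, laplacian = lap,
              samples = sl$samples, profiles = sl$profiles, Y = sl$Y,
              truth = sl$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write.csv(transit$stations, p("stations.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(transit$turnstiles, p("turnstile.csv"), row.names = FALSE,
              quote = FALSE)
    write.csv(sl$samples, p("samples.csv"), row.names = FALSE, quote = FALSE)
    kingdom_of <- setNames(markers$kingdom[!duplicated(markers$genus)],
                           markers$genus[!duplicated(markers$genus)])
    write_profile_table(sl$profiles, p("profiles.tsv"),
                        kingdom_of = kingdom_of)
    write_marker_fasta(markers, p("markers.fasta"))
    write_matrix_tsv(gsim$P, p("P.tsv"), id_col = "genus")
    write_matrix_tsv(lap$L, p("L.tsv"), id_col = "genus")
    write_matrix_tsv(sl$Y, p("Y.tsv"), id_col = "sample_id")
    jsonlite::write_json(list(config = unclass(config),
                              generated = "metamlann synthetic scenario"),
                         p("manifest.json"), auto_unbox = TRUE, digits = NA)
    out$paths <- vapply(c("stations.csv", "turnstile.csv", "samples.csv",
                          "profiles.tsv", "markers.fasta", "P.tsv", "L.tsv",
                          "Y.tsv", "manifest.json"), p, "")
  }
  out
}
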