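test_that("station association: direct hit, between-stations fallback, removal", {
  st <- make_stations(c("A", "B", "C"),
                      lat = c(40.70, 40.71, 40.80),
                      lon = c(-74, -74, -73.5),
                      lines = c("1;2", "1", "9"))
  # exact coordinates: that station
  a <- associate_station(40.70, -74, st, radius = 0.01)
  expect_equal(a$type, "station")
  expect_equal(a$station_ids, "A")
  expect_equal(a$distance, 0)
  # midway between A and B (~0.69 miles apart), beyond the radius:
  # shared line of the two nearest
  b <- associate_station(40.705, -74, st, radius = 0.01)
  expect_equal(b$type, "between")
  expect_setequal(b$station_ids, c("A", "B"))
  expect_equal(b$lines, "1")
  # far from all, two nearest on disjoint lines: no association
  st2 <- make_stations(c("A", "C"), c(40.70, 40.80), c(-74, -73.5),
                       c("1", "9"))
  n <- associate_station(40.75, -73.75, st2, radius = 0.01)
  expect_equal(n$type, "none")
  expect_error(associate_station(95, -74, st, radius = 0.01), "coordinates")
})

test_that("line feature is an indicator scaled by station busyness", {
  assoc <- list(type = "station", station_ids = "A", lines = c("1", "2"))
  expect_equal(line_feature(assoc, c("1", "2", "3"),
                            weights = c(A = 2.0)), c(2, 2, 0))
  # no turnstile information: pure binary
  expect_equal(line_feature(assoc, c("1", "2", "3")), c(1, 1, 0))
  expect_error(line_feature(assoc, c("1", "3")), "catalogue")
  expect_error(line_feature(list(type = "none", lines = character(0)),
                            c("1")), "unassociated")
})

test_that("busyness weights average daily entries+exits, normalized to (0,1]", {
  tt <- data.frame(station_id = c("A", "A", "B"),
                   date = c("d1", "d2", "d1"),
                   entries = c(100, 200, 300), exits = c(100, 200, 300))
  w <- busyness_weights(tt, c("A", "B", "C"))
  expect_equal(unname(w["B"]), 1)           # busiest station
  expect_equal(unname(w["A"]), 300 / 600)   # mean daily 300 vs 600
  expect_equal(unname(w["C"]), 1 / 600)     # no data: raw weight 1, scaled
  raw <- busyness_weights(tt, c("A", "B"), normalize = FALSE)
  expect_equal(unname(raw), c(300, 600))
  expect_equal(unname(busyness_weights(NULL, c("A", "B"))), c(1, 1))
})

test_that("transit graph: stop-count weights, express override, disjoint lines", {
  st <- linear_stations(3)                   # A1 - A2 - A3 along one line
  tg <- build_transit_graph(st)
  w <- function(a, b) {
    e <- tg$edges
    e$weight[(e$from == a & e$to == b) | (e$from == b & e$to == a)]
  }
  expect_equal(w("A1", "A2"), 1)
  expect_equal(w("A2", "A3"), 1)
  expect_equal(w("A1", "A3"), 2)
  # express pair forces weight 1
  tge <- build_transit_graph(st, express_pairs = cbind("A1", "A3"))
  we <- tge$edges
  expect_equal(we$weight[(we$from == "A1" & we$to == "A3") |
                         (we$from == "A3" & we$to == "A1")], 1)
  expect_true(any(we$express))
  # disjoint lines never share an edge
  st2 <- make_stations(c("A", "B"), c(40.7, 40.71), c(-74, -74), c("1", "2"))
  expect_equal(nrow(build_transit_graph(st2)$edges), 0)
})

test_that("single line of s stations: s(s-1)/2 edges, max weight s-1", {
  for (s in c(4, 7)) {
    tg <- build_transit_graph(linear_stations(s))
    expect_equal(nrow(tg$edges), s * (s - 1) / 2)
    expect_equal(max(tg$edges$weight), s - 1)
  }
  # adjacent-only alternative keeps consecutive edges only
  tga <- build_transit_graph(linear_stations(5), adjacent_only = TRUE)
  expect_equal(nrow(tga$edges), 4)
  expect_true(all(tga$edges$weight == 1))
})

test_that("material one-hot follows the printed catalogue order", {
  ny <- c("concrete", "metal", "plastic", "water", "wood")
  expect_equal(material_feature("metal", ny), c(0, 1, 0, 0, 0))
  expect_warning(v <- material_feature("granite", ny), "unknown")
  expect_equal(v, rep(0, 5))
  for (m in ny) expect_equal(sum(material_feature(m, ny)), 1)
  boston <- c("glass", "polyester", "PVC", "steel")
  expect_equal(material_feature("PVC", boston), c(0, 0, 1, 0))
})

test_that("assembled features have NY-like width 46 and block structure", {
  # 25-line city, d = 16 embedding, 5 materials -> k = 46
  lines <- paste0("L", 1:25)
  st <- make_stations(paste0("S", 1:25), 40.7 + (1:25) / 200,
                      rep(-74, 25), lines)
  emb <- matrix(rnorm(25 * 16), 25, 16, dimnames = list(st$station_id, NULL))
  samples <- data.frame(sample_id = c("a", "b"),
                        lat = st$lat[c(3, 10)], lon = st$lon[c(3, 10)],
                        material = c("metal", "wood"),
                        date = "2017-06-01", stringsAsFactors = FALSE)
  ny <- c("concrete", "metal", "plastic", "water", "wood")
  fm <- assemble_features(samples, st, embedding = emb, materials = ny,
                          all_lines = lines)
  expect_equal(ncol(fm$X), 46)
  expect_equal(lengths(fm$blocks), c(Fs = 25L, Fc = 16L, Fm = 5L))
  expect_equal(nrow(fm$X), 2)
  # single sample still yields a 1 x k matrix
  fm1 <- assemble_features(samples[1, ], st, embedding = emb,
                           materials = ny, all_lines = lines)
  expect_equal(dim(fm1$X), c(1L, 46L))
  # ablation subsets: width equals the sum of selected block widths
  combos <- list(c("Fs", "Fc"), c("Fs", "Fm"), c("Fc", "Fm"),
                 "Fs", "Fc", "Fm")
  widths <- c(Fs = 25, Fc = 16, Fm = 5)
  for (bl in combos) {
    fmb <- assemble_features(samples, st, embedding = emb, materials = ny,
                             all_lines = lines, blocks = bl)
    expect_equal(ncol(fmb$X), sum(widths[bl]))
  }
})

test_that("feature assembly is permutation-equivariant and drops unassociated samples", {
  # two two-station lines far apart; a sample between them has its two
  # nearest stations on disjoint lines and is dropped
  st <- make_stations(c("A1", "A2", "B1", "B2"),
                      lat = c(40.70, 40.71, 40.90, 40.91),
                      lon = rep(-74, 4), lines = c("1", "1", "2", "2"))
  set.seed(8)
  emb <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(st$station_id, NULL))
  samples <- data.frame(sample_id = paste0("s", 1:5),
                        lat = c(st$lat, 40.805),
                        lon = c(st$lon, -74),
                        material = "wood", date = "2017-06-01",
                        stringsAsFactors = FALSE)
  fm <- suppressMessages(assemble_features(samples, st, embedding = emb,
                                           materials = c("wood")))
  expect_equal(fm$dropped, "s5")
  perm <- c(3, 1, 4, 2, 5)
  fmp <- suppressMessages(assemble_features(samples[perm, ], st,
                                            embedding = emb,
                                            materials = c("wood")))
  expect_equal(fmp$X[sort(fmp$sample_ids), ], fm$X[sort(fm$sample_ids), ])
})

test_that("omitting turnstiles equals all-ones busyness weights", {
  st <- linear_stations(3)
  emb <- matrix(0, 3, 2, dimnames = list(st$station_id, NULL))
  samples <- data.frame(sample_id = "s1", lat = st$lat[2], lon = st$lon[2],
                        material = "wood", date = "2017-06-01")
  no_tt <- assemble_features(samples, st, embedding = emb,
                             materials = "wood")
  ones <- data.frame(station_id = st$station_id, date = "2017-06-01",
                     entries = 1, exits = 1)
  with_ones <- assemble_features(samples, st, embedding = emb,
                                 turnstiles = ones, materials = "wood")
  expect_equal(no_tt$X, with_ones$X)
})

test_that("CSV readers validate schemas", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,name,lat,lon,lines", "A,A,40.7,-74,1;2"), f)
  st <- read_stations_csv(f)
  expect_equal(st$lines[[1]], c("1", "2"))
  writeLines(c("station_id,name,lat,lon", "A,A,40.7,-74"), f)
  expect_error(read_stations_csv(f), "columns")
  writeLines(c("station_id,date,entries,exits", "A,2017-06-01,-3,0"), f)
  expect_error(read_turnstile_csv(f), "negative")
  writeLines(c("sample_id,lat,lon,material,date", "s,91,0,wood,2017-06-01"), f)
  expect_error(read_samples_csv(f), "coordinates")
})
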