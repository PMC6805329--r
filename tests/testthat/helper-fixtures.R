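# Shared fixture builders: everything is generated in code at test time.

# Small station table: `lines` given as semicolon strings (the CSV dialect).
make_stations <- function(ids, lat, lon, lines) {
  data.frame(station_id = ids, name = ids, lat = lat, lon = lon,
             lines = lines, stringsAsFactors = FALSE)
}

# Three stations 0.3 miles apart on one north-south line.
linear_stations <- function(n = 3, line = "A", spacing_mi = 0.3,
                            lat0 = 40.7, lon0 = -74) {
  make_stations(sprintf("%s%d", line, seq_len(n)),
                lat0 + (seq_len(n) - 1) * spacing_mi / 69.054,
                rep(lon0, n), rep(line, n))
}

# Features + aligned labels for a generated scenario; embeds the transit
# graph and drops unassociated samples.
scenario_features <- function(sc, seed = 1, d = 16) {
  tg <- build_transit_graph(sc$transit$stations)
  emb <- embed_stations(tg, d = d, seed = seed)
  fm <- assemble_features(sc$samples, sc$transit$stations, embedding = emb,
                          turnstiles = sc$transit$turnstiles,
                          materials = sc$config$materials)
  list(fm = fm, X = fm$X, Y = sc$Y[fm$sample_ids, , drop = FALSE],
       coords = fm$coords)
}

# Held-out micro-F1 of a model trained on the true labels minus one trained
# on row-shuffled labels (the label-shuffled control), on a 1/3 holdout.
heldout_f1_gap <- function(config, seed, epochs = 200) {
  sc <- generate_scenario(config)
  sf <- scenario_features(sc, seed = seed)
  X <- sf$X; Y <- sf$Y
  n <- nrow(X)
  set.seed(seed)
  test <- sample.int(n, round(n / 3)); train <- setdiff(seq_len(n), test)
  cfg <- metamlann_config(k = ncol(X), m = ncol(Y), seed = seed,
                          epochs = epochs)
  fit_f1 <- function(Ytr) {
    fit <- metamlann_train(X[train, , drop = FALSE], Ytr, cfg)
    suppressWarnings(
      micro_prf(Y[test, , drop = FALSE],
                predict(fit, X[test, , drop = FALSE])$predictions)[["f1"]])
  }
  real <- fit_f1(Y[train, , drop = FALSE])
  set.seed(seed + 1000)
  shuf <- fit_f1(Y[train, , drop = FALSE][sample(length(train)), ,
                                          drop = FALSE])
  real - shuf
}

# Random symmetric nonnegative similarity matrix.
random_similarity <- function(m) {
  P <- matrix(runif(m * m), m, m)
  (P + t(P)) / 2
}

# Independent half-sum oracle for the Laplacian penalty:
# 0.5 * sum_{i,j} P_ij (beta_i - beta_j)^2, by explicit double loop.
omega_halfsum <- function(P, beta) {
  s <- 0
  for (i in seq_along(beta)) for (j in seq_along(beta))
    s <- s + P[i, j] * (beta[i] - beta[j])^2
  s / 2
}

# Brute-force micro metrics from one flat binary confusion.
micro_prf_oracle <- function(Yt, Yp) {
  yt <- as.vector(Yt); yp <- as.vector(Yp)
  tp <- sum(yt == 1 & yp == 1); fp <- sum(yt == 0 & yp == 1)
  fn <- sum(yt == 1 & yp == 0)
  pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  c(precision = pr, recall = rc, f1 = f1)
}

# Exhaustive pair-count oracle for ranking loss (strict inequality; samples
# with degenerate truth rows skipped).
ranking_loss_oracle <- function(Yt, S) {
  vals <- c()
  for (i in seq_len(nrow(Yt))) {
    y <- Yt[i, ]; s <- S[i, ]
    npos <- sum(y); m <- length(y)
    if (npos == 0 || npos == m) next
    bad <- 0
    for (a in which(y == 1)) for (b in which(y == 0))
      if (s[a] < s[b]) bad <- bad + 1
    vals <- c(vals, bad / (npos * (m - npos)))
  }
  mean(vals)
}
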