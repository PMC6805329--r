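# Spatial IDW baseline and the MetaMLAnn+ convex-combination ensemble.

#' Inverse-distance-weighted label interpolation
#'
#' Estimates a query location's label-score vector as the weighted average of
#' sampled locations' vectors, with weights `1 / (d + eps)^power` and `d`
#' the great-circle distance in miles. A query coinciding with a sampled
#' point (distance `< eps`) returns that point's vector exactly.
#'
#' @param query numeric `c(lat, lon)` for the query location.
#' @param coords n x 2 matrix of sampled lat/lon.
#' @param values n x m matrix of sampled label vectors (binary presence or
#'   presence frequencies).
#' @param power distance exponent, `> 0` (default 2).
#' @param eps zero-distance guard in miles (default 1e-6).
#' @return length-m score vector.
#' @export
idw_predict <- function(query, coords, values, power = 2, eps = 1e-6) {
  stopifnot(power > 0, nrow(coords) >= 1, nrow(coords) == nrow(values))
  check_coords(query[1], query[2], "IDW query")
  check_coords(coords[, 1], coords[, 2], "IDW sample")
  d <- haversine_miles(coords[, 2], coords[, 1], query[2], query[1])
  hit <- which(d < eps)
  if (length(hit)) return(values[hit[1], ])
  w <- 1 / (d + eps)^power
  drop(crossprod(values, w)) / sum(w)
}

#' IDW scores for many query points
#'
#' @param queries q x 2 matrix of lat/lon.
#' @inheritParams idw_predict
#' @return q x m score matrix.
#' @export
idw_predict_matrix <- function(queries, coords, values, power = 2, eps = 1e-6) {
  t(apply(queries, 1, idw_predict, coords = coords, values = values,
          power = power, eps = eps))
}

#' Hybrid ensemble prediction (MetaMLAnn+)
#'
#' Elementwise convex combination `o_h = alpha * o + (1 - alpha) * o_m` of
#' MetaMLAnn scores with a partner model's scores. `alpha = 1` returns the
#' MetaMLAnn scores unchanged, `alpha = 0` the partner's.
#'
#' @param o MetaMLAnn score matrix.
#' @param o_m partner score matrix, same shape.
#' @param alpha ensemble weight in \[0, 1\] (0.7 is the tuned default).
#' @return hybrid score matrix.
#' @export
ensemble_predict <- function(o, o_m, alpha = 0.7) {
  if (!all(dim(as.matrix(o)) == dim(as.matrix(o_m))))
    stop("score matrices must have identical shape")
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 1) return(o)
  if (alpha == 0) return(o_m)
  alpha * o + (1 - alpha) * o_m
}

#' Trainer adapters for the cross-validation harness
#'
#' Each adapter has the [kfold_cv()] trainer signature
#' `(X, Y, train_idx, test_idx, fold_seed) -> score matrix` for the test
#' rows.
#'
#' `idw_trainer` interpolates the training fold's binary label vectors at
#' the test locations; it consumes per-sample coordinates (aligned with the
#' rows of `Y`), not features.
#'
#' @param coords n x 2 lat/lon matrix for all samples.
#' @param power,eps IDW parameters.
#' @return a trainer function.
#' @export
idw_trainer <- function(coords, power = 2, eps = 1e-6) {
  force(coords)
  function(X, Y, train, test, fold_seed) {
    idw_predict_matrix(coords[test, , drop = FALSE],
                       coords[train, , drop = FALSE],
                       Y[train, , drop = FALSE], power = power, eps = eps)
  }
}

#' @rdname idw_trainer
#' @param config a `metamlann_config`; `seed` is replaced per fold.
#' @param lap optional `laplacian` for regularized training.
#' @export
metamlann_trainer <- function(config, lap = NULL) {
  force(config); force(lap)
  function(X, Y, train, test, fold_seed) {
    cfg <- config
    cfg$seed <- as.integer(fold_seed %% .Machine$integer.max)
    fit <- metamlann_train(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                           cfg, lap = lap)
    predict(fit, X[test, , drop = FALSE])$scores
  }
}

#' @rdname idw_trainer
#' @param trainer_a,trainer_b component trainers to combine.
#' @param alpha ensemble weight on `trainer_a`.
#' @export
ensemble_trainer <- function(trainer_a, trainer_b, alpha = 0.7) {
  force(trainer_a); force(trainer_b); force(alpha)
  function(X, Y, train, test, fold_seed) {
    ensemble_predict(trainer_a(X, Y, train, test, fold_seed),
                     trainer_b(X, Y, train, test, fold_seed),
                     alpha)
  }
}
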