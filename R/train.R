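# SGD training of the block network and prediction / checkpointing.

apply_gradients <- function(params, g, lr) {
  for (bl in names(g$W1)) {
    params$W1[[bl]] <- params$W1[[bl]] - lr * g$W1[[bl]]
    params$b1[[bl]] <- params$b1[[bl]] - lr * g$b1[[bl]]
  }
  if (!is.null(g$W2_ind)) params$W2_ind <- params$W2_ind - lr * g$W2_ind
  if (!is.null(g$W2_shared)) params$W2_shared <- params$W2_shared - lr * g$W2_shared
  params$b2 <- params$b2 - lr * g$b2
  params
}

#' Train a MetaMLAnn model
#'
#' Stochastic gradient descent on the Laplacian-regularized cross-entropy.
#' Two schemes are supported. `"minibatch"` (default) backpropagates the
#' full multi-label loss on shuffled minibatches. `"block-sampling"` follows
#' the per-block sampling scheme: each step draws a location and one label
#' and updates that label's individual-block path, then draws a location and
#' a label over all classes and updates the shared-block path. The per-epoch
#' loss trace records the full-data regularized loss.
#'
#' @param X n x k feature matrix (a `feature_matrix` or plain matrix).
#' @param Y n x m binary label matrix (a `microbial_distribution` or matrix).
#' @param config a `metamlann_config`.
#' @param lap optional `laplacian` (required when `config$lambda > 0`).
#' @return object of class `metamlann`: list with `params`, `config`,
#'   `trace` (data.frame epoch / ce / omega / total), label and feature
#'   names.
#' @export
metamlann_train <- function(X, Y, config, lap = NULL) {
  if (inherits(X, "feature_matrix")) { feat_names <- colnames(X$X); X <- X$X }
  else feat_names <- colnames(X)
  if (inherits(Y, "microbial_distribution")) { labels <- Y$index; Y <- Y$Y }
  else labels <- colnames(Y)
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  if (nrow(X) < 2) stop("need at least 2 training samples")
  if (ncol(X) != config$k) stop("config$k does not match ncol(X)")
  if (ncol(Y) != config$m) stop("config$m does not match ncol(Y)")
  if (config$lambda > 0 && is.null(lap))
    stop("lambda > 0 requires a Laplacian")
  L <- if (is.null(lap)) matrix(0, config$m, config$m)
       else if (inherits(lap, "laplacian")) lap$L else lap

  params <- init_parameters(config)
  set.seed(config$seed + 1L)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  trace <- data.frame(epoch = integer(0), ce = numeric(0),
                      omega = numeric(0), total = numeric(0))
  record <- function(epoch, params) {
    o <- model_forward(params, X)
    ce <- cross_entropy_loss(o, Y)
    omega <- sum((o %*% L) * o) / n
    rbind(trace, data.frame(epoch = epoch, ce = ce, omega = omega,
                            total = ce + config$lambda * omega))
  }
  trace <- record(0L, params)
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    lr <- config$learning_rate / (1 + (config$lr_decay %||% 0) * ep)
    if (config$training_scheme == "minibatch") {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        g <- model_gradients(params, X[idx, , drop = FALSE],
                             Y[idx, , drop = FALSE], L, config$lambda)
        params <- apply_gradients(params, g, lr)
      }
    } else {
      params <- block_sampling_epoch(params, X, Y, L, config, lr)
    }
    trace <- record(ep, params)
    if (!is.finite(trace$total[nrow(trace)])) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           "; trace so far:\n", paste(utils::capture.output(print(trace)),
                                      collapse = "\n"))
    }
  }
  structure(list(params = params, config = config, trace = trace,
                 labels = labels, features = feat_names),
            class = "metamlann")
}

# One epoch of the per-block sampling scheme: n steps; each step updates one
# sampled label's individual path on one sampled location, then the shared
# path on a fresh (location, label) draw over all classes.
block_sampling_epoch <- function(params, X, Y, L, config, lr = config$learning_rate) {
  n <- nrow(X); m <- config$m
  for (step in seq_len(n)) {
    if (has_individual(config)) {
      i <- sample.int(n, 1); j <- sample.int(m, 1)
      g <- model_gradients(params, X[i, , drop = FALSE],
                           Y[i, , drop = FALSE], L, config$lambda)
      bl <- paste0("B", j)
      params$W1[[bl]] <- params$W1[[bl]] - lr * g$W1[[bl]]
      params$b1[[bl]] <- params$b1[[bl]] - lr * g$b1[[bl]]
      params$W2_ind[j, ] <- params$W2_ind[j, ] - lr * g$W2_ind[j, ]
      if (length(params$b2) > 1) params$b2[j] <- params$b2[j] - lr * g$b2[j]
      else params$b2 <- params$b2 - lr * g$b2
    }
    if (has_shared(config)) {
      i <- sample.int(n, 1)
      g <- model_gradients(params, X[i, , drop = FALSE],
                           Y[i, , drop = FALSE], L, config$lambda)
      params$W1[["Bshare"]] <- params$W1[["Bshare"]] - lr * g$W1[["Bshare"]]
      params$b1[["Bshare"]] <- params$b1[["Bshare"]] - lr * g$b1[["Bshare"]]
      params$W2_shared <- params$W2_shared - lr * g$W2_shared
    }
  }
  params
}

#' Predict presence scores and binary calls
#'
#' @param object a trained `metamlann`.
#' @param X feature matrix (n x k) or `feature_matrix`.
#' @param threshold presence cut on the sigmoid score; `score >= threshold`
#'   is called present (default 0.5).
#' @param ... unused.
#' @return list with `scores` (n x m, in (0, 1)) and `predictions`
#'   (binary n x m).
#' @export
predict.metamlann <- function(object, X, threshold = 0.5, ...) {
  if (inherits(X, "feature_matrix")) X <- X$X
  scores <- model_forward(object$params, X)
  colnames(scores) <- object$labels
  preds <- (scores >= threshold) * 1L
  list(scores = scores, predictions = preds)
}

#' @export
print.metamlann <- function(x, ...) {
  cat(sprintf("<metamlann> k=%d features, m=%d labels, p=%d, mode=%s, lambda=%g\n",
              x$config$k, x$config$m, x$config$p, x$config$mode,
              x$config$lambda))
  cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
              max(x$trace$epoch), x$trace$total[1],
              x$trace$total[nrow(x$trace)]))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the config echo and all
#' weight arrays, plus the loss trace as CSV alongside when requested.
#'
#' @param model a `metamlann`.
#' @param path checkpoint path (.json).
#' @param trace_path optional CSV path for the per-epoch loss trace.
#' @export
save_checkpoint <- function(model, path, trace_path = NULL) {
  payload <- list(
    config = unclass(model$config),
    labels = model$labels, features = model$features,
    W1 = lapply(model$params$W1, function(w) unclass(w)),
    b1 = model$params$b1,
    W2_ind = model$params$W2_ind,
    W2_shared = model$params$W2_shared,
    b2 = model$params$b2)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(trace_path))
    write.csv(model$trace, trace_path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint path written by [save_checkpoint()].
#' @export
load_checkpoint <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(metamlann_config,
                 pl$config[setdiff(names(pl$config), character(0))])
  params <- init_parameters(cfg)
  for (bl in names(params$W1)) {
    params$W1[[bl]] <- matrix(unlist(pl$W1[[bl]]), cfg$p, cfg$k)
    params$b1[[bl]] <- as.numeric(pl$b1[[bl]])
  }
  if (!is.null(params$W2_ind))
    params$W2_ind <- matrix(as.numeric(pl$W2_ind), cfg$m, cfg$p)
  if (!is.null(params$W2_shared)) {
    params$W2_shared <- if (cfg$shared_output_weights == "single")
      as.numeric(pl$W2_shared) else matrix(as.numeric(pl$W2_shared), cfg$m, cfg$p)
  }
  params$b2 <- as.numeric(pl$b2)
  structure(list(params = params, config = cfg, trace = NULL,
                 labels = pl$labels, features = pl$features),
            class = "metamlann")
}
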