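# The MetaMLAnn network: m individual hidden blocks plus one shared block,
# each a single hidden layer of p units feeding sigmoid output neurons.
# Output o_i = sigmoid(W2_i B_i + W2_share B_share + b2); the shared block is
# connected to every output label, each individual block only to its own.

#' Model configuration
#'
#' @param k input dimension (number of features).
#' @param m number of labels (microbes).
#' @param p hidden units per block.
#' @param lambda graph-Laplacian regularization weight, `>= 0`.
#' @param learning_rate initial SGD step size.
#' @param lr_decay epoch-wise step decay: the step at epoch t is
#'   `learning_rate / (1 + lr_decay * t)` (0 disables).
#' @param epochs training epochs.
#' @param batch_size minibatch size (capped at n during training).
#' @param seed RNG seed for initialization and batch order.
#' @param mode which blocks are active: `"both"` (default), or the ablation
#'   variants `"individual-only"` / `"shared-only"`.
#' @param shared_output_weights `"single"` keeps one shared-block output
#'   weight vector and one scalar output bias common to all labels (the
#'   literal block formula); `"per-label"` gives every label its own shared
#'   weights and bias.
#' @param hidden_activation `"tanh"` (default) or `"sigmoid"`.
#' @param training_scheme `"minibatch"` (full-label backprop, default) or
#'   `"block-sampling"` (per step, draw a location and one label and update
#'   that label's individual path; draw again over all labels for the shared
#'   path).
#' @return a `metamlann_config` list.
#' @export
metamlann_config <- function(k, m, p = 32, lambda = 0, learning_rate = 0.05,
                             lr_decay = 0.02, epochs = 200, batch_size = 32,
                             seed = 1,
                             mode = c("both", "individual-only", "shared-only"),
                             shared_output_weights = c("single", "per-label"),
                             hidden_activation = c("tanh", "sigmoid"),
                             training_scheme = c("minibatch", "block-sampling")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, m >= 1, p >= 1, lambda >= 0, epochs >= 0,
            learning_rate > 0, batch_size >= 1)
  stopifnot(lr_decay >= 0)
  structure(list(k = as.integer(k), m = as.integer(m), p = as.integer(p),
                 lambda = lambda, learning_rate = learning_rate,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 mode = mode,
                 shared_output_weights = match.arg(shared_output_weights),
                 hidden_activation = match.arg(hidden_activation),
                 training_scheme = match.arg(training_scheme)),
            class = "metamlann_config")
}

has_individual <- function(config) config$mode %in% c("both", "individual-only")
has_shared <- function(config) config$mode %in% c("both", "shared-only")

hidden_fn <- function(config) {
  switch(config$hidden_activation, tanh = tanh, sigmoid = sigmoid)
}
# derivative of the hidden activation expressed through its value
hidden_fn_deriv <- function(config, B) {
  switch(config$hidden_activation, tanh = 1 - B^2, sigmoid = B * (1 - B))
}

#' Initialize model parameters
#'
#' Input weights uniform in `+/- 1/sqrt(k)`, output weights in
#' `+/- 1/sqrt(p)`, biases zero; deterministic given `config$seed`. Ablation
#' modes omit the unused blocks entirely.
#'
#' @param config a `metamlann_config`.
#' @return a `metamlann_params` list: `W1`/`b1` (lists over blocks; the
#'   shared block, when present, is the last element), `W2_ind` (m x p),
#'   `W2_shared` (p or m x p), `b2` (scalar or length m).
#' @export
init_parameters <- function(config) {
  set.seed(config$seed)
  k <- config$k; m <- config$m; p <- config$p
  blocks <- character(0)
  if (has_individual(config)) blocks <- paste0("B", seq_len(m))
  if (has_shared(config)) blocks <- c(blocks, "Bshare")
  lim1 <- 1 / sqrt(k); lim2 <- 1 / sqrt(p)
  W1 <- lapply(blocks, function(.) matrix(runif(p * k, -lim1, lim1), p, k))
  b1 <- lapply(blocks, function(.) numeric(p))
  names(W1) <- names(b1) <- blocks
  W2_ind <- if (has_individual(config))
    matrix(runif(m * p, -lim2, lim2), m, p) else NULL
  if (has_shared(config)) {
    W2_shared <- if (config$shared_output_weights == "single")
      runif(p, -lim2, lim2) else matrix(runif(m * p, -lim2, lim2), m, p)
  } else W2_shared <- NULL
  b2 <- if (has_shared(config) && config$shared_output_weights == "single")
    0 else numeric(m)
  if (config$mode == "both" || config$mode == "individual-only") {
    # per-label bias unless the literal single-output-weight form is used
    if (!(has_shared(config) && config$shared_output_weights == "single"))
      b2 <- numeric(m)
  }
  structure(list(W1 = W1, b1 = b1, W2_ind = W2_ind,
                 W2_shared = W2_shared, b2 = b2, config = config),
            class = "metamlann_params")
}

#' Forward pass
#'
#' Computes the n x m matrix of output activations (presence scores in
#' (0, 1)) for a feature matrix.
#'
#' @param params a `metamlann_params`.
#' @param X numeric matrix n x k (or a length-k vector).
#' @param return_hidden also return the hidden block activations.
#' @return n x m score matrix, or a list `(scores, hidden)` when
#'   `return_hidden = TRUE`.
#' @export
model_forward <- function(params, X, return_hidden = FALSE) {
  config <- params$config
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == config$k)
  n <- nrow(X); m <- config$m
  fB <- hidden_fn(config)
  hidden <- lapply(params$W1, function(W) NULL)
  Z2 <- matrix(0, n, m)
  if (has_shared(config)) {
    Bsh <- fB(sweep(X %*% t(params$W1[["Bshare"]]), 2, params$b1[["Bshare"]], "+"))
    hidden[["Bshare"]] <- Bsh
    if (config$shared_output_weights == "single") {
      Z2 <- Z2 + drop(Bsh %*% params$W2_shared)           # same term every label
    } else {
      Z2 <- Z2 + Bsh %*% t(params$W2_shared)
    }
  }
  if (has_individual(config)) {
    for (i in seq_len(m)) {
      bl <- paste0("B", i)
      Bi <- fB(sweep(X %*% t(params$W1[[bl]]), 2, params$b1[[bl]], "+"))
      hidden[[bl]] <- Bi
      Z2[, i] <- Z2[, i] + drop(Bi %*% params$W2_ind[i, ])
    }
  }
  Z2 <- sweep(Z2, 2, rep_len(params$b2, m), "+")
  if (any(!is.finite(Z2))) stop("non-finite activation in output layer")
  scores <- sigmoid(Z2)
  if (return_hidden) list(scores = scores, hidden = hidden) else scores
}

#' Cross-entropy loss
#'
#' `J = -sum_j [ y_j log o_j + (1 - y_j) log(1 - o_j) ]` summed over labels
#' and averaged over samples. Scores at exactly 0 or 1 are clipped at 1e-12
#' with a warning.
#'
#' @param scores n x m matrix in (0, 1).
#' @param Y n x m binary matrix.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(scores, Y) {
  stopifnot(all(dim(scores) == dim(Y)))
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores at 0/1 clipped to (1e-12, 1 - 1e-12) inside log")
    scores <- clip01(scores)
  }
  -sum(Y * log(scores) + (1 - Y) * log(1 - scores)) / nrow(Y)
}

#' Regularized loss
#'
#' Cross-entropy plus `lambda` times the mean (over samples) Laplacian
#' quadratic form of each sample's predicted score vector: phylogenetically
#' similar genera are pulled toward similar scores.
#'
#' @param scores n x m score matrix.
#' @param Y n x m binary labels.
#' @param lap a `laplacian` (or m x m matrix).
#' @param lambda regularization weight, `>= 0`.
#' @return scalar loss.
#' @export
regularized_loss <- function(scores, Y, lap, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  L <- if (inherits(lap, "laplacian")) lap$L else lap
  stopifnot(ncol(scores) == nrow(L))
  ce <- cross_entropy_loss(scores, Y)
  if (lambda == 0) return(ce)
  omega <- sum((scores %*% L) * scores) / nrow(scores)
  ce + lambda * omega
}

# Full-batch analytic gradient of the regularized loss w.r.t. every
# parameter; the finite-difference test in the suite is its contract.
model_gradients <- function(params, X, Y, L = NULL, lambda = 0) {
  config <- params$config
  n <- nrow(X); m <- config$m
  fwd <- model_forward(params, X, return_hidden = TRUE)
  o <- clip01(fwd$scores)
  dZ2 <- (o - Y) / n
  if (lambda > 0) {
    Lm <- if (inherits(L, "laplacian")) L$L else L
    dZ2 <- dZ2 + (lambda * 2 / n) * (o %*% Lm) * o * (1 - o)
  }
  g <- list(W1 = list(), b1 = list(), W2_ind = NULL, W2_shared = NULL, b2 = NULL)
  if (has_individual(config)) {
    g$W2_ind <- matrix(0, m, config$p)
    for (i in seq_len(m)) {
      bl <- paste0("B", i)
      Bi <- fwd$hidden[[bl]]
      g$W2_ind[i, ] <- drop(crossprod(Bi, dZ2[, i]))
      dZ1 <- (dZ2[, i] %o% params$W2_ind[i, ]) * hidden_fn_deriv(config, Bi)
      g$W1[[bl]] <- crossprod(dZ1, X)
      g$b1[[bl]] <- colSums(dZ1)
    }
  }
  if (has_shared(config)) {
    Bsh <- fwd$hidden[["Bshare"]]
    if (config$shared_output_weights == "single") {
      rs <- rowSums(dZ2)
      g$W2_shared <- drop(crossprod(Bsh, rs))
      dZ1 <- (rs %o% params$W2_shared) * hidden_fn_deriv(config, Bsh)
    } else {
      g$W2_shared <- crossprod(dZ2, Bsh)
      dZ1 <- (dZ2 %*% params$W2_shared) * hidden_fn_deriv(config, Bsh)
    }
    g$W1[["Bshare"]] <- crossprod(dZ1, X)
    g$b1[["Bshare"]] <- colSums(dZ1)
  }
  g$b2 <- if (length(params$b2) == 1) sum(dZ2) else colSums(dZ2)
  g
}

# Flatten parameters (or a same-shaped gradient list) to one numeric vector;
# used by the finite-difference check and the checkpoint writer.
flatten_params <- function(params) {
  unlist(list(W1 = lapply(params$W1, as.vector),
              b1 = params$b1,
              W2_ind = params$W2_ind,
              W2_shared = params$W2_shared,
              b2 = params$b2), use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 1L
  take <- function(nval) {
    v <- theta[pos:(pos + nval - 1L)]; pos <<- pos + nval; v
  }
  for (bl in names(template$W1)) {
    out$W1[[bl]] <- matrix(take(length(template$W1[[bl]])),
                           nrow(template$W1[[bl]]), ncol(template$W1[[bl]]))
    }
  for (bl in names(template$b1)) out$b1[[bl]] <- take(length(template$b1[[bl]]))
  if (!is.null(template$W2_ind))
    out$W2_ind <- matrix(take(length(template$W2_ind)),
                         nrow(template$W2_ind), ncol(template$W2_ind))
  if (!is.null(template$W2_shared)) {
    if (is.matrix(template$W2_shared))
      out$W2_shared <- matrix(take(length(template$W2_shared)),
                              nrow(template$W2_shared), ncol(template$W2_shared))
    else out$W2_shared <- take(length(template$W2_shared))
  }
  out$b2 <- take(length(template$b2))
  out
}
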