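test_that("initialization is seeded and counts parameters by shape arithmetic", {
  cfg <- metamlann_config(k = 4, m = 3, p = 2, seed = 7)
  p1 <- init_parameters(cfg)
  p2 <- init_parameters(cfg)
  expect_identical(p1$W1, p2$W1)
  expect_identical(p1$W2_ind, p2$W2_ind)
  # (m+1) input blocks of p x k, (m+1) biases of p, m + 1 output weight
  # rows of p, plus the scalar shared output bias: 4*8 + 4*2 + 3*2 + 2 + 1
  expect_length(metamlann:::flatten_params(p1), 49)
  # ablations drop the unused blocks entirely
  ps <- init_parameters(metamlann_config(k = 4, m = 3, p = 2,
                                         mode = "shared-only"))
  expect_null(ps$W2_ind)
  expect_named(ps$W1, "Bshare")
  pi_ <- init_parameters(metamlann_config(k = 4, m = 3, p = 2,
                                          mode = "individual-only"))
  expect_null(pi_$W2_shared)
  expect_false("Bshare" %in% names(pi_$W1))
})

test_that("forward pass: sigmoid outputs, zero-parameter 0.5, single-label form", {
  cfg <- metamlann_config(k = 3, m = 2, p = 4, seed = 1)
  params <- init_parameters(cfg)
  zero <- metamlann:::unflatten_params(
    numeric(length(metamlann:::flatten_params(params))), params)
  o <- model_forward(zero, matrix(rnorm(6), 2, 3))
  expect_equal(unname(o), matrix(0.5, 2, 2))
  # scores always strictly inside (0, 1)
  set.seed(2)
  o2 <- model_forward(params, matrix(rnorm(30), 10, 3))
  expect_true(all(o2 > 0 & o2 < 1))
  # m = 1 with the shared path zeroed reduces to the plain one-hidden-layer
  # network sigmoid(W2 tanh(W1 x + b1) + b2)
  cfg1 <- metamlann_config(k = 3, m = 1, p = 4, seed = 3)
  pp <- init_parameters(cfg1)
  pp$W2_shared[] <- 0
  x <- rnorm(3)
  direct <- 1 / (1 + exp(-(drop(pp$W2_ind %*% tanh(pp$W1$B1 %*% x + pp$b1$B1))
                           + pp$b2)))
  expect_equal(drop(model_forward(pp, x)), direct, tolerance = 1e-12)
})

test_that("cross-entropy matches hand values and brute-force summation", {
  expect_equal(cross_entropy_loss(matrix(0.5, 1, 2), matrix(c(1, 0), 1)),
               2 * log(2), tolerance = 1e-12)
  # perfect-fit limit
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  o_near <- abs(Y - 1e-9)
  expect_lt(cross_entropy_loss(o_near, Y), 1e-8)
  # brute force elementwise on a random 5 x 4 case
  set.seed(17)
  o <- matrix(runif(20, 0.05, 0.95), 5, 4)
  Yr <- matrix(rbinom(20, 1, 0.5), 5, 4)
  acc <- 0
  for (i in 1:5) for (j in 1:4)
    acc <- acc - (Yr[i, j] * log(o[i, j]) + (1 - Yr[i, j]) * log(1 - o[i, j]))
  expect_equal(cross_entropy_loss(o, Yr), acc / 5, tolerance = 1e-12)
})

test_that("regularized loss composes cross-entropy with the Laplacian penalty", {
  set.seed(23)
  o <- matrix(runif(12, 0.1, 0.9), 3, 4)
  Y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  P <- random_similarity(4)
  lap <- build_laplacian(P)
  expect_equal(regularized_loss(o, Y, lap, 0), cross_entropy_loss(o, Y))
  # constant score rows: the penalty vanishes
  oc <- matrix(0.4, 3, 4)
  expect_equal(regularized_loss(oc, Y, lap, 5), cross_entropy_loss(oc, Y),
               tolerance = 1e-12)
  omega <- mean(apply(o, 1, function(r) laplacian_quadratic_form(lap, r)))
  expect_equal(regularized_loss(o, Y, lap, 0.7),
               cross_entropy_loss(o, Y) + 0.7 * omega, tolerance = 1e-12)
  expect_error(regularized_loss(o, Y, lap, -1), "lambda")
})

test_that("analytic gradients agree with central finite differences", {
  # one spot-check per hidden activation; the acceptance suite sweeps
  # lambda and all three modes
  for (act in c("tanh", "sigmoid")) {
    cfg <- metamlann_config(k = 3, m = 3, p = 2, seed = 42, lambda = 0.1,
                            hidden_activation = act)
    params <- init_parameters(cfg)
    set.seed(9)
    X <- matrix(rnorm(15), 5, 3); Y <- matrix(rbinom(15, 1, 0.5), 5, 3)
    lap <- build_laplacian(random_similarity(3))
    g <- metamlann:::flatten_params(
      metamlann:::model_gradients(params, X, Y, lap, 0.1))
    th <- metamlann:::flatten_params(params); h <- 1e-6
    num <- vapply(seq_along(th), function(i) {
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      (regularized_loss(model_forward(
         metamlann:::unflatten_params(tp, params), X), Y, lap, 0.1) -
       regularized_loss(model_forward(
         metamlann:::unflatten_params(tm, params), X), Y, lap, 0.1)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - num) / pmax(1e-8, abs(g) + abs(num))), 1e-5)
  }
})

test_that("training reduces loss on separable data; zero epochs is the identity", {
  set.seed(60)
  n <- 60; k <- 5; m <- 4
  W <- matrix(rnorm(k * m, sd = 2), k, m)
  X <- matrix(rnorm(n * k), n, k)
  Y <- (X %*% W > 0) * 1L
  cfg <- metamlann_config(k = k, m = m, p = 8, seed = 2, epochs = 50)
  fit <- metamlann_train(X, Y, cfg)
  expect_lt(fit$trace$total[nrow(fit$trace)], fit$trace$total[1])
  sm <- stats::filter(fit$trace$total, rep(1 / 5, 5), sides = 1)
  expect_true(all(diff(sm[!is.na(sm)]) <= 1e-8))
  # zero epochs returns the seeded initialization unchanged
  cfg0 <- metamlann_config(k = k, m = m, p = 8, seed = 2, epochs = 0)
  fit0 <- metamlann_train(X, Y, cfg0)
  expect_identical(metamlann:::flatten_params(fit0$params),
                   metamlann:::flatten_params(init_parameters(cfg0)))
  # the per-block sampling scheme also learns
  cfgs <- metamlann_config(k = k, m = m, p = 8, seed = 2, epochs = 50,
                           training_scheme = "block-sampling")
  fits <- metamlann_train(X, Y, cfgs)
  expect_lt(fits$trace$total[nrow(fits$trace)], fits$trace$total[1])
})

test_that("zeroing the shared path reproduces individual-only output bitwise", {
  cfg_both <- metamlann_config(k = 4, m = 3, p = 2, seed = 5, mode = "both")
  pb <- init_parameters(cfg_both)
  pb$W2_shared[] <- 0
  cfg_ind <- metamlann_config(k = 4, m = 3, p = 2, seed = 5,
                              mode = "individual-only")
  pi_ <- init_parameters(cfg_ind)
  for (bl in paste0("B", 1:3)) {
    pi_$W1[[bl]] <- pb$W1[[bl]]; pi_$b1[[bl]] <- pb$b1[[bl]]
  }
  pi_$W2_ind <- pb$W2_ind
  pi_$b2 <- rep(pb$b2, 3)
  set.seed(6)
  X <- matrix(rnorm(20), 5, 4)
  expect_identical(model_forward(pb, X), model_forward(pi_, X))
  # and symmetrically: zeroed individual paths reproduce shared-only
  pb2 <- init_parameters(cfg_both)
  pb2$W2_ind[] <- 0
  cfg_sh <- metamlann_config(k = 4, m = 3, p = 2, seed = 5,
                             mode = "shared-only")
  ps <- init_parameters(cfg_sh)
  ps$W1$Bshare <- pb2$W1$Bshare; ps$b1$Bshare <- pb2$b1$Bshare
  ps$W2_shared <- pb2$W2_shared; ps$b2 <- pb2$b2
  expect_identical(model_forward(pb2, X), model_forward(ps, X))
})

test_that("label permutation permutes scores when parameters and L follow", {
  cfg <- metamlann_config(k = 4, m = 4, p = 3, seed = 8)
  params <- init_parameters(cfg)
  set.seed(9)
  X <- matrix(rnorm(12), 3, 4)
  o <- model_forward(params, X)
  perm <- c(3, 1, 4, 2)
  pp <- params
  pp$W1[paste0("B", 1:4)] <- params$W1[paste0("B", perm)]
  names(pp$W1) <- names(params$W1)
  pp$b1[paste0("B", 1:4)] <- params$b1[paste0("B", perm)]
  names(pp$b1) <- names(params$b1)
  pp$W2_ind <- params$W2_ind[perm, ]
  op <- model_forward(pp, X)
  expect_equal(op, o[, perm], tolerance = 1e-15)
})

test_that("prediction thresholds behave at the boundaries", {
  cfg <- metamlann_config(k = 2, m = 2, p = 2, seed = 1, epochs = 0)
  fit <- metamlann_train(matrix(rnorm(8), 4, 2),
                         matrix(rbinom(8, 1, 0.5), 4, 2), cfg)
  X <- matrix(rnorm(6), 3, 2)
  expect_true(all(predict(fit, X, threshold = 0)$predictions == 1))
  expect_true(all(predict(fit, X, threshold = 1)$predictions == 0))
  # zero parameters score exactly 0.5, and 0.5 >= 0.5 counts as present
  fit$params <- metamlann:::unflatten_params(
    numeric(length(metamlann:::flatten_params(fit$params))), fit$params)
  expect_true(all(predict(fit, X, threshold = 0.5)$predictions == 1))
})

test_that("checkpoints round-trip config, weights and predictions", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4); Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  cfg <- metamlann_config(k = 4, m = 3, p = 2, seed = 3, epochs = 5)
  fit <- metamlann_train(X, Y, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  tr <- withr::local_tempfile(fileext = ".csv")
  save_checkpoint(fit, f, trace_path = tr)
  back <- load_checkpoint(f)
  expect_equal(back$config$p, 2L)
  expect_equal(unname(predict(back, X)$scores),
               unname(predict(fit, X)$scores), tolerance = 1e-12)
  expect_equal(nrow(read.csv(tr)), 6)   # epoch 0 + 5 epochs
})

test_that("training recovers labels generated by a planted network", {
  gaps <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 500; k <- 10; m <- 6
    cfg_true <- metamlann_config(k = k, m = m, p = 4, seed = s + 100)
    theta <- init_parameters(cfg_true)
    # spread the planted weights so labels are not near-constant
    theta <- metamlann:::unflatten_params(
      5 * metamlann:::flatten_params(theta), theta)
    X <- matrix(rnorm(n * k), n, k)
    Y <- (model_forward(theta, X) >= 0.5) * 1L
    test <- sample.int(n, 150); train <- setdiff(seq_len(n), test)
    cfg <- metamlann_config(k = k, m = m, p = 16, seed = s, epochs = 100)
    f1 <- function(Ytr) {
      fit <- metamlann_train(X[train, ], Ytr, cfg)
      suppressWarnings(micro_prf(Y[test, ],
                                 predict(fit, X[test, ])$predictions)[["f1"]])
    }
    real <- f1(Y[train, ])
    shuf <- f1(Y[train, ][sample(length(train)), ])
    real - shuf
  }, numeric(1))
  expect_gte(mean(gaps), 0.2)
})

test_that("training validates shapes and the Laplacian requirement", {
  X <- matrix(rnorm(8), 4, 2); Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  cfg <- metamlann_config(k = 2, m = 3, lambda = 0.5, epochs = 1)
  expect_error(metamlann_train(X, Y, cfg), "Laplacian")
  cfg2 <- metamlann_config(k = 5, m = 3, epochs = 1)
  expect_error(metamlann_train(X, Y, cfg2), "k does not match")
  cfg3 <- metamlann_config(k = 2, m = 9, epochs = 1)
  expect_error(metamlann_train(X, Y, cfg3), "m does not match")
  expect_error(metamlann_train(X[1, , drop = FALSE], Y[1, , drop = FALSE],
                               metamlann_config(k = 2, m = 3, epochs = 1)),
               "2 training samples")
})
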