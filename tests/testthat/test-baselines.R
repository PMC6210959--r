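test_that("linear regression baseline is exact OLS", {
  set.seed(1)
  X <- matrix(runif(60), 20, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + 3
  m <- fit_linear_regression(make_set(X, y))
  expect_lt(rmse(y, predict(m, X)), 1e-8)
  expect_equal(m$intercept, 3, tolerance = 1e-8)
  # 5-point case against an independent normal-equations oracle
  X5 <- matrix(c(1, 2, 3, 4, 5, 2, 1, 4, 3, 5), 5, 2)
  y5 <- c(3, 4, 8, 9, 13)
  m5 <- fit_linear_regression(make_set(X5, y5))
  A <- cbind(1, X5)
  oracle <- solve(t(A) %*% A, t(A) %*% y5)
  expect_equal(c(m5$intercept, m5$coefficients), drop(oracle),
               tolerance = 1e-8)
  # residual orthogonality
  res <- y5 - predict(m5, X5)
  expect_lt(max(abs(t(A) %*% res)), 1e-8)
})

test_that("constant-column design is handled with a warning", {
  y <- c(2, 4, 6, 8)
  X <- matrix(1, 4, 1)
  expect_warning(m <- fit_linear_regression(make_set(X, y)), "rank-deficient")
  expect_equal(m$coefficients, 0)
  expect_equal(m$intercept, mean(y))
  expect_equal(unname(predict(m, X)), rep(mean(y), 4), tolerance = 1e-10)
})

test_that("NN-BP respects epochs, seed and learning-rate contracts", {
  set.seed(2)
  tr <- make_set(matrix(runif(60), 20, 3), rnorm(20, 5))
  # zero epochs: untouched initialization, empty curve
  m0 <- train_nn_bp(tr, hidden_nodes = 4, epochs = 0, seed = 7)
  expect_length(m0$loss_curve, 0)
  # zero learning rate: parameters identical to initialization
  mlr0 <- train_nn_bp(tr, hidden_nodes = 4, learning_rate = 0,
                      epochs = 50, seed = 7)
  expect_equal(mlr0$W1, m0$W1)
  expect_equal(mlr0$W2, m0$W2)
  expect_equal(mlr0$b1, m0$b1)
  expect_equal(mlr0$b2, m0$b2)
  # determinism
  ma <- train_nn_bp(tr, 4, epochs = 30, seed = 3)
  mb <- train_nn_bp(tr, 4, epochs = 30, seed = 3)
  expect_identical(ma$W1, mb$W1)
  expect_identical(predict(ma, tr$X), predict(mb, tr$X))
  expect_length(ma$loss_curve, 30)
  expect_error(train_nn_bp(tr, 0), "hidden_nodes")
})

test_that("NN-BP descends to a near-linear fit on a noise-free target", {
  set.seed(4)
  X <- matrix(runif(150), 50, 3)
  y <- drop(X %*% c(2, -1, 3)) + 5
  m <- train_nn_bp(make_set(X, y), hidden_nodes = 8, learning_rate = 0.001,
                   epochs = 2000, seed = 1)
  expect_lt(m$loss_curve[2000], 0.1 * sd(y))
  # divergence is caught with a diagnostic
  expect_error(train_nn_bp(make_set(X, y), 8, learning_rate = 100,
                           epochs = 200, seed = 1), "diverged")
})

test_that("NN-BP prediction matches a hand-evaluated composition", {
  tr <- make_set(matrix(runif(20), 10, 2), rnorm(10))
  m <- train_nn_bp(tr, hidden_nodes = 1, epochs = 0, seed = 5)
  x <- c(0.3, 0.8)
  xs <- (x - m$x_scaler$center) / m$x_scaler$scale
  hidden <- 1 / (1 + exp(-(sum(m$W1[1, ] * xs) + m$b1[1])))
  hand <- (m$W2[1] * hidden + m$b2) * m$y_scaler$scale + m$y_scaler$center
  expect_equal(unname(predict(m, matrix(x, 1, 2))), hand, tolerance = 1e-12)
})

test_that("fuzzy c-means clusters separated clouds with normalized rows", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2),
             matrix(rnorm(40, mean = 5, sd = 0.3), 20, 2))
  cl <- fcm_cluster(X, r = 2, seed = 1)
  expect_equal(rowSums(cl$memberships), rep(1, 40), tolerance = 1e-12)
  centers <- cl$centers[order(cl$centers[, 1]), ]
  expect_true(all(abs(centers[1, ]) < 1))
  expect_true(all(abs(centers[2, ] - 5) < 1))
  # objective non-increasing along the trace
  expect_true(all(diff(cl$objective_trace) <= 1e-10))
  expect_error(fcm_cluster(matrix(1, 10, 2), r = 2), "degenerate")
  expect_error(fcm_cluster(X, r = 1), "r must be >= 2")
})

test_that("fcm objective matches brute force and is locally optimal", {
  x <- matrix(c(0, 0.1, 0.2, 5, 5.1, 5.2), 6, 1)
  cl <- fcm_cluster(x, r = 2, seed = 2)
  # independent evaluation of J = sum u^m d^2 at the returned solution
  J <- function(centers, U) {
    D2 <- outer(drop(x), drop(centers), function(a, b) (a - b)^2)
    sum(U^2 * D2)
  }
  expect_equal(cl$objective, J(cl$centers, cl$memberships), tolerance = 1e-8)
  # no single-center perturbation (with memberships re-optimized) improves it
  best <- cl$objective
  refit_J <- function(centers) {
    D2 <- outer(drop(x), drop(centers), function(a, b) pmax((a - b)^2, 1e-12))
    P <- D2^(-1); U <- P / rowSums(P)
    sum(U^2 * D2)
  }
  for (j in 1:2) for (eps in c(-0.25, 0.25)) {
    cpert <- cl$centers; cpert[j, 1] <- cpert[j, 1] + eps
    expect_gte(refit_J(cpert), best - 1e-9)
  }
})

test_that("fcm agrees with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  X <- rbind(matrix(rnorm(30, 0, 0.5), 15, 2),
             matrix(rnorm(30, 4, 0.5), 15, 2))
  ours <- fcm_cluster(X, r = 2, seed = 3)
  set.seed(3)
  ref <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 200)
  # same optimum: objectives agree (e1071 reports the per-point mean)
  expect_equal(ours$objective, ref$withinerror * nrow(X), tolerance = 1e-3)
  oc <- ours$centers[order(ours$centers[, 1]), ]
  rc <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(oc), unname(rc), tolerance = 1e-3)
})

test_that("single-rule ANFIS collapses to multiple linear regression", {
  set.seed(9)
  tr <- make_set(matrix(runif(80), 40, 2), rnorm(40, 8, 2))
  a1 <- build_anfis_fcm(tr, r = 1)
  lr <- fit_linear_regression(tr)
  Xnew <- matrix(runif(20), 10, 2)
  expect_equal(predict(a1, Xnew), unname(predict(lr, Xnew)),
               tolerance = 1e-8)
})

test_that("anfis rule strengths normalize and the guard blocks overfitting", {
  set.seed(10)
  tr <- make_set(matrix(runif(120), 40, 3), rnorm(40))
  a <- build_anfis_fcm(tr, r = 2, seed = 1)
  Xs <- elmbloom:::apply_scaler(a$x_scaler, tr$X)
  W <- elmbloom:::anfis_strengths(a, Xs)
  expect_equal(rowSums(W), rep(1, 40), tolerance = 1e-12)
  expect_true(all(a$spreads > 0))
  # the parameter-count guard: r (d + 1) >= N must refuse
  small <- make_set(matrix(runif(60), 20, 3), rnorm(20))
  expect_error(build_anfis_fcm(small, r = 5), "overfitting guard")  # 20 >= 20
  expect_silent(build_anfis_fcm(small, r = 4, seed = 1))            # 16 < 20
  # consequent LSE optimality: residuals orthogonal to the design
  Phi <- elmbloom:::anfis_design(a, Xs)
  res <- tr$T - predict(a, tr$X)
  expect_lt(max(abs(t(Phi) %*% res)), 1e-6 * sqrt(sum(tr$T^2)))
})

test_that("two-rule ANFIS beats plain LR on a piecewise-linear target", {
  set.seed(11)
  x <- matrix(sort(runif(30, -2, 2)), 30, 1)
  y <- ifelse(x < 0, 2 * x + 1, -x + 1) + rnorm(30, sd = 0.05)
  tr <- make_set(x, y)
  a <- build_anfis_fcm(tr, r = 2, seed = 2)
  lr <- fit_linear_regression(tr)
  expect_lt(rmse(y, predict(a, x)), rmse(y, predict(lr, x)))
})

test_that("hybrid learning keeps contracts: zero epochs, monotone train", {
  set.seed(12)
  pair <- cached_pair(4, n_weeks = 60)
  sp <- split_half(assemble_features(pair$down, "ELM1"))
  a <- build_anfis_fcm(sp$train, r = 2, seed = 1)
  h0 <- train_anfis_hybrid(a, sp$train, sp$test, epochs = 0)
  expect_length(h0$train_curve, 0)
  expect_equal(h0$model$centers, a$centers)
  # noise-free smooth target: the training curve must not increase
  x <- matrix(seq(-2, 2, length.out = 40), 40, 1)
  yc <- tanh(2 * x[, 1])
  trc <- make_set(x, yc)
  ac <- build_anfis_fcm(trc, r = 2, seed = 3)
  hc <- train_anfis_hybrid(ac, trc, trc, epochs = 40)
  expect_true(all(diff(hc$train_curve) <= 1e-6))
})

test_that("anfis antecedent gradients match numerical differentiation", {
  set.seed(13)
  tr <- make_set(matrix(runif(40), 20, 2), rnorm(20))
  a <- build_anfis_fcm(tr, r = 2, seed = 4)
  Xs <- elmbloom:::apply_scaler(a$x_scaler, tr$X)
  sse <- function(centers, spreads) {
    m <- a; m$centers <- centers; m$spreads <- spreads
    Wraw <- elmbloom:::anfis_raw_strengths(m, Xs)
    G <- cbind(1, Xs) %*% t(m$consequents)
    sum((rowSums((Wraw / rowSums(Wraw)) * G) - tr$T)^2)
  }
  # analytic gradient (as used in the backward pass)
  Wraw <- elmbloom:::anfis_raw_strengths(a, Xs)
  S <- rowSums(Wraw)
  G <- cbind(1, Xs) %*% t(a$consequents)
  yhat <- rowSums((Wraw / S) * G)
  err <- yhat - tr$T
  dEdw <- (2 * err / S) * (G - yhat)
  for (j in 1:2) for (k in 1:2) {
    Z <- Xs[, k] - a$centers[j, k]
    gC <- sum(dEdw[, j] * Wraw[, j] * Z / a$spreads[j, k]^2)
    gS <- sum(dEdw[, j] * Wraw[, j] * Z^2 / a$spreads[j, k]^3)
    eps <- 1e-6
    cp <- a$centers; cp[j, k] <- cp[j, k] + eps
    cm <- a$centers; cm[j, k] <- cm[j, k] - eps
    expect_equal(gC, (sse(cp, a$spreads) - sse(cm, a$spreads)) / (2 * eps),
                 tolerance = 1e-4)
    sp_ <- a$spreads; sp_[j, k] <- sp_[j, k] + eps
    sm_ <- a$spreads; sm_[j, k] <- sm_[j, k] - eps
    expect_equal(gS, (sse(a$centers, sp_) - sse(a$centers, sm_)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("predict_baseline dispatches across model classes", {
  set.seed(14)
  tr <- make_set(matrix(runif(60), 30, 2), rnorm(30, 4))
  X <- tr$X[1:5, ]
  lr <- fit_linear_regression(tr)
  expect_equal(predict_baseline(lr, X), predict(lr, X))
  # zero-coefficient linear model predicts its intercept everywhere
  lr0 <- structure(list(coefficients = c(0, 0), intercept = 2.5,
                        feature_names = c("x1", "x2")),
                   class = "linear_baseline")
  expect_equal(unname(predict_baseline(lr0, X)), rep(2.5, 5))
  nn <- train_nn_bp(tr, 3, epochs = 5, seed = 1)
  expect_equal(predict_baseline(nn, X), predict(nn, X))
  an <- build_anfis_fcm(tr, r = 2, seed = 1)
  expect_equal(predict_baseline(an, X), predict(an, X))
})
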