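test_that("scalar activations match their defining formulas", {
  # symmetry / zero-radius / zero-phase points
  expect_equal(activation("sigmoid", w = c(1, -1), b = 0, x = c(0.5, 0.5)), 0.5)
  expect_equal(activation("rbf", w = c(1, 2), b = 0.7, x = c(1, 2)), 1.0)
  expect_equal(activation("sine", w = c(2, 1), b = -3, x = c(1, 1)), 0.0)
  # generic points against direct evaluation
  w <- c(0.3, -0.8); x <- c(1.2, 0.4); b <- 0.25
  expect_equal(activation("sigmoid", w, b, x), 1 / (1 + exp(-(sum(w * x) + b))))
  expect_equal(activation("rbf", w, 0.5, x), exp(-(0.5 * sqrt(sum((x - w)^2)))^2))
  expect_equal(activation("sine", w, b, x), sin(sum(w * x) + b))
  expect_error(activation("cubic", w, b, x))
  expect_error(activation("sigmoid", w, Inf, x), "non-finite")
})

test_that("init_hidden is reproducible, correctly shaped, and nested in L", {
  h1 <- init_hidden(3, 2, seed = 9)
  h2 <- init_hidden(3, 2, seed = 9)
  expect_identical(h1, h2)
  expect_equal(dim(h1$W), c(3L, 2L))
  expect_length(h1$b, 3)
  # rbf inverse widths strictly positive
  hr <- init_hidden(50, 4, activation = "rbf", seed = 1)
  expect_gt(min(hr$b), 0)
  # layers with the same seed are nested: enlarging L keeps earlier nodes
  h5 <- init_hidden(5, 3, seed = 7)
  h9 <- init_hidden(9, 3, seed = 7)
  expect_identical(h5$W, h9$W[1:5, , drop = FALSE])
  expect_identical(h5$b, h9$b[1:5])
  expect_error(init_hidden(0, 2), "L must be")
  expect_error(init_hidden(3, 0), "d must be")
})

test_that("hidden_matrix agrees with entrywise scalar activation calls", {
  X <- matrix(c(0.2, -1, 1.5, 0.7), 2, 2)
  for (kind in c("sigmoid", "rbf", "sine")) {
    h <- init_hidden(3, 2, activation = kind, seed = 4)
    H <- hidden_matrix(h, X)
    expect_equal(dim(H), c(2L, 3L))
    # independent loop oracle
    H_loop <- matrix(0, 2, 3)
    for (i in 1:2) for (j in 1:3)
      H_loop[i, j] <- activation(kind, h$W[j, ], h$b[j], X[i, ])
    expect_equal(H, H_loop, tolerance = 1e-12)
  }
  # degenerate all-zero sigmoid layer gives a constant half matrix
  h0 <- init_hidden(4, 2, seed = 1)
  h0$W[] <- 0; h0$b[] <- 0
  expect_equal(hidden_matrix(h0, X), matrix(0.5, 2, 4))
  expect_equal(dim(hidden_matrix(init_hidden(6, 2, seed = 2),
                                 X[1, , drop = FALSE])), c(1L, 6L))
  expect_error(hidden_matrix(init_hidden(3, 4, seed = 1), X), "feature columns")
})

test_that("fit_output_weights is the minimum-norm least-squares solution", {
  # orthonormal columns: pseudoinverse is the transpose
  Q <- qr.Q(qr(matrix(rnorm(20), 5, 4)))
  Tv <- c(1, -2, 0.5, 3, -1)
  expect_equal(fit_output_weights(Q, Tv), drop(t(Q) %*% Tv), tolerance = 1e-10)
  # square nonsingular: exact interpolation
  set.seed(11)
  H <- matrix(rnorm(16), 4, 4); y <- rnorm(4)
  b <- fit_output_weights(H, y)
  expect_lt(sqrt(sum((H %*% b - y)^2)), 1e-8 * sqrt(sum(y^2)))
  # overdetermined: matches an independent normal-equations oracle
  set.seed(12)
  H <- matrix(rnorm(48), 12, 4); y <- rnorm(12)
  oracle <- solve(t(H) %*% H, t(H) %*% y)
  expect_equal(fit_output_weights(H, y), drop(oracle), tolerance = 1e-8)
  # rank-deficient: residual still orthogonal, and norm is minimal among
  # solutions differing along the null space
  H2 <- cbind(H, H[, 1] + H[, 2])
  b2 <- fit_output_weights(H2, y)
  expect_lt(max(abs(t(H2) %*% (H2 %*% b2 - y))), 1e-8)
  null_dir <- c(1, 1, 0, 0, -1)                 # H2 %*% null_dir = 0
  for (eps in c(-0.1, 0.1))
    expect_gt(sum((b2 + eps * null_dir)^2), sum(b2^2))
  expect_error(fit_output_weights(matrix(c(1, NA), 1, 2), 1), "non-finite")
})

test_that("elm training interpolates when L = N and is seed-deterministic", {
  set.seed(3)
  X <- matrix(runif(30), 10, 3); y <- rnorm(10)
  f <- elm(X, y, L = 10, seed = 5)
  expect_lt(rmse(y, fitted(f)), 1e-6)
  f2 <- elm(X, y, L = 10, seed = 5)
  expect_identical(coef(f), coef(f2))
  expect_identical(predict(f, X), predict(f2, X))
})

test_that("elm recovers the generating output weights of a known network", {
  gen <- init_hidden(5, 3, seed = 11)
  beta0 <- c(2, -1, 0.5, 1.5, -0.7)
  set.seed(21)
  X <- matrix(runif(300, -1, 1), 100, 3)
  y <- drop(hidden_matrix(gen, X) %*% beta0)
  # same seed => same hidden layer; the LSE must recover beta exactly
  refit <- elm(X, y, L = 5, seed = 11, standardize = FALSE)
  expect_equal(coef(refit), beta0, tolerance = 1e-6)
})

test_that("elm residuals are LSE-optimal (orthogonality and no better beta)", {
  set.seed(31)
  X <- matrix(runif(80), 20, 4); y <- rnorm(20, sd = 2)
  f <- elm(X, y, L = 8, seed = 2)
  H <- hidden_matrix(f$hidden, elmbloom:::apply_scaler(f$scaler, X))
  res <- y - fitted(f)
  expect_lt(max(abs(t(H) %*% res)), 1e-6 * sqrt(sum(y^2)))
  sse0 <- sum(res^2)
  set.seed(32)
  for (k in 1:25) {
    delta <- rnorm(8, sd = 0.1)
    expect_gte(sum((y - H %*% (coef(f) + delta))^2), sse0 - 1e-9)
  }
})

test_that("training error is monotone non-increasing in L for a fixed seed", {
  set.seed(41)
  X <- matrix(rnorm(120), 40, 3)
  y <- sin(X[, 1]) + X[, 2]^2 + rnorm(40, sd = 0.1)
  for (s in 1:20) {
    rms <- vapply(2:12, function(L) rmse(y, fitted(elm(X, y, L = L, seed = s))),
                  numeric(1))
    expect_true(all(diff(rms) <= 1e-9))
  }
})

test_that("degenerate zero layers collapse to the SSE-minimizing constant", {
  set.seed(51)
  X <- matrix(rnorm(30), 10, 3); y <- rnorm(10)
  for (kind in c("sigmoid", "sine")) {
    f <- elm(X, y, L = 3, activation = kind, seed = 1)
    f$hidden$W[] <- 0; f$hidden$b[] <- 0
    H <- hidden_matrix(f$hidden, elmbloom:::apply_scaler(f$scaler, X))
    beta <- fit_output_weights(H, y)
    pred <- drop(H %*% beta)
    if (kind == "sigmoid") {
      expect_equal(pred, rep(mean(y), 10), tolerance = 1e-8)
    } else {
      expect_equal(pred, rep(0, 10)) # sin(0) = 0: zero feature, zero fit
    }
  }
})

test_that("elm predictions follow the explicit output formula", {
  # zero output weights predict zero everywhere
  f <- elm(matrix(runif(20), 10, 2), rnorm(10), L = 4, seed = 1)
  f$beta <- rep(0, 4)
  expect_equal(predict(f, matrix(runif(6), 3, 2)), rep(0, 3))
  # hand-set single saturated sigmoid node approaches its output weight
  h <- init_hidden(1, 1, seed = 1)
  h$W[1, 1] <- 50; h$b[1] <- 0
  m <- structure(list(hidden = h, beta = 2.5,
                      scaler = list(center = 0, scale = 1),
                      d = 1L, feature_names = "x"), class = "elm")
  expect_equal(predict(m, matrix(10, 1, 1)), 2.5, tolerance = 1e-8)
  # 3-point hand case, L = 2: direct evaluation of the sum
  h2 <- init_hidden(2, 2, seed = 1)
  h2$W <- matrix(c(1, 0, -1, 2), 2, 2, byrow = TRUE); h2$b <- c(0.5, -0.5)
  m2 <- structure(list(hidden = h2, beta = c(1.5, -2),
                       scaler = list(center = c(0, 0), scale = c(1, 1)),
                       d = 2L, feature_names = c("a", "b")), class = "elm")
  Xn <- matrix(c(0, 0, 1, 1, -1, 0.5), 3, 2, byrow = TRUE)
  hand <- vapply(1:3, function(i)
    1.5 / (1 + exp(-(sum(c(1, 0) * Xn[i, ]) + 0.5))) -
      2 * (1 / (1 + exp(-(sum(c(-1, 2) * Xn[i, ]) - 0.5)))), numeric(1))
  expect_equal(predict(m2, Xn), hand, tolerance = 1e-12)
})

test_that("formula interface matches the matrix interface", {
  df <- data.frame(y = rnorm(20), a = runif(20), b = runif(20))
  f1 <- elm(y ~ a + b, df, L = 6, seed = 3)
  f2 <- elm(as.matrix(df[, c("a", "b")]), df$y, L = 6, seed = 3)
  expect_equal(unname(fitted(f1)), unname(fitted(f2)))
  expect_equal(unname(predict(f1, df[1:5, ])),
               unname(predict(f2, as.matrix(df[1:5, c("a", "b")]))))
})

test_that("simulate() adds Gaussian noise of the requested scale", {
  set.seed(61)
  X <- matrix(runif(40), 20, 2)
  f <- elm(X, rnorm(20), L = 5, seed = 1)
  # zero noise reproduces predictions exactly, reproducibly
  expect_equal(sample_from_elm(f, X, noise_sd = 0), unname(predict(f, X)))
  s1 <- sample_from_elm(f, X, noise_sd = 1, seed = 8)
  s2 <- sample_from_elm(f, X, noise_sd = 1, seed = 8)
  expect_identical(s1, s2)
  # CLT check on the noise scale
  Xbig <- matrix(runif(2e4), 1e4, 2)
  sb <- sample_from_elm(f, Xbig, noise_sd = 1, seed = 9)
  expect_true(abs(sd(sb - predict(f, Xbig)) - 1) < 0.03)
})
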