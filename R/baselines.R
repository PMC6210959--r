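#' Multiple linear regression baseline
#'
#' Ordinary least squares with intercept, the simplest comparison model for
#' the chlorophyll-a regression. A rank-deficient design is handled with a
#' warning by taking the minimum-norm pseudoinverse solution.
#'
#' @param train a `"supervised_set"` (or any object with `$X`, `$T`).
#' @return a `"linear_baseline"`: list with `coefficients` (slopes),
#'   `intercept`, `feature_names`, `fitted.values`, `residuals`.
#' @export
fit_linear_regression <- function(train) {
  X <- as.matrix(train$X); y <- as.numeric(train$T)
  const <- apply(X, 2L, function(v) max(v) == min(v))
  A <- cbind(`(Intercept)` = 1, X[, !const, drop = FALSE])
  fit <- stats::lm.fit(A, y)
  if (any(const) || fit$rank < ncol(A)) {
    warning("fit_linear_regression(): rank-deficient design; ",
            "constant columns get zero slope, remaining aliasing resolved ",
            "by the minimum-norm pseudoinverse", call. = FALSE)
    coefs <- if (fit$rank < ncol(A)) fit_output_weights(A, y)
             else fit$coefficients
  } else {
    coefs <- fit$coefficients
  }
  full <- numeric(ncol(X) + 1L)
  full[1L] <- coefs[1L]
  full[c(FALSE, !const)] <- coefs[-1L]
  coefs <- full
  fitted <- drop(cbind(1, X) %*% coefs)
  structure(list(coefficients = unname(coefs[-1L]), intercept = unname(coefs[1L]),
                 feature_names = colnames(X),
                 fitted.values = fitted, residuals = y - fitted),
            class = "linear_baseline")
}

#' @export
predict.linear_baseline <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "supervised_set")) newdata <- newdata$X
  X <- as_matrix_checked(newdata, length(object$coefficients), "predict")
  drop(X %*% object$coefficients) + object$intercept
}

#' @export
print.linear_baseline <- function(x, ...) {
  cat("Multiple linear regression baseline\n")
  print(c(`(Intercept)` = x$intercept,
          stats::setNames(x$coefficients, x$feature_names)))
  invisible(x)
}

#' Backpropagation neural network baseline
#'
#' A single-hidden-layer network (sigmoid hidden units, linear output)
#' trained by full-batch gradient descent on the sum of squared errors —
#' the conventional iterative counterpart to the ELM's one-pass fit.
#' Inputs and target are z-scored internally using training statistics
#' (predictions are returned in original units); the per-epoch training RMSE
#' (original units) is recorded in `loss_curve`.
#'
#' @param train a `"supervised_set"`.
#' @param hidden_nodes hidden-layer width (>= 1).
#' @param learning_rate gradient-descent step size (default 0.001).
#' @param epochs number of full-batch epochs (default 1000).
#' @param seed integer seed for the weight initialization.
#' @return an `"nn_bp"` model: weights `W1` (hidden x d), `b1`, `W2`, `b2`,
#'   scalers, `loss_curve` (length `epochs`).
#' @export
train_nn_bp <- function(train, hidden_nodes, learning_rate = 0.001,
                        epochs = 1000, seed = NULL) {
  if (hidden_nodes < 1) stop("train_nn_bp(): hidden_nodes must be >= 1",
                             call. = FALSE)
  X <- as.matrix(train$X); y <- as.numeric(train$T)
  x_scaler <- make_scaler(X, TRUE)
  Xs <- unname(apply_scaler(x_scaler, X))
  y_scaler <- list(center = mean(y), scale = if (stats::sd(y) > 0) stats::sd(y) else 1)
  ys <- (y - y_scaler$center) / y_scaler$scale
  d <- ncol(X); h <- as.integer(hidden_nodes); N <- nrow(X)

  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  W1 <- matrix(stats::runif(h * d, -0.5, 0.5), h, d)
  b1 <- stats::runif(h, -0.5, 0.5)
  W2 <- stats::runif(h, -0.5, 0.5)
  b2 <- stats::runif(1, -0.5, 0.5)

  loss_curve <- numeric(epochs)
  if (epochs > 0) for (ep in seq_len(epochs)) {
    A <- Xs %*% t(W1)
    A <- sweep(A, 2L, b1, "+")
    Hh <- 1 / (1 + exp(-A))               # N x h
    yhat <- drop(Hh %*% W2) + b2
    err <- yhat - ys                      # dE/dyhat / 2
    # full-batch gradients of SSE
    gW2 <- drop(2 * crossprod(Hh, err))   # h
    gb2 <- 2 * sum(err)
    delta <- (2 * err %o% W2) * Hh * (1 - Hh)  # N x h
    gW1 <- crossprod(delta, Xs)           # h x d
    gb1 <- colSums(delta)
    W2 <- W2 - learning_rate * gW2
    b2 <- b2 - learning_rate * gb2
    W1 <- W1 - learning_rate * gW1
    b1 <- b1 - learning_rate * gb1
    loss <- sqrt(mean(err^2)) * y_scaler$scale
    if (!is.finite(loss))
      stop("train_nn_bp(): training diverged (non-finite loss) at epoch ", ep,
           "; reduce learning_rate", call. = FALSE)
    loss_curve[ep] <- loss
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 hidden_nodes = h, learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = seed,
                 loss_curve = loss_curve,
                 x_scaler = x_scaler, y_scaler = y_scaler,
                 feature_names = colnames(X)),
            class = "nn_bp")
}

#' @export
predict.nn_bp <- function(object, newdata, ...) {
  if (inherits(newdata, "supervised_set")) newdata <- newdata$X
  X <- as_matrix_checked(newdata, ncol(object$W1), "predict")
  Xs <- apply_scaler(object$x_scaler, X)
  A <- Xs %*% t(object$W1)
  A <- sweep(A, 2L, object$b1, "+")
  Hh <- 1 / (1 + exp(-A))
  ys <- drop(Hh %*% object$W2) + object$b2
  ys * object$y_scaler$scale + object$y_scaler$center
}

#' @export
print.nn_bp <- function(x, ...) {
  cat(sprintf(paste0("Backpropagation NN baseline: %d hidden nodes, ",
                     "lr = %g, %d epochs\n"),
              x$hidden_nodes, x$learning_rate, x$epochs))
  if (x$epochs > 0)
    cat(sprintf("  final training RMSE: %.4f\n",
                x$loss_curve[length(x$loss_curve)]))
  invisible(x)
}

#' Fuzzy c-means clustering
#'
#' Standard alternating-optimization FCM minimizing
#' \eqn{J = \sum_{i,j} u_{ij}^m \|x_i - c_j\|^2} subject to each
#' membership row summing to 1. Used to place the antecedent rule centers
#' of the ANFIS baseline. The per-iteration objective trace is returned so
#' monotone descent can be verified.
#'
#' @param X N x d data matrix (N >= r).
#' @param r number of clusters (>= 2).
#' @param fuzzifier membership exponent m > 1 (default 2).
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter iteration cap.
#' @param seed seed for the random membership initialization.
#' @return list with `centers` (r x d), `memberships` (N x r, rows sum to
#'   1), `objective`, `objective_trace`, `iterations`.
#' @export
fcm_cluster <- function(X, r, fuzzifier = 2, tol = 1e-6, max_iter = 200,
                        seed = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (r < 2) stop("fcm_cluster(): r must be >= 2 (use a single-rule model ",
                  "for r = 1)", call. = FALSE)
  if (N < r) stop("fcm_cluster(): need at least r data points", call. = FALSE)
  if (all(apply(X, 2L, function(v) max(v) - min(v)) == 0))
    stop("fcm_cluster(): degenerate input (all points identical)",
         call. = FALSE)
  if (fuzzifier <= 1) stop("fcm_cluster(): fuzzifier must be > 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  U <- matrix(stats::runif(N * r), N, r)
  U <- U / rowSums(U)
  m <- fuzzifier
  trace <- numeric(0)
  prev <- Inf
  centers <- NULL
  for (it in seq_len(max_iter)) {
    Um <- U^m
    centers <- (t(Um) %*% X) / colSums(Um)
    D2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    D2[D2 < .Machine$double.eps] <- .Machine$double.eps
    J <- sum(Um * D2)
    trace <- c(trace, J)
    # membership update: u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))
    P <- D2^(-1 / (m - 1))
    U <- P / rowSums(P)
    if (is.finite(prev) && abs(prev - J) < tol) break
    prev <- J
  }
  list(centers = centers, memberships = U, objective = trace[length(trace)],
       objective_trace = trace, iterations = length(trace))
}

#' ANFIS with fuzzy c-means rule induction (one-pass LSE)
#'
#' A first-order Takagi-Sugeno fuzzy system whose `r` if-then rules come
#' from fuzzy c-means clustering of the (z-scored) training inputs:
#' antecedents are per-feature Gaussian membership functions centered at the
#' cluster centers, with spreads set to the membership-weighted standard
#' deviation of each feature within each cluster (floored at 1e-3 of the
#' feature range). The linear consequents are fitted in a single pass by
#' least squares on the rule-weighted design matrix — no iterative learning.
#'
#' To keep the consequent LSE overdetermined, construction refuses rule
#' counts whose consequent parameter count `r * (d + 1)` reaches the number
#' of training rows (with ~100 weekly training rows and 7-8 features this
#' excludes 4 or more rules — the overfitting regime).
#'
#' `r = 1` is the degenerate single-rule system, which is exactly multiple
#' linear regression.
#'
#' @param train a `"supervised_set"`.
#' @param r rule count (default 2).
#' @param fuzzifier FCM membership exponent.
#' @param seed FCM initialization seed.
#' @return an `"anfis"` model: `r`, `centers`, `spreads` (both r x d, on the
#'   z-scored scale), `consequents` (r x (d+1)), `x_scaler`,
#'   `trained_epochs` (0 for the one-pass fit).
#' @export
build_anfis_fcm <- function(train, r = 2, fuzzifier = 2, seed = NULL) {
  X <- as.matrix(train$X); y <- as.numeric(train$T)
  N <- nrow(X); d <- ncol(X)
  r <- as.integer(r)
  if (r < 1) stop("build_anfis_fcm(): r must be >= 1", call. = FALSE)
  if (r * (d + 1) >= N)
    stop(sprintf(paste0("build_anfis_fcm(): overfitting guard: r*(d+1) = %d ",
                        "parameters >= %d training rows; reduce the rule count"),
                 r * (d + 1), N), call. = FALSE)
  x_scaler <- make_scaler(X, TRUE)
  Xs <- apply_scaler(x_scaler, X)
  if (r == 1L) {
    centers <- matrix(colMeans(Xs), 1L, d)
    spreads <- matrix(1, 1L, d) # irrelevant: single rule fires with weight 1
    U <- matrix(1, N, 1L)
  } else {
    cl <- fcm_cluster(Xs, r, fuzzifier = fuzzifier, seed = seed)
    centers <- cl$centers
    U <- cl$memberships
    spreads <- matrix(0, r, d)
    rng <- apply(Xs, 2L, function(v) max(v) - min(v))
    floor_s <- pmax(1e-3 * rng, 1e-8)
    Um <- U^fuzzifier
    for (j in seq_len(r)) {
      wsum <- sum(Um[, j])
      for (k in seq_len(d)) {
        s2 <- sum(Um[, j] * (Xs[, k] - centers[j, k])^2) / wsum
        spreads[j, k] <- max(sqrt(s2), floor_s[k])
      }
    }
  }
  model <- structure(list(r = r, centers = centers, spreads = spreads,
                          consequents = NULL, trained_epochs = 0L,
                          x_scaler = x_scaler,
                          spread_floor = if (r == 1L) rep(1e-8, d) else
                            pmax(1e-3 * apply(Xs, 2L, function(v) max(v) - min(v)), 1e-8),
                          feature_names = colnames(X)),
                     class = "anfis")
  model$consequents <- anfis_fit_consequents(model, Xs, y)
  model
}

# normalized rule firing strengths on z-scored inputs, N x r
anfis_strengths <- function(model, Xs) {
  N <- nrow(Xs); r <- model$r
  logW <- matrix(0, N, r)
  for (j in seq_len(r)) {
    Z <- sweep(Xs, 2L, model$centers[j, ], "-")
    Z <- sweep(Z, 2L, model$spreads[j, ], "/")
    logW[, j] <- -0.5 * rowSums(Z^2)
  }
  # normalize in log space for numerical safety
  logW <- logW - apply(logW, 1L, max)
  W <- exp(logW)
  W / rowSums(W)
}

# rule-weighted first-order design matrix, N x r(d+1)
anfis_design <- function(model, Xs) {
  Wbar <- anfis_strengths(model, Xs)
  N <- nrow(Xs); d <- ncol(Xs)
  Phi <- matrix(0, N, model$r * (d + 1))
  for (j in seq_len(model$r)) {
    cols <- ((j - 1) * (d + 1) + 1):(j * (d + 1))
    Phi[, cols] <- Wbar[, j] * cbind(1, Xs)
  }
  Phi
}

anfis_fit_consequents <- function(model, Xs, y) {
  Phi <- anfis_design(model, Xs)
  theta <- fit_output_weights(Phi, y)
  matrix(theta, nrow = model$r, byrow = TRUE)
}

#' @export
predict.anfis <- function(object, newdata, ...) {
  if (inherits(newdata, "supervised_set")) newdata <- newdata$X
  X <- as_matrix_checked(newdata, ncol(object$centers), "predict")
  Xs <- apply_scaler(object$x_scaler, X)
  Wbar <- anfis_strengths(object, Xs)
  G <- cbind(1, Xs) %*% t(object$consequents) # N x r rule outputs
  rowSums(Wbar * G)
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf("ANFIS-FCM: %d rule(s), %d features, %d hybrid epoch(s)\n",
              x$r, ncol(x$centers), x$trained_epochs))
  invisible(x)
}

#' Hybrid learning for ANFIS-FCM
#'
#' The classical two-pass training loop: each epoch, the forward pass refits
#' the linear consequents by least squares given the current antecedents,
#' and the backward pass moves the membership centers and spreads one
#' gradient-descent step (fixed step 0.01, global gradient-norm clipping)
#' down the training sum of squared errors. Train and test RMSE are recorded
#' after every epoch, giving the learning curves on which overfitting is
#' diagnosed: on short noisy series the training error keeps falling while
#' the test error rises, which is why the one-pass (no-learning) fit of
#' [build_anfis_fcm()] is the reporting default.
#'
#' @param model a fitted `"anfis"` model.
#' @param train,test supervised sets from one split.
#' @param epochs number of hybrid epochs (default 100).
#' @param step antecedent gradient step size.
#' @param clip global gradient-norm ceiling for the backward pass.
#' @return list with the updated `model`, `train_curve`, `test_curve`
#'   (RMSE per epoch, length `epochs`).
#' @export
train_anfis_hybrid <- function(model, train, test, epochs = 100,
                               step = 0.01, clip = 3) {
  stopifnot(inherits(model, "anfis"))
  if (model$r < 2)
    stop("train_anfis_hybrid(): hybrid learning needs r >= 2", call. = FALSE)
  Xtr <- apply_scaler(model$x_scaler, as.matrix(train$X))
  ytr <- as.numeric(train$T)
  Xte <- as.matrix(test$X)
  yte <- as.numeric(test$T)
  d <- ncol(Xtr)
  train_curve <- test_curve <- numeric(epochs)
  if (epochs > 0) for (ep in seq_len(epochs)) {
    # forward pass: LSE refit of consequents
    model$consequents <- anfis_fit_consequents(model, Xtr, ytr)
    # backward pass: gradient step on centers and spreads
    Wraw <- anfis_raw_strengths(model, Xtr)        # N x r
    S <- rowSums(Wraw)
    Wbar <- Wraw / S
    G <- cbind(1, Xtr) %*% t(model$consequents)    # N x r
    yhat <- rowSums(Wbar * G)
    err <- yhat - ytr
    if (!all(is.finite(yhat)))
      stop("train_anfis_hybrid(): non-finite loss at epoch ", ep, call. = FALSE)
    # dE/dw_ij = 2 err_i (G_ij - yhat_i) / S_i
    dEdw <- (2 * err / S) * (G - yhat)             # N x r
    gC <- matrix(0, model$r, d)
    gS <- matrix(0, model$r, d)
    for (j in seq_len(model$r)) {
      Z <- sweep(Xtr, 2L, model$centers[j, ], "-") # x - c
      common <- dEdw[, j] * Wraw[, j]
      gC[j, ] <- colSums(common * sweep(Z, 2L, model$spreads[j, ]^2, "/"))
      gS[j, ] <- colSums(common * sweep(Z^2, 2L, model$spreads[j, ]^3, "/"))
    }
    gnorm <- sqrt(sum(gC^2) + sum(gS^2))
    if (gnorm > clip) { gC <- gC * clip / gnorm; gS <- gS * clip / gnorm }
    model$centers <- model$centers - step * gC
    model$spreads <- model$spreads - step * gS
    model$spreads <- pmax(model$spreads,
                          matrix(model$spread_floor, model$r, d, byrow = TRUE))
    # re-fit consequents to the moved antecedents before measuring
    model$consequents <- anfis_fit_consequents(model, Xtr, ytr)
    train_curve[ep] <- rmse(ytr, predict(model, train$X))
    test_curve[ep] <- rmse(yte, predict(model, Xte))
  }
  model$trained_epochs <- model$trained_epochs + as.integer(epochs)
  list(model = model, train_curve = train_curve, test_curve = test_curve)
}

# unnormalized Gaussian firing strengths (no log rescale), N x r
anfis_raw_strengths <- function(model, Xs) {
  N <- nrow(Xs)
  W <- matrix(0, N, model$r)
  for (j in seq_len(model$r)) {
    Z <- sweep(Xs, 2L, model$centers[j, ], "-")
    Z <- sweep(Z, 2L, model$spreads[j, ], "/")
    W[, j] <- exp(-0.5 * rowSums(Z^2))
  }
  W[W < 1e-300] <- 1e-300
  W
}

#' Predict from any baseline model
#'
#' Convenience dispatcher equivalent to calling [predict()] on the model.
#'
#' @param model a `"linear_baseline"`, `"nn_bp"` or `"anfis"` model (an
#'   `"elm"` also works).
#' @param X predictor matrix or supervised set.
#' @return numeric predictions.
#' @export
predict_baseline <- function(model, X) predict(model, X)

#' Export a learning curve as CSV
#'
#' Two columns, `epoch` and `rmse`.
#' @param curve numeric RMSE-per-epoch vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(epoch = seq_along(curve), rmse = curve),
                   path, row.names = FALSE)
  invisible(path)
}
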