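#' Hidden-node activation functions
#'
#' Evaluate a single hidden node \eqn{G(w, b, x)} of a single-hidden-layer
#' feedforward network. Three node types are supported:
#' \describe{
#'   \item{sigmoid}{\eqn{1 / (1 + \exp(-(w \cdot x + b)))}}
#'   \item{rbf}{Gaussian radial basis, \eqn{\exp(-(b \, \|x - w\|)^2)} with
#'     \eqn{b > 0} acting as an inverse width}
#'   \item{sine}{\eqn{\sin(w \cdot x + b)}}
#' }
#'
#' @param kind one of `"sigmoid"`, `"rbf"`, `"sine"`.
#' @param w numeric weight vector of length `d`.
#' @param b scalar bias (inverse width for `"rbf"`, must be positive).
#' @param x numeric input vector of length `d`.
#' @return scalar activation value.
#' @examples
#' activation("sigmoid", w = c(1, -1), b = 0, x = c(0.5, 0.5)) # 0.5
#' activation("rbf", w = c(1, 2), b = 0.7, x = c(1, 2))        # 1
#' @export
activation <- function(kind, w, b, x) {
  kind <- match.arg(kind, c("sigmoid", "rbf", "sine"))
  stopifnot(length(w) == length(x), length(b) == 1L)
  if (!all(is.finite(w)) || !all(is.finite(x)) || !is.finite(b))
    stop("activation(): non-finite inputs", call. = FALSE)
  switch(kind,
    sigmoid = 1 / (1 + exp(-(sum(w * x) + b))),
    rbf     = exp(-(b * sqrt(sum((x - w)^2)))^2),
    sine    = sin(sum(w * x) + b)
  )
}

#' Draw a random hidden layer
#'
#' Step 1 of the ELM algorithm: hidden-node input weights and biases are
#' assigned randomly and are never updated afterwards. Weights and (for the
#' additive nodes) biases are i.i.d. uniform on \eqn{[-1, 1]}; RBF inverse
#' widths are uniform on \eqn{(0, 1]} so they are strictly positive.
#'
#' @param L number of hidden nodes (>= 1).
#' @param d input dimension (>= 1).
#' @param activation node type, see [activation()].
#' @param seed integer seed; the draw is fully reproducible given
#'   `(L, d, activation, seed)`.
#' @return an object of class `"elm_hidden"`: list with `W` (L x d matrix),
#'   `b` (length-L vector), `activation`, `L`, `d`, `seed`.
#' @export
init_hidden <- function(L, d, activation = "sigmoid", seed = NULL) {
  activation <- match.arg(activation, c("sigmoid", "rbf", "sine"))
  if (!is.numeric(L) || L < 1) stop("init_hidden(): L must be >= 1", call. = FALSE)
  if (!is.numeric(d) || d < 1) stop("init_hidden(): d must be >= 1", call. = FALSE)
  L <- as.integer(L); d <- as.integer(d)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  # node-wise draws (d weights then the bias per node): layers with the
  # same seed are nested in L, so enlarging the layer only widens the
  # span of H and training SSE is non-increasing in L seed-for-seed
  draws <- matrix(stats::runif(L * (d + 1L), -1, 1),
                  nrow = L, ncol = d + 1L, byrow = TRUE)
  W <- draws[, seq_len(d), drop = FALSE]
  b <- if (activation == "rbf") {
    # map uniform [-1, 1) onto (0, 1]: strictly positive inverse widths
    (1 - draws[, d + 1L]) / 2
  } else {
    draws[, d + 1L]
  }
  structure(list(W = W, b = b, activation = activation,
                 L = L, d = d, seed = seed),
            class = "elm_hidden")
}

#' Hidden-layer output matrix
#'
#' Step 2 of the ELM algorithm: maps an N x d input matrix through the fixed
#' random hidden layer, giving the N x L matrix `H` with
#' `H[i, j] = G(w_j, b_j, x_i)`.
#'
#' @param hidden an `"elm_hidden"` object from [init_hidden()].
#' @param X numeric matrix, N rows, `hidden$d` columns.
#' @return N x L numeric matrix.
#' @export
hidden_matrix <- function(hidden, X) {
  stopifnot(inherits(hidden, "elm_hidden"))
  X <- as_matrix_checked(X, hidden$d, "hidden_matrix")
  H <- switch(hidden$activation,
    sigmoid = {
      A <- X %*% t(hidden$W)
      A <- sweep(A, 2L, hidden$b, "+")
      1 / (1 + exp(-A))
    },
    sine = {
      A <- X %*% t(hidden$W)
      sin(sweep(A, 2L, hidden$b, "+"))
    },
    rbf = {
      # squared distances ||x_i - w_j||^2 without explicit loops
      D2 <- outer(rowSums(X^2), rowSums(hidden$W^2), "+") - 2 * X %*% t(hidden$W)
      D2[D2 < 0] <- 0 # numerical negatives
      exp(-sweep(D2, 2L, hidden$b^2, "*"))
    }
  )
  if (!all(is.finite(H)))
    stop("hidden_matrix(): non-finite activations", call. = FALSE)
  H
}

#' Least-squares output weights
#'
#' Step 3 of the ELM algorithm: the output weights are the minimum-norm
#' least-squares solution \eqn{\beta = H^{+} T}, with the Moore-Penrose
#' pseudoinverse computed by SVD. Singular values below
#' `max(N, L) * eps * sigma_max` are treated as zero, so rank-deficient
#' hidden matrices are handled (where the normal-equations inverse
#' \eqn{(H'H)^{-1}} would not exist).
#'
#' @param H N x L hidden output matrix.
#' @param T length-N target vector.
#' @return length-L vector of output weights.
#' @export
fit_output_weights <- function(H, T) {
  H <- as.matrix(H)
  T <- as.numeric(T)
  if (nrow(H) != length(T))
    stop("fit_output_weights(): rows(H) != length(T)", call. = FALSE)
  if (!all(is.finite(H)) || !all(is.finite(T)))
    stop("fit_output_weights(): non-finite entries", call. = FALSE)
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, ncol(H)))
  dinv <- ifelse(pos, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * (t(sv$u) %*% T)))
}

#' Fit an extreme learning machine regressor
#'
#' Fits a single-hidden-layer feedforward network in which the hidden-layer
#' weights and biases are drawn at random and frozen; only the linear output
#' weights are estimated, in one pass, by a minimum-norm least-squares fit of
#' the hidden output matrix onto the target. No iterative training occurs.
#'
#' The fitted predictor is \eqn{f_L(x) = \sum_{i=1}^{L} \beta_i G(w_i, b_i, x)}.
#'
#' Inputs are z-scored per feature using training statistics by default
#' (`standardize = TRUE`); on raw environmental scales (rainfall in mm next to
#' phosphorus in mg/L) sigmoid nodes saturate otherwise. Constant features get
#' unit scale.
#'
#' @param x an N x d predictor matrix, a data frame of predictors, or a
#'   `"supervised_set"` (see [assemble_features()]). A formula interface is
#'   also provided: `elm(y ~ ., data)`.
#' @param y length-N numeric target (ignored when `x` is a supervised set).
#' @param L number of hidden nodes.
#' @param activation hidden-node type: `"sigmoid"` (default), `"rbf"`, `"sine"`.
#' @param seed integer seed for the random hidden layer.
#' @param standardize z-score inputs using training statistics (default TRUE).
#' @param ... passed between methods.
#' @return an object of class `"elm"` with components `hidden`, `beta`,
#'   `scaler`, `d`, `feature_names`, `fitted.values`, `residuals`, `call`.
#' @seealso [predict.elm()], [elm_save()], [select_hidden_nodes()]
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), 100, 2)
#' y <- sin(4 * x[, 1]) + x[, 2]^2 + rnorm(100, sd = 0.05)
#' fit <- elm(x, y, L = 20, seed = 42)
#' fit
#' @export
elm <- function(x, ...) UseMethod("elm")

#' @rdname elm
#' @export
elm.default <- function(x, y, L = 10, activation = "sigmoid", seed = NULL,
                        standardize = TRUE, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y))
    stop("elm(): rows(x) != length(y)", call. = FALSE)
  if (nrow(X) < 1L) stop("elm(): empty training set", call. = FALSE)
  feature_names <- colnames(X)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))

  scaler <- make_scaler(X, standardize)
  Xs <- apply_scaler(scaler, X)
  hidden <- init_hidden(L, ncol(X), activation, seed)
  H <- hidden_matrix(hidden, Xs)
  beta <- fit_output_weights(H, y)
  fitted <- drop(H %*% beta)

  structure(list(
    hidden = hidden, beta = beta, scaler = scaler,
    d = ncol(X), feature_names = feature_names,
    fitted.values = fitted, residuals = y - fitted, y = y,
    standardize = standardize, call = match.call()
  ), class = "elm")
}

#' @rdname elm
#' @export
elm.supervised_set <- function(x, L = 10, activation = "sigmoid", seed = NULL,
                               standardize = TRUE, ...) {
  fit <- elm.default(x$X, x$T, L = L, activation = activation, seed = seed,
                     standardize = standardize)
  fit$variant <- x$variant
  fit$call <- match.call()
  fit
}

#' @rdname elm
#' @param formula a model formula; the response is the target series.
#' @param data a data frame holding the variables of `formula`.
#' @export
elm.formula <- function(formula, data, L = 10, activation = "sigmoid",
                        seed = NULL, standardize = TRUE, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  tt <- attr(mf, "terms")
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- elm.default(X, y, L = L, activation = activation, seed = seed,
                     standardize = standardize)
  fit$terms <- tt
  fit$call <- match.call()
  fit
}

#' Predict from a fitted ELM
#'
#' @param object an `"elm"` fit.
#' @param newdata matrix, data frame or supervised set with `object$d`
#'   feature columns; if missing, training fitted values are returned.
#' @param ... unused.
#' @return numeric vector of predicted chlorophyll-a (target units).
#' @export
predict.elm <- function(object, newdata, ...) {
  if (missing(newdata) || is.null(newdata)) return(object$fitted.values)
  X <- resolve_newdata(object, newdata)
  Xs <- apply_scaler(object$scaler, X)
  H <- hidden_matrix(object$hidden, Xs)
  drop(H %*% object$beta)
}

#' Simulate noisy targets from a fitted ELM
#'
#' Draws `nsim` independent target vectors `predict(object, newdata) +
#' N(0, noise_sd)`. With `noise_sd = 0` the predictions are returned exactly.
#' Used as the generating oracle in function-recovery experiments.
#'
#' @param object an `"elm"` fit.
#' @param nsim number of response vectors.
#' @param seed integer seed.
#' @param newdata predictor matrix (defaults to training fitted values' inputs
#'   not being retained, so `newdata` is required unless simulating at the
#'   fitted values).
#' @param noise_sd Gaussian noise standard deviation (target units).
#' @param ... unused.
#' @return data frame with `nsim` columns, one simulated target vector each.
#' @export
simulate.elm <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                         noise_sd = 0, ...) {
  mu <- if (is.null(newdata)) object$fitted.values else predict(object, newdata)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, noise_sd),
                                 simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @rdname simulate.elm
#' @param model an `"elm"` fit.
#' @param X predictor matrix.
#' @export
sample_from_elm <- function(model, X, noise_sd = 0, seed = NULL) {
  simulate.elm(model, nsim = 1, seed = seed, newdata = X,
               noise_sd = noise_sd)[[1L]]
}

#' @export
coef.elm <- function(object, ...) object$beta

#' @export
residuals.elm <- function(object, ...) object$residuals

#' @export
fitted.elm <- function(object, ...) object$fitted.values

#' @export
print.elm <- function(x, ...) {
  cat("Extreme learning machine regressor\n")
  cat(sprintf("  hidden nodes: %d (%s), input dim: %d\n",
              x$hidden$L, x$hidden$activation, x$d))
  cat(sprintf("  training RMSE: %.4g on n = %d\n",
              rmse(x$y, x$fitted.values), length(x$y)))
  invisible(x)
}

#' @export
summary.elm <- function(object, ...) {
  out <- list(
    L = object$hidden$L, activation = object$hidden$activation,
    d = object$d, n = length(object$y),
    feature_names = object$feature_names,
    rmse_train = rmse(object$y, object$fitted.values),
    r2_train = r_squared(object$y, object$fitted.values),
    beta_norm = sqrt(sum(object$beta^2)),
    seed = object$hidden$seed
  )
  class(out) <- "summary.elm"
  out
}

#' @export
print.summary.elm <- function(x, ...) {
  cat("Extreme learning machine regressor\n")
  cat(sprintf("  hidden nodes L = %d, activation = %s, features d = %d, n = %d\n",
              x$L, x$activation, x$d, x$n))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  cat(sprintf("  training RMSE = %.4f, R2 = %.4f, ||beta|| = %.3g\n",
              x$rmse_train, x$r2_train, x$beta_norm))
  if (!is.null(x$seed)) cat(sprintf("  hidden-layer seed = %d\n", x$seed))
  invisible(x)
}

#' @export
plot.elm <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values,
                 xlab = "observed", ylab = "fitted",
                 main = "ELM training fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# -- internal helpers --------------------------------------------------------

make_scaler <- function(X, standardize) {
  if (!standardize) {
    return(list(center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

as_matrix_checked <- function(X, d, where) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != d)
    stop(sprintf("%s(): expected %d feature columns, got %d", where, d, ncol(X)),
         call. = FALSE)
  X
}

resolve_newdata <- function(object, newdata) {
  if (inherits(newdata, "supervised_set")) newdata <- newdata$X
  if (is.data.frame(newdata)) {
    if (!is.null(object$terms)) {
      tt <- stats::delete.response(object$terms)
      mf <- stats::model.frame(tt, newdata)
      X <- stats::model.matrix(tt, mf)
      newdata <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    } else if (all(object$feature_names %in% names(newdata))) {
      newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
    } else {
      newdata <- as.matrix(newdata)
    }
  }
  as_matrix_checked(newdata, object$d, "predict")
}

# Seed handling that restores the caller's RNG state, so seeded model fits
# do not perturb an enclosing simulation.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
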