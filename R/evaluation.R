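#' Evaluate a fitted model on a train/test split
#'
#' Computes the six-number report used throughout: R-squared (Nash-Sutcliffe
#' form), RMSE and AIC, each on the training and the test half.
#'
#' @param model a fitted `"elm"`, `"linear_baseline"`, `"nn_bp"` or
#'   `"anfis"` model.
#' @param split a `"train_test_split"`.
#' @param label model label for reports.
#' @return a `"fit_report"`: list with `model_label`, `r2_train`, `r2_test`,
#'   `rmse_train`, `rmse_test`, `aic_train`, `aic_test`, `L_or_r`,
#'   `seeds_used`.
#' @export
evaluate_model <- function(model, split, label = class(model)[1L]) {
  stopifnot(inherits(split, "train_test_split"))
  yhat_tr <- predict(model, split$train$X)
  yhat_te <- predict(model, split$test$X)
  k <- model_param_count(model)
  fit_report(
    model_label = label,
    r2_train = r_squared(split$train$T, yhat_tr),
    r2_test = r_squared(split$test$T, yhat_te),
    rmse_train = rmse(split$train$T, yhat_tr),
    rmse_test = rmse(split$test$T, yhat_te),
    aic_train = safe_aic(split$train$T, yhat_tr, k),
    aic_test = safe_aic(split$test$T, yhat_te, k),
    L_or_r = capacity_of(model), seeds_used = 1L
  )
}

fit_report <- function(model_label, r2_train, r2_test, rmse_train, rmse_test,
                       aic_train, aic_test, L_or_r, seeds_used) {
  structure(list(model_label = model_label,
                 r2_train = r2_train, r2_test = r2_test,
                 rmse_train = rmse_train, rmse_test = rmse_test,
                 aic_train = aic_train, aic_test = aic_test,
                 L_or_r = L_or_r, seeds_used = seeds_used),
            class = "fit_report")
}

safe_aic <- function(y, yhat, k) {
  sse <- sum((y - yhat)^2)
  if (sse <= 0) return(NA_real_) # numerically perfect fit: flagged, not -Inf
  aic_score(length(y), sse, k)
}

model_param_count <- function(model) {
  if (inherits(model, "elm")) return(model$hidden$L)
  if (inherits(model, "linear_baseline")) return(length(model$coefficients) + 1L)
  if (inherits(model, "nn_bp"))
    return(length(model$W1) + length(model$b1) + length(model$W2) + 1L)
  if (inherits(model, "anfis")) return(model$r * (ncol(model$centers) + 1L))
  stop("unknown model class", call. = FALSE)
}

capacity_of <- function(model) {
  if (inherits(model, "elm")) return(model$hidden$L)
  if (inherits(model, "nn_bp")) return(model$hidden_nodes)
  if (inherits(model, "anfis")) return(model$r)
  NA_integer_
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("%s  (capacity %s, %d seed%s)\n", x$model_label,
              ifelse(is.na(x$L_or_r), "-", x$L_or_r), x$seeds_used,
              if (x$seeds_used == 1) "" else "s"))
  cat(sprintf("  R2    train %.2f  test %.2f\n", x$r2_train, x$r2_test))
  cat(sprintf("  RMSE  train %.1f  test %.1f\n", x$rmse_train, x$rmse_test))
  cat(sprintf("  AIC   train %.1f  test %.1f\n", x$aic_train, x$aic_test))
  invisible(x)
}

#' @export
as.data.frame.fit_report <- function(x, ...) {
  data.frame(model_label = x$model_label,
             r2_train = x$r2_train, r2_test = x$r2_test,
             rmse_train = x$rmse_train, rmse_test = x$rmse_test,
             aic_train = x$aic_train, aic_test = x$aic_test,
             L_or_r = x$L_or_r, seeds_used = x$seeds_used)
}

#' Seed-averaged ELM evaluation
#'
#' Because the hidden layer is random, single-draw ELM metrics are
#' themselves random. This fits one ELM per seed on the training half and
#' reports the mean of each metric over seeds (the package's default
#' reporting protocol; pass one seed for a single-draw report).
#'
#' @param split a `"train_test_split"`.
#' @param L hidden nodes.
#' @param activation hidden-node type.
#' @param seeds integer vector of hidden-layer seeds.
#' @param standardize passed to [elm()].
#' @param label report label.
#' @return a `"fit_report"` with `seeds_used = length(seeds)`.
#' @export
evaluate_elm_seeds <- function(split, L, activation = "sigmoid",
                               seeds = 1:30, standardize = TRUE,
                               label = "ELM") {
  reps <- lapply(seeds, function(s) {
    m <- elm(split$train, L = L, activation = activation, seed = s,
             standardize = standardize)
    evaluate_model(m, split, label = label)
  })
  avg <- function(f) mean(vapply(reps, `[[`, numeric(1), f))
  fit_report(label,
             avg("r2_train"), avg("r2_test"),
             avg("rmse_train"), avg("rmse_test"),
             avg("aic_train"), avg("aic_test"),
             L_or_r = L, seeds_used = length(seeds))
}

#' Select the hidden-node count by validation sweep
#'
#' Trains ELMs for each candidate node count (default 2 to 30), averaging
#' train and test RMSE over the supplied hidden-layer seeds, and selects the
#' count at which the mean test RMSE reaches its minimum. Ties are broken
#' toward the smaller (more parsimonious) count. Candidates at or above the
#' training-set size are flagged (`unstable`) — the fit interpolates there —
#' but still swept.
#'
#' @param train,test supervised sets from one split.
#' @param L_range integer candidates (default `2:30`).
#' @param activation hidden-node type.
#' @param seeds hidden-layer seeds averaged per candidate.
#' @param standardize passed to [elm()].
#' @return a `"node_sweep"`: list with `table` (columns `L, train_rmse,
#'   test_rmse, unstable`) and `selected_L`.
#' @export
select_hidden_nodes <- function(train, test, L_range = 2:30,
                                activation = "sigmoid", seeds = 1:10,
                                standardize = TRUE) {
  if (length(L_range) == 0L)
    stop("select_hidden_nodes(): empty candidate range", call. = FALSE)
  L_range <- sort(unique(as.integer(L_range)))
  n_train <- length(train$T)
  rows <- lapply(L_range, function(L) {
    tr_rmse <- te_rmse <- numeric(length(seeds))
    for (i in seq_along(seeds)) {
      m <- elm(train, L = L, activation = activation, seed = seeds[i],
               standardize = standardize)
      tr_rmse[i] <- rmse(train$T, predict(m, train$X))
      te_rmse[i] <- rmse(test$T, predict(m, test$X))
    }
    data.frame(L = L, train_rmse = mean(tr_rmse), test_rmse = mean(te_rmse),
               unstable = L >= n_train)
  })
  tab <- do.call(rbind, rows)
  selected_L <- tab$L[which.min(tab$test_rmse)] # first minimum = smallest L
  structure(list(table = tab, selected_L = selected_L,
                 activation = activation, seeds = seeds),
            class = "node_sweep")
}

#' @export
print.node_sweep <- function(x, ...) {
  cat(sprintf("Hidden-node sweep (%s, %d seed(s) per candidate)\n",
              x$activation, length(x$seeds)))
  cat(sprintf("  candidates %d..%d, selected L = %d (test RMSE %.3f)\n",
              min(x$table$L), max(x$table$L), x$selected_L,
              min(x$table$test_rmse)))
  invisible(x)
}

#' @export
plot.node_sweep <- function(x, ...) {
  graphics::matplot(x$table$L, cbind(x$table$train_rmse, x$table$test_rmse),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "hidden nodes L", ylab = "RMSE",
                    main = "ELM capacity sweep", ...)
  graphics::abline(v = x$selected_L, lty = 3)
  graphics::legend("topright", c("train", "test"), pch = c(1, 2), lty = 1,
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Percent improvement between two model reports
#'
#' Computes the per-metric percentage changes used when comparing the
#' upstream-augmented model with the baseline feature design. For R-squared,
#' improvement is `(after - before) / before * 100`; for RMSE it is
#' `(before - after) / before * 100`, so a positive number is an improvement
#' for both metrics. Full precision is retained; the print method rounds to
#' one decimal for display.
#'
#' @param before,after `"fit_report"` objects on the same split.
#' @return an `"improvement_report"` data frame with columns
#'   `metric, before, after, improvement_pct`.
#' @export
improvement_percent <- function(before, after) {
  stopifnot(inherits(before, "fit_report"), inherits(after, "fit_report"))
  metrics <- c("r2_train", "r2_test", "rmse_train", "rmse_test")
  rows <- lapply(metrics, function(m) {
    b <- before[[m]]; a <- after[[m]]
    pct <- if (b == 0) NA_real_ # undefined denominator, flagged
    else if (startsWith(m, "rmse")) (b - a) / b * 100
    else (a - b) / b * 100
    data.frame(metric = m, before = b, after = a, improvement_pct = pct)
  })
  structure(do.call(rbind, rows),
            class = c("improvement_report", "data.frame"))
}

#' @export
print.improvement_report <- function(x, ...) {
  out <- as.data.frame(x)
  out$improvement_pct <- round(out$improvement_pct, 1)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Compare the ELM against its baselines on one shared split
#'
#' Fits every requested model on the identical train/test rows and collects
#' their reports into one grid: the seed-averaged ELM, multiple linear
#' regression, the backpropagation neural network, and ANFIS-FCM at each
#' requested rule count. A model that errors (e.g. the ANFIS overfitting
#' guard) is recorded as a failed cell and the run continues.
#'
#' @param split a `"train_test_split"` (typically on ELM2 features).
#' @param config list of settings: `models` (subset of `"ELM"`, `"LR"`,
#'   `"NN-BP"`, `"ANFIS"`), `elm_L`, `activation`, `elm_seeds`, `nn_hidden`
#'   (defaults to `elm_L`), `nn_learning_rate`, `nn_epochs`, `nn_seed`,
#'   `anfis_r` (vector of rule counts), `standardize`.
#' @return a `"comparison_report"`: list with `reports` (named list of
#'   `"fit_report"` or error message strings) and `split_sizes`.
#' @export
compare_models <- function(split, config = list()) {
  stopifnot(inherits(split, "train_test_split"))
  cfg <- utils::modifyList(list(
    models = c("ELM", "LR", "NN-BP", "ANFIS"),
    elm_L = 10L, activation = "sigmoid", elm_seeds = 1:30,
    nn_hidden = NULL, nn_learning_rate = 0.001, nn_epochs = 1000L,
    nn_seed = 1L, anfis_r = c(2L, 3L), standardize = TRUE
  ), config)
  if (is.null(cfg$nn_hidden)) cfg$nn_hidden <- cfg$elm_L
  reports <- list()
  run <- function(label, expr) {
    reports[[label]] <<- tryCatch(expr, error = function(e) conditionMessage(e))
  }
  if ("ELM" %in% cfg$models)
    run(paste0("ELM (", split$train$variant, ")"),
        evaluate_elm_seeds(split, L = cfg$elm_L, activation = cfg$activation,
                           seeds = cfg$elm_seeds,
                           standardize = cfg$standardize,
                           label = paste0("ELM (", split$train$variant, ")")))
  if ("LR" %in% cfg$models)
    run("Multiple LR",
        evaluate_model(fit_linear_regression(split$train), split,
                       label = "Multiple LR"))
  if ("NN-BP" %in% cfg$models)
    run("NN with BP",
        evaluate_model(train_nn_bp(split$train, hidden_nodes = cfg$nn_hidden,
                                   learning_rate = cfg$nn_learning_rate,
                                   epochs = cfg$nn_epochs, seed = cfg$nn_seed),
                       split, label = "NN with BP"))
  if ("ANFIS" %in% cfg$models)
    for (r in cfg$anfis_r) {
      lab <- sprintf("ANFIS-FCM (r = %d)", r)
      run(lab, evaluate_model(build_anfis_fcm(split$train, r = r,
                                              seed = cfg$nn_seed),
                              split, label = lab))
    }
  structure(list(reports = reports,
                 split_sizes = c(train = length(split$train$T),
                                 test = length(split$test$T)),
                 config = cfg),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Model comparison on shared split (train %d / test %d)\n",
              x$split_sizes["train"], x$split_sizes["test"]))
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.comparison_report <- function(x, ...) {
  rows <- lapply(names(x$reports), function(nm) {
    r <- x$reports[[nm]]
    if (inherits(r, "fit_report")) as.data.frame(r)
    else data.frame(model_label = nm, r2_train = NA, r2_test = NA,
                    rmse_train = NA, rmse_test = NA, aic_train = NA,
                    aic_test = NA, L_or_r = NA, seeds_used = NA)
  })
  do.call(rbind, rows)
}

#' Write a comparison report as a Table-5-shaped CSV grid
#'
#' @param report a `"comparison_report"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
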