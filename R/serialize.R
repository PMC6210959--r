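#' Save and load fitted models as structured text
#'
#' Fitted models are serialized to JSON holding the hidden-layer weights,
#' biases, activation kind, output weights, input scaler and seed, at full
#' double precision, so that a save/load round trip reproduces predictions
#' exactly.
#'
#' @param model a fitted `"elm"`, `"linear_baseline"`, `"nn_bp"` or
#'   `"anfis"` model.
#' @param path file to write.
#' @return `elm_save()` returns `path` invisibly; `elm_load()` returns the
#'   reconstructed model.
#' @export
elm_save <- function(model, path) {
  cls <- class(model)[1L]
  payload <- switch(cls,
    elm = list(
      class = "elm",
      W = model$hidden$W, b = model$hidden$b,
      activation = model$hidden$activation,
      L = model$hidden$L, d = model$d,
      seed = model$hidden$seed,
      beta = model$beta,
      scaler_center = model$scaler$center, scaler_scale = model$scaler$scale,
      feature_names = model$feature_names
    ),
    linear_baseline = list(
      class = "linear_baseline",
      coefficients = model$coefficients, intercept = model$intercept,
      feature_names = model$feature_names
    ),
    nn_bp = list(
      class = "nn_bp",
      W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
      hidden_nodes = model$hidden_nodes,
      learning_rate = model$learning_rate, epochs = model$epochs,
      seed = model$seed, loss_curve = model$loss_curve,
      x_center = model$x_scaler$center, x_scale = model$x_scaler$scale,
      y_center = model$y_scaler$center, y_scale = model$y_scaler$scale,
      feature_names = model$feature_names
    ),
    anfis = list(
      class = "anfis",
      r = model$r, centers = model$centers, spreads = model$spreads,
      consequents = model$consequents, trained_epochs = model$trained_epochs,
      x_center = model$x_scaler$center, x_scale = model$x_scaler$scale,
      feature_names = model$feature_names
    ),
    stop("elm_save(): unsupported model class ", cls, call. = FALSE)
  )
  # digits = NA writes full double precision: round trip is value-exact
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname elm_save
#' @export
elm_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(p$class,
    elm = {
      # rebuild row-major regardless of how simplifyVector collapsed it
      W <- matrix(as.numeric(unlist(p$W)), nrow = as.integer(p$L),
                  ncol = as.integer(p$d), byrow = !is.matrix(p$W))
      if (is.matrix(p$W)) W[] <- p$W
      hidden <- structure(list(W = W, b = as.numeric(p$b),
                               activation = p$activation,
                               L = as.integer(p$L), d = as.integer(p$d),
                               seed = p$seed),
                          class = "elm_hidden")
      structure(list(hidden = hidden, beta = as.numeric(p$beta),
                     scaler = list(center = as.numeric(p$scaler_center),
                                   scale = as.numeric(p$scaler_scale)),
                     d = as.integer(p$d), feature_names = p$feature_names,
                     standardize = TRUE),
                class = "elm")
    },
    linear_baseline = structure(
      list(coefficients = as.numeric(p$coefficients),
           intercept = as.numeric(p$intercept),
           feature_names = p$feature_names),
      class = "linear_baseline"),
    nn_bp = structure(
      list(W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
           W2 = as.numeric(p$W2), b2 = as.numeric(p$b2),
           hidden_nodes = as.integer(p$hidden_nodes),
           learning_rate = p$learning_rate, epochs = as.integer(p$epochs),
           seed = p$seed, loss_curve = as.numeric(p$loss_curve),
           x_scaler = list(center = as.numeric(p$x_center),
                           scale = as.numeric(p$x_scale)),
           y_scaler = list(center = as.numeric(p$y_center),
                           scale = as.numeric(p$y_scale)),
           feature_names = p$feature_names),
      class = "nn_bp"),
    anfis = structure(
      list(r = as.integer(p$r), centers = as.matrix(p$centers),
           spreads = as.matrix(p$spreads),
           consequents = as.matrix(p$consequents),
           trained_epochs = as.integer(p$trained_epochs),
           x_scaler = list(center = as.numeric(p$x_center),
                           scale = as.numeric(p$x_scale)),
           feature_names = p$feature_names),
      class = "anfis"),
    stop("elm_load(): unknown model class in file", call. = FALSE)
  )
}
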