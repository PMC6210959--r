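#' Published ELM performance tables for the four Nakdong weirs
#'
#' The study's printed per-weir performance of the two feature designs
#' (R-squared, RMSE and AIC on the training and testing halves), shipped as
#' a plain-text fixture. These are inputs for the feature-design improvement
#' arithmetic; the underlying monitoring data are not public, so the table
#' values themselves are not recomputable here.
#'
#' @return data frame with columns `weir, model, r2_train, r2_test,
#'   rmse_train, rmse_test, aic_train, aic_test`.
#' @export
published_elm_reports <- function() {
  utils::read.csv(system.file("extdata", "published_elm_reports.csv",
                              package = "elmbloom", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Feature-design improvement percentages from the published tables
#'
#' Applies [improvement_percent()] to the published per-weir reports:
#' the percentage change in R-squared and RMSE when the lagged upstream
#' chlorophyll-a covariate is added to the feature design.
#'
#' @return data frame with one row per weir and metric: columns `weir,
#'   metric, before, after, improvement_pct`.
#' @export
published_improvements <- function() {
  tab <- published_elm_reports()
  out <- lapply(unique(tab$weir), function(w) {
    mk <- function(model) {
      row <- tab[tab$weir == w & tab$model == model, ]
      fit_report(model, row$r2_train, row$r2_test, row$rmse_train,
                 row$rmse_test, row$aic_train, row$aic_test, NA, 1L)
    }
    imp <- improvement_percent(mk("ELM1"), mk("ELM2"))
    cbind(weir = w, as.data.frame(imp))
  })
  do.call(rbind, out)
}
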