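#' @section Weekly series data model:
#' A site series is an ordered weekly record of the seven model variables at
#' one monitoring station: AT (air temperature, weekly mean, deg C), RF
#' (rainfall, weekly accumulation, mm), SR (solar radiation, weekly mean,
#' MJ/m2), TN (total nitrogen, mg/L), TP (total phosphorus, mg/L), NP (the
#' dimensionless TN/TP ratio) and Chla (chlorophyll-a, ug/L).
#' @name elmbloom-data
#' @keywords internal
NULL

WEEKLY_COLS <- c("AT", "RF", "SR", "TN", "TP", "NP", "Chla")

#' Construct a weekly site series
#'
#' @param records data frame with columns `week_start` (Date) and the weekly
#'   variables `AT, RF, SR, TN, TP, NP, Chla` (NP recomputed from TN/TP when
#'   absent).
#' @param site_id label for the monitoring site.
#' @return a `"site_series"`: data frame sorted by `week_start` with
#'   attribute `site_id`.
#' @export
site_series <- function(records, site_id = "site") {
  records <- as.data.frame(records)
  if (!"week_start" %in% names(records))
    stop("site_series(): missing column 'week_start'", call. = FALSE)
  records$week_start <- as.Date(records$week_start)
  if (!"NP" %in% names(records)) records$NP <- records$TN / records$TP
  need <- setdiff(c("week_start", WEEKLY_COLS), names(records))
  if (length(need))
    stop("site_series(): missing column(s) ", paste(need, collapse = ", "),
         call. = FALSE)
  records <- records[order(records$week_start),
                     c("week_start", WEEKLY_COLS), drop = FALSE]
  if (anyDuplicated(records$week_start))
    stop("site_series(): duplicated week_start dates", call. = FALSE)
  rownames(records) <- NULL
  validate_site_series(records)
  structure(records, site_id = site_id,
            class = c("site_series", "data.frame"))
}

validate_site_series <- function(records) {
  bad_np <- which(is.finite(records$NP) & is.finite(records$TN) &
                  is.finite(records$TP) &
                  abs(records$NP - records$TN / records$TP) >
                    1e-6 * pmax(abs(records$NP), 1))
  if (length(bad_np))
    stop("site_series(): NP inconsistent with TN/TP at row(s) ",
         paste(utils::head(bad_np, 5), collapse = ", "), call. = FALSE)
  if (any(records$Chla < 0, na.rm = TRUE))
    stop("site_series(): negative Chla", call. = FALSE)
  if (any(records$RF < 0, na.rm = TRUE))
    stop("site_series(): negative rainfall", call. = FALSE)
  if (any(is.finite(records$NP) & is.finite(records$TP) & records$TP <= 0))
    stop("site_series(): TP must be > 0 where NP is present", call. = FALSE)
  invisible(records)
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("Weekly site series '%s': %d weeks (%s to %s)\n",
              attr(x, "site_id"), nrow(x),
              format(min(x$week_start)), format(max(x$week_start))))
  gaps <- diff(as.integer(x$week_start))
  if (any(gaps != 7))
    cat(sprintf("  note: %d non-7-day gap(s) between consecutive weeks\n",
                sum(gaps != 7)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Read a weekly site CSV
#'
#' Expects header `week_start,AT,RF,SR,TN,TP,NP,Chla` (ISO-8601 dates; the
#' `NP` column is optional and recomputed from TN/TP when absent). Rows are
#' returned sorted by `week_start`.
#'
#' @param path CSV file path.
#' @param site_id site label; defaults to the file name without extension.
#' @return a `"site_series"`.
#' @export
read_weekly_csv <- function(path, site_id = NULL) {
  if (!file.exists(path))
    stop("read_weekly_csv(): file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  mandatory <- c("week_start", setdiff(WEEKLY_COLS, "NP"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("read_weekly_csv(): missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- intersect(WEEKLY_COLS, names(raw))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !(raw[[cc]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf(
        "read_weekly_csv(): unparsable numeric value '%s' in column %s, line %d",
        raw[[cc]][bad[1L]], cc, bad[1L] + 1L), call. = FALSE)
    raw[[cc]] <- v
  }
  ws <- as.Date(raw$week_start)
  if (anyNA(ws))
    stop("read_weekly_csv(): unparsable week_start date, line ",
         which(is.na(ws))[1L] + 1L, call. = FALSE)
  raw$week_start <- ws
  if (is.null(site_id)) {
    site_id <- if ("site" %in% names(raw) && length(unique(raw$site)) == 1L)
      raw$site[1L] else sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  }
  site_series(raw[, intersect(c("week_start", WEEKLY_COLS), names(raw))],
              site_id = site_id)
}

#' Write a weekly site CSV
#'
#' Numeric fields are written at full double precision so that
#' `read_weekly_csv(write_weekly_csv(x))` round-trips exactly.
#'
#' @param series a `"site_series"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weekly_csv <- function(series, path) {
  stopifnot(inherits(series, "site_series"))
  out <- as.data.frame(series)
  out$week_start <- format(out$week_start, "%Y-%m-%d")
  for (cc in WEEKLY_COLS) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate daily weather to weekly records
#'
#' Weekly air temperature and solar radiation are the means of the available
#' daily values; weekly rainfall is the accumulated total. Calendar weeks are
#' anchored on `week_anchor`; weeks with no daily records are omitted.
#'
#' @param daily data frame with columns `date`, `air_temp` (deg C),
#'   `rainfall` (mm/day), `solar` (MJ/m2/day).
#' @param week_anchor weekday that starts each week (default `"Monday"`).
#' @return data frame with columns `week_start, AT, RF, SR`.
#' @export
aggregate_daily_to_weekly <- function(daily, week_anchor = "Monday") {
  daily <- as.data.frame(daily)
  if (nrow(daily) == 0L)
    stop("aggregate_daily_to_weekly(): empty daily input", call. = FALSE)
  need <- setdiff(c("date", "air_temp", "rainfall", "solar"), names(daily))
  if (length(need))
    stop("aggregate_daily_to_weekly(): missing column(s) ",
         paste(need, collapse = ", "), call. = FALSE)
  d <- as.Date(daily$date)
  if (any(daily$rainfall < 0, na.rm = TRUE))
    stop("aggregate_daily_to_weekly(): negative rainfall", call. = FALSE)
  anchors <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
               "Saturday", "Sunday")
  week_anchor <- match.arg(week_anchor, anchors)
  # day-of-week with Monday = 0, shift so anchor = 0
  dow <- (as.integer(d) + 3L) %% 7L
  shift <- (dow - (match(week_anchor, anchors) - 1L)) %% 7L
  week_start <- d - shift
  agg <- function(v, f) tapply(v, week_start, f, na.rm = TRUE)
  out <- data.frame(
    week_start = as.Date(names(agg(daily$air_temp, mean))),
    AT = as.numeric(agg(daily$air_temp, mean)),
    RF = as.numeric(agg(daily$rainfall, sum)),
    SR = as.numeric(agg(daily$solar, mean))
  )
  out[order(out$week_start), , drop = FALSE]
}

#' Assemble a supervised predictor/target set
#'
#' Builds the design used by the chlorophyll-a models. For target week `t`
#' the predictors are the contemporaneous drivers `AT(t), RF(t), SR(t),
#' TN(t), TP(t), NP(t)` plus the one-week-lagged (7 days prior) downstream
#' chlorophyll `Chla_lag1 = Chla(t-1)`; the `"ELM2"` variant appends the
#' lagged upstream chlorophyll `Chla_u_lag1 = Chla_u(t-1)`. The lagged value
#' must come from the calendar week exactly 7 days earlier; rows with any
#' missing predictor or target are dropped.
#'
#' @param down downstream `"site_series"` (holds the target).
#' @param variant `"ELM1"` (7 predictors), `"ELM2"` (adds upstream lagged
#'   chlorophyll, 8 predictors) or `"custom"`.
#' @param up upstream `"site_series"`; required for `"ELM2"`.
#' @param extra optional named list of extra feature vectors aligned with
#'   `down$week_start` (e.g. a water-residence-time series); appended after
#'   the canonical columns.
#' @return a `"supervised_set"`: list with `X` (N x d matrix), `T` (targets,
#'   ug/L), `feature_names`, `week_index` (Date), `variant`.
#' @export
assemble_features <- function(down, variant = c("ELM1", "ELM2", "custom"),
                              up = NULL, extra = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(down, "site_series"))
  if (variant == "ELM2" && is.null(up))
    stop("assemble_features(): variant ELM2 requires an upstream series",
         call. = FALSE)
  dd <- as.data.frame(down)
  lag_map <- function(series) {
    s <- as.data.frame(series)
    stats::setNames(s$Chla, format(s$week_start, "%Y-%m-%d"))
  }
  chla_down <- lag_map(down)
  prev_key <- format(dd$week_start - 7L, "%Y-%m-%d")
  X <- cbind(AT = dd$AT, RF = dd$RF, SR = dd$SR,
             TN = dd$TN, TP = dd$TP, NP = dd$NP,
             Chla_lag1 = unname(chla_down[prev_key]))
  if (variant == "ELM2") {
    if (!inherits(up, "site_series"))
      stop("assemble_features(): 'up' must be a site_series", call. = FALSE)
    chla_up <- lag_map(up)
    X <- cbind(X, Chla_u_lag1 = unname(chla_up[prev_key]))
  }
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("assemble_features(): 'extra' features must be named", call. = FALSE)
    for (nm in names(extra)) {
      v <- extra[[nm]]
      if (length(v) != nrow(dd))
        stop("assemble_features(): extra feature '", nm,
             "' length != number of downstream weeks", call. = FALSE)
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  T <- dd$Chla
  keep <- stats::complete.cases(X) & !is.na(T)
  if (sum(keep) < 2L)
    stop("assemble_features(): fewer than 2 usable weeks", call. = FALSE)
  structure(list(X = X[keep, , drop = FALSE], T = T[keep],
                 feature_names = colnames(X),
                 week_index = dd$week_start[keep], variant = variant),
            class = "supervised_set")
}

#' @export
print.supervised_set <- function(x, ...) {
  cat(sprintf("Supervised set (%s): N = %d, d = %d\n",
              x$variant, length(x$T), ncol(x$X)))
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Export a supervised set as CSV
#'
#' Writes `week_start,<feature_names...>,target` at full precision.
#' @param set a `"supervised_set"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_supervised_csv <- function(set, path) {
  out <- data.frame(week_start = format(set$week_index, "%Y-%m-%d"))
  for (j in seq_along(set$feature_names))
    out[[set$feature_names[j]]] <- sprintf("%.17g", set$X[, j])
  out$target <- sprintf("%.17g", set$T)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

subset_supervised <- function(set, idx) {
  structure(list(X = set$X[idx, , drop = FALSE], T = set$T[idx],
                 feature_names = set$feature_names,
                 week_index = set$week_index[idx], variant = set$variant),
            class = "supervised_set")
}

#' Split a supervised set 50/50 into train and test halves
#'
#' The study protocol: half the weeks train the model, the other half
#' measure prediction skill. `"chronological"` (the default) gives the first
#' `ceiling(N/2)` weeks to training — the natural choice for an
#' autocorrelated series, avoiding temporal leakage. `"random"` permutes the
#' rows uniformly under `seed` first; within each half the week order is
#' preserved.
#'
#' @param set a `"supervised_set"` with at least 4 rows.
#' @param mode `"chronological"` or `"random"`.
#' @param seed integer seed for `"random"` mode.
#' @return a `"train_test_split"`: list with `train`, `test`
#'   (supervised sets), `mode`, `seed`.
#' @export
split_half <- function(set, mode = c("chronological", "random"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "supervised_set"))
  N <- length(set$T)
  if (N < 4L)
    stop("split_half(): need at least 4 rows, got ", N, call. = FALSE)
  n_train <- ceiling(N / 2)
  idx <- seq_len(N)
  if (mode == "random") {
    if (!is.null(seed)) {
      old <- local_seed(seed)
      on.exit(restore_seed(old), add = TRUE)
    }
    perm <- sample.int(N)
    tr <- sort(perm[seq_len(n_train)])
    te <- sort(perm[-seq_len(n_train)])
  } else {
    tr <- idx[seq_len(n_train)]
    te <- idx[-seq_len(n_train)]
  }
  structure(list(train = subset_supervised(set, tr),
                 test = subset_supervised(set, te),
                 mode = mode, seed = seed),
            class = "train_test_split")
}

#' @export
print.train_test_split <- function(x, ...) {
  cat(sprintf("Train/test split (%s): |train| = %d, |test| = %d\n",
              x$mode, length(x$train$T), length(x$test$T)))
  invisible(x)
}
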