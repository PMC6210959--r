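# shared fixtures, all generated in code

# minimal supervised set around arbitrary X / target vectors
make_set <- function(X, T, variant = "custom") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, T = as.numeric(T), feature_names = colnames(X),
                 week_index = as.Date("2013-01-06") + 7 * seq_along(T),
                 variant = variant),
            class = "supervised_set")
}

# small weekly data frame with exact NP consistency
weekly_df <- function(n = 10, start = as.Date("2013-01-07"), chla = NULL) {
  tn <- seq(2.0, 3.0, length.out = n)
  tp <- seq(0.04, 0.06, length.out = n)
  data.frame(week_start = start + 7 * (seq_len(n) - 1),
             AT = seq(5, 25, length.out = n),
             RF = rep(c(0, 12, 30, 5, 8), length.out = n),
             SR = seq(8, 20, length.out = n),
             TN = tn, TP = tp, NP = tn / tp,
             Chla = if (is.null(chla)) seq(5, 30, length.out = n) else chla)
}

small_series <- function(n = 10, ...) site_series(weekly_df(n, ...), "test_site")

# a small generated weir pair (memoised per seed to keep tests quick)
.pair_cache <- new.env(parent = emptyenv())
cached_pair <- function(seed = 1, ...) {
  key <- paste(seed, paste(c(...), collapse = "_"), sep = "_")
  if (is.null(.pair_cache[[key]]))
    .pair_cache[[key]] <- generate_pair(synth_config(seed = seed, ...))
  .pair_cache[[key]]
}
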