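# Morphological and entropy window statistics and the feature registry.
#
# Nine statistics per raw channel (3 sensors x 3 axes = 9 channels) plus one
# mean-magnitude feature per sensor: 81 + 3 = 84 features per window.
# Feature names follow the `<Axis>-<sensor>-<STAT>` convention, e.g.
# "Y-accelerometer-MAV", with "Total-acceleration" etc. for the magnitudes.

#' Euclidean magnitude of a 3-axis sample
#'
#' `sqrt(x^2 + y^2 + z^2)`, the total acceleration / angular rate / field
#' strength of one sensor sample.
#'
#' @param x,y,z Axis components.
#' @return Non-negative magnitude.
#' @export
#' @examples
#' magnitude(3, 4, 0) # 5
magnitude <- function(x, y, z) {
  sqrt(x^2 + y^2 + z^2)
}

check_nonempty <- function(x) {
  if (length(x) == 0) abort("empty sample vector", class = "sitsense_empty")
}

#' Window statistics
#'
#' The per-window statistics of the feature bank. All moment statistics use
#' the population convention (divisor N). `skewness()` is the standardized
#' third moment; `as_printed = TRUE` divides the central third moment by
#' sigma instead of sigma^3 (a non-standard variant kept for comparison).
#' `wavelet_entropy()` is the Shannon entropy (natural log) of the window's
#' relative energy distribution `p_i = x_i^2 / sum(x^2)`, in `[0, ln N]`;
#' an all-zero window has no energy and returns 0. `log_energy_entropy()`
#' is `sum(log2(x_i^2 + eps))` and `harmonic_mean()` is
#' `N / sum(1 / (|x_i| + eps))` (absolute values, since channels are
#' signed), both with a small `eps` guarding zeros.
#'
#' @param x Numeric sample vector.
#' @param as_printed Skewness only: divide by sigma rather than sigma^3.
#' @param eps Zero guard for the logarithm / reciprocal.
#' @return A single numeric value.
#' @name window_stats
NULL

#' @rdname window_stats
#' @export
#' @examples
#' mav(c(1, -2, 3)) # 2
mav <- function(x) {
  check_nonempty(x)
  mean(abs(x))
}

#' @rdname window_stats
#' @export
variance_pop <- function(x) {
  check_nonempty(x)
  mean((x - mean(x))^2)
}

#' @rdname window_stats
#' @export
sd_pop <- function(x) {
  sqrt(variance_pop(x))
}

#' @rdname window_stats
#' @export
skewness <- function(x, as_printed = FALSE) {
  check_nonempty(x)
  mu <- mean(x)
  sigma <- sd_pop(x)
  if (sigma == 0) {
    return(0) # degenerate constant window
  }
  m3 <- mean((x - mu)^3)
  if (as_printed) m3 / sigma else m3 / sigma^3
}

#' @rdname window_stats
#' @export
rms <- function(x) {
  check_nonempty(x)
  sqrt(mean(x^2))
}

#' @rdname window_stats
#' @export
ssi <- function(x) {
  check_nonempty(x)
  sum(x^2)
}

#' @rdname window_stats
#' @export
wavelet_entropy <- function(x) {
  check_nonempty(x)
  e <- x^2
  tot <- sum(e)
  if (tot == 0) {
    return(0)
  }
  p <- e / tot
  p <- p[p > 0] # 0 * log(0) := 0
  -sum(p * log(p))
}

#' @rdname window_stats
#' @export
log_energy_entropy <- function(x, eps = 1e-12) {
  check_nonempty(x)
  sum(log2(x^2 + eps))
}

#' @rdname window_stats
#' @export
harmonic_mean <- function(x, eps = 1e-12) {
  check_nonempty(x)
  length(x) / sum(1 / (abs(x) + eps))
}

# stat id -> function, in registry order
stat_funs <- list(
  MAV = mav, HM = harmonic_mean, Var = variance_pop, SD = sd_pop,
  skewness = skewness, RMS = rms, SSI = ssi, WE = wavelet_entropy,
  LEE = log_energy_entropy
)

sensor_long <- c(
  a = "accelerometer", g = "gyroscope", m = "magnetometer"
)
magnitude_feature_names <- c(
  amag = "Total-acceleration", gmag = "Total-gyroscope",
  mmag = "Total-magnetometer"
)

channel_feature_prefix <- function(ch) {
  # "ax" -> "X-accelerometer"
  paste0(toupper(substr(ch, 2, 2)), "-", sensor_long[[substr(ch, 1, 1)]])
}

#' The feature registry
#'
#' The default bank: 9 statistics (MAV, HM, Var, SD, skewness, RMS, SSI, WE,
#' LEE) on each of the 9 raw channels, plus the window-mean of each sensor's
#' magnitude channel — 84 named features.
#'
#' @param sensors Subset of `c("accelerometer", "gyroscope", "magnetometer")`
#'   to include.
#' @return Tibble with `name`, `channel`, `stat`, `sensor`.
#' @export
#' @examples
#' nrow(feature_registry()) # 84
feature_registry <- function(sensors = c("accelerometer", "gyroscope", "magnetometer")) {
  sensors <- match.arg(sensors, several.ok = TRUE)
  chans <- raw_channels
  grid <- tidyr::expand_grid(channel = chans, stat = names(stat_funs))
  grid$sensor <- sensor_long[substr(grid$channel, 1, 1)]
  grid$name <- paste0(
    vapply(grid$channel, channel_feature_prefix, character(1)), "-", grid$stat
  )
  mags <- tibble(
    channel = names(magnitude_feature_names),
    stat = "mean",
    sensor = c("accelerometer", "gyroscope", "magnetometer"),
    name = unname(magnitude_feature_names)
  )
  out <- bind_rows(grid[c("name", "channel", "stat", "sensor")], mags)
  out[out$sensor %in% sensors, ]
}

#' The published 27-feature preset
#'
#' The 27-feature subset reported (with contribution ratings) by the
#' smartphone sitting-behavior study this pipeline models, shipped so the
#' classification stage can be run "as published" on synthetic data,
#' independently of the CFS/PSO search.
#'
#' @return Character vector of 27 feature names.
#' @export
published_feature_subset <- function() {
  c(
    "Total-acceleration", "Total-magnetometer",
    "Y-accelerometer-MAV", "X-gyroscope-MAV", "Y-gyroscope-MAV",
    "Y-magnetometer-MAV",
    "X-accelerometer-HM", "X-gyroscope-HM",
    "Y-accelerometer-Var", "Z-accelerometer-Var", "Z-magnetometer-Var",
    "X-gyroscope-SD", "Y-gyroscope-SD", "X-magnetometer-SD",
    "Z-magnetometer-SD",
    "Z-accelerometer-skewness", "X-gyroscope-skewness",
    "Y-gyroscope-skewness", "Z-gyroscope-skewness",
    "Y-magnetometer-skewness",
    "Y-accelerometer-LEE", "Y-magnetometer-LEE",
    "X-gyroscope-SSI",
    "X-accelerometer-WE", "X-gyroscope-WE", "X-magnetometer-WE",
    "Y-magnetometer-WE"
  )
}

#' Extract the feature matrix from windows
#'
#' Applies every registry statistic to every window. Any non-finite value
#' aborts, naming the offending feature and window.
#'
#' @param windows Window tibble from [make_windows()].
#' @param registry Feature registry tibble (default [feature_registry()]).
#' @param skewness_as_printed Use the sigma-denominator skewness variant.
#'
#' @return Tibble: `window_id`, `label`, then one column per feature.
#' @export
extract_features <- function(windows, registry = feature_registry(),
                             skewness_as_printed = FALSE) {
  stopifnot(nrow(windows) >= 1)
  sfuns <- stat_funs
  if (skewness_as_printed) {
    sfuns$skewness <- function(x) skewness(x, as_printed = TRUE)
  }
  nfeat <- nrow(registry)
  vals <- matrix(NA_real_, nrow(windows), nfeat,
    dimnames = list(NULL, registry$name)
  )
  for (j in seq_len(nfeat)) {
    ch <- registry$channel[j]
    st <- registry$stat[j]
    f <- if (st == "mean") mean else sfuns[[st]]
    vals[, j] <- vapply(
      windows$data,
      function(m) tryCatch(f(m[, ch]), error = function(e) NaN),
      numeric(1)
    )
  }
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    abort(
      paste0(
        "non-finite feature value: ", registry$name[bad[2]],
        " in window ", windows$window_id[bad[1]]
      ),
      class = "sitsense_nonfinite_feature"
    )
  }
  out <- tibble(
    window_id = windows$window_id, label = windows$label,
    as_tibble(vals)
  )
  out
}

feature_columns <- function(fm) {
  setdiff(names(fm), c("window_id", "label", "subject", "start"))
}

#' Read / write a feature-matrix CSV
#'
#' Header `window_id,label,<feature names...>`, one row per window.
#'
#' @param fm Feature matrix tibble.
#' @param path File path.
#' @return `write_feature_csv()` returns `path` invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  readr::write_csv(fm, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      window_id = readr::col_integer(),
      label = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
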