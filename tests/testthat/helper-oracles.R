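# Independent brute-force oracles, written as explicit loops so they share
# no code path with the implementation they check.

loop_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

loop_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

loop_var <- function(x) {
  m <- loop_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / length(x)
}

loop_sd <- function(x) sqrt(loop_var(x))

loop_skew <- function(x) {
  m <- loop_mean(x)
  sg <- loop_sd(x)
  if (sg == 0) {
    return(0)
  }
  s <- 0
  for (v in x) s <- s + ((v - m) / sg)^3
  s / length(x)
}

loop_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}

loop_ssi <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  s
}

loop_we <- function(x) {
  tot <- 0
  for (v in x) tot <- tot + v^2
  if (tot == 0) {
    return(0)
  }
  h <- 0
  for (v in x) {
    p <- v^2 / tot
    if (p > 0) h <- h - p * log(p)
  }
  h
}

loop_lee <- function(x, eps = 1e-12) {
  s <- 0
  for (v in x) s <- s + log2(v^2 + eps)
  s
}

loop_hm <- function(x, eps = 1e-12) {
  s <- 0
  for (v in x) s <- s + 1 / (abs(v) + eps)
  length(x) / s
}

# A valid correlation structure with random entries, built directly (not
# through build_correlation_table) so selection tests are independent of
# the discretization code.
random_corr_table <- function(p, seed) {
  set.seed(seed)
  fc <- runif(p)
  m <- matrix(runif(p * p), p, p)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  nm <- paste0("f", seq_len(p))
  structure(
    list(
      feature_class = stats::setNames(fc, nm), feature_feature = m,
      features = nm, measure = "su", bins = 10
    ),
    class = "cfs_correlations"
  )
}

# Exhaustive merit maximum computed with its own enumeration (expand.grid),
# independent of brute_force_best_subset()'s bit arithmetic.
enumerate_best_merit <- function(tab) {
  p <- length(tab$features)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  best <- -Inf
  for (i in seq_len(nrow(grid))) {
    mask <- grid[i, ]
    if (!any(mask)) next
    best <- max(best, cfs_merit(mask, tab))
  }
  best
}

# Two well-separated Gaussian classes in 2-D (class-mean gap 5 sigma).
gaussian_two_class <- function(n_per_class = 100, gap = 5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    label = rep(c("A1", "A2"), each = n_per_class),
    f1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap)),
    f2 = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap))
  )
}

# A tiny but complete simulated dataset shared by several tests.
tiny_sim <- function(seed = 42, subjects = 2, secs = 6) {
  cfg <- sim_config(
    durations_s = c(A1 = secs, A2 = secs, A3 = secs, A4 = secs, A5 = secs),
    subject_count = subjects, seed = seed
  )
  simulate_dataset(cfg)
}

tiny_feature_matrix <- function(seed = 42, subjects = 2, secs = 6) {
  rec <- tiny_sim(seed, subjects, secs)
  pre <- preprocess_recording(rec)
  extract_features(make_windows(pre))
}
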