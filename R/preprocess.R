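# Preprocessing: zero-phase low-pass denoising, max-abs normalization to
# [-1, 1], magnitude channels, and fixed-length sliding-window segmentation.

raw_channels <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
magnitude_channels <- c("amag", "gmag", "mmag")
all_channels <- c(raw_channels, magnitude_channels)

#' Window specification
#'
#' A window holds `N = round(omega_t * sample_rate_hz)` consecutive samples.
#' Defaults: 1-s windows (N = 50 at 50 Hz) with 50% overlap (stride 25) —
#' standard settings for static-posture recognition at 50 Hz.
#'
#' @param omega_t Window length, seconds.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param stride Samples between window starts (1..N).
#'
#' @return List of class `window_spec` with `omega_t`, `sample_rate_hz`,
#'   `n_samples`, `stride`.
#' @export
#' @examples
#' window_spec() # N = 50, stride 25
window_spec <- function(omega_t = 1.0, sample_rate_hz = 50, stride = 25) {
  n <- round(omega_t * sample_rate_hz)
  stopifnot(n >= 2, stride >= 1, stride <= n)
  structure(
    list(
      omega_t = omega_t, sample_rate_hz = sample_rate_hz,
      n_samples = as.integer(n), stride = as.integer(stride)
    ),
    class = "window_spec"
  )
}

#' Zero-phase low-pass denoising
#'
#' 4th-order Butterworth low-pass applied forward and backward
#' (zero phase), preserving the DC level. Static postures are sub-Hz
#' phenomena, so the default 5 Hz cutoff removes tremor and sensor noise
#' while leaving the gravity signature untouched.
#'
#' @param x Numeric signal.
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist rate.
#' @param fs Sampling rate, Hz.
#' @param order Filter order.
#'
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' denoise(rep(2, 100), cutoff_hz = 5, fs = 50) # constant preserved
denoise <- function(x, cutoff_hz = 5, fs = 50, order = 4) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort("cutoff_hz must lie in (0, fs/2)", class = "sitsense_bad_cutoff")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # filtfilt needs some run-up; pad by reflection to stabilize edges
  npad <- min(length(x) - 1, 3 * order * 10)
  xp <- c(rev(x[seq_len(npad) + 1]), x, rev(x[length(x) - seq_len(npad)]))
  yp <- signal::filtfilt(bf, xp)
  yp[npad + seq_along(x)]
}

#' Max-abs normalization to \[-1, 1\]
#'
#' Divides by the maximum absolute value so the output spans exactly
#' \[-1, 1\] (at least one sample reaches +/-1 unless the input is all
#' zero, which is returned unchanged). When `scale` is supplied — e.g. a
#' scale fit on training data only — it is used instead and the output is
#' clipped to \[-1, 1\].
#'
#' @param x Numeric signal (non-empty).
#' @param scale Optional positive divisor; default `max(abs(x))`.
#'
#' @return Normalized signal in \[-1, 1\].
#' @export
#' @examples
#' normalize(c(-2, 0, 2)) # -1 0 1
normalize <- function(x, scale = NULL) {
  stopifnot(length(x) >= 1)
  if (is.null(scale)) {
    scale <- max(abs(x))
    if (scale == 0) {
      return(x)
    }
    return(x / scale)
  }
  stopifnot(scale > 0)
  pmin(pmax(x / scale, -1), 1)
}

#' Preprocess a recording
#'
#' Denoises each raw channel, derives the per-sensor magnitude channels
#' `sqrt(x^2 + y^2 + z^2)` (after denoising, before normalization), then
#' max-abs-normalizes all 12 channels per channel and per subject.
#'
#' @param recording Recording tibble (see [generate_recording()]).
#' @param cutoff_hz Low-pass cutoff, Hz; `NULL` disables denoising.
#' @param normalize Logical; normalize channels to \[-1, 1\]?
#'
#' @return The recording with channels replaced and `amag`, `gmag`, `mmag`
#'   added.
#' @export
preprocess_recording <- function(recording, cutoff_hz = 5, normalize = TRUE) {
  fs <- attr(recording, "sample_rate_hz")
  stopifnot(!is.null(fs))
  out <- recording %>%
    group_by(.data$subject) %>%
    group_modify(function(df, key) {
      if (!is.null(cutoff_hz)) {
        for (ch in raw_channels) df[[ch]] <- denoise(df[[ch]], cutoff_hz, fs)
      }
      df$amag <- sqrt(df$ax^2 + df$ay^2 + df$az^2)
      df$gmag <- sqrt(df$gx^2 + df$gy^2 + df$gz^2)
      df$mmag <- sqrt(df$mx^2 + df$my^2 + df$mz^2)
      if (normalize) {
        for (ch in all_channels) df[[ch]] <- normalize(df[[ch]])
      }
      df
    }) %>%
    ungroup()
  attr(out, "sample_rate_hz") <- fs
  out
}

#' Segment a recording into fixed-length labelled windows
#'
#' Windows start every `stride` samples within each subject's stream. A
#' window's label is the majority per-sample label; windows that mix
#' activities (majority share below 100%) are dropped, so every retained
#' window is label-pure. Per subject, the pre-drop window count is
#' `floor((L - N) / stride) + 1`.
#'
#' @param recording (Preprocessed) recording tibble.
#' @param spec A [window_spec()].
#'
#' @return Tibble with `window_id`, `subject`, `start` (1-based sample
#'   index), `label`, and a list-column `data` of N x C channel matrices.
#'   Empty (with a warning) if the recording is shorter than N.
#' @export
make_windows <- function(recording, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  n <- spec$n_samples
  chans <- intersect(all_channels, names(recording))
  out <- vector("list", 0)
  for (sub in unique(recording$subject)) {
    df <- recording[recording$subject == sub, ]
    l <- nrow(df)
    if (l < n) {
      warn(paste0("subject ", sub, ": recording shorter than one window"))
      next
    }
    starts <- seq(1L, l - n + 1L, by = spec$stride)
    chan_mat <- as.matrix(df[chans])
    labs <- df$label
    rows <- lapply(starts, function(s) {
      idx <- s:(s + n - 1L)
      wl <- labs[idx]
      if (length(unique(wl)) != 1L) {
        return(NULL) # mixed-activity window: dropped
      }
      tibble(
        subject = sub, start = s, label = wl[1],
        data = list(chan_mat[idx, , drop = FALSE])
      )
    })
    out <- c(out, rows)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    warn("no windows produced")
    return(tibble(
      window_id = integer(), subject = integer(), start = integer(),
      label = character(), data = list()
    ))
  }
  tibble(window_id = seq_len(nrow(res)), res)
}
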