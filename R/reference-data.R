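# Reference results from a published smartphone-based sitting-behavior
# study (five postures, trunk-mounted phone, 50 Hz; the underlying human
# dataset is private).  Shipped as worked examples for the evaluation
# metrics: recomputing class recall from these matrices reproduces the
# study's per-activity accuracy tables.

#' Published reference confusion matrices
#'
#' Three confusion matrices reported by a published smartphone
#' sitting-behavior study, used as worked examples for
#' [per_activity_accuracy()] and [overall_accuracy()]:
#' \describe{
#'   \item{`svm_all_sensors`}{SVM on features selected from accelerometer +
#'     gyroscope + magnetometer.}
#'   \item{`svm_accel_gyro`}{SVM on features selected from accelerometer +
#'     gyroscope.}
#'   \item{`knn3_accel`}{KNN (K = 3) on features selected from the
#'     accelerometer only.}
#' }
#'
#' @param which One of the three ids above.
#' @return A `posture_confusion` matrix (rows = true class A1..A5).
#' @export
#' @examples
#' per_activity_accuracy(reference_confusion("svm_all_sensors"), "A4") # 99.76
reference_confusion <- function(which = c(
                                  "svm_all_sensors", "svm_accel_gyro",
                                  "knn3_accel"
                                )) {
  which <- match.arg(which)
  m <- switch(which,
    svm_all_sensors = matrix(c(
      10669, 0, 0, 0, 1,
      1, 11476, 0, 0, 0,
      1, 0, 10055, 1, 0,
      0, 0, 0, 8762, 21,
      0, 0, 2, 16, 8044
    ), 5, 5, byrow = TRUE),
    svm_accel_gyro = matrix(c(
      10341, 7, 108, 8, 185,
      3, 11460, 3, 2, 5,
      130, 2, 10038, 1, 2,
      1, 1, 0, 8746, 106,
      69, 4, 1, 59, 7868
    ), 5, 5, byrow = TRUE),
    knn3_accel = matrix(c(
      10634, 6, 18, 1, 14,
      3, 11467, 1, 0, 1,
      9, 0, 10049, 0, 1,
      1, 0, 0, 8769, 127,
      15, 1, 0, 39, 7994
    ), 5, 5, byrow = TRUE)
  )
  as_posture_confusion(m, activity_levels())
}

#' Published per-activity instance counts
#'
#' Instance counts and recording durations per activity from the same
#' published study (163,501 instances over 3272 s at 50 Hz).
#'
#' @return Tibble with `activity`, `name`, `instances`, `seconds`.
#' @export
#' @examples
#' sum(reference_instance_counts()$instances) # 163501
reference_instance_counts <- function() {
  tibble(
    activity = activity_levels(),
    name = unname(activity_names()),
    instances = c(35565L, 37757L, 33268L, 29460L, 27451L),
    seconds = c(712, 756, 665, 590, 549)
  )
}
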