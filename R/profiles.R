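#' Gaussian kernel regression smoothing of a thermogram
#'
#' Nadaraya--Watson estimate with a Gaussian kernel, evaluated on the input
#' grid itself. Used before peak extraction so that measurement noise does
#' not move the argmax.
#'
#' @param thermogram A data frame with numeric columns `temp` (strictly
#'   increasing, degrees C) and `dcp` (excess heat capacity).
#' @param bandwidth Kernel standard deviation in degrees C (> 0).
#' @return A tibble with the same `temp` grid and smoothed `dcp`.
#' @examples
#' tg <- tibble::tibble(temp = seq(45, 90, 0.5),
#'                      dcp = exp(-0.5 * ((temp - 63) / 4)^2))
#' smooth_curve(tg, bandwidth = 1)
#' @export
smooth_curve <- function(thermogram, bandwidth = 1) {
  stopifnot(is.data.frame(thermogram),
            all(c("temp", "dcp") %in% names(thermogram)))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
    abort("`bandwidth` must be a single value > 0",
          class = "rankcbr_invalid_parameter")
  }
  tibble::tibble(
    temp = thermogram$temp,
    dcp = smooth_vec(thermogram$temp, thermogram$dcp, bandwidth)
  )
}

smooth_vec <- function(temps, y, bandwidth) {
  w <- dnorm(outer(temps, temps, "-") / bandwidth)
  as.vector((w %*% y) / rowSums(w))
}

#' Extract the six thermogram features of one cohort
#'
#' For each subject, the curve is smoothed by Gaussian kernel regression and
#' six features are extracted:
#' \describe{
#'   \item{IR}{initial response: 1 if the least-squares slope of the smoothed
#'     curve over the first `initial_window` degrees C is positive, else 0
#'     (a flat start counts as non-increasing).}
#'   \item{T1, PEAK1}{location and height of the maximum of the smoothed
#'     curve restricted to \[45, 55\] degrees C.}
#'   \item{T2, PEAK2}{location and height of the maximum restricted to
#'     (55, 90\] degrees C.}
#'   \item{IND}{the raw (unsmoothed) curve, kept as a list-column of numeric
#'     vectors; this is the default measurement that enters the Frechet
#'     distance.}
#' }
#' Argmax plateaus resolve to the lowest temperature, so extraction is
#' deterministic and grid-stable.
#'
#' @param cohort A cohort tibble from [generate_cohort()] / [read_cohort()].
#' @param bandwidth Smoothing bandwidth in degrees C (default 1).
#' @param initial_window Width in degrees C of the window used for the IR
#'   slope (default 2, i.e. the first 21 points of the 0.1-degree grid).
#' @return A tibble with columns `subject_id`, `label`, `IR`, `T1`, `T2`,
#'   `PEAK1`, `PEAK2` and list-column `IND`; the temperature grid is attached
#'   as attribute `"temps"`.
#' @export
extract_features <- function(cohort, bandwidth = 1, initial_window = 2) {
  temps <- cohort_temps(cohort)
  curves <- cohort_matrix(cohort)
  w1 <- temps >= 45 & temps <= 55
  w2 <- temps > 55 & temps <= 90
  if (!any(w1) || !any(w2)) {
    abort("temperature grid must cover both the [45, 55] and (55, 90] windows",
          class = "rankcbr_coverage_error")
  }
  init <- temps <= temps[1] + initial_window
  if (sum(init) < 2) init <- seq_along(temps) <= 2
  feats <- purrr::map(seq_len(nrow(curves)), function(i) {
    y <- smooth_vec(temps, curves[i, ], bandwidth)
    i1 <- which(w1)[which.max(y[w1])]
    i2 <- which(w2)[which.max(y[w2])]
    slope <- stats::cov(temps[init], y[init]) / stats::var(temps[init])
    list(IR = as.numeric(slope > 0),
         T1 = temps[i1], T2 = temps[i2],
         PEAK1 = y[i1], PEAK2 = y[i2])
  })
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id, label = cohort$label),
    purrr::map_dfr(feats, tibble::as_tibble)
  )
  out$IND <- lapply(seq_len(nrow(curves)), function(i) unname(curves[i, ]))
  attr(out, "temps") <- temps
  out
}

#' Write / read an extracted feature table
#'
#' The scalar features go to a CSV with header
#' `subject_id,label,IR,T1,T2,PEAK1,PEAK2`; the raw curves (the IND feature)
#' go to a sidecar file in the cohort CSV layout so the pair round-trips the
#' full feature table.
#'
#' @param features A feature tibble from [extract_features()].
#' @param path Path for the scalar feature CSV.
#' @param curves_path Path for the IND sidecar CSV.
#' @return `write_features()` returns `features` invisibly; `read_features()`
#'   returns a feature tibble.
#' @export
write_features <- function(features, path, curves_path) {
  readr::write_csv(
    features[, c("subject_id", "label", "IR", "T1", "T2", "PEAK1", "PEAK2")],
    path
  )
  temps <- attr(features, "temps")
  curves <- do.call(rbind, features$IND)
  colnames(curves) <- paste0("T", format_temp(temps))
  write_cohort(
    dplyr::bind_cols(
      tibble::tibble(subject_id = features$subject_id, label = features$label),
      tibble::as_tibble(curves)
    ),
    curves_path
  )
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path, curves_path) {
  scalars <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), label = readr::col_character(),
    .default = readr::col_double()
  ), show_col_types = FALSE)
  need <- c("subject_id", "label", "IR", "T1", "T2", "PEAK1", "PEAK2")
  if (!all(need %in% names(scalars))) {
    abort("feature CSV must have columns subject_id,label,IR,T1,T2,PEAK1,PEAK2",
          class = "rankcbr_parse_error")
  }
  sidecar <- read_cohort(curves_path)
  if (!identical(sidecar$subject_id, scalars$subject_id)) {
    abort("curve sidecar subject ids do not match the feature CSV",
          class = "rankcbr_parse_error")
  }
  curves <- cohort_matrix(sidecar)
  out <- scalars
  out$IND <- lapply(seq_len(nrow(curves)), function(i) unname(curves[i, ]))
  attr(out, "temps") <- cohort_temps(sidecar)
  out
}
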