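#' Per-class peak geometry for the synthetic thermogram generator
#'
#' Plasma thermograms typically show one or two peaks over the 45--90 degree C
#' scan: a lower-temperature peak (fibrinogen/IgG region, roughly 45--55) and
#' a dominant albumin-region peak above 55. Each class of a synthetic cohort
#' is described by the centres, widths and amplitudes of these two Gaussian
#' bumps, the probability that a subject presents a single-peaked profile,
#' and the between-subject jitter of the peak locations.
#'
#' @param mu1,mu2 Peak-centre temperatures in degrees C. `mu1` must lie in
#'   \[45, 55\] and `mu2` in \[56, 90\], matching the feature windows used by
#'   [extract_features()].
#' @param sd1,sd2 Peak widths (Gaussian standard deviations) in degrees C;
#'   strictly positive.
#' @param amp1,amp2 Peak heights in excess-heat-capacity units; strictly
#'   positive.
#' @param p_single_peak Probability in \[0, 1\] that a subject's second peak
#'   is suppressed entirely.
#' @param jitter_sd Standard deviation (degrees C) of the per-subject random
#'   shifts of the peak centres; the two peaks are jittered independently,
#'   since the underlying denaturation transitions involve different protein
#'   fractions.
#' @param p_neg_start Probability in \[0, 1\] that the subject's profile
#'   starts with a decreasing tendency (a decaying low-temperature shoulder
#'   is added), the negative initial-response phenotype picked up by the IR
#'   feature.
#'
#' @return A list of class `peak_params`.
#' @seealso [cohort_spec()], [generate_cohort()]
#' @export
peak_params <- function(mu1 = 50, mu2 = 63, sd1 = 2.5, sd2 = 4,
                        amp1 = 3.5, amp2 = 5,
                        p_single_peak = 0.1, jitter_sd = 1.5,
                        p_neg_start = 0.1) {
  stopifnot(is.numeric(mu1), is.numeric(mu2))
  if (mu1 < 45 || mu1 > 55) {
    abort("`mu1` must lie in [45, 55] degrees C", class = "rankcbr_invalid_spec")
  }
  if (mu2 < 56 || mu2 > 90) {
    abort("`mu2` must lie in [56, 90] degrees C", class = "rankcbr_invalid_spec")
  }
  if (any(c(sd1, sd2, amp1, amp2) <= 0)) {
    abort("peak widths and amplitudes must be > 0", class = "rankcbr_invalid_spec")
  }
  if (p_single_peak < 0 || p_single_peak > 1) {
    abort("`p_single_peak` must lie in [0, 1]", class = "rankcbr_invalid_spec")
  }
  if (p_neg_start < 0 || p_neg_start > 1) {
    abort("`p_neg_start` must lie in [0, 1]", class = "rankcbr_invalid_spec")
  }
  if (jitter_sd < 0) {
    abort("`jitter_sd` must be >= 0", class = "rankcbr_invalid_spec")
  }
  structure(
    list(mu1 = mu1, mu2 = mu2, sd1 = sd1, sd2 = sd2, amp1 = amp1,
         amp2 = amp2, p_single_peak = p_single_peak, jitter_sd = jitter_sd,
         p_neg_start = p_neg_start),
    class = "peak_params"
  )
}

#' Specification of a synthetic two-class thermogram cohort
#'
#' Describes a cohort of subjects whose excess heat capacity curves are
#' simulated on a fixed temperature grid. The defaults emulate the study
#' conditions of a 70-subject cervical-carcinoma screening cohort: a balanced
#' two-class design on a 451-point grid from 45 to 90 degrees C, with the
#' cancer class shifted in its second peak location and peak-height balance,
#' and substantial between-subject variability in both classes.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param cancer_fraction Proportion of subjects labelled `"cancer"`;
#'   `round(n_subjects * cancer_fraction)` subjects receive the label, exactly.
#' @param grid_start,grid_end Temperature range in degrees C
#'   (`grid_start < grid_end`).
#' @param grid_length Number of grid points (>= 2); the default 451 gives
#'   0.1-degree steps over 45--90.
#' @param control,cancer Per-class [peak_params()].
#' @param noise_sd Standard deviation of i.i.d. measurement noise added to
#'   each grid point (heat-capacity units).
#' @param subject_sd Spread of the per-subject positive scale factor: each
#'   curve is multiplied by `exp(rnorm(1, 0, subject_sd))`, so `subject_sd = 0`
#'   means no between-subject amplitude variation.
#' @param seed Integer root seed. Each subject draws from an independent
#'   substream derived from `seed` and the subject index, so subject `i`'s
#'   curve does not change when `n_subjects` changes.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 70, cancer_fraction = 0.5,
                        grid_start = 45, grid_end = 90, grid_length = 451,
                        control = peak_params(mu1 = 50, mu2 = 62.5,
                                              sd1 = 2.5, sd2 = 4,
                                              amp1 = 3.5, amp2 = 5,
                                              p_single_peak = 0.2,
                                              jitter_sd = 2,
                                              p_neg_start = 0.15),
                        cancer = peak_params(mu1 = 50, mu2 = 66.5,
                                             sd1 = 2.5, sd2 = 4,
                                             amp1 = 3.5, amp2 = 5,
                                             p_single_peak = 0.2,
                                             jitter_sd = 2,
                                             p_neg_start = 0.3),
                        noise_sd = 0.3, subject_sd = 0.4, seed = 20180531) {
  if (!is.numeric(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects)) {
    abort("`n_subjects` must be a positive integer", class = "rankcbr_invalid_spec")
  }
  if (cancer_fraction < 0 || cancer_fraction > 1) {
    abort("`cancer_fraction` must lie in [0, 1]", class = "rankcbr_invalid_spec")
  }
  if (grid_start >= grid_end) {
    abort("`grid_start` must be < `grid_end`", class = "rankcbr_invalid_spec")
  }
  if (!is.numeric(grid_length) || grid_length < 2 || grid_length != round(grid_length)) {
    abort("`grid_length` must be an integer >= 2", class = "rankcbr_invalid_spec")
  }
  if (noise_sd < 0 || subject_sd < 0) {
    abort("`noise_sd` and `subject_sd` must be >= 0", class = "rankcbr_invalid_spec")
  }
  stopifnot(inherits(control, "peak_params"), inherits(cancer, "peak_params"))
  structure(
    list(n_subjects = as.integer(n_subjects), cancer_fraction = cancer_fraction,
         grid_start = grid_start, grid_end = grid_end,
         grid_length = as.integer(grid_length),
         control = control, cancer = cancer,
         noise_sd = noise_sd, subject_sd = subject_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Substream seed for subject i: a counter-mixed function of the root seed,
# kept inside 32-bit integer range.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

unit_gauss <- function(x, mu, sd) exp(-0.5 * ((x - mu) / sd)^2)

#' Generate a synthetic thermogram cohort
#'
#' Simulates one excess-heat-capacity curve per subject: a sum of one or two
#' Gaussian bumps with per-subject jittered centres, multiplied by a
#' per-subject log-normal scale factor, plus i.i.d. Gaussian measurement
#' noise, clipped at zero from below (excess heat capacity is reported
#' nonnegative). The same `cohort_spec` (including its seed) always yields a
#' bitwise-identical cohort.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A tibble with one row per subject: `subject_id`, `label`
#'   (`"control"` or `"cancer"`), then one numeric column per grid point named
#'   `T<temperature>` (e.g. `T45`, `T45.1`, ..., `T90`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 8, grid_length = 51))
#' dplyr::count(cohort, label)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  temps <- seq(spec$grid_start, spec$grid_end, length.out = spec$grid_length)
  n_cancer <- round(spec$n_subjects * spec$cancer_fraction)
  labels <- c(rep("cancer", n_cancer), rep("control", spec$n_subjects - n_cancer))
  curves <- matrix(0, nrow = spec$n_subjects, ncol = spec$grid_length)
  for (i in seq_len(spec$n_subjects)) {
    pp <- if (labels[i] == "cancer") spec$cancer else spec$control
    curves[i, ] <- withr::with_seed(subject_seed(spec$seed, i), {
      # the two transitions reflect different protein fractions, so their
      # per-subject location jitters are drawn independently
      jitter1 <- if (pp$jitter_sd > 0) stats::rnorm(1, 0, pp$jitter_sd) else 0
      jitter2 <- if (pp$jitter_sd > 0) stats::rnorm(1, 0, pp$jitter_sd) else 0
      keep2 <- stats::runif(1) >= pp$p_single_peak
      neg_start <- stats::runif(1) < pp$p_neg_start
      scale <- exp(if (spec$subject_sd > 0) stats::rnorm(1, 0, spec$subject_sd) else 0)
      y <- pp$amp1 * unit_gauss(temps, pp$mu1 + jitter1, pp$sd1)
      if (keep2) y <- y + pp$amp2 * unit_gauss(temps, pp$mu2 + jitter2, pp$sd2)
      if (neg_start) {
        # decaying low-temperature shoulder: the curve enters the scanned
        # range already falling, so the initial response is negative
        y <- y + 0.5 * pp$amp1 * exp(-(temps - spec$grid_start) / 2)
      }
      y <- scale * y
      if (spec$noise_sd > 0) y <- y + stats::rnorm(length(temps), 0, spec$noise_sd)
      pmax(y, 0)
    })
  }
  colnames(curves) <- paste0("T", format_temp(temps))
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(spec$n_subjects)),
      label = labels
    ),
    tibble::as_tibble(curves)
  )
}

format_temp <- function(temps) {
  # Stable, locale-independent column labels; trailing zeros trimmed.
  out <- formatC(temps, format = "fg", digits = 10)
  gsub(" ", "", out)
}

#' Temperature grid of a cohort or thermogram matrix
#'
#' Recovers the numeric temperature grid from the `T<temperature>` column
#' names of a cohort tibble produced by [generate_cohort()] or
#' [read_cohort()].
#'
#' @param cohort A cohort tibble.
#' @return Numeric vector of temperatures in degrees C.
#' @export
cohort_temps <- function(cohort) {
  cols <- grep("^T[0-9]", names(cohort), value = TRUE)
  if (length(cols) == 0) {
    abort("no temperature columns (named like 'T45.1') found",
          class = "rankcbr_parse_error")
  }
  as.numeric(sub("^T", "", cols))
}

# Curve matrix (subjects x grid) from a cohort tibble.
cohort_matrix <- function(cohort) {
  cols <- grep("^T[0-9]", names(cohort), value = TRUE)
  as.matrix(cohort[, cols])
}

#' Write / read a thermogram cohort as CSV
#'
#' The on-disk layout is one row per subject with a header
#' `subject_id,label,T45,...,T90`; values round-trip at full double
#' precision. `read_cohort()` validates the header shape, the numeric grid
#' and the label alphabet, and reports the offending row or column on
#' failure.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param path File path.
#' @param grid_length Optional expected number of temperature columns;
#'   `read_cohort()` errors if the file disagrees.
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns a cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  readr::write_csv(cohort, path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, grid_length = NULL) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (length(header) < 3 || header[1] != "subject_id" || header[2] != "label") {
    abort("malformed header: expected 'subject_id,label,T<temp>,...'",
          class = "rankcbr_parse_error")
  }
  temp_cols <- header[-(1:2)]
  if (!all(grepl("^T[0-9.]+$", temp_cols))) {
    bad <- temp_cols[!grepl("^T[0-9.]+$", temp_cols)][1]
    abort(paste0("malformed temperature column name: '", bad, "'"),
          class = "rankcbr_parse_error")
  }
  if (!is.null(grid_length) && length(temp_cols) != grid_length) {
    abort(sprintf("expected %d temperature columns, found %d",
                  grid_length, length(temp_cols)),
          class = "rankcbr_shape_error")
  }
  cohort <- suppressWarnings(readr::read_csv(
    path,
    col_types = do.call(
      readr::cols,
      c(list(subject_id = readr::col_character(), label = readr::col_character()),
        setNames(rep(list(readr::col_double()), length(temp_cols)), temp_cols))
    ),
    show_col_types = FALSE
  ))
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    abort(sprintf("non-numeric cell at row %d, column %d ('%s')",
                  probs$row[1], probs$col[1], header[probs$col[1]]),
          class = "rankcbr_parse_error")
  }
  bad_label <- which(!cohort$label %in% cbr_classes())
  if (length(bad_label) > 0) {
    abort(sprintf("invalid label '%s' at row %d: labels must be 'control' or 'cancer'",
                  cohort$label[bad_label[1]], bad_label[1]),
          class = "rankcbr_parse_error")
  }
  temps <- as.numeric(sub("^T", "", temp_cols))
  if (is.unsorted(temps, strictly = TRUE)) {
    abort("temperature grid must be strictly increasing",
          class = "rankcbr_parse_error")
  }
  cohort
}

#' Read a cohort specification from a YAML or JSON config file
#'
#' The config mirrors the fields of [cohort_spec()] one-to-one, with the
#' per-class peak geometry nested under `control:` and `cancer:`.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A `cohort_spec`.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[setdiff(names(cfg), c("control", "cancer"))]
  if (!is.null(cfg$control)) args$control <- do.call(peak_params, cfg$control)
  if (!is.null(cfg$cancer)) args$cancer <- do.call(peak_params, cfg$cancer)
  do.call(cohort_spec, args)
}

#' Spaghetti plot of a thermogram cohort
#'
#' @param cohort A cohort tibble.
#' @param alpha Line transparency.
#' @return A ggplot object: one curve per subject, coloured by class label.
#' @export
plot_cohort <- function(cohort, alpha = 0.5) {
  long <- tidyr::pivot_longer(cohort, dplyr::matches("^T[0-9]"),
                              names_to = "temp", values_to = "dcp")
  long$temp <- as.numeric(sub("^T", "", long$temp))
  ggplot2::ggplot(long, ggplot2::aes(.data$temp, .data$dcp,
                                     group = .data$subject_id,
                                     colour = .data$label)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "Temperature (°C)",
                  y = expression(Delta * C[p]),
                  colour = "Class") +
    ggplot2::theme_minimal()
}
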