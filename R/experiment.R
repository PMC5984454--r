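cbr_models <- function() c("KNN", "SCUCC", "CLCBR", "ETCBR", "LWCBR", "RWCBR")

#' Run the full cross-validated classification experiment
#'
#' Extracts features from a thermogram cohort, partitions it into stratified
#' folds, and evaluates the requested classifiers fold by fold. Within each
#' fold the feature weights of the weighted CBR variants (ETCBR, LWCBR,
#' RWCBR) are estimated on the training cases only and then applied to
#' classify every test case; the k-NN and SCUCC baselines likewise see only
#' the training cases. The per-feature local distance tables of each test
#' case are computed once per fold and shared by all CBR variants and the
#' k-NN baseline, since weighting changes how distances combine, not the
#' distances themselves. The whole run is driven by `seed` and rerunning with
#' the same inputs is byte-identical.
#'
#' @param cohort A cohort tibble from [generate_cohort()] / [read_cohort()].
#' @param models Character vector among `"KNN"`, `"SCUCC"`, `"CLCBR"`,
#'   `"ETCBR"`, `"LWCBR"`, `"RWCBR"`.
#' @param k_folds Number of stratified folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param bandwidth Smoothing bandwidth for feature extraction (degrees C).
#' @param knn_k Neighbour count for the k-NN baseline (default 5).
#' @param cbr_k Neighbour count for the CBR variants (default 1, the
#'   classical most-similar-case retrieval).
#' @param reference Reference rule for the rank-based weights (see
#'   [rank_weights()]).
#' @return An object of class `cbr_experiment`: a list with `weights` (fold
#'   x model x feature), `fold_reports` (fold x model information indices),
#'   `summary` (MIN/AVG/STD/MAX per model and index), and the run settings.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_subjects = 20, grid_length = 51))
#' fit <- run_experiment(cohort, models = c("CLCBR", "RWCBR"), seed = 1)
#' glance(fit)
#' }
#' @export
run_experiment <- function(cohort, models = cbr_models(), k_folds = 5,
                           seed = 1, bandwidth = 1, knn_k = 5, cbr_k = 1,
                           reference = "median") {
  unknown <- setdiff(models, cbr_models())
  if (length(unknown) > 0) {
    abort(paste0("unknown model name(s): ", paste(unknown, collapse = ", ")),
          class = "rankcbr_config_error")
  }
  features <- extract_features(cohort, bandwidth = bandwidth)
  temps <- attr(features, "temps")
  folds <- stratified_kfold(features$label, k_folds = k_folds, seed = seed)
  cbr_variants <- intersect(models, c("CLCBR", "ETCBR", "LWCBR", "RWCBR"))
  weight_rows <- list()
  report_rows <- list()
  for (fold in seq_len(k_folds)) {
    train <- features[folds != fold, ]
    test <- features[folds == fold, ]
    attr(train, "temps") <- temps
    attr(test, "temps") <- temps
    w <- list()
    if ("CLCBR" %in% cbr_variants) w$CLCBR <- equal_weights(train)
    if ("ETCBR" %in% cbr_variants) w$ETCBR <- entropy_weights(train, temps = temps)
    if ("LWCBR" %in% cbr_variants) w$LWCBR <- wald_weights(train, temps = temps)
    if ("RWCBR" %in% cbr_variants) {
      w$RWCBR <- rank_weights(train, reference = reference, temps = temps)
    }
    for (m in intersect(names(w), c("ETCBR", "LWCBR", "RWCBR"))) {
      weight_rows[[length(weight_rows) + 1]] <-
        dplyr::mutate(w[[m]], fold = fold, model = m, .before = 1)
    }
    preds <- list()
    if (length(cbr_variants) > 0 || "KNN" %in% models) {
      dist_tables <- purrr::map(seq_len(nrow(test)), function(i) {
        local_distance_table(train, test[i, ], temps = temps)
      })
      for (m in cbr_variants) {
        preds[[m]] <- vapply(dist_tables, function(dt) {
          s <- global_similarity(dt, w[[m]])
          nbrs <- order(-s, seq_along(s))[seq_len(cbr_k)]
          p_cancer <- mean(train$label[nbrs] == "cancer")
          if (p_cancer > 0.5) "cancer" else "control"
        }, character(1))
      }
      if ("KNN" %in% models) {
        preds$KNN <- vapply(dist_tables, function(dt) {
          scaled <- purrr::map(dt, function(d) {
            rng <- range(d)
            if (diff(rng) == 0) rep(0, length(d)) else (d - rng[1]) / diff(rng)
          })
          total <- Reduce(`+`, scaled)
          nbrs <- order(total, seq_along(total))[seq_len(knn_k)]
          p_cancer <- mean(train$label[nbrs] == "cancer")
          if (p_cancer > 0.5) "cancer" else "control"
        }, character(1))
      }
    }
    if ("SCUCC" %in% models) {
      preds$SCUCC <- scucc_classify(train, test)$label
    }
    for (m in models) {
      cc <- confusion_counts(test$label, preds[[m]])
      idx <- suppressWarnings(information_indices(cc$tp, cc$fp, cc$fn, cc$tn))
      report_rows[[length(report_rows) + 1]] <-
        dplyr::mutate(idx, fold = fold, model = m, .before = 1)
    }
  }
  fold_reports <- dplyr::bind_rows(report_rows)
  fold_reports$model <- factor(fold_reports$model, levels = cbr_models())
  out <- list(
    weights = if (length(weight_rows) > 0) dplyr::bind_rows(weight_rows) else NULL,
    fold_reports = fold_reports,
    summary = summarize_folds(fold_reports),
    models = models, k_folds = k_folds, seed = seed,
    n_subjects = nrow(features)
  )
  class(out) <- "cbr_experiment"
  out
}

#' @export
print.cbr_experiment <- function(x, ...) {
  cat(sprintf("Cross-validated thermogram classification (%d subjects, %d folds, seed %d)\n",
              x$n_subjects, x$k_folds, x$seed))
  cat("Models:", paste(x$models, collapse = ", "), "\n\n")
  avg <- tidyr::pivot_wider(
    x$summary[, c("model", "index", "AVG")],
    names_from = "index", values_from = "AVG"
  )
  cat("Average information indices over folds:\n")
  print(as.data.frame(avg), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy the results of a classification experiment
#'
#' @param x A `cbr_experiment` from [run_experiment()].
#' @param type `"folds"` (per-fold information indices, the default),
#'   `"weights"` (per-fold estimated feature weights), or `"summary"`
#'   (MIN/AVG/STD/MAX per model and index).
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.cbr_experiment <- function(x, type = c("folds", "weights", "summary"), ...) {
  type <- match.arg(type)
  switch(type,
         folds = x$fold_reports,
         weights = x$weights %||% tibble::tibble(),
         summary = x$summary)
}

#' One-row overview of a classification experiment
#'
#' @param x A `cbr_experiment`.
#' @param ... Ignored.
#' @return A one-row tibble with the run size and the model with the best
#'   average F-1 score.
#' @export
glance.cbr_experiment <- function(x, ...) {
  f1 <- x$summary[x$summary$index == "f1", ]
  best <- f1[which.max(f1$AVG), ]
  tibble::tibble(
    n_subjects = x$n_subjects,
    k_folds = x$k_folds,
    n_models = length(x$models),
    best_model = as.character(best$model),
    best_avg_f1 = best$AVG
  )
}

#' Plot per-fold information indices by model
#'
#' @param object A `cbr_experiment`.
#' @param ... Ignored.
#' @return A ggplot object: one panel per index, per-fold points with the
#'   fold average marked per model.
#' @export
autoplot.cbr_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$fold_reports,
    dplyr::all_of(c("precision", "recall", "f1", "g")),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6,
                         ggplot2::aes(colour = .data$model)) +
    ggplot2::facet_wrap(~index) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "Index value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
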