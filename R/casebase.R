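#' Build a case-base from a feature table
#'
#' The case-base is the knowledge store of the classifier: labelled feature
#' vectors against which a target case is compared at retrieval time. It is
#' a validated feature tibble (see [extract_features()]) whose row order is
#' the insertion order -- similarity ties at retrieval resolve to the oldest
#' case, so the order matters for reproducibility.
#'
#' @param features Feature tibble with columns `subject_id`, `label`, the
#'   five scalar features and the `IND` list-column; labels must be
#'   `"control"` or `"cancer"`.
#' @return The feature tibble with class `case_base`.
#' @export
case_base <- function(features) {
  need <- c("subject_id", "label", cbr_features())
  if (!is.data.frame(features) || !all(need %in% names(features))) {
    abort("a case-base needs subject_id, label and the six features",
          class = "rankcbr_schema_error")
  }
  if (!all(features$label %in% cbr_classes())) {
    abort("labels must be 'control' or 'cancer'",
          class = "rankcbr_invalid_label")
  }
  class(features) <- unique(c("case_base", class(features)))
  features
}

#' Retrieve the most similar cases for a target
#'
#' Computes the local distance of the target to every stored case for each
#' feature, converts each feature's distances to dense ranks, combines them
#' into the weighted rank-order global similarity (see
#' [global_similarity()]), and returns the k cases with the largest
#' similarity. Ties on similarity break by insertion order (oldest case
#' first), so retrieval is deterministic.
#'
#' @param cb A [case_base()] (nonempty).
#' @param target One-row feature tibble (the target case).
#' @param weights Feature weights (tibble or named vector summing to 1).
#' @param k Number of neighbours to retrieve, `1 <= k <= nrow(cb)`.
#' @param temps Temperature grid; defaults to the case-base attribute.
#' @return A tibble of class `cbr_retrieval` with one row per retrieved
#'   neighbour: `subject_id`, `label`, `similarity`, sorted by similarity
#'   descending. The full similarity vector is attached as attribute
#'   `"similarities"`.
#' @export
retrieve <- function(cb, target, weights, k = 1, temps = attr(cb, "temps")) {
  if (!is.data.frame(cb) || nrow(cb) == 0) {
    abort("the case-base is empty", class = "rankcbr_retrieval_error")
  }
  if (k < 1 || k > nrow(cb)) {
    abort(sprintf("`k` must lie in [1, %d]", nrow(cb)),
          class = "rankcbr_retrieval_error")
  }
  dists <- local_distance_table(cb, target, temps = temps)
  s <- global_similarity(dists, weights)
  ord <- order(-s, seq_along(s))  # ties: oldest (insertion order) first
  picked <- ord[seq_len(k)]
  out <- tibble::tibble(
    subject_id = cb$subject_id[picked],
    label = cb$label[picked],
    similarity = s[picked]
  )
  attr(out, "similarities") <- s
  attr(out, "target_id") <- target$subject_id[[1]]
  class(out) <- unique(c("cbr_retrieval", class(out)))
  out
}

#' Predict the class of a target case
#'
#' k-nearest-neighbour class-conditional probability over the retrieved
#' neighbourhood: `p(j | target)` is the fraction of the k retrieved cases
#' carrying label j, and the predicted label is the argmax. An exact 50/50
#' split predicts `"control"` -- the conservative call for a diagnostic
#' screen; with the default `k = 1` used by all the CBR variants, ties
#' cannot arise.
#'
#' @inheritParams retrieve
#' @return A one-row tibble with `label` (predicted class) and `probability`
#'   (`p(cancer | target)`).
#' @export
cbr_predict <- function(cb, target, weights, k = 1, temps = attr(cb, "temps")) {
  nbrs <- retrieve(cb, target, weights, k = k, temps = temps)
  p_cancer <- mean(nbrs$label == "cancer")
  tibble::tibble(
    label = if (p_cancer > 0.5) "cancer" else "control",
    probability = p_cancer
  )
}

#' Retain a solved case in the case-base
#'
#' Appends the target case with its confirmed label, completing the
#' retrieve--reuse--revise--retain cycle. Inside cross-validation the
#' evaluation harness never calls this (retaining test cases would leak them
#' into later retrievals).
#'
#' @param cb A [case_base()].
#' @param case One-row feature tibble.
#' @param confirmed_label `"control"` or `"cancer"`.
#' @return The case-base with one more row; earlier cases untouched.
#' @export
retain <- function(cb, case, confirmed_label) {
  if (!confirmed_label %in% cbr_classes()) {
    abort(paste0("unknown label '", confirmed_label, "'"),
          class = "rankcbr_invalid_label")
  }
  case$label <- confirmed_label
  temps <- attr(cb, "temps")
  out <- dplyr::bind_rows(cb, case[names(cb)])
  attr(out, "temps") <- temps
  class(out) <- class(cb)
  out
}

#' Plot a retrieval result against its target curve
#'
#' Overlays the target thermogram (black) with the retrieved neighbour
#' curves (red), the standard visual check that the retrieved case shares
#' the target's shape.
#'
#' @param object A `cbr_retrieval` from [retrieve()].
#' @param cb The case-base the retrieval was run against.
#' @param target The target case (one-row feature tibble).
#' @param temps Temperature grid.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cbr_retrieval <- function(object, cb, target,
                                   temps = attr(cb, "temps"), ...) {
  tgt <- tibble::tibble(temp = temps, dcp = target$IND[[1]], role = "target",
                        id = target$subject_id[[1]])
  nbr <- purrr::map_dfr(seq_len(nrow(object)), function(i) {
    row <- which(cb$subject_id == object$subject_id[i])[1]
    tibble::tibble(temp = temps, dcp = cb$IND[[row]], role = "retrieved",
                   id = object$subject_id[i])
  })
  ggplot2::ggplot(dplyr::bind_rows(nbr, tgt),
                  ggplot2::aes(.data$temp, .data$dcp, group = .data$id,
                               colour = .data$role)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(target = "black", retrieved = "red")) +
    ggplot2::labs(x = "Temperature (°C)", y = expression(Delta * C[p]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
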