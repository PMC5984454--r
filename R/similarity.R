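#' Dense ranks of a distance vector
#'
#' Converts local distances to rank-order information: equal distances share
#' a rank and the next distinct value takes the next integer, so the maximal
#' rank equals the number of distinct distance values, N'. Dense ranking is
#' what maps the similarity term exactly onto \[0, 1\]; "min"-style
#' competition ranking would let ranks exceed N' and drive terms negative.
#'
#' @param d Nonempty numeric vector of nonnegative distances.
#' @return A list with `ranks` (integer dense ranks, smaller distance =
#'   smaller rank) and `n_distinct` (N', the number of distinct values).
#' @examples
#' rank_distances(c(2, 0.5, 0.9)) # ranks 3 1 2, N' = 3
#' rank_distances(c(1, 1, 2))     # ranks 1 1 2, N' = 2
#' @export
rank_distances <- function(d) {
  if (length(d) == 0 || !is.numeric(d)) {
    abort("`d` must be a nonempty numeric vector",
          class = "rankcbr_invalid_input")
  }
  u <- sort(unique(d))
  list(ranks = match(d, u), n_distinct = length(u))
}

#' Rank-order global similarity to a target case
#'
#' For each case i of the case-base, the weighted global similarity
#' \deqn{S_i = \sum_f \omega_f \, \frac{N'_f - \mathrm{rank}(d_f(i))}{N'_f - 1},}
#' where ranks are dense ranks of the per-feature local distances to the
#' target and \eqn{N'_f} is the number of distinct distance values for
#' feature f. The best (smallest) rank contributes 1, the worst contributes
#' 0, so with weights summing to 1 the similarity lies in \[0, 1\] and equals
#' 1 only for a case that is rank-1 on every feature. A feature with a single
#' distinct distance value (\eqn{N'_f = 1}) is uninformative and contributes
#' the constant 1.
#'
#' @param distances A local distance table from [local_distance_table()]
#'   (one column per feature, one row per case).
#' @param weights A weight vector: either a named numeric vector over the six
#'   features or a tibble with columns `feature` and `weight`. Must be
#'   nonnegative and sum to 1.
#' @return Numeric vector of similarities, one per case.
#' @export
global_similarity <- function(distances, weights) {
  w <- as_weight_vector(weights, names(distances))
  terms <- purrr::map(names(distances), function(f) {
    r <- rank_distances(distances[[f]])
    if (r$n_distinct == 1) rep(1, length(r$ranks))
    else (r$n_distinct - r$ranks) / (r$n_distinct - 1)
  })
  Reduce(`+`, purrr::map2(terms, w[names(distances)], `*`))
}

# Normalise weight input (tibble or named vector) to a named numeric vector
# over `features`, validating the box and sum constraints.
as_weight_vector <- function(weights, features = cbr_features()) {
  if (is.data.frame(weights)) {
    if (!all(c("feature", "weight") %in% names(weights))) {
      abort("a weight table needs columns `feature` and `weight`",
            class = "rankcbr_schema_error")
    }
    weights <- setNames(weights$weight, weights$feature)
  }
  if (is.null(names(weights)) || !all(features %in% names(weights))) {
    abort(paste0("weights must be named for every feature: ",
                 paste(features, collapse = ", ")),
          class = "rankcbr_schema_error")
  }
  w <- weights[features]
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6) {
    abort("weights must be nonnegative and sum to 1",
          class = "rankcbr_schema_error")
  }
  w
}
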