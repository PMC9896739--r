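#' Ranking metric configuration
#'
#' @param gain `"identity"` (g(r) = r, the default — graded labels here reach
#'   17+, where the exponential gain would overflow usefulness) or
#'   `"exponential"` (g(r) = 2^r - 1, the web-search convention for small
#'   integer grades).
#' @param k positive integer cutoff for truncated metrics, or `NULL` for the
#'   full list.
#' @param zero_ideal value returned by [ndcg()] when the ideal DCG is zero
#'   (an all-zero label list); 0 by default.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(gain = c("identity", "exponential"), k = NULL,
                          zero_ideal = 0) {
  gain <- match.arg(gain)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 1L) {
      stop("cutoff k must be a positive integer or NULL", call. = FALSE)
    }
  }
  structure(list(gain = gain, k = k, zero_ideal = as.numeric(zero_ideal)),
            class = "metric_config")
}

gain_fun <- function(r, gain) {
  if (gain == "identity") r else 2^r - 1
}

#' Discounted cumulative gain of an already-ordered label vector
#'
#' `DCG@k = sum_{i=1..k} g(rel_i) / log2(i + 1)` with 1-based positions.
#'
#' @param ordered_labels numeric labels, already in ranked order.
#' @param config a [metric_config()].
#' @return Nonnegative scalar.
#' @examples
#' dcg(c(3, 2, 1, 0))  # 3 + 2/log2(3) + 1/2
#' @export
dcg <- function(ordered_labels, config = metric_config()) {
  ordered_labels <- as.numeric(ordered_labels)
  n <- length(ordered_labels)
  k <- if (is.null(config$k)) n else min(config$k, n)
  if (k == 0L) return(0)
  g <- gain_fun(ordered_labels[seq_len(k)], config$gain)
  sum(g / log2(seq_len(k) + 1))
}

#' Descending-score ranking order with vocabulary-index tie-break
#'
#' @param scores numeric vector.
#' @return Integer permutation: `ranking_order(s)[r]` is the item at rank r.
#' @keywords internal
ranking_order <- function(scores) {
  order(-scores, seq_along(scores))
}

#' Normalized discounted cumulative gain of a scored list
#'
#' DCG of the labels ordered by descending model score (ties broken by
#' vocabulary index), normalized by the ideal DCG (labels in descending
#' order). In `[0, 1]`; a list whose labels are all zero returns
#' `config$zero_ideal`.
#'
#' @param list a [scored_list()].
#' @param config a [metric_config()]; set `k` for ndcg@k.
#' @return Scalar in `[0, 1]`.
#' @examples
#' sl <- scored_list(scores = c(1, 2, 3), rel = c(3, 0, 0))
#' ndcg(sl)  # 0.5
#' @export
ndcg <- function(list, config = metric_config()) {
  stopifnot(inherits(list, "scored_list"))
  ideal <- dcg(sort(list$rel, decreasing = TRUE), config)
  if (ideal == 0) return(config$zero_ideal)
  dcg(list$rel[ranking_order(list$scores)], config) / ideal
}

#' Rank of one disease under a score vector
#'
#' 1-based position of the item after descending-score sort, equal scores
#' broken by vocabulary index. For fixed scores this is a bijection between
#' item indices and ranks.
#'
#' @param list a [scored_list()] (labels are ignored).
#' @param index 1-based item (disease) index.
#' @return Positive integer rank.
#' @export
rank_of <- function(list, index) {
  stopifnot(inherits(list, "scored_list"))
  index <- as.integer(index)
  n <- length(list$scores)
  if (length(index) != 1L || is.na(index) || index < 1L || index > n) {
    stop(sprintf("disease index must be in 1..%d", n), call. = FALSE)
  }
  s <- list$scores
  # items strictly ahead, plus equal-scored items with smaller index
  1L + sum(s > s[index]) + sum(s == s[index] & seq_len(n) < index)
}

#' Top-k hit: is any target disease ranked within the cutoff?
#'
#' The differential-diagnosis success criterion: true iff at least one
#' target disease (confirmed or clinically related) is ranked in the top k.
#'
#' @param list a [scored_list()].
#' @param targets integer vector of 1-based target disease indices,
#'   non-empty.
#' @param k positive integer cutoff (the headline criterion uses k = 10).
#' @return Logical scalar.
#' @export
topk_hit <- function(list, targets, k) {
  stopifnot(inherits(list, "scored_list"))
  targets <- as.integer(targets)
  if (length(targets) == 0L) {
    stop("targets must be a non-empty set of disease indices", call. = FALSE)
  }
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  min(vapply(targets, function(t) rank_of(list, t), 1L)) <= k
}
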