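#' Rank candidate diseases for a set of inputted symptoms
#'
#' The physician-facing operation: symptoms in, ranked scored disease list
#' out. Ranks follow descending model score with ties broken by disease
#' vocabulary order — exactly the ordering [rank_of()] assigns.
#'
#' @param object a trained `dx_model`.
#' @param symptoms character vector of symptom codes (acquisition order).
#' @param top_n number of diseases to return (default 10).
#' @param on_unknown `"error"` (default: an unknown symptom code aborts —
#'   silently dropping input would change the ranking invisibly) or
#'   `"skip"` (drop unknown codes with a warning).
#' @param ... unused.
#' @return An object of class `dx_prediction`: a data.frame with columns
#'   `rank`, `code`, `disease`, `score`; attributes carry the inputted
#'   symptoms actually used.
#' @export
predict.dx_model <- function(object, symptoms, top_n = 10L,
                             on_unknown = c("error", "skip"), ...) {
  on_unknown <- match.arg(on_unknown)
  symptoms <- as.character(symptoms)
  if (length(symptoms) == 0L) {
    stop("at least one symptom is required", call. = FALSE)
  }
  known <- symptoms %in% object$symptom_vocab$code
  if (!all(known)) {
    if (on_unknown == "error") {
      stop(sprintf("unknown symptom code: '%s'", symptoms[!known][1L]),
           call. = FALSE)
    }
    warning(sprintf("skipping unknown symptom code(s): %s",
                    paste(symptoms[!known], collapse = ", ")),
            call. = FALSE)
    symptoms <- symptoms[known]
    if (length(symptoms) == 0L) {
      stop("no known symptom codes remain after skipping", call. = FALSE)
    }
  }
  x <- numeric(vocab_size(object$symptom_vocab))
  x[vocab_index(object$symptom_vocab, symptoms)] <- 1
  s <- forward(object, x)
  top_n <- min(as.integer(top_n), length(s))
  ord <- ranking_order(s)[seq_len(top_n)]
  out <- data.frame(rank = seq_len(top_n),
                    code = object$disease_vocab$code[ord],
                    disease = object$disease_vocab$label[ord],
                    score = s[ord], row.names = NULL)
  attr(out, "symptoms") <- symptoms
  class(out) <- c("dx_prediction", "data.frame")
  out
}

#' @export
print.dx_prediction <- function(x, ...) {
  cat(sprintf("Inputted symptoms: %s\n",
              paste(attr(x, "symptoms"), collapse = ", ")))
  disp <- as.data.frame(x)
  disp$score <- sprintf("%.2f", disp$score)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Rank trajectory under progressive symptom input
#'
#' Replays the bedside workflow: for each prefix of the symptom sequence
#' (first symptom only, first two, ...), predicts and records the rank of
#' each target disease. Flags the earliest prefix at which any target
#' enters the top `cutoff`.
#'
#' @param model a trained `dx_model`.
#' @param symptoms ordered character vector of symptom codes.
#' @param targets character vector of target disease codes (confirmed and
#'   clinically related diseases).
#' @param cutoff rank cutoff for the hit flag (default 10).
#' @return An object of class `dx_trajectory`: a data.frame with one row
#'   per prefix (`step`, `symptom`, one `rank_<code>` column per target,
#'   `hit`); attribute `first_hit` is the earliest hitting step (NA if
#'   never).
#' @export
rank_trajectory <- function(model, symptoms, targets, cutoff = 10L) {
  stopifnot(inherits(model, "dx_model"))
  symptoms <- as.character(symptoms)
  targets <- as.character(targets)
  if (length(symptoms) < 1L) stop("at least one symptom", call. = FALSE)
  if (length(targets) < 1L) stop("at least one target", call. = FALSE)
  tgt_idx <- vocab_index(model$disease_vocab, targets)
  n_dis <- vocab_size(model$disease_vocab)
  x <- numeric(vocab_size(model$symptom_vocab))
  rows <- vector("list", length(symptoms))
  for (t in seq_along(symptoms)) {
    x[vocab_index(model$symptom_vocab, symptoms[t])] <- 1
    sl <- scored_list(forward(model, x), numeric(n_dis))
    ranks <- vapply(tgt_idx, function(i) rank_of(sl, i), 1L)
    row <- data.frame(step = t, symptom = symptoms[t])
    for (j in seq_along(targets)) {
      row[[paste0("rank_", targets[j])]] <- ranks[j]
    }
    row$hit <- min(ranks) <= cutoff
    rows[[t]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "first_hit") <- if (any(out$hit)) min(out$step[out$hit]) else
    NA_integer_
  attr(out, "cutoff") <- as.integer(cutoff)
  class(out) <- c("dx_trajectory", "data.frame")
  out
}

#' @export
print.dx_trajectory <- function(x, ...) {
  cat(sprintf("Inputted symptoms and the target diseases' rankings (cutoff %d)\n",
              attr(x, "cutoff")))
  print(as.data.frame(x), row.names = FALSE)
  fh <- attr(x, "first_hit")
  cat(if (is.na(fh)) "No target entered the cutoff.\n" else
    sprintf("First top-%d hit at step %d.\n", attr(x, "cutoff"), fh))
  invisible(x)
}

#' Top-k hit rate of a model over a corpus
#'
#' Fraction of cases whose confirmed (max-label) disease is ranked within
#' the top k by the model — the headline differential-diagnosis success
#' criterion at k = 10.
#'
#' @param model a trained `dx_model`.
#' @param corpus a non-empty `dx_corpus` on the model's vocabularies.
#' @param k rank cutoff (default 10).
#' @return Scalar in `[0, 1]`; attribute `per_case` holds the named
#'   per-case logical vector.
#' @export
topk_report <- function(model, corpus, k = 10L) {
  stopifnot(inherits(model, "dx_model"), inherits(corpus, "dx_corpus"))
  if (length(corpus$cases) == 0L) {
    stop("corpus must be non-empty", call. = FALSE)
  }
  dense <- densify_corpus(corpus)
  S <- forward(model, dense$X)
  hits <- vapply(seq_len(nrow(S)), function(i) {
    sl <- scored_list(S[i, ], dense$R[i, ])
    topk_hit(sl, which(dense$R[i, ] == max(dense$R[i, ])), k)
  }, TRUE)
  names(hits) <- rownames(dense$X)
  structure(mean(hits), per_case = hits)
}
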