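#' Cross-validation configuration
#'
#' @param k number of folds (default 5).
#' @param cutoffs integer cutoffs for the truncated ndcg evaluation
#'   functions (default `c(5, 10, 20)`; the untruncated ndcg and mse are
#'   always reported).
#' @param train a shared [train_config()] applied identically to every
#'   system compared.
#' @param metric a [metric_config()] for the evaluation functions.
#' @param fold_seed seed of the fold split (default 1).
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(k = 5L, cutoffs = c(5L, 10L, 20L),
                        train = train_config(), metric = metric_config(),
                        fold_seed = 1L) {
  k <- as.integer(k)
  cutoffs <- as.integer(cutoffs)
  stopifnot(k >= 2L, all(cutoffs >= 1L))
  structure(list(k = k, cutoffs = cutoffs, train = train, metric = metric,
                 fold_seed = as.integer(fold_seed)),
            class = "eval_config")
}

#' Split a corpus into k cross-validation folds
#'
#' Case-level split: the case is the listwise unit. Test sets are disjoint,
#' exhaust the corpus, and differ in size by at most one.
#'
#' @param corpus a `dx_corpus` (or anything with a length).
#' @param k number of folds.
#' @param seed split seed.
#' @return List of `k` elements, each `list(train = indices, test = indices)`.
#' @export
kfold_split <- function(corpus, k = 5L, seed = 1L) {
  n <- length(corpus)
  k <- as.integer(k)
  if (n < k) {
    stop(sprintf("corpus has %d cases but k = %d folds requested", n, k),
         call. = FALSE)
  }
  rng <- local_rng(seed)
  perm <- rng$sample_int(n, n)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    test <- sort(perm[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

subset_corpus <- function(corpus, idx) {
  case_corpus(corpus$symptom_vocab, corpus$disease_vocab, corpus$cases[idx])
}

# Mean evaluation-function values of a scorer over a dense test set.
# `scorer` maps a multi-hot matrix X to a score matrix; injectable so a
# perfect oracle (scores := labels) can be evaluated in place of a model.
evaluate_scores <- function(scorer, X, R, cutoffs, metric = metric_config()) {
  metric_row_means(scorer(X), R, cutoffs = cutoffs, config = metric)
}

#' Cross-validated evaluation of one system
#'
#' For each fold: train the model on the training split under the given
#' loss, score the held-out cases, and average the evaluation functions
#' (ndcg, ndcg@k for each cutoff, mse) over test cases. Reports per-fold
#' values and their mean and standard deviation.
#'
#' @param corpus a `dx_corpus`.
#' @param loss_cfg a [loss_config()] naming the system.
#' @param cfg an [eval_config()].
#' @param folds optionally, a precomputed [kfold_split()] (so two systems
#'   can share byte-identical folds).
#' @return List of class `dx_eval` with `system`, `per_fold` (matrix: folds
#'   x evaluation functions), `mean`, `sd`, and `curves` (per-fold learning
#'   curves, concatenated with a `fold` column).
#' @export
evaluate_system <- function(corpus, loss_cfg, cfg = eval_config(),
                            folds = NULL) {
  stopifnot(inherits(corpus, "dx_corpus"), inherits(loss_cfg, "loss_config"),
            inherits(cfg, "eval_config"))
  if (is.null(folds)) folds <- kfold_split(corpus, cfg$k, cfg$fold_seed)
  dense <- densify_corpus(corpus)
  per_fold <- NULL
  curves <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fit <- train(subset_corpus(corpus, folds[[f]]$train), loss_cfg, cfg$train)
    m <- evaluate_scores(function(X) forward(fit$model, X),
                         dense$X[folds[[f]]$test, , drop = FALSE],
                         dense$R[folds[[f]]$test, , drop = FALSE],
                         cutoffs = cfg$cutoffs, metric = cfg$metric)
    per_fold <- rbind(per_fold, m)
    curves[[f]] <- cbind(fold = f, fit$curves)
  }
  rownames(per_fold) <- paste0("fold_", seq_along(folds))
  structure(list(system = toupper(sub("approx_ndcg", "A-NDCG",
                                      loss_cfg$loss)),
                 loss_cfg = loss_cfg, per_fold = per_fold,
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2L, stats::sd),
                 curves = do.call(rbind, curves)),
            class = "dx_eval")
}

#' @export
print.dx_eval <- function(x, ...) {
  cat(sprintf("<dx_eval: %s, %d folds>\nmean:\n", x$system,
              nrow(x$per_fold)))
  print(round(x$mean, 4))
  invisible(x)
}

#' Compare the listwise and pointwise systems under identical conditions
#'
#' Runs [evaluate_system()] for the Approximate-NDCG system and the MSE
#' baseline on byte-identical fold splits and an identical shared training
#' configuration — the fairness contract: nothing but the loss function
#' differs between the two rows.
#'
#' @param corpus a `dx_corpus`.
#' @param cfg an [eval_config()].
#' @param alpha logistic steepness of the Approximate-NDCG loss.
#' @return List of class `dx_report` with elements `A-NDCG` and `MSE` (each
#'   a `dx_eval`) plus the shared `folds` and `cfg`.
#' @export
compare_systems <- function(corpus, cfg = eval_config(), alpha = 10) {
  folds <- kfold_split(corpus, cfg$k, cfg$fold_seed)
  metric <- cfg$metric
  systems <- list(
    "A-NDCG" = loss_config("approx_ndcg", alpha = alpha, metric = metric),
    "MSE" = loss_config("mse", metric = metric))
  out <- lapply(systems, function(lc) {
    evaluate_system(corpus, lc, cfg, folds = folds)
  })
  out$folds <- folds
  out$cfg <- cfg
  class(out) <- "dx_report"
  out
}

#' @export
print.dx_report <- function(x, ...) {
  cat("Value of evaluation functions (mean over folds)\n")
  print(round(rbind("A-NDCG" = x[["A-NDCG"]]$mean, "MSE" = x[["MSE"]]$mean),
              4))
  invisible(x)
}

#' Tabulate a comparison report
#'
#' @param report a `dx_report` from [compare_systems()].
#' @return data.frame: system, metric, mean, sd, fold_1..fold_k.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "dx_report"))
  rows <- lapply(c("A-NDCG", "MSE"), function(sys) {
    ev <- report[[sys]]
    folds <- t(ev$per_fold)
    colnames(folds) <- paste0("fold_", seq_len(ncol(folds)))
    data.frame(system = sys, metric = names(ev$mean),
               mean = unname(ev$mean), sd = unname(ev$sd), folds,
               row.names = NULL, check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a comparison report to CSV
#' @param report a `dx_report`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report_table(report), path, row.names = FALSE)
  invisible(path)
}
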