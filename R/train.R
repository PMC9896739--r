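#' Training configuration
#'
#' @param epochs number of passes over the training cases (default 20).
#' @param lr learning rate (default 0.01).
#' @param batch_size cases per mini-batch; the per-case (per-list) losses in
#'   a batch are averaged (default 64).
#' @param optimizer `"adam"` (adaptive moments, the default) or `"sgd"`.
#' @param seed integer seed controlling weight initialization, the
#'   validation split and batch shuffling; training is bit-reproducible
#'   given the seed.
#' @param hidden hidden-layer width of the scorer (default 64).
#' @param validation fraction of cases held out for the validation learning
#'   curve (default 0.1; 0 disables the validation curve).
#' @param patience optional early-stopping patience: stop when the
#'   validation ndcg has not improved for this many epochs and restore the
#'   best weights. `NULL` (default) trains for the full epoch budget.
#' @param curve_cases per-epoch learning curves are computed on at most this
#'   many (deterministically subsampled) cases per split, to keep curve
#'   bookkeeping cheap relative to the optimization itself (default 512).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 20L, lr = 0.01, batch_size = 64L,
                         optimizer = c("adam", "sgd"), seed = 1L,
                         hidden = 64L, validation = 0.1, patience = NULL,
                         curve_cases = 512L) {
  optimizer <- match.arg(optimizer)
  epochs <- as.integer(epochs)
  stopifnot(epochs >= 1L, is.finite(lr), lr > 0,
            batch_size >= 1L, validation >= 0, validation < 1,
            curve_cases >= 1L)
  if (!is.null(patience)) stopifnot(patience >= 1L)
  structure(list(epochs = epochs, lr = lr,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 seed = as.integer(seed), hidden = as.integer(hidden),
                 validation = validation, patience = patience,
                 curve_cases = as.integer(curve_cases)),
            class = "train_config")
}

# Mean evaluation-function values over rows of score/label matrices.
# Returns c(ndcg, ndcg@k..., mse) means; the single row sort is shared
# across cutoffs.
metric_row_means <- function(S, R, cutoffs = integer(), config = metric_config()) {
  n <- ncol(S)
  disc <- 1 / log2(seq_len(n) + 1)
  ks <- c(n, pmin(cutoffs, n))
  acc <- numeric(length(ks))
  nz <- 0L
  for (i in seq_len(nrow(S))) {
    g <- gain_fun(R[i, ], config$gain)
    gi <- sort(g, decreasing = TRUE)
    if (gi[1L] <= 0) next # zero-ideal rows score the policy value (0)
    nz <- nz + 1L
    go <- g[order(-S[i, ], seq_len(n))]
    cg <- cumsum(go * disc)
    icg <- cumsum(gi * disc)
    acc <- acc + cg[ks] / icg[ks]
  }
  ndcgs <- if (nrow(S) > 0L) {
    (acc + config$zero_ideal * (nrow(S) - nz)) / nrow(S)
  } else {
    rep(NA_real_, length(ks))
  }
  out <- c(ndcgs, mean((S - R)^2))
  names(out) <- c("ndcg", if (length(cutoffs)) paste0("ndcg@", cutoffs), "mse")
  out
}

#' Train the ranking model on a case corpus
#'
#' Mini-batch gradient training of the one-hidden-layer scorer under either
#' the listwise Approximate-NDCG loss or the pointwise MSE baseline. The
#' per-case (per-list) losses in a mini-batch are averaged, so both losses
#' see the same optimization machinery: only the loss (and its score
#' gradient) differs between the two systems.
#'
#' @param corpus a non-empty `dx_corpus`.
#' @param loss_cfg a [loss_config()].
#' @param train_cfg a [train_config()].
#' @return List of class `dx_fit` with elements `model` (the trained
#'   `dx_model`) and `curves` (data.frame: epoch, split, ndcg, mse — the
#'   per-epoch learning curves on the train and validation splits).
#' @export
train <- function(corpus, loss_cfg = loss_config(),
                  train_cfg = train_config()) {
  stopifnot(inherits(corpus, "dx_corpus"), inherits(loss_cfg, "loss_config"),
            inherits(train_cfg, "train_config"))
  if (length(corpus$cases) == 0L) {
    stop("cannot train on an empty corpus", call. = FALSE)
  }
  dense <- densify_corpus(corpus)
  X <- dense$X
  R <- dense$R
  n_cases <- nrow(X)

  rng <- local_rng(train_cfg$seed)
  n_val <- floor(train_cfg$validation * n_cases)
  perm <- rng$sample_int(n_cases, n_cases)
  val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer()
  tr_idx <- if (n_val > 0L) perm[-seq_len(n_val)] else perm
  if (length(tr_idx) == 0L) {
    stop("validation fraction leaves no training cases", call. = FALSE)
  }

  model <- ranking_model(corpus$symptom_vocab, corpus$disease_vocab,
                         hidden = train_cfg$hidden, seed = train_cfg$seed)
  opt <- optimizer_state(model, train_cfg)

  # deterministic curve subsamples
  curve_sub <- function(idx) {
    if (length(idx) <= train_cfg$curve_cases) idx
    else idx[round(seq(1L, length(idx), length.out = train_cfg$curve_cases))]
  }
  tr_curve <- curve_sub(tr_idx)
  va_curve <- curve_sub(val_idx)

  curves <- vector("list", train_cfg$epochs)
  best <- list(ndcg = -Inf, model = NULL, since = 0L)
  n_epochs_run <- 0L

  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- tr_idx[rng$sample_int(length(tr_idx), length(tr_idx))]
    starts <- seq(1L, length(ord), by = train_cfg$batch_size)
    epoch_loss <- 0
    for (s0 in starts) {
      rows <- ord[s0:min(s0 + train_cfg$batch_size - 1L, length(ord))]
      step <- sgd_step(model, X[rows, , drop = FALSE],
                       R[rows, , drop = FALSE], loss_cfg)
      if (!is.finite(step$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      }
      epoch_loss <- epoch_loss + step$loss * length(rows)
      model <- opt$update(model, step$grads)
    }

    tr_m <- metric_row_means(forward(model, X[tr_curve, , drop = FALSE]),
                             R[tr_curve, , drop = FALSE],
                             config = loss_cfg$metric)
    row <- data.frame(epoch = epoch, split = "train",
                      ndcg = tr_m[["ndcg"]], mse = tr_m[["mse"]])
    if (length(va_curve)) {
      va_m <- metric_row_means(forward(model, X[va_curve, , drop = FALSE]),
                               R[va_curve, , drop = FALSE],
                               config = loss_cfg$metric)
      row <- rbind(row, data.frame(epoch = epoch, split = "validation",
                                   ndcg = va_m[["ndcg"]],
                                   mse = va_m[["mse"]]))
    }
    curves[[epoch]] <- row
    n_epochs_run <- epoch

    if (!is.null(train_cfg$patience) && length(va_curve)) {
      va_ndcg <- row$ndcg[row$split == "validation"]
      if (va_ndcg > best$ndcg + 1e-12) {
        best <- list(ndcg = va_ndcg, model = model, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= train_cfg$patience) {
          model <- best$model
          break
        }
      }
    }
  }

  model$trained <- TRUE
  model$loss <- loss_cfg$loss
  structure(list(model = model,
                 curves = do.call(rbind, curves[seq_len(n_epochs_run)])),
            class = "dx_fit")
}

#' @export
print.dx_fit <- function(x, ...) {
  last <- x$curves[x$curves$epoch == max(x$curves$epoch), ]
  cat(sprintf("<dx_fit: %s loss, %d epochs>\n", x$model$loss,
              max(x$curves$epoch)))
  print(last, row.names = FALSE)
  invisible(x)
}

# One forward/backward pass on a mini-batch; returns mean per-case loss and
# weight gradients.
sgd_step <- function(model, Xb, Rb, loss_cfg) {
  B <- nrow(Xb)
  Z1 <- sweep(Xb %*% model$W1, 2L, model$b1, `+`)
  H <- pmax(Z1, 0)
  S <- sweep(H %*% model$W2, 2L, model$b2, `+`)
  bl <- batch_loss_grad(S, Rb, loss_cfg)
  G <- bl$grad / B
  dW2 <- crossprod(H, G)
  db2 <- colSums(G)
  dH <- G %*% t(model$W2)
  dZ1 <- dH * (Z1 > 0)
  dW1 <- crossprod(Xb, dZ1)
  db1 <- colSums(dZ1)
  list(loss = mean(bl$loss),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

optimizer_state <- function(model, train_cfg) {
  params <- c("W1", "b1", "W2", "b2")
  if (train_cfg$optimizer == "sgd") {
    return(list(update = function(model, grads) {
      for (p in params) model[[p]] <- model[[p]] - train_cfg$lr * grads[[p]]
      model
    }))
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  for (p in params) {
    st[[paste0("m_", p)]] <- model[[p]] * 0
    st[[paste0("v_", p)]] <- model[[p]] * 0
  }
  list(update = function(model, grads) {
    st$t <- st$t + 1L
    for (p in params) {
      m <- beta1 * st[[paste0("m_", p)]] + (1 - beta1) * grads[[p]]
      v <- beta2 * st[[paste0("v_", p)]] + (1 - beta2) * grads[[p]]^2
      st[[paste0("m_", p)]] <- m
      st[[paste0("v_", p)]] <- v
      mhat <- m / (1 - beta1^st$t)
      vhat <- v / (1 - beta2^st$t)
      model[[p]] <- model[[p]] - train_cfg$lr * mhat / (sqrt(vhat) + eps)
    }
    model
  })
}

#' Write learning curves to CSV
#' @param curves the `curves` data.frame of a [train()] fit.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
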