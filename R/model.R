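#' Initialize the one-hidden-layer ranking model
#'
#' The scorer is deliberately shallow — a single internal hidden layer —
#' which keeps the mapping from inputted symptoms to disease scores simple
#' enough to inspect: multi-hot symptom vector -> rectified hidden layer ->
#' linear score per disease. Weights use He-style Gaussian initialization
#' scaled by fan-in; biases start at zero.
#'
#' @param symptom_vocab,disease_vocab the `dx_vocabulary` objects fixing the
#'   input and output dimensions (and code order).
#' @param hidden number of hidden units (default 64).
#' @param seed integer seed for weight initialization.
#' @return An object of class `dx_model`.
#' @export
ranking_model <- function(symptom_vocab, disease_vocab, hidden = 64L,
                          seed = 1L) {
  stopifnot(inherits(symptom_vocab, "dx_vocabulary"),
            inherits(disease_vocab, "dx_vocabulary"))
  hidden <- as.integer(hidden)
  stopifnot(hidden >= 1L)
  n_in <- vocab_size(symptom_vocab)
  n_out <- vocab_size(disease_vocab)
  rng <- local_rng(seed)
  W1 <- matrix(rng$norm(n_in * hidden, sd = sqrt(2 / n_in)), n_in, hidden)
  W2 <- matrix(rng$norm(hidden * n_out, sd = sqrt(2 / hidden)), hidden, n_out)
  structure(
    list(symptom_vocab = symptom_vocab, disease_vocab = disease_vocab,
         hidden = hidden, seed = as.integer(seed),
         W1 = W1, b1 = numeric(hidden), W2 = W2, b2 = numeric(n_out),
         activation = "relu", trained = FALSE, loss = NA_character_),
    class = "dx_model")
}

#' @export
print.dx_model <- function(x, ...) {
  cat(sprintf(
    "<dx_model: %d symptoms -> %d hidden (relu) -> %d diseases; %s>\n",
    nrow(x$W1), x$hidden, ncol(x$W2),
    if (x$trained) sprintf("trained (%s loss)", x$loss) else "untrained"))
  invisible(x)
}

#' Forward pass: symptom vector(s) to disease scores
#'
#' @param model a `dx_model`.
#' @param x numeric multi-hot vector (length = symptom vocabulary size) or a
#'   matrix with one case per row.
#' @return Score vector over the disease vocabulary, or a matrix of score
#'   rows for matrix input. Deterministic given the weights.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "dx_model"))
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), 1L) else as.matrix(x)
  if (ncol(X) != nrow(model$W1)) {
    stop(sprintf("input has %d columns but the model expects %d symptoms",
                 ncol(X), nrow(model$W1)), call. = FALSE)
  }
  H <- pmax(sweep(X %*% model$W1, 2L, model$b1, `+`), 0)
  S <- sweep(H %*% model$W2, 2L, model$b2, `+`)
  if (single) as.numeric(S) else S
}

# Deterministic local RNG that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(f) {
    function(...) {
      prev <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(prev)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", prev, globalenv())
        }
      })
      f(...)
    }
  }
  list(norm = with_state(stats::rnorm),
       unif = with_state(stats::runif),
       pois = with_state(stats::rpois),
       sample = with_state(base::sample),
       sample_int = with_state(base::sample.int))
}
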