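# Independent brute-force oracles and small fixture builders shared by the
# tests. The oracles deliberately avoid the package's vectorized paths:
# explicit sorts and positionwise loops only.

oracle_ndcg <- function(scores, rel, k = NULL, gain = c("identity", "exponential")) {
  gain <- match.arg(gain)
  g <- function(r) if (gain == "identity") r else 2^r - 1
  n <- length(scores)
  kk <- if (is.null(k)) n else min(k, n)
  ord <- order(-scores, seq_len(n))
  iord <- order(-rel, seq_len(n))
  num <- 0
  den <- 0
  for (i in seq_len(kk)) {
    num <- num + g(rel[ord[i]]) / log2(i + 1)
    den <- den + g(rel[iord[i]]) / log2(i + 1)
  }
  if (den == 0) 0 else num / den
}

oracle_rank <- function(scores, index) {
  ord <- order(-scores, seq_along(scores))
  which(ord == index)
}

fd_gradient <- function(scores, rel, config, h = 1e-5) {
  f <- function(s) {
    sl <- scored_list(s, rel)
    if (config$loss == "mse") mse_loss(sl) else approx_ndcg_loss(sl, config)
  }
  vapply(seq_along(scores), function(i) {
    sp <- scores; sp[i] <- sp[i] + h
    sm <- scores; sm[i] <- sm[i] - h
    (f(sp) - f(sm)) / (2 * h)
  }, 0)
}

# scores guaranteed distinct with gaps >= 0.02, so a steep logistic is fully
# saturated and the smooth positions coincide with the true ranks
distinct_scores <- function(n) {
  sample(seq(0, 4, by = 0.02), n)
}

# hand-built two-case fixture on a small vocabulary
tiny_corpus <- function() {
  sv <- vocabulary(c("fever", "head", "sore", "myalg"),
                   c("Fever", "Headache", "Sore throat", "Muscles ache"),
                   "symptom")
  dv <- vocabulary(c("548", "296", "102"),
                   c("Acute HIV-1 infection", "Acute hepatitis",
                     "Toxoplasmosis"),
                   "disease")
  cases <- list(
    case_record("c1", c("fever", "head", "sore"),
                c("548" = 17.078, "296" = 12.086, "102" = 11.25),
                provenance = "fixture"),
    case_record("c2", c("fever", "myalg"),
                c("296" = 17.078, "102" = 12.086)))
  case_corpus(sv, dv, cases)
}

random_corpus <- function(n_cases = 5L, n_sym = 8L, n_dis = 6L) {
  sv <- vocabulary(sprintf("s%02d", seq_len(n_sym)), kind = "symptom")
  dv <- vocabulary(sprintf("d%02d", seq_len(n_dis)),
                   sprintf("Disease é%d", seq_len(n_dis)), "disease")
  cases <- lapply(seq_len(n_cases), function(i) {
    sy <- sample(sv$code, sample(1:n_sym, 1))
    nd <- sample(1:n_dis, 1)
    di <- sample(dv$code, nd)
    case_record(sprintf("case-%03d", i), sy,
                stats::setNames(c(round(runif(1, 5, 20), 3),
                                  round(runif(nd - 1L, 0, 10), 3))[seq_len(nd)],
                                di),
                provenance = sprintf("random %d", i))
  })
  case_corpus(sv, dv, cases)
}

# default study-condition corpus, generated once per test run
.default_corpus_cache <- new.env(parent = emptyenv())
default_corpus <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.default_corpus_cache[[key]])) {
    .default_corpus_cache[[key]] <- generate_corpus(generator_config(seed = seed))
  }
  .default_corpus_cache[[key]]
}

small_gen_config <- function(seed = 42L, ...) {
  generator_config(n_diseases = 12L, n_symptoms = 50L, n_cases = 80L,
                   profile_size = c(4L, 6L), n_differentials = c(2L, 4L),
                   seed = seed, ...)
}
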