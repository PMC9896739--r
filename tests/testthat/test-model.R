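make_model <- function(n_sym = 6, n_dis = 4, hidden = 8, seed = 3) {
  ranking_model(vocabulary(sprintf("s%d", 1:n_sym), kind = "symptom"),
                vocabulary(sprintf("d%d", 1:n_dis), kind = "disease"),
                hidden = hidden, seed = seed)
}

test_that("forward is deterministic with the contracted dimensions", {
  m <- make_model()
  x <- c(1, 0, 1, 0, 0, 1)
  s1 <- forward(m, x)
  expect_length(s1, 4)
  expect_identical(s1, forward(m, x))
  expect_error(forward(m, c(1, 0)), "expects 6 symptoms")
  # zero input: relu(b1) = 0 at zero biases, so scores equal the output bias
  expect_equal(forward(m, numeric(6)), m$b2)
  m$b2 <- c(0.5, -1, 2, 0)
  expect_equal(forward(m, numeric(6)), m$b2)
  # batched forward agrees with rowwise forward
  X <- rbind(x, numeric(6), c(1, 1, 1, 0, 0, 0))
  S <- forward(m, X)
  expect_equal(S[1, ], forward(m, x))
  expect_equal(S[3, ], forward(m, c(1, 1, 1, 0, 0, 0)))
})

test_that("smooth positions respect their bounds and conservation identity", {
  expect_equal(approx_positions(c(0, 0, 0), alpha = 1), c(2, 2, 2))
  set.seed(21)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    s <- rnorm(n, sd = 3)
    for (a in c(0.1, 1, 10, 1e4)) {
      p <- approx_positions(s, a)
      expect_equal(sum(p), n * (n + 1) / 2, tolerance = 1e-12)
      expect_true(all(p >= 1 - 1e-12 & p <= n + 1e-12))
    }
  }
  # steep logistic recovers the true ranks on well-separated scores
  s <- c(0.3, 1.4, -0.8, 0.9)
  expect_equal(approx_positions(s, 1e4), c(3, 1, 4, 2), tolerance = 1e-3)
})

test_that("the listwise loss matches its contracted values and limits", {
  expect_equal(approx_ndcg_loss(scored_list(0.7, 5)), -1)
  expect_equal(approx_ndcg_loss(scored_list(rnorm(4), rep(0, 4))), 0)
  set.seed(33)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    s <- distinct_scores(n)
    r <- sample(0:4, n, replace = TRUE) + c(1, numeric(n - 1))
    sl <- scored_list(s, r)
    l <- approx_ndcg_loss(sl)
    expect_gte(l, -1 - 1e-12)
    expect_lte(l, 0)
    expect_lt(abs(-approx_ndcg_loss(sl, loss_config(alpha = 1e4)) - ndcg(sl)),
              1e-3)
  }
})

test_that("the pointwise loss is the mean squared error with its symmetries", {
  expect_equal(mse_loss(scored_list(c(1, 3), c(1, 3))), 0)
  expect_equal(mse_loss(scored_list(c(0, 0), c(1, 3))), 5)
  set.seed(4)
  s <- rnorm(6); r <- abs(rnorm(6))
  expect_equal(mse_loss(scored_list(3 * s, 3 * r)),
               9 * mse_loss(scored_list(s, r)))
})

test_that("analytic gradients match central finite differences", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    s <- rnorm(n)
    r <- sample(0:3, n, replace = TRUE) + c(1, numeric(n - 1))
    for (cfg in list(loss_config("approx_ndcg", alpha = 2),
                     loss_config("approx_ndcg", alpha = 10),
                     loss_config("mse"))) {
      g <- loss_gradient(scored_list(s, r), cfg)
      fd <- fd_gradient(s, r, cfg)
      expect_lt(max(abs(g - fd)) / max(max(abs(fd)), 1e-8), 1e-4)
    }
  }
  # the pointwise gradient in closed form, zero at the optimum
  sl <- scored_list(c(0.5, 2, -1), c(1, 0, 3))
  expect_equal(loss_gradient(sl, loss_config("mse")),
               2 * (sl$scores - sl$rel) / 3)
  expect_equal(loss_gradient(scored_list(c(1, 2), c(1, 2)),
                             loss_config("mse")), c(0, 0))
})

test_that("training is bit-reproducible and reduces its own loss", {
  corp <- generate_corpus(small_gen_config())
  tc <- train_config(epochs = 4, seed = 9, hidden = 16)
  f1 <- train(corp, loss_config(), tc)
  f2 <- train(corp, loss_config(), tc)
  expect_identical(f1$model$W1, f2$model$W1)
  expect_identical(f1$model$W2, f2$model$W2)
  expect_identical(f1$curves, f2$curves)

  dense <- densify_corpus(corp)
  mean_loss <- function(model, lc) {
    S <- forward(model, dense$X)
    mean(vapply(seq_len(nrow(S)), function(i) {
      sl <- scored_list(S[i, ], dense$R[i, ])
      if (lc$loss == "mse") mse_loss(sl) else approx_ndcg_loss(sl, lc)
    }, 0))
  }
  for (lc in list(loss_config(), loss_config("mse"))) {
    init <- ranking_model(corp$symptom_vocab, corp$disease_vocab,
                          hidden = 16, seed = 9)
    fit <- train(corp, lc, train_config(epochs = 8, seed = 9, hidden = 16))
    expect_lt(mean_loss(fit$model, lc), mean_loss(init, lc))
  }
})

test_that("learning curves track both evaluation functions per epoch", {
  corp <- generate_corpus(small_gen_config())
  fit <- train(corp, loss_config("mse"),
               train_config(epochs = 3, seed = 1, validation = 0.2))
  expect_setequal(names(fit$curves), c("epoch", "split", "ndcg", "mse"))
  expect_equal(sort(unique(fit$curves$epoch)), 1:3)
  expect_setequal(unique(fit$curves$split), c("train", "validation"))
  expect_true(all(fit$curves$ndcg >= 0 & fit$curves$ndcg <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(fit$curves, path)
  back <- read.csv(path)
  expect_equal(back, data.frame(fit$curves, row.names = NULL),
               tolerance = 1e-12)
})

test_that("listwise training recovers a tiny separable mapping exactly", {
  cfg <- generator_config(n_diseases = 5, n_symptoms = 30, n_cases = 60,
                          profile_size = 4, sensitivity = 1, noise_rate = 0,
                          n_differentials = c(0, 0),
                          profile_mode = "disjoint", seed = 2)
  corp <- generate_corpus(cfg)
  fit <- train(corp, loss_config(),
               train_config(epochs = 150, seed = 1, hidden = 16,
                            validation = 0))
  dense <- densify_corpus(corp)
  S <- forward(fit$model, dense$X)
  ndcgs <- vapply(seq_len(nrow(S)), function(i) {
    ndcg(scored_list(S[i, ], dense$R[i, ]))
  }, 0)
  expect_equal(mean(ndcgs), 1, tolerance = 1e-6)
})

test_that("non-finite training loss is reported with its epoch", {
  corp <- generate_corpus(small_gen_config())
  expect_error(
    train(corp, loss_config("mse"),
          train_config(epochs = 12, lr = 1e8, optimizer = "sgd")),
    "non-finite training loss at epoch")
})

test_that("model archives round-trip and refuse mismatched vocabularies", {
  corp <- generate_corpus(small_gen_config())
  fit <- train(corp, loss_config("mse"), train_config(epochs = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit$model, path)
  back <- read_model(path, corp$symptom_vocab, corp$disease_vocab)
  expect_equal(back$W1, fit$model$W1, tolerance = 1e-12)
  expect_equal(back$b2, fit$model$b2, tolerance = 1e-12)
  expect_equal(forward(back, densify(corp$cases[[1]], corp)$x),
               forward(fit$model, densify(corp$cases[[1]], corp)$x),
               tolerance = 1e-12)
  other <- vocabulary(c("zz", "yy"), kind = "symptom")
  expect_error(read_model(path, symptom_vocab = other), "does not match")
})
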