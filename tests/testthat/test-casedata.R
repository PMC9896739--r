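test_that("vocabularies enforce unique non-empty codes and stable order", {
  v <- vocabulary(c("a", "b", "c"), c("A", "B", "C"), "symptom")
  expect_equal(vocab_size(v), 3L)
  expect_equal(vocab_index(v, c("c", "a")), c(3L, 1L))
  expect_error(vocabulary(c("a", "a"), kind = "symptom"), "duplicate")
  expect_error(vocabulary(c("a", ""), kind = "symptom"), "non-empty")
  expect_error(vocab_index(v, "zz"), "unknown symptom code")
})

test_that("vocabulary TSV round-trips including unicode labels", {
  v <- vocabulary(c("x1", "x2"), c("Ménière", "Sjögren"), "disease")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v, path)
  v2 <- read_vocabulary(path, "disease")
  expect_equal(v2$code, v$code)
  expect_equal(v2$label, v$label)
})

test_that("case records enforce the graded-list invariants", {
  expect_error(case_record("c", character(), c(d = 1)), "at least one symptom")
  expect_error(case_record("c", c("a", "a"), c(d = 1)), "duplicate symptom")
  expect_error(case_record("c", "a", c(d = 0)), "positive")
  expect_error(case_record("c", "a", c(d = -1)), "nonnegative")
  expect_error(case_record("c", "a", c(d = 1, d = 2)), "duplicate disease")
  cs <- case_record("c", "a", c(d1 = 2, d2 = 5, d3 = 5))
  expect_equal(confirmed_diseases(cs), c("d2", "d3"))
})

test_that("corpus validation names the offending case and code", {
  sv <- vocabulary("a", kind = "symptom")
  dv <- vocabulary("d", kind = "disease")
  expect_error(
    case_corpus(sv, dv, list(case_record("c9", "zz", c(d = 1)))),
    "case 'c9': unknown symptom code 'zz'")
  expect_error(
    case_corpus(sv, dv, list(case_record("c9", "a", c(q = 1)))),
    "unknown disease code 'q'")
  expect_error(
    case_corpus(sv, dv, list(case_record("c1", "a", c(d = 1)),
                             case_record("c1", "a", c(d = 2)))),
    "duplicate case_id")
})

test_that("corpus files round-trip exactly, including the empty corpus", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("corpus.jsonl", "sym.tsv", "dis.tsv"))
  for (rep in 1:5) {
    set.seed(100 + rep)
    corp <- random_corpus()
    write_corpus(corp, paths[1], paths[2], paths[3])
    back <- read_corpus(paths[1], paths[2], paths[3])
    expect_equal(back, corp)
  }
  empty <- case_corpus(vocabulary("a", kind = "symptom"),
                       vocabulary("d", kind = "disease"), list())
  write_corpus(empty, paths[1], paths[2], paths[3])
  back <- read_corpus(paths[1], paths[2], paths[3])
  expect_length(back$cases, 0)
  expect_error(train(back, loss_config(), train_config()), "empty corpus")
})

test_that("malformed corpus lines are reported with their line number", {
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("corpus.jsonl", "sym.tsv", "dis.tsv"))
  corp <- tiny_corpus()
  write_corpus(corp, paths[1], paths[2], paths[3])
  writeLines(c(readLines(paths[1]), "{not json"), paths[1])
  expect_error(read_corpus(paths[1], paths[2], paths[3]), "line 3")
  writeLines('{"case_id": "x", "symptoms": ["fever"]}', paths[1])
  expect_error(read_corpus(paths[1], paths[2], paths[3]),
               "missing field.*relevances")
})

test_that("densify places symptoms and graded scores at vocabulary indices", {
  sv <- vocabulary(c("a", "b", "c", "d"), kind = "symptom")
  dv <- vocabulary(c("x", "y"), kind = "disease")
  corp <- case_corpus(sv, dv, list(
    case_record("c1", c("a", "c"), c(y = 3.5))))
  d <- densify(corp$cases[[1]], corp)
  expect_equal(d$x, c(1, 0, 1, 0))
  expect_equal(d$rel, c(0, 3.5))

  # listwise case-table shape: graded scores land at the coded diseases
  tc <- tiny_corpus()
  d1 <- densify(tc$cases[[1]], tc)
  expect_equal(d1$rel[vocab_index(tc$disease_vocab, "548")], 17.078)
  expect_equal(d1$rel[vocab_index(tc$disease_vocab, "296")], 12.086)
  expect_equal(d1$rel[vocab_index(tc$disease_vocab, "102")], 11.25)
  expect_equal(sum(d1$x), length(tc$cases[[1]]$symptoms))
})

test_that("densify is injective and dimensions track the vocabularies", {
  set.seed(7)
  corp <- random_corpus(n_cases = 12)
  dense <- densify_corpus(corp)
  expect_equal(dim(dense$X),
               c(12L, vocab_size(corp$symptom_vocab)))
  expect_equal(dim(dense$R),
               c(12L, vocab_size(corp$disease_vocab)))
  keys <- apply(cbind(dense$X, dense$R), 1, paste, collapse = ",")
  cases_key <- vapply(corp$cases, function(cs) {
    paste(paste(sort(cs$symptoms), collapse = "|"),
          paste(sort(paste(names(cs$relevances), cs$relevances)),
                collapse = "|"))
  }, "")
  expect_equal(anyDuplicated(keys) > 0, anyDuplicated(cases_key) > 0)
})

test_that("scored lists require matching lengths and finite inputs", {
  expect_error(scored_list(1:3, 1:2), "equal length")
  expect_error(scored_list(c(1, Inf), c(0, 1)), "finite")
  expect_error(scored_list(c(1, 2), c(-1, 0)), "nonnegative")
  sl <- scored_list(c(1, 2), c(0, 3))
  expect_s3_class(sl, "scored_list")
})
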