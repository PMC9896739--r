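test_that("generator config validates counts, probabilities and feasibility", {
  expect_error(generator_config(profile_size = c(10, 20), n_symptoms = 15),
               "profile size")
  expect_error(generator_config(sensitivity = 1.2), "sensitivity")
  expect_error(generator_config(decay = 1), "decay")
  expect_error(generator_config(profile_mode = "disjoint", n_diseases = 50,
                                n_symptoms = 100, profile_size = c(3, 4)),
               "disjoint")
})

test_that("profiles are seeded, sized and indexed correctly", {
  cfg <- generator_config(n_diseases = 5, n_symptoms = 10,
                          profile_size = 3, seed = 1)
  p1 <- make_profiles(cfg)
  p2 <- make_profiles(cfg)
  expect_identical(p1, p2)
  expect_length(p1, 5)
  for (p in p1) {
    expect_length(p$symptoms, 3)
    expect_true(all(p$symptoms >= 1 & p$symptoms <= 10))
    expect_gt(p$prevalence, 0)
  }
  p3 <- make_profiles(generator_config(n_diseases = 5, n_symptoms = 10,
                                       profile_size = 3, seed = 2))
  expect_false(identical(lapply(p1, `[[`, "symptoms"),
                         lapply(p3, `[[`, "symptoms")))
})

test_that("generated corpora satisfy every case invariant by construction", {
  corp <- generate_corpus(small_gen_config())
  expect_s3_class(corp, "dx_corpus")
  expect_length(corp$cases, 80)
  cfg <- small_gen_config()
  for (cs in corp$cases) {
    rel <- cs$relevances
    expect_equal(max(rel), cfg$confirmed_score)
    # exactly one top score, then monotonically decaying differentials
    expect_equal(sum(rel == max(rel)), 1)
    expect_true(all(diff(sort(rel, decreasing = TRUE)) <= 0))
    expect_lte(length(rel), 1 + cfg$n_differentials[2])
    expect_gte(length(cs$symptoms), 1)
  }
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- small_gen_config()
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  attr(c1, "profiles") <- attr(c2, "profiles") <- NULL
  expect_identical(c1, c2)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.jsonl"); f2 <- file.path(dir, "b.jsonl")
  write_corpus(generate_corpus(cfg), f1)
  write_corpus(generate_corpus(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
})

test_that("noiseless full-sensitivity cases reproduce the disease profile", {
  cfg <- small_gen_config(sensitivity = 1, noise_rate = 0)
  corp <- generate_corpus(cfg)
  profiles <- attr(corp, "profiles")
  codes <- vapply(profiles, `[[`, "", "disease")
  for (cs in corp$cases) {
    d <- match(confirmed_diseases(cs), codes)
    expect_setequal(vocab_index(corp$symptom_vocab, cs$symptoms),
                    profiles[[d]]$symptoms)
  }
})

test_that("mean symptoms per case matches the closed-form expectation", {
  cfg <- generator_config(seed = 7)  # default study conditions
  corp <- default_corpus(7)
  sizes <- vapply(attr(corp, "profiles"), function(p) length(p$symptoms), 0)
  counts <- vapply(corp$cases, function(cs) length(cs$symptoms), 0)
  confirmed <- vapply(corp$cases, function(cs) {
    match(confirmed_diseases(cs), vapply(attr(corp, "profiles"), `[[`, "",
                                         "disease"))
  }, 0)
  expected <- cfg$sensitivity * mean(sizes[confirmed]) + cfg$noise_rate
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("confirmed-disease frequencies follow the prevalence weights", {
  corp <- default_corpus(7)
  profiles <- attr(corp, "profiles")
  codes <- vapply(profiles, `[[`, "", "disease")
  prev <- vapply(profiles, `[[`, 0, "prevalence")
  confirmed <- vapply(corp$cases, function(cs) {
    match(confirmed_diseases(cs), codes)
  }, 0)
  counts <- tabulate(confirmed, nbins = length(codes))
  # bin prevalence-sorted diseases so expected counts are large enough for
  # the chi-square approximation
  ord <- order(prev)
  bins <- cut(seq_along(ord), 10)
  obs <- tapply(counts[ord], bins, sum)
  p <- tapply(prev[ord], bins, sum) / sum(prev)
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("trajectory fixtures order symptoms most-common-first", {
  cfg <- small_gen_config()
  profiles <- make_profiles(cfg)
  cs1 <- generate_trajectory_fixture(cfg, "D003", profiles)
  cs2 <- generate_trajectory_fixture(cfg, "D003", profiles)
  expect_identical(cs1, cs2)
  expect_error(generate_trajectory_fixture(cfg, "nope"), "unknown disease")
  df <- tabulate(unlist(lapply(profiles, `[[`, "symptoms")),
                 nbins = cfg$n_symptoms)
  freq <- df[as.integer(sub("^S", "", cs1$symptoms))]
  expect_true(all(diff(freq) <= 0))
  expect_gte(freq[1], freq[length(freq)])
  expect_equal(confirmed_diseases(cs1), "D003")
})
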