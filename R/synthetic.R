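#' Synthetic case-corpus generator configuration
#'
#' The generator emulates the statistical structure of graded listwise case
#' data: each disease carries a latent characteristic-symptom profile;
#' a case observes a noisy subset of its confirmed disease's profile; the
#' differential diseases are the other diseases whose profiles best overlap
#' the observed symptoms, graded with geometrically decaying scores below
#' the confirmed disease's score.
#'
#' @param n_diseases,n_symptoms,n_cases corpus dimensions
#'   (defaults 200, 400, 2000).
#' @param profile_size integer range `c(min, max)` of characteristic-profile
#'   sizes per disease (default 6..12 symptoms).
#' @param sensitivity probability that a profile symptom is observed in a
#'   case of that disease (default 0.8).
#' @param noise_rate expected count (Poisson mean) of off-profile symptoms
#'   added per case (default 1.5).
#' @param n_differentials integer range of differential diseases graded per
#'   case (default 4..9).
#' @param confirmed_score relevance score of the confirmed disease
#'   (default 17, cosmetically matching published listwise case tables).
#' @param decay geometric decay in (0, 1) of differential scores by overlap
#'   rank (default 0.7).
#' @param profile_mode `"random"` (profiles sampled independently, so they
#'   overlap — which is what makes differentials plausible) or `"disjoint"`
#'   (symptoms partitioned between diseases: a noiseless separable corpus).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_diseases = 200L, n_symptoms = 400L,
                             n_cases = 2000L, profile_size = c(6L, 12L),
                             sensitivity = 0.8, noise_rate = 1.5,
                             n_differentials = c(4L, 9L),
                             confirmed_score = 17, decay = 0.7,
                             profile_mode = c("random", "disjoint"),
                             seed = 7L) {
  profile_mode <- match.arg(profile_mode)
  profile_size <- as.integer(rep(profile_size, length.out = 2L))
  n_differentials <- as.integer(rep(n_differentials, length.out = 2L))
  cfg <- structure(
    list(n_diseases = as.integer(n_diseases),
         n_symptoms = as.integer(n_symptoms), n_cases = as.integer(n_cases),
         profile_size = profile_size, sensitivity = as.numeric(sensitivity),
         noise_rate = as.numeric(noise_rate),
         n_differentials = n_differentials,
         confirmed_score = as.numeric(confirmed_score),
         decay = as.numeric(decay), profile_mode = profile_mode,
         seed = as.integer(seed)),
    class = "generator_config")
  with(cfg, {
    stopifnot(n_diseases >= 1L, n_symptoms >= 1L, n_cases >= 0L,
              profile_size[1L] >= 1L, profile_size[1L] <= profile_size[2L],
              sensitivity >= 0, sensitivity <= 1, noise_rate >= 0,
              n_differentials[1L] >= 0L,
              n_differentials[1L] <= n_differentials[2L],
              confirmed_score > 0, decay > 0, decay < 1)
  })
  if (cfg$profile_size[2L] > cfg$n_symptoms) {
    stop("profile size cannot exceed the number of symptoms", call. = FALSE)
  }
  if (cfg$profile_mode == "disjoint" &&
      cfg$n_diseases * cfg$profile_size[2L] > cfg$n_symptoms) {
    stop("disjoint profiles need n_diseases * max profile size <= n_symptoms",
         call. = FALSE)
  }
  cfg
}

#' Draw latent disease profiles
#'
#' Each disease gets a characteristic symptom set (profile) and a positive
#' prevalence weight (log-normal, giving the long tail of rare diseases).
#' Under `profile_mode = "random"` profiles are sampled independently and
#' may share symptoms; under `"disjoint"` the symptom vocabulary is
#' partitioned.
#'
#' @param config a [generator_config()].
#' @return List of `n_diseases` profiles, each a list with `disease`
#'   (code), `symptoms` (integer symptom indices) and `prevalence`
#'   (positive weight).
#' @export
make_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rng <- local_rng(config$seed)
  sizes <- if (config$profile_size[1L] == config$profile_size[2L]) {
    rep(config$profile_size[1L], config$n_diseases)
  } else {
    config$profile_size[1L] + rng$sample_int(
      config$profile_size[2L] - config$profile_size[1L] + 1L,
      config$n_diseases, replace = TRUE) - 1L
  }
  prevalence <- exp(rng$norm(config$n_diseases, sd = 1))
  profiles <- vector("list", config$n_diseases)
  if (config$profile_mode == "disjoint") {
    pool <- rng$sample_int(config$n_symptoms, config$n_symptoms)
    at <- 1L
    for (d in seq_len(config$n_diseases)) {
      profiles[[d]] <- list(disease = disease_code(d),
                            symptoms = sort(pool[at:(at + sizes[d] - 1L)]),
                            prevalence = prevalence[d])
      at <- at + sizes[d]
    }
  } else {
    for (d in seq_len(config$n_diseases)) {
      profiles[[d]] <- list(disease = disease_code(d),
                            symptoms = sort(rng$sample_int(config$n_symptoms,
                                                           sizes[d])),
                            prevalence = prevalence[d])
    }
  }
  profiles
}

disease_code <- function(i) sprintf("D%03d", i)
symptom_code <- function(i) sprintf("S%03d", i)

synthetic_vocabs <- function(config) {
  list(symptom = vocabulary(symptom_code(seq_len(config$n_symptoms)),
                            sprintf("Symptom %d", seq_len(config$n_symptoms)),
                            "symptom"),
       disease = vocabulary(disease_code(seq_len(config$n_diseases)),
                            sprintf("Disease %d", seq_len(config$n_diseases)),
                            "disease"))
}

# Jaccard similarity of each profile to an observed symptom index set.
profile_overlap <- function(profiles, observed) {
  obs <- unique(observed)
  vapply(profiles, function(p) {
    inter <- length(intersect(p$symptoms, obs))
    inter / (length(p$symptoms) + length(obs) - inter)
  }, 0)
}

#' Generate a synthetic graded case corpus
#'
#' For each case: a confirmed disease is drawn proportional to prevalence;
#' its profile symptoms are each observed with probability `sensitivity`,
#' plus a Poisson(`noise_rate`) count of uniformly drawn off-profile
#' symptoms (at least one profile symptom is always retained so the case is
#' non-empty); the differential diseases are the other diseases with the
#' highest Jaccard overlap between their profile and the observed symptoms
#' (ties broken by vocabulary index), scored
#' `confirmed_score * decay^rank`; the confirmed disease scores
#' `confirmed_score`. Symptom order within the case is a random permutation
#' (acquisition order carries no signal here).
#'
#' @param config a [generator_config()].
#' @param profiles optionally, profiles from [make_profiles()] (re-drawn
#'   from the config when omitted).
#' @return A validated `dx_corpus`; the latent profiles are attached as
#'   attribute `"profiles"`.
#' @export
generate_corpus <- function(config, profiles = make_profiles(config)) {
  stopifnot(inherits(config, "generator_config"))
  vocabs <- synthetic_vocabs(config)
  rng <- local_rng(config$seed + 1L) # profiles consumed seed; offset stream
  prev <- vapply(profiles, `[[`, 0, "prevalence")
  n_diff_span <- config$n_differentials[2L] - config$n_differentials[1L] + 1L
  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    d <- rng$sample_int(config$n_diseases, 1L, prob = prev)
    prof <- profiles[[d]]$symptoms
    keep <- rng$unif(length(prof)) < config$sensitivity
    if (!any(keep)) keep[rng$sample_int(length(prof), 1L)] <- TRUE
    observed <- prof[keep]
    off <- setdiff(seq_len(config$n_symptoms), prof)
    n_noise <- min(rng$pois(1L, config$noise_rate), length(off))
    if (n_noise > 0L) {
      observed <- c(observed, off[rng$sample_int(length(off), n_noise)])
    }
    observed <- observed[rng$sample_int(length(observed), length(observed))]

    n_diff <- min(config$n_differentials[1L] +
                    rng$sample_int(n_diff_span, 1L) - 1L,
                  config$n_diseases - 1L)
    rel <- stats::setNames(config$confirmed_score, disease_code(d))
    if (n_diff > 0L) {
      ov <- profile_overlap(profiles, observed)
      ov[d] <- -Inf
      diff_idx <- order(-ov, seq_along(ov))[seq_len(n_diff)]
      rel <- c(rel, stats::setNames(
        config$confirmed_score * config$decay^seq_len(n_diff),
        disease_code(diff_idx)))
    }
    cases[[i]] <- case_record(
      case_id = sprintf("case%05d", i),
      symptoms = symptom_code(observed),
      relevances = rel,
      provenance = sprintf("synthetic: disease %s", disease_code(d)))
  }
  corpus <- case_corpus(vocabs$symptom, vocabs$disease, cases)
  attr(corpus, "profiles") <- profiles
  corpus
}

#' Build a progressive-input trajectory fixture
#'
#' Emits one case for a chosen target disease whose symptoms are ordered
#' least-specific-first: ascending inverse document frequency across the
#' disease profiles, so common, uninformative symptoms are "acquired" before
#' rare, characteristic ones — the shape of progressive bedside input in
#' published case studies.
#'
#' @param config a [generator_config()].
#' @param target target disease code (must exist).
#' @param profiles optionally, profiles from [make_profiles()].
#' @return A `dx_case` whose `symptoms` are IDF-ordered.
#' @export
generate_trajectory_fixture <- function(config, target,
                                        profiles = make_profiles(config)) {
  stopifnot(inherits(config, "generator_config"))
  codes <- vapply(profiles, `[[`, "", "disease")
  d <- match(target, codes)
  if (is.na(d)) {
    stop(sprintf("unknown disease code: '%s'", target), call. = FALSE)
  }
  rng <- local_rng(config$seed + 2L)
  prof <- profiles[[d]]$symptoms
  keep <- rng$unif(length(prof)) < config$sensitivity
  if (!any(keep)) keep[rng$sample_int(length(prof), 1L)] <- TRUE
  observed <- prof[keep]
  off <- setdiff(seq_len(config$n_symptoms), prof)
  n_noise <- min(rng$pois(1L, config$noise_rate), length(off))
  if (n_noise > 0L) {
    observed <- c(observed, off[rng$sample_int(length(off), n_noise)])
  }
  # document frequency of each symptom across profiles; frequent first
  df <- tabulate(unlist(lapply(profiles, `[[`, "symptoms")),
                 nbins = config$n_symptoms)
  observed <- observed[order(-df[observed], observed)]

  n_diff <- min(config$n_differentials[2L], config$n_diseases - 1L)
  rel <- stats::setNames(config$confirmed_score, disease_code(d))
  if (n_diff > 0L) {
    ov <- profile_overlap(profiles, observed)
    ov[d] <- -Inf
    diff_idx <- order(-ov, seq_along(ov))[seq_len(n_diff)]
    rel <- c(rel, stats::setNames(
      config$confirmed_score * config$decay^seq_len(n_diff),
      disease_code(diff_idx)))
  }
  case_record(case_id = sprintf("trajectory_%s", target),
              symptoms = symptom_code(observed), relevances = rel,
              provenance = sprintf("synthetic trajectory: target %s", target))
}
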