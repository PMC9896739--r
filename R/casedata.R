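#' Construct a single diagnostic case record
#'
#' A case is the listwise training unit: the symptoms observed for one
#' patient (in order of clinical acquisition) together with a graded
#' relevance list over diseases. The maximum-scoring entry (or entries)
#' designate the confirmed disease(s); lower positive scores grade the
#' differential diseases; every disease not listed has relevance 0.
#'
#' @param case_id unique case identifier string.
#' @param symptoms character vector of symptom codes, acquisition order,
#'   no duplicates, at least one.
#' @param relevances named numeric vector: names are disease codes, values
#'   are nonnegative relevance scores; at least one value must be positive.
#' @param provenance free-text origin note (e.g. a citation).
#' @return An object of class `dx_case`.
#' @export
case_record <- function(case_id, symptoms, relevances, provenance = "") {
  case_id <- as.character(case_id)
  if (length(case_id) != 1L || !nzchar(case_id)) {
    stop("case_id must be a single non-empty string", call. = FALSE)
  }
  symptoms <- as.character(symptoms)
  if (length(symptoms) < 1L) {
    stop(sprintf("case '%s': at least one symptom required", case_id),
         call. = FALSE)
  }
  if (anyDuplicated(symptoms)) {
    stop(sprintf("case '%s': duplicate symptom code '%s'", case_id,
                 symptoms[duplicated(symptoms)][1L]), call. = FALSE)
  }
  rel <- as.numeric(relevances)
  codes <- names(relevances)
  if (is.null(codes) || any(!nzchar(codes))) {
    stop(sprintf("case '%s': relevances must be named by disease code",
                 case_id), call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop(sprintf("case '%s': duplicate disease code '%s'", case_id,
                 codes[duplicated(codes)][1L]), call. = FALSE)
  }
  if (anyNA(rel) || any(rel < 0)) {
    stop(sprintf("case '%s': relevance scores must be nonnegative", case_id),
         call. = FALSE)
  }
  if (!any(rel > 0)) {
    stop(sprintf("case '%s': at least one relevance score must be positive",
                 case_id), call. = FALSE)
  }
  structure(
    list(case_id = case_id, symptoms = symptoms,
         relevances = stats::setNames(rel, codes),
         provenance = as.character(provenance)),
    class = "dx_case")
}

#' @export
print.dx_case <- function(x, ...) {
  cat(sprintf("<dx_case '%s': %d symptoms, %d graded diseases>\n",
              x$case_id, length(x$symptoms), length(x$relevances)))
  invisible(x)
}

#' Confirmed disease(s) of a case
#'
#' The disease code(s) carrying the maximal relevance score.
#'
#' @param case a `dx_case`.
#' @return Character vector of disease codes (usually length 1).
#' @export
confirmed_diseases <- function(case) {
  stopifnot(inherits(case, "dx_case"))
  names(case$relevances)[case$relevances == max(case$relevances)]
}

#' Construct a validated case corpus
#'
#' Binds a set of case records to the symptom and disease vocabularies they
#' reference, checking that every code exists and case ids are unique.
#'
#' @param symptom_vocab a symptom `dx_vocabulary`.
#' @param disease_vocab a disease `dx_vocabulary`.
#' @param cases list of `dx_case` records.
#' @return An object of class `dx_corpus`.
#' @export
case_corpus <- function(symptom_vocab, disease_vocab, cases) {
  stopifnot(inherits(symptom_vocab, "dx_vocabulary"),
            inherits(disease_vocab, "dx_vocabulary"))
  if (!is.list(cases) || !all(vapply(cases, inherits, TRUE, "dx_case"))) {
    stop("cases must be a list of dx_case records", call. = FALSE)
  }
  ids <- vapply(cases, `[[`, "", "case_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate case_id: '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  for (cs in cases) {
    bad_s <- setdiff(cs$symptoms, symptom_vocab$code)
    if (length(bad_s)) {
      stop(sprintf("case '%s': unknown symptom code '%s'",
                   cs$case_id, bad_s[1L]), call. = FALSE)
    }
    bad_d <- setdiff(names(cs$relevances), disease_vocab$code)
    if (length(bad_d)) {
      stop(sprintf("case '%s': unknown disease code '%s'",
                   cs$case_id, bad_d[1L]), call. = FALSE)
    }
  }
  structure(
    list(symptom_vocab = symptom_vocab, disease_vocab = disease_vocab,
         cases = cases),
    class = "dx_corpus")
}

#' @export
print.dx_corpus <- function(x, ...) {
  cat(sprintf("<dx_corpus: %d cases, %d symptoms, %d diseases>\n",
              length(x$cases), vocab_size(x$symptom_vocab),
              vocab_size(x$disease_vocab)))
  invisible(x)
}

#' @export
length.dx_corpus <- function(x) length(x$cases)

#' Read a case corpus from JSON-lines plus vocabulary files
#'
#' The corpus file holds one case per line as a JSON object with fields
#' `case_id`, `symptoms` (array of codes), `relevances` (array of
#' `[code, score]` pairs) and optional `provenance`. Vocabularies are
#' two-column TSV files (see [read_vocabulary()]).
#'
#' @param path corpus JSONL file path.
#' @param symptom_vocab_path,disease_vocab_path vocabulary TSV paths.
#' @return A validated `dx_corpus`. An empty corpus file yields a corpus
#'   with zero cases.
#' @export
read_corpus <- function(path, symptom_vocab_path, disease_vocab_path) {
  sv <- read_vocabulary(symptom_vocab_path, "symptom")
  dv <- read_vocabulary(disease_vocab_path, "disease")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cases <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed corpus line %d in '%s': %s",
                     i, path, conditionMessage(e)), call. = FALSE)
      })
    need <- c("case_id", "symptoms", "relevances")
    if (!all(need %in% names(rec))) {
      stop(sprintf("malformed corpus line %d in '%s': missing field(s) %s",
                   i, path,
                   paste(setdiff(need, names(rec)), collapse = ", ")),
           call. = FALSE)
    }
    rel_codes <- vapply(rec$relevances, function(p) as.character(p[[1L]]), "")
    rel_vals <- vapply(rec$relevances, function(p) as.numeric(p[[2L]]), 0)
    cases[[i]] <- case_record(
      case_id = rec$case_id,
      symptoms = unlist(rec$symptoms, use.names = FALSE),
      relevances = stats::setNames(rel_vals, rel_codes),
      provenance = if (is.null(rec$provenance)) "" else rec$provenance)
  }
  case_corpus(sv, dv, cases)
}

#' Write a case corpus to JSON-lines plus vocabulary files
#'
#' Inverse of [read_corpus()]: reading the written files reproduces the
#' corpus exactly.
#'
#' @param corpus a `dx_corpus`.
#' @param path corpus JSONL output path.
#' @param symptom_vocab_path,disease_vocab_path vocabulary TSV output paths;
#'   omit (`NULL`) to skip writing the vocabularies.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path, symptom_vocab_path = NULL,
                         disease_vocab_path = NULL) {
  stopifnot(inherits(corpus, "dx_corpus"))
  lines <- vapply(corpus$cases, function(cs) {
    jsonlite::toJSON(
      list(case_id = jsonlite::unbox(cs$case_id),
           symptoms = cs$symptoms,
           relevances = lapply(seq_along(cs$relevances), function(i) {
             list(jsonlite::unbox(names(cs$relevances)[i]),
                  jsonlite::unbox(unname(cs$relevances[i])))
           }),
           provenance = jsonlite::unbox(cs$provenance)),
      digits = NA)
  }, "")
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(lines, con)
  close(con)
  if (!is.null(symptom_vocab_path)) {
    write_vocabulary(corpus$symptom_vocab, symptom_vocab_path)
  }
  if (!is.null(disease_vocab_path)) {
    write_vocabulary(corpus$disease_vocab, disease_vocab_path)
  }
  invisible(path)
}

#' Expand a case to dense model vectors
#'
#' Converts a case to the explanatory/explained variable pair the scorer
#' consumes: a multi-hot symptom indicator over the symptom vocabulary and a
#' dense relevance label vector over the disease vocabulary (0 for every
#' disease the case does not grade).
#'
#' @param case a `dx_case`.
#' @param corpus the `dx_corpus` carrying the vocabularies (or any object
#'   with `symptom_vocab` / `disease_vocab` fields).
#' @return List with `x` (0/1 numeric vector, length = symptom vocabulary
#'   size) and `rel` (nonnegative numeric vector, length = disease
#'   vocabulary size).
#' @export
densify <- function(case, corpus) {
  stopifnot(inherits(case, "dx_case"))
  x <- numeric(vocab_size(corpus$symptom_vocab))
  x[vocab_index(corpus$symptom_vocab, case$symptoms)] <- 1
  rel <- numeric(vocab_size(corpus$disease_vocab))
  rel[vocab_index(corpus$disease_vocab, names(case$relevances))] <-
    unname(case$relevances)
  list(x = x, rel = rel)
}

#' Dense matrices for a whole corpus
#'
#' Stacks [densify()] over all cases: rows are cases.
#'
#' @param corpus a `dx_corpus`.
#' @return List with `X` (cases x symptom-vocab 0/1 matrix) and `R`
#'   (cases x disease-vocab label matrix), rownames = case ids.
#' @export
densify_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "dx_corpus"))
  n <- length(corpus$cases)
  X <- matrix(0, n, vocab_size(corpus$symptom_vocab))
  R <- matrix(0, n, vocab_size(corpus$disease_vocab))
  for (i in seq_len(n)) {
    d <- densify(corpus$cases[[i]], corpus)
    X[i, ] <- d$x
    R[i, ] <- d$rel
  }
  rownames(X) <- rownames(R) <- vapply(corpus$cases, `[[`, "", "case_id")
  list(X = X, R = R)
}

#' Pair model scores with relevance labels for one case
#'
#' The container every metric and loss consumes: two parallel numeric
#' vectors over the disease vocabulary.
#'
#' @param scores numeric vector of model scores.
#' @param rel numeric vector of nonnegative relevance labels, same length.
#' @return An object of class `scored_list`.
#' @export
scored_list <- function(scores, rel) {
  scores <- as.numeric(scores)
  rel <- as.numeric(rel)
  if (length(scores) != length(rel)) {
    stop(sprintf("scores (%d) and labels (%d) must have equal length",
                 length(scores), length(rel)), call. = FALSE)
  }
  if (length(scores) == 0L) stop("scored_list must be non-empty", call. = FALSE)
  if (anyNA(scores) || anyNA(rel) || any(!is.finite(scores))) {
    stop("scores and labels must be finite", call. = FALSE)
  }
  if (any(rel < 0)) stop("relevance labels must be nonnegative", call. = FALSE)
  structure(list(scores = scores, rel = rel), class = "scored_list")
}

#' @export
print.scored_list <- function(x, ...) {
  cat(sprintf("<scored_list: %d items, %d with positive relevance>\n",
              length(x$scores), sum(x$rel > 0)))
  invisible(x)
}
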