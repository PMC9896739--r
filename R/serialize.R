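#' Write a ranking model to a portable JSON archive
#'
#' Weights are stored with explicit shapes at maximum JSON precision
#' (15 significant digits), alongside both vocabularies verbatim, so that
#' [read_model()]
#' can refuse a load against mismatched vocabularies and report exactly
#' which code differs.
#'
#' @param model a `dx_model`.
#' @param path output path (plain-text JSON).
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "dx_model"))
  payload <- list(
    format = "dxrank-model/1",
    hidden = model$hidden, seed = model$seed,
    activation = model$activation, trained = model$trained,
    loss = model$loss,
    symptom_vocab = list(code = model$symptom_vocab$code,
                         label = model$symptom_vocab$label),
    disease_vocab = list(code = model$disease_vocab$code,
                         label = model$disease_vocab$label),
    shapes = list(W1 = dim(model$W1), W2 = dim(model$W2)),
    W1 = as.numeric(model$W1), b1 = model$b1,
    W2 = as.numeric(model$W2), b2 = model$b2)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a ranking model from a JSON archive
#'
#' @param path archive path written by [write_model()].
#' @param symptom_vocab,disease_vocab optional vocabularies to validate
#'   against: loading fails if codes or order differ from those stored in
#'   the archive.
#' @return A `dx_model`.
#' @export
read_model <- function(path, symptom_vocab = NULL, disease_vocab = NULL) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dxrank-model/1")) {
    stop(sprintf("'%s' is not a dxrank model archive", path), call. = FALSE)
  }
  sv <- vocabulary(p$symptom_vocab$code, p$symptom_vocab$label, "symptom")
  dv <- vocabulary(p$disease_vocab$code, p$disease_vocab$label, "disease")
  if (!is.null(symptom_vocab) && !identical(symptom_vocab$code, sv$code)) {
    stop("symptom vocabulary does not match the one the model was trained on",
         call. = FALSE)
  }
  if (!is.null(disease_vocab) && !identical(disease_vocab$code, dv$code)) {
    stop("disease vocabulary does not match the one the model was trained on",
         call. = FALSE)
  }
  model <- structure(
    list(symptom_vocab = sv, disease_vocab = dv,
         hidden = as.integer(p$hidden), seed = as.integer(p$seed),
         W1 = matrix(p$W1, p$shapes$W1[1L], p$shapes$W1[2L]),
         b1 = as.numeric(p$b1),
         W2 = matrix(p$W2, p$shapes$W2[1L], p$shapes$W2[2L]),
         b2 = as.numeric(p$b2),
         activation = p$activation, trained = isTRUE(p$trained),
         loss = if (is.null(p$loss)) NA_character_ else p$loss),
    class = "dx_model")
  if (vocab_size(sv) != nrow(model$W1) || vocab_size(dv) != ncol(model$W2)) {
    stop("model archive is inconsistent: weight shapes do not match vocabularies",
         call. = FALSE)
  }
  model
}
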