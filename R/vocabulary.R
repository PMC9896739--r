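#' Construct a symptom or disease vocabulary
#'
#' A vocabulary is an ordered set of unique codes with display labels. Its
#' order is the file order and is load-bearing: it fixes the dimension and
#' element order of every vector the model consumes, and it is the global
#' tie-breaking order wherever ranks are assigned to equal scores.
#'
#' @param codes character vector of unique, non-empty codes.
#' @param labels character vector of display labels, same length as `codes`.
#'   Defaults to the codes themselves.
#' @param kind `"symptom"` or `"disease"`.
#' @return An object of class `dx_vocabulary`: a data.frame with columns
#'   `code` and `label`, row order defining the code -> 0-based index map.
#' @examples
#' v <- vocabulary(c("fever", "headache"), c("Fever", "Headache"), "symptom")
#' vocab_index(v, "headache")  # 2 (1-based position)
#' @export
vocabulary <- function(codes, labels = codes, kind = c("symptom", "disease")) {
  kind <- match.arg(kind)
  codes <- as.character(codes)
  labels <- as.character(labels)
  if (length(codes) == 0L) {
    stop("vocabulary must contain at least one code", call. = FALSE)
  }
  if (length(labels) != length(codes)) {
    stop("codes and labels must have equal length", call. = FALSE)
  }
  if (anyNA(codes) || any(!nzchar(codes))) {
    stop("vocabulary codes must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    dup <- codes[duplicated(codes)][1L]
    stop(sprintf("duplicate vocabulary code: '%s'", dup), call. = FALSE)
  }
  out <- data.frame(code = codes, label = labels, stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  class(out) <- c("dx_vocabulary", "data.frame")
  out
}

#' @export
print.dx_vocabulary <- function(x, ...) {
  cat(sprintf("<dx_vocabulary: %d %s codes>\n", nrow(x), attr(x, "kind")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Size of a vocabulary
#' @param vocab a `dx_vocabulary`.
#' @return Integer count of codes.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "dx_vocabulary"))
  nrow(vocab)
}

#' Look up 1-based positions of codes in a vocabulary
#'
#' @param vocab a `dx_vocabulary`.
#' @param codes character vector of codes.
#' @return Integer vector of 1-based positions (NA never returned: unknown
#'   codes are an error).
#' @export
vocab_index <- function(vocab, codes) {
  stopifnot(inherits(vocab, "dx_vocabulary"))
  idx <- match(as.character(codes), vocab$code)
  if (anyNA(idx)) {
    bad <- codes[is.na(idx)][1L]
    stop(sprintf("unknown %s code: '%s'", attr(vocab, "kind"), bad),
         call. = FALSE)
  }
  idx
}

#' Read a vocabulary from a two-column TSV file
#'
#' Expects a UTF-8 tab-separated file with a header row naming the columns
#' `code` and `label`.
#'
#' @param path file path.
#' @param kind `"symptom"` or `"disease"`.
#' @return A `dx_vocabulary`.
#' @export
read_vocabulary <- function(path, kind = c("symptom", "disease")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8", check.names = FALSE)
  if (!all(c("code", "label") %in% names(tab))) {
    stop(sprintf("vocabulary file '%s' must have 'code' and 'label' columns",
                 path), call. = FALSE)
  }
  vocabulary(tab$code, tab$label, kind)
}

#' Write a vocabulary to a two-column TSV file
#' @param vocab a `dx_vocabulary`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "dx_vocabulary"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("code\tlabel", con)
  writeLines(paste(vocab$code, vocab$label, sep = "\t"), con)
  invisible(path)
}
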