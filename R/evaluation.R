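#' Precision, recall and F1 for binary labels
#'
#' Computes the confusion counts and the derived metrics for a binary
#' classification task, with class 1 ("relevant") as the positive class.
#' Degenerate cases use the conventions that keep F1 defined: with no
#' predicted positives precision is 0, with no true positives recall is 0,
#' and F1 is 0 whenever precision + recall is 0.
#'
#' @param truth integer or logical vector of reference labels (0/1).
#' @param predicted integer or logical vector of predicted labels (0/1),
#'   same length as `truth`.
#' @return An object of class `hbgru_metrics`: a list with counts `tp`,
#'   `fp`, `fn`, `tn` and reals `precision`, `recall`, `f1`.
#' @examples
#' m <- precision_recall_f1(c(1, 1, 1, 0), c(1, 1, 0, 1))
#' m$f1  # 2/3
#' @export
precision_recall_f1 <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    validation_error("`truth` (%d) and `predicted` (%d) lengths differ",
                     length(truth), length(predicted))
  }
  if (length(truth) < 1L) validation_error("need at least one label pair")
  if (anyNA(truth) || anyNA(predicted) ||
      !all(truth %in% 0:1) || !all(predicted %in% 0:1)) {
    validation_error("labels must be binary 0/1 with no missing values")
  }
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  tn <- sum(truth == 0L & predicted == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = precision, recall = recall, f1 = f1),
    class = "hbgru_metrics"
  )
}

#' @export
print.hbgru_metrics <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (tp %d, fp %d, fn %d, tn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' F1 score from a precision/recall pair
#'
#' The harmonic mean 2pr/(p + r), rounded for reporting. Useful as an
#' arithmetic identity check against published precision/recall/F1 triples.
#'
#' @param p precision in \[0, 1\].
#' @param r recall in \[0, 1\].
#' @param digits decimal places for the reported value (default 4, matching
#'   the usual presentation of shared-task scores); `NA` for no rounding.
#' @return The (rounded) F1 score; 0 when both inputs are 0.
#' @examples
#' f1_from_precision_recall(0.6289, 0.7656)  # 0.6906
#' @export
f1_from_precision_recall <- function(p, r, digits = 4) {
  assert_scalar_number(p, "p", 0, 1)
  assert_scalar_number(r, "r", 0, 1)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  if (is.na(digits)) f1 else round(f1, digits)
}

#' Corpus statistics for choosing document dimensions
#'
#' Class balance plus sentence-count and words-per-sentence distributions,
#' the quantities used to choose the maximum number of sentences per
#' document (M) and words per sentence (N).
#'
#' @param corpus a documents data frame (see [read_documents()]) or a list
#'   of tokenized documents from [preprocess_document()].
#' @param config a [preprocess_config()] used to tokenize raw documents;
#'   ignored for already-tokenized input.
#' @return An object of class `hbgru_corpus_stats` with fields
#'   `n_documents`, `n_positive`, `positive_fraction` (percent),
#'   `sentences_per_document` and `words_per_sentence` (integer vectors).
#' @seealso [coverage_sentences()], [coverage_words()]
#' @export
corpus_stats <- function(corpus, config = preprocess_config()) {
  if (is.data.frame(corpus)) {
    validate_documents(corpus)
    labels <- corpus$label
    toks <- lapply(seq_len(nrow(corpus)), function(i) {
      preprocess_document(corpus[i, , drop = FALSE], config = config)
    })
  } else if (is.list(corpus) && length(corpus) > 0L &&
             all(vapply(corpus, inherits, logical(1), "tokenized_document"))) {
    labels <- vapply(corpus, function(d) attr(d, "label") %||% NA_integer_,
                     numeric(1))
    toks <- corpus
  } else {
    validation_error("`corpus` must be a documents data frame or a list of tokenized documents")
  }
  if (length(toks) == 0L) validation_error("corpus is empty")
  n_sent <- vapply(toks, function(d) length(d$sentences), integer(1))
  n_words <- unlist(lapply(toks, function(d) lengths(d$sentences)), use.names = FALSE)
  n_pos <- sum(labels == 1, na.rm = TRUE)
  structure(
    list(n_documents = length(toks),
         n_positive = n_pos,
         positive_fraction = 100 * n_pos / length(toks),
         sentences_per_document = n_sent,
         words_per_sentence = n_words),
    class = "hbgru_corpus_stats"
  )
}

#' @rdname corpus_stats
#' @param stats an `hbgru_corpus_stats` object.
#' @param m maximum sentence count being considered.
#' @return `coverage_sentences()`: the percentage of documents with at most
#'   `m` sentences; non-decreasing in `m`.
#' @export
coverage_sentences <- function(stats, m) {
  stopifnot(inherits(stats, "hbgru_corpus_stats"))
  100 * mean(stats$sentences_per_document <= m)
}

#' @rdname corpus_stats
#' @param n maximum words-per-sentence being considered.
#' @return `coverage_words()`: the percentage of sentences with at most `n`
#'   words.
#' @export
coverage_words <- function(stats, n) {
  stopifnot(inherits(stats, "hbgru_corpus_stats"))
  100 * mean(stats$words_per_sentence <= n)
}

#' @export
print.hbgru_corpus_stats <- function(x, ...) {
  cat(sprintf("%d documents, %d positive (%.2f%%)\n",
              x$n_documents, x$n_positive, x$positive_fraction))
  cat(sprintf("sentences/document: median %d, max %d\n",
              as.integer(stats::median(x$sentences_per_document)),
              max(x$sentences_per_document)))
  cat(sprintf("words/sentence: median %d, max %d\n",
              as.integer(stats::median(x$words_per_sentence)),
              max(x$words_per_sentence)))
  invisible(x)
}
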