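# Vocabulary construction and embedding-matrix initialization: pre-trained
# vectors where available, uniform(-0.05, 0.05) for the unknown token and
# the entity tag tokens, zeros for padding.

UNK_TOKEN <- "<unk>"
PAD_TOKEN <- "<pad>"

#' Build a vocabulary from a tokenized corpus
#'
#' Index 0 is reserved for padding and `<unk>` holds index 1; corpus
#' tokens follow, ordered by decreasing frequency with ties broken
#' lexicographically, so the mapping is deterministic under any permutation
#' of the corpus. With `annotate = TRUE` the ten entity tag tokens
#' (`<gene>`, `</gene>`, ...) are guaranteed a slot even if absent from
#' the corpus.
#'
#' @param corpus non-empty list of `tokenized_document` objects (or plain
#'   character vectors of tokens).
#' @param annotate reserve slots for the entity tag tokens.
#' @return An object of class `hbgru_vocab`: a named integer vector of
#'   0-based indices with attribute `annotate`.
#' @export
build_vocab <- function(corpus, annotate = FALSE) {
  if (length(corpus) == 0L) validation_error("corpus is empty")
  tokens <- unlist(lapply(corpus, function(d) {
    if (inherits(d, "tokenized_document")) unlist(d$sentences, use.names = FALSE)
    else as.character(d)
  }), use.names = FALSE)
  if (length(tokens) == 0L) validation_error("corpus contains no tokens")
  freq <- table(tokens)
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  words <- names(freq)[ord]
  words <- setdiff(words, c(PAD_TOKEN, UNK_TOKEN))
  extra <- if (annotate) setdiff(ENTITY_TAG_TOKENS, words) else character(0)
  all_tokens <- c(PAD_TOKEN, UNK_TOKEN, words, extra)
  idx <- seq_along(all_tokens) - 1L
  names(idx) <- all_tokens
  structure(idx, annotate = annotate, class = "hbgru_vocab")
}

#' @rdname build_vocab
#' @param vocab an `hbgru_vocab`.
#' @return `vocab_size()`: number of entries including padding and
#'   `<unk>`.
#' @export
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "hbgru_vocab"))
  length(vocab)
}

#' Map tokens to vocabulary indices
#'
#' Tokens absent from the vocabulary map to the `<unk>` index.
#'
#' @param vocab an `hbgru_vocab`.
#' @param tokens character vector.
#' @return Integer vector of 0-based indices.
#' @export
token_index <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "hbgru_vocab"))
  idx <- unclass(vocab)[tokens]
  idx[is.na(idx)] <- unclass(vocab)[[UNK_TOKEN]]
  unname(idx)
}

#' @rdname build_vocab
#' @param path file path for the two-column (token, index) serialization.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "hbgru_vocab"))
  writeLines(sprintf("%s\t%d", names(vocab), unclass(vocab)), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname build_vocab
#' @export
read_vocab <- function(path) {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) parse_error("vocabulary lines must be token<TAB>index")
  idx <- as.integer(vapply(parts, `[[`, character(1), 2L))
  names(idx) <- vapply(parts, `[[`, character(1), 1L)
  idx <- sort(idx)
  if (!identical(unname(idx), seq_along(idx) - 1L)) {
    validation_error("vocabulary indices must be contiguous from 0")
  }
  structure(idx, annotate = all(ENTITY_TAG_TOKENS %in% names(idx)),
            class = "hbgru_vocab")
}

#' Initialize the embedding matrix
#'
#' Rows for words found in the pre-trained set are copied verbatim; the
#' `<unk>` token and the entity tag tokens draw i.i.d. uniform(-0.05, 0.05)
#' components from the seeded generator; the padding row (index 0) is all
#' zeros. By default, corpus words with no pre-trained vector receive no
#' row of their own: they are collapsed onto `<unk>` in the returned
#' vocabulary, the strict reading of the out-of-vocabulary policy. Set
#' `trainable_oov_rows = TRUE` to instead give each such word its own
#' uniformly initialized (trainable) row. With `pretrained = NULL` every
#' non-padding row is uniformly initialized so the pipeline runs with no
#' external embedding file.
#'
#' @param vocab an `hbgru_vocab` from [build_vocab()].
#' @param pretrained a `pretrained_vectors` object from
#'   [read_word_vectors()], or `NULL`.
#' @param dim embedding dimension `E`; defaults to the pre-trained
#'   dimension (200 for the published PubMed vectors) or 200.
#' @param seed integer seed for the uniform draws.
#' @param trainable_oov_rows give out-of-pretrained corpus words their own
#'   uniform rows instead of collapsing them to `<unk>`.
#' @return An object of class `hbgru_embedding`: list with `weights`
#'   (V x E numeric matrix, row `i + 1` holding index `i`), `vocab` (the
#'   possibly collapsed vocabulary to encode with) and `init_report`
#'   (character vector, per row: `"pretrained"`, `"uniform"` or `"zero"`).
#' @export
init_embedding_matrix <- function(vocab, pretrained = NULL, dim = NULL,
                                  seed = 1L, trainable_oov_rows = FALSE) {
  stopifnot(inherits(vocab, "hbgru_vocab"))
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "pretrained_vectors"))
    if (is.null(dim)) dim <- pretrained$dimension
    if (dim != pretrained$dimension) {
      validation_error("requested dimension %d != pre-trained dimension %d",
                       dim, pretrained$dimension)
    }
  }
  if (is.null(dim)) dim <- 200L
  special <- c(PAD_TOKEN, UNK_TOKEN, ENTITY_TAG_TOKENS)
  words <- names(vocab)
  if (!is.null(pretrained) && !trainable_oov_rows) {
    keep <- words %in% special | words %in% names(pretrained$vectors)
    kept <- words[keep]
    idx <- seq_along(kept) - 1L
    names(idx) <- kept
    new_vocab <- structure(idx, annotate = attr(vocab, "annotate"),
                           class = "hbgru_vocab")
  } else {
    new_vocab <- vocab
  }
  tokens <- names(new_vocab)
  V <- length(tokens)
  weights <- matrix(0, nrow = V, ncol = dim)
  report <- character(V)
  report[[1L]] <- "zero"  # padding row
  with_seed(seed, {
    for (i in seq_len(V)[-1L]) {
      tok <- tokens[[i]]
      vec <- if (!is.null(pretrained)) pretrained$vectors[[tok]] else NULL
      if (!is.null(vec)) {
        weights[i, ] <- vec
        report[[i]] <- "pretrained"
      } else {
        weights[i, ] <- stats::runif(dim, -0.05, 0.05)
        report[[i]] <- "uniform"
      }
    }
  })
  names(report) <- tokens
  structure(list(weights = weights, vocab = new_vocab, init_report = report),
            class = "hbgru_embedding")
}
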