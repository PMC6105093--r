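# From raw citation text to the M x N token-index matrix fed to the model:
# sentence segmentation, entity tag insertion, entity-aware tokenization,
# stop-word/punctuation removal with entity protection, padding/truncation.

ENTITY_TAG_TOKENS <- as.vector(rbind(sprintf("<%s>", ENTITY_TYPES),
                                     sprintf("</%s>", ENTITY_TYPES)))

#' Preprocessing configuration
#'
#' Collects every knob of the text pipeline. The defaults are the published
#' document dimensions: at most `M = 23` sentences per document (title +
#' 22 abstract sentences) and `N = 45` words per sentence, which cover
#' about 99% of abstracts and sentences in the triage corpus the model was
#' built for.
#'
#' Two presets reproduce the two published pipeline variants:
#' `preset = "run3"` is the competition pipeline (stop words kept, text
#' lower-cased, no entity annotation), `preset = "followup"` is the
#' post-competition pipeline (case retained, stop words and punctuation
#' removed, entity annotation available).
#'
#' @param max_sentences `M`, maximum sentences per document incl. title
#'   (>= 2).
#' @param max_words `N`, maximum words per sentence (>= 1).
#' @param tokenization_option how entity mentions are tokenized: `"tokens"`
#'   (punctuation stripped), `"mwe"` (split on spaces only, intra-word
#'   punctuation kept) or `"both"` (MWE sequence followed by the token
#'   sequence, deduplicated when equal).
#' @param annotate_entities emit `<type>`/`</type>` tag tokens around
#'   entity mentions.
#' @param remove_stopwords drop stop words and pure-punctuation tokens
#'   outside entity spans.
#' @param lowercase lower-case all non-tag tokens.
#' @param preset optional preset name, `"run3"` or `"followup"`; explicit
#'   arguments override preset values.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(max_sentences = 23L,
                              max_words = 45L,
                              tokenization_option = c("tokens", "mwe", "both"),
                              annotate_entities = FALSE,
                              remove_stopwords = TRUE,
                              lowercase = FALSE,
                              preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("run3", "followup"))
    defaults <- switch(preset,
      run3 = list(annotate_entities = FALSE, remove_stopwords = FALSE,
                  lowercase = TRUE),
      followup = list(annotate_entities = TRUE, remove_stopwords = TRUE,
                      lowercase = FALSE)
    )
    call <- as.list(match.call())[-1L]
    for (nm in names(defaults)) {
      if (!nm %in% names(call)) assign(nm, defaults[[nm]])
    }
  }
  max_sentences <- as.integer(max_sentences)
  max_words <- as.integer(max_words)
  if (is.na(max_sentences) || max_sentences < 2L) {
    validation_error("max_sentences must be >= 2 (title plus at least one abstract row)")
  }
  if (is.na(max_words) || max_words < 1L) {
    validation_error("max_words must be >= 1")
  }
  structure(
    list(max_sentences = max_sentences,
         max_words = max_words,
         tokenization_option = match.arg(tokenization_option),
         annotate_entities = isTRUE(annotate_entities),
         remove_stopwords = isTRUE(remove_stopwords),
         lowercase = isTRUE(lowercase)),
    class = "preprocess_config"
  )
}

#' Split text into sentences
#'
#' Rule-based segmentation tuned for biomedical prose: a sentence ends at
#' `.`, `!` or `?` followed by whitespace and an upper-case letter, digit,
#' `(` or tag opener — unless the period terminates a known abbreviation
#' (e.g. "Fig.", "et al.") or falls inside an unclosed parenthesis, so
#' parenthesized abbreviations like "(approx. 5)" never split.
#'
#' @param text a single string; empty text yields an empty character
#'   vector.
#' @return Character vector of trimmed sentences whose concatenation
#'   (modulo inter-sentence whitespace) reconstructs the input.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(character())
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  depth <- cumsum((chars == "(") - (chars == ")"))
  boundaries <- integer()
  i <- 1L
  while (i <= n) {
    if (chars[[i]] %in% c(".", "!", "?") && (i == n || depth[[i]] == 0L)) {
      # look ahead: whitespace then a plausible sentence opener
      j <- i + 1L
      while (j <= n && chars[[j]] %in% c(".", "!", "?")) j <- j + 1L
      k <- j
      while (k <= n && grepl("^\\s$", chars[[k]])) k <- k + 1L
      opener <- k <= n && grepl("^[A-Za-z0-9(<\"']$", chars[[k]])
      if (k > j && opener) {  # at least one whitespace consumed
        # abbreviation guard: word immediately before the period
        prefix <- paste(chars[seq_len(i - 1L)], collapse = "")
        word <- regmatches(prefix, regexpr("[A-Za-z][A-Za-z.]*$", prefix))
        abbrev <- length(word) == 1L &&
          tolower(word) %in% HBGRU_ABBREVIATIONS
        if (!abbrev) boundaries <- c(boundaries, j - 1L)
        i <- j - 1L
      }
    }
    i <- i + 1L
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  out <- vapply(seq_along(starts), function(s) {
    trimws(paste(chars[starts[[s]]:ends[[s]]], collapse = ""))
  }, character(1))
  out[nzchar(out)]
}

#' Surround entity mentions with type tags
#'
#' Each annotated mention `m` of type `tau` is replaced in place by
#' `<tau>m</tau>`; text outside mentions is unchanged. Overlapping
#' annotations are resolved by keeping the longest span (ties: the earlier
#' start), so maximal entity context survives.
#'
#' @param text the string the annotation offsets refer to.
#' @param annotations a data frame with columns `start`, `end` (0-based,
#'   half-open), `mention`, `entity_type`, sorted by `start`.
#' @return The tagged text.
#' @export
insert_entity_tags <- function(text, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(text)
  validate_annotations(annotations, text)
  ann <- annotations[order(annotations$start, annotations$end), , drop = FALSE]
  # longest-span overlap resolution, earlier start breaking ties
  keep <- rep(TRUE, nrow(ann))
  ord <- order(-(ann$end - ann$start), ann$start)
  taken_end <- -1L
  occupied <- logical(nchar(text))
  for (i in ord) {
    span <- (ann$start[i] + 1L):ann$end[i]
    if (any(occupied[span])) {
      keep[i] <- FALSE
    } else {
      occupied[span] <- TRUE
    }
  }
  ann <- ann[keep, , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  out <- character(0)
  cursor <- 0L  # 0-based position consumed so far
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] > cursor) {
      out <- c(out, substr(text, cursor + 1L, ann$start[i]))
    }
    out <- c(out, sprintf("<%s>%s</%s>", ann$entity_type[i], ann$mention[i],
                          ann$entity_type[i]))
    cursor <- ann$end[i]
  }
  if (cursor < nchar(text)) out <- c(out, substr(text, cursor + 1L, nchar(text)))
  paste(out, collapse = "")
}

#' Tokenize an entity mention
#'
#' Implements the three tokenization options for biomedical entity
#' mentions: `"tokens"` strips punctuation (alphanumeric runs only),
#' `"mwe"` keeps the mention as space-delimited multi-word-expression units
#' with intra-word punctuation intact, and `"both"` emits the MWE sequence
#' followed by the token sequence — except when the two coincide, in which
#' case only the token sequence is kept.
#'
#' @param mention non-empty mention string.
#' @param option `"tokens"`, `"mwe"` or `"both"`.
#' @return Character vector of tokens.
#' @examples
#' tokenize_entity("branchio-oto-renal (BOR) syndrome", "both")
#' @export
tokenize_entity <- function(mention, option = c("tokens", "mwe", "both")) {
  option <- match.arg(option)
  if (!nzchar(mention)) validation_error("mention must be non-empty")
  tokens <- regmatches(mention, gregexpr("[A-Za-z0-9]+", mention))[[1L]]
  if (option == "tokens") return(tokens)
  mwe <- strsplit(trimws(mention), "\\s+")[[1L]]
  if (option == "mwe") return(mwe)
  if (identical(mwe, tokens)) tokens else c(mwe, tokens)
}

ENTITY_SPAN_RE <- sprintf("<(%s)>(.*?)</\\1>", paste(ENTITY_TYPES, collapse = "|"))
ANY_TAG_RE <- sprintf("</?(%s)>", paste(ENTITY_TYPES, collapse = "|"))

# Word-level tokenization outside entity spans: alphanumeric runs as words,
# runs of other non-space characters as punctuation tokens.
tokenize_words <- function(text) {
  regmatches(text, gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]+", text))[[1L]]
}

#' Tokenize a (possibly entity-tagged) sentence
#'
#' Entity spans are located from their `<type>...</type>` tags and
#' tokenized with [tokenize_entity()]; tokens inside an entity span are
#' never removed by stop-word filtering, and the opening/closing tags are
#' kept as distinct tokens when `config$annotate_entities` is on. Outside
#' entity spans the sentence is word-tokenized, and stop words plus
#' pure-punctuation tokens are dropped when `config$remove_stopwords` is
#' on.
#'
#' @param sentence sentence string, possibly containing well-formed entity
#'   tag pairs.
#' @param config a [preprocess_config()].
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_sentence <- function(sentence, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  m <- gregexpr(ENTITY_SPAN_RE, sentence, perl = TRUE)[[1L]]
  tokens <- character(0)
  cursor <- 1L
  spans <- if (m[[1L]] == -1L) integer(0) else seq_along(m)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  plain <- function(txt) {
    if (grepl(ANY_TAG_RE, txt)) {
      validation_error("unbalanced entity tags in sentence: %s", sentence)
    }
    toks <- tokenize_words(txt)
    if (config$remove_stopwords && length(toks)) {
      is_punct <- !grepl("[A-Za-z0-9]", toks)
      is_stop <- tolower(toks) %in% HBGRU_STOPWORDS
      toks <- toks[!(is_punct | is_stop)]
    }
    toks
  }
  for (i in spans) {
    if (starts[[i]] > cursor) {
      tokens <- c(tokens, plain(substr(sentence, cursor, starts[[i]] - 1L)))
    }
    span_txt <- substr(sentence, starts[[i]], starts[[i]] + lens[[i]] - 1L)
    type <- sub(ENTITY_SPAN_RE, "\\1", span_txt, perl = TRUE)
    mention <- sub(ENTITY_SPAN_RE, "\\2", span_txt, perl = TRUE)
    ent <- if (nzchar(mention)) {
      tokenize_entity(mention, config$tokenization_option)
    } else {
      character(0)
    }
    if (config$annotate_entities) {
      ent <- c(sprintf("<%s>", type), ent, sprintf("</%s>", type))
    }
    tokens <- c(tokens, ent)
    cursor <- starts[[i]] + lens[[i]]
  }
  if (cursor <= nchar(sentence)) {
    tokens <- c(tokens, plain(substr(sentence, cursor, nchar(sentence))))
  }
  if (config$lowercase && length(tokens)) {
    is_tag <- tokens %in% ENTITY_TAG_TOKENS
    tokens[!is_tag] <- tolower(tokens[!is_tag])
  }
  tokens
}

#' Tokenize a full document
#'
#' Runs the whole text pipeline for one citation: optional entity tag
#' insertion (annotation offsets are interpreted against
#' `title + " " + abstract`, the PubTator convention), sentence
#' segmentation of the abstract, and per-sentence tokenization. Sentence 1
#' of the result is always the title.
#'
#' @param doc a one-row documents data frame or a list with `title`,
#'   `abstract` and optionally `doc_id`, `label` entries.
#' @param annotations optional annotation data frame for this document
#'   (see [read_pubtator()]).
#' @param config a [preprocess_config()].
#' @return An object of class `tokenized_document`: a list with element
#'   `sentences` (list of token vectors, title first) and attributes
#'   `doc_id` and `label`.
#' @export
preprocess_document <- function(doc, annotations = NULL,
                                config = preprocess_config()) {
  if (is.data.frame(doc)) {
    stopifnot(nrow(doc) == 1L)
    doc <- as.list(doc)
  }
  title <- doc$title
  abstract <- doc$abstract %||% ""
  if (is.null(title) || !nzchar(title)) {
    validation_error("document %s has an empty title", doc$doc_id %||% "?")
  }
  if (config$annotate_entities && !is.null(annotations) && nrow(annotations)) {
    full <- paste(title, abstract)
    validate_annotations(annotations, full)
    nt <- nchar(title)
    in_title <- annotations$end <= nt
    in_abstract <- annotations$start >= nt + 1L
    straddle <- !(in_title | in_abstract)
    if (any(straddle)) {
      warning("dropping annotation(s) straddling the title/abstract boundary")
    }
    title <- insert_entity_tags(title, annotations[in_title, , drop = FALSE])
    ab_ann <- annotations[in_abstract, , drop = FALSE]
    ab_ann$start <- ab_ann$start - nt - 1L
    ab_ann$end <- ab_ann$end - nt - 1L
    abstract <- insert_entity_tags(abstract, ab_ann)
  }
  sentences <- c(list(tokenize_sentence(title, config)),
                 lapply(segment_sentences(abstract), tokenize_sentence, config))
  keep <- c(TRUE, lengths(sentences[-1L]) > 0L)
  structure(
    list(sentences = sentences[keep]),
    doc_id = doc$doc_id %||% NA_character_,
    label = if (is.null(doc$label) || is.na(doc$label)) NA_integer_
            else as.integer(doc$label),
    class = "tokenized_document"
  )
}

#' Encode a tokenized document as an index matrix
#'
#' Maps tokens to vocabulary indices and lays the document out as the
#' fixed-shape `M x N` matrix the network consumes: row 1 is the title,
#' rows 2..M the abstract sentences in order. Zero padding is appended to
#' the end of each sentence and after the last sentence; over-long
#' sentences and documents are truncated from the end. Out-of-vocabulary
#' tokens map to the `<unk>` index.
#'
#' @param tok a `tokenized_document` from [preprocess_document()].
#' @param vocab an `hbgru_vocab` from [build_vocab()].
#' @param config a [preprocess_config()] supplying `M` and `N`.
#' @return An object of class `document_matrix`: a list with `values`
#'   (`M x N` integer matrix of 0-based vocabulary indices, 0 = padding),
#'   `sentence_mask` (length-`M` logical) and `word_mask` (`M x N`
#'   logical), plus `doc_id`/`label` attributes carried over.
#' @export
encode_document <- function(tok, vocab, config = preprocess_config()) {
  stopifnot(inherits(tok, "tokenized_document"), inherits(vocab, "hbgru_vocab"))
  M <- config$max_sentences
  N <- config$max_words
  if (length(tok$sentences) == 0L || length(tok$sentences[[1L]]) == 0L) {
    validation_error("document %s: empty title row", attr(tok, "doc_id"))
  }
  sentences <- tok$sentences[seq_len(min(length(tok$sentences), M))]
  values <- matrix(0L, nrow = M, ncol = N)
  word_mask <- matrix(FALSE, nrow = M, ncol = N)
  for (i in seq_along(sentences)) {
    toks <- sentences[[i]]
    toks <- toks[seq_len(min(length(toks), N))]
    if (length(toks)) {
      values[i, seq_along(toks)] <- token_index(vocab, toks)
      word_mask[i, seq_along(toks)] <- TRUE
    }
  }
  sentence_mask <- rowSums(word_mask) > 0L
  sentence_mask[1L] <- TRUE
  structure(
    list(values = values, sentence_mask = sentence_mask, word_mask = word_mask),
    doc_id = attr(tok, "doc_id"), label = attr(tok, "label"),
    class = "document_matrix"
  )
}

#' Preprocess and encode a whole corpus
#'
#' Convenience wrapper: [preprocess_document()] then [encode_document()]
#' for every row of a documents data frame.
#'
#' @inheritParams preprocess_document
#' @param docs documents data frame.
#' @param annotations named list mapping `doc_id` to annotation data
#'   frames, as returned by [read_pubtator()].
#' @param vocab an `hbgru_vocab`; when `NULL` one is built from the
#'   tokenized corpus first.
#' @return A list with `matrices` (list of `document_matrix`), `vocab`,
#'   `tokenized` and `labels` (integer vector, `NA` where unlabeled).
#' @export
encode_corpus <- function(docs, annotations = NULL, vocab = NULL,
                          config = preprocess_config()) {
  validate_documents(docs)
  toks <- lapply(seq_len(nrow(docs)), function(i) {
    ann <- if (!is.null(annotations)) annotations[[docs$doc_id[[i]]]] else NULL
    preprocess_document(docs[i, , drop = FALSE], ann, config)
  })
  if (is.null(vocab)) {
    vocab <- build_vocab(toks, annotate = config$annotate_entities)
  }
  mats <- lapply(toks, encode_document, vocab = vocab, config = config)
  labels <- vapply(toks, function(d) attr(d, "label") %||% NA_integer_, integer(1))
  list(matrices = mats, vocab = vocab, tokenized = toks, labels = labels)
}
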