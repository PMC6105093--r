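test_that("sentence segmentation recovers boundaries and spares abbreviations", {
  expect_equal(segment_sentences(""), character())
  expect_equal(segment_sentences("A is B. C is D."), c("A is B.", "C is D."))

  # generated two-sentence strings with known boundaries
  set.seed(31)
  words <- c("Protein", "kinase", "binding", "domain", "complex", "residue")
  for (rep in 1:20) {
    s1 <- paste0(paste(sample(words, sample(3:6, 1), replace = TRUE),
                       collapse = " "), ".")
    s2 <- paste0(paste(sample(words, sample(3:6, 1), replace = TRUE),
                       collapse = " "), ".")
    expect_equal(segment_sentences(paste(s1, s2)), c(s1, s2))
  }

  expect_equal(
    segment_sentences("Results are shown in Fig. 2 and Table 1. They agree."),
    c("Results are shown in Fig. 2 and Table 1.", "They agree."))
  expect_equal(
    segment_sentences("Mutants were rare (approx. 5 per cohort). Controls were not."),
    c("Mutants were rare (approx. 5 per cohort).", "Controls were not."))
  expect_equal(
    segment_sentences("Binding was reduced et al. 2010 reported. We confirm this."),
    c("Binding was reduced et al. 2010 reported.", "We confirm this."))
})

test_that("entity tags wrap mentions in place", {
  text <- "Mutations in human EYA1 cause branchio-oto-renal (BOR) syndrome"
  ann <- data.frame(
    start = c(13L, 19L, 30L),
    end = c(18L, 23L, 63L),
    mention = c("human", "EYA1", "branchio-oto-renal (BOR) syndrome"),
    entity_type = c("species", "gene", "disease"),
    stringsAsFactors = FALSE
  )
  expect_equal(
    insert_entity_tags(text, ann),
    paste0("Mutations in <species>human</species> <gene>EYA1</gene> cause ",
           "<disease>branchio-oto-renal (BOR) syndrome</disease>"))
  expect_equal(insert_entity_tags(text, ann[0, ]), text)
  bad <- ann
  bad$end[3] <- 99L
  expect_error(insert_entity_tags(text, bad), class = "hbgru_validation_error")
})

test_that("overlapping annotations keep the longest span, earliest on ties", {
  text <- "renal syndrome onset"
  long_first <- data.frame(start = c(0L, 6L), end = c(14L, 14L),
                           mention = c("renal syndrome", "syndrome"),
                           entity_type = c("disease", "disease"),
                           stringsAsFactors = FALSE)
  expect_equal(insert_entity_tags(text, long_first),
               "<disease>renal syndrome</disease> onset")
  # same pair presented in the other order
  expect_equal(insert_entity_tags(text, long_first[2:1, ]),
               "<disease>renal syndrome</disease> onset")
  # equal lengths: the earlier span wins
  tie <- data.frame(start = c(0L, 6L), end = c(5L, 11L),
                    mention = c("renal", "syndr"),
                    entity_type = c("disease", "disease"),
                    stringsAsFactors = FALSE)
  expect_equal(insert_entity_tags(text, tie[1, , drop = FALSE]),
               "<disease>renal</disease> syndrome onset")
  # non-overlapping equal-length spans are both applied
  expect_equal(insert_entity_tags(text, tie),
               "<disease>renal</disease> <disease>syndr</disease>ome onset")
})

test_that("entity tokenization implements the tokens/MWE/both options", {
  m <- "branchio-oto-renal (BOR) syndrome"
  expect_equal(tokenize_entity(m, "tokens"),
               c("branchio", "oto", "renal", "BOR", "syndrome"))
  expect_equal(tokenize_entity(m, "mwe"),
               c("branchio-oto-renal", "(BOR)", "syndrome"))
  expect_equal(tokenize_entity(m, "both"),
               c("branchio-oto-renal", "(BOR)", "syndrome",
                 "branchio", "oto", "renal", "BOR", "syndrome"))
  # when MWE and token forms coincide, only the token form is kept
  expect_equal(tokenize_entity("Rieger Syndrome", "both"),
               c("Rieger", "Syndrome"))
})

test_that("the 'both' option is always MWE + tokens, deduplicated when equal", {
  set.seed(17)
  pieces <- c("alpha", "beta", "gamma", "delta2")
  for (rep in 1:40) {
    k <- sample(1:3, 1)
    units <- replicate(k, {
      w <- sample(pieces, sample(1:3, 1), replace = TRUE)
      glue <- sample(c("-", ""), 1)
      u <- paste(w, collapse = glue)
      if (runif(1) < 0.3) u <- paste0("(", u, ")")
      u
    })
    mention <- paste(units, collapse = " ")
    both <- tokenize_entity(mention, "both")
    mwe <- tokenize_entity(mention, "mwe")
    toks <- tokenize_entity(mention, "tokens")
    if (identical(mwe, toks)) {
      expect_equal(both, toks)
    } else {
      expect_equal(both, c(mwe, toks))
    }
  }
})

test_that("sentence tokenization protects entity spans from stop-word removal", {
  cfg <- preprocess_config(annotate_entities = TRUE, remove_stopwords = TRUE)
  expect_equal(
    tokenize_sentence("cause <disease>BOR syndrome</disease> .", cfg),
    c("cause", "<disease>", "BOR", "syndrome", "</disease>"))
  expect_equal(tokenize_sentence("of the and", cfg), character())
  # stop word inside an entity span survives
  expect_equal(
    tokenize_sentence("<disease>loss of function</disease> observed", cfg),
    c("<disease>", "loss", "of", "function", "</disease>", "observed"))
  # without tags the pipeline reduces to plain tokenization minus stop words
  plain_cfg <- preprocess_config(annotate_entities = FALSE)
  expect_equal(tokenize_sentence("The kinase binds the receptor.", plain_cfg),
               c("kinase", "binds", "receptor"))
  expect_error(tokenize_sentence("broken <gene>EYA1 tail", cfg),
               class = "hbgru_validation_error")
})

test_that("tag tokens are emitted only when annotation is enabled", {
  s <- "<gene>EYA1</gene> signaling"
  on <- preprocess_config(annotate_entities = TRUE)
  off <- preprocess_config(annotate_entities = FALSE)
  expect_equal(tokenize_sentence(s, on), c("<gene>", "EYA1", "</gene>", "signaling"))
  expect_equal(tokenize_sentence(s, off), c("EYA1", "signaling"))
})

test_that("presets reproduce the two published pipeline variants", {
  run3 <- preprocess_config(preset = "run3")
  expect_false(run3$remove_stopwords)
  expect_true(run3$lowercase)
  expect_false(run3$annotate_entities)
  followup <- preprocess_config(preset = "followup")
  expect_true(followup$remove_stopwords)
  expect_false(followup$lowercase)
  expect_equal(tokenize_sentence("The Kinase binds.", run3),
               c("the", "kinase", "binds", "."))
})

test_that("document encoding pads, truncates and masks as specified", {
  fx <- tiny_encoded_corpus(n = 4, seed = 21)
  vocab <- fx$enc$vocab

  cfg_default <- preprocess_config()
  tok <- fx$enc$tokenized[[1]]
  mat <- encode_document(tok, vocab, cfg_default)
  expect_equal(dim(mat$values), c(23, 45))

  # 3-word title, 1-sentence abstract, M = 4, N = 5
  small <- structure(list(sentences = list(c("kinase", "binds", "receptor"),
                                           c("complex", "forms"))),
                     doc_id = "t", label = 1L, class = "tokenized_document")
  cfg_small <- preprocess_config(max_sentences = 4, max_words = 5)
  msmall <- encode_document(small, vocab, cfg_small)
  expect_equal(sum(msmall$values[1, ] != 0), 3)
  expect_equal(msmall$values[1, 4:5], c(0L, 0L))
  expect_true(all(msmall$values[3:4, ] == 0))
  expect_equal(msmall$sentence_mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(msmall$word_mask[1, ], c(TRUE, TRUE, TRUE, FALSE, FALSE))

  # 30-sentence abstract against M = 23: title + 22 abstract rows kept
  big <- structure(list(sentences = c(list(c("title", "words")),
                                      replicate(30, c("a1", "b2"),
                                                simplify = FALSE))),
                   doc_id = "big", label = 0L, class = "tokenized_document")
  mbig <- encode_document(big, vocab, cfg_default)
  expect_equal(sum(mbig$sentence_mask), 23)
  expect_equal(sum(rowSums(mbig$word_mask) > 0), 23)

  # out-of-vocabulary tokens map to <unk>
  oov <- structure(list(sentences = list(c("zzz-not-in-vocab"))),
                   doc_id = "o", label = NA_integer_,
                   class = "tokenized_document")
  moov <- encode_document(oov, vocab, cfg_small)
  expect_equal(moov$values[1, 1], token_index(vocab, "<unk>"))

  empty_title <- structure(list(sentences = list(character())),
                           doc_id = "e", label = NA_integer_,
                           class = "tokenized_document")
  expect_error(encode_document(empty_title, vocab, cfg_small),
               class = "hbgru_validation_error")
})

test_that("encoding is deterministic and always M x N", {
  fx <- tiny_encoded_corpus(n = 10, seed = 3, annotate = TRUE)
  for (m in fx$enc$matrices) {
    expect_equal(dim(m$values), c(6, 10))
    expect_equal(dim(m$word_mask), c(6, 10))
    expect_true(m$sentence_mask[1])
    expect_true(all((m$values != 0) == m$word_mask))
  }
  again <- encode_corpus(fx$corpus$documents, fx$corpus$annotations,
                         vocab = fx$enc$vocab, config = fx$cfg)
  expect_identical(lapply(again$matrices, `[[`, "values"),
                   lapply(fx$enc$matrices, `[[`, "values"))
})
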