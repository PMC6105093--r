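# Synthetic labeled corpora with a plantable lexical class signal. The
# generator targets structural fidelity (titled documents, multi-sentence
# abstracts, entity mentions with valid offsets, controllable class
# balance) so that every pipeline stage is testable offline; it makes no
# attempt to mimic real PubMed language statistics. Because the signal is
# a set of dedicated trigger tokens, the Bayes-optimal rule classifier is
# computable exactly and serves as a learnability reference.

SIGNAL_TOKENS <- c("disrupts", "abolishes", "destabilizes")

# Entity surface forms chosen to exercise all three tokenization branches:
# hyphens, parentheses, multi-word spans, intra-word punctuation.
ENTITY_TEMPLATES <- list(
  gene = c("EYA1", "BRCA1", "TP53", "SHOC2"),
  species = c("human", "Mus musculus"),
  chemical = c("p-Benzoyl-L-phenylalanine", "imatinib"),
  mutation = c("p.Arg123Cys", "c.1254A>G"),
  disease = c("branchio-oto-renal (BOR) syndrome", "Rieger Syndrome",
              "autosomal-dominant polycystic kidney disease")
)

# Pseudo-biomedical filler vocabulary: deterministic syllable compounds.
synthetic_vocabulary <- function(size) {
  syl1 <- c("pro", "kin", "gly", "phos", "lig", "recep", "enzy", "mut",
            "bind", "dimer", "fold", "domain", "helix", "loop", "site")
  syl2 <- c("ase", "ome", "itin", "ation", "osis", "ine", "ide", "ant",
            "ergic", "form", "meric", "plex", "gen", "tide", "cept")
  words <- as.vector(outer(syl1, syl2, paste0))
  words <- setdiff(words, c(SIGNAL_TOKENS, HBGRU_STOPWORDS))
  if (size > length(words)) {
    extra <- paste0("protein", seq_len(size - length(words)))
    words <- c(words, extra)
  }
  words[seq_len(size)]
}

#' Specification for a synthetic corpus
#'
#' The defaults emulate the shape of the triage study corpus: a 42.36%
#' positive class balance, titled documents with multi-sentence abstracts,
#' and entity mentions of the five supported types. The class signal is
#' lexical: positive documents carry one of a small set of trigger tokens
#' in the configured location with probability `signal_strength`, while
#' negative documents leak a trigger with the complementary low
#' probability `noise_rate * (1 - signal_strength)` — so at
#' `signal_strength = 1` the corpus is exactly separable by the rule
#' classifier.
#'
#' @param n_documents corpus size.
#' @param positive_fraction target positive fraction in \[0, 1\]
#'   (default 0.4236); the realized count is `round(n * fraction)`,
#'   planted deterministically.
#' @param sentence_range inclusive range of abstract sentence counts.
#' @param words_range inclusive range of words per sentence (and title).
#' @param vocab_size filler vocabulary size (>= 20).
#' @param signal_location `"title"`, `"abstract"` or `"both"`.
#' @param signal_strength probability a positive document carries a
#'   trigger token in its signal location.
#' @param entity_rate expected entity mentions per document (Poisson).
#' @param noise_rate scale of the trigger leakage into negatives.
#' @param seed integer seed; regeneration from the same spec is
#'   byte-identical.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_documents = 400L,
                           positive_fraction = 0.4236,
                           sentence_range = c(3L, 8L),
                           words_range = c(6L, 12L),
                           vocab_size = 120L,
                           signal_location = c("title", "abstract", "both"),
                           signal_strength = 1.0,
                           entity_rate = 1.0,
                           noise_rate = 0.1,
                           seed = 42L) {
  assert_scalar_number(positive_fraction, "positive_fraction", 0, 1)
  assert_scalar_number(signal_strength, "signal_strength", 0, 1)
  assert_scalar_number(entity_rate, "entity_rate", 0, Inf)
  assert_scalar_number(noise_rate, "noise_rate", 0, 1)
  if (length(sentence_range) != 2L || sentence_range[1L] > sentence_range[2L] ||
      sentence_range[1L] < 1L) {
    validation_error("sentence_range must be a non-empty range >= 1")
  }
  if (length(words_range) != 2L || words_range[1L] > words_range[2L] ||
      words_range[1L] < 2L) {
    validation_error("words_range must be a non-empty range >= 2 (room for a signal token)")
  }
  if (vocab_size < 20L) validation_error("vocab_size must be >= 20")
  structure(
    list(n_documents = as.integer(n_documents),
         positive_fraction = positive_fraction,
         sentence_range = as.integer(sentence_range),
         words_range = as.integer(words_range),
         vocab_size = as.integer(vocab_size),
         signal_location = match.arg(signal_location),
         signal_strength = signal_strength,
         entity_rate = entity_rate,
         noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic labeled corpus
#'
#' Draws a corpus from a [synthetic_spec()]. Entity mentions are spliced
#' into sentences as whole units and their 0-based half-open offsets are
#' recorded against the concatenation `title + " " + abstract`, so every
#' generated annotation round-trips through [insert_entity_tags()].
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `synthetic_corpus`: list with `documents`
#'   (a documents data frame with labels), `annotations` (named list of
#'   annotation data frames) and `manifest` (the generating spec — the
#'   corpus is exactly reproducible from it).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_documents
  if (n < 1L) validation_error("n_documents must be >= 1")
  vocab <- synthetic_vocabulary(spec$vocab_size)
  n_pos <- round(n * spec$positive_fraction)
  with_seed(spec$seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    docs <- vector("list", n)
    anns <- vector("list", n)
    for (i in seq_len(n)) {
      rint <- function(rng) {
        if (rng[1L] == rng[2L]) rng[1L] else sample(seq(rng[1L], rng[2L]), 1L)
      }
      title_units <- sample(vocab, rint(spec$words_range), replace = TRUE)
      n_sent <- rint(spec$sentence_range)
      sent_units <- lapply(seq_len(n_sent), function(j) {
        sample(vocab, rint(spec$words_range), replace = TRUE)
      })
      # plant the class signal
      plant_prob <- if (labels[[i]] == 1L) {
        spec$signal_strength
      } else {
        spec$noise_rate * (1 - spec$signal_strength)
      }
      if (stats::runif(1) < plant_prob) {
        tok <- sample(SIGNAL_TOKENS, 1L)
        in_title <- spec$signal_location %in% c("title", "both")
        in_abstract <- spec$signal_location %in% c("abstract", "both")
        if (in_title) {
          pos <- sample(length(title_units), 1L)
          title_units[[pos]] <- tok
        }
        if (in_abstract) {
          s <- sample(n_sent, 1L)
          pos <- sample(length(sent_units[[s]]), 1L)
          sent_units[[s]][[pos]] <- tok
        }
      }
      # plant entity mentions (as whole units) and remember where
      n_ent <- stats::rpois(1L, spec$entity_rate)
      ent_slots <- list()
      for (e in seq_len(n_ent)) {
        type <- sample(ENTITY_TYPES, 1L)
        mention <- sample(ENTITY_TEMPLATES[[type]], 1L)
        s <- sample(n_sent, 1L)
        pos <- sample(length(sent_units[[s]]), 1L)
        sent_units[[s]][[pos]] <- mention
        ent_slots[[length(ent_slots) + 1L]] <-
          list(sentence = s, pos = pos, type = type, mention = mention)
      }
      # assemble text and compute unit offsets on title + " " + abstract
      title <- paste(title_units, collapse = " ")
      sentences <- vapply(sent_units, function(u) {
        paste0(paste(u, collapse = " "), ".")
      }, character(1))
      abstract <- paste(sentences, collapse = " ")
      unit_start <- function(s, pos) {
        # 0-based offset of unit `pos` of sentence `s` in title+" "+abstract
        off <- nchar(title) + 1L
        if (s > 1L) {
          off <- off + sum(nchar(sentences[seq_len(s - 1L)]) + 1L)
        }
        units <- sent_units[[s]]
        if (pos > 1L) {
          off <- off + sum(nchar(units[seq_len(pos - 1L)]) + 1L)
        }
        off
      }
      if (length(ent_slots)) {
        # a later plant may overwrite an earlier one in the same slot
        keys <- vapply(ent_slots, function(x) {
          sprintf("%d:%d", x$sentence, x$pos)
        }, character(1))
        ent_slots <- ent_slots[!duplicated(keys, fromLast = TRUE)]
        ann <- do.call(rbind, lapply(ent_slots, function(x) {
          st <- unit_start(x$sentence, x$pos)
          data.frame(start = st, end = st + nchar(x$mention),
                     mention = x$mention, entity_type = x$type,
                     stringsAsFactors = FALSE)
        }))
        anns[[i]] <- ann[order(ann$start), , drop = FALSE]
      }
      docs[[i]] <- data.frame(doc_id = sprintf("SYN%05d", i), title = title,
                              abstract = abstract, label = labels[[i]],
                              stringsAsFactors = FALSE)
    }
  })
  documents <- do.call(rbind, docs)
  names(anns) <- documents$doc_id
  anns <- anns[!vapply(anns, is.null, logical(1))]
  structure(
    list(documents = documents, annotations = anns,
         manifest = list(spec = spec, signal_tokens = SIGNAL_TOKENS)),
    class = "synthetic_corpus"
  )
}

signal_rule_predict <- function(corpus) {
  spec <- corpus$manifest$spec
  tokens <- corpus$manifest$signal_tokens
  re <- sprintf("\\b(%s)\\b", paste(tokens, collapse = "|"))
  docs <- corpus$documents
  hit <- switch(spec$signal_location,
    title = grepl(re, docs$title),
    abstract = grepl(re, docs$abstract),
    both = grepl(re, docs$title) | grepl(re, docs$abstract)
  )
  as.integer(hit)
}

#' Reference F1 of the signal-rule classifier
#'
#' Evaluates the classifier that predicts "relevant" exactly when a
#' trigger token from the generation manifest occurs in the signal
#' location. On corpora generated with `signal_strength = 1` this rule is
#' Bayes-optimal with F1 = 1; it upper-bounds what a trained model can
#' achieve from the planted signal and anchors learnability tests.
#'
#' @param corpus a `synthetic_corpus` carrying its manifest.
#' @return An `hbgru_metrics` object.
#' @export
bayes_reference_f1 <- function(corpus) {
  if (!inherits(corpus, "synthetic_corpus") || is.null(corpus$manifest)) {
    validation_error("corpus must carry its generation manifest")
  }
  precision_recall_f1(corpus$documents$label, signal_rule_predict(corpus))
}

#' Random word vectors covering a synthetic corpus
#'
#' Writes/returns a small word2vec-style vector set for every token the
#' default pipeline produces from the corpus, so embedding-initialization
#' paths can be exercised without an external embedding file.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dim vector dimension.
#' @param seed integer seed.
#' @param config [preprocess_config()] used to tokenize.
#' @return A `pretrained_vectors` object.
#' @export
synthetic_word_vectors <- function(corpus, dim = 20L, seed = 1L,
                                   config = preprocess_config()) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  toks <- lapply(seq_len(nrow(corpus$documents)), function(i) {
    preprocess_document(corpus$documents[i, , drop = FALSE],
                        corpus$annotations[[corpus$documents$doc_id[[i]]]],
                        config)
  })
  words <- sort(unique(unlist(lapply(toks, function(d) {
    unlist(d$sentences, use.names = FALSE)
  }))))
  words <- setdiff(words, c(PAD_TOKEN, UNK_TOKEN))
  vecs <- with_seed(seed, {
    out <- lapply(words, function(w) stats::runif(dim, -0.5, 0.5))
    names(out) <- words
    out
  })
  structure(list(dimension = as.integer(dim), vectors = vecs),
            class = "pretrained_vectors")
}
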