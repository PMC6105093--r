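# Readers and writers for every external format the pipeline touches:
# document records, PubTator annotation files, word2vec-format vectors,
# and ranked prediction output.

ENTITY_TYPES <- c("gene", "species", "chemical", "mutation", "disease")

validate_documents <- function(docs) {
  need <- c("doc_id", "title", "abstract")
  if (!is.data.frame(docs) || !all(need %in% names(docs))) {
    validation_error("documents need columns doc_id, title, abstract (and optionally label)")
  }
  if (anyDuplicated(docs$doc_id)) {
    validation_error("duplicate doc_id: %s",
                     paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "))
  }
  if (any(!nzchar(docs$doc_id))) validation_error("doc_id must be non-empty")
  if (any(!nzchar(docs$title))) validation_error("every document needs a non-empty title")
  if ("label" %in% names(docs)) {
    lab <- docs$label[!is.na(docs$label)]
    if (length(lab) && !all(lab %in% c(0, 1))) {
      validation_error("labels must be 0/1 (or NA for unlabeled)")
    }
  }
  invisible(docs)
}

#' Read and write document records
#'
#' A corpus is stored one citation per line as tab-separated fields with a
#' header: `doc_id`, `title`, `abstract` and an optional `label` column
#' (1 = relevant, 0 = not relevant, empty = unlabeled test data). Tabs and
#' newlines inside the text fields are normalized to single spaces on
#' write, so write-then-read is the identity on normalized corpora.
#'
#' @param path file path.
#' @return `read_documents()`: a data frame with columns `doc_id`, `title`,
#'   `abstract`, `label` (integer, `NA` when absent), one row per record in
#'   file order.
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || (length(lines) == 1L && !nzchar(lines))) {
    return(data.frame(doc_id = character(), title = character(),
                      abstract = character(), label = integer(),
                      stringsAsFactors = FALSE))
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!all(c("doc_id", "title", "abstract") %in% header)) {
    parse_error("line 1: header must name doc_id, title, abstract")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  has_label <- "label" %in% header
  n_min <- length(setdiff(header, "label"))
  bad <- which(lengths(rows) < n_min | lengths(rows) > length(header))
  if (length(bad)) {
    parse_error("line %d: expected %d tab-separated fields, found %d",
                bad[[1L]] + 1L, length(header), lengths(rows)[bad[[1L]]])
  }
  get <- function(row, field) {
    i <- match(field, header)
    if (i <= length(row)) row[[i]] else ""
  }
  docs <- data.frame(
    doc_id = vapply(rows, get, character(1), "doc_id"),
    title = vapply(rows, get, character(1), "title"),
    abstract = vapply(rows, get, character(1), "abstract"),
    label = if (has_label) {
      vals <- vapply(rows, get, character(1), "label")
      ifelse(nzchar(vals), suppressWarnings(as.integer(vals)), NA_integer_)
    } else {
      NA_integer_
    },
    stringsAsFactors = FALSE
  )
  validate_documents(docs)
  docs
}

#' @rdname read_documents
#' @param docs a documents data frame as returned by [read_documents()] or
#'   [generate_corpus()].
#' @export
write_documents <- function(docs, path) {
  validate_documents(docs)
  if (!"label" %in% names(docs)) docs$label <- NA_integer_
  lines <- c(
    "doc_id\ttitle\tabstract\tlabel",
    sprintf("%s\t%s\t%s\t%s",
            squash_ws(docs$doc_id), squash_ws(docs$title),
            squash_ws(docs$abstract),
            ifelse(is.na(docs$label), "", as.character(docs$label)))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a PubTator annotation file
#'
#' Parses tab-separated entity-annotation lines of the form
#' `doc_id <TAB> start <TAB> end <TAB> mention <TAB> type <TAB> concept_id`
#' (the trailing concept identifier is optional). Offsets are 0-based,
#' half-open, interpreted against the concatenation `title + " " + abstract`.
#' Entity types are matched case-insensitively against the five supported
#' types (gene, species, chemical, mutation, disease); lines with other
#' types are skipped with a warning, since annotation services emit types
#' beyond these five.
#'
#' @param path file path.
#' @return A named list mapping `doc_id` to a data frame of annotations with
#'   columns `start`, `end`, `mention`, `entity_type`, sorted by `start`.
#' @export
read_pubtator <- function(path) {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  skipped <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L) {
      parse_error("line %d: expected at least 5 tab-separated fields", i)
    }
    start <- suppressWarnings(as.integer(f[[2L]]))
    end <- suppressWarnings(as.integer(f[[3L]]))
    if (is.na(start) || is.na(end) || start < 0L || end <= start) {
      parse_error("line %d: invalid offsets '%s'..'%s'", i, f[[2L]], f[[3L]])
    }
    type <- tolower(f[[5L]])
    if (!type %in% ENTITY_TYPES) {
      skipped <- c(skipped, f[[5L]])
      next
    }
    ann <- data.frame(start = start, end = end, mention = f[[4L]],
                      entity_type = type, stringsAsFactors = FALSE)
    id <- f[[1L]]
    out[[id]] <- rbind(out[[id]], ann)
  }
  if (length(skipped)) {
    warning(sprintf("skipped %d annotation(s) with unsupported type(s): %s",
                    length(skipped), paste(unique(skipped), collapse = ", ")))
  }
  lapply(out, function(a) a[order(a$start, a$end), , drop = FALSE])
}

# Validate annotations against the text their offsets refer to.
validate_annotations <- function(ann, text) {
  if (is.null(ann) || nrow(ann) == 0L) return(invisible(ann))
  n <- nchar(text)
  bad <- ann$start < 0L | ann$end > n | ann$start >= ann$end
  if (any(bad)) {
    validation_error("annotation offsets [%d, %d) out of range for text of length %d",
                     ann$start[bad][1L], ann$end[bad][1L], n)
  }
  sub <- substr(rep(text, nrow(ann)), ann$start + 1L, ann$end)
  if (any(sub != ann$mention)) {
    i <- which(sub != ann$mention)[1L]
    validation_error("annotation mention '%s' does not match text span '%s' at [%d, %d)",
                     ann$mention[i], sub[i], ann$start[i], ann$end[i])
  }
  invisible(ann)
}

#' Read and write word vectors in word2vec text format
#'
#' The text format is an optional header line `"<count> <dimension>"`
#' followed by one `word v1 ... vE` line per entry. The dimension is
#' inferred from the first entry and must be uniform.
#'
#' @param path file path.
#' @return `read_word_vectors()`: an object of class `pretrained_vectors`
#'   with fields `dimension` and `vectors` (a named list of numeric
#'   vectors).
#' @export
read_word_vectors <- function(path) {
  if (!file.exists(path)) validation_error("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) format_error("empty word-vector file: %s", path)
  first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))) &&
      all(as.numeric(first) == round(as.numeric(first)))) {
    lines <- lines[-1L]  # header "count dimension"
    if (length(lines) == 0L) format_error("word-vector file has a header but no entries")
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(words)) format_error("duplicate word in vector file: %s",
                                         words[duplicated(words)][1L])
  dim_e <- length(parts[[1L]]) - 1L
  if (dim_e < 1L) format_error("first entry has no vector components")
  if (any(lengths(parts) != dim_e + 1L)) {
    format_error("inconsistent vector lengths (expected %d components)", dim_e)
  }
  vecs <- lapply(parts, function(p) {
    v <- as.numeric(p[-1L])
    if (anyNA(v)) format_error("non-numeric vector component for word '%s'", p[[1L]])
    v
  })
  names(vecs) <- words
  structure(list(dimension = dim_e, vectors = vecs),
            class = "pretrained_vectors")
}

#' @rdname read_word_vectors
#' @param vectors a `pretrained_vectors` object or a named list of
#'   equal-length numeric vectors.
#' @param header write the `"count dimension"` header line (default TRUE).
#' @export
write_word_vectors <- function(vectors, path, header = TRUE) {
  if (inherits(vectors, "pretrained_vectors")) vectors <- vectors$vectors
  if (length(vectors) == 0L) validation_error("no vectors to write")
  dims <- unique(lengths(vectors))
  if (length(dims) != 1L) validation_error("vectors have inconsistent lengths")
  body <- vapply(seq_along(vectors), function(i) {
    paste(c(names(vectors)[[i]],
            formatC(vectors[[i]], format = "g", digits = 8)), collapse = " ")
  }, character(1))
  lines <- if (header) c(sprintf("%d %d", length(vectors), dims), body) else body
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write ranked predictions
#'
#' Writes one tab-separated line per document (`doc_id`, `probability`,
#' `label`), sorted by descending probability so the file doubles as the
#' relevance ranking asked of a triage system and, through the thresholded
#' label column, as classifier output.
#'
#' @param predictions a data frame with columns `doc_id`, `probability`
#'   (in \[0, 1\]) and `label` (0/1).
#' @param path output file path.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("doc_id", "probability", "label")
  if (!is.data.frame(predictions) || !all(need %in% names(predictions))) {
    validation_error("predictions need columns doc_id, probability, label")
  }
  if (nrow(predictions) &&
      (any(predictions$probability < 0) || any(predictions$probability > 1))) {
    validation_error("probabilities must lie in [0, 1]")
  }
  ord <- order(-predictions$probability)
  p <- predictions[ord, , drop = FALSE]
  lines <- c("doc_id\tprobability\tlabel",
             if (nrow(p)) sprintf("%s\t%.6f\t%d", p$doc_id, p$probability,
                                  as.integer(p$label)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
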