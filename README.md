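# hbgru — hierarchical attention BGRU networks for biomedical abstract triage

Manual curation of biomedical databases starts with *triage*: deciding
from a PubMed citation's title and abstract whether the paper is worth a
curator's time — here, whether it describes protein–protein interactions
(PPI) affected by genetic mutations. `hbgru` implements a hierarchical
bi-directional GRU network with attention for this binary classification
task, for researchers in biomedical text mining who need a complete,
dependency-light, fully offline-testable pipeline in R.

## The model

A document is a matrix **A** ∈ ℝ^(M×N) of token indices (row 1 = title,
rows 2..M = abstract sentences, zero-padded; M = 23, N = 45 by default).
One reusable *sequence encoder* — a bi-directional GRU whose
per-position annotations h_j = h⃗_j ∥ h⃖_j are pooled by an attention
layer with scalar scores

&nbsp;&nbsp;&nbsp;&nbsp;e_j = tanh(W·h_j + b),&nbsp;&nbsp;
α_j = exp(e_j) / Σ_t exp(e_t),&nbsp;&nbsp;
v = Σ_j α_j h_j

(softmax restricted to unpadded positions) — is applied at the word
level to produce sentence vectors v^(i) ∈ ℝ^(2S) and at the sentence
level to encode the abstract's vectors into a ∈ ℝ^(2D). The title vector
t = v^(1) bypasses the document encoder through a **shortcut
connection** and is concatenated directly into the document feature
vector

&nbsp;&nbsp;&nbsp;&nbsp;d = t ∥ a ∈ ℝ^(2S+2D),

classified by a logistic neuron p = σ(w·d + b). Training follows the
full recipe: Adam on mean cross-entropy + L2, Gaussian input noise,
dropout at three sites, global gradient-norm clipping at 5, and early
stopping (patience 6) on development-set F1. Forward pass *and* analytic
backpropagation are implemented directly in R matrix code and verified
against independent scalar-loop oracles in the test suite.

The pipeline around the model covers PubTator-style entity annotations
(tag insertion, `tokens`/`mwe`/`both` entity tokenization, stop-word
removal that never touches entity spans), word2vec-format embeddings
with `<unk>` handling, stratified splits and 5-fold cross-validation,
precision/recall/F1, and a synthetic-corpus generator with a plantable
lexical signal whose Bayes-optimal reference classifier is computable
exactly.

## Worked example

```r
library(hbgru)

# a synthetic triage corpus: 400 citations, 42.36% relevant,
# full-strength lexical signal planted in the titles
corpus <- generate_corpus(synthetic_spec(seed = 42))
corpus_stats(corpus$documents)
#> 400 documents, 169 positive (42.25%)
#> sentences/document: median 6, max 9
#> words/sentence: median 9, max 19

cfg <- preprocess_config(max_sentences = 10, max_words = 20)
enc <- encode_corpus(corpus$documents, config = cfg)
vecs <- synthetic_word_vectors(corpus, dim = 16, seed = 5, config = cfg)
emb <- init_embedding_matrix(enc$vocab, pretrained = vecs, seed = 5)
model <- hbgru_init(model_config(embedding_dim = 16, sentence_size = 8,
                                 document_size = 8), emb, seed = 9)
model
#> Hierarchical BGRU model: E=16, S=8, D=8 (d length 32), vocab 153

parts <- split_corpus(enc$labels, c(0.8, 0.1, 0.1), seed = 3)
ds <- function(ix) list(matrices = enc$matrices[ix], labels = enc$labels[ix])
fit <- hbgru_fit(model, ds(parts[[1]]), ds(parts[[2]]),
                 train_config(learning_rate = 0.01, max_epochs = 20, seed = 17))
attr(fit$history, "best_f1")
#> [1] 1

pred <- hbgru_predict(fit$model, ds(parts[[3]])$matrices)
precision_recall_f1(ds(parts[[3]])$labels, pred$label)
#> P = 1.0000  R = 1.0000  F1 = 1.0000  (tp 17, fp 0, fn 0, tn 23)
bayes_reference_f1(corpus)
#> P = 1.0000  R = 1.0000  F1 = 1.0000  (tp 169, fp 0, fn 0, tn 231)
```

The trained model recovers the planted title signal exactly, matching
the Bayes-optimal rule classifier on the held-out split — the
learnability property the title shortcut is designed for. The F1
identity of published triage scores is a one-liner:

```r
f1_from_precision_recall(0.6289, 0.7656)
#> [1] 0.6905
```

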