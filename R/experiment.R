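#' Desk-scale ensemble experiment: voter vs. annotators vs. majority vote
#'
#' Runs the package's central experiment end to end on synthetic data: draw
#' an annotated corpus, simulate K noisy stage-one annotators with the given
#' label-flip rates, hold out 20% of the documents, train the voter on the
#' remainder (with a dev carve-out of 20% of the training documents for
#' early stopping), and score every system on the held-out documents with
#' strict-span entity F1. This is the desk-scale analogue of the claim the
#' architecture was built for: the trained voter should outperform every
#' annotator it integrates and the majority-vote baseline.
#'
#' @param seed integer; drives corpus generation, annotator corruption,
#'   splitting and training.
#' @param n_documents corpus size (default 200 documents of 10 sentences,
#'   roughly 2,000 sentences).
#' @param rates per-annotator label-flip corruption rates.
#' @param config optional [voter_config()]; by default the package defaults
#'   with `epochs = 12` and the experiment seed.
#' @param verbose print training progress.
#' @return list with `voter_f1`, `majority_vote_f1`, `annotator_f1` (named
#'   vector), `n_test_sentences`, `n_train_sentences` and the fitted `model`.
#' @export
ensemble_experiment <- function(seed = 1L, n_documents = 200L,
                                rates = c(0.15, 0.20, 0.25),
                                config = NULL, verbose = FALSE) {
  corp <- generate_corpus(synth_config(
    n_documents = n_documents, sentences_per_doc = c(10L, 10L),
    tokens_per_sentence = c(6L, 12L), entity_rate = 0.2, seed = seed))
  streams <- lapply(seq_along(rates), function(k)
    simulate_annotator(corp$labels, rates[k], "label_flip",
                       seed = seed + 1000L * k))
  corp$annotators <- annotator_outputs(paste0("a", seq_along(rates)), streams)

  split <- split_corpus(corp$documents, "joined_80_20", seed = seed)
  train_all <- corpus_subset(corp, split$train)
  test <- corpus_subset(corp, split$test)
  ntr <- length(train_all$documents)
  dev_ix <- (ntr - floor(0.2 * ntr) + 1L):ntr
  train <- corpus_subset(train_all, setdiff(seq_len(ntr), dev_ix))
  dev <- corpus_subset(train_all, dev_ix)

  if (is.null(config)) config <- voter_config(seed = seed, epochs = 12L)
  fit <- lstm_voter(train$documents, train$labels,
                    annotators = train$annotators, dev = dev,
                    config = config, verbose = verbose)

  gold <- test$mentions
  voter_f1 <- evaluate_mentions(
    gold, predict(fit, test$documents, test$annotators))$f1
  mv_f1 <- evaluate_mentions(
    gold, decode_corpus_labels(test$documents,
                               majority_vote(test$annotators)))$f1
  ann_f1 <- vapply(seq_along(rates), function(k)
    evaluate_mentions(gold, decode_corpus_labels(
      test$documents, annotator_stream(test$annotators, k)))$f1, 0)
  names(ann_f1) <- corp$annotators$annotator_ids

  list(voter_f1 = voter_f1, majority_vote_f1 = mv_f1,
       annotator_f1 = ann_f1,
       n_train_sentences = sum(vapply(train$documents, function(d)
         length(d$sentences), 0L)),
       n_test_sentences = sum(vapply(test$documents, function(d)
         length(d$sentences), 0L)),
       model = fit)
}
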