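# shared tiny fitted ingredients
setup_engine <- function(seed = 11L, K = 2L) {
  corp <- make_tiny_corpus(seed = seed,
                           annotator_rates = if (K) rep(0.3, K))
  cfg <- tiny_config()
  vocab <- lstmvoter:::build_vocab(corp$documents)
  enc <- lstmvoter:::encode_for_engine(corp$documents, vocab, corp$labels,
                                       corp$annotators)
  set.seed(cfg$seed)
  params <- lstmvoter:::init_voter_params(cfg, length(vocab$chars),
                                          length(vocab$words), K = K)
  model <- structure(list(params = params, config = cfg, vocab = vocab,
                          tagset = chem_tagset(), K = K,
                          annotator_ids = if (K) corp$annotators$annotator_ids),
                     class = "lstm_voter")
  list(corp = corp, cfg = cfg, vocab = vocab, enc = enc, params = params,
       model = model)
}

test_that("engine forward pass equals the composed reference kernels", {
  for (K in c(0L, 2L)) {
    st <- setup_engine(seed = 7L + K, K = K)
    s1 <- if (K) encode_stage_one(st$corp$annotators)
    fw <- lstmvoter:::cpp_forward(st$enc$sents, st$params, TRUE, TRUE)
    i <- 0L
    for (di in seq_along(st$corp$documents)) {
      d <- st$corp$documents[[di]]
      for (si in seq_along(d$sentences)) {
        i <- i + 1L
        reps <- build_word_representation(
          d$sentences[[si]], if (K) s1[[di]][[si]], st$model)
        expect_equal(ncol(reps),
                     st$cfg$word_embed_dim + 2L * st$cfg$char_hidden_dim +
                       K * 15L)
        E <- forward_emissions(reps, st$model)
        expect_equal(fw[[i]]$emissions, E, tolerance = 1e-10)
      }
      if (di == 2L) break  # two documents are plenty
    }
  }
})

test_that("analytic gradients match finite differences everywhere", {
  st <- setup_engine(seed = 5L, K = 2L)
  batch <- st$enc$sents[1:3]
  res <- lstmvoter:::cpp_loss_grad(batch, st$params, 0, TRUE)
  loss_at <- function(p) lstmvoter:::cpp_loss_grad(batch, p, 0, TRUE)$loss
  eps <- 1e-6
  set.seed(99)
  for (nm in names(st$params)) {
    idx <- sample(length(st$params[[nm]]), min(3L, length(st$params[[nm]])))
    for (ii in idx) {
      up <- st$params; up[[nm]][ii] <- up[[nm]][ii] + eps
      dn <- st$params; dn[[nm]][ii] <- dn[[nm]][ii] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      # central differences carry O(eps) absolute noise; compare with a
      # mixed absolute/relative band
      expect_lt(abs(res$grads[[nm]][ii] - num),
                1e-5 + 1e-4 * abs(num),
                label = paste0("|grad ", nm, "[", ii, "] - numeric|"))
    }
  }
  # no-peephole mode zeroes the peephole gradients
  res_np <- lstmvoter:::cpp_loss_grad(batch, st$params, 0, FALSE)
  expect_true(all(res_np$grads$cf_wci == 0))
  expect_true(all(res_np$grads$wb_wco == 0))
})

test_that("attention distributions normalize on every forward pass", {
  st <- setup_engine(seed = 3L, K = 3L)
  fw <- lstmvoter:::cpp_forward(st$enc$sents, st$params, TRUE, TRUE)
  for (s in fw) {
    for (a in s$char_attention) {
      expect_true(all(a >= 0))
      expect_equal(sum(a), 1, tolerance = 1e-6)
    }
    expect_equal(rowSums(s$stage_one_attention),
                 rep(1, nrow(s$stage_one_attention)), tolerance = 1e-6)
  }
})

test_that("training descends and is seed-deterministic", {
  corp <- make_tiny_corpus(seed = 19L, n_docs = 5L,
                           annotator_rates = c(0.2, 0.3))
  cfg <- tiny_config(epochs = 3L, learning_rate = 0.01)
  fit1 <- lstm_voter(corp$documents, corp$labels, corp$annotators,
                     config = cfg)
  expect_lt(fit1$history$loss[3L], fit1$history$loss[1L])
  fit2 <- lstm_voter(corp$documents, corp$labels, corp$annotators,
                     config = cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  p1 <- predict(fit1, corp$documents, corp$annotators)
  expect_identical(p1, predict(fit2, corp$documents, corp$annotators))
  expect_identical(p1, predict(fit1, corp$documents, corp$annotators))
  expect_error(lstm_voter(list(), list()), "empty")
})

test_that("a tiny corpus is memorized to training F1 = 1", {
  w <- setNames(c(0, 0, 0, 0, 0, 1, 1) / 2, chem_subtypes())
  corp <- generate_corpus(synth_config(
    n_documents = 5L, sentences_per_doc = c(2L, 2L),
    tokens_per_sentence = c(5L, 8L), subtype_weights = w,
    entity_rate = 0.25, seed = 3L))
  fit <- lstm_voter(corp$documents, corp$labels,
                    config = voter_config(epochs = 80L, batch_size = 2L,
                                          dropout = 0, learning_rate = 0.01,
                                          patience = 80L, seed = 1L))
  pred <- predict(fit, corp$documents)
  expect_equal(evaluate_mentions(corp$mentions, pred)$f1, 1)
})

test_that("save/load round-trips to bitwise-identical predictions", {
  corp <- make_tiny_corpus(seed = 23L, annotator_rates = 0.25)
  fit <- lstm_voter(corp$documents, corp$labels, corp$annotators,
                    config = tiny_config(epochs = 2L))
  f <- withr::local_tempfile(fileext = ".rds")
  save_lstm_voter(fit, f)
  back <- load_lstm_voter(f)
  expect_identical(predict(back, corp$documents, corp$annotators),
                   predict(fit, corp$documents, corp$annotators))
  expect_error(load_lstm_voter(file.path(tempdir(), "nope.rds")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("garbage", bad)
  expect_error(load_lstm_voter(bad), "model file")
})

test_that("attention report aggregates per annotator and sums to one", {
  corp <- make_tiny_corpus(seed = 29L, annotator_rates = c(0.2, 0.4, 0.1))
  fit <- lstm_voter(corp$documents, corp$labels, corp$annotators,
                    config = tiny_config(epochs = 1L))
  rep_ <- attention_report(fit, corp$documents, corp$annotators)
  s <- rep_[[1L]][[1L]]
  expect_equal(colnames(s$per_annotator), c("a1", "a2", "a3"))
  expect_equal(rowSums(s$per_component), rep(1, nrow(s$per_component)),
               tolerance = 1e-6)
  expect_equal(rowSums(s$per_annotator), rep(1, nrow(s$per_annotator)),
               tolerance = 1e-6)
  # K = 0 model refuses
  fit0 <- lstm_voter(corp$documents, corp$labels,
                     config = tiny_config(epochs = 1L))
  expect_error(attention_report(fit0, corp$documents, corp$annotators),
               "without stage-one")
  expect_error(predict(fit, corp$documents), "supply")
})

test_that("a perfect annotator attracts the most attention after training", {
  corp <- generate_corpus(synth_config(
    n_documents = 15L, sentences_per_doc = c(4L, 6L),
    tokens_per_sentence = c(6L, 10L), entity_rate = 0.25, seed = 8L))
  streams <- list(
    simulate_annotator(corp$labels, 0.5, "label_flip", seed = 1L),
    simulate_annotator(corp$labels, 0.0, "label_flip", seed = 2L),  # perfect
    simulate_annotator(corp$labels, 0.5, "label_flip", seed = 3L))
  ann <- annotator_outputs(c("noisy1", "oracle", "noisy2"), streams)
  fit <- lstm_voter(corp$documents, corp$labels, annotators = ann,
                    config = voter_config(epochs = 12L, seed = 2L))
  rep_ <- attention_report(fit, corp$documents, ann)
  w <- do.call(rbind, unlist(lapply(rep_, function(d)
    lapply(d, `[[`, "per_annotator")), recursive = FALSE))
  mw <- colMeans(w)
  expect_equal(names(which.max(mw)), "oracle")
  expect_gt(mw["oracle"], max(mw[c("noisy1", "noisy2")]))
})

test_that("print, summary and plot methods describe the fit", {
  corp <- make_tiny_corpus(seed = 43L, annotator_rates = 0.2)
  fit <- lstm_voter(corp$documents, corp$labels, corp$annotators,
                    config = tiny_config(epochs = 2L))
  expect_output(print(fit), "lstm_voter: K=1")
  expect_output(summary(fit), "dropout")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_output(print(corp$documents[[1L]]), "chem_document")
  expect_output(print(corp$annotators), "K=1")
})

test_that("pretrained word vectors seed the embedding table", {
  corp <- make_tiny_corpus(seed = 31L)
  word <- corp$documents[[1L]]$sentences[[1L]]$surface[1L]
  f <- withr::local_tempfile(fileext = ".vec")
  set.seed(41)
  vec <- round(runif(5, 0.4, 1), 3)
  writeLines(c("2 5",
               paste(word, paste(vec, collapse = " ")),
               paste("zzznotinvocab", paste(rep("0.1", 5), collapse = " "))),
             f)
  tab <- read_word_vectors(f)
  expect_equal(dim(tab), c(5L, 2L))
  cfg <- tiny_config(epochs = 1L)
  fit <- lstm_voter(corp$documents, corp$labels, config = cfg,
                    embeddings = tab)
  # the table row survived initialization (training for 1 epoch moves it only
  # slightly; compare against a fit without embeddings)
  wid <- match(word, fit$vocab$words)
  fit0 <- lstm_voter(corp$documents, corp$labels, config = cfg)
  expect_gt(max(abs(fit0$params$word_embed[, wid] -
                      fit$params$word_embed[, wid])), 0.05)
  expect_lt(max(abs(fit$params$word_embed[, wid] - vec)), 0.05)
})

test_that("random hyperparameter search returns the best logged trial", {
  corp <- make_tiny_corpus(seed = 37L, n_docs = 6L,
                           annotator_rates = c(0.2, 0.3))
  sp <- split_corpus(corp$documents, "joined_80_20", seed = 1L)
  tr <- corpus_subset(corp, sp$train)
  dv <- corpus_subset(corp, sp$test)
  res <- tune_lstm_voter(tr$documents, tr$labels, tr$annotators,
                         dev = list(documents = dv$documents,
                                    labels = dv$labels,
                                    annotators = dv$annotators),
                         space = list(learning_rate = c(1e-3, 1e-2),
                                      char_hidden_dim = c(3L, 5L)),
                         budget = 2L, seed = 2L,
                         base_config = tiny_config(epochs = 2L))
  expect_equal(nrow(res$trials), 2L)
  expect_equal(res$best_f1, max(res$trials$f1))
  expect_s3_class(res$best_config, "voter_config")
  expect_error(tune_lstm_voter(tr$documents, tr$labels, budget = 0L,
                               dev = NULL, space = list()),
               "budget")
})
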