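# Independent oracles used across tests. These are deliberately naive,
# straight-line implementations kept separate from the package's own code
# paths: scalar loops for the LSTM cell equations, full path enumeration for
# the CRF. They are only ever run at tiny sizes.

# scalar-loop transcription of the five peephole LSTM cell equations
oracle_lstm_step <- function(x, h_prev, c_prev, p) {
  d_h <- length(p$b_i)
  sig <- function(z) 1 / (1 + exp(-z))
  lin <- function(W, v) {
    out <- numeric(nrow(W))
    for (r in seq_len(nrow(W))) {
      acc <- 0
      for (cc in seq_len(ncol(W))) acc <- acc + W[r, cc] * v[cc]
      out[r] <- acc
    }
    out
  }
  i <- f <- c_new <- o <- h_new <- numeric(d_h)
  ai <- lin(p$W_xi, x) + lin(p$W_hi, h_prev)
  af <- lin(p$W_xf, x) + lin(p$W_hf, h_prev)
  ac <- lin(p$W_xc, x) + lin(p$W_hc, h_prev)
  ao_part <- lin(p$W_xo, x) + lin(p$W_ho, h_prev)
  for (k in seq_len(d_h)) {
    i[k] <- sig(ai[k] + p$w_ci[k] * c_prev[k] + p$b_i[k])
    f[k] <- sig(af[k] + p$w_cf[k] * c_prev[k] + p$b_f[k])
    c_new[k] <- f[k] * c_prev[k] + i[k] * tanh(ac[k] + p$b_c[k])
    o[k] <- sig(ao_part[k] + p$w_co[k] * c_new[k] + p$b_o[k])
    h_new[k] <- o[k] * tanh(c_new[k])
  }
  list(h = h_new, c = c_new)
}

# all L^n label paths of a linear-chain CRF, scored explicitly
oracle_crf_paths <- function(emissions, params) {
  n <- nrow(emissions)
  L <- params$n_labels
  tr <- params$transitions
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), n)))
  scores <- apply(paths, 1L, function(y) {
    s <- tr[params$start, y[1L]] + emissions[1L, y[1L]] + tr[y[n], params$stop]
    if (n > 1L) for (t in 2L:n)
      s <- s + tr[y[t - 1L], y[t]] + emissions[t, y[t]]
    s
  })
  list(paths = paths, scores = scores)
}

oracle_crf_log_partition <- function(emissions, params) {
  s <- oracle_crf_paths(emissions, params)$scores
  m <- max(s)
  m + log(sum(exp(s - m)))
}

oracle_crf_argmax <- function(emissions, params) {
  o <- oracle_crf_paths(emissions, params)
  best <- which.max(o$scores)
  list(labels = as.integer(o$paths[best, ]), score = o$scores[best])
}

random_cell <- function(d_in, d_h, scale = 0.5) {
  lstm_cell_params(d_in, d_h, init = function(n) runif(n, -scale, scale))
}

random_crf <- function(L, scale = 1) {
  p <- crf_params(L, init = function(n) runif(n, -scale, scale))
  p$transitions[, p$start] <- -1e4
  p$transitions[p$stop, ] <- -1e4
  p
}

# small fully-annotated corpus + simulated annotators, seeded
make_tiny_corpus <- function(seed = 3L, n_docs = 4L, annotator_rates = NULL) {
  cfg <- synth_config(n_documents = n_docs, sentences_per_doc = c(2L, 3L),
                      tokens_per_sentence = c(4L, 8L), entity_rate = 0.25,
                      seed = seed)
  corp <- generate_corpus(cfg)
  if (!is.null(annotator_rates)) {
    streams <- lapply(seq_along(annotator_rates), function(k)
      simulate_annotator(corp$labels, annotator_rates[k], "label_flip",
                         seed = seed + 100L * k))
    corp$annotators <- annotator_outputs(paste0("a", seq_along(annotator_rates)),
                                         streams)
  }
  corp
}

tiny_config <- function(...) {
  defaults <- list(char_embed_dim = 4L, char_hidden_dim = 3L,
                   word_embed_dim = 5L, word_hidden_dim = 4L,
                   attention_dim = 3L, dropout = 0, epochs = 2L,
                   batch_size = 4L, seed = 11L)
  do.call(voter_config, utils::modifyList(defaults, list(...)))
}

# the worked bidirectional-tagging example sentence
fig_sentence <- function() {
  text <- "Treatment with haloperidol or reserpine"
  tokenize(text)[[1L]]
}
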