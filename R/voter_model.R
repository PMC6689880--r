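#' Configuration of the voter network
#'
#' Hyperparameters of the two-stage voter model. Dimensions are in units of
#' embedding/hidden-vector components; `dropout` is the drop probability
#' applied to word representations before the word Bi-LSTM (the only dropout
#' site); `learning_rate` is the Adam step size; `patience` is the number of
#' epochs without dev-F1 improvement tolerated before early stopping.
#' `peephole = TRUE` uses the peephole LSTM cell exactly as
#' [lstm_cell_step()] computes it; `FALSE` gives the stock no-peephole
#' variant. Training is fully reproducible given `seed`.
#'
#' @param char_embed_dim,char_hidden_dim character embedding / char-LSTM
#'   hidden size.
#' @param word_embed_dim,word_hidden_dim word embedding / word-LSTM hidden
#'   size.
#' @param attention_dim width of the additive attention scoring layer.
#' @param dropout drop probability in `[0, 1)`.
#' @param learning_rate,epochs,batch_size,patience optimizer settings.
#' @param grad_clip global gradient-norm clip.
#' @param seed integer RNG seed for initialization, shuffling and dropout.
#' @param peephole use peephole LSTM cells.
#' @return list of class `"voter_config"`.
#' @export
voter_config <- function(char_embed_dim = 16L, char_hidden_dim = 16L,
                         word_embed_dim = 32L, word_hidden_dim = 32L,
                         attention_dim = 16L, dropout = 0.1,
                         learning_rate = 0.003, epochs = 20L,
                         batch_size = 8L, patience = 10L, grad_clip = 5,
                         seed = 42L, peephole = TRUE) {
  stopifnot(char_embed_dim > 0, char_hidden_dim > 0, word_embed_dim > 0,
            word_hidden_dim > 0, attention_dim > 0,
            dropout >= 0, dropout < 1, learning_rate > 0, epochs > 0,
            batch_size > 0, patience > 0)
  structure(list(char_embed_dim = as.integer(char_embed_dim),
                 char_hidden_dim = as.integer(char_hidden_dim),
                 word_embed_dim = as.integer(word_embed_dim),
                 word_hidden_dim = as.integer(word_hidden_dim),
                 attention_dim = as.integer(attention_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), grad_clip = grad_clip,
                 seed = as.integer(seed), peephole = isTRUE(peephole)),
            class = "voter_config")
}

# ---- parameter initialization -------------------------------------------

glorot <- function(r, c) {
  s <- sqrt(6 / (r + c))
  matrix(runif(r * c, -s, s), r, c)
}

init_cell <- function(d_in, d_h, prefix) {
  p <- list()
  for (g in c("Wxi", "Wxf", "Wxc", "Wxo")) p[[paste0(prefix, g)]] <- glorot(d_h, d_in)
  for (g in c("Whi", "Whf", "Whc", "Who")) p[[paste0(prefix, g)]] <- glorot(d_h, d_h)
  for (g in c("wci", "wcf", "wco")) p[[paste0(prefix, g)]] <- runif(d_h, -0.1, 0.1)
  p[[paste0(prefix, "bi")]] <- numeric(d_h)
  p[[paste0(prefix, "bf")]] <- rep(1, d_h)  # standard forget-gate bias
  p[[paste0(prefix, "bc")]] <- numeric(d_h)
  p[[paste0(prefix, "bo")]] <- numeric(d_h)
  p
}

init_voter_params <- function(config, n_char, n_word, K, L = 15L) {
  dce <- config$char_embed_dim; dch <- config$char_hidden_dim
  dwe <- config$word_embed_dim; dwh <- config$word_hidden_dim
  da <- config$attention_dim
  p <- list(char_embed = matrix(runif(dce * n_char, -0.1, 0.1), dce, n_char),
            word_embed = matrix(runif(dwe * n_word, -0.1, 0.1), dwe, n_word))
  p <- c(p, init_cell(dce, dch, "cf_"), init_cell(dce, dch, "cb_"))
  D1 <- K * L
  D <- dwe + 2L * dch + D1
  p <- c(p, init_cell(D, dwh, "wf_"), init_cell(D, dwh, "wb_"))
  p$ac_W <- glorot(da, 2L * dch); p$ac_b <- numeric(da)
  p$ac_v <- runif(da, -0.1, 0.1)
  if (K > 0L) {
    p$as_W1 <- glorot(da, D1); p$as_b1 <- numeric(da)
    p$as_W2 <- glorot(D1, da); p$as_b2 <- numeric(D1)
  }
  p$proj_W <- glorot(L, 2L * dwh); p$proj_b <- numeric(L)
  tr <- matrix(0, L + 2L, L + 2L)
  tr[, L + 1L] <- -1e4; tr[L + 2L, ] <- -1e4
  p$crf_trans <- tr
  p
}

# nested LSTM cell view over the flat parameter list (for the R reference
# kernels and external inspection)
cell_from_flat <- function(params, prefix) {
  structure(list(
    W_xi = params[[paste0(prefix, "Wxi")]], W_xf = params[[paste0(prefix, "Wxf")]],
    W_xc = params[[paste0(prefix, "Wxc")]], W_xo = params[[paste0(prefix, "Wxo")]],
    W_hi = params[[paste0(prefix, "Whi")]], W_hf = params[[paste0(prefix, "Whf")]],
    W_hc = params[[paste0(prefix, "Whc")]], W_ho = params[[paste0(prefix, "Who")]],
    w_ci = params[[paste0(prefix, "wci")]], w_cf = params[[paste0(prefix, "wcf")]],
    w_co = params[[paste0(prefix, "wco")]],
    b_i = params[[paste0(prefix, "bi")]], b_f = params[[paste0(prefix, "bf")]],
    b_c = params[[paste0(prefix, "bc")]], b_o = params[[paste0(prefix, "bo")]]),
    class = "lstm_cell_params")
}

crf_from_flat <- function(params, L = 15L) {
  list(transitions = params$crf_trans, n_labels = L, start = L + 1L,
       stop = L + 2L)
}

# ---- vocabulary and engine encoding -------------------------------------

UNK <- "<unk>"

build_vocab <- function(documents) {
  surfaces <- unlist(lapply(documents, function(d)
    lapply(d$sentences, function(s) s$surface)))
  words <- c(UNK, sort(unique(surfaces)))
  chars <- c(UNK, sort(unique(unlist(strsplit(surfaces, "", fixed = TRUE)))))
  list(words = words, chars = chars)
}

map_or_unk <- function(x, vocab) {
  idx <- match(x, vocab)
  idx[is.na(idx)] <- 1L
  idx
}

# flatten a corpus into the per-sentence structures the C++ engine consumes
encode_for_engine <- function(documents, vocab, labels = NULL,
                              annotators = NULL, tagset = chem_tagset()) {
  s1 <- if (!is.null(annotators)) encode_stage_one(annotators, tagset)
  sents <- list()
  index <- list()
  for (di in seq_along(documents)) {
    d <- documents[[di]]
    for (si in seq_along(d$sentences)) {
      s <- d$sentences[[si]]
      if (nrow(s) == 0L) next
      item <- list(
        word = map_or_unk(s$surface, vocab$words),
        chars = lapply(strsplit(s$surface, "", fixed = TRUE), map_or_unk,
                       vocab = vocab$chars))
      if (!is.null(s1)) item$s1 <- s1[[di]][[si]]
      if (!is.null(labels)) item$y <- label_index(labels[[di]][[si]], tagset)
      sents[[length(sents) + 1L]] <- item
      index[[length(index) + 1L]] <- c(di, si)
    }
  }
  list(sents = sents, index = index)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, state, lr, clip,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  scl <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scl
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  L <- nrow(params$crf_trans) - 2L
  params$crf_trans[, L + 1L] <- -1e4  # nothing enters START
  params$crf_trans[L + 2L, ] <- -1e4  # nothing leaves STOP
  list(params = params, state = state)
}

# ---- fitting ------------------------------------------------------------

#' Fit the two-stage voter model
#'
#' Trains the full network — character Bi-LSTM with attention pooling,
#' trainable word embeddings, attention-weighted stage-one one-hot features,
#' word-level Bi-LSTM and a linear-chain CRF output layer — by minimizing
#' the mean per-sentence negative CRF log-likelihood with Adam. After each
#' epoch the entity-level F1 on the dev partition is logged and the
#' parameters achieving the best dev F1 are kept (early stopping once
#' `patience` epochs pass without improvement; without a dev set the
#' training loss is the criterion). Training is deterministic given
#' `config$seed`.
#'
#' @param documents training documents (list of [chem_document()]).
#' @param labels per-document list of per-sentence gold IOB label vectors.
#' @param annotators optional [annotator_outputs()] aligned to `documents`;
#'   their one-hot encodings become the stage-one feature block (omit for a
#'   plain char/word tagger, K = 0).
#' @param dev optional list with `documents`, `labels` and (if `annotators`
#'   was given) `annotators` for the development partition.
#' @param config a [voter_config()].
#' @param embeddings optional pretrained word-vector matrix from
#'   [read_word_vectors()]; matching vocabulary rows initialize the word
#'   embedding table (which remains trainable).
#' @param verbose print per-epoch progress.
#' @return an object of class `"lstm_voter"` with elements `params` (named
#'   list of weight arrays), `config`, `vocab`, `tagset`, `history`
#'   (per-epoch loss and dev F1) and `best_epoch`.
#' @export
lstm_voter <- function(documents, labels, annotators = NULL, dev = NULL,
                       config = voter_config(), embeddings = NULL,
                       verbose = FALSE) {
  if (!length(documents)) stop("empty training set", call. = FALSE)
  stopifnot(inherits(config, "voter_config"))
  tagset <- chem_tagset()
  K <- if (is.null(annotators)) 0L else length(annotators$annotator_ids)
  vocab <- build_vocab(documents)

  train <- encode_for_engine(documents, vocab, labels, annotators, tagset)
  if (!length(train$sents)) stop("empty training set", call. = FALSE)
  dev_enc <- NULL
  dev_gold <- NULL
  if (!is.null(dev)) {
    dev_enc <- encode_for_engine(dev$documents, vocab, NULL, dev$annotators,
                                 tagset)
    dev_gold <- decode_corpus_labels(dev$documents, dev$labels)
  }

  set.seed(config$seed)
  params <- init_voter_params(config, n_char = length(vocab$chars),
                              n_word = length(vocab$words), K = K)
  if (!is.null(embeddings)) {
    hit <- intersect(colnames(embeddings), vocab$words)
    if (nrow(embeddings) != config$word_embed_dim)
      stop("pretrained embeddings have ", nrow(embeddings),
           " dimensions; config says ", config$word_embed_dim, call. = FALSE)
    params$word_embed[, match(hit, vocab$words)] <- embeddings[, hit]
  }

  opt <- adam_init(params)
  n_sent <- length(train$sents)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_f1 = numeric())
  best <- list(score = -Inf, params = params, epoch = 0L)
  stall <- 0L

  model_view <- function(p) {
    structure(list(params = p, config = config, vocab = vocab,
                   tagset = tagset, K = K,
                   annotator_ids = if (K) annotators$annotator_ids),
              class = "lstm_voter")
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_sent)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      res <- tryCatch(
        cpp_loss_grad(train$sents[b], params, config$dropout,
                      config$peephole),
        error = function(e) stop("epoch ", epoch, ", batch ", bi, ": ",
                                 conditionMessage(e), call. = FALSE))
      upd <- adam_step(params, res$grads, opt, config$learning_rate,
                       config$grad_clip)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + res$loss * length(b)
    }
    ep_loss <- ep_loss / n_sent

    dev_f1 <- NA_real_
    if (!is.null(dev_enc)) {
      pred <- predict_encoded(model_view(params), dev_enc, dev$documents)
      dev_f1 <- evaluate_mentions(dev_gold, pred)$f1
      score <- dev_f1
    } else {
      score <- -ep_loss
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss,
                                dev_f1 = dev_f1))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  dev F1 %s", epoch, ep_loss,
                      ifelse(is.na(dev_f1), "-", sprintf("%.4f", dev_f1))))
    if (score > best$score + 1e-12) {
      best <- list(score = score, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  out <- model_view(best$params)
  out$history <- history
  out$best_epoch <- best$epoch
  out
}

# decode engine-encoded sentences into a mention table
predict_encoded <- function(model, enc, documents) {
  if (!length(enc$sents)) return(empty_mentions())
  fw <- cpp_forward(enc$sents, model$params, model$config$peephole, FALSE)
  crf <- crf_from_flat(model$params)
  labels <- lapply(documents, function(d)
    lapply(d$sentences, function(s) rep("O", nrow(s))))
  for (i in seq_along(fw)) {
    ix <- enc$index[[i]]
    vit <- viterbi_decode(fw[[i]]$emissions, crf, tagset = model$tagset)
    labels[[ix[1L]]][[ix[2L]]] <- vit$labels
  }
  decode_corpus_labels(documents, labels)
}

#' Predict entity mentions with a fitted voter model
#'
#' Runs the network forward, Viterbi-decodes the CRF per sentence, and
#' converts the IOB labels back into character-offset mentions. Prediction
#' is deterministic (dropout is off). Unknown words and characters fall back
#' to the learned UNK vectors.
#'
#' @param object a fitted `"lstm_voter"`.
#' @param documents documents to tag.
#' @param annotators stage-one outputs for those documents (required iff the
#'   model was trained with K > 0 annotators).
#' @param type `"mentions"` (default) for a mention data frame, `"labels"`
#'   for the per-document IOB label streams.
#' @param ... unused.
#' @export
predict.lstm_voter <- function(object, documents, annotators = NULL,
                               type = c("mentions", "labels"), ...) {
  type <- match.arg(type)
  if (object$K > 0L && is.null(annotators))
    stop("model was trained with ", object$K,
         " stage-one annotators; supply `annotators`", call. = FALSE)
  if (object$K == 0L) annotators <- NULL
  enc <- encode_for_engine(documents, object$vocab, NULL, annotators,
                           object$tagset)
  if (type == "mentions") return(predict_encoded(object, enc, documents))
  fw <- if (length(enc$sents))
    cpp_forward(enc$sents, object$params, object$config$peephole, FALSE)
  else list()
  crf <- crf_from_flat(object$params)
  labels <- lapply(documents, function(d)
    lapply(d$sentences, function(s) rep("O", nrow(s))))
  for (i in seq_along(fw)) {
    ix <- enc$index[[i]]
    labels[[ix[1L]]][[ix[2L]]] <-
      viterbi_decode(fw[[i]]$emissions, crf, tagset = object$tagset)$labels
  }
  names(labels) <- vapply(documents, `[[`, "", "doc_id")
  labels
}

#' @export
print.lstm_voter <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("<lstm_voter: K=%d stage-one annotator(s), %d words, ",
                     "%d chars, %s parameters>\n"),
              x$K, length(x$vocab$words), length(x$vocab$chars),
              format(np, big.mark = ",")))
  if (!is.null(x$best_epoch))
    cat(sprintf("  best epoch %d of %d trained\n", x$best_epoch,
                nrow(x$history)))
  invisible(x)
}

#' @export
summary.lstm_voter <- function(object, ...) {
  print(object)
  cfg <- object$config
  cat(sprintf(paste0("  dims: char %d/%d, word %d/%d, attention %d; ",
                     "dropout %.2f, lr %g, batch %d\n"),
              cfg$char_embed_dim, cfg$char_hidden_dim, cfg$word_embed_dim,
              cfg$word_hidden_dim, cfg$attention_dim, cfg$dropout,
              cfg$learning_rate, cfg$batch_size))
  if (!is.null(object$history) && nrow(object$history)) {
    h <- object$history
    cat(sprintf("  final loss %.4f", h$loss[nrow(h)]))
    if (!all(is.na(h$dev_f1)))
      cat(sprintf(", best dev F1 %.4f (epoch %d)",
                  max(h$dev_f1, na.rm = TRUE), object$best_epoch))
    cat("\n")
  }
  invisible(object)
}

#' @export
plot.lstm_voter <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history", call. = FALSE)
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(h$epoch, h$loss, type = "b", pch = 16, xlab = "epoch",
       ylab = "mean sentence NLL", main = "voter training", ...)
  if (!all(is.na(h$dev_f1))) {
    par(new = TRUE)
    plot(h$epoch, h$dev_f1, type = "b", pch = 1, col = "red3", axes = FALSE,
         xlab = "", ylab = "", ylim = c(0, 1))
    axis(4, col.axis = "red3")
    legend("bottomright", legend = c("loss", "dev F1"), pch = c(16, 1),
           col = c("black", "red3"), bty = "n")
  }
  invisible(x)
}

# ---- attention report ----------------------------------------------------

#' Stage-one attention report
#'
#' Returns, for every token, the attention distribution the model places on
#' the stage-one feature vector — per component (K x 15 columns) and
#' aggregated per annotator block (K columns) — making visible how much each
#' upstream annotator's vote contributed. Every row sums to 1.
#'
#' @param model a fitted `"lstm_voter"` with K >= 1.
#' @param documents,annotators inputs as for [predict.lstm_voter()].
#' @return per document, a list of per-sentence lists with matrices
#'   `per_component` (`n x 15K`) and `per_annotator` (`n x K`, columns named
#'   by annotator).
#' @export
attention_report <- function(model, documents, annotators) {
  if (model$K == 0L)
    stop("model was trained without stage-one annotators", call. = FALSE)
  enc <- encode_for_engine(documents, model$vocab, NULL, annotators,
                           model$tagset)
  fw <- cpp_forward(enc$sents, model$params, model$config$peephole, TRUE)
  L <- length(model$tagset)
  out <- lapply(documents, function(d) vector("list", length(d$sentences)))
  for (i in seq_along(fw)) {
    ix <- enc$index[[i]]
    beta <- fw[[i]]$stage_one_attention
    per_ann <- vapply(seq_len(model$K), function(k)
      rowSums(beta[, (k - 1L) * L + seq_len(L), drop = FALSE]),
      numeric(nrow(beta)))
    if (is.null(dim(per_ann))) per_ann <- matrix(per_ann, nrow = nrow(beta))
    colnames(per_ann) <- model$annotator_ids
    out[[ix[1L]]][[ix[2L]]] <- list(per_component = beta,
                                    per_annotator = per_ann)
  }
  out
}

# ---- persistence ---------------------------------------------------------

#' Save / load a fitted voter model
#'
#' The model file is a single RDS archive holding a format version, the
#' configuration, vocabularies and all parameter arrays; a round-trip
#' reproduces bitwise-identical predictions.
#'
#' @param model a fitted `"lstm_voter"`.
#' @param path file path.
#' @export
save_lstm_voter <- function(model, path) {
  stopifnot(inherits(model, "lstm_voter"))
  saveRDS(list(format = "lstm_voter", version = 1L, model = unclass(model)),
          path)
  invisible(path)
}

#' @rdname save_lstm_voter
#' @export
load_lstm_voter <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "lstm_voter"))
    stop("not a voter model file: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("unsupported model file version: ", obj$version, call. = FALSE)
  structure(obj$model, class = "lstm_voter")
}

# ---- R reference forward path -------------------------------------------

#' Word representation of a sentence (reference implementation)
#'
#' Composes the documented kernels of the package into the per-token word
#' representation: character embeddings run through the char Bi-LSTM and
#' attention-pooled into a context vector; the word embedding (UNK fallback
#' for out-of-vocabulary tokens); and, when the model has stage-one
#' annotators, the attention-rescaled one-hot feature vector. This pure-R
#' path defines the semantics the fast training engine must reproduce.
#'
#' @param sentence a [chem_sentence()].
#' @param stage_one optional `n x 15K` one-hot matrix for the sentence (one
#'   block per annotator, from [encode_stage_one()]).
#' @param model a fitted `"lstm_voter"` (or any list with compatible
#'   `params`, `vocab`, `config`).
#' @return `n x D` matrix, `D = word_embed_dim + 2*char_hidden_dim + 15K`.
#' @export
build_word_representation <- function(sentence, stage_one = NULL, model) {
  p <- model$params
  cfg <- model$config
  cf <- cell_from_flat(p, "cf_"); cb <- cell_from_flat(p, "cb_")
  att <- list(W = p$ac_W, b = p$ac_b, v = p$ac_v)
  n <- nrow(sentence)
  wid <- map_or_unk(sentence$surface, model$vocab$words)
  reps <- vector("list", n)
  for (t in seq_len(n)) {
    cid <- map_or_unk(strsplit(sentence$surface[t], "", fixed = TRUE)[[1L]],
                      model$vocab$chars)
    Xc <- t(p$char_embed[, cid, drop = FALSE])  # m x d_ce
    S <- bilstm_encode(Xc, cf, cb, peephole = cfg$peephole)
    ctx <- attention_pool(S, att)$context
    rep_t <- c(p$word_embed[, wid[t]], ctx)
    if (!is.null(stage_one) && !is.null(p$as_W1)) {
      u <- stage_one[t, ]
      q <- tanh(drop(p$as_W1 %*% u) + p$as_b1)
      e <- drop(p$as_W2 %*% q) + p$as_b2
      beta <- exp(e - max(e)); beta <- beta / sum(beta)
      rep_t <- c(rep_t, beta * u)
    }
    reps[[t]] <- rep_t
  }
  do.call(rbind, reps)
}

#' Emission scores of a sentence (reference implementation)
#'
#' Runs the word-level Bi-LSTM over the word representations and projects
#' each position to the 15 label scores. Together with
#' [build_word_representation()] this is the pure-R composition of the
#' package's kernels that the C++ engine is tested against.
#'
#' @param representations `n x D` matrix from [build_word_representation()].
#' @param model a fitted `"lstm_voter"`.
#' @return `n x 15` emission score matrix.
#' @export
forward_emissions <- function(representations, model) {
  p <- model$params
  wf <- cell_from_flat(p, "wf_"); wb <- cell_from_flat(p, "wb_")
  H <- bilstm_encode(representations, wf, wb,
                     peephole = model$config$peephole)
  t(p$proj_W %*% t(H) + p$proj_b)
}

# ---- embeddings ----------------------------------------------------------

#' Read a word2vec-style text embedding table
#'
#' Format: one word per line, `word v1 v2 ... vd` separated by spaces; an
#' optional first line `n d` (the word2vec header) is skipped.
#'
#' @param path file path.
#' @return numeric matrix, one column per word, `colnames` = words.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) && grepl("^[0-9]+ [0-9]+$", lines[1L])) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " +")
  words <- vapply(parts, `[`, "", 1L)
  vecs <- vapply(parts, function(x) as.numeric(x[-1L]),
                 numeric(length(parts[[1L]]) - 1L))
  if (is.null(dim(vecs))) vecs <- matrix(vecs, nrow = 1L)
  colnames(vecs) <- words
  vecs
}

# ---- hyperparameter search ----------------------------------------------

#' Random search over voter hyperparameters
#'
#' Sequential model-based search (TPE) has no R implementation available, so
#' the search harness is a seeded random search over the supplied space:
#' each trial samples one value per field (uniformly from a choice vector,
#' or log-uniformly from a `c(lo, hi)` numeric range for `learning_rate` /
#' uniformly otherwise), trains a voter, and scores entity F1 on the dev
#' partition. The best configuration and the full trial log are returned;
#' the best trial's objective is by construction >= every logged trial's.
#'
#' @param documents,labels,annotators,dev as in [lstm_voter()].
#' @param space named list over [voter_config()] fields: a vector of choices
#'   or a length-2 numeric range.
#' @param budget number of trials (>= 1).
#' @param seed search seed; trial t trains with seed `seed + t`.
#' @param base_config defaults for fields absent from `space`.
#' @return list with `best_config`, `best_f1` and `trials` (data frame, one
#'   row per trial).
#' @export
tune_lstm_voter <- function(documents, labels, annotators = NULL, dev,
                            space, budget = 10L, seed = 1L,
                            base_config = voter_config()) {
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  draws <- with_seed(seed, lapply(seq_len(budget), function(i)
    lapply(space, function(fld) {
      if (is.numeric(fld) && length(fld) == 2L && fld[1L] < fld[2L] &&
          !is.integer(fld)) {
        exp(runif(1, log(fld[1L]), log(fld[2L])))
      } else fld[[sample.int(length(fld), 1L)]]
    })))
  trials <- vector("list", budget)
  best <- list(f1 = -Inf, config = NULL)
  for (i in seq_len(budget)) {
    cfg <- base_config
    for (nm in names(draws[[i]])) cfg[[nm]] <- draws[[i]][[nm]]
    cfg$seed <- as.integer(seed + i)
    cfg <- do.call(voter_config, cfg[setdiff(names(cfg), character())])
    fit <- lstm_voter(documents, labels, annotators, dev = dev, config = cfg)
    f1 <- if (all(is.na(fit$history$dev_f1))) 0 else
      max(fit$history$dev_f1, na.rm = TRUE)
    trials[[i]] <- data.frame(trial = i, f1 = f1,
                              as.data.frame(draws[[i]]))
    if (f1 > best$f1) best <- list(f1 = f1, config = cfg)
  }
  list(best_config = best$config, best_f1 = best$f1,
       trials = do.call(rbind, trials))
}
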