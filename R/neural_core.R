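#' Peephole LSTM cell parameters
#'
#' Containers for the weights of one LSTM memory cell with peephole
#' connections. The cell follows the standard peephole formulation: the input
#' and forget gates additionally see the previous cell state and the output
#' gate sees the current cell state. Peepholes are diagonal (elementwise
#' weight vectors, the Graves convention). Matrices are oriented rows =
#' hidden, columns = input, so a gate pre-activation is `W %*% x`.
#'
#' @param d_in input dimension.
#' @param d_h hidden dimension.
#' @param init `"zero"` for all-zero weights, or a function `f(n)` drawing
#'   `n` random values (used for every matrix/vector).
#' @return a named list of class `"lstm_cell_params"` with elements
#'   `W_xi, W_xf, W_xc, W_xo` (`d_h x d_in`), `W_hi, W_hf, W_hc, W_ho`
#'   (`d_h x d_h`), peephole vectors `w_ci, w_cf, w_co` (`d_h`) and biases
#'   `b_i, b_f, b_c, b_o` (`d_h`).
#' @export
lstm_cell_params <- function(d_in, d_h, init = "zero") {
  draw <- if (identical(init, "zero")) function(n) numeric(n) else init
  mk <- function(r, c) matrix(draw(r * c), r, c)
  structure(list(
    W_xi = mk(d_h, d_in), W_xf = mk(d_h, d_in),
    W_xc = mk(d_h, d_in), W_xo = mk(d_h, d_in),
    W_hi = mk(d_h, d_h), W_hf = mk(d_h, d_h),
    W_hc = mk(d_h, d_h), W_ho = mk(d_h, d_h),
    w_ci = draw(d_h), w_cf = draw(d_h), w_co = draw(d_h),
    b_i = draw(d_h), b_f = draw(d_h), b_c = draw(d_h), b_o = draw(d_h)),
    class = "lstm_cell_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One step of the peephole LSTM cell
#'
#' Computes, in order,
#' \deqn{i_t = \sigma(W_{xi} x_t + W_{hi} h_{t-1} + w_{ci} \odot c_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf} x_t + W_{hf} h_{t-1} + w_{cf} \odot c_{t-1} + b_f)}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + w_{co} \odot c_t + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#' where \eqn{\sigma} is the logistic sigmoid, so every gate lies in (0, 1)
#' and `|h|` is elementwise bounded by 1. With `peephole = FALSE` the
#' \eqn{w_{c\cdot}} terms are dropped (the stock framework-LSTM variant,
#' useful for cross-checking against implementations without peepholes).
#'
#' @param x_t input vector (length `d_in`).
#' @param state list with `h` and `c` vectors (length `d_h`), e.g.
#'   `list(h = numeric(d_h), c = numeric(d_h))`.
#' @param params an [lstm_cell_params()].
#' @param peephole include the peephole terms (default `TRUE`).
#' @return list with the new `h` and `c`.
#' @export
lstm_cell_step <- function(x_t, state, params, peephole = TRUE) {
  if (!all(is.finite(x_t))) stop("non-finite input", call. = FALSE)
  d_h <- length(params$b_i)
  if (length(x_t) != ncol(params$W_xi) || length(state$h) != d_h ||
      length(state$c) != d_h)
    stop("dimension mismatch in lstm_cell_step", call. = FALSE)
  h <- state$h; cc <- state$c
  peep <- function(w, c) if (peephole) w * c else 0
  i <- sigmoid(drop(params$W_xi %*% x_t) + drop(params$W_hi %*% h) +
                 peep(params$w_ci, cc) + params$b_i)
  f <- sigmoid(drop(params$W_xf %*% x_t) + drop(params$W_hf %*% h) +
                 peep(params$w_cf, cc) + params$b_f)
  c_new <- f * cc + i * tanh(drop(params$W_xc %*% x_t) +
                               drop(params$W_hc %*% h) + params$b_c)
  o <- sigmoid(drop(params$W_xo %*% x_t) + drop(params$W_ho %*% h) +
                 peep(params$w_co, c_new) + params$b_o)
  list(h = o * tanh(c_new), c = c_new)
}

#' Bidirectional LSTM encoding of a sequence
#'
#' Runs the input sequence forward through one cell and backward through a
#' second, and concatenates the two hidden states at each position, so
#' position t sees both past (forward state) and future (backward state)
#' context.
#'
#' @param inputs numeric matrix, one row per position (`n x d_in`), `n >= 1`.
#' @param fwd,bwd [lstm_cell_params()] for the two directions.
#' @param peephole passed to [lstm_cell_step()].
#' @return `n x (2 d_h)` matrix; columns `1:d_h` are the forward states,
#'   the rest the backward states.
#' @export
bilstm_encode <- function(inputs, fwd, bwd, peephole = TRUE) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1L)
  n <- nrow(inputs)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  d_h <- length(fwd$b_i)
  run <- function(params, idx) {
    st <- list(h = numeric(d_h), c = numeric(d_h))
    H <- matrix(0, n, d_h)
    for (t in idx) {
      st <- lstm_cell_step(inputs[t, ], st, params, peephole)
      H[t, ] <- st$h
    }
    H
  }
  cbind(run(fwd, seq_len(n)), run(bwd, rev(seq_len(n))))
}

#' Additive attention parameters
#'
#' Weights of the additive (tanh) scoring function
#' `score(s) = v' tanh(W s + b)` used to turn a sequence of state vectors
#' into a probability distribution and a context vector.
#'
#' @param d_in state dimension.
#' @param d_att attention (scoring) dimension.
#' @param init `"zero"` or a drawing function as in [lstm_cell_params()].
#' @return named list with `W` (`d_att x d_in`), `b` (`d_att`), `v` (`d_att`).
#' @export
attention_params <- function(d_in, d_att, init = "zero") {
  draw <- if (identical(init, "zero")) function(n) numeric(n) else init
  list(W = matrix(draw(d_att * d_in), d_att, d_in), b = draw(d_att),
       v = draw(d_att))
}

#' Attention pooling of a state sequence
#'
#' Scores every position with the additive function `v' tanh(W s_i + b)`,
#' softmax-normalizes the scores into a probability distribution, and returns
#' the weighted-sum context vector together with the weights (kept for
#' interpretability; rows of weights always lie on the simplex).
#'
#' @param states numeric matrix, one row per position (`n x d_in`), `n >= 1`.
#' @param params an [attention_params()].
#' @return list with `context` (length `d_in`) and `weights` (length `n`,
#'   nonnegative, summing to 1).
#' @export
attention_pool <- function(states, params) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  n <- nrow(states)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  U <- tanh(params$W %*% t(states) + params$b)  # d_att x n
  e <- drop(crossprod(U, params$v))
  w <- exp(e - max(e))
  w <- w / sum(w)
  list(context = drop(crossprod(states, w)), weights = w)
}

#' Linear-chain CRF parameters
#'
#' The transition score matrix of a linear-chain CRF over `n_labels` labels
#' plus two auxiliary states START (`n_labels + 1`) and STOP
#' (`n_labels + 2`): entry (i, j) scores the transition i -> j. Emission
#' scores are supplied per token by the upstream network. Structurally
#' forbidden moves (into START, out of STOP) are fixed at a large negative
#' constant (-1e4) rather than -Inf to keep the log-space arithmetic finite.
#'
#' @param n_labels number of real labels L.
#' @param init `"zero"` or a drawing function for the trainable entries.
#' @return list with `transitions` (`(L+2) x (L+2)`), `n_labels`, `start`,
#'   `stop` indices.
#' @export
crf_params <- function(n_labels, init = "zero") {
  draw <- if (identical(init, "zero")) function(n) numeric(n) else init
  L <- n_labels
  tr <- matrix(draw((L + 2L)^2), L + 2L, L + 2L)
  tr[, L + 1L] <- -1e4     # nothing enters START
  tr[L + 2L, ] <- -1e4     # nothing leaves STOP
  list(transitions = tr, n_labels = L, start = L + 1L, stop = L + 2L)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' CRF forward algorithm: log-partition function
#'
#' Computes `log Z_x`, the log of the sum over all label paths of
#' `exp(path score)`, by the forward recursion in log space (logsumexp at
#' every step). A path's score is the sum of its emission scores, the
#' START -> first and last -> STOP transitions, and the first-order
#' transitions in between — the universal emission-plus-transition
#' specialization of the CRF's weighted feature functions.
#'
#' @param emissions `n x L` matrix of per-token scores over the L labels,
#'   `n >= 1`.
#' @param params a [crf_params()].
#' @return scalar `log Z_x`.
#' @export
crf_log_partition <- function(emissions, params) {
  if (is.null(dim(emissions))) emissions <- matrix(emissions, nrow = 1L)
  n <- nrow(emissions)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  L <- params$n_labels
  tr <- params$transitions
  alpha <- tr[params$start, seq_len(L)] + emissions[1L, ]
  if (n > 1L) for (t in 2L:n) {
    alpha <- vapply(seq_len(L), function(j)
      logsumexp(alpha + tr[seq_len(L), j]), 0) + emissions[t, ]
  }
  logsumexp(alpha + tr[seq_len(L), params$stop])
}

#' CRF log-likelihood of a label sequence
#'
#' `log P(y | x)` = path score of `y` minus `log Z_x`; always <= 0, and
#' `exp()` of it sums to one over the label-sequence space.
#'
#' @param emissions `n x L` score matrix.
#' @param labels integer vector of label indices (1-based) or character
#'   labels resolved against `tagset`.
#' @param params a [crf_params()].
#' @param tagset label order used to resolve character labels.
#' @return scalar log-likelihood.
#' @export
crf_log_likelihood <- function(emissions, labels, params,
                               tagset = chem_tagset()) {
  if (is.null(dim(emissions))) emissions <- matrix(emissions, nrow = 1L)
  if (is.character(labels)) labels <- label_index(labels, tagset)
  n <- nrow(emissions)
  if (length(labels) != n)
    stop("labels and emissions misaligned", call. = FALSE)
  tr <- params$transitions
  score <- tr[params$start, labels[1L]] + sum(emissions[cbind(seq_len(n), labels)]) +
    tr[labels[n], params$stop]
  if (n > 1L)
    score <- score + sum(tr[cbind(labels[-n], labels[-1L])])
  score - crf_log_partition(emissions, params)
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Dynamic-programming argmax over label sequences. Ties are broken toward
#' the lowest label index at the earliest decision, so with all scores equal
#' the first label is repeated.
#'
#' @inheritParams crf_log_partition
#' @param tagset optional label order; when supplied the returned `labels`
#'   are the corresponding strings, otherwise 1-based indices.
#' @return list with `labels` and the best path `score`.
#' @export
viterbi_decode <- function(emissions, params, tagset = NULL) {
  if (is.null(dim(emissions))) emissions <- matrix(emissions, nrow = 1L)
  n <- nrow(emissions)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  L <- params$n_labels
  tr <- params$transitions
  delta <- tr[params$start, seq_len(L)] + emissions[1L, ]
  back <- matrix(0L, n, L)
  if (n > 1L) for (t in 2L:n) {
    new_delta <- numeric(L)
    for (j in seq_len(L)) {
      s <- delta + tr[seq_len(L), j]
      b <- which.max(s)          # first maximum: lowest-index tie-break
      back[t, j] <- b
      new_delta[j] <- s[b] + emissions[t, j]
    }
    delta <- new_delta
  }
  final <- delta + tr[seq_len(L), params$stop]
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1L) for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  labels <- if (is.null(tagset)) path else tagset[path]
  list(labels = labels, score = final[path[n]])
}
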