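test_that("LSTM cell reproduces the analytically forced cases", {
  # all-zero parameters: gates 0.5, tanh(0)=0 -> h = c = 0 exactly
  p <- lstm_cell_params(3L, 2L)
  st <- lstm_cell_step(c(1, -2, 0.5), list(h = numeric(2), c = numeric(2)), p)
  expect_identical(st$h, c(0, 0))
  expect_identical(st$c, c(0, 0))

  # d_h = 1 hand computation: b_i = b_o = 10, W_xc = 1, x = 1, zero state
  p1 <- lstm_cell_params(1L, 1L)
  p1$b_i <- 10; p1$b_o <- 10; p1$W_xc <- matrix(1, 1, 1)
  st1 <- lstm_cell_step(1, list(h = 0, c = 0), p1)
  sig <- function(z) 1 / (1 + exp(-z))
  c_expect <- sig(10) * tanh(1)
  expect_equal(st1$c, c_expect, tolerance = 1e-12)
  expect_equal(st1$h, sig(10 + 0 * c_expect) * tanh(c_expect),
               tolerance = 1e-12)
})

test_that("LSTM cell matches a scalar transcription of the five equations", {
  set.seed(31)
  for (i in 1:50) {
    d_in <- sample(1:4, 1L); d_h <- sample(1:3, 1L)
    p <- random_cell(d_in, d_h)
    x <- runif(d_in, -2, 2)
    h0 <- runif(d_h, -0.5, 0.5); c0 <- runif(d_h, -1, 1)
    got <- lstm_cell_step(x, list(h = h0, c = c0), p)
    want <- oracle_lstm_step(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$c, want$c, tolerance = 1e-10)
  }
})

test_that("gates stay in (0,1) and |h| is bounded by 1", {
  set.seed(8)
  p <- random_cell(2L, 4L, scale = 3)
  st <- list(h = numeric(4), c = numeric(4))
  for (t in 1:20) {
    st <- lstm_cell_step(runif(2, -5, 5), st, p)
    expect_true(all(abs(st$h) <= 1))
  }
  expect_error(lstm_cell_step(c(1, NaN), st, p), "non-finite")
  expect_error(lstm_cell_step(1, st, p), "dimension")
})

test_that("bidirectional encoding concatenates both directions correctly", {
  set.seed(12)
  fwd <- random_cell(3L, 2L); bwd <- random_cell(3L, 2L)
  # single position: just the two single-step cells
  x <- matrix(runif(3), 1L)
  H <- bilstm_encode(x, fwd, bwd)
  zero <- list(h = numeric(2), c = numeric(2))
  expect_equal(H[1L, 1:2], lstm_cell_step(x[1L, ], zero, fwd)$h)
  expect_equal(H[1L, 3:4], lstm_cell_step(x[1L, ], zero, bwd)$h)
  # zero parameters -> all-zero outputs
  z <- lstm_cell_params(3L, 2L)
  expect_equal(bilstm_encode(matrix(runif(9), 3L), z, z),
               matrix(0, 3L, 4L))
  # reversal symmetry: flip input, swap cells -> flipped output with halves
  # swapped
  X <- matrix(runif(15, -1, 1), 5L)
  H1 <- bilstm_encode(X, fwd, bwd)
  H2 <- bilstm_encode(X[5:1, ], bwd, fwd)
  expect_equal(H2, H1[5:1, c(3:4, 1:2)], tolerance = 1e-12)
  expect_error(bilstm_encode(matrix(0, 0L, 3L), fwd, bwd), "empty")
})

test_that("attention weights form a simplex point and weight the context", {
  set.seed(77)
  ap <- attention_params(3L, 2L, init = function(n) runif(n, -1, 1))
  # single state: weight 1, context = the state
  s <- matrix(runif(3), 1L)
  got <- attention_pool(s, ap)
  expect_equal(got$weights, 1)
  expect_equal(got$context, drop(s))
  # identical states: uniform weights
  S <- matrix(rep(runif(3), 4), 4L, byrow = TRUE)
  expect_equal(attention_pool(S, ap)$weights, rep(0.25, 4))
  # two distinct states: hand-computed softmax of v' tanh(W s + b)
  S2 <- rbind(c(1, 0, -1), c(0.5, 2, 0))
  e <- apply(S2, 1L, function(r) sum(ap$v * tanh(ap$W %*% r + ap$b)))
  w <- exp(e - max(e)); w <- w / sum(w)
  got2 <- attention_pool(S2, ap)
  expect_equal(got2$weights, w, tolerance = 1e-12)
  expect_equal(got2$context, drop(crossprod(S2, w)), tolerance = 1e-12)
  # property: simplex within 1e-6 for random inputs
  for (i in 1:20) {
    Sr <- matrix(runif(15, -10, 10), 5L, 3L)
    wr <- attention_pool(Sr, ap)$weights
    expect_true(all(wr >= 0))
    expect_equal(sum(wr), 1, tolerance = 1e-6)
  }
})

test_that("CRF forward equals brute-force enumeration and normalizes", {
  # uniform case: n = 1, all scores 0, L = 15 -> log Z = log 15
  p15 <- crf_params(15L)
  expect_equal(crf_log_partition(matrix(0, 1L, 15L), p15), log(15),
               tolerance = 1e-9)
  expect_equal(crf_log_likelihood(matrix(0, 1L, 15L), 3L, p15), -log(15),
               tolerance = 1e-9)
  set.seed(101)
  for (i in 1:10) {
    n <- sample(2:4, 1L); L <- sample(2:5, 1L)
    E <- matrix(runif(n * L, -2, 2), n, L)
    cp <- random_crf(L)
    expect_equal(crf_log_partition(E, cp), oracle_crf_log_partition(E, cp),
                 tolerance = 1e-8)
    # sum of exp(log-likelihood) over all paths = 1
    o <- oracle_crf_paths(E, cp)
    ll <- apply(o$paths, 1L, function(y) crf_log_likelihood(E, y, cp))
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-8)
    expect_true(all(ll <= 1e-12))
  }
  # shifting one position's emissions by kappa shifts log Z by kappa
  E <- matrix(runif(12), 3L, 4L)
  cp <- random_crf(4L)
  E2 <- E; E2[2L, ] <- E2[2L, ] + 1.7
  expect_equal(crf_log_partition(E2, cp), crf_log_partition(E, cp) + 1.7,
               tolerance = 1e-9)
})

test_that("Viterbi equals enumeration argmax; ties go to the first label", {
  set.seed(202)
  # decoupled case: zero transitions -> per-token argmax
  L <- 5L
  cp <- crf_params(L)
  E <- matrix(runif(20), 4L, L)
  vit <- viterbi_decode(E, cp)
  expect_equal(vit$labels, apply(E, 1L, which.max))
  # random instances vs brute force (n = 4, L = 5: 625 paths)
  for (i in 1:10) {
    E <- matrix(runif(20, -3, 3), 4L, L)
    cpr <- random_crf(L)
    want <- oracle_crf_argmax(E, cpr)
    got <- viterbi_decode(E, cpr)
    expect_equal(got$labels, want$labels)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    # the argmax path's likelihood is >= every other path's
    ll_best <- crf_log_likelihood(E, got$labels, cpr)
    o <- oracle_crf_paths(E, cpr)
    expect_true(all(ll_best + 1e-9 >=
                      apply(o$paths, 1L, function(y)
                        crf_log_likelihood(E, y, cpr))))
  }
  # all scores equal: first label repeated
  expect_equal(viterbi_decode(matrix(1, 3L, L), cp)$labels, rep(1L, 3L))
  expect_error(viterbi_decode(matrix(0, 0L, L), cp), "empty")
})
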