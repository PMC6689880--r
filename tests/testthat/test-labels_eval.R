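test_that("IOB encoding matches the worked haloperidol/reserpine example", {
  sent <- fig_sentence()
  mentions <- data.frame(
    doc_id = "d1",
    start = c(15L, 30L), end = c(26L, 39L),
    text = c("haloperidol", "reserpine"),
    subtype = "TRIVIAL", stringsAsFactors = FALSE)
  expect_identical(iob_encode(sent, mentions),
                   c("O", "O", "B-TRIVIAL", "O", "B-TRIVIAL"))
  # decoding recovers exactly the two mentions
  dec <- iob_decode(sent, c("O", "O", "B-TRIVIAL", "O", "B-TRIVIAL"),
                    doc_id = "d1")
  expect_equal(dec$text, c("haloperidol", "reserpine"))
  expect_equal(dec$start, c(15L, 30L))
  expect_equal(dec$end, c(26L, 39L))
  expect_equal(dec$subtype, c("TRIVIAL", "TRIVIAL"))
  # and re-encodes identically
  expect_identical(iob_encode(sent, dec),
                   c("O", "O", "B-TRIVIAL", "O", "B-TRIVIAL"))
})

test_that("IOB encode handles empty, multi-token and misaligned input", {
  sent <- fig_sentence()
  expect_identical(iob_encode(sent, NULL), rep("O", 5L))
  # one 3-token mention -> B, I, I
  m <- data.frame(doc_id = "d", start = 0L, end = 26L,
                  text = "Treatment with haloperidol", subtype = "MULTIPLE",
                  stringsAsFactors = FALSE)
  expect_identical(iob_encode(sent, m),
                   c("B-MULTIPLE", "I-MULTIPLE", "I-MULTIPLE", "O", "O"))
  # boundary inside a token
  bad <- data.frame(doc_id = "d", start = 1L, end = 9L, text = "reatment",
                    subtype = "TRIVIAL", stringsAsFactors = FALSE)
  expect_error(iob_encode(sent, bad), "token boundaries")
  # overlapping mentions
  ov <- rbind(m, data.frame(doc_id = "d", start = 10L, end = 26L,
                            text = "with haloperidol", subtype = "TRIVIAL",
                            stringsAsFactors = FALSE))
  expect_error(iob_encode(sent, ov), "overlap")
})

test_that("malformed IOB sequences are repaired, not rejected", {
  sent <- fig_sentence()
  # orphan I-run becomes a mention
  dec <- iob_decode(sent, c("I-TRIVIAL", "I-TRIVIAL", "O", "O", "O"))
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$start, 0L)
  expect_equal(dec$end, 14L)
  # subtype change inside a run starts a new mention
  dec2 <- iob_decode(sent, c("B-TRIVIAL", "I-FAMILY", "O", "O", "O"))
  expect_equal(dec2$subtype, c("TRIVIAL", "FAMILY"))
  expect_equal(nrow(dec2), 2L)
  # all O -> no mentions
  expect_equal(nrow(iob_decode(sent, rep("O", 5L))), 0L)
  expect_error(iob_decode(sent, c("O", "O")), "labels")
  expect_error(iob_decode(sent, c("O", "O", "O", "O", "B-DRUG")), "unknown")
})

test_that("encode/decode round-trips on generated corpora", {
  for (seed in c(2L, 5L, 8L)) {
    corp <- make_tiny_corpus(seed = seed, n_docs = 6L)
    for (di in seq_along(corp$documents)) {
      d <- corp$documents[[di]]
      dm <- corp$mentions[corp$mentions$doc_id == d$doc_id, , drop = FALSE]
      for (si in seq_along(d$sentences)) {
        s <- d$sentences[[si]]
        lab <- iob_encode(s, dm)
        expect_identical(lab, corp$labels[[di]][[si]])
        dec <- iob_decode(s, lab, doc_id = d$doc_id)
        span <- dm[dm$start >= min(s$start) & dm$end <= max(s$end), ,
                   drop = FALSE]
        rownames(span) <- NULL
        expect_equal(dec[c("doc_id", "start", "end", "subtype")],
                     span[c("doc_id", "start", "end", "subtype")])
      }
    }
  }
})

test_that("evaluation counts strict span matches micro-averaged", {
  g <- data.frame(doc_id = "d1", start = 0L, end = 5L, text = "abcde",
                  subtype = "TRIVIAL", stringsAsFactors = FALSE)
  # exact match
  r <- evaluate_mentions(g, g)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  # one correct + one spurious -> P=0.5, R=1, F=2/3
  p <- rbind(g, data.frame(doc_id = "d1", start = 8L, end = 10L, text = "xy",
                           subtype = "FORMULA", stringsAsFactors = FALSE))
  r <- evaluate_mentions(g, p)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 2 / 3)
  # nothing predicted
  r0 <- evaluate_mentions(g, g[0, ])
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
  # duplicates counted once
  rd <- evaluate_mentions(g, rbind(g, g))
  expect_equal(rd$fp, 0)
  expect_equal(rd$precision, 1)
  # same span, different subtype: match by default, miss in strict mode
  p2 <- g; p2$subtype <- "FORMULA"
  expect_equal(evaluate_mentions(g, p2)$f1, 1)
  strict <- evaluate_mentions(g, p2, strict_subtype = TRUE)
  expect_equal(strict$f1, 0)
  expect_s3_class(strict$by_subtype, "data.frame")
})

test_that("evaluation is P/R-symmetric and F1 lies between P and R", {
  set.seed(14)
  for (i in 1:10) {
    mk <- function(n) data.frame(
      doc_id = sample(c("a", "b"), n, TRUE),
      start = s <- sample(0:50, n), end = s + sample(1:5, n, TRUE),
      text = "t", subtype = sample(chem_subtypes(), n, TRUE),
      stringsAsFactors = FALSE)
    g <- mk(8L); p <- mk(8L)
    r1 <- evaluate_mentions(g, p)
    r2 <- evaluate_mentions(p, g)
    expect_equal(r1$precision, r2$recall)
    expect_equal(r1$recall, r2$precision)
    expect_equal(r1$f1, r2$f1)
    expect_gte(r1$f1 + 1e-12, min(r1$precision, r1$recall))
    expect_lte(r1$f1 - 1e-12, max(r1$precision, r1$recall))
  }
})

test_that("evaluation report TSV has the documented columns", {
  g <- data.frame(doc_id = "d1", start = 0L, end = 5L, text = "abcde",
                  subtype = "TRIVIAL", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(evaluate_mentions(g, g, strict_subtype = TRUE), f)
  tab <- read.delim(f)
  expect_equal(names(tab),
               c("scope", "tp", "fp", "fn", "precision", "recall", "f1"))
  expect_equal(tab$scope[1L], "overall")
  expect_equal(nrow(tab), 1L + 7L)
})
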