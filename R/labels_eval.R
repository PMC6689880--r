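#' Encode entity mentions as per-token IOB labels
#'
#' The first token of each mention receives `B-<subtype>`, subsequent tokens
#' `I-<subtype>`, and every other token `O`. Mentions must be non-overlapping
#' and their character offsets must coincide with token boundaries of the
#' sentence; violations are errors (the synthetic generator and the
#' annotation reader both guarantee these preconditions).
#'
#' @param sentence a [chem_sentence()].
#' @param mentions mention data frame (see [read_annotations()]); only rows
#'   whose span lies inside the sentence's token range are used.
#' @return character vector of IOB labels, one per token.
#' @export
iob_encode <- function(sentence, mentions) {
  n <- nrow(sentence)
  labels <- rep("O", n)
  if (is.null(mentions) || nrow(mentions) == 0L || n == 0L) return(labels)
  m <- mentions[mentions$start >= min(sentence$start) &
                  mentions$end <= max(sentence$end), , drop = FALSE]
  if (!nrow(m)) return(labels)
  m <- m[order(m$start), , drop = FALSE]
  if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)]))
    stop("overlapping mentions", call. = FALSE)
  for (i in seq_len(nrow(m))) {
    first <- match(m$start[i], sentence$start)
    last <- match(m$end[i], sentence$end)
    if (is.na(first) || is.na(last))
      stop("mention [", m$start[i], ",", m$end[i],
           ") does not align with token boundaries", call. = FALSE)
    if (any(labels[first:last] != "O")) stop("overlapping mentions", call. = FALSE)
    labels[first:last] <- paste0("I-", m$subtype[i])
    labels[first] <- paste0("B-", m$subtype[i])
  }
  labels
}

#' Decode per-token IOB labels into entity mentions
#'
#' Maximal `B-s (I-s)*` runs become mentions whose character span covers the
#' first through last token. Malformed sequences — the kind a model can emit —
#' are repaired with the usual conlleval-style leniency rather than rejected:
#' an `I-s` not preceded by `B-s`/`I-s` of the same subtype opens a new
#' mention (treated as `B-s`), and a subtype change inside a run starts a new
#' mention. On valid input this is the exact inverse of [iob_encode()].
#'
#' @param sentence a [chem_sentence()].
#' @param labels character vector of IOB labels aligned to the tokens.
#' @param doc_id document id stamped on the returned mentions.
#' @return a mention data frame (doc_id, start, end, text, subtype).
#' @export
iob_decode <- function(sentence, labels, doc_id = "doc") {
  n <- nrow(sentence)
  if (length(labels) != n)
    stop(length(labels), " labels for ", n, " tokens", call. = FALSE)
  assert_labels(labels)
  runs <- list()
  cur <- NULL  # c(first_token, subtype)
  cur_sub <- NULL
  cur_first <- NA_integer_
  close_run <- function(last) {
    if (!is.na(cur_first))
      runs[[length(runs) + 1L]] <<- list(first = cur_first, last = last,
                                         subtype = cur_sub)
    cur_first <<- NA_integer_
    cur_sub <<- NULL
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") { close_run(i - 1L); next }
    pre <- substr(lab, 1L, 1L)
    sub <- substr(lab, 3L, nchar(lab))
    if (pre == "B" || is.na(cur_first) || !identical(sub, cur_sub)) {
      close_run(i - 1L)
      cur_first <- i
      cur_sub <- sub
    }
    # I-s continuing a run of the same subtype: nothing to do
  }
  close_run(n)
  if (!length(runs)) return(empty_mentions())
  out <- data.frame(
    doc_id = doc_id,
    start = vapply(runs, function(r) sentence$start[r$first], 0L),
    end = vapply(runs, function(r) sentence$end[r$last], 0L),
    text = vapply(runs, function(r)
      paste(sentence$surface[r$first:r$last], collapse = " "), ""),
    subtype = vapply(runs, `[[`, "", "subtype"),
    stringsAsFactors = FALSE)
  # mention text: slice via offsets when the sentence belongs to a document
  out
}

# decode a whole corpus worth of label streams into one mention table,
# slicing mention text from the document when available
decode_corpus_labels <- function(documents, labels) {
  res <- vector("list", length(documents))
  for (di in seq_along(documents)) {
    d <- documents[[di]]
    ms <- lapply(seq_along(d$sentences), function(si)
      iob_decode(d$sentences[[si]], labels[[di]][[si]], doc_id = d$doc_id))
    m <- do.call(rbind, ms)
    if (!is.null(m) && nrow(m) && nzchar(d$text))
      m$text <- substring(d$text, m$start + 1L, m$end)
    res[[di]] <- m
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty_mentions())
  sort_mentions(out)
}

#' Entity-level precision, recall and F1 with strict span matching
#'
#' Micro-averaged over all documents: a predicted mention is a true positive
#' iff some gold mention matches it exactly on `(doc_id, start, end)` — the
#' BioCreative-style strict-span criterion; subtype is ignored for matching
#' unless `strict_subtype = TRUE`, in which case the subtype must also agree
#' and per-subtype rows are reported. Duplicate predicted spans for one
#' document are counted once. Precision is `tp/(tp+fp)`, recall `tp/(tp+fn)`
#' (each 0 when its denominator is 0) and F1 their harmonic mean (0 when
#' `p + r = 0`).
#'
#' @param gold,predicted mention data frames (see [read_annotations()]).
#' @param strict_subtype also require subtype agreement and report
#'   per-subtype counts.
#' @return an object of class `"ner_eval"`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` and, in strict mode, `by_subtype`.
#' @export
evaluate_mentions <- function(gold, predicted, strict_subtype = FALSE) {
  key <- function(m) {
    if (strict_subtype) paste(m$doc_id, m$start, m$end, m$subtype, sep = "\r")
    else paste(m$doc_id, m$start, m$end, sep = "\r")
  }
  g <- unique(key(gold))
  p <- unique(key(predicted))
  tp <- sum(p %in% g)
  res <- eval_counts(tp, fp = length(p) - tp, fn = length(g) - tp)
  if (strict_subtype) {
    subs <- chem_subtypes()
    res$by_subtype <- do.call(rbind, lapply(subs, function(s) {
      gs <- unique(key(gold[gold$subtype == s, , drop = FALSE]))
      ps <- unique(key(predicted[predicted$subtype == s, , drop = FALSE]))
      tps <- sum(ps %in% gs)
      r <- eval_counts(tps, length(ps) - tps, length(gs) - tps)
      data.frame(subtype = s, tp = r$tp, fp = r$fp, fn = r$fn,
                 precision = r$precision, recall = r$recall, f1 = r$f1,
                 stringsAsFactors = FALSE)
    }))
  }
  res
}

eval_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = p, recall = r, f1 = f),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat(sprintf("Entity-level evaluation (strict span)\n  TP %d  FP %d  FN %d\n",
              x$tp, x$fp, x$fn))
  cat(sprintf("  P %.2f  R %.2f  F1 %.2f\n", x$precision, x$recall, x$f1))
  if (!is.null(x$by_subtype)) {
    cat("  per subtype:\n")
    b <- x$by_subtype
    for (i in seq_len(nrow(b)))
      cat(sprintf("    %-13s P %.2f  R %.2f  F1 %.2f (tp %d fp %d fn %d)\n",
                  b$subtype[i], b$precision[i], b$recall[i], b$f1[i],
                  b$tp[i], b$fp[i], b$fn[i]))
  }
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One overall row of `tp fp fn precision recall f1`, plus per-subtype rows
#' when the evaluation was subtype-strict.
#'
#' @param eval a `"ner_eval"` object from [evaluate_mentions()].
#' @param path output path.
#' @export
write_eval_report <- function(eval, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste("scope", "tp", "fp", "fn", "precision", "recall", "f1",
                   sep = "\t"), con, useBytes = TRUE)
  fmt <- function(scope, e)
    paste(scope, e$tp, e$fp, e$fn, sprintf("%.4f", e$precision),
          sprintf("%.4f", e$recall), sprintf("%.4f", e$f1), sep = "\t")
  writeLines(fmt("overall", eval), con, useBytes = TRUE)
  if (!is.null(eval$by_subtype)) {
    b <- eval$by_subtype
    for (i in seq_len(nrow(b)))
      writeLines(paste(b$subtype[i], b$tp[i], b$fp[i], b$fn[i],
                       sprintf("%.4f", b$precision[i]),
                       sprintf("%.4f", b$recall[i]),
                       sprintf("%.4f", b$f1[i]), sep = "\t"),
                 con, useBytes = TRUE)
  }
  invisible(path)
}
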