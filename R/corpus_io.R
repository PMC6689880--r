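#' Construct a tokenized sentence
#'
#' A sentence is a data frame with one row per token: `surface` (the token
#' string, never containing whitespace), `start`/`end` (0-based, half-open
#' character offsets into the owning document's text) and any number of
#' additional character feature columns (opaque passthrough, e.g. lemmas or
#' POS tags produced upstream).
#'
#' @param surface character vector of token strings.
#' @param start,end integer character offsets, 0-based, half-open `[start, end)`.
#' @param features optional named list/data.frame of character feature columns.
#' @return a `data.frame` with class `c("chem_sentence", "data.frame")`.
#' @export
chem_sentence <- function(surface, start, end, features = NULL) {
  surface <- as.character(surface)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(surface) > 0L) {
    if (any(end <= start)) stop("token end must exceed start", call. = FALSE)
    if (any(nchar(surface) != end - start))
      stop("token surface length must equal end - start", call. = FALSE)
    if (any(grepl("[[:space:]]", surface)))
      stop("token surface must not contain whitespace", call. = FALSE)
    if (length(surface) > 1L) {
      if (any(start[-1L] < end[-length(end)]))
        stop("token offsets must be strictly increasing and non-overlapping",
             call. = FALSE)
    }
  }
  out <- data.frame(surface = surface, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.null(features) && length(features)) {
    for (nm in names(features)) out[[nm]] <- as.character(features[[nm]])
  }
  class(out) <- c("chem_sentence", "data.frame")
  out
}

#' Construct a document
#'
#' A document couples an identifier, the raw text and its tokenized
#' sentences. Every token's `[start, end)` slice of `text` must equal its
#' surface string, so entity character offsets are always reconstructible.
#'
#' @param doc_id document identifier string.
#' @param text the raw document text.
#' @param sentences list of [chem_sentence()] data frames.
#' @return a list with class `"chem_document"`.
#' @export
chem_document <- function(doc_id, text, sentences) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L, is.list(sentences))
  for (s in sentences) {
    if (nrow(s) == 0L) next
    slice <- substring(text, s$start + 1L, s$end)
    if (!all(slice == s$surface))
      stop("document '", doc_id, "': token offsets do not slice text back to ",
           "the token surface", call. = FALSE)
  }
  structure(list(doc_id = doc_id, text = text, sentences = sentences),
            class = "chem_document")
}

#' @export
print.chem_document <- function(x, ...) {
  nt <- sum(vapply(x$sentences, nrow, 0L))
  cat(sprintf("<chem_document '%s': %d sentence(s), %d token(s), %d chars>\n",
              x$doc_id, length(x$sentences), nt, nchar(x$text)))
  invisible(x)
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tokenize raw text into sentences of offset-preserving tokens
#'
#' Tokens are maximal runs of (Unicode) letters and digits; every other
#' non-whitespace character becomes a single-character token. Whitespace
#' separates tokens and is never a token itself, so hyphens, parentheses and
#' other punctuation inside chemical names are preserved as tokens and entity
#' spans remain reconstructible from offsets. Sentences are split on runs of
#' `.`, `!` or `?` followed by whitespace (the punctuation stays with the
#' preceding sentence); pre-sentenced TSV input bypasses this rule entirely.
#'
#' @param text a single string.
#' @return list of [chem_sentence()] data frames; empty or whitespace-only
#'   input yields an empty list. Offsets index into `text` (0-based,
#'   half-open).
#' @examples
#' tokenize("2-acetoxybenzoic acid")[[1]]
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(list())
  # sentence boundaries: terminator run followed by whitespace (or text end)
  bnd <- gregexpr("[.!?]+(?=[[:space:]]|$)", text, perl = TRUE)[[1]]
  seg_start <- 1L
  segs <- list()
  if (bnd[1L] != -1L) {
    ends <- as.integer(bnd) + attr(bnd, "match.length") - 1L
    for (e in ends) {
      segs[[length(segs) + 1L]] <- c(seg_start, e)
      seg_start <- e + 1L
    }
  }
  if (seg_start <= nchar(text)) segs[[length(segs) + 1L]] <- c(seg_start, nchar(text))

  tok_re <- "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]"
  out <- list()
  for (sg in segs) {
    seg_text <- substring(text, sg[1L], sg[2L])
    m <- gregexpr(tok_re, seg_text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    start0 <- as.integer(m) + sg[1L] - 2L          # 0-based into full text
    len <- attr(m, "match.length")
    out[[length(out) + 1L]] <- chem_sentence(
      surface = regmatches(seg_text, list(m))[[1L]],
      start = start0, end = start0 + len)
  }
  out
}

# reconstruct document text from offset tokens (gaps become spaces)
reconstruct_text <- function(sentences) {
  ends <- unlist(lapply(sentences, function(s) s$end))
  if (!length(ends)) return("")
  chars <- rep(" ", max(ends))
  for (s in sentences) {
    if (!nrow(s)) next
    pieces <- strsplit(s$surface, "", fixed = TRUE)
    for (i in seq_len(nrow(s)))
      chars[(s$start[i] + 1L):s$end[i]] <- pieces[[i]]
  }
  paste(chars, collapse = "")
}

#' Read and write token-per-line TSV corpora
#'
#' The TSV dialect is CoNLL-style: one token per line with tab-separated
#' fields `surface`, `start`, `end`, optional feature columns, the gold IOB
#' label, and optionally K trailing annotator label columns (the shared
#' ingestion path for real stage-one tool outputs and simulated annotators).
#' Sentences are separated by a blank line; a `#doc <id>` comment line opens
#' each document; optional `#features <names>` and `#annotators <ids>` header
#' lines declare the extra columns. A minimal 2-field dialect
#' (`surface<TAB>label`) is also accepted, with offsets reconstructed by
#' space-joining tokens.
#'
#' @param path file path.
#' @return `read_corpus_tsv()`: a list with elements `documents` (list of
#'   [chem_document()]), `labels` (per document, list of per-sentence label
#'   character vectors), `annotators` (an [annotator_outputs()] object or
#'   `NULL`) and `feature_names`.
#' @export
read_corpus_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  feature_names <- character()
  annotator_ids <- character()

  docs <- list(); doc_labels <- list(); doc_ann <- list()
  cur_id <- NULL
  cur_sents <- list(); cur_labs <- list(); cur_ann <- list()
  tok <- list()  # accumulating rows of the current sentence

  flush_sentence <- function() {
    if (!length(tok)) return()
    n <- length(tok)
    surf <- vapply(tok, `[[`, "", "surface")
    st <- vapply(tok, `[[`, 0L, "start")
    en <- vapply(tok, `[[`, 0L, "end")
    if (anyNA(st)) {  # minimal dialect: reconstruct offsets by space-joining
      len <- nchar(surf)
      en <- cumsum(len + 1L) - 1L
      st <- en - len
      base <- if (length(cur_sents))
        max(vapply(cur_sents, function(s) if (nrow(s)) max(s$end) + 1L else 0L, 0L))
      else 0L
      st <- st + base; en <- en + base
    }
    feats <- NULL
    if (length(feature_names)) {
      feats <- lapply(seq_along(feature_names), function(j)
        vapply(tok, function(r) r$features[j], ""))
      names(feats) <- feature_names
    }
    sent <- chem_sentence(surf, st, en, feats)
    cur_sents[[length(cur_sents) + 1L]] <<- sent
    cur_labs[[length(cur_labs) + 1L]] <<- vapply(tok, `[[`, "", "label")
    if (length(annotator_ids)) {
      m <- do.call(rbind, lapply(tok, function(r) r$ann))
      colnames(m) <- annotator_ids
      cur_ann[[length(cur_ann) + 1L]] <<- m
    }
    tok <<- list()
  }
  flush_document <- function() {
    flush_sentence()
    if (is.null(cur_id)) {
      if (length(cur_sents)) stop("token line before any #doc header", call. = FALSE)
      return()
    }
    text <- reconstruct_text(cur_sents)
    docs[[length(docs) + 1L]] <<- chem_document(cur_id, text, cur_sents)
    doc_labels[[length(doc_labels) + 1L]] <<- cur_labs
    if (length(annotator_ids)) doc_ann[[length(doc_ann) + 1L]] <<- cur_ann
    cur_sents <<- list(); cur_labs <<- list(); cur_ann <<- list()
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#doc ")) {
        flush_document()
        cur_id <- sub("^#doc ", "", ln)
      } else if (startsWith(ln, "#features ")) {
        feature_names <- strsplit(sub("^#features ", "", ln), " ", fixed = TRUE)[[1L]]
      } else if (startsWith(ln, "#annotators ")) {
        annotator_ids <- strsplit(sub("^#annotators ", "", ln), " ", fixed = TRUE)[[1L]]
      }
      next
    }
    if (!nzchar(ln)) { flush_sentence(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    nextra <- length(feature_names) + length(annotator_ids)
    if (length(f) == 2L && nextra == 0L) {
      tok[[length(tok) + 1L]] <- list(surface = f[1L], start = NA_integer_,
                                      end = NA_integer_, label = f[2L])
    } else if (length(f) == 4L + nextra) {
      st <- suppressWarnings(as.integer(f[2L]))
      en <- suppressWarnings(as.integer(f[3L]))
      if (is.na(st) || is.na(en))
        stop("line ", i, ": non-numeric offsets", call. = FALSE)
      nf <- length(feature_names)
      tok[[length(tok) + 1L]] <- list(
        surface = f[1L], start = st, end = en,
        features = if (nf) f[3L + seq_len(nf)] else NULL,
        label = f[4L + nf - 1L + 1L],
        ann = if (length(annotator_ids)) f[(4L + nf + 1L):length(f)] else NULL)
    } else {
      stop("line ", i, ": expected ", if (nextra) 4L + nextra else "2 or 4",
           " tab-separated fields, found ", length(f), call. = FALSE)
    }
  }
  flush_document()
  names(doc_labels) <- vapply(docs, `[[`, "", "doc_id")
  ann <- NULL
  if (length(annotator_ids)) ann <- annotator_outputs(annotator_ids, doc_ann)
  list(documents = docs, labels = doc_labels, annotators = ann,
       feature_names = feature_names)
}

#' @rdname read_corpus_tsv
#' @param documents list of [chem_document()].
#' @param labels optional per-document list of per-sentence IOB label vectors,
#'   aligned one-to-one with tokens; when omitted every token is written `O`.
#' @param annotators optional [annotator_outputs()] whose label matrices are
#'   written as trailing columns after the gold label.
#' @export
write_corpus_tsv <- function(documents, path, labels = NULL, annotators = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(x) writeLines(x, con, useBytes = TRUE)

  feature_names <- character()
  for (d in documents) for (s in d$sentences) {
    fn <- setdiff(names(s), c("surface", "start", "end"))
    if (length(fn)) { feature_names <- fn; break }
  }
  if (length(feature_names)) emit(paste("#features", paste(feature_names, collapse = " ")))
  if (!is.null(annotators))
    emit(paste("#annotators", paste(annotators$annotator_ids, collapse = " ")))

  for (di in seq_along(documents)) {
    d <- documents[[di]]
    emit(paste0("#doc ", d$doc_id))
    for (si in seq_along(d$sentences)) {
      s <- d$sentences[[si]]
      n <- nrow(s)
      lab <- if (is.null(labels)) rep("O", n) else labels[[di]][[si]]
      if (length(lab) != n)
        stop("document '", d$doc_id, "' sentence ", si,
             ": ", length(lab), " labels for ", n, " tokens", call. = FALSE)
      cols <- list(s$surface, s$start, s$end)
      for (fn in feature_names) cols <- c(cols, list(s[[fn]]))
      cols <- c(cols, list(lab))
      if (!is.null(annotators)) {
        m <- annotators$labels[[di]][[si]]
        if (is.null(dim(m)) || nrow(m) != n)
          stop("annotator labels misaligned in document '", d$doc_id, "'",
               call. = FALSE)
        for (k in seq_len(ncol(m))) cols <- c(cols, list(m[, k]))
      }
      if (n) emit(do.call(paste, c(cols, sep = "\t")))
      emit("")
    }
  }
  invisible(path)
}

#' Read and write character-offset entity annotation tables
#'
#' The annotation table is the CHEMDNER/CEMP-style TSV with columns
#' `doc_id`, `start`, `end`, `text`, `subtype` (0-based, half-open offsets
#' into the document text; subtype one of [chem_subtypes()]). Mentions are
#' kept sorted by `(doc_id, start)`.
#'
#' @param path file path.
#' @param mentions data frame with the five columns above.
#' @return `read_annotations()`: the mentions data frame, sorted.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(strsplit(lines[1L], "\t")[[1L]][1L], "doc_id"))
    lines <- lines[-1L]
  if (!length(lines)) return(empty_mentions())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 5L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 5 tab-separated fields", call. = FALSE)
  m <- data.frame(doc_id = vapply(f, `[`, "", 1L),
                  start = as.integer(vapply(f, `[`, "", 2L)),
                  end = as.integer(vapply(f, `[`, "", 3L)),
                  text = vapply(f, `[`, "", 4L),
                  subtype = vapply(f, `[`, "", 5L),
                  stringsAsFactors = FALSE)
  validate_mentions(m)
  sort_mentions(m)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(mentions, path) {
  validate_mentions(mentions)
  m <- sort_mentions(mentions)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste("doc_id", "start", "end", "text", "subtype", sep = "\t"),
             con, useBytes = TRUE)
  if (nrow(m))
    writeLines(paste(m$doc_id, m$start, m$end, m$text, m$subtype, sep = "\t"),
               con, useBytes = TRUE)
  invisible(path)
}

empty_mentions <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             text = character(), subtype = character(), stringsAsFactors = FALSE)
}

validate_mentions <- function(m) {
  need <- c("doc_id", "start", "end", "text", "subtype")
  if (!all(need %in% names(m)))
    stop("mentions must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(m)) {
    if (any(m$end <= m$start)) stop("mention end must exceed start", call. = FALSE)
    bad <- setdiff(unique(m$subtype), chem_subtypes())
    if (length(bad))
      stop("unknown subtype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

sort_mentions <- function(m) {
  m <- m[order(m$doc_id, m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Split a corpus into the training protocols of the two-stage voter
#'
#' Two schemes are supported. `two_series_60_20_20` shuffles the documents by
#' `seed`, halves them (the first half takes any odd remainder) and partitions
#' each half into train/dev/test by document count at 60/20/20 — dev and test
#' take `floor(0.2 m)` documents each and train takes the remainder. Series 1
#' is intended for fitting/ingesting the stage-one annotators and series 2 for
#' training the voter. `joined_80_20` produces a single shuffled 80/20
#' train/test partition (test takes `floor(0.2 n)`). Splitting is by document,
#' partitions are disjoint and cover the input, and the same seed always
#' yields the same partitions.
#'
#' @param documents list of [chem_document()] (length >= 5 for the two-series
#'   scheme, >= 2 for 80/20).
#' @param scheme `"two_series_60_20_20"` or `"joined_80_20"`.
#' @param seed integer; shuffling seed.
#' @return for `two_series_60_20_20`, `list(series1 = list(train, dev, test),
#'   series2 = ...)`; for `joined_80_20`, `list(train, test)`. Each leaf holds
#'   the integer indices of the documents (into `documents`), plus an `ids`
#'   attribute mapping; use [corpus_subset()] to materialize.
#' @export
split_corpus <- function(documents,
                         scheme = c("two_series_60_20_20", "joined_80_20"),
                         seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(documents)
  min_n <- if (scheme == "two_series_60_20_20") 5L else 2L
  if (n < min_n)
    stop("need at least ", min_n, " documents for scheme '", scheme, "', got ",
         n, call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  part <- function(idx) {
    m <- length(idx)
    ndev <- floor(0.2 * m); ntest <- floor(0.2 * m)
    ntrain <- m - ndev - ntest
    list(train = sort(idx[seq_len(ntrain)]),
         dev = sort(idx[ntrain + seq_len(ndev)]),
         test = sort(idx[ntrain + ndev + seq_len(ntest)]))
  }
  out <- if (scheme == "two_series_60_20_20") {
    n1 <- ceiling(n / 2)
    list(series1 = part(ord[seq_len(n1)]), series2 = part(ord[(n1 + 1L):n]))
  } else {
    ntest <- floor(0.2 * n)
    list(train = sort(ord[seq_len(n - ntest)]),
         test = sort(ord[(n - ntest + 1L):n]))
  }
  attr(out, "scheme") <- scheme
  attr(out, "seed") <- seed
  out
}

#' Materialize a corpus partition
#'
#' Subset parallel corpus containers (documents, label lists, annotator
#' outputs, mention tables) by the document indices a [split_corpus()]
#' partition holds.
#'
#' @param corpus a list with elements `documents`, optionally `labels`,
#'   `annotators`, `mentions` (as returned by [read_corpus_tsv()] or
#'   [generate_corpus()]).
#' @param idx integer document indices.
#' @return a list of the same shape restricted to `idx`.
#' @export
corpus_subset <- function(corpus, idx) {
  out <- list(documents = corpus$documents[idx])
  ids <- vapply(out$documents, `[[`, "", "doc_id")
  if (!is.null(corpus$labels)) out$labels <- corpus$labels[idx]
  if (!is.null(corpus$annotators))
    out$annotators <- annotator_outputs(corpus$annotators$annotator_ids,
                                        corpus$annotators$labels[idx])
  if (!is.null(corpus$mentions))
    out$mentions <- sort_mentions(
      corpus$mentions[corpus$mentions$doc_id %in% ids, , drop = FALSE])
  out
}
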