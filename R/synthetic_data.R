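# Fixed morphology pools. Entity tokens are built from subtype-specific
# templates so that character-level features (prefixes/suffixes/digit
# patterns) carry genuine signal, mirroring the structure of chemical names
# that makes a char-level encoder worthwhile.
synth_pools <- function() {
  list(
    background = c("the", "of", "and", "in", "to", "with", "for", "was",
                   "were", "treated", "patients", "study", "results",
                   "effects", "observed", "compared", "after", "before",
                   "levels", "increased", "decreased", "method", "analysis",
                   "treatment", "using", "showed", "significant", "control",
                   "group", "dose", "daily", "oral", "administration",
                   "reported", "clinical", "trial", "measured", "plasma",
                   "serum", "cells", "activity", "response", "data", "model",
                   "test", "between", "during", "exposure"),
    stems = c("chlor", "meth", "eth", "prop", "but", "phen", "benz", "amin",
              "oxy", "hydro", "cycl", "nitro", "sulf", "carb", "fluor",
              "brom", "iod", "acet", "form", "glyc"),
    trivial_suffix = c("ol", "ine", "ide", "ane", "ate", "one"),
    family_suffix = c("oids", "ines", "ates", "amides", "anes", "ols"),
    systematic_suffix = c("yl", "oxy", "ene", "oate", "ylamine", "oxide"),
    identifier_prefix = c("CID", "CHEBI", "DB", "CAS"),
    elements = c("C", "H", "N", "O", "S", "Cl", "Na", "Fe", "P", "K"))
}

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the voter model assumes:
#' documents of pseudo-chemical tokens whose character morphology is
#' informative of the mention subtype, gold entity spans over the seven
#' CHEMDNER subtypes, and K simulated stage-one annotators with independent,
#' configurable corruption. Default subtype weights follow the subtype
#' mixture of the CEMP patent corpus annotations (FAMILY, SYSTEMATIC and
#' TRIVIAL dominate); `entity_rate` is the expected fraction of tokens inside
#' entities.
#'
#' @param n_documents number of documents.
#' @param sentences_per_doc length-2 integer range.
#' @param tokens_per_sentence length-2 integer range (content tokens; a
#'   sentence-final "." token is appended).
#' @param subtype_weights named nonnegative weights over [chem_subtypes()];
#'   normalized to sum to 1.
#' @param entity_rate target fraction of tokens inside entities, in [0, 0.8].
#' @param annotators list of annotator specs, each
#'   `list(id =, rate =, kind =)` with kind one of `"label_flip"`,
#'   `"boundary_shift"`, `"deletion"`, `"spurious"`.
#' @param seed integer seed; the same config always generates the same corpus.
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(n_documents = 20L,
                         sentences_per_doc = c(3L, 6L),
                         tokens_per_sentence = c(6L, 12L),
                         subtype_weights = NULL,
                         entity_rate = 0.2,
                         annotators = list(),
                         seed = 1L) {
  if (is.null(subtype_weights)) {
    # CEMP annotation mixture by subtype (Abbreviation ... Trivial)
    w <- c(1373, 36238, 6818, 278, 418, 28580, 25927)
    subtype_weights <- setNames(w / sum(w), chem_subtypes())
  }
  if (is.null(names(subtype_weights)))
    names(subtype_weights) <- chem_subtypes()
  stopifnot(setequal(names(subtype_weights), chem_subtypes()),
            all(subtype_weights >= 0), sum(subtype_weights) > 0)
  subtype_weights <- subtype_weights[chem_subtypes()]
  subtype_weights <- subtype_weights / sum(subtype_weights)
  if (entity_rate < 0 || entity_rate > 0.8)
    stop("entity_rate must lie in [0, 0.8] (higher rates are infeasible for ",
         "the configured sentence lengths)", call. = FALSE)
  for (a in annotators) {
    stopifnot(is.character(a$id), a$rate >= 0, a$rate <= 1)
    if (!a$kind %in% c("label_flip", "boundary_shift", "deletion", "spurious"))
      stop("unknown corruption kind: ", a$kind, call. = FALSE)
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 tokens_per_sentence = as.integer(tokens_per_sentence),
                 subtype_weights = subtype_weights,
                 entity_rate = entity_rate,
                 annotators = annotators,
                 seed = as.integer(seed)),
            class = "synth_config")
}

rint <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

# draw the token strings of one mention of the given subtype
synth_mention_tokens <- function(subtype, pools) {
  stem <- function(k = 1L) paste(sample(pools$stems, k, replace = TRUE),
                                 collapse = "")
  switch(subtype,
    TRIVIAL = paste0(stem(rint(1L, 2L)), sample(pools$trivial_suffix, 1L)),
    FAMILY = paste0(stem(1L), sample(pools$family_suffix, 1L)),
    SYSTEMATIC = {
      nm <- paste0(stem(rint(2L, 3L)), sample(pools$systematic_suffix, 1L))
      if (runif(1) < 0.3) c(as.character(rint(1L, 19L)), nm) else nm
    },
    FORMULA = {
      el <- sample(pools$elements, rint(2L, 4L))
      paste(paste0(el, sample(1:12, length(el), replace = TRUE)),
            collapse = "")
    },
    ABBREVIATION = paste(sample(LETTERS, rint(2L, 4L), replace = TRUE),
                         collapse = ""),
    IDENTIFIER = paste0(sample(pools$identifier_prefix, 1L),
                        paste(sample(0:9, rint(4L, 6L), replace = TRUE),
                              collapse = "")),
    MULTIPLE = c(paste0(stem(1L), sample(pools$trivial_suffix, 1L)), "and",
                 paste0(stem(1L), sample(pools$trivial_suffix, 1L))),
    stop("unknown subtype: ", subtype, call. = FALSE))
}

#' Generate a synthetic annotated corpus
#'
#' Draws documents of pseudo-chemical text under a [synth_config()]:
#' background tokens come from a fixed common-word pool, entity mentions are
#' built from subtype-specific morphology templates (e.g. TRIVIAL names end
#' in -ol/-ine/-ide, FORMULA tokens interleave element symbols and digits,
#' ABBREVIATIONs are short and uppercase, MULTIPLE mentions span
#' "x and y"), gold labels are the IOB encoding of the mention spans, and
#' everything is deterministic in `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `documents` (list of [chem_document()]), `mentions`
#'   (gold mention data frame) and `labels` (per-document list of
#'   per-sentence IOB label vectors).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  pools <- synth_pools()
  mean_len <- 1.6  # rough mean mention length under the templates
  p_start <- min(1, config$entity_rate / mean_len)
  with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    labels <- vector("list", config$n_documents)
    mention_rows <- list()
    for (di in seq_len(config$n_documents)) {
      doc_id <- sprintf("d%04d", di)
      nsent <- rint(config$sentences_per_doc[1L], config$sentences_per_doc[2L])
      offset <- 0L
      sents <- vector("list", nsent)
      sent_labels <- vector("list", nsent)
      for (si in seq_len(nsent)) {
        ntok <- rint(config$tokens_per_sentence[1L],
                     config$tokens_per_sentence[2L])
        surf <- character(); lab <- character()
        while (length(surf) < ntok) {
          if (runif(1) < p_start && config$entity_rate > 0) {
            sub <- sample(names(config$subtype_weights), 1L,
                          prob = config$subtype_weights)
            toks <- synth_mention_tokens(sub, pools)
            surf <- c(surf, toks)
            lab <- c(lab, paste0("B-", sub),
                     rep(paste0("I-", sub), length(toks) - 1L))
          } else {
            surf <- c(surf, sample(pools$background, 1L))
            lab <- c(lab, "O")
          }
        }
        surf <- c(surf, "."); lab <- c(lab, "O")
        len <- nchar(surf)
        en <- offset + cumsum(len + 1L) - 1L
        st <- en - len
        offset <- en[length(en)] + 1L
        sents[[si]] <- chem_sentence(surf, st, en)
        sent_labels[[si]] <- lab
        # collect mentions from the label runs
        j <- 1L
        while (j <= length(lab)) {
          if (startsWith(lab[j], "B-")) {
            sub <- substr(lab[j], 3L, nchar(lab[j]))
            k <- j
            while (k < length(lab) && lab[k + 1L] == paste0("I-", sub))
              k <- k + 1L
            mention_rows[[length(mention_rows) + 1L]] <-
              data.frame(doc_id = doc_id, start = st[j], end = en[k],
                         text = paste(surf[j:k], collapse = " "),
                         subtype = sub, stringsAsFactors = FALSE)
            j <- k + 1L
          } else j <- j + 1L
        }
      }
      text <- reconstruct_text(sents)
      docs[[di]] <- chem_document(doc_id, text, sents)
      labels[[di]] <- sent_labels
    }
    mentions <- if (length(mention_rows)) sort_mentions(do.call(rbind, mention_rows))
    else empty_mentions()
    names(labels) <- vapply(docs, `[[`, "", "doc_id")
    list(documents = docs, mentions = mentions, labels = labels)
  })
}

#' Simulate a noisy stage-one annotator
#'
#' Corrupts a gold label stream independently, standing in for the output of
#' a trained stage-one NER tool. Corruption kinds: `label_flip` replaces each
#' token's label with a uniformly random *different* tagset label with
#' probability `rate`; `boundary_shift` moves each mention's start or end by
#' one token with probability `rate` (clipped at sentence bounds, skipped if
#' it would collide with a neighboring mention); `deletion` erases each
#' mention (labels to O) with probability `rate`; `spurious` converts, with
#' probability `rate` per maximal O-run, a random 1-2 token sub-run into a
#' mention of a random subtype. Outputs are always valid tagset symbols and
#' deterministic in `seed`.
#'
#' @param labels per-document list of per-sentence gold IOB label vectors.
#' @param rate corruption probability in [0, 1].
#' @param kind one of `"label_flip"`, `"boundary_shift"`, `"deletion"`,
#'   `"spurious"`.
#' @param seed integer seed.
#' @return a label stream of the same shape as `labels`.
#' @export
simulate_annotator <- function(labels, rate, kind = "label_flip", seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (!kind %in% c("label_flip", "boundary_shift", "deletion", "spurious"))
    stop("unknown corruption kind: ", kind, call. = FALSE)
  tagset <- chem_tagset()
  subs <- chem_subtypes()

  corrupt_sentence <- function(lab) {
    n <- length(lab)
    if (n == 0L) return(lab)
    if (kind == "label_flip") {
      hit <- runif(n) < rate
      if (any(hit)) {
        lab[hit] <- vapply(lab[hit], function(l)
          sample(setdiff(tagset, l), 1L), "")
      }
      return(lab)
    }
    # mention-level kinds operate on B-s (I-s)* runs
    runs <- label_runs(lab)
    if (kind %in% c("boundary_shift", "deletion")) {
      for (r in runs) {
        if (runif(1) >= rate) next
        if (kind == "deletion") {
          lab[r$first:r$last] <- "O"
        } else {
          lab <- shift_run(lab, r, runs)
        }
      }
      return(lab)
    }
    # spurious: per maximal O-run
    o_runs <- rle_runs(lab == "O")
    for (orun in o_runs) {
      if (!orun$value || runif(1) >= rate) next
      len <- min(rint(1L, 2L), orun$last - orun$first + 1L)
      st <- rint(orun$first, orun$last - len + 1L)
      sub <- sample(subs, 1L)
      lab[st:(st + len - 1L)] <- paste0("I-", sub)
      lab[st] <- paste0("B-", sub)
    }
    lab
  }
  with_seed(seed, lapply(labels, function(d) lapply(d, corrupt_sentence)))
}

# maximal B-s (I-s)* runs as list(first, last, subtype)
label_runs <- function(lab) {
  runs <- list()
  j <- 1L
  while (j <= length(lab)) {
    if (lab[j] != "O") {
      sub <- substr(lab[j], 3L, nchar(lab[j]))
      k <- j
      while (k < length(lab) && lab[k + 1L] == paste0("I-", sub)) k <- k + 1L
      runs[[length(runs) + 1L]] <- list(first = j, last = k, subtype = sub)
      j <- k + 1L
    } else j <- j + 1L
  }
  runs
}

rle_runs <- function(x) {
  r <- rle(x)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  lapply(seq_along(r$values),
         function(i) list(first = first[i], last = last[i], value = r$values[i]))
}

shift_run <- function(lab, r, runs) {
  n <- length(lab)
  sub <- r$subtype
  grow_start <- r$first > 1L && lab[r$first - 1L] == "O"
  shrink_start <- r$last > r$first
  grow_end <- r$last < n && lab[r$last + 1L] == "O"
  shrink_end <- r$last > r$first
  moves <- c(if (grow_start) "gs", if (shrink_start) "ss",
             if (grow_end) "ge", if (shrink_end) "se")
  if (!length(moves)) return(lab)
  mv <- if (length(moves) == 1L) moves else sample(moves, 1L)
  if (mv == "gs") {
    lab[r$first - 1L] <- paste0("B-", sub)
    lab[r$first] <- paste0("I-", sub)
  } else if (mv == "ss") {
    lab[r$first] <- "O"
    lab[r$first + 1L] <- paste0("B-", sub)
  } else if (mv == "ge") {
    lab[r$last + 1L] <- paste0("I-", sub)
  } else {
    lab[r$last] <- "O"
  }
  lab
}

#' Write a complete on-disk fixture bundle
#'
#' Generates a corpus, simulates the configured annotators, and writes every
#' external format the package reads: the TSV corpus with gold and annotator
#' label columns, the offset annotation table, and a JSON split manifest.
#' Fixtures are generated at call time, never stored.
#'
#' @param dir output directory (created if missing).
#' @param config a [synth_config()]; its `annotators` field drives the
#'   simulated annotator columns.
#' @return invisibly, a list with the in-memory `corpus`, `annotators`,
#'   `split`, and the written `paths`.
#' @export
make_fixture_suite <- function(dir, config = synth_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config)
  ann <- NULL
  if (length(config$annotators)) {
    streams <- lapply(seq_along(config$annotators), function(k) {
      a <- config$annotators[[k]]
      simulate_annotator(corpus$labels, a$rate, a$kind,
                         seed = config$seed + 1000L * k)
    })
    ann <- annotator_outputs(vapply(config$annotators, `[[`, "", "id"),
                             streams)
  }
  paths <- list(corpus = file.path(dir, "corpus.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                manifest = file.path(dir, "splits.json"))
  write_corpus_tsv(corpus$documents, paths$corpus, labels = corpus$labels,
                   annotators = ann)
  write_annotations(corpus$mentions, paths$annotations)
  split <- if (length(corpus$documents) >= 5L)
    split_corpus(corpus$documents, "two_series_60_20_20", seed = config$seed)
  else NULL
  ids <- vapply(corpus$documents, `[[`, "", "doc_id")
  manifest <- list(scheme = if (is.null(split)) NULL else attr(split, "scheme"),
                   seed = config$seed,
                   partitions = if (is.null(split)) NULL else
                     rapply(split, function(ix) ids[ix], how = "list"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(corpus = corpus, annotators = ann, split = split,
                 paths = paths))
}
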