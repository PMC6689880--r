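#' Bundle the label streams of K stage-one annotators
#'
#' All K streams must align to the same tokenization: for every document and
#' sentence, the labels form an `n_tokens x K` character matrix over the
#' 15-symbol tagset. Real tool outputs and simulated annotators
#' ([simulate_annotator()]) share this container and the TSV ingestion path
#' of [read_corpus_tsv()] (one trailing column per annotator).
#'
#' @param annotator_ids character vector of K annotator names (K >= 1).
#' @param labels per document, a list of per-sentence `n x K` character
#'   matrices (columns in `annotator_ids` order). A convenience form is also
#'   accepted: a list of K per-annotator streams (each a per-document list of
#'   per-sentence label vectors), which is transposed into the matrix form.
#' @return an object of class `"annotator_outputs"`.
#' @export
annotator_outputs <- function(annotator_ids, labels) {
  stopifnot(is.character(annotator_ids), length(annotator_ids) >= 1L)
  K <- length(annotator_ids)
  if (length(labels) && length(labels[[1L]]) && is.list(labels[[1L]][[1L]])) {
    # per-annotator streams: labels[[k]][[doc]][[sent]] -> matrix form
    if (length(labels) != K)
      stop("per-annotator stream form needs one stream per annotator",
           call. = FALSE)
    ndoc <- length(labels[[1L]])
    labels <- lapply(seq_len(ndoc), function(d) {
      nsent <- length(labels[[1L]][[d]])
      lapply(seq_len(nsent), function(s) {
        m <- do.call(cbind, lapply(seq_len(K), function(k) labels[[k]][[d]][[s]]))
        colnames(m) <- annotator_ids
        m
      })
    })
  }
  for (d in labels) for (m in d) {
    if (!is.matrix(m) || ncol(m) != K)
      stop("each sentence needs an n x ", K, " label matrix", call. = FALSE)
  }
  structure(list(annotator_ids = annotator_ids, labels = labels),
            class = "annotator_outputs")
}

#' @export
print.annotator_outputs <- function(x, ...) {
  cat(sprintf("<annotator_outputs: K=%d (%s), %d document(s)>\n",
              length(x$annotator_ids), paste(x$annotator_ids, collapse = ", "),
              length(x$labels)))
  invisible(x)
}

#' Encode stage-one annotator labels as concatenated one-hot features
#'
#' Each token's feature vector is the concatenation of K one-hot blocks of
#' width 15 (annotator-major layout): block k, position p is 1 iff annotator
#' k emitted `tagset_order[p]` for that token, so every block sums to exactly
#' 1 and the whole vector sums to K. This is the ensemble signal the voter's
#' feature-level attention learns to weight.
#'
#' @param outputs an [annotator_outputs()].
#' @param tagset_order the fixed label order defining one-hot positions;
#'   defaults to [chem_tagset()].
#' @return per document, a list of per-sentence numeric matrices of shape
#'   `n_tokens x (K * length(tagset_order))`.
#' @export
encode_stage_one <- function(outputs, tagset_order = chem_tagset()) {
  K <- length(outputs$annotator_ids)
  L <- length(tagset_order)
  lapply(seq_along(outputs$labels), function(d) {
    lapply(outputs$labels[[d]], function(m) {
      n <- nrow(m)
      out <- matrix(0, n, K * L)
      for (k in seq_len(K)) {
        idx <- match(m[, k], tagset_order)
        if (anyNA(idx)) {
          t_bad <- which(is.na(idx))[1L]
          stop("annotator '", outputs$annotator_ids[k], "', token ", t_bad,
               ": unknown label '", m[t_bad, k], "'", call. = FALSE)
        }
        out[cbind(seq_len(n), (k - 1L) * L + idx)] <- 1
      }
      out
    })
  })
}

#' Per-token majority vote over stage-one annotators
#'
#' For every token the label assigned by the most annotators wins. Ties are
#' broken in two documented steps: (1) any entity label beats `O`, so the
#' vote favors recall; (2) among remaining tied labels the earliest in the
#' fixed tagset order wins. Voting is per token on the full 15-symbol label
#' space; `collapse_iob = TRUE` optionally votes on the collapsed
#' `{O, B, I}` space and keeps the earliest-subtype expansion.
#'
#' @param outputs an [annotator_outputs()].
#' @param tagset_order fixed label order used for tie-breaking.
#' @param collapse_iob vote on IOB prefixes only (subtype chosen by tagset
#'   order among the winners' subtypes).
#' @return per document, a list of per-sentence label character vectors.
#' @export
majority_vote <- function(outputs, tagset_order = chem_tagset(),
                          collapse_iob = FALSE) {
  vote_one <- function(labs) {
    if (collapse_iob) {
      pref <- ifelse(labs == "O", "O", substr(labs, 1L, 1L))
      tab <- table(pref)
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) > 1L) winners <- setdiff(winners, "O")
      win <- sort(winners)[1L]  # B before I
      if (win == "O") return("O")
      cand <- labs[pref == win]
      return(cand[which.min(match(cand, tagset_order))])
    }
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L && "O" %in% winners)
      winners <- setdiff(winners, "O")
    winners[which.min(match(winners, tagset_order))]
  }
  lapply(outputs$labels, function(d)
    lapply(d, function(m) {
      if (nrow(m) == 0L) return(character())
      apply(m, 1L, vote_one)
    }))
}

# extract one annotator's stream as a per-document list of label vectors
annotator_stream <- function(outputs, k) {
  lapply(outputs$labels, function(d) lapply(d, function(m) m[, k]))
}
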