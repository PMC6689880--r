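#' Chemical mention subtypes and the IOB tagset
#'
#' The seven chemical mention subtypes used by the CHEMDNER/CEMP annotation
#' guidelines, and the 15-symbol IOB tagset they induce: `O` plus `B-`/`I-`
#' prefixed variants of each subtype. The tagset order is fixed (O first,
#' then subtypes alphabetically, B before I) and defines the one-hot layout
#' used everywhere downstream (stage-one feature blocks, CRF label indices,
#' emission score columns).
#'
#' @return `chem_subtypes()`: character vector of the 7 subtype names.
#'   `chem_tagset()`: character vector of the 15 IOB labels in canonical order.
#' @examples
#' chem_subtypes()
#' chem_tagset()
#' @export
chem_subtypes <- function() {
  c("ABBREVIATION", "FAMILY", "FORMULA", "IDENTIFIER",
    "MULTIPLE", "SYSTEMATIC", "TRIVIAL")
}

#' @rdname chem_subtypes
#' @export
chem_tagset <- function() {
  subs <- chem_subtypes()
  c("O", as.vector(rbind(paste0("B-", subs), paste0("I-", subs))))
}

# label -> 1-based index in the canonical tagset; errors on unknown labels
label_index <- function(labels, tagset = chem_tagset()) {
  idx <- match(labels, tagset)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

assert_labels <- function(labels, tagset = chem_tagset()) {
  invisible(label_index(labels, tagset))
}
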