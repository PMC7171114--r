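#' Assemble the pair feature matrix
#'
#' Joins protein descriptors and drug fingerprints on the labelled pairs: each
#' row is the concatenation of the target's descriptor (400 values for the
#' DCT encoder) and the drug's 881 fingerprint bits, giving the 1281-column
#' design matrix the classifier trains on.  Pairs whose drug or target lacks
#' a feature vector are dropped with a warning (the skipped pairs are
#' reported in the `skipped` attribute).
#'
#' @param pair_set a `labeled_pair_set` from [sample_balanced_pairs()], or any
#'   list with a `pairs` data.frame and `labels` vector.
#' @param protein_features named list of numeric vectors (or
#'   `protein_descriptor`s) keyed by target id.
#' @param drug_features named list of numeric vectors (or
#'   `fingerprint_vector`s) keyed by drug id.
#' @return a `dataset_matrix`: list with numeric matrix `x` (one row per kept
#'   pair), integer vector `y`, and data.frame `pairs` recording provenance;
#'   attribute `skipped` lists dropped pairs.
#' @export
assemble_feature_matrix <- function(pair_set, protein_features, drug_features) {
  as_values <- function(f) {
    if (inherits(f, "protein_descriptor")) f$values
    else if (inherits(f, "fingerprint_vector")) f$bits
    else as.numeric(f)
  }
  pf <- lapply(protein_features, as_values)
  df_ <- lapply(drug_features, as_values)
  p_len <- unique(lengths(pf))
  d_len <- unique(lengths(df_))
  if (length(p_len) != 1L) stop("protein feature vectors have inconsistent lengths")
  if (length(d_len) != 1L) stop("drug feature vectors have inconsistent lengths")
  pairs <- pair_set$pairs
  keep <- pairs$target_id %in% names(pf) & pairs$drug_id %in% names(df_)
  if (!all(keep)) {
    warning(sum(!keep), " pair(s) dropped: missing protein or drug features")
  }
  skipped <- pairs[!keep, , drop = FALSE]
  pairs <- pairs[keep, , drop = FALSE]
  labels <- pair_set$labels[keep]
  x <- matrix(0, nrow = nrow(pairs), ncol = p_len + d_len)
  for (i in seq_len(nrow(pairs))) {
    x[i, ] <- c(pf[[pairs$target_id[i]]], df_[[pairs$drug_id[i]]])
  }
  colnames(x) <- c(paste0("p", seq_len(p_len)), paste0("d", seq_len(d_len)))
  rownames(pairs) <- NULL
  structure(
    list(x = x, y = as.integer(labels), pairs = pairs),
    skipped = skipped,
    class = "dataset_matrix"
  )
}

#' @export
print.dataset_matrix <- function(x, ...) {
  cat(sprintf("Dataset: %d pairs x %d features (%d positive)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L)))
  invisible(x)
}
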