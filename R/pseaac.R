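#' Amino-acid property tables for pseudo amino acid composition
#'
#' Loads the packaged hydrophobicity (Tanford), hydrophilicity (Hopp-Woods)
#' and side-chain mass tables and standardizes each to zero mean and unit
#' variance over the 20 standard residues, the conventional preprocessing for
#' the sequence-correlation factors of pseudo amino acid composition.
#'
#' @param path optional path to a custom table: TSV with a `residue` column
#'   and one numeric column per property.
#' @return numeric matrix, 20 rows named by residue, one standardized column
#'   per property.
#' @export
load_aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "rotadti",
                        mustWork = TRUE)
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$residue
  # population standardization over the 20 residues
  scale_pop <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  apply(mat, 2, scale_pop)
}

#' Parameters for the pseudo amino acid composition encoder
#'
#' @param w weighting factor for the sequence-order terms (> 0 to include
#'   them; 0 reduces the descriptor to plain amino-acid composition).
#' @param q number of sequence-correlation tiers (lag depth); must be
#'   smaller than every sequence it is applied to.
#' @param properties standardized property matrix from
#'   [load_aa_properties()].
#' @return a `pseaac_params` list.
#' @export
pseaac_params <- function(w = 0.05, q = 10L, properties = load_aa_properties()) {
  stopifnot(w >= 0, q >= 0)
  structure(list(w = w, q = as.integer(q), properties = properties),
            class = "pseaac_params")
}

# split a sequence into residue indices of the property matrix, enforcing the
# residue policy: strict -> error on non-standard letters, drop -> remove them
sequence_indices <- function(sequence, properties,
                             unknown = c("error", "drop")) {
  unknown <- match.arg(unknown)
  res <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(res, rownames(properties))
  if (anyNA(idx)) {
    if (unknown == "error") {
      stop("non-standard residue(s): ",
           paste(unique(res[is.na(idx)]), collapse = ", "))
    }
    idx <- idx[!is.na(idx)]
  }
  idx
}

#' Tier-j sequence correlation factor
#'
#' The lag-`j` correlation factor of pseudo amino acid composition:
#' `theta_j = mean over i of Theta(R_i, R_{i+j})`, where `Theta` is the mean
#' squared difference of the standardized hydrophobicity, hydrophilicity and
#' side-chain mass of the two residues.  It is nonnegative, zero on
#' homopolymers, and invariant under sequence reversal.
#'
#' @param sequence amino-acid string of length L; `1 <= j < L`.
#' @param j correlation tier (lag).
#' @param properties standardized property matrix ([load_aa_properties()]).
#' @param unknown `"error"` rejects non-standard residues, `"drop"` removes
#'   them before computing.
#' @return theta_j, a nonnegative scalar.
#' @export
sequence_correlation_factor <- function(sequence, j,
                                        properties = load_aa_properties(),
                                        unknown = c("error", "drop")) {
  idx <- sequence_indices(sequence, properties, unknown)
  L <- length(idx)
  if (j < 1L || j >= L) stop(sprintf("tier j = %d out of range [1, %d]", j, L - 1L))
  p1 <- properties[idx[seq_len(L - j)], , drop = FALSE]
  p2 <- properties[idx[seq_len(L - j) + j], , drop = FALSE]
  mean(rowMeans((p1 - p2)^2))
}

#' Pseudo amino acid composition descriptor
#'
#' Encodes a protein sequence as the (20 + q)-vector of Chou's pseudo amino
#' acid composition: the first 20 components are the amino-acid frequencies
#' `F_u / (sum F_i + w * sum theta_j)` and the remaining q components are the
#' weighted sequence-order terms `w * theta_{u-20} / (same denominator)`.
#' The shared denominator makes all components nonnegative with total sum 1,
#' so the descriptor is a probability-like partition augmenting composition
#' with local order information that plain composition discards.
#'
#' @param sequence amino-acid string (length > `params$q`).
#' @param params a [pseaac_params()].
#' @param protein_id identifier for the returned descriptor.
#' @param unknown residue policy, see [sequence_correlation_factor()].
#' @return a [protein_descriptor()] with `method = "pseaac"` and
#'   `20 + params$q` values.
#' @export
pseaac_descriptor <- function(sequence, params = pseaac_params(),
                              protein_id = "protein",
                              unknown = c("error", "drop")) {
  stopifnot(inherits(params, "pseaac_params"))
  unknown <- match.arg(unknown)
  idx <- sequence_indices(sequence, params$properties, unknown)
  L <- length(idx)
  if (params$q >= L) {
    stop(sprintf("q = %d must be smaller than the sequence length %d",
                 params$q, L))
  }
  freqs <- tabulate(idx, nbins = 20L) / L
  theta <- if (params$q > 0L) {
    vapply(seq_len(params$q), function(j) {
      p1 <- params$properties[idx[seq_len(L - j)], , drop = FALSE]
      p2 <- params$properties[idx[seq_len(L - j) + j], , drop = FALSE]
      mean(rowMeans((p1 - p2)^2))
    }, numeric(1))
  } else numeric(0)
  denom <- sum(freqs) + params$w * sum(theta)
  protein_descriptor(protein_id, c(freqs, params$w * theta) / denom,
                     method = "pseaac")
}
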