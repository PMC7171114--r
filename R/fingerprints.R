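FINGERPRINT_BITS <- 881L

#' 881-bit substructure fingerprint for a drug
#'
#' The PubChem substructure fingerprint flags the presence (1) or absence (0)
#' of each of 881 predefined chemical substructure keys, giving a
#' fixed-length binary descriptor of the molecule that needs no 3-D
#' conformation.  Fingerprints are consumed precomputed; to plug in a
#' structure-based generator, pass any function mapping a structure string to
#' 881 bits where a fingerprint is expected.
#'
#' @param drug_id identifier string.
#' @param bits integer/numeric vector of exactly 881 zeros and ones.
#' @return an object of class `fingerprint_vector`.
#' @export
fingerprint_vector <- function(drug_id, bits) {
  bits <- as.integer(bits)
  if (length(bits) != FINGERPRINT_BITS) {
    stop(sprintf("fingerprint for drug '%s' has %d bits; expected %d",
                 drug_id, length(bits), FINGERPRINT_BITS))
  }
  if (!all(bits %in% c(0L, 1L))) {
    stop(sprintf("fingerprint for drug '%s' contains non-binary values", drug_id))
  }
  structure(list(drug_id = as.character(drug_id), bits = bits),
            class = "fingerprint_vector")
}

#' @export
print.fingerprint_vector <- function(x, ...) {
  cat(sprintf("<fingerprint> %s: %d/%d bits set\n", x$drug_id, sum(x$bits),
              length(x$bits)))
  invisible(x)
}

#' Read a table of drug fingerprints
#'
#' Accepts a TSV/CSV with a drug id column followed by either 881 individual
#' 0/1 bit columns or a single 881-character 0/1 string column.  Rows of the
#' wrong length or with non-binary values are rejected with the offending
#' drug id.
#'
#' @param path file path; the separator is taken from the extension
#'   (`.csv` means comma, anything else tab) unless `sep` is given.
#' @param sep optional field separator override.
#' @return named list of [fingerprint_vector()]s keyed by drug id.
#' @export
read_fingerprint_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    id <- df[i, 1]
    if (ncol(df) == 2L) {
      bits <- as.integer(strsplit(df[i, 2], "")[[1]])
    } else {
      bits <- suppressWarnings(as.integer(df[i, -1]))
    }
    if (anyNA(bits)) stop(sprintf("non-binary fingerprint value for drug '%s'", id))
    fingerprint_vector(id, bits)
  })
  names(out) <- as.character(df[[1]])
  out
}

#' Write a fingerprint table
#'
#' One row per drug: the id and the 881 bits as a single 0/1 string
#' (round-trips through [read_fingerprint_table()]).
#'
#' @param fingerprints list of [fingerprint_vector()]s.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(fingerprints, path) {
  df <- data.frame(
    drug_id = vapply(fingerprints, function(f) f$drug_id, character(1)),
    bits = vapply(fingerprints, function(f) paste(f$bits, collapse = ""), character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Decode a PubChem base64 fingerprint string
#'
#' PubChem distributes fingerprints as base64 text encoding a 4-byte
#' big-endian bit-length prefix followed by the bit-packed payload, most
#' significant bit first.  The declared length must be 881.
#'
#' @param encoded base64 string.
#' @param drug_id id to attach to the decoded fingerprint.
#' @return a [fingerprint_vector()].
#' @export
decode_pubchem_base64 <- function(encoded, drug_id = "drug") {
  raw <- tryCatch(jsonlite::base64_dec(encoded),
                  error = function(e) stop("invalid base64 fingerprint: ", conditionMessage(e)))
  if (length(raw) < 4L) stop("fingerprint payload too short for the length prefix")
  declared <- sum(as.integer(raw[1:4]) * 256^(3:0))
  if (declared != FINGERPRINT_BITS) {
    stop(sprintf("declared bit length %d; expected %d", declared, FINGERPRINT_BITS))
  }
  payload <- raw[-(1:4)]
  if (length(payload) < ceiling(FINGERPRINT_BITS / 8)) {
    stop("fingerprint payload shorter than the declared bit length")
  }
  # rawToBits is LSB-first within each byte; PubChem packs MSB-first
  bits_lsb <- as.integer(rawToBits(payload))
  msb <- as.vector(matrix(bits_lsb, nrow = 8)[8:1, ])
  fingerprint_vector(drug_id, msb[seq_len(FINGERPRINT_BITS)])
}

#' Encode a fingerprint as a PubChem base64 string
#'
#' Inverse of [decode_pubchem_base64()]: prepends the 4-byte big-endian bit
#' length (881), packs bits MSB-first and zero-pads the final byte.
#'
#' @param fingerprint a [fingerprint_vector()].
#' @return base64 string.
#' @export
encode_pubchem_base64 <- function(fingerprint) {
  stopifnot(inherits(fingerprint, "fingerprint_vector"))
  n_bytes <- ceiling(FINGERPRINT_BITS / 8)
  bits <- c(fingerprint$bits, rep(0L, n_bytes * 8L - FINGERPRINT_BITS))
  msb_first <- as.vector(matrix(bits, nrow = 8)[8:1, ])
  payload <- packBits(as.raw(msb_first), type = "raw")
  prefix <- as.raw(c(
    FINGERPRINT_BITS %/% 256^3 %% 256, FINGERPRINT_BITS %/% 256^2 %% 256,
    FINGERPRINT_BITS %/% 256 %% 256, FINGERPRINT_BITS %% 256
  ))
  jsonlite::base64_enc(c(prefix, payload))
}
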