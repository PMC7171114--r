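#' @keywords internal
"_PACKAGE"

# PSI-BLAST amino-acid column order, shared by PSSM scores and the
# physicochemical property tables.
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Position-specific scoring matrix for one protein
#'
#' A PSSM is the L x 20 matrix of log-odds substitution scores produced by
#' iterative profile search (PSI-BLAST, `-out_ascii_pssm`): row i scores the
#' substitution of residue i by each of the 20 standard amino acids, in the
#' fixed column order A R N D C Q E G H I L K M F P S T W Y V.  It carries
#' the evolutionary conservation signal that the DCT descriptor compresses.
#'
#' @param protein_id identifier string.
#' @param sequence amino-acid sequence of length L.
#' @param scores numeric L x 20 matrix of log-odds scores.
#' @return an object of class `pssm`.
#' @export
pssm <- function(protein_id, sequence, scores) {
  sequence <- toupper(as.character(sequence))
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop("PSSM must have exactly 20 score columns, got ", ncol(scores))
  }
  if (nrow(scores) != nchar(sequence)) {
    stop(sprintf(
      "PSSM has %d score rows but the sequence has %d residues",
      nrow(scores), nchar(sequence)
    ))
  }
  structure(
    list(protein_id = as.character(protein_id), sequence = sequence,
         scores = unname(scores)),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM for", x$protein_id, "-", nchar(x$sequence), "residues x 20 scores\n")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: three header lines, then one row per
#' residue holding the position, the residue letter, 20 log-odds columns and
#' 20 weighted-percentage columns (plus two trailing per-position statistics).
#' Only the first 20 numeric columns -- the log-odds scores -- are kept; the
#' sequence is reconstructed from the residue column.
#'
#' @param path path to the file, or `NULL` when `text` is given.
#' @param text character scalar (or vector of lines) holding file content.
#' @param protein_id identifier for the resulting [pssm()]; defaults to the
#'   file base name without extension, or `"pssm"` for text input.
#' @return a [pssm()].
#' @export
parse_ascii_pssm <- function(path = NULL, text = NULL, protein_id = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(path))
    }
  } else {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
    if (is.null(protein_id)) protein_id <- "pssm"
  }
  # the alphabet header is the first line whose fields are 40 single letters
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) == 40L && all(nchar(f) == 1L)) { header_at <- i; break }
  }
  if (is.na(header_at)) stop("not an ASCII PSSM: no 40-letter alphabet header found")
  residues <- character(0)
  scores <- list()
  n <- 0L
  for (i in seq(header_at + 1L, length(lines))) {
    line <- trimws(lines[[i]])
    if (line == "") break  # blank line ends the per-residue block
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) < 2L) stop("truncated PSSM row at line ", i)
    pos <- suppressWarnings(as.integer(f[[1]]))
    if (is.na(pos)) break  # footer statistics reached without blank line
    nums <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(nums)) {
      stop(sprintf("non-numeric score cell at line %d: '%s'",
                   i, f[-(1:2)][which(is.na(nums))[1]]))
    }
    # 40 score/percentage columns, optionally followed by the two
    # per-position information/weight statistics
    if (!length(nums) %in% c(40L, 42L)) {
      stop(sprintf("line %d has %d numeric columns; expected 40 or 42",
                   i, length(nums)))
    }
    n <- n + 1L
    if (pos != n) {
      stop(sprintf("line %d declares position %d; expected %d", i, pos, n))
    }
    residues[n] <- f[[2]]
    scores[[n]] <- nums[1:20]
  }
  if (n == 0L) stop("no residue rows found after the alphabet header")
  pssm(protein_id, paste(residues, collapse = ""),
       do.call(rbind, scores))
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Produces a file that [parse_ascii_pssm()] reads back to an identical
#' score matrix and sequence (the weighted-percentage block is filled with
#' zeros; only log-odds carry information).
#'
#' @param x a [pssm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  res <- strsplit(x$sequence, "")[[1]]
  header <- paste0(
    "\nLast position-specific scoring matrix computed, weighted, and scaled\n",
    "            ", paste(sprintf("%3s", c(PSSM_ALPHABET, PSSM_ALPHABET)), collapse = " ")
  )
  rows <- vapply(seq_along(res), function(i) {
    paste0(
      sprintf("%5d %s  ", i, res[i]),
      paste(sprintf("%3d", round(x$scores[i, ])), collapse = " "),
      " ",
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
      sprintf("  %4.2f %8.2f", 0, 0)
    )
  }, character(1))
  writeLines(c(header, rows, ""), path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Minimal FASTA reader for the pseudo amino acid composition baseline:
#' returns upper-cased sequences named by the first whitespace-delimited
#' token of each record header.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no FASTA records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(starts), function(i) {
    toupper(paste(lines[seq(starts[i] + 1L, ends[i])], collapse = ""))
  }, character(1))
  names(seqs) <- sub("^>", "", vapply(strsplit(lines[starts], "\\s+"), `[[`, character(1), 1))
  seqs
}
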