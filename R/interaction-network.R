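#' Bipartite drug-target interaction network
#'
#' An `interaction_network` holds the two node sets of a bipartite
#' drug-target graph and the set of experimentally verified (positive)
#' interaction pairs.  Every drug-target combination is a candidate pair;
#' candidates that are not positives are the negative pool used for
#' down-sampling.
#'
#' @param drug_ids character vector of drug identifiers (opaque strings).
#' @param target_ids character vector of target identifiers.
#' @param positives data.frame with character columns `drug_id` and
#'   `target_id`, one row per known interaction.
#'
#' @return An object of class `interaction_network` with elements
#'   `drug_ids`, `target_ids` and `positives` (a de-duplicated data.frame).
#' @examples
#' net <- interaction_network(
#'   drug_ids = c("d1", "d2"), target_ids = c("t1", "t2"),
#'   positives = data.frame(drug_id = "d1", target_id = "t2")
#' )
#' n_candidate_pairs(net)
#' @export
interaction_network <- function(drug_ids, target_ids, positives) {
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug ids: ", paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  }
  if (anyDuplicated(target_ids)) {
    stop("duplicate target ids: ", paste(unique(target_ids[duplicated(target_ids)]), collapse = ", "))
  }
  positives <- as.data.frame(positives)
  if (!all(c("drug_id", "target_id") %in% names(positives))) {
    stop("`positives` must have columns drug_id and target_id")
  }
  positives <- data.frame(
    drug_id = as.character(positives$drug_id),
    target_id = as.character(positives$target_id),
    stringsAsFactors = FALSE
  )
  positives <- unique(positives)
  bad_d <- setdiff(positives$drug_id, drug_ids)
  bad_t <- setdiff(positives$target_id, target_ids)
  if (length(bad_d) || length(bad_t)) {
    stop(
      "positive pairs reference unknown ids: ",
      paste(c(bad_d, bad_t), collapse = ", ")
    )
  }
  structure(
    list(drug_ids = drug_ids, target_ids = target_ids, positives = positives),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(
    "Drug-target interaction network:",
    length(x$drug_ids), "drugs x", length(x$target_ids), "targets,",
    nrow(x$positives), "known interactions",
    sprintf("(%d candidate pairs)\n", n_candidate_pairs(x))
  )
  invisible(x)
}

#' Number of candidate drug-target pairs
#'
#' @param network an [interaction_network()].
#' @return `length(drug_ids) * length(target_ids)`.
#' @export
n_candidate_pairs <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  length(network$drug_ids) * length(network$target_ids)
}

# canonical "drug\x1ftarget" key used for set operations on pairs
pair_key <- function(drug_id, target_id) paste(drug_id, target_id, sep = "\x1f")

#' Read an interaction network from disk
#'
#' Two dialects are supported.  `"adjacency"` is the gold-standard benchmark
#' layout: a tab-separated 0/1 matrix whose rows are targets and columns are
#' drugs, with target ids in the first column and drug ids in the header row
#' (use `transpose = TRUE` for files using the opposite convention).
#' `"edgelist"` is a two-column TSV (`drug_id`, `target_id`), one known
#' interaction per row; node sets are taken from the union of ids in order of
#' first appearance.
#'
#' @param path path to the file.
#' @param dialect `"adjacency"` or `"edgelist"`.
#' @param transpose adjacency only: set `TRUE` if rows are drugs and columns
#'   are targets.
#' @return an [interaction_network()].
#' @export
load_interaction_matrix <- function(path, dialect = c("adjacency", "edgelist"),
                                    transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "edgelist") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    if (ncol(df) < 2) stop("edge list must have two columns (drug_id, target_id)")
    names(df)[1:2] <- c("drug_id", "target_id")
    drugs <- unique(df$drug_id)
    targets <- unique(df$target_id)
    return(interaction_network(drugs, targets, df[, 1:2]))
  }
  lines <- readLines(path)
  if (length(lines) < 2) stop("adjacency file needs a header row and at least one data row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  col_ids <- header[-1]
  row_ids <- character(length(lines) - 1L)
  mat <- matrix(0L, nrow = length(lines) - 1L, ncol = length(col_ids))
  for (i in seq_along(lines)[-1]) {
    cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(col_ids) + 1L) {
      stop(sprintf("row %d has %d cells; expected %d", i, length(cells), length(col_ids) + 1L))
    }
    row_ids[i - 1L] <- cells[[1]]
    vals <- cells[-1]
    bad <- which(!vals %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf(
        "non-0/1 cell '%s' at row id '%s', column id '%s'",
        vals[bad[1]], cells[[1]], col_ids[bad[1]]
      ))
    }
    mat[i - 1L, ] <- as.integer(vals)
  }
  if (transpose) {
    drugs <- row_ids; targets <- col_ids; mat <- t(mat)
  } else {
    drugs <- col_ids; targets <- row_ids
  }
  # mat is now targets x drugs
  hits <- which(mat == 1L, arr.ind = TRUE)
  positives <- data.frame(
    drug_id = drugs[hits[, "col"]],
    target_id = targets[hits[, "row"]],
    stringsAsFactors = FALSE
  )
  interaction_network(drugs, targets, positives)
}

#' Write an interaction network to disk
#'
#' Inverse of [load_interaction_matrix()]; a write followed by a read
#' reproduces the network exactly (id order included).
#'
#' @inheritParams load_interaction_matrix
#' @param network an [interaction_network()].
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(network, path,
                                     dialect = c("adjacency", "edgelist")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(network, "interaction_network"))
  if (dialect == "edgelist") {
    utils::write.table(network$positives, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  mat <- matrix(0L, nrow = length(network$target_ids),
                ncol = length(network$drug_ids),
                dimnames = list(network$target_ids, network$drug_ids))
  mat[cbind(match(network$positives$target_id, network$target_ids),
            match(network$positives$drug_id, network$drug_ids))] <- 1L
  lines <- c(
    paste(c("", network$drug_ids), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(network$target_ids[i], mat[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' All negative (non-interacting) candidate pairs
#'
#' Enumerates every drug-target combination absent from the positive set.
#'
#' @param network an [interaction_network()].
#' @return data.frame with columns `drug_id`, `target_id`;
#'   `n_candidate_pairs(network) - nrow(positives)` rows.
#' @export
enumerate_negatives <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  all_pairs <- expand.grid(
    drug_id = network$drug_ids, target_id = network$target_ids,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  pos_keys <- pair_key(network$positives$drug_id, network$positives$target_id)
  neg <- all_pairs[!pair_key(all_pairs$drug_id, all_pairs$target_id) %in% pos_keys, ]
  rownames(neg) <- NULL
  neg
}

#' Balanced positive/negative pair sampling
#'
#' Keeps every positive pair (label 1) and draws exactly as many negatives
#' (label 0), uniformly without replacement from the full negative pool, so
#' the resulting labelled set is balanced 1:1.  The known interactions are
#' hugely outnumbered by non-interacting candidates (about 97% of the pair
#' space on the GPCR benchmark), so training uses this down-sampled set.
#'
#' @param network an [interaction_network()].
#' @param seed integer seed controlling the negative draw; the same seed
#'   always yields the same pair set.
#' @return A `labeled_pair_set`: list with data.frame `pairs`
#'   (`drug_id`, `target_id`), integer `labels` (1 = interaction) and
#'   `sampling_seed`.
#' @export
sample_balanced_pairs <- function(network, seed) {
  stopifnot(inherits(network, "interaction_network"))
  seed <- as.integer(seed)
  negatives <- enumerate_negatives(network)
  n_pos <- nrow(network$positives)
  if (nrow(negatives) < n_pos) {
    stop(sprintf(
      "cannot draw %d negatives: only %d non-interacting pairs available",
      n_pos, nrow(negatives)
    ))
  }
  idx <- with_seed(seed, sample.int(nrow(negatives), n_pos))
  sampled_neg <- negatives[idx, , drop = FALSE]
  pairs <- rbind(network$positives, sampled_neg)
  rownames(pairs) <- NULL
  # a sampled negative must never coincide with a positive
  stopifnot(!any(
    pair_key(sampled_neg$drug_id, sampled_neg$target_id) %in%
      pair_key(network$positives$drug_id, network$positives$target_id)
  ))
  structure(
    list(
      pairs = pairs,
      labels = rep(c(1L, 0L), c(n_pos, n_pos)),
      sampling_seed = seed
    ),
    class = "labeled_pair_set"
  )
}

#' @export
print.labeled_pair_set <- function(x, ...) {
  cat(
    "Labeled pair set:", length(x$labels), "pairs,",
    sum(x$labels == 1L), "positive /", sum(x$labels == 0L),
    "negative (seed", paste0(x$sampling_seed, ")\n")
  )
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All stochastic operations take explicit
# seeds and route through here; nothing depends on hidden global state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
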