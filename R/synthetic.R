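#' Configuration for the synthetic DTI generator
#'
#' Describes a synthetic drug-target study: network dimensions, how many
#' pairs interact, protein lengths, and how strongly the planted latent
#' signal determines which pairs those are.  The four presets reproduce the
#' dimensions of the gold-standard benchmark networks (enzymes 445 drugs x
#' 664 targets / 2926 interactions; ion channels 210 x 204 / 1476; GPCRs
#' 223 x 95 / 635; nuclear receptors 54 x 26 / 90).
#'
#' @param n_drugs,n_targets,n_positives network dimensions;
#'   `n_positives <= n_drugs * n_targets`.
#' @param seq_len_range integer (min, max) protein length, sampled uniformly.
#' @param signal_strength nonnegative scaling of the latent pair affinity
#'   against unit observation noise; 0 plants no signal (labels are pure
#'   chance), larger values make interactions increasingly determined by the
#'   latent embeddings that also tilt the generated features.
#' @param seed integer master seed; all generator randomness derives from it.
#' @param preset optional name: `"enzyme"`, `"ion_channel"`, `"gpcr"`,
#'   `"nuclear_receptor"`; overrides the three dimension arguments.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 50L, n_targets = 30L, n_positives = 100L,
                             seq_len_range = c(150L, 500L),
                             signal_strength = 1, seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    presets <- list(
      enzyme = c(445L, 664L, 2926L),
      ion_channel = c(210L, 204L, 1476L),
      gpcr = c(223L, 95L, 635L),
      nuclear_receptor = c(54L, 26L, 90L)
    )
    preset <- match.arg(preset, names(presets))
    dims <- presets[[preset]]
    n_drugs <- dims[1]; n_targets <- dims[2]; n_positives <- dims[3]
  }
  n_drugs <- as.integer(n_drugs); n_targets <- as.integer(n_targets)
  n_positives <- as.integer(n_positives)
  if (n_positives > n_drugs * n_targets) {
    stop(sprintf("n_positives = %d exceeds the %d candidate pairs",
                 n_positives, n_drugs * n_targets))
  }
  stopifnot(signal_strength >= 0, length(seq_len_range) == 2L,
            seq_len_range[1] >= 1L, seq_len_range[1] <= seq_len_range[2])
  structure(
    list(n_drugs = n_drugs, n_targets = n_targets, n_positives = n_positives,
         seq_len_range = as.integer(seq_len_range),
         signal_strength = signal_strength, seed = as.integer(seed),
         preset = preset),
    class = "synthetic_config"
  )
}

# generator calibration constants (fixed; see the methods vignette)
SYN_EMBED_DIM <- 8L        # latent embedding dimension
SYN_EMBED_MEAN <- 1        # nonzero mean -> degree heterogeneity (hub nodes)
SYN_PSSM_COLS <- 10L       # PSSM columns carrying the target embedding
SYN_PSSM_TILT <- 2         # score offset scale on those columns
SYN_FP_BITS <- 120L        # fingerprint bits carrying the drug embedding
SYN_FP_TILT <- 2.5         # logit tilt scale on those bits
SYN_FP_BASE <- 0.1         # baseline bit density

#' Generate a complete synthetic DTI study
#'
#' Draws latent 8-dimensional embeddings for every drug and target (entries
#' normal with unit mean, so node degrees are heterogeneous as in real
#' interaction networks) and scores every candidate pair as
#' `signal_strength * <u_drug, v_target> / sqrt(8) + noise`; the
#' `n_positives` highest-scoring pairs become the known interactions, so the
#' positive count is exact.  Features carry the same embeddings: each
#' pseudo-PSSM adds an embedding projection to a fixed subset of its score
#' columns (visible to the low-frequency DCT block), and each fingerprint
#' tilts the on-probability of a fixed subset of bits.  With
#' `signal_strength = 0` the labels are independent of the features.
#'
#' All randomness flows from `config$seed` through fixed substreams
#' (embeddings/network, sequences, fingerprints), so output is fully
#' deterministic.
#'
#' @param config a [synthetic_config()].
#' @return list with `network` ([interaction_network()]), `pssms` (named list
#'   of [pssm()] by target id), `fingerprints` (named list of
#'   [fingerprint_vector()] by drug id), and `embeddings` (list of matrices
#'   `drug`, `target`).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 3L))
  drug_ids <- sprintf("D%04d", seq_len(config$n_drugs))
  target_ids <- sprintf("T%04d", seq_len(config$n_targets))

  # substream 1: embeddings, pair scores, network
  net <- with_seed(seeds[1], {
    u <- matrix(stats::rnorm(config$n_drugs * SYN_EMBED_DIM, SYN_EMBED_MEAN),
                config$n_drugs, SYN_EMBED_DIM, dimnames = list(drug_ids, NULL))
    v <- matrix(stats::rnorm(config$n_targets * SYN_EMBED_DIM, SYN_EMBED_MEAN),
                config$n_targets, SYN_EMBED_DIM, dimnames = list(target_ids, NULL))
    affinity <- (u %*% t(v)) / sqrt(SYN_EMBED_DIM)   # drugs x targets
    score <- config$signal_strength * affinity +
      stats::rnorm(length(affinity))
    top <- order(score, decreasing = TRUE)[seq_len(config$n_positives)]
    positives <- data.frame(
      drug_id = drug_ids[(top - 1L) %% config$n_drugs + 1L],
      target_id = target_ids[(top - 1L) %/% config$n_drugs + 1L],
      stringsAsFactors = FALSE
    )
    list(network = interaction_network(drug_ids, target_ids, positives),
         u = u, v = v)
  })

  # substream 2: pseudo-PSSMs; the column projection W is shared by all
  # targets so the tilt lands in comparable descriptor coordinates
  pssms <- with_seed(seeds[2], {
    w_proj <- matrix(stats::rnorm(SYN_PSSM_COLS * SYN_EMBED_DIM,
                                  sd = 1 / sqrt(SYN_EMBED_DIM)),
                     SYN_PSSM_COLS, SYN_EMBED_DIM)
    tilt_cols <- sample.int(20L, SYN_PSSM_COLS)
    lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]),
                   config$n_targets, replace = TRUE)
    out <- lapply(seq_len(config$n_targets), function(t) {
      L <- lens[t]
      scores <- matrix(round(stats::rnorm(L * 20L, mean = -1, sd = 3)), L, 20L)
      offset <- round(SYN_PSSM_TILT * as.numeric(w_proj %*% net$v[t, ]))
      scores[, tilt_cols] <- sweep(scores[, tilt_cols, drop = FALSE], 2L,
                                   offset, `+`)
      scores <- pmin(pmax(scores, -10L), 12L)
      seq <- paste(sample(PSSM_ALPHABET, L, replace = TRUE), collapse = "")
      pssm(target_ids[t], seq, scores)
    })
    names(out) <- target_ids
    out
  })

  # substream 3: fingerprints; the bit projection M is shared by all drugs
  fingerprints <- with_seed(seeds[3], {
    m_proj <- matrix(stats::rnorm(SYN_FP_BITS * SYN_EMBED_DIM,
                                  sd = 1 / sqrt(SYN_EMBED_DIM)),
                     SYN_FP_BITS, SYN_EMBED_DIM)
    tilt_bits <- sample.int(881L, SYN_FP_BITS)
    base_logit <- stats::qlogis(SYN_FP_BASE)
    out <- lapply(seq_len(config$n_drugs), function(d) {
      p <- rep(SYN_FP_BASE, 881L)
      p[tilt_bits] <- stats::plogis(
        base_logit + SYN_FP_TILT * as.numeric(m_proj %*% net$u[d, ])
      )
      fingerprint_vector(drug_ids[d], stats::rbinom(881L, 1L, p))
    })
    names(out) <- drug_ids
    out
  })

  list(network = net$network, pssms = pssms, fingerprints = fingerprints,
       embeddings = list(drug = net$u, target = net$v))
}

#' Write a synthetic study as a fixture bundle
#'
#' Materializes a generated study in the same on-disk formats the readers of
#' the real-data interfaces consume: `network.tsv` (adjacency dialect),
#' `pssm/<target_id>.pssm` (PSI-BLAST ASCII dialect) and `fingerprints.tsv`.
#' Reading the bundle back reproduces the in-memory objects; two bundles
#' written from the same config are byte-identical.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return named character vector of the paths written (`network`,
#'   `fingerprints`, and one entry per PSSM), invisibly.
#' @export
write_fixture_bundle <- function(config, dir) {
  synth <- generate_synthetic(config)
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  paths <- c(network = file.path(dir, "network.tsv"),
             fingerprints = file.path(dir, "fingerprints.tsv"))
  write_interaction_matrix(synth$network, paths[["network"]], "adjacency")
  write_fingerprint_table(synth$fingerprints, paths[["fingerprints"]])
  pssm_paths <- vapply(synth$pssms, function(p) {
    path <- file.path(dir, "pssm", paste0(p$protein_id, ".pssm"))
    write_ascii_pssm(p, path)
    path
  }, character(1))
  invisible(c(paths, pssm_paths))
}

#' Balanced, featurized dataset from network + features
#'
#' Convenience wrapper chaining [sample_balanced_pairs()] and
#' [assemble_feature_matrix()]: draws the balanced pair set from the network
#' and joins it with the given feature vectors.
#'
#' @param network an [interaction_network()].
#' @param protein_features,drug_features named feature lists as accepted by
#'   [assemble_feature_matrix()].
#' @param seed seed for the negative down-sampling.
#' @return a `dataset_matrix`.
#' @export
dti_dataset <- function(network, protein_features, drug_features, seed) {
  assemble_feature_matrix(sample_balanced_pairs(network, seed),
                          protein_features, drug_features)
}
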