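# Shared fixtures, built in code at test time.

# a tiny network: 3 drugs x 2 targets, 3 known interactions
tiny_network <- function() {
  interaction_network(
    drug_ids = c("d1", "d2", "d3"), target_ids = c("t1", "t2"),
    positives = data.frame(
      drug_id = c("d1", "d2", "d3"),
      target_id = c("t1", "t2", "t1")
    )
  )
}

# GPCR-shaped network: 223 drugs x 95 targets with 635 positives laid out
# deterministically (first 635 candidate pairs column-major)
gpcr_shaped_network <- function() {
  drugs <- sprintf("D%03d", 1:223)
  targets <- sprintf("T%02d", 1:95)
  idx <- seq_len(635)
  interaction_network(
    drugs, targets,
    data.frame(drug_id = drugs[(idx - 1) %% 223 + 1],
               target_id = targets[(idx - 1) %/% 223 + 1])
  )
}

# ASCII PSSM text for sequence MKTAY with scores row i = (i, i+1, ..., i+19)
toy_pssm_text <- function() {
  res <- c("M", "K", "T", "A", "Y")
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  c(
    "",
    "Last position-specific scoring matrix computed, weighted, and scaled",
    paste0("            ", paste(sprintf("%3s", c(alphabet, alphabet)), collapse = " ")),
    vapply(1:5, function(i) {
      paste0(sprintf("%5d %s  ", i, res[i]),
             paste(sprintf("%3d", i:(i + 19)), collapse = " "), " ",
             paste(sprintf("%3d", rep(0, 20)), collapse = " "),
             "  0.30     1.00")
    }, character(1)),
    ""
  )
}

# brute-force orthonormal 2-D DCT: direct double-loop evaluation of the
# transform definition, independent of the implementation under test
dct2_bruteforce <- function(f) {
  m <- nrow(f); n <- ncol(f)
  out <- matrix(0, m, n)
  for (i in 0:(m - 1)) {
    for (j in 0:(n - 1)) {
      di <- if (i == 0) sqrt(1 / m) else sqrt(2 / m)
      dj <- if (j == 0) sqrt(1 / n) else sqrt(2 / n)
      acc <- 0
      for (x in 0:(m - 1)) {
        for (y in 0:(n - 1)) {
          acc <- acc + f[x + 1, y + 1] *
            cos(pi * (2 * x + 1) * i / (2 * m)) *
            cos(pi * (2 * y + 1) * j / (2 * n))
        }
      }
      out[i + 1, j + 1] <- di * dj * acc
    }
  }
  out
}

# exhaustive pairwise-concordance AUC: concordant positive/negative score
# pairs count 1, ties 1/2
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# small linearly separable two-class dataset in 2-D
separable_blobs <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per_class, -3, 0.5), rnorm(n_per_class, -3, 0.5)),
    cbind(rnorm(n_per_class, 3, 0.5), rnorm(n_per_class, 3, 0.5))
  )
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# small synthetic study featurized end to end (DCT + fingerprints)
small_synthetic_dataset <- function(signal_strength, seed,
                                    n_drugs = 20, n_targets = 15,
                                    n_positives = 40) {
  cfg <- synthetic_config(n_drugs, n_targets, n_positives,
                          seq_len_range = c(40, 90),
                          signal_strength = signal_strength, seed = seed)
  synth <- generate_synthetic(cfg)
  prot <- lapply(synth$pssms, extract_dct_descriptor)
  dti_dataset(synth$network, prot, synth$fingerprints, seed = seed)
}
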