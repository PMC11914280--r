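# Shared fixtures, all built in code.

# Ten-gene DE marker table with known filter outcome: exactly 4 genes pass
# adjusted_p < 0.05 AND |log2FC| > 0.6.
toyDeTable <- function() {
  data.frame(
    gene = paste0("G", 1:10),
    cluster = rep(c("IL4I1", "HES1"), each = 5),
    p_value = c(0.001, 0.002, 0.2, 0.01, 0.04,
                0.0005, 0.03, 0.5, 0.008, 0.06),
    adjusted_p = c(0.01, 0.02, 0.6, 0.04, 0.20,
                   0.005, 0.20, 0.9, 0.03, 0.30),
    log2_fold_change = c(0.7, -1.2, 2.0, 0.5, 0.9,
                         1.5, 0.8, -0.1, -0.9, 0.65),
    stringsAsFactors = FALSE
  )
  # passing both rules: G1, G2, G6, G9
}

# Reference profiles covering clusters and genes of toyDeTable().
toyReference <- function(genes = paste0("G", 1:10),
                         clusters = c("IL4I1", "HES1")) {
  m <- matrix(seq_len(length(genes) * length(clusters)),
              nrow = length(genes),
              dimnames = list(genes, clusters))
  m * 1.0
}

# Small blood-draw table spanning all four periods for one patient.
toyDraws <- function() {
  data.frame(
    patient_id = "P1",
    day = c(-3L, 5L, 10L, 15L, 30L, 50L),
    neutrophils = c(4, 5, 6, 5, 4, 3),
    lymphocytes = c(1.0, 0.5, 1.0, 2.0, 0.8, 0.6),
    monocytes = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.3),
    stringsAsFactors = FALSE
  )
}

# Deterministic fractions for k cell types, rows summing to 1.
toyFractions <- function(n, sig, seed = 42) {
  set.seed(seed)
  k <- ncol(sig)
  f <- matrix(rgamma(n * k, shape = 1), nrow = n)
  f <- f / rowSums(f)
  dimnames(f) <- list(paste0("S", seq_len(n)), colnames(sig))
  f
}

# Separated-MonoLR configuration used for threshold-recovery experiments:
# monocyte medians 0.75 vs 0.25 over a common lymphocyte median of 1.0
# gives group MonoLR medians separated threefold, analogous to the
# high-risk threshold (~0.75) versus healthy (~0.25) reference values.
separatedConfig <- function(seed) {
  gm <- matrix(c(1.0, 0.75, 5.7,
                 1.0, 0.25, 3.5), nrow = 2, byrow = TRUE,
               dimnames = list(c("Progressive", "StableElite"),
                               c("lymphocytes", "monocytes", "neutrophils")))
  cohortConfig(seed = seed, groupBloodMedians = gm, noiseDispersion = 0.25,
               withExpression = FALSE)
}
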