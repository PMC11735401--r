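# shared in-code fixtures for the suite

toy_oriented <- function(p = c(0.5, 0.1), beta = c(0.1, 0.2),
                         ids = sprintf("L%02d", seq_along(p))) {
  out <- data.frame(locus_id = ids, p_undesirable = p, beta = beta,
                    rank_score = p * beta, stringsAsFactors = FALSE)
  class(out) <- c("oriented_loci", "data.frame")
  out
}

write_locus_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal well-formed summary-statistic rows
toy_records <- function() {
  data.frame(
    locus_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.6, 0.15),
    beta_raw = c(0.12, -0.08, 0.2),
    se = c(0.01, 0.012, 0.02),
    n_samples = c(50000L, 50000L, 50000L),
    stringsAsFactors = FALSE
  )
}

# explicit-genotype Monte-Carlo oracle for the liability threshold model:
# simulates HWE genotypes at each locus, residual normal holding var(l) = 1
# in the unedited population, and returns prevalence among unedited and
# among genomes forced to the protective homozygote at every locus.
# Note: the closed form 1 - pnorm(t + delta) keeps the conditional liability
# s.d. at 1, whereas the exact conditional s.d. is sqrt(1 - var_g); the two
# agree to within MC error only when var_g (the variance explained by the
# edited loci) is small, which is the regime the model targets.
mc_liability_oracle <- function(K, p, beta, n_sim = 2e6, seed = 1) {
  set.seed(seed)
  t <- qnorm(1 - K)
  m <- length(p)
  g <- matrix(rbinom(n_sim * m, 2, rep(p, each = n_sim)), ncol = m)
  gval <- sweep(g, 2, 2 * p, "-") %*% beta
  var_g <- sum(2 * p * (1 - p) * beta^2)
  e <- rnorm(n_sim, sd = sqrt(1 - var_g))
  gval_edited <- sum((0 - 2 * p) * beta)  # all loci homozygous protective
  list(
    K_hat = mean(gval + e > t),
    K_g_hat = mean(gval_edited + e > t),
    mc_se = sqrt(K * (1 - K) / n_sim)
  )
}

# brute-force pairwise Gini oracle, O(n^2)
gini_pairwise <- function(x) {
  mean(abs(outer(x, x, "-"))) / (2 * mean(x))
}
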