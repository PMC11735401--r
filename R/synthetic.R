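#' Configuration for the synthetic GWAS generator
#'
#' Parameters of the synthetic locus tables used to exercise the full
#' pipeline without external data. True allele frequencies come from
#' \code{freq_dist}; true per-allele effects are drawn with standard
#' deviation \code{effect_sd * (2p(1-p))^(alpha/2)}, so
#' \code{coupling_alpha = 0} decouples effect size from frequency while
#' \code{coupling_alpha = -1} equalises expected per-locus variance
#' contributions, mimicking the negative selection seen in real GWAS where
#' large-effect variants sit at lower frequencies. Estimates are then
#' perturbed by sampling noise consistent with a standardized-trait GWAS of
#' \code{n_gwas} samples, and filtered at the genome-wide significance
#' threshold.
#'
#' @param m_loci Number of true causal loci (>= 1).
#' @param freq_dist Frequency distribution: \code{list("uniform", lo, hi)}
#'   or \code{list("beta", a, b)} (frequencies resampled into (0.01, 0.99)).
#' @param effect_sd Baseline s.d. of true effects on the model scale (> 0).
#' @param coupling_alpha Frequency-effect coupling exponent (default 0).
#' @param n_gwas GWAS sample size used for the sampling noise.
#' @param gws_threshold Genome-wide significance p-value cutoff (default
#'   5e-8).
#' @param seed Integer seed.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(m_loci = 200L,
                             freq_dist = list("uniform", 0.01, 0.99),
                             effect_sd = 0.02,
                             coupling_alpha = 0,
                             n_gwas = 1e5L,
                             gws_threshold = 5e-8,
                             seed = 1L) {
  stopifnot(m_loci >= 1, effect_sd > 0,
            gws_threshold > 0, gws_threshold < 1, n_gwas >= 2)
  kind <- freq_dist[[1]]
  if (!kind %in% c("uniform", "beta")) {
    stop("freq_dist must be uniform or beta")
  }
  if (kind == "uniform") {
    lo <- freq_dist[[2]]; hi <- freq_dist[[3]]
    if (!(0 < lo && lo < hi && hi < 1)) {
      stop("degenerate uniform frequency bounds")
    }
  } else if (freq_dist[[2]] <= 0 || freq_dist[[3]] <= 0) {
    stop("beta frequency parameters must be positive")
  }
  structure(list(m_loci = as.integer(m_loci), freq_dist = freq_dist,
                 effect_sd = effect_sd, coupling_alpha = coupling_alpha,
                 n_gwas = n_gwas,
                 gws_threshold = gws_threshold, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate true oriented causal loci
#'
#' Draws the ground-truth locus set of a synthetic trait: frequencies from
#' the configured distribution and non-negative effects of the undesirable
#' allele on the model scale (liability s.d. for diseases, phenotypic s.d.
#' for quantitative traits). Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @param trait A [trait_config()] (names the trait; effects are generated
#'   on the model scale for either kind).
#' @return An \code{oriented_loci} data frame with the true loci.
#' @export
simulate_true_loci <- function(config, trait) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(trait, "trait_config"))
  set.seed(config$seed)
  fd <- config$freq_dist
  p <- if (fd[[1]] == "uniform") {
    stats::runif(config$m_loci, fd[[2]], fd[[3]])
  } else {
    q <- stats::rbeta(config$m_loci, fd[[2]], fd[[3]])
    pmin(pmax(q, 0.01), 0.99)
  }
  sd_i <- config$effect_sd * (2 * p * (1 - p))^(config$coupling_alpha / 2)
  beta <- abs(stats::rnorm(config$m_loci, sd = sd_i))
  out <- data.frame(
    locus_id = sprintf("L%04d", seq_len(config$m_loci)),
    p_undesirable = p,
    beta = beta,
    rank_score = p * beta,
    stringsAsFactors = FALSE
  )
  class(out) <- c("oriented_loci", "data.frame")
  attr(out, "trait") <- trait
  out
}

#' Simulate noisy GWAS estimates of true loci
#'
#' Adds sampling noise to the true effects, with per-locus standard error
#' \eqn{1/\sqrt{2 p (1-p) n_{gwas}}} on the model scale (the exact value for
#' a standardized continuous trait), computes two-sided p-values, flags
#' genome-wide-significant loci, and randomly reports each locus for either
#' allele so downstream orientation is exercised. For binary traits the
#' model-scale estimates and standard errors are expressed as log odds
#' ratios by inverting the liability conversion, so that round-tripping
#' through [orient_loci()] recovers the liability scale.
#'
#' Significance selection induces the winner's curse: among selected loci
#' with modest power, estimated effects exceed true effects on average.
#'
#' @param true_loci Output of [simulate_true_loci()].
#' @param config A [synthetic_config()].
#' @param trait A [trait_config()]; defaults to the one attached to
#'   \code{true_loci}.
#' @param seed Optional seed for the noise draw (defaults to
#'   \code{config$seed + 1} so truth and noise are independent streams).
#' @return A \code{locus_table} data frame with canonical summary-statistic
#'   columns plus logical \code{gws}.
#' @export
simulate_gwas_estimates <- function(true_loci, config,
                                    trait = attr(true_loci, "trait"),
                                    seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(trait, "trait_config"))
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  m <- nrow(true_loci)
  p <- true_loci$p_undesirable
  se_model <- 1 / sqrt(2 * p * (1 - p) * config$n_gwas)
  beta_hat <- true_loci$beta + stats::rnorm(m, sd = se_model)
  pval <- 2 * stats::pnorm(-abs(beta_hat) / se_model)
  # express on the reported scale
  if (trait$kind == "binary") {
    mult <- logor_to_liability(1, trait$prevalence_K)
    beta_rep <- beta_hat / mult
    se_rep <- se_model / mult
  } else {
    beta_rep <- beta_hat
    se_rep <- se_model
  }
  # report a random allele of each locus
  flip <- stats::runif(m) < 0.5
  out <- data.frame(
    locus_id = true_loci$locus_id,
    chrom = NA_character_,
    pos = NA_integer_,
    effect_allele = ifelse(flip, "G", "A"),
    other_allele = ifelse(flip, "A", "G"),
    eaf = ifelse(flip, 1 - p, p),
    beta_raw = ifelse(flip, -beta_rep, beta_rep),
    se = se_rep,
    n_samples = config$n_gwas,
    p_value = pval,
    trait_name = trait$name,
    gws = pval < config$gws_threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("locus_table", "data.frame")
  attr(out, "trait") <- trait
  out
}

#' Write a synthetic locus-table fixture for a preset trait
#'
#' Generates a schema-complete, genome-wide-significant synthetic summary
#' statistic table for one of the ten preset traits and writes it as a TSV
#' whose header comment marks it SYNTHETIC, preventing accidental
#' scientific use. The trait configuration is returned alongside the path.
#'
#' @param name One of the preset trait names (see [trait_presets()]).
#' @param dir Output directory (default \code{tempdir()}).
#' @param config A [synthetic_config()]; the seed is offset per trait so
#'   each trait gets its own reproducible table.
#' @return A list with elements \code{trait} (a \code{trait_config}) and
#'   \code{path} (the TSV file).
#' @export
make_disease_fixture <- function(name, dir = tempdir(),
                                 config = synthetic_config()) {
  trait <- trait_presets(name)  # errors on unknown names
  config$seed <- config$seed + match(name, names(trait_presets())) * 1000L
  truth <- simulate_true_loci(config, trait)
  est <- simulate_gwas_estimates(truth, config, trait)
  est <- est[est$gws, setdiff(names(est), "gws"), drop = FALSE]
  path <- file.path(dir, paste0("synthetic_", tolower(name), "_loci.tsv"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(paste0("# SYNTHETIC data generated by polyedit::make_disease_fixture;",
                    " not real GWAS results"), con)
  utils::write.table(est, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  list(trait = trait, path = path)
}
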