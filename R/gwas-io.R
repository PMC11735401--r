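#' Read a GWAS genome-wide-significant locus table
#'
#' Reads a tab-separated summary-statistic table (UTF-8, one header row,
#' \code{#} comment lines ignored) into a validated locus data frame. Source
#' GWAS use heterogeneous headers, so a column mapping from canonical names
#' to file names may be supplied (e.g.
#' \code{c(eaf = "EAF", beta_raw = "BETA")}).
#'
#' Canonical columns: \code{locus_id}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta_raw}, and \code{se}; optional:
#' \code{chrom}, \code{pos}, \code{n_samples}, \code{p_value}. For binary
#' traits \code{beta_raw} is a log odds ratio and \code{se}/\code{n_samples}
#' may be absent; for quantitative traits \code{se} and \code{n_samples} are
#' required so the phenotypic standard deviation can be estimated.
#'
#' @param path Path to a TSV file.
#' @param trait A [trait_config()].
#' @param col_map Named character vector mapping canonical names to the
#'   file's column names.
#' @return A data frame of class \code{locus_table} with canonical columns
#'   and the trait name attached as attribute \code{"trait"}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("locus_id\teffect_allele\tother_allele\teaf\tbeta_raw\tse",
#'              "rs1\tA\tG\t0.3\t0.12\t0.01"), tf)
#' read_locus_table(tf, trait_presets("AD"))
#' @export
read_locus_table <- function(path, trait, col_map = NULL) {
  stopifnot(inherits(trait, "trait_config"))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  required <- c("locus_id", "effect_allele", "other_allele", "eaf", "beta_raw")
  if (trait$kind == "quantitative") required <- c(required, "se", "n_samples")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("chrom", "pos", "se", "n_samples", "p_value")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  df$trait_name <- trait$name
  validate_locus_table(df)
  df <- df[c("locus_id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta_raw", "se", "n_samples", "p_value", "trait_name")]
  class(df) <- c("locus_table", "data.frame")
  attr(df, "trait") <- trait
  df
}

validate_locus_table <- function(df) {
  bad_beta <- which(!is.finite(df$beta_raw))
  if (length(bad_beta)) {
    stop("non-finite beta_raw for locus ",
         paste(df$locus_id[bad_beta], collapse = ", "),
         " (row ", paste(bad_beta, collapse = ", "), ")")
  }
  bad_eaf <- which(!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1)
  if (length(bad_eaf)) {
    stop("eaf outside (0, 1) for locus ",
         paste(df$locus_id[bad_eaf], collapse = ", "),
         " (row ", paste(bad_eaf, collapse = ", "), ")")
  }
  bad_se <- which(!is.na(df$se) & df$se <= 0)
  if (length(bad_se)) {
    stop("non-positive se for locus ",
         paste(df$locus_id[bad_se], collapse = ", "),
         " (row ", paste(bad_se, collapse = ", "), ")")
  }
  same <- which(df$effect_allele == df$other_allele)
  if (length(same)) {
    stop("effect_allele equals other_allele for locus ",
         paste(df$locus_id[same], collapse = ", "),
         " (row ", paste(same, collapse = ", "), ")")
  }
  invisible(df)
}

#' Convert a log odds ratio to the liability scale
#'
#' Disease effect sizes reported as log odds ratios are converted to
#' liability standard deviations with the linear approximation
#' \eqn{\beta = \beta_{\log OR} \, K(1-K)/z}, where \eqn{z = \phi(t)} is the
#' standard normal density at the liability threshold
#' \eqn{t = \Phi^{-1}(1-K)}.
#'
#' @param beta_logor Effect size(s) in log odds ratio units (vectorised).
#' @param K Lifetime prevalence in (0, 1).
#' @return Effect size(s) in liability s.d. units.
#' @examples
#' logor_to_liability(1, 0.05) # ~ 0.4606
#' @export
logor_to_liability <- function(beta_logor, K) {
  th <- threshold_from_prevalence(K)
  beta_logor * K * (1 - K) / th$z
}

#' Estimate the phenotypic standard deviation from summary statistics
#'
#' Not all GWAS report standardized trait values. The phenotypic variance is
#' recovered from reported per-locus sampling variances as the mean of
#' \eqn{2 p_i (1 - p_i) N_i \,\mathrm{s.e.}_i^2} across loci, which equals 1
#' for a standardized trait.
#'
#' @param records A \code{locus_table} (or data frame) with columns
#'   \code{eaf}, \code{n_samples} and \code{se}.
#' @return The estimated phenotypic standard deviation (positive scalar).
#' @export
estimate_phenotypic_sd <- function(records) {
  need <- c("eaf", "n_samples", "se")
  stopifnot(all(need %in% names(records)))
  bad <- which(is.na(records$se) | is.na(records$n_samples))
  if (length(bad)) {
    stop("missing se or n_samples for locus ",
         paste(records$locus_id[bad], collapse = ", "))
  }
  p <- records$eaf
  sqrt(mean(2 * p * (1 - p) * records$n_samples * records$se^2))
}

#' Orient loci to the undesirable allele and standardize effects
#'
#' Re-expresses each locus in terms of its undesirable allele: the allele
#' that increases disease liability or moves the biomarker in the harmful
#' direction. If the reported effect is negative the allele labels are
#' flipped (frequency \code{1 - eaf}, effect negated), so the returned effect
#' is always non-negative. Disease log odds ratios are converted to the
#' liability scale ([logor_to_liability()]); quantitative effects are
#' expressed in phenotypic standard deviations, dividing by
#' \code{phenotypic_sd} (estimated from the table via
#' [estimate_phenotypic_sd()] when not supplied).
#'
#' A zero effect produces a warning but the locus is retained with
#' \code{beta = 0}.
#'
#' @param records A \code{locus_table} from [read_locus_table()].
#' @param trait A [trait_config()].
#' @param phenotypic_sd Optional phenotypic s.d. override (quantitative
#'   traits only).
#' @return A data frame of class \code{oriented_loci} with columns
#'   \code{locus_id}, \code{p_undesirable}, \code{beta} (liability or
#'   phenotypic s.d.) and \code{rank_score = p_undesirable * beta}.
#' @export
orient_loci <- function(records, trait, phenotypic_sd = NULL) {
  stopifnot(inherits(trait, "trait_config"))
  if (trait$kind == "binary") {
    beta_model <- logor_to_liability(records$beta_raw, trait$prevalence_K)
  } else {
    if (is.null(phenotypic_sd)) {
      phenotypic_sd <- trait$phenotypic_sd
      if (is.null(phenotypic_sd) || is.na(phenotypic_sd)) {
        phenotypic_sd <- estimate_phenotypic_sd(records)
      }
    }
    beta_model <- records$beta_raw / phenotypic_sd
  }
  if (any(beta_model == 0)) {
    warning("zero effect size for locus ",
            paste(records$locus_id[beta_model == 0], collapse = ", "),
            "; retained with beta = 0")
  }
  flip <- beta_model < 0
  out <- data.frame(
    locus_id = records$locus_id,
    p_undesirable = ifelse(flip, 1 - records$eaf, records$eaf),
    beta = abs(beta_model),
    stringsAsFactors = FALSE
  )
  out$rank_score <- out$p_undesirable * out$beta
  class(out) <- c("oriented_loci", "data.frame")
  attr(out, "trait") <- trait
  if (trait$kind == "quantitative") attr(out, "phenotypic_sd") <- phenotypic_sd
  out
}

#' Rank loci for editing
#'
#' Orders loci by the product of effect size and undesirable-allele
#' frequency, \code{rank_score = p_undesirable * beta}, which is half the
#' per-locus gain \eqn{2 p_i \beta_i} realised by editing a population-mean
#' genome to homozygous protective — so the ranking maximises the predicted
#' change per edit. Ties are broken lexicographically on \code{locus_id} for
#' determinism.
#'
#' @param loci An \code{oriented_loci} data frame.
#' @param max_m Maximum number of loci to retain (default 10).
#' @return The top \code{max_m} loci in decreasing \code{rank_score} order.
#' @export
rank_loci <- function(loci, max_m = 10L) {
  stopifnot(max_m >= 1)
  if (nrow(loci) == 0L) {
    warning("empty locus list")
    return(loci)
  }
  ord <- order(-loci$rank_score, loci$locus_id)
  out <- loci[ord, , drop = FALSE][seq_len(min(max_m, nrow(loci))), ,
                                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write oriented loci to a TSV file
#'
#' @param loci An \code{oriented_loci} data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_oriented_loci <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
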