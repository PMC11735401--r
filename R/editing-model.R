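#' Define an editing plan
#'
#' Bundles a trait, its ranked loci, the maximum number of loci to edit, and
#' the genetic correlation \code{rg} between current and future environments.
#' \code{rg < 1} models gene-by-environment interaction (or, equivalently,
#' epistatic background effects): the realised liability shift is shrunk by a
#' factor of \code{rg}.
#'
#' @param trait A [trait_config()].
#' @param loci An \code{oriented_loci} data frame; ranked with [rank_loci()]
#'   if not already ordered by decreasing \code{rank_score}.
#' @param max_m Maximum number of loci to edit (default 10).
#' @param rg Genetic correlation with the future environment, in [0, 1]
#'   (default 1 = no attenuation).
#' @return An object of class \code{edit_plan}.
#' @export
edit_plan <- function(trait, loci, max_m = 10L, rg = 1) {
  stopifnot(inherits(trait, "trait_config"),
            is.numeric(rg), length(rg) == 1L, rg >= 0, rg <= 1,
            max_m >= 1)
  if (is.unsorted(rev(loci$rank_score))) loci <- rank_loci(loci, max_m)
  structure(list(trait = trait,
                 loci = loci[seq_len(min(max_m, nrow(loci))), , drop = FALSE],
                 max_m = as.integer(max_m), rg = rg),
            class = "edit_plan")
}

#' @export
print.edit_plan <- function(x, ...) {
  cat(sprintf("<edit_plan> %s: %d ranked loci, rg = %g\n",
              x$trait$name, nrow(x$loci), x$rg))
  invisible(x)
}

#' Mean trait shift from editing the top loci
#'
#' Expected difference in phenotypic (or liability) mean between edited and
#' unedited genomes when the first \code{m} ranked loci are set homozygous.
#' Editing to the protective homozygote removes \eqn{2 p_i \beta_i} per
#' locus (direction \code{"decrease"}); editing to the undesirable
#' homozygote adds \eqn{2 (1 - p_i) \beta_i} (direction \code{"increase"}).
#'
#' @param loci Ranked \code{oriented_loci}.
#' @param m Number of loci edited.
#' @param direction \code{"decrease"} (default) or \code{"increase"}.
#' @return Signed shift in the loci's effect units (negative for
#'   \code{"decrease"}).
#' @examples
#' loci <- data.frame(locus_id = c("a", "b"),
#'                    p_undesirable = c(0.5, 0.1), beta = c(0.1, 0.2))
#' trait_shift(loci, 2) # -0.14
#' @export
trait_shift <- function(loci, m, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (m > nrow(loci)) {
    stop("m = ", m, " exceeds the ", nrow(loci), " available loci")
  }
  idx <- seq_len(m)
  p <- loci$p_undesirable[idx]
  b <- loci$beta[idx]
  if (direction == "decrease") -sum(2 * p * b) else sum(2 * (1 - p) * b)
}

#' Standard deviation of the per-genome editing gain
#'
#' Between-genome spread of the gain from editing the first \code{m} loci:
#' the square root of the variance explained by those loci in the general
#' population, \eqn{\sqrt{\sum 2 p_i (1 - p_i) \beta_i^2}}. Individual
#' genomes carry more or fewer undesirable alleles than average, so not
#' everyone benefits equally; this quantifies that spread.
#'
#' @inheritParams trait_shift
#' @return Non-negative scalar in the loci's effect units.
#' @export
sd_of_gain <- function(loci, m) {
  if (m > nrow(loci)) {
    stop("m = ", m, " exceeds the ", nrow(loci), " available loci")
  }
  idx <- seq_len(m)
  p <- loci$p_undesirable[idx]
  sqrt(sum(2 * p * (1 - p) * loci$beta[idx]^2))
}

curve_skeleton <- function(plan) {
  m_max <- min(plan$max_m, nrow(plan$loci))
  p <- plan$loci$p_undesirable[seq_len(m_max)]
  b <- plan$loci$beta[seq_len(m_max)]
  list(m = seq_len(m_max),
       delta = cumsum(2 * p * b),
       sd_gain = sqrt(cumsum(2 * p * (1 - p) * b^2)))
}

#' Disease prediction curve
#'
#' For each number of edited loci \code{m = 1..max_m}, the cumulative
#' liability reduction \eqn{\delta_m = \sum_{i \le m} 2 p_i \beta_i}, the
#' predicted prevalence among edited genomes
#' \eqn{K_g = 1 - \Phi(t + r_g \delta_m)}, the fold change in lifetime
#' prevalence \eqn{K / K_g}, and a one-standard-deviation band obtained by
#' shifting \eqn{r_g \delta_m} by \eqn{\pm} [sd_of_gain()] before the probit
#' transformation (so \code{band_low <= K_g <= band_high} on the prevalence
#' scale).
#'
#' @param plan An [edit_plan()] for a binary trait with effects on the
#'   liability scale.
#' @return A data frame of class \code{prediction_curve} with columns
#'   \code{trait}, \code{m}, \code{delta}, \code{sd_gain}, \code{K_g},
#'   \code{fold_change}, \code{band_low}, \code{band_high}, \code{rg}.
#' @export
disease_curve <- function(plan) {
  stopifnot(inherits(plan, "edit_plan"))
  if (plan$trait$kind != "binary") {
    stop("disease_curve requires a binary trait; see quantitative_curve()")
  }
  K <- plan$trait$prevalence_K
  sk <- curve_skeleton(plan)
  shift <- plan$rg * sk$delta
  out <- data.frame(
    trait = plan$trait$name,
    m = sk$m,
    delta = sk$delta,
    sd_gain = sk$sd_gain,
    K_g = prevalence_from_shift(K, shift),
    fold_change = NA_real_,
    band_low = prevalence_from_shift(K, shift + sk$sd_gain),
    band_high = prevalence_from_shift(K, shift - sk$sd_gain),
    rg = plan$rg,
    stringsAsFactors = FALSE
  )
  out$fold_change <- K / out$K_g
  class(out) <- c("prediction_curve", "data.frame")
  attr(out, "trait") <- plan$trait
  out
}

#' Quantitative-trait prediction curve
#'
#' For each number of edited loci, the predicted phenotypic shift among
#' edited genomes, \eqn{-r_g \sum_{i \le m} 2 p_i \beta_i} phenotypic
#' standard deviations (risk-decreasing direction), with a
#' one-standard-deviation band \code{delta +/- sd_gain}. When the trait
#' carries a phenotypic s.d. in physical units a \code{delta_units} column
#' is added.
#'
#' @param plan An [edit_plan()] for a quantitative trait with effects in
#'   phenotypic s.d.
#' @return A data frame of class \code{prediction_curve} with columns
#'   \code{trait}, \code{m}, \code{delta}, \code{sd_gain}, \code{band_low},
#'   \code{band_high}, \code{rg} (and \code{delta_units} when available);
#'   \code{delta} is the signed shift (negative = reduction).
#' @export
quantitative_curve <- function(plan) {
  stopifnot(inherits(plan, "edit_plan"))
  if (plan$trait$kind != "quantitative") {
    stop("quantitative_curve requires a quantitative trait; see disease_curve()")
  }
  sk <- curve_skeleton(plan)
  delta <- -plan$rg * sk$delta
  out <- data.frame(
    trait = plan$trait$name,
    m = sk$m,
    delta = delta,
    sd_gain = sk$sd_gain,
    band_low = delta - sk$sd_gain,
    band_high = delta + sk$sd_gain,
    rg = plan$rg,
    stringsAsFactors = FALSE
  )
  sd_units <- plan$trait$phenotypic_sd %||% attr(plan$loci, "phenotypic_sd")
  if (!is.null(sd_units) && !is.na(sd_units)) {
    out$delta_units <- out$delta * sd_units
  }
  class(out) <- c("prediction_curve", "data.frame")
  attr(out, "trait") <- plan$trait
  out
}

#' Population-level mean shift
#'
#' Editing changes the population mean only in proportion to the fraction of
#' genomes edited: a 5 s.d. reduction in 1\% of genomes shifts the
#' population mean by 0.05 s.d.
#'
#' @param delta_edited Mean shift among edited genomes.
#' @param fraction_edited Fraction of the population with edited genomes, in
#'   [0, 1].
#' @return \code{fraction_edited * delta_edited}.
#' @examples
#' population_mean_shift(-5, 0.01) # -0.05
#' @export
population_mean_shift <- function(delta_edited, fraction_edited) {
  stopifnot(fraction_edited >= 0, fraction_edited <= 1)
  fraction_edited * delta_edited
}

#' Probability of carrying the protective genotype at every locus
#'
#' Under Hardy-Weinberg and linkage equilibrium, the chance that a random
#' unedited genome already carries the protective genotype class at all the
#' listed loci: homozygous protective, \eqn{\prod_i (1 - p_i)^2}, or at
#' least one protective copy, \eqn{\prod_i (1 - p_i^2)}. Small values show
#' that the genotype produced by editing may be essentially absent from
#' today's population (of order one per billions for ten loci).
#'
#' @param loci \code{oriented_loci} (nonempty).
#' @param mode \code{"hom_protective"} or \code{"at_least_one_copy"}.
#' @return Probability in (0, 1).
#' @export
protective_genotype_probability <- function(loci,
                                            mode = c("hom_protective",
                                                     "at_least_one_copy")) {
  mode <- match.arg(mode)
  stopifnot(nrow(loci) >= 1)
  p <- loci$p_undesirable
  if (mode == "hom_protective") prod((1 - p)^2) else prod(1 - p^2)
}
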