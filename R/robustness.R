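#' Prediction curve with misidentified causal variants
#'
#' If some of the loci chosen for editing are not in fact causal, editing
#' them changes nothing: their effects are set to zero while they keep their
#' slot in the ranking (the edit list was drawn up believing them causal, so
#' the ranking is not recomputed). For quantitative traits with equal
#' per-locus contributions the final outcome shrinks proportionally to the
#' fraction misidentified; for diseases the fold-change reduction can be far
#' larger when top-ranked loci are nulled, because of the nonlinear
#' liability-to-prevalence map.
#'
#' @param plan An [edit_plan()].
#' @param null_indices Integer rank positions (1-based within the ranked
#'   list) whose true effect is zero.
#' @return A \code{prediction_curve} (disease or quantitative per the
#'   plan's trait kind).
#' @export
apply_misidentification <- function(plan, null_indices = integer(0)) {
  stopifnot(inherits(plan, "edit_plan"))
  m_avail <- nrow(plan$loci)
  null_indices <- as.integer(null_indices)
  if (length(null_indices) &&
      (any(null_indices < 1L) || any(null_indices > m_avail))) {
    stop("null_indices must lie in 1..", m_avail)
  }
  plan$loci$beta[null_indices] <- 0
  plan$loci$rank_score[null_indices] <- 0
  if (plan$trait$kind == "binary") disease_curve(plan) else
    quantitative_curve(plan)
}

#' Prediction curve under effect-size shrinkage
#'
#' Winner's curse, population stratification or indirect effects inflate
#' published effect sizes; the realised outcome of editing then shrinks in
#' proportion. All effects are multiplied by \code{factor} before the curve
#' is computed, so a 10\% overestimate (\code{factor = 0.9}) gives exactly a
#' 10\% smaller quantitative shift.
#'
#' @param plan An [edit_plan()].
#' @param factor Multiplicative shrinkage in (0, 1].
#' @return A \code{prediction_curve}.
#' @export
shrink_effects <- function(plan, factor) {
  stopifnot(inherits(plan, "edit_plan"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 ||
      factor > 1) {
    stop("factor must be in (0, 1]")
  }
  plan$loci$beta <- plan$loci$beta * factor
  plan$loci$rank_score <- plan$loci$rank_score * factor
  if (plan$trait$kind == "binary") disease_curve(plan) else
    quantitative_curve(plan)
}

#' Expected relative fitness under off-target mutational load
#'
#' Each intended edit carries probability \code{q} of introducing an
#' off-target mutation; mutations act multiplicatively on fitness with
#' selection coefficient \code{s} each. With the off-target count
#' \eqn{X \sim \mathrm{Poisson}(\lambda)}, \eqn{\lambda = \mathrm{edits}
#' \times q}, the expected relative fitness is
#' \eqn{E[(1-s)^X] = e^{-\lambda s}} (exact for the Poisson model). It
#' equals 1 when \code{q = 0} or \code{s = 0} and decreases in each of
#' \code{q}, \code{s} and \code{edits}.
#'
#' @param q Per-edit off-target probability, in [0, 1].
#' @param s Selection coefficient per off-target mutation, in [0, 1].
#' @param edits Number of intended edits (non-negative).
#' @param lambda_mode Off-target count model; only \code{"poisson"} is
#'   implemented (the slot exists so alternative count models can be added).
#' @return Expected relative fitness in (0, 1].
#' @examples
#' offtarget_fitness(q = 0.2, s = 0.01, edits = 10) # ~ 0.980
#' @export
offtarget_fitness <- function(q, s, edits, lambda_mode = "poisson") {
  stopifnot(q >= 0, q <= 1, edits >= 0)
  if (s < 0 || s > 1) stop("s must be in [0, 1]")
  lambda_mode <- match.arg(lambda_mode)
  exp(-edits * q * s)
}

#' Relative fitness under stabilizing selection
#'
#' Many quantitative traits sit at an intermediate optimum maintained by
#' stabilizing selection; moving the phenotype \code{delta_z} standard
#' deviations away reduces fitness along the standard Gaussian profile
#' \eqn{\exp(-(\Delta z - \mathrm{optimum})^2 / (2 V_s))}. The width
#' \code{Vs} is in squared phenotypic standard deviations; the conventional
#' default 20 corresponds to moderately strong stabilizing selection.
#'
#' @param delta_z Phenotypic change in phenotypic s.d. (vectorised).
#' @param Vs Width of the fitness profile (> 0), default 20.
#' @param optimum Optimal phenotype (default 0, the current mean).
#' @return Relative fitness in (0, 1].
#' @examples
#' stabilizing_fitness(5, Vs = 20) # ~ 0.535
#' @export
stabilizing_fitness <- function(delta_z, Vs = 20, optimum = 0) {
  stopifnot(Vs > 0)
  exp(-(delta_z - optimum)^2 / (2 * Vs))
}
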