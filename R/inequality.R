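#' Simulate individual disease risks in a mixed edited/unedited population
#'
#' Draws a population of latent liabilities and converts them to individual
#' risk values, with a fraction of genomes edited so that the edited risk
#' distribution is consistent with an edited-genome prevalence
#' \code{K_prime}. Three risk definitions are available:
#'
#' \describe{
#'   \item{\code{"percentile"} (default)}{The risk of individual \eqn{i} is
#'     its liability percentile,
#'     \eqn{R_i = 1 - \Phi(\ell_i + \mu_E E_i)}, with \eqn{\ell_i} standard
#'     normal, \eqn{E_i} the edited indicator, and
#'     \eqn{\mu_E = \Phi^{-1}(1 - K') - \Phi^{-1}(1 - K) \ge 0} the liability
#'     reduction achieved by editing. Unedited risks are Uniform(0, 1) in
#'     distribution; edited risks are stochastically lower.}
#'   \item{\code{"guarantee"}}{Unedited genomes bear the full liability
#'     lottery (percentile risks as above); edited genomes carry the fixed
#'     lifetime risk \code{K_prime} determined by their shared edited
#'     genotype. This is the two-component mixture used by [gini_curve()] by
#'     default; see that help page for why.}
#'   \item{\code{"heritability"}}{Risk is the probability of disease
#'     conditional on genetic value,
#'     \eqn{R_i = 1 - \Phi((t - g_i + \mu_E E_i)/\sigma_e)} with
#'     \eqn{g_i \sim N(0, h^2)}, \eqn{\sigma_e = \sqrt{1 - h^2}} and
#'     \eqn{t = \Phi^{-1}(1-K)}.}
#' }
#'
#' The first \code{floor(fraction_edited * n)} individuals are edited;
#' membership is exchangeable so no randomisation is needed.
#'
#' @param K Prevalence among unedited genomes, in (0, 1).
#' @param K_prime Prevalence among edited genomes, in (0, K].
#' @param fraction_edited Fraction of edited genomes, in [0, 1].
#' @param n Population size (default 1e6).
#' @param seed Optional integer seed for reproducibility.
#' @param form Risk definition, one of \code{"percentile"},
#'   \code{"guarantee"}, \code{"heritability"}.
#' @param h2 Liability heritability, used by the \code{"heritability"} form.
#' @return Numeric vector of \code{n} individual risks in (0, 1).
#' @export
individual_risks <- function(K, K_prime, fraction_edited, n = 1e6L,
                             seed = NULL,
                             form = c("percentile", "guarantee",
                                      "heritability"),
                             h2 = 0.5) {
  form <- match.arg(form)
  check_mixture(K, K_prime, fraction_edited)
  if (!is.null(seed)) set.seed(seed)
  mu_E <- stats::qnorm(1 - K_prime) - stats::qnorm(1 - K)
  edited <- seq_len(n) <= floor(fraction_edited * n)
  switch(form,
    percentile = {
      ell <- stats::rnorm(n)
      stats::pnorm(ell + mu_E * edited, lower.tail = FALSE)
    },
    guarantee = {
      r <- stats::pnorm(stats::rnorm(n), lower.tail = FALSE)
      r[edited] <- K_prime
      r
    },
    heritability = {
      stopifnot(h2 > 0, h2 < 1)
      t <- stats::qnorm(1 - K)
      g <- stats::rnorm(n, sd = sqrt(h2))
      stats::pnorm((t - g + mu_E * edited) / sqrt(1 - h2),
                   lower.tail = FALSE)
    })
}

check_mixture <- function(K, K_prime, fraction_edited) {
  stopifnot(K > 0, K < 1, K_prime > 0)
  if (K_prime > K) {
    stop("K_prime must not exceed K (risk-increasing mixtures not supported)")
  }
  stopifnot(fraction_edited >= 0, fraction_edited <= 1)
  invisible(TRUE)
}

#' Gini index
#'
#' Mean absolute pairwise difference divided by twice the mean, computed by
#' the sorted \eqn{O(n \log n)} identity
#' \eqn{G = \sum_i (2i - n - 1) x_{(i)} / (n^2 \bar{x})}. The population
#' (uncorrected) form is used. Scale-invariant; 0 for constant input; for a
#' Uniform(0, 1) sample it converges to 1/3.
#'
#' @param values Non-negative numeric vector with a positive mean.
#' @return Gini index in [0, 1).
#' @examples
#' gini_index(rep(1, 10))   # 0
#' gini_index(c(0, 1))      # 0.5
#' @export
gini_index <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            all(is.finite(values)), all(values >= 0))
  total <- sum(values)
  if (total == 0) stop("Gini index undefined for all-zero input")
  n <- length(values)
  x <- sort(values)
  sum((2 * seq_len(n) - n - 1) * x) / (n * total)
}

#' Gini-index curve over the fraction of edited genomes
#'
#' Simulates one population of \code{n} liabilities and, for each fraction
#' on the grid, computes the Gini index of individual risks in the mixture
#' of edited (prevalence \code{K_prime}) and unedited (prevalence \code{K})
#' genomes, normalised by the Gini index at fraction 0. A common liability
#' draw is used across fractions, so the curve varies only through the
#' mixture composition.
#'
#' The default \code{"guarantee"} form contrasts the genetic lottery borne
#' by unedited genomes (liability-percentile risks, Uniform(0, 1), baseline
#' Gini 1/3) with the fixed risk \code{K_prime} conferred by the shared
#' edited genotype. Under this mixture, inequality rises as soon as a small
#' fraction is edited, attains its maximum at an interior fraction
#' (\code{argmax_fraction}), and falls below the all-unedited baseline only
#' past the \code{crossing_fraction}, which exceeds 50\% whenever
#' \code{K_prime} is well below the unedited mean risk. The alternative
#' forms (see [individual_risks()]) keep the liability lottery for edited
#' genomes too; they produce monotone curves that never drop below baseline
#' and are provided for sensitivity analysis.
#'
#' @inheritParams individual_risks
#' @param fractions Grid of edited fractions in [0, 1] (default 0 to 1 in
#'   steps of 0.01).
#' @param fold Optional prevalence-reduction factor; supply instead of
#'   \code{K_prime} to use \code{K_prime = K / fold} (e.g. 10, 100, 1000).
#' @param seed Integer seed (default 1).
#' @return A data frame of class \code{gini_curve} with columns
#'   \code{fraction}, \code{gini}, \code{relative_gini}, and attributes
#'   \code{argmax_fraction} (fraction with maximal Gini) and
#'   \code{crossing_fraction} (smallest positive fraction with relative Gini
#'   below 1, \code{NA} if never).
#' @examples
#' gc <- gini_curve(0.15, 0.09, n = 1e4, seed = 1)
#' attr(gc, "crossing_fraction")
#' @export
gini_curve <- function(K, K_prime = NULL, fractions = seq(0, 1, by = 0.01),
                       n = 1e6L, seed = 1L, fold = NULL,
                       form = c("guarantee", "percentile", "heritability"),
                       h2 = 0.5) {
  form <- match.arg(form)
  if (is.null(K_prime)) {
    if (is.null(fold)) stop("supply K_prime or fold")
    K_prime <- K / fold
  }
  check_mixture(K, K_prime, 0)
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  set.seed(seed)
  mu_E <- stats::qnorm(1 - K_prime) - stats::qnorm(1 - K)
  if (form == "heritability") {
    stopifnot(h2 > 0, h2 < 1)
    t <- stats::qnorm(1 - K)
    g <- stats::rnorm(n, sd = sqrt(h2))
    risk_un <- stats::pnorm((t - g) / sqrt(1 - h2), lower.tail = FALSE)
    risk_ed <- stats::pnorm((t - g + mu_E) / sqrt(1 - h2),
                            lower.tail = FALSE)
  } else {
    ell <- stats::rnorm(n)
    risk_un <- stats::pnorm(ell, lower.tail = FALSE)
    risk_ed <- if (form == "guarantee") rep(K_prime, n) else
      stats::pnorm(ell + mu_E, lower.tail = FALSE)
  }
  gini <- vapply(fractions, function(f) {
    k <- floor(f * n)
    v <- risk_un
    if (k > 0) v[seq_len(k)] <- risk_ed[seq_len(k)]
    gini_index(v)
  }, numeric(1))
  baseline <- if (any(fractions == 0)) gini[match(0, fractions)] else
    gini_index(risk_un)
  out <- data.frame(fraction = fractions, gini = gini,
                    relative_gini = gini / baseline)
  below <- out$fraction > 0 & out$relative_gini < 1
  class(out) <- c("gini_curve", "data.frame")
  attr(out, "argmax_fraction") <- out$fraction[which.max(out$gini)]
  attr(out, "crossing_fraction") <-
    if (any(below)) min(out$fraction[below]) else NA_real_
  attr(out, "params") <- list(K = K, K_prime = K_prime, n = n, seed = seed,
                              form = form)
  out
}

#' @export
print.gini_curve <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<gini_curve> K = %g, K' = %g, n = %g (%s form):\n  max relative Gini %.3f at fraction %.2f; drops below baseline at %s\n",
    p$K, p$K_prime, p$n, p$form, max(x$relative_gini),
    attr(x, "argmax_fraction"),
    format(attr(x, "crossing_fraction"))))
  invisible(x)
}
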