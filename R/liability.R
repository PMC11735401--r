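#' Liability threshold for a given lifetime prevalence
#'
#' Under the liability threshold model, disease occurs when a latent
#' standard-normal liability exceeds the threshold
#' \eqn{t = \Phi^{-1}(1 - K)}, where \eqn{K} is the lifetime prevalence.
#' The triple \eqn{(K, t, z)} with \eqn{z = \phi(t)} parameterises every
#' downstream conversion (the log-odds-to-liability multiplier is
#' \eqn{K(1-K)/z}).
#'
#' @param K Lifetime prevalence, in (0, 1).
#' @return A list of class \code{liability_threshold} with elements
#'   \code{K}, \code{t} (threshold, liability s.d.) and \code{z} (standard
#'   normal density at \code{t}).
#' @examples
#' threshold_from_prevalence(0.05) # t ~ 1.645
#' @export
threshold_from_prevalence <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0 || K >= 1) {
    stop("K must be a single value in (0, 1)")
  }
  t <- stats::qnorm(K, lower.tail = FALSE)  # tail-accurate for small K
  structure(list(K = K, t = t, z = stats::dnorm(t)),
            class = "liability_threshold")
}

#' @export
print.liability_threshold <- function(x, ...) {
  cat(sprintf("<liability_threshold> K = %g, t = %.4f, z = %.4f\n",
              x$K, x$t, x$z))
  invisible(x)
}

#' Disease prevalence after a liability shift
#'
#' Prevalence among genomes whose mean liability has been reduced by
#' \code{delta} standard deviations: \eqn{K_g = 1 - \Phi(t + \delta)}. The
#' residual (unexplained) liability variance is held at its population value,
#' so the unedited population recovers \code{K} exactly at \code{delta = 0}.
#' Upper-tail evaluation is used so that very small prevalences retain full
#' relative accuracy; values below 1e-12 are returned as computed but flagged
#' via the \code{"underflow"} attribute.
#'
#' @param K Lifetime prevalence among unedited genomes, in (0, 1).
#' @param delta Total liability reduction in liability s.d. (vectorised;
#'   non-negative for risk-reducing edits).
#' @return Prevalence(s) among shifted genomes, same length as \code{delta}.
#' @examples
#' prevalence_from_shift(0.05, 0)    # 0.05
#' prevalence_from_shift(0.05, 0.12) # ~ 0.0388
#' @export
prevalence_from_shift <- function(K, delta) {
  th <- threshold_from_prevalence(K)
  stopifnot(is.numeric(delta), all(is.finite(delta)))
  out <- stats::pnorm(th$t + delta, lower.tail = FALSE)
  if (any(out < 1e-12)) attr(out, "underflow") <- TRUE
  out
}

#' Hardy-Weinberg genotype probability
#'
#' Probability of carrying \code{count} copies of an allele of frequency
#' \code{p} under Hardy-Weinberg equilibrium. With linkage equilibrium the
#' joint probability of a multi-locus genotype is the product of these
#' per-locus probabilities.
#'
#' @param p Allele frequency in (0, 1).
#' @param count Allele count, 0, 1 or 2 (vectorised).
#' @return HWE genotype probability/ies.
#' @examples
#' genotype_probability(0.5, 2) # 0.25
#' sum(genotype_probability(0.3, 0:2)) # 1
#' @export
genotype_probability <- function(p, count) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  if (!all(count %in% c(0L, 1L, 2L))) {
    stop("count must be 0, 1 or 2")
  }
  stats::dbinom(count, size = 2, prob = p)
}
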