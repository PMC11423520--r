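#' Fixed-design sample size
#'
#' Per-group sample size of a fixed (single-stage) two-arm design with
#' power `1 - beta` at standardized effect `delta` and one-sided level
#' `alpha`: \eqn{N_{fix}(\delta) = 2(z_{1-\alpha}+z_{1-\beta})^2/\delta^2}.
#'
#' @param delta standardized effect size, > 0 (vectorized).
#' @param alpha one-sided type I error level.
#' @param beta type II error level.
#' @param ceiling round up to whole patients.
#' @return Per-group sample size (continuous unless `ceiling = TRUE`).
#' @examples
#' nFix(0.2)          # 392.44; a cap of 393 makes 80% power attainable
#' nFix(0.2, ceiling = TRUE)
#' @export
nFix <- function(delta, alpha = 0.025, beta = 0.2, ceiling = FALSE) {
  if (any(delta <= 0)) stop("'delta' must be positive")
  n <- 2 * (stats::qnorm(1 - alpha) + stats::qnorm(1 - beta))^2 / delta^2
  if (ceiling) ceiling(n) else n
}

#' Power-per-patient trade-off constant
#'
#' The slope of the fixed-design power curve
#' \eqn{Pow_\delta(N) = \Phi(\delta\sqrt{N/2} - z_{1-\alpha})} with respect
#' to the per-group size N, evaluated at \eqn{N = N_{fix}(\delta)}. In
#' closed form \eqn{\gamma_\delta = \varphi(z_{1-\beta})\,\delta /
#' (2\sqrt{2 N_{fix}(\delta)})}. Used as the cost per patient in the global
#' trade-off score, so that the score is maximal when power sits near
#' `1 - beta` and the expected sample size near \eqn{N_{fix}(\delta)}.
#'
#' @inheritParams nFix
#' @return The trade-off constant (probability per per-group patient).
#' @examples
#' gammaDelta(0.3)    # 0.002248
#' @export
gammaDelta <- function(delta, alpha = 0.025, beta = 0.2) {
  if (any(delta <= 0)) stop("'delta' must be positive")
  stats::dnorm(stats::qnorm(1 - beta)) * delta /
    (2 * sqrt(2 * nFix(delta, alpha, beta)))
}

#' Global trade-off score
#'
#' \eqn{S^G(\delta) = Pow_\delta - \gamma_\delta E_\delta[N]}. Defined only
#' on the clinically relevant effect range `delta >= deltaMin`; smaller
#' effects return `NA`, matching the convention that performance is not
#' evaluated where the required sample size is infeasible.
#'
#' @param power rejection probability at `delta`.
#' @param expectedN expected per-group total sample size at `delta`.
#' @param delta standardized effect size.
#' @param alpha,beta error levels entering \eqn{\gamma_\delta}.
#' @param deltaMin smallest effect size deemed clinically relevant.
#' @return The score (vectorized); `NA` below `deltaMin`.
#' @export
globalScore <- function(power, expectedN, delta, alpha = 0.025, beta = 0.2,
                        deltaMin = 0.2) {
  v <- .recycle(power, expectedN, delta)
  out <- rep(NA_real_, length(v[[1L]]))
  ok <- v[[3L]] >= deltaMin - 1e-12
  if (any(ok)) {
    out[ok] <- v[[1L]][ok] -
      gammaDelta(v[[3L]][ok], alpha, beta) * v[[2L]][ok]
  }
  out
}

#' Conditional performance score
#'
#' Scores a recalculation procedure from samples of the observed
#' conditional power and the realized total per-group sample size,
#' both taken conditional on the trial continuing past the first interim
#' analysis. Four components, each scaled to \eqn{[0,1]}:
#' \describe{
#'   \item{lCP}{location of conditional power,
#'     \eqn{1 - |E[CP] - CP_{target,\delta}|/(1-\alpha)}.}
#'   \item{vCP}{variation of conditional power,
#'     \eqn{1 - \sqrt{Var(CP)/(1/4)}}.}
#'   \item{lN}{location of sample size,
#'     \eqn{1 - |E[N] - N_{target,\delta}|/(n_{max}-n_1)}.}
#'   \item{vN}{variation of sample size,
#'     \eqn{1 - \sqrt{Var(N)/((n_{max}-n_1)/2)^2}}.}
#' }
#' Targets: \eqn{CP_{target,\delta} = 1-\beta} and
#' \eqn{N_{target,\delta} = N_{fix}(\delta)} (continuous) when a fixed
#' design within `nMax` patients per group can reach power `1 - beta` at
#' `delta`; otherwise \eqn{\alpha} and \eqn{n_1} (the effect is too small to
#' chase). `N` here is the *realized* cumulative per-group size — for a
#' design that can still stop at the second interim, `N` varies even when
#' the stage sizes are fixed. Components are clamped at 0; the raw `lN` can
#' go negative under extreme oversizing.
#'
#' @param cp observed conditional power values, one per continuing trial.
#' @param n realized total per-group sample sizes, same length.
#' @param delta true standardized effect the samples were generated under.
#' @param n1 first-stage per-group size.
#' @param nMax maximum total per-group size.
#' @param alpha,beta error levels (targets and scaling).
#' @param weights non-negative component weights `(lCP, vCP, lN, vN)`
#'   summing to 1.
#' @return A list with the four components, the weighted `score`, the
#'   targets used and the number of samples.
#' @examples
#' # degenerate samples exactly on target score 1 in every component
#' conditionalScore(rep(0.8, 10), rep(nFix(0.3), 10), 0.3, 70, 393)$score
#' @export
conditionalScore <- function(cp, n, delta, n1, nMax,
                             alpha = 0.025, beta = 0.2,
                             weights = rep(1 / 4, 4)) {
  if (length(cp) != length(n)) stop("'cp' and 'n' must have equal length")
  if (length(cp) < 2L) {
    stop("need at least 2 continuation samples to estimate the variances")
  }
  if (length(weights) != 4L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must be 4 non-negative values summing to 1")
  }
  attainable <- delta > 0 && nFix(delta, alpha, beta) <= nMax
  cpTarget <- if (attainable) 1 - beta else alpha
  nTarget <- if (attainable) nFix(delta, alpha, beta) else n1

  clamp <- function(x) min(max(x, 0), 1)
  lCP <- clamp(1 - abs(mean(cp) - cpTarget) / (1 - alpha))
  vCP <- clamp(1 - sqrt(stats::var(cp) / (1 / 4)))
  lN <- clamp(1 - abs(mean(n) - nTarget) / (nMax - n1))
  vN <- clamp(1 - sqrt(stats::var(n) / ((nMax - n1) / 2)^2))
  comp <- c(lCP = lCP, vCP = vCP, lN = lN, vN = vN)
  list(lCP = lCP, vCP = vCP, lN = lN, vN = vN,
       score = sum(weights * comp),
       cpTarget = cpTarget, nTarget = nTarget, nSamples = length(cp))
}
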