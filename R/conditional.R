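# Conditional rejection probabilities and conditional power for the
# inverse normal combination test. All functions work on the normal
# approximation to the stage statistics and are vectorized over
# z1Star / z2Star / n2 / n3 / delta (recycled to a common length).

.recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

#' Conditional rejection probability at stage two
#'
#' Probability that the stage-two combination statistic exceeds its efficacy
#' boundary, given the first-interim value \eqn{z^*_1}, a second-stage
#' per-group size `n2` and effect `delta`:
#' \deqn{1 - \Phi\!\left(\frac{\sqrt{w_1^2+w_2^2}\,c_2 - w_1 z^*_1}{w_2}
#'   - \delta\sqrt{n_2/2}\right).}
#'
#' @param z1Star observed first-stage combination statistic.
#' @param n2 second-stage per-group sample size (may be 0).
#' @param delta standardized effect used for the evaluation (true value or
#'   an interim estimate).
#' @param design a `gsrDesign` supplying weights and boundaries; or supply
#'   `weights`/`efficacy` directly.
#' @param weights,efficacy optional explicit combination weights and
#'   efficacy boundaries overriding `design`.
#' @return Probability (vectorized).
#' @export
crpStage2 <- function(z1Star, n2, delta, design = NULL,
                      weights = design$weights,
                      efficacy = design$boundaries$efficacy) {
  if (any(n2 < 0)) stop("'n2' must be non-negative")
  v <- .recycle(z1Star, n2, delta)
  a2 <- sqrt(weights[1L]^2 + weights[2L]^2)
  stats::pnorm((a2 * efficacy[2L] - weights[1L] * v[[1L]]) / weights[2L] -
                 v[[3L]] * sqrt(v[[2L]] / 2), lower.tail = FALSE)
}

#' Conditional rejection probability at stage three
#'
#' Probability that the final combination statistic exceeds \eqn{c_3} given
#' the stage-two value \eqn{z^*_2}, third-stage size `n3` and effect
#' `delta`:
#' \deqn{1 - \Phi\!\left(\frac{c_3 - \sqrt{w_1^2+w_2^2}\,z^*_2}{w_3}
#'   - \delta\sqrt{n_3/2}\right).}
#'
#' @param z2Star observed second-stage combination statistic.
#' @param n3 third-stage per-group sample size (may be 0).
#' @inheritParams crpStage2
#' @return Probability (vectorized).
#' @export
crpStage3 <- function(z2Star, n3, delta, design = NULL,
                      weights = design$weights,
                      efficacy = design$boundaries$efficacy) {
  if (any(n3 < 0)) stop("'n3' must be non-negative")
  v <- .recycle(z2Star, n3, delta)
  a2 <- sqrt(weights[1L]^2 + weights[2L]^2)
  stats::pnorm((efficacy[3L] - a2 * v[[1L]]) / weights[3L] -
                 v[[3L]] * sqrt(v[[2L]] / 2), lower.tail = FALSE)
}

#' Conditional law of the stage-two combination statistic
#'
#' Given \eqn{Z^*_1 = z^*_1}, a second-stage size and an effect size,
#' \eqn{Z^*_2} is normal with mean
#' \eqn{(w_1 z^*_1 + w_2\,\delta\sqrt{n_2/2})/\sqrt{w_1^2+w_2^2}} and
#' standard deviation \eqn{w_2/\sqrt{w_1^2+w_2^2}}, because
#' \eqn{Z_2 \sim N(\delta\sqrt{n_2/2}, 1)} independently of \eqn{Z_1}.
#'
#' @inheritParams crpStage2
#' @return A list with vectors `mean` and scalar `sd`.
#' @export
z2ConditionalLaw <- function(z1Star, n2, delta, design = NULL,
                             weights = design$weights) {
  if (any(n2 < 0)) stop("'n2' must be non-negative")
  v <- .recycle(z1Star, n2, delta)
  a2 <- sqrt(weights[1L]^2 + weights[2L]^2)
  list(mean = (weights[1L] * v[[1L]] + weights[2L] * v[[3L]] * sqrt(v[[2L]] / 2)) / a2,
       sd = weights[2L] / a2)
}

#' Three-stage conditional power at the first interim analysis
#'
#' Probability of rejecting the null at stage two or three, given the
#' first-interim combination statistic and chosen later-stage sizes:
#' the stage-two conditional rejection probability plus the stage-three
#' conditional rejection probability integrated over the stage-two
#' continuation region \eqn{[f_2, c_2]} against the conditional density of
#' \eqn{Z^*_2}. The integral is evaluated by fixed Gauss-Legendre
#' quadrature; the integrand is a smooth product of normal cdf terms and a
#' normal density on a short interval, so few nodes suffice.
#'
#' @param z1Star observed first-stage combination statistic.
#' @param n2,n3 per-group sizes of stages two and three.
#' @param delta standardized effect at which to evaluate.
#' @param design a three-stage `gsrDesign`; or supply `weights`,
#'   `efficacy`, `futility` directly.
#' @param weights,efficacy,futility explicit design quantities.
#' @param nodes Gauss-Legendre nodes on \eqn{[f_2, c_2]} (at least 2).
#' @return Probability (vectorized over `z1Star`, `n2`, `n3`, `delta`).
#' @examples
#' d <- gsrDesign(3, 70, c(70, 70))
#' conditionalPower(1.5, 70, 70, 0.3, d)
#' @export
conditionalPower <- function(z1Star, n2, n3, delta, design = NULL,
                             weights = design$weights,
                             efficacy = design$boundaries$efficacy,
                             futility = design$boundaries$futility,
                             nodes = 64) {
  if (nodes < 2) stop("'nodes' must be at least 2")
  if (any(n2 < 0) || any(n3 < 0)) stop("stage sizes must be non-negative")
  v <- .recycle(z1Star, n2, n3, delta)
  z1 <- v[[1L]]; n2v <- v[[2L]]; n3v <- v[[3L]]; dl <- v[[4L]]
  a2 <- sqrt(weights[1L]^2 + weights[2L]^2)

  crp2 <- crpStage2(z1, n2v, dl, weights = weights, efficacy = efficacy)

  gl <- pracma::gaussLegendre(nodes, futility[2L], efficacy[2L])
  m <- (weights[1L] * z1 + weights[2L] * dl * sqrt(n2v / 2)) / a2
  s <- weights[2L] / a2
  dens <- stats::dnorm(outer(-m, gl$x, "+"), sd = s)      # samples x nodes
  crp3 <- stats::pnorm(
    outer(dl * sqrt(n3v / 2), (efficacy[3L] - a2 * gl$x) / weights[3L],
          function(d, b) b - d),
    lower.tail = FALSE
  )
  crp2 + as.vector((dens * crp3) %*% gl$w)
}
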