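#' Stage-wise crossing probabilities of an inverse normal combination test
#'
#' Computes, by recursive Gauss-Legendre quadrature, the probability that the
#' combination statistic \eqn{Z^*_k} first exceeds its efficacy boundary at
#' each stage of a multi-stage design, together with the probability of
#' entering each later stage.
#'
#' The stage statistics \eqn{Z_i} are independent with
#' \eqn{Z_i \sim N(\delta\sqrt{n_i/2}, 1)}; the combination statistic is
#' \eqn{Z^*_k = \sum_{i\le k} w_i Z_i / \sqrt{\sum_{i\le k} w_i^2}}. The
#' recursion propagates the (sub-)density of \eqn{Z^*_k} restricted to the
#' continuation region from one analysis to the next.
#'
#' @param efficacy numeric vector of efficacy critical values, one per stage.
#' @param weights combination weights \eqn{w_i} with \eqn{\sum w_i^2 = 1}.
#' @param means stage-wise means of the \eqn{Z_i}, e.g.
#'   \eqn{\delta\sqrt{n_i/2}}; defaults to the null (all zero).
#' @param futility numeric vector of futility bounds at the interim analyses
#'   (length `k - 1`), or `NULL` to ignore futility stopping (non-binding
#'   boundary calibration). A trial stops for futility when the combination
#'   statistic falls below the bound.
#' @param nodes number of Gauss-Legendre nodes per stage.
#' @param lower lower truncation point (z scale) used when `futility` is
#'   `NULL`; the density mass below is negligible for practical boundaries.
#'
#' @return A list with `reject` (stage-wise first-crossing probabilities),
#'   `continue` (probability of continuing past each interim), and
#'   `overall` (total rejection probability).
#' @examples
#' # three-stage Pocock-type boundary spends 2.5% one-sided overall
#' p <- crossingProbabilities(rep(2.2895, 3), rep(1 / sqrt(3), 3))
#' sum(p$reject)
#' @export
crossingProbabilities <- function(efficacy, weights, means = NULL,
                                  futility = NULL, nodes = 256, lower = -8) {
  k <- length(efficacy)
  stopifnot(length(weights) == k, nodes >= 2)
  if (is.null(means)) means <- numeric(k)
  stopifnot(length(means) == k)
  if (!is.null(futility) && length(futility) != k - 1L) {
    stop("'futility' must have one bound per interim analysis (length k - 1)")
  }
  a <- sqrt(cumsum(weights^2))

  reject <- numeric(k)
  continue <- numeric(max(k - 1L, 0L))
  reject[1L] <- stats::pnorm(efficacy[1L] - means[1L], lower.tail = FALSE)
  if (k == 1L) {
    return(list(reject = reject, continue = continue, overall = reject))
  }

  lo <- if (is.null(futility)) lower else futility[1L]
  gl <- pracma::gaussLegendre(nodes, lo, efficacy[1L])
  x <- gl$x
  g <- gl$w * stats::dnorm(x, mean = means[1L], sd = 1)
  continue[1L] <- sum(g)

  for (s in 2:k) {
    condMean <- (a[s - 1L] * x + weights[s] * means[s]) / a[s]
    condSd <- weights[s] / a[s]
    reject[s] <- sum(g * stats::pnorm((efficacy[s] - condMean) / condSd,
                                      lower.tail = FALSE))
    if (s < k) {
      lo <- if (is.null(futility)) lower else futility[s]
      gl <- pracma::gaussLegendre(nodes, lo, efficacy[s])
      dens <- outer(gl$x, condMean, function(z, m) stats::dnorm(z, m, condSd))
      g <- gl$w * as.vector(dens %*% g)
      x <- gl$x
      continue[s] <- sum(g)
    }
  }
  list(reject = reject, continue = continue, overall = sum(reject))
}

#' Pocock-type group sequential boundaries
#'
#' Finds the constant critical value `c` such that a standard group
#' sequential z process observed at the given cumulative information
#' fractions crosses `c` at any analysis with probability `alpha` under the
#' null hypothesis. Futility bounds are treated as non-binding: they play no
#' role in the calibration and are attached for use at analysis time only.
#'
#' @param nStages number of analyses (1, 2 or 3).
#' @param alpha one-sided type I error level, in (0, 0.5).
#' @param infoFractions cumulative information fractions, strictly
#'   increasing with last element 1. Defaults to equal spacing.
#' @param futility futility bounds attached to the interim analyses
#'   (combination-statistic scale). Use `-Inf` to disable a bound.
#' @param nodes quadrature nodes per stage.
#' @param tol tolerance on the crossing probability for the root finder.
#'
#' @return An object of class `boundarySet`: a list with `efficacy`,
#'   `futility`, `alpha`, `infoFractions` and the `attained` crossing
#'   probability.
#' @examples
#' pocockBoundaries(1, 0.025)$efficacy           # the fixed-design quantile
#' pocockBoundaries(3, 0.025)$efficacy           # approx 2.2895 at each stage
#' @export
pocockBoundaries <- function(nStages, alpha,
                             infoFractions = seq_len(nStages) / nStages,
                             futility = rep(0, max(nStages - 1L, 0L)),
                             nodes = 256, tol = 1e-8) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 0.5)) {
    stop("'alpha' must be a single value in (0, 0.5)")
  }
  if (length(infoFractions) != nStages ||
      any(diff(c(0, infoFractions)) <= 0) ||
      abs(infoFractions[nStages] - 1) > 1e-12) {
    stop("'infoFractions' must be strictly increasing with last element 1")
  }
  w <- sqrt(diff(c(0, infoFractions)))
  if (nStages == 1L) {
    c0 <- stats::qnorm(1 - alpha)
    attained <- alpha
  } else {
    f <- function(cc) {
      crossingProbabilities(rep(cc, nStages), w, nodes = nodes)$overall - alpha
    }
    c0 <- stats::uniroot(f, c(stats::qnorm(1 - alpha), stats::qnorm(1 - alpha / (2 * nStages))),
                         tol = tol, extendInt = "downX")$root
    attained <- f(c0) + alpha
  }
  structure(
    list(efficacy = rep(c0, nStages), futility = futility, alpha = alpha,
         infoFractions = infoFractions, attained = attained),
    class = "boundarySet"
  )
}

#' @export
print.boundarySet <- function(x, ...) {
  cat("Group sequential boundary set (one-sided alpha =", x$alpha, ")\n")
  print(boundaryTable(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate a boundary set
#'
#' @param boundaries a `boundarySet`.
#' @return A data frame with columns `stage`, `info`, `efficacy`, `futility`
#'   (`NA` at the final analysis).
#' @export
boundaryTable <- function(boundaries) {
  k <- length(boundaries$efficacy)
  data.frame(
    stage = seq_len(k),
    info = boundaries$infoFractions,
    efficacy = boundaries$efficacy,
    futility = c(boundaries$futility, NA_real_)[seq_len(k)]
  )
}

#' Write a boundary set to CSV
#'
#' @param boundaries a `boundarySet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBoundaryCsv <- function(boundaries, path) {
  utils::write.csv(boundaryTable(boundaries), path, row.names = FALSE)
  invisible(path)
}
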