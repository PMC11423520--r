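# Monte Carlo engine. Trials are simulated from sufficient statistics:
# the standardized mean difference of a stage is delta + sqrt(2/n) * U with
# U ~ N(0,1), and the pooled variance estimate is chi-square with 2(n-1)
# degrees of freedom over its df. This has exactly the patient-level law of
# the two-sample t statistic and vectorizes over replicates. Storing the
# stage draws as (U, P) pairs with P a chi-square probability lets different
# designs (with different stage sizes, hence df) share one set of random
# numbers: qchisq(P, df) maps the common uniforms to the right df.

.stageDraws <- function(nReps, nStages = 3L) {
  list(u = matrix(stats::rnorm(nReps * nStages), nReps, nStages),
       p = matrix(stats::runif(nReps * nStages), nReps, nStages))
}

.stageStatistic <- function(n, u, p, delta, mode) {
  num <- sqrt(n / 2) * delta + u
  if (mode == "z") return(num)
  df <- 2 * (n - 1)
  num / sqrt(stats::qchisq(p, df) / df)
}

#' Simulate one stage statistic
#'
#' Draws the stage-wise test statistic of a two-arm comparison with `n`
#' patients per group at standardized effect `delta`: the two-sample pooled
#' t statistic (`mode = "t"`, requires `n >= 2`) or the known-variance z
#' statistic (`mode = "z"`). Either way the statistic is asymptotically
#' \eqn{N(\delta\sqrt{n/2}, 1)}.
#'
#' @param n per-group sample size.
#' @param delta standardized effect size.
#' @param nReps number of independent draws.
#' @param mode `"t"` or `"z"`.
#' @return Numeric vector of `nReps` statistics.
#' @export
simulateStage <- function(n, delta, nReps = 1L, mode = c("t", "z")) {
  mode <- match.arg(mode)
  if (mode == "t" && n < 2) stop("t statistics need n >= 2 per group")
  if (mode == "z" && n < 1) stop("'n' must be at least 1")
  .stageStatistic(n, stats::rnorm(nReps), stats::runif(nReps), delta, mode)
}

# Core vectorized trial engine operating on pre-drawn randomness.
.simTrials <- function(design, delta, draws, mode, nodes = 64) {
  w <- design$weights
  eff <- design$boundaries$efficacy
  fut <- design$boundaries$futility
  k <- design$nStages
  nReps <- nrow(draws$u)
  n1 <- design$n1

  z1 <- .stageStatistic(n1, draws$u[, 1L], draws$p[, 1L], delta, mode)
  stopStage <- rep(1L, nReps)
  rejected <- z1 > eff[1L]
  cont1 <- !rejected & z1 >= fut[1L]
  nTotal <- rep(n1, nReps)
  z2s <- rep(NA_real_, nReps)
  z3s <- rep(NA_real_, nReps)
  cpObs <- rep(NA_real_, nReps)

  ii <- which(cont1)
  if (length(ii)) {
    if (!is.null(design$rule)) {
      sizes <- lookupSizes(design$rule, z1[ii])
      n2 <- sizes$n2
      n3 <- sizes$n3
    } else {
      n2 <- rep(design$stageSizes[1L], length(ii))
      n3 <- if (k == 3L) rep(design$stageSizes[2L], length(ii)) else NULL
    }
    deltaHat <- sqrt(2 / n1) * z1[ii]
    evalEff <- (design$evalBoundaries %||% design$boundaries)$efficacy
    cpObs[ii] <- if (k == 3L) {
      conditionalPower(z1[ii], n2, n3, deltaHat, weights = w,
                       efficacy = evalEff, futility = fut, nodes = nodes)
    } else {
      crpStage2(z1[ii], n2, deltaHat, weights = w, efficacy = evalEff)
    }

    z2 <- .stageStatistic(n2, draws$u[ii, 2L], draws$p[ii, 2L], delta, mode)
    a2 <- sqrt(w[1L]^2 + w[2L]^2)
    zs2 <- (w[1L] * z1[ii] + w[2L] * z2) / a2
    z2s[ii] <- zs2
    nTotal[ii] <- n1 + n2
    stopStage[ii] <- 2L
    rej2 <- zs2 > eff[2L]
    rejected[ii[rej2]] <- TRUE

    if (k == 3L) {
      cont2 <- !rej2 & zs2 >= fut[2L]
      jj <- ii[cont2]
      if (length(jj)) {
        n3c <- n3[cont2]
        z3 <- .stageStatistic(n3c, draws$u[jj, 3L], draws$p[jj, 3L], delta, mode)
        zs3 <- w[1L] * z1[jj] + w[2L] * z2[cont2] + w[3L] * z3
        z3s[jj] <- zs3
        nTotal[jj] <- nTotal[jj] + n3c
        stopStage[jj] <- 3L
        rejected[jj[zs3 > eff[3L]]] <- TRUE
      }
    }
  }
  data.frame(stopStage = stopStage, rejected = rejected, nTotal = nTotal,
             z1Star = z1, z2Star = z2s, z3Star = z3s, cpObserved = cpObs)
}

#' Simulate trials under a design
#'
#' Runs `nReps` independent trials at effect size `delta` and returns the
#' per-trial outcomes: stopping stage, rejection flag, realized cumulative
#' per-group sample size, the observed combination statistics, and — for
#' trials that continued past the first interim — the observed conditional
#' power at the interim estimate \eqn{\hat\delta = \sqrt{2/n_1}\,z^*_1}
#' with the (possibly recalculated) later-stage sizes.
#'
#' Rule-based designs must carry a tabulated rule (see [tabulateRule()]);
#' sizes are looked up at the nearest grid point.
#'
#' @param design a `gsrDesign`.
#' @param delta true standardized effect size.
#' @param nReps number of replicates.
#' @param seed optional integer seed.
#' @param mode `"t"` for pooled two-sample t statistics (the default; the
#'   boundaries treat them as standard normal, so the realized type I error
#'   sits marginally above nominal), `"z"` for exact normal statistics.
#' @param nodes quadrature nodes for the observed conditional power.
#' @return A data frame with one row per trial.
#' @examples
#' d <- gsrDesign(3, 70, c(70, 70))
#' sims <- simulateTrials(d, 0.3, 2000, seed = 1)
#' mean(sims$rejected); mean(sims$nTotal)
#' @export
simulateTrials <- function(design, delta, nReps, seed = NULL,
                           mode = c("t", "z"), nodes = 64) {
  mode <- match.arg(mode)
  if (!is.null(design$rule) && is.null(design$rule$table)) {
    stop("tabulate the design's rule first (tabulateRule)")
  }
  if (!is.null(seed)) set.seed(seed)
  .simTrials(design, delta, .stageDraws(nReps), mode, nodes = nodes)
}
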