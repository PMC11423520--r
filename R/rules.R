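# Recalculation rules applied at the first interim analysis. Each rule maps
# the observed combination statistic z1* to equal per-group sizes for stages
# two and three, under the cap n1 + n2 + n3 <= nMax. Rules are evaluated
# exactly on demand and, for simulation speed, precomputed once over a fine
# z1* grid with nearest-neighbour lookup.

#' Observed conditional power rule
#'
#' At the first interim analysis, plug the effect estimate
#' \eqn{\hat\delta = \sqrt{2/n_1}\,z^*_1} into the three-stage conditional
#' power and pick the smallest equal per-stage size `n` with
#' \eqn{CP_{\hat\delta}(z^*_1, n, n) \ge} `targetPower`, capped at
#' `floor((nMax - n1)/2)` per stage.
#'
#' @param targetPower targeted conditional power (defaults to 0.8).
#' @param nMin smallest admissible per-stage size; 2 by default so that a
#'   stage always yields a variance estimate for its t statistic.
#' @return A `recalcRule` of kind `"ocp"`.
#' @export
ocpRule <- function(targetPower = 0.8, nMin = 2) {
  stopifnot(targetPower > 0, targetPower < 1, nMin >= 1)
  structure(list(kind = "ocp", targetPower = targetPower, nMin = as.integer(nMin),
                 table = NULL),
            class = "recalcRule")
}

#' Trade-off-optimizing recalculation rules
#'
#' Chooses the equal per-stage size `n` maximizing the expected trade-off
#' between conditional rejection probability and a linear sample size cost:
#' \deqn{g_\delta(n) = CRP^{(2)}_\delta(z^*_1, n) - \gamma n +
#'   \int_{f_2}^{c_2}\! CRP^{(3)}_\delta(z^*_2, n)\,
#'   f(z^*_2 \mid z^*_1, n, \delta)\, dz^*_2 - \mathrm{cost}_3,}
#' where the stage-three cost is either `gamma * n` times the probability of
#' continuing past the second interim (`cost = "expected"`, the realized
#' expected cost) or `gamma * n` unconditionally (`cost = "committed"`, the
#' size committed at recalculation time).
#'
#' With a `prior`, the objective is averaged over effect sizes with
#' posterior weights \eqn{w(\delta \mid z^*_1) \propto
#' \varphi(z^*_1 - \delta\sqrt{n_1/2})\, prior(\delta)}; with
#' `useGammaDelta = TRUE` the effect-indexed cost \eqn{\gamma_\delta}
#' replaces the constant `gamma`, which makes the rule optimize the global
#' score \eqn{S^G} rather than raw expected sample size. Ties in the argmax
#' break toward the smaller (cheaper) size.
#'
#' `sampleSizeOptimizedRule()` and `scoreOptimizedRule()` are the two
#' pre-configured variants used in the benchmark comparison.
#'
#' @param gamma constant cost per per-group patient (ignored when
#'   `useGammaDelta = TRUE`).
#' @param deltaPlan effect size at which to optimize (fixed-effect variant;
#'   supply either this or `prior`).
#' @param prior data frame with columns `delta` and `weight` (non-negative,
#'   summing to 1) describing effect size uncertainty.
#' @param useGammaDelta use \eqn{\gamma_\delta} from [gammaDelta()] instead
#'   of a constant `gamma`.
#' @param cost `"expected"` or `"committed"`, see Details.
#' @param deltaGrid effect sizes of the uniform prior used by
#'   `scoreOptimizedRule`.
#' @param alpha,beta error levels entering \eqn{\gamma_\delta}.
#' @param nMin smallest admissible per-stage size.
#' @return A `recalcRule` of kind `"optN"`/`"optSG"` (or `"tradeoff"`).
#' @export
tradeoffRule <- function(gamma = NULL, deltaPlan = NULL, prior = NULL,
                         useGammaDelta = FALSE,
                         cost = c("expected", "committed"),
                         alpha = 0.025, beta = 0.2, nMin = 2) {
  cost <- match.arg(cost)
  if (is.null(deltaPlan) == is.null(prior)) {
    stop("supply exactly one of 'deltaPlan' or 'prior'")
  }
  if (!is.null(prior)) {
    if (!all(c("delta", "weight") %in% names(prior))) {
      stop("'prior' needs columns 'delta' and 'weight'")
    }
    if (any(prior$weight < 0) || abs(sum(prior$weight) - 1) > 1e-8) {
      stop("prior weights must be non-negative and sum to 1")
    }
  }
  if (!useGammaDelta && (is.null(gamma) || gamma <= 0)) {
    stop("'gamma' must be positive")
  }
  structure(list(kind = "tradeoff", gamma = gamma, deltaPlan = deltaPlan,
                 prior = prior, useGammaDelta = useGammaDelta, cost = cost,
                 alpha = alpha, beta = beta, nMin = as.integer(nMin),
                 table = NULL),
            class = "recalcRule")
}

#' @rdname tradeoffRule
#' @export
sampleSizeOptimizedRule <- function(gamma = 0.0028, deltaPlan = 0.3,
                                    cost = "committed", nMin = 2) {
  r <- tradeoffRule(gamma = gamma, deltaPlan = deltaPlan, cost = cost,
                    nMin = nMin)
  r$kind <- "optN"
  r
}

#' @rdname tradeoffRule
#' @export
scoreOptimizedRule <- function(deltaGrid = seq(0.2, 0.6, by = 0.05),
                               alpha = 0.025, beta = 0.2, nMin = 2) {
  prior <- data.frame(delta = deltaGrid,
                      weight = rep(1 / length(deltaGrid), length(deltaGrid)))
  r <- tradeoffRule(prior = prior, useGammaDelta = TRUE, cost = "expected",
                    alpha = alpha, beta = beta, nMin = nMin)
  r$kind <- "optSG"
  r
}

#' @export
print.recalcRule <- function(x, ...) {
  cat("<recalcRule>", x$kind)
  if (!is.null(x$table)) {
    cat(" — tabulated over", nrow(x$table), "z1* grid points, n2 range [",
        min(x$table$n2), ",", max(x$table$n2), "]")
  }
  cat("\n")
  invisible(x)
}

# trade-off objective g_delta(n) for vector z1, scalar n/delta/gamma
.tradeoffObjective <- function(z1, n, delta, gamma, design, cost, nodes = 64) {
  w <- design$weights
  eff <- design$boundaries$efficacy
  fut <- design$boundaries$futility
  a2 <- sqrt(w[1L]^2 + w[2L]^2)
  crp2 <- crpStage2(z1, n, delta, weights = w, efficacy = eff)
  gl <- pracma::gaussLegendre(nodes, fut[2L], eff[2L])
  m <- (w[1L] * z1 + w[2L] * delta * sqrt(n / 2)) / a2
  dens <- stats::dnorm(outer(-m, gl$x, "+"), sd = w[2L] / a2)
  crp3 <- stats::pnorm((eff[3L] - a2 * gl$x) / w[3L] - delta * sqrt(n / 2),
                       lower.tail = FALSE)
  integ <- as.vector(dens %*% (gl$w * crp3))
  cost3 <- if (cost == "expected") {
    gamma * n * as.vector(dens %*% gl$w)      # pay n3 only if stage 3 runs
  } else {
    gamma * n                                 # n3 committed at recalculation
  }
  crp2 - gamma * n + integ - cost3
}

.ruleCandidates <- function(rule, design) {
  seq.int(max(rule$nMin, 1L), stageCap(design))
}

#' Evaluate a recalculation rule exactly
#'
#' Computes the per-stage size the rule assigns to each first-interim
#' statistic value by direct search over all admissible sizes (no table
#' lookup). `z1Star` values must lie in the continuation region
#' \eqn{[f_1, c_1]}.
#'
#' @param rule a `recalcRule`.
#' @param z1Star vector of first-interim combination statistics.
#' @param design the three-stage `gsrDesign` the rule operates in.
#' @param nodes quadrature nodes for the conditional power integrals.
#' @return Integer vector of equal per-stage sizes `n2 = n3`.
#' @export
ruleSizes <- function(rule, z1Star, design, nodes = 64) {
  stopifnot(inherits(rule, "recalcRule"))
  f1 <- design$boundaries$futility[1L]
  c1 <- design$boundaries$efficacy[1L]
  if (any(z1Star < f1 - 1e-9 | z1Star > c1 + 1e-9)) {
    stop("'z1Star' outside the continuation region [f1, c1]")
  }
  ns <- .ruleCandidates(rule, design)
  if (length(ns) == 0L) stop("no admissible stage size under the cap")

  if (rule$kind == "ocp") {
    deltaHat <- sqrt(2 / design$n1) * z1Star
    cp <- vapply(ns, function(n) {
      conditionalPower(z1Star, n, n, deltaHat, design, nodes = nodes)
    }, numeric(length(z1Star)))
    cp <- matrix(cp, nrow = length(z1Star))
    sel <- apply(cp >= rule$targetPower, 1L, function(r) {
      i <- which(r)
      if (length(i)) i[1L] else length(ns)  # cap when the target is unreachable
    })
    return(ns[sel])
  }

  # trade-off rules: objective matrix (z1 x n), posterior-weighted if a prior
  if (is.null(rule$prior)) {
    grid <- data.frame(delta = rule$deltaPlan, weight = 1)
    wpost <- matrix(1, length(z1Star), 1L)
  } else {
    grid <- rule$prior
    lik <- vapply(grid$delta, function(d) {
      stats::dnorm(z1Star, mean = d * sqrt(design$n1 / 2))
    }, numeric(length(z1Star)))
    lik <- matrix(lik, nrow = length(z1Star))
    wpost <- lik * rep(grid$weight, each = length(z1Star))
    tot <- rowSums(wpost)
    bad <- tot <= 0 | !is.finite(tot)
    if (any(bad)) {  # posterior underflow: fall back to the prior
      message("posterior weights underflowed for ", sum(bad),
              " z1* value(s); using prior weights there")
      wpost[bad, ] <- rep(grid$weight, each = sum(bad))
      tot[bad] <- 1
    }
    wpost <- wpost / tot
  }
  obj <- matrix(0, length(z1Star), length(ns))
  for (k in seq_len(nrow(grid))) {
    gam <- if (rule$useGammaDelta) {
      gammaDelta(grid$delta[k], rule$alpha, rule$beta)
    } else {
      rule$gamma
    }
    gk <- vapply(ns, function(n) {
      .tradeoffObjective(z1Star, n, grid$delta[k], gam, design, rule$cost,
                         nodes = nodes)
    }, numeric(length(z1Star)))
    obj <- obj + wpost[, k] * matrix(gk, nrow = length(z1Star))
  }
  ns[apply(obj, 1L, which.max)]  # which.max takes the first (smaller n) on ties
}

#' Precompute a rule over a grid of first-interim statistics
#'
#' Evaluates the rule on an equidistant grid covering the continuation
#' region \eqn{[f_1, c_1]} and attaches the resulting lookup table to the
#' rule. Simulations then use nearest-neighbour lookup, which is
#' deterministic given the design and quadrature settings.
#'
#' @param rule a `recalcRule`.
#' @param design the three-stage `gsrDesign`.
#' @param zGridStep grid spacing (must be <= 0.02; conditional power varies
#'   slowly on that scale relative to Monte Carlo noise).
#' @param nodes quadrature nodes.
#' @return The rule with a `table` data frame (`z1Star`, `n2`, `n3`).
#' @export
tabulateRule <- function(rule, design, zGridStep = 0.01, nodes = 64) {
  if (zGridStep > 0.02) stop("'zGridStep' must not exceed 0.02")
  f1 <- design$boundaries$futility[1L]
  c1 <- design$boundaries$efficacy[1L]
  grid <- seq(f1, c1, by = zGridStep)
  if (grid[length(grid)] < c1) grid <- c(grid, c1)
  n <- ruleSizes(rule, grid, design, nodes = nodes)
  rule$table <- data.frame(z1Star = grid, n2 = n, n3 = n)
  rule
}

#' Look up tabulated stage sizes
#'
#' Nearest-neighbour lookup of `(n2, n3)` in a tabulated rule.
#'
#' @param rule a tabulated `recalcRule`.
#' @param z1Star vector of first-interim statistics.
#' @return A list with integer vectors `n2` and `n3`.
#' @export
lookupSizes <- function(rule, z1Star) {
  if (is.null(rule$table)) stop("rule is not tabulated; see tabulateRule()")
  grid <- rule$table$z1Star
  step <- grid[2L] - grid[1L]
  idx <- pmin(pmax(round((z1Star - grid[1L]) / step), 0L),
              length(grid) - 1L) + 1L
  # the last grid point may be an off-step endpoint at c1
  near <- abs(z1Star - grid[idx]) > abs(z1Star - grid[length(grid)])
  idx[near] <- length(grid)
  list(n2 = rule$table$n2[idx], n3 = rule$table$n3[idx])
}

#' Read or write a rule table as CSV
#'
#' @param rule a tabulated `recalcRule`.
#' @param path file path.
#' @return `writeRuleTable` returns `path` invisibly; `readRuleTable`
#'   returns a `recalcRule` of kind `"table"` carrying only the lookup
#'   table.
#' @export
writeRuleTable <- function(rule, path) {
  if (is.null(rule$table)) stop("rule is not tabulated")
  utils::write.csv(rule$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRuleTable
#' @export
readRuleTable <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("z1Star", "n2", "n3") %in% names(tab))) {
    stop("rule table needs columns z1Star, n2, n3")
  }
  structure(list(kind = "table", nMin = min(tab$n2), table = tab),
            class = "recalcRule")
}
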