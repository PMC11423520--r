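#' Inverse normal combination of stage-wise statistics
#'
#' Returns the combination statistic
#' \eqn{Z^*_s = \sum_{i \le s} w_i Z_i / \sqrt{\sum_{i \le s} w_i^2}}
#' at the requested stage. At stage 1 this is simply \eqn{Z_1}; at the final
#' stage of a fully weighted design the denominator is 1.
#'
#' @param zStage numeric vector of stage-wise z statistics observed so far.
#' @param weights pre-specified combination weights with \eqn{\sum w_i^2 = 1}.
#' @param stage analysis stage at which to combine (defaults to all observed).
#' @return The combination statistic \eqn{Z^*_{stage}}.
#' @examples
#' combineStages(c(1, 2), rep(1 / sqrt(3), 3), 2)  # (1 + 2)/sqrt(2)
#' @export
combineStages <- function(zStage, weights, stage = length(zStage)) {
  if (stage < 1L || stage > length(zStage) || stage > length(weights)) {
    stop("'stage' out of range for the supplied statistics/weights")
  }
  if (abs(sum(weights^2) - 1) > 1e-8) {
    stop("combination weights must satisfy sum(w^2) = 1")
  }
  i <- seq_len(stage)
  sum(weights[i] * zStage[i]) / sqrt(sum(weights[i]^2))
}

#' Construct a multi-stage trial design
#'
#' Bundles the stage structure, combination weights, error levels and
#' efficacy/futility boundaries of a two- or three-stage design for a
#' two-arm comparison of normal endpoints (common unknown variance). Stage
#' sizes are per group. Either fixed `stageSizes` or a recalculation `rule`
#' (applied at the first interim analysis) determines the sizes of stages
#' two and three.
#'
#' Default combination weights are proportional to the square roots of the
#' planned stage sizes, so that for fixed designs the combination statistic
#' coincides with the cumulative-information z statistic. For rule-based
#' designs the planning sizes `n1` at every stage give equal weights
#' \eqn{1/\sqrt{3}}; the weights stay fixed when the rule changes the sizes,
#' which is what preserves the type I error under adaptation.
#'
#' @param nStages 2 or 3.
#' @param n1 first-stage per-group sample size.
#' @param stageSizes per-group sizes of the later stages (length
#'   `nStages - 1`), or `NULL` when a `rule` is supplied.
#' @param rule a `recalcRule` (see [ocpRule()], [tradeoffRule()]), or `NULL`.
#' @param alpha one-sided type I error level.
#' @param beta type II error level at the planning effect.
#' @param nMax maximum total per-group sample size of the whole trial.
#' @param weights optional combination weights (length `nStages`,
#'   \eqn{\sum w_i^2 = 1}).
#' @param boundaries optional `boundarySet`; computed as Pocock-type at the
#'   weight-implied information fractions when omitted.
#' @param deltaAssumed standardized effect used at the planning stage.
#' @param evalBoundaries optional `boundarySet` used only when evaluating
#'   the observed conditional power for the conditional performance score.
#'   Defaults to `boundaries`. Supplying the boundary set shared by a
#'   comparator family scores every design's interim prospects against the
#'   same yardstick, so the CP components reflect the sample-size choice
#'   rather than boundary differences.
#' @param name short label used in printed tables.
#'
#' @return An object of class `gsrDesign`.
#' @examples
#' d3 <- gsrDesign(3, 70, c(70, 70))
#' d3$boundaries$efficacy
#' @export
gsrDesign <- function(nStages, n1, stageSizes = NULL, rule = NULL,
                      alpha = 0.025, beta = 0.2, nMax = 393,
                      weights = NULL, boundaries = NULL,
                      deltaAssumed = 0.3, evalBoundaries = NULL,
                      name = NULL) {
  if (!nStages %in% c(2L, 3L)) stop("'nStages' must be 2 or 3")
  if (!(n1 >= 2 && n1 == round(n1))) stop("'n1' must be an integer >= 2")
  if (!(alpha > 0 && alpha < 0.5)) stop("'alpha' must be in (0, 0.5)")
  if (!(beta > 0 && beta < 1)) stop("'beta' must be in (0, 1)")
  if (nMax < n1) stop("'nMax' must be at least 'n1'")
  if (is.null(stageSizes) == is.null(rule)) {
    stop("supply exactly one of 'stageSizes' or 'rule'")
  }
  if (!is.null(stageSizes)) {
    if (length(stageSizes) != nStages - 1L) {
      stop("'stageSizes' must have length nStages - 1")
    }
    if (any(stageSizes < 0) || any(stageSizes != round(stageSizes))) {
      stop("'stageSizes' must be non-negative integers")
    }
    planned <- c(n1, stageSizes)
  } else {
    if (!inherits(rule, "recalcRule")) stop("'rule' must be a recalcRule")
    if (nStages != 3L) stop("recalculation rules are defined for 3-stage designs")
    planned <- rep(n1, nStages)
  }
  if (is.null(weights)) {
    weights <- sqrt(planned / sum(planned))
  }
  if (length(weights) != nStages || abs(sum(weights^2) - 1) > 1e-8) {
    stop("'weights' must have length nStages with sum(w^2) = 1")
  }
  if (is.null(boundaries)) {
    boundaries <- pocockBoundaries(nStages, alpha,
                                   infoFractions = cumsum(weights^2))
  }
  structure(
    list(nStages = as.integer(nStages), n1 = as.integer(n1),
         stageSizes = if (is.null(stageSizes)) NULL else as.integer(stageSizes),
         rule = rule, weights = weights, alpha = alpha, beta = beta,
         nMax = as.integer(nMax), deltaAssumed = deltaAssumed,
         boundaries = boundaries,
         evalBoundaries = evalBoundaries %||% boundaries,
         name = name %||% if (is.null(rule)) paste0("gs", nStages) else rule$kind),
    class = "gsrDesign"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gsrDesign <- function(x, ...) {
  cat("<gsrDesign>", x$name, "-", x$nStages, "stages, n1 =", x$n1, "\n")
  if (!is.null(x$stageSizes)) {
    cat("  fixed stage sizes:", paste(c(x$n1, x$stageSizes), collapse = ", "),
        "per group\n")
  } else {
    cat("  recalculated at interim 1 by rule:", x$rule$kind,
        if (!is.null(x$rule$table)) "(tabulated)" else "(not tabulated)", "\n")
  }
  cat("  weights:", paste(round(x$weights, 4), collapse = ", "), "\n")
  cat("  efficacy:", paste(round(x$boundaries$efficacy, 4), collapse = ", "),
      " futility:", paste(round(x$boundaries$futility, 4), collapse = ", "), "\n")
  cat("  alpha =", x$alpha, " beta =", x$beta, " nMax =", x$nMax, "\n")
  invisible(x)
}

#' Per-stage cap on recalculated sample sizes
#'
#' The largest equal per-stage size a recalculation rule may choose so that
#' the trial total never exceeds `nMax`: `floor((nMax - n1)/2)`.
#'
#' @param design a `gsrDesign`.
#' @return Integer per-stage cap.
#' @export
stageCap <- function(design) {
  as.integer(floor((design$nMax - design$n1) / 2))
}

#' Analytic operating characteristics of a fixed group sequential design
#'
#' Power, stage-wise stopping probabilities and expected per-group sample
#' size under the normal approximation to the stage statistics, with the
#' futility bounds applied (as they are at analysis time).
#'
#' @param design a `gsrDesign` with fixed stage sizes.
#' @param delta true standardized effect size.
#' @param nodes quadrature nodes per stage.
#' @return A list with `power`, `expectedN`, `reject` and `continue`.
#' @export
designOperatingCharacteristics <- function(design, delta, nodes = 256) {
  if (is.null(design$stageSizes)) {
    stop("analytic operating characteristics require fixed stage sizes")
  }
  sizes <- c(design$n1, design$stageSizes)
  p <- crossingProbabilities(design$boundaries$efficacy, design$weights,
                             means = delta * sqrt(sizes / 2),
                             futility = design$boundaries$futility,
                             nodes = nodes)
  expectedN <- sizes[1L] + sum(sizes[-1L] * p$continue)
  list(power = p$overall, expectedN = expectedN,
       reject = p$reject, continue = p$continue)
}

#' The five benchmark designs
#'
#' Builds the comparator set used throughout the package's simulation
#' study: a two-stage group sequential design (`gs2`, stages 70/140), a
#' three-stage group sequential design (`gs3`, stages 70/70/70), and three
#' three-stage designs with recalculation at the first interim analysis
#' (`ocp`, `optSG`, `optN`).
#'
#' All five designs share the first interim analysis: `n1 = 70` and the
#' first-stage efficacy boundary of the three-stage Pocock set, so the
#' continuation event conditioned on by the conditional performance score is
#' identical across designs. `gs2`'s second-stage critical value is the
#' Pocock-type constant of a two-stage design at information fractions
#' (1/3, 1); its overall type I error is therefore slightly below `alpha`
#' (conservative). Futility bounds are 0 at every interim.
#'
#' @param alpha,beta one-sided error levels.
#' @param n1 shared first-stage per-group size.
#' @param nMax maximum total per-group sample size.
#' @param rules tabulate the recalculation rules (a few seconds); if
#'   `FALSE`, rules are attached untabulated.
#' @param zGridStep step of the first-interim statistic grid for rule tables.
#' @return Named list of `gsrDesign` objects: `gs2`, `gs3`, `ocp`, `optSG`,
#'   `optN`.
#' @export
benchmarkDesigns <- function(alpha = 0.025, beta = 0.2, n1 = 70, nMax = 393,
                             rules = TRUE, zGridStep = 0.01) {
  b3 <- pocockBoundaries(3, alpha)
  c2s <- pocockBoundaries(2, alpha, infoFractions = c(1 / 3, 1))$efficacy[1L]
  b2 <- structure(
    list(efficacy = c(b3$efficacy[1L], c2s), futility = 0, alpha = alpha,
         infoFractions = c(1 / 3, 1), attained = NA_real_),
    class = "boundarySet"
  )
  gs2 <- gsrDesign(2, n1, 2 * n1, alpha = alpha, beta = beta, nMax = nMax,
                   boundaries = b2, evalBoundaries = b3, name = "gs2")
  gs3 <- gsrDesign(3, n1, c(n1, n1), alpha = alpha, beta = beta, nMax = nMax,
                   boundaries = b3, name = "gs3")
  mk <- function(rule, nm) {
    d <- gsrDesign(3, n1, rule = rule, alpha = alpha, beta = beta,
                   nMax = nMax, boundaries = b3, name = nm)
    if (rules) d$rule <- tabulateRule(d$rule, d, zGridStep = zGridStep)
    d
  }
  list(
    gs2 = gs2,
    gs3 = gs3,
    ocp = mk(ocpRule(targetPower = 1 - beta), "ocp"),
    optSG = mk(scoreOptimizedRule(alpha = alpha, beta = beta), "optSG"),
    optN = mk(sampleSizeOptimizedRule(), "optN")
  )
}

#' Read or write a design configuration
#'
#' Serializes the scalar fields of a design (not the rule table) as YAML so
#' that a configuration can be versioned alongside simulation output.
#'
#' @param design a `gsrDesign` with fixed stage sizes.
#' @param path file path.
#' @return `writeDesignConfig` returns `path` invisibly; `readDesignConfig`
#'   returns a `gsrDesign`.
#' @export
writeDesignConfig <- function(design, path) {
  if (is.null(design$stageSizes)) {
    stop("only fixed-size designs can round-trip through a config file")
  }
  cfg <- list(
    nStages = design$nStages, n1 = design$n1,
    stageSizes = design$stageSizes, alpha = design$alpha, beta = design$beta,
    nMax = design$nMax, weights = design$weights,
    efficacy = design$boundaries$efficacy,
    futility = design$boundaries$futility,
    deltaAssumed = design$deltaAssumed, name = design$name
  )
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname writeDesignConfig
#' @export
readDesignConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # guard against serialization rounding of the weight constraint
  cfg$weights <- as.numeric(cfg$weights) / sqrt(sum(as.numeric(cfg$weights)^2))
  boundaries <- structure(
    list(efficacy = as.numeric(cfg$efficacy),
         futility = as.numeric(cfg$futility),
         alpha = cfg$alpha,
         infoFractions = cumsum(as.numeric(cfg$weights)^2),
         attained = NA_real_),
    class = "boundarySet"
  )
  gsrDesign(cfg$nStages, cfg$n1, as.numeric(cfg$stageSizes),
            alpha = cfg$alpha, beta = cfg$beta, nMax = cfg$nMax,
            weights = as.numeric(cfg$weights), boundaries = boundaries,
            deltaAssumed = cfg$deltaAssumed, name = cfg$name)
}
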