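#' Operating characteristic study over a grid of effect sizes
#'
#' Simulates every design at every effect size and aggregates the global
#' measures (power, expected per-group sample size, global score \eqn{S^G})
#' and the conditional performance score with its four components. All
#' designs share the same random numbers within a replicate (the stage
#' draws are mapped through the design-specific sample sizes), which
#' sharpens between-design comparisons; effect sizes use independent
#' streams. Conditional measures are computed over trials that continued
#' past the first interim analysis.
#'
#' Designs must share `n1` — the conditional score conditions on the first
#' interim result, so that analysis must happen at the same point in every
#' design for the comparison to be meaningful.
#'
#' @param designs named list of `gsrDesign` objects (rules tabulated).
#' @param deltaGrid effect sizes to evaluate.
#' @param nReps replicates per effect size.
#' @param seed integer seed; recorded in the result.
#' @param mode `"t"` or `"z"` stage statistics.
#' @param scoreWeights component weights of the conditional score.
#' @param nodes quadrature nodes for observed conditional power.
#' @return A `gsrStudy`: list with data frames `global`
#'   (design, delta, power, expectedN, sG) and `conditional`
#'   (design, delta, lCP, vCP, lN, vN, sC, nCont), plus `config`.
#' @examples
#' ds <- benchmarkDesigns(rules = FALSE)[c("gs2", "gs3")]
#' st <- runStudy(ds, deltaGrid = c(0, 0.3), nReps = 2000, seed = 1)
#' globalTable(st)
#' @export
runStudy <- function(designs, deltaGrid = seq(0, 0.6, by = 0.1),
                     nReps = 1e5, seed = 1, mode = c("t", "z"),
                     scoreWeights = rep(1 / 4, 4), nodes = 64) {
  mode <- match.arg(mode)
  stopifnot(length(designs) >= 1L, nReps >= 2L)
  if (is.null(names(designs))) {
    names(designs) <- vapply(designs, `[[`, "", "name")
  }
  n1s <- vapply(designs, `[[`, integer(1), "n1")
  if (length(unique(n1s)) != 1L) {
    stop("all designs must share the first-stage sample size n1")
  }
  set.seed(seed)
  globalRows <- list()
  condRows <- list()
  for (delta in deltaGrid) {
    draws <- .stageDraws(nReps)
    for (nm in names(designs)) {
      d <- designs[[nm]]
      sims <- .simTrials(d, delta, draws, mode, nodes = nodes)
      power <- mean(sims$rejected)
      expectedN <- mean(sims$nTotal)
      globalRows[[length(globalRows) + 1L]] <- data.frame(
        design = nm, delta = delta, power = power, expectedN = expectedN,
        sG = globalScore(power, expectedN, delta, d$alpha, d$beta)
      )
      cont <- sims$stopStage >= 2L
      sc <- conditionalScore(sims$cpObserved[cont], sims$nTotal[cont],
                             delta, d$n1, d$nMax, d$alpha, d$beta,
                             weights = scoreWeights)
      condRows[[length(condRows) + 1L]] <- data.frame(
        design = nm, delta = delta, lCP = sc$lCP, vCP = sc$vCP,
        lN = sc$lN, vN = sc$vN, sC = sc$score, nCont = sc$nSamples
      )
    }
  }
  structure(
    list(global = do.call(rbind, globalRows),
         conditional = do.call(rbind, condRows),
         config = list(deltaGrid = deltaGrid, nReps = nReps, seed = seed,
                       mode = mode, designs = names(designs))),
    class = "gsrStudy"
  )
}

#' @export
print.gsrStudy <- function(x, ...) {
  cfg <- x$config
  cat("<gsrStudy>", length(cfg$designs), "designs x",
      length(cfg$deltaGrid), "effect sizes,", cfg$nReps,
      "replicates each (seed", cfg$seed, ", mode", cfg$mode, ")\n")
  cat("designs:", paste(cfg$designs, collapse = ", "), "\n")
  invisible(x)
}

.wideTable <- function(long, measures) {
  deltas <- sort(unique(long$delta))
  rows <- list()
  for (nm in unique(long$design)) {
    for (ms in measures) {
      sub <- long[long$design == nm, ]
      vals <- sub[[ms]][match(deltas, sub$delta)]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(design = nm, measure = ms),
        stats::setNames(as.data.frame(as.list(vals)),
                        paste0("delta_", deltas))
      )
    }
  }
  do.call(rbind, rows)
}

#' Global and conditional performance tables
#'
#' Reshape a study into the wide design-by-effect-size layout of the
#' benchmark tables: one row per design and measure, one column per effect
#' size. `globalTable` reports power, expected sample size and \eqn{S^G};
#' `conditionalTable` the four score components and \eqn{S^C}.
#'
#' @param study a `gsrStudy`.
#' @return A data frame in wide layout.
#' @export
globalTable <- function(study) {
  .wideTable(study$global, c("power", "expectedN", "sG"))
}

#' @rdname globalTable
#' @export
conditionalTable <- function(study) {
  .wideTable(study$conditional, c("lCP", "vCP", "lN", "vN", "sC"))
}

#' Export study results as tidy CSV
#'
#' Writes one tidy file with columns
#' (design, delta, measure, value, nReps, seed) covering both the global
#' and the conditional measures.
#'
#' @param study a `gsrStudy`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStudyCsv <- function(study, path) {
  tidy <- function(df, measures) {
    out <- lapply(measures, function(ms) {
      data.frame(design = df$design, delta = df$delta, measure = ms,
                 value = df[[ms]])
    })
    do.call(rbind, out)
  }
  long <- rbind(tidy(study$global, c("power", "expectedN", "sG")),
                tidy(study$conditional, c("lCP", "vCP", "lN", "vN", "sC")))
  long$nReps <- study$config$nReps
  long$seed <- study$config$seed
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
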