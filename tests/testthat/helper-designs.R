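# Shared fixtures. Boundary computation and rule tabulation are cached so
# the suite pays for them once.

.fixtures <- new.env(parent = emptyenv())

benchmarkFixture <- function() {
  if (is.null(.fixtures$designs)) {
    .fixtures$designs <- benchmarkDesigns()
  }
  .fixtures$designs
}

gs3Fixture <- function() benchmarkFixture()$gs3

# Monte Carlo oracle for three-stage conditional power: simulate stages two
# and three directly from the stage-statistic law, independent of the
# package's quadrature path.
cpMonteCarlo <- function(z1, n2, n3, delta, design, nReps = 2e5, seed = 42) {
  set.seed(seed)
  w <- design$weights
  eff <- design$boundaries$efficacy
  fut <- design$boundaries$futility
  a2 <- sqrt(w[1]^2 + w[2]^2)
  Z2 <- rnorm(nReps, mean = delta * sqrt(n2 / 2))
  zs2 <- (w[1] * z1 + w[2] * Z2) / a2
  rej2 <- zs2 > eff[2]
  cont <- !rej2 & zs2 >= fut[2]
  Z3 <- rnorm(nReps, mean = delta * sqrt(n3 / 2))
  zs3 <- w[1] * z1 + w[2] * Z2 + w[3] * Z3
  mean(rej2 | (cont & zs3 > eff[3]))
}
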