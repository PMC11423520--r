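d3 <- NULL
setup <- function() {
  if (is.null(d3)) d3 <<- gs3Fixture()
  d3
}

test_that("stage-two conditional rejection probability matches a Monte Carlo oracle", {
  d <- setup()
  p <- crpStage2(2.0, 70, 0.3, d)
  # oracle: simulate Z2 ~ N(sqrt(35)*0.3, 1) and count combination exceedances
  set.seed(31)
  nmc <- 1e6
  z2 <- rnorm(nmc, mean = sqrt(35) * 0.3)
  w <- d$weights
  zs2 <- (w[1] * 2.0 + w[2] * z2) / sqrt(w[1]^2 + w[2]^2)
  phat <- mean(zs2 > d$boundaries$efficacy[2])
  expect_lt(abs(p - phat), 3 * sqrt(phat * (1 - phat) / nmc))
  expect_equal(p, 0.7044, tolerance = 1e-3)
})

test_that("conditional rejection probabilities hit their limits", {
  d <- setup()
  expect_equal(crpStage2(1, 70, 1e6, d), 1)
  expect_equal(crpStage3(1, 70, -1e6, d), 0)
  # with n2 = 0 and z1 = 0 only the boundary term remains
  w <- d$weights
  a2 <- sqrt(w[1]^2 + w[2]^2)
  expect_equal(crpStage2(0, 0, 5, d),
               1 - pnorm(a2 * d$boundaries$efficacy[2] / w[2]))
})

test_that("conditional law of the stage-two statistic is the stated normal", {
  d <- setup()
  law <- z2ConditionalLaw(2, 70, 0.3, d)
  expect_equal(law$mean, (2 + 0.3 * sqrt(35)) / sqrt(2), tolerance = 1e-9)
  expect_equal(law$sd, 1 / sqrt(2), tolerance = 1e-12)
  law0 <- z2ConditionalLaw(0, 0, 0.77, d)
  expect_equal(law0$mean, 0)
  # empirical check against simulated combination statistics
  set.seed(13)
  z2 <- rnorm(2e5, mean = 0.3 * sqrt(35))
  zs2 <- (d$weights[1] * 2 + d$weights[2] * z2) / sqrt(2 / 3)
  expect_lt(abs(mean(zs2) - law$mean), 4 * sd(zs2) / sqrt(2e5))
  expect_lt(abs(sd(zs2) - law$sd), 0.005)
})

test_that("conditional power agrees with simulation and a second quadrature", {
  d <- setup()
  cp <- conditionalPower(0, 70, 70, 0, d)
  expect_lt(abs(cp - cpMonteCarlo(0, 70, 70, 0, d, nReps = 1e6)),
            3 * sqrt(cp * (1 - cp) / 1e6) + 1e-4)
  cp2 <- conditionalPower(1.2, 90, 90, 0.25, d)
  expect_lt(abs(cp2 - cpMonteCarlo(1.2, 90, 90, 0.25, d, nReps = 1e6)), 0.002)

  # independent integration route: stats::integrate over the same integrand
  w <- d$weights
  eff <- d$boundaries$efficacy
  a2 <- sqrt(w[1]^2 + w[2]^2)
  integrand <- function(z2) {
    law <- z2ConditionalLaw(1.2, 90, 0.25, d)
    crpStage3(z2, 90, 0.25, d) * dnorm(z2, law$mean, law$sd)
  }
  ref <- crpStage2(1.2, 90, 0.25, d) +
    integrate(integrand, d$boundaries$futility[2], eff[2],
              rel.tol = 1e-10)$value
  expect_equal(cp2, ref, tolerance = 1e-7)
})

test_that("conditional power dominates the stage-two term and is monotone", {
  d <- setup()
  z1s <- seq(0, 2.2, by = 0.4)
  for (z1 in z1s) {
    expect_gte(conditionalPower(z1, 70, 70, 0.2, d),
               crpStage2(z1, 70, 0.2, d))
  }
  grid <- seq(10, 160, by = 30)
  cpN2 <- conditionalPower(1, grid, 70, 0.3, d)
  cpN3 <- conditionalPower(1, 70, grid, 0.3, d)
  cpD <- conditionalPower(1, 70, 70, seq(0, 0.6, 0.1), d)
  cpZ <- conditionalPower(seq(0, 2.2, 0.2), 70, 70, 0.3, d)
  expect_true(all(diff(cpN2) > 0))
  expect_true(all(diff(cpN3) > 0))
  expect_true(all(diff(cpD) > 0))
  expect_true(all(diff(cpZ) > 0))
})

test_that("at delta = 0 conditional power does not depend on the stage sizes", {
  d <- setup()
  cps <- conditionalPower(0.8, c(2, 50, 161), c(2, 50, 161), 0, d)
  expect_lt(max(cps) - min(cps), 1e-12)
})

test_that("quadrature is stable under node doubling", {
  d <- setup()
  cp64 <- conditionalPower(1.1, 85, 85, 0.27, d, nodes = 64)
  cp128 <- conditionalPower(1.1, 85, 85, 0.27, d, nodes = 128)
  expect_lt(abs(cp64 - cp128), 1e-8)
  expect_error(conditionalPower(1, 70, 70, 0.3, d, nodes = 1), "nodes")
})

test_that("law of total probability recovers the design's global power", {
  d <- setup()
  delta <- 0.3
  f1 <- d$boundaries$futility[1]
  c1 <- d$boundaries$efficacy[1]
  m1 <- delta * sqrt(d$n1 / 2)
  total <- pnorm(c1 - m1, lower.tail = FALSE) +
    integrate(function(z1) {
      conditionalPower(z1, 70, 70, delta, d) * dnorm(z1, m1, 1)
    }, f1, c1, rel.tol = 1e-9)$value
  expect_equal(total, designOperatingCharacteristics(d, delta)$power,
               tolerance = 1e-6)
  sims <- simulateTrials(d, delta, 4e4, seed = 21, mode = "z")
  expect_lt(abs(mean(sims$rejected) - total),
            3 * sqrt(total * (1 - total) / 4e4))
})
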