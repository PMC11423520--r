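test_that("observed conditional power rule caps at the maximum stage size", {
  d <- gs3Fixture()
  # at z1 = 0 the interim estimate is 0, conditional power is flat in n,
  # the 80% target is unreachable and the cap applies
  expect_equal(ruleSizes(ocpRule(), 0, d), 161L)
  expect_equal(stageCap(d), 161L)
})

test_that("observed conditional power rule matches a linear-scan oracle", {
  d <- gs3Fixture()
  rule <- ocpRule()
  for (z1 in c(0.8, 1.4, 2.0, 2.28)) {
    n <- ruleSizes(rule, z1, d)
    deltaHat <- sqrt(2 / 70) * z1
    # brute force: walk n upward until the target is reached
    oracle <- 161L
    for (cand in 2:161) {
      if (conditionalPower(z1, cand, cand, deltaHat, d) >= 0.8) {
        oracle <- cand
        break
      }
    }
    expect_identical(n, oracle)
    if (n < 161L && n > 2L) {
      expect_gte(conditionalPower(z1, n, n, deltaHat, d), 0.8)
      expect_lt(conditionalPower(z1, n - 1L, n - 1L, deltaHat, d), 0.8)
    }
  }
})

test_that("rule sizes respect the overall cap and the continuation region", {
  d <- benchmarkFixture()
  for (nm in c("ocp", "optSG", "optN")) {
    tab <- d[[nm]]$rule$table
    expect_true(all(70 + tab$n2 + tab$n3 <= 393))
    expect_true(all(tab$n2 >= 2 & tab$n2 == tab$n3))
    expect_equal(tab$z1Star[1], 0)
    expect_equal(tab$z1Star[nrow(tab)], d$gs3$boundaries$efficacy[1],
                 tolerance = 1e-9)
  }
  expect_error(ruleSizes(ocpRule(), 3, d$gs3), "continuation region")
  expect_error(ruleSizes(ocpRule(), -0.5, d$gs3), "continuation region")
})

test_that("ocp sizes shrink once conditional power becomes achievable", {
  tab <- benchmarkFixture()$ocp$rule$table
  uncapped <- which(tab$n2 < 161L)
  expect_gt(length(uncapped), 50)
  expect_true(all(diff(tab$n2[uncapped]) <= 0))
})

test_that("cost extremes drive the trade-off rule to its bounds", {
  d <- gs3Fixture()
  tiny <- tradeoffRule(gamma = 1e-9, deltaPlan = 0.3)
  huge <- tradeoffRule(gamma = 1, deltaPlan = 0.3)
  expect_equal(ruleSizes(tiny, 1, d), 161L)
  expect_equal(ruleSizes(huge, 1, d), 2L)
})

test_that("a degenerate prior reproduces the fixed-effect trade-off rule", {
  d <- gs3Fixture()
  fixed <- tradeoffRule(gamma = 0.0028, deltaPlan = 0.3, cost = "expected")
  point <- tradeoffRule(gamma = 0.0028, cost = "expected",
                        prior = data.frame(delta = 0.3, weight = 1))
  z1s <- c(0, 0.7, 1.5, 2.2)
  expect_identical(ruleSizes(fixed, z1s, d), ruleSizes(point, z1s, d))
})

test_that("trade-off argmax equals an exhaustive scan with independent integration", {
  d <- gs3Fixture()
  rule <- sampleSizeOptimizedRule()   # fixed delta 0.3, committed cost
  w <- d$weights
  eff <- d$boundaries$efficacy
  fut <- d$boundaries$futility
  objective <- function(z1, n) {
    law <- z2ConditionalLaw(z1, n, 0.3, d)
    integ <- integrate(function(z2) {
      crpStage3(z2, n, 0.3, d) * dnorm(z2, law$mean, law$sd)
    }, fut[2], eff[2], rel.tol = 1e-10)$value
    crpStage2(z1, n, 0.3, d) + integ - 0.0028 * 2 * n
  }
  for (z1 in c(0.3, 1.1, 1.9)) {
    vals <- vapply(2:161, function(n) objective(z1, n), numeric(1))
    expect_identical(ruleSizes(rule, z1, d), (2:161)[which.max(vals)])
  }
})

test_that("larger interim statistics shift the prior-based rule to smaller sizes", {
  tab <- benchmarkFixture()$optSG$rule$table
  lower <- mean(tab$n2[tab$z1Star <= 0.3])
  upper <- mean(tab$n2[tab$z1Star >= 2.0])
  expect_gt(lower, upper)
  # the score-optimized rule recruits more than the fixed gs3 stages at
  # small interim statistics, buying power against small true effects
  expect_gt(lower, 70)
})

test_that("tabulation is deterministic and lookup returns nearest entries", {
  d <- gs3Fixture()
  r1 <- tabulateRule(ocpRule(), d, zGridStep = 0.02)
  r2 <- tabulateRule(ocpRule(), d, zGridStep = 0.02)
  expect_identical(r1$table, r2$table)
  expect_error(tabulateRule(ocpRule(), d, zGridStep = 0.05), "zGridStep")

  got <- lookupSizes(r1, c(0, 0.009, 0.011, 2.2894))
  expect_equal(got$n2[1], r1$table$n2[1])
  expect_equal(got$n2[2], r1$table$n2[1])   # nearest is the 0 grid point
  expect_equal(got$n2[3], r1$table$n2[2])
  expect_equal(got$n2[4], r1$table$n2[nrow(r1$table)])
  expect_error(lookupSizes(ocpRule(), 1), "not tabulated")
})

test_that("rule tables round-trip through CSV", {
  d <- gs3Fixture()
  rule <- tabulateRule(ocpRule(), d, zGridStep = 0.02)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRuleTable(rule, path)
  back <- readRuleTable(path)
  expect_equal(back$table$n2, rule$table$n2)
  expect_equal(lookupSizes(back, 1.5), lookupSizes(rule, 1.5))
})

test_that("rule constructors validate their arguments", {
  expect_error(tradeoffRule(gamma = -1, deltaPlan = 0.3), "gamma")
  expect_error(tradeoffRule(gamma = 0.01), "exactly one")
  expect_error(tradeoffRule(gamma = 0.01, deltaPlan = 0.3,
                            prior = data.frame(delta = 0.3, weight = 1)),
               "exactly one")
  expect_error(tradeoffRule(prior = data.frame(delta = 0.3, weight = 2),
                            gamma = 0.01), "sum to 1")
  expect_error(ocpRule(targetPower = 1.2), "targetPower")
})
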