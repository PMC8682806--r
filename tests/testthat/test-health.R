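# Exposure-response risk, population weighting, person-days and Monte
# Carlo uncertainty propagation.

test_that("sd back-calculation from a relative-risk CI is exact", {
  expect_identical(sdFromCI(1.2, 1.2), 0)               # degenerate CI
  expect_equal(sdFromCI(0.9, 1.1), log(11 / 9) / (2 * qnorm(0.975)))
  expect_equal(sdFromCI(0.9, 1.1), 0.0511924, tolerance = 1e-6)
  expect_lt(abs(sdFromCI(1.0, exp(2 * qnorm(0.975))) - 1), 1e-12)
  expect_error(sdFromCI(-1, 2), "ci_lower")
})

test_that("increased risk is zero at zero and compounds log-linearly", {
  lin <- riskFunction(form = "linear", slope = 1, ci_lower = 0.5, ci_upper = 1.5)
  log_ <- riskFunction(form = "log_linear", slope = 1, ci_lower = 0.5,
                       ci_upper = 1.5)
  expect_identical(irAtConcentration(lin, 0), 0)
  expect_identical(irAtConcentration(log_, 0), 0)
  expect_equal(irAtConcentration(lin, 100), 10)         # proportional
  expect_equal(irAtConcentration(log_, 20), 100 * (1.01^2 - 1))  # 2.01%
  # monotone in concentration
  cc <- seq(0, 500, by = 50)
  expect_true(all(diff(irAtConcentration(log_, cc)) > 0))
})

test_that("the default risk slope reproduces the occupational anchor", {
  r <- riskFunction("burnett-style")
  expect_equal(irAtConcentration(r, 1600), 530, tolerance = 0.01)
})

test_that("population weighting averages IR over exposed cells only", {
  spec <- tinySpec(days = 1)
  d <- gridDim(spec)
  r <- riskFunction(form = "linear", slope = 1, ci_lower = 0.5, ci_upper = 1.5)
  # uniform concentration: weighted IR equals the pointwise IR
  pm <- makePM(spec, matrix(50, d[2], d[3]))
  pop <- uniformPop(spec)
  res <- populationWeightedIR(pm, pop, r)
  expect_equal(res$ir, irAtConcentration(r, 50))
  expect_equal(res$exposed_pop, sum(populationCount(pop)))
  # all population in one cell: weighted IR is that cell's IR
  cnt <- matrix(0, d[2], d[3]); cnt[3, 4] <- 1000
  conc <- matrix(runif(d[2] * d[3], 20, 80), d[2], d[3])
  pop1 <- new("PopulationGrid", grid = spec, count = cnt)
  res1 <- populationWeightedIR(makePM(spec, conc), pop1, r)
  expect_equal(res1$ir, irAtConcentration(r, conc[3, 4]))
  # nothing exposed: defined = FALSE, IR 0
  res0 <- populationWeightedIR(makePM(spec, matrix(1, d[2], d[3])), pop, r)
  expect_identical(res0$defined, FALSE)
  expect_identical(res0$ir, 0)
})

test_that("population-weighted IR equals a brute-force double loop", {
  spec <- tinySpec(days = 1)
  d <- gridDim(spec)
  r <- riskFunction()
  set.seed(11)
  for (rep in 1:20) {
    conc <- matrix(rexp(d[2] * d[3], 1 / 20), d[2], d[3])
    cnt <- matrix(rpois(d[2] * d[3], 40), d[2], d[3])
    pop <- new("PopulationGrid", grid = spec, count = cnt)
    res <- populationWeightedIR(makePM(spec, conc), pop, r)
    num <- den <- 0
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
      if (conc[i, j] >= 10 && cnt[i, j] > 0) {
        num <- num + irAtConcentration(r, conc[i, j]) * cnt[i, j]
        den <- den + cnt[i, j]
      }
    }
    if (den > 0) expect_equal(res$ir, num / den, tolerance = 1e-12)
  }
})

test_that("person-days count exposed population per day above threshold", {
  spec <- tinySpec(days = 1)
  d <- gridDim(spec)
  cnt <- matrix(0, d[2], d[3]); cnt[2, 2] <- 100
  pop <- new("PopulationGrid", grid = spec, count = cnt)
  daily <- array(0, c(3, d[2], d[3])); daily[, 2, 2] <- c(12, 15, 30)
  pm <- makePM(spec, matrix(12, d[2], d[3]), daily = daily,
               release_hours = 72)
  expect_equal(personDays(pm, pop), 300)
  # below threshold everywhere: zero person-days
  pm0 <- makePM(spec, matrix(1, d[2], d[3]),
                daily = array(1, c(3, d[2], d[3])), release_hours = 72)
  expect_equal(personDays(pm0, pop), 0)
  # non-increasing in threshold, non-decreasing in duration
  expect_gte(personDays(pm, pop, threshold = 10),
             personDays(pm, pop, threshold = 20))
  expect_gte(personDays(pm, pop, duration_days = 3),
             personDays(pm, pop, duration_days = 2))
})

test_that("degenerate Monte Carlo input collapses the uncertainty interval", {
  spec <- tinySpec(days = 1)
  d <- gridDim(spec)
  pm <- makePM(spec, matrix(40, d[2], d[3]))
  pop <- uniformPop(spec)
  r <- riskFunction(form = "linear", slope = 2, ci_lower = 2, ci_upper = 2)
  out <- propagateUncertainty(pm, pop, r,
                              monteCarloConfig(n_draws = 50, seed = 1,
                                               conversion_rate_sd = 0))
  expect_equal(out$IR_lo, out$mean_IR, tolerance = 1e-12)
  expect_equal(out$IR_hi, out$mean_IR, tolerance = 1e-12)
  expect_equal(out$mean_IR, 2 * 40 / 10)
  expect_false(out$possibly_null)
})

test_that("a slope CI straddling zero yields a reported lower bound of 0", {
  spec <- tinySpec(days = 1)
  d <- gridDim(spec)
  pm <- makePM(spec, matrix(40, d[2], d[3]))
  pop <- uniformPop(spec)
  r <- riskFunction(form = "linear", slope = 0.3, ci_lower = -1.2,
                    ci_upper = 1.8)
  out <- propagateUncertainty(pm, pop, r,
                              monteCarloConfig(n_draws = 400, seed = 2,
                                               conversion_rate_sd = 0))
  expect_identical(out$IR_lo, 0)
  expect_true(out$possibly_null)
  expect_gt(out$mean_IR, 0)
})

test_that("uncertainty propagation recovers known Normal parameters", {
  spec <- tinySpec(days = 1)
  d <- gridDim(spec)
  conc <- 30
  pm <- makePM(spec, matrix(conc, d[2], d[3]))
  pop <- uniformPop(spec)
  slope <- 2; lo <- 1.5; hi <- 2.5
  r <- riskFunction(form = "linear", slope = slope, ci_lower = lo,
                    ci_upper = hi)
  n <- 4000
  out <- propagateUncertainty(pm, pop, r,
                              monteCarloConfig(n_draws = n, seed = 3,
                                               conversion_rate_sd = 0))
  # linear form + uniform field: IR draws are Normal(slope*c/10, sd*c/10)
  sd_ir <- sdFromCI(1 + lo / 100, 1 + hi / 100) * 100 * conc / 10
  mu <- slope * conc / 10
  expect_lt(abs(out$mean_IR - mu), 3 * sd_ir / sqrt(n))
  z <- qnorm(0.975)
  se_q <- sqrt(0.025 * 0.975 / n) / dnorm(z)  # quantile standard error
  expect_lt(abs(out$IR_lo - (mu - z * sd_ir)), 3 * se_q * sd_ir)
  expect_lt(abs(out$IR_hi - (mu + z * sd_ir)), 3 * se_q * sd_ir)
})
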