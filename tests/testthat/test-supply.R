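# Supply-disruption estimators: ports, desalination, fuel, prices, food
# aid, fisheries.

pctField <- function() {
  percentileTransform(makeField(data.frame(
    lat = rep(c(15.0, 15.1), each = 2),
    lon = rep(c(43.0, 43.1), 2),
    value = c(1, 2, 3, 4)), decimals = 1))
}

test_that("port exposure interpolates percentiles and applies the threshold", {
  f <- pctField()
  ports <- data.frame(name = c("at-max", "untouched", "between"),
                      lon = c(43.1, 43.0, 43.05),
                      lat = c(15.1, 14.2, 15.05))
  out <- portExposure(f, ports)
  expect_equal(out$percentile[1], 100)
  expect_true(out$exposed[1])
  expect_false(out$reached[2])
  expect_identical(out$status[2], "outside_domain")
  # hand-computed bilinear at the centroid: mean of 25, 50, 75, 100
  expect_equal(out$percentile[3], 62.5)
  expect_false(out$exposed[3])
  expect_true(out$reached[3])
  expect_error(portExposure(makeField(data.frame(lat = 1, lon = 1, value = 1)),
                            ports), "percentile")
})

test_that("unknown plant capacities get an equal division of the country total", {
  f <- makeField(data.frame(lat = c(15, 15.1), lon = c(43, 43),
                            value = c(2, 3)), decimals = 1)
  plants <- data.frame(name = c("a", "b", "c"),
                       lon = c(43, 43, 40), lat = c(15, 15.1, 10),
                       capacity_m3_per_day = rep(NA_real_, 3),
                       country = "yemenlike")
  out <- desalDisruption(f, plants, c(yemenlike = 0.02),
                         c(yemenlike = 30000))
  expect_true(all(out$plants$capacity_m3_per_day == 10000))  # conserves total
  expect_identical(out$plants$disrupted, c(TRUE, TRUE, FALSE))
  expect_equal(out$total_disrupted_m3_day, 20000)
  expect_equal(out$population_equivalent, 20000 / 0.02)      # 1,000,000
})

test_that("unexposed plants produce zero impact", {
  f <- makeField(data.frame(lat = 15, lon = 43, value = 2), decimals = 1)
  plants <- data.frame(name = "far", lon = 40, lat = 10,
                       capacity_m3_per_day = 5000, country = "west")
  out <- desalDisruption(f, plants, c(west = 0.05))
  expect_equal(out$total_disrupted_m3_day, 0)
  expect_equal(out$population_equivalent, 0)
})

test_that("fuel disruption reports mean and type-7 quantile interval", {
  x <- c(1, 2, 3, 4, 5)
  out <- fuelDisruption(x)
  expect_equal(out$mean, 3)
  expect_equal(out$lo95, 1.1)   # (n-1)p + 1 = 1.1: linear interpolation
  expect_equal(out$hi95, 4.9)
  expect_identical(fuelDisruption(sample(x)), out)  # permutation-invariant
  const <- fuelDisruption(rep(7, 5))
  expect_identical(c(const$lo95, const$hi95), c(7, 7))
  expect_error(fuelDisruption(3), "at least 2")
})

test_that("price spike compares medians across fuels between two dates", {
  expect_equal(priceSpike(c(diesel = 100, petrol = 100, gas = 100),
                          c(diesel = 172, petrol = 172, gas = 172)), 72)
  expect_equal(priceSpike(c(a = 5), c(a = 5)), 0)
  expect_equal(priceSpike(c(a = 50), c(a = 75)), 50)  # single fuel: ratio
  expect_error(priceSpike(c(a = 0), c(a = 10)), "zero baseline")
})

test_that("food-aid disruption multiplies shares by the targeted series", {
  shares <- c(hud = 0.45, salif = 0.23, aden = 0.32)
  expect_equal(foodAidDisruption(shares, c(1e6, 2e6), character(0))$mean, 0)
  const <- foodAidDisruption(c(p = 0.5), rep(1e7, 10), "p")
  expect_equal(const$mean, 5e6)
  expect_equal(const$lo95, 5e6)  # degenerate interval
  set.seed(12)
  series <- runif(10, 5e6, 12e6)
  out <- foodAidDisruption(shares, series, c("hud", "salif"))
  expect_equal(out$share, 0.68)
  expect_equal(out$mean, 0.68 * mean(series))
  expect_equal(out$lo95, 0.68 * unname(quantile(series, 0.025, type = 7)))
  expect_equal(out$hi95, 0.68 * unname(quantile(series, 0.975, type = 7)))
})

test_that("fishery loss covers the whole region under full overlap", {
  yg <- expand.grid(lat = c(15, 15.1), lon = c(43, 43.1))
  yg$yield_tons <- c(10, 20, 30, 40); yg$region <- "Red Sea"
  full <- makeField(data.frame(lat = yg$lat, lon = yg$lon, value = 1:4),
                    decimals = 1)
  out <- fisheryLoss(full, yg, "Red Sea", "none")
  expect_equal(out$threatened_fraction, 100)
  none <- makeField(data.frame(lat = 10, lon = 40, value = 1), decimals = 1)
  expect_equal(fisheryLoss(none, yg, "Red Sea", "none")$threatened_fraction, 0)
  expect_error(fisheryLoss(full, yg, "Gulf of Aden"), "zero regional")
})

test_that("fishery loss matches a brute-force masked sum on random grids", {
  set.seed(13)
  for (rep in 1:30) {
    yg <- expand.grid(lat = seq(14, 15, 0.1), lon = seq(42, 43, 0.1))
    yg$yield_tons <- rpois(nrow(yg), 20); yg$region <- "Red Sea"
    n_oil <- sample(5:40, 1)
    cells <- data.frame(
      lat = round(runif(n_oil, 14, 15), 1),
      lon = round(runif(n_oil, 42, 43), 1),
      value = rexp(n_oil))
    cells <- cells[!duplicated(cells[, 1:2]), ]
    f <- makeField(cells, decimals = 1)
    for (th in c("none", "p10", "p20")) {
      cut <- c(none = 0, p10 = 10, p20 = 20)[[th]]
      pct <- 100 * rank(cells$value, ties.method = "max") / nrow(cells)
      kept <- cells[pct >= cut, ]
      hit <- mapply(function(la, lo)
        any(abs(kept$lat - la) < 0.05 & abs(kept$lon - lo) < 0.05),
        yg$lat, yg$lon)
      expected <- 100 * sum(yg$yield_tons[hit]) / sum(yg$yield_tons)
      expect_equal(fisheryLoss(f, yg, "Red Sea", th)$threatened_fraction,
                   expected, tolerance = 1e-9)
    }
    # threshold ordering: stricter thresholds never threaten more yield
    v <- vapply(c("none", "p10", "p20"), function(th)
      fisheryLoss(f, yg, "Red Sea", th)$threatened_fraction, numeric(1))
    expect_true(v["p20"] <= v["p10"] + 1e-9 && v["p10"] <= v["none"] + 1e-9)
  }
})
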