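# Gridding, percentile transform, bilinear interpolation and convex hulls.

test_that("gridded cell values are per-simulation sums averaged over sims", {
  one <- list(data.frame(lon = 43.001, lat = 15.002, value = 7))
  f <- gridConcentration(one, decimals = 3)
  expect_identical(cellValues(f)$value, 7)
  expect_identical(cellValues(f)$lon, 43.001)
  # two simulations placing 2 and 4 in the same cell average to 3
  two <- list(data.frame(lon = 43.0, lat = 15.0, value = 2),
              data.frame(lon = 43.0004, lat = 14.9996, value = 4))
  f <- gridConcentration(two, decimals = 3)
  expect_identical(nrow(cellValues(f)), 1L)
  expect_identical(cellValues(f)$value, 3)
  expect_error(gridConcentration(list()), "at least one")
})

test_that("gridding matches a brute-force recomputation on random input", {
  set.seed(7)
  sims <- lapply(1:100, function(i)
    data.frame(lon = runif(20, 43, 43.05), lat = runif(20, 15, 15.05),
               value = runif(20)))
  f <- gridConcentration(sims, decimals = 2)
  cells <- cellValues(f)
  # oracle: double loop over cells and simulations
  for (r in sample(nrow(cells), 10)) {
    tot <- 0
    for (s in sims) {
      sel <- round(s$lat, 2) == cells$lat[r] & round(s$lon, 2) == cells$lon[r]
      tot <- tot + sum(s$value[sel])
    }
    expect_equal(cells$value[r], tot / 100, tolerance = 1e-12)
  }
})

test_that("percentile transform ranks exposed cells, ties at highest rank", {
  f <- makeField(data.frame(lat = c(15, 15, 15.1, 15.1),
                            lon = c(43, 43.1, 43, 43.1),
                            value = c(1, 2, 3, 4)), decimals = 1)
  p <- percentileTransform(f)
  expect_equal(sort(cellValues(p)$value), c(25, 50, 75, 100))
  expect_identical(fieldUnits(p), "percentile")
  # all equal: every cell at the 100th percentile
  f2 <- makeField(data.frame(lat = c(15, 15.1), lon = c(43, 43),
                             value = c(2, 2)), decimals = 1)
  expect_equal(cellValues(percentileTransform(f2))$value, c(100, 100))
  # invariance under strictly monotone rescaling
  f3 <- makeField(data.frame(lat = c(15, 15, 15.1, 15.1),
                             lon = c(43, 43.1, 43, 43.1),
                             value = 10 * c(1, 2, 3, 4)), decimals = 1)
  expect_equal(cellValues(percentileTransform(f3))$value,
               cellValues(p)$value)
})

test_that("bilinear interpolation weights the four surrounding centres", {
  f <- makeField(data.frame(lat = c(15.0, 15.0, 15.1, 15.1),
                            lon = c(43.0, 43.1, 43.0, 43.1),
                            value = c(0, 0, 10, 10)), decimals = 1)
  expect_equal(interpolateBilinear(f, 43.0, 15.0), 0)      # at a centre
  expect_equal(interpolateBilinear(f, 43.05, 15.1), 10)    # equal-valued pair
  expect_equal(interpolateBilinear(f, 43.05, 15.05), 5)    # centroid: 1/4 each
  # absent neighbours count as zero
  expect_equal(interpolateBilinear(f, 43.05, 15.15), 5)
  expect_error(interpolateBilinear(f, 44.5, 15.05), "outside")
})

test_that("convex hull encloses all points with the shoelace area", {
  sq <- rbind(data.frame(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1)),
              data.frame(lon = runif(50), lat = runif(50)))
  r <- uncertaintyRegion(sq)
  expect_equal(hullArea(r), 1, tolerance = 1e-12)
  expect_true(all(regionContains(r, sq$lon, sq$lat)))
  # random interior points of a known convex quadrilateral: hull area equals
  # the quadrilateral's hand-computed shoelace area
  quad <- data.frame(lon = c(0, 4, 5, 1), lat = c(0, 1, 4, 3))
  shoelace <- 0.5 * abs(sum(quad$lon * c(quad$lat[-1], quad$lat[1]) -
                              c(quad$lon[-1], quad$lon[1]) * quad$lat))
  set.seed(3)
  w <- matrix(stats::rexp(4 * 200), 200)
  w <- w / rowSums(w)  # convex combinations stay inside the quad
  pts <- rbind(quad, data.frame(lon = w %*% quad$lon, lat = w %*% quad$lat))
  r2 <- uncertaintyRegion(pts)
  expect_equal(hullArea(r2), shoelace, tolerance = 1e-12)
  expect_true(all(regionContains(r2, pts$lon, pts$lat)))
})

test_that("degenerate point sets are rejected", {
  expect_error(uncertaintyRegion(data.frame(lon = c(0, 1), lat = c(0, 0))),
               "degenerate")
  expect_error(uncertaintyRegion(data.frame(lon = 0:5, lat = 0:5)),
               "degenerate")
})

test_that("accumulated weekly footprints grow monotonically", {
  wk1 <- makeField(data.frame(lat = 15, lon = 43, value = 2), decimals = 1)
  wk2 <- makeField(data.frame(lat = c(15, 15.1), lon = c(43, 43),
                              value = c(1, 5)), decimals = 1)
  acc <- accumulateFields(list(week1 = wk1, week2 = wk2))
  expect_identical(nrow(cellValues(acc$week1)), 1L)
  c2 <- cellValues(acc$week2)
  expect_identical(nrow(c2), 2L)
  expect_equal(c2$value[c2$lat == 15], 2)   # keeps the weekly maximum
  expect_equal(c2$value[c2$lat == 15.1], 5)
})
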