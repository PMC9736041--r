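test_that("doseAtVolume interpolates linearly between bracketing points", {
  cv <- dvhCurve(c(0, 20, 40), c(1, 0.5, 0))
  expect_equal(doseAtVolume(cv, 25), 30)
  expect_equal(doseAtVolume(cv, 50), 20)
  expect_equal(doseAtVolume(cv, 100), 0)
  expect_equal(doseAtVolume(cv, 75), 10)
})

test_that("doseAtVolume resolves flat segments to the highest dose", {
  cv <- dvhCurve(c(0, 10, 20, 30), c(1, 0.5, 0.5, 0))
  expect_equal(doseAtVolume(cv, 50), 20)  # tie: highest dose at volume 0.5
})

test_that("doseAtVolume validates inputs and clamps to the dose range", {
  cv <- dvhCurve(c(5, 20, 40), c(1, 0.5, 0))
  expect_error(doseAtVolume(cumulativeToDifferential(cv), 50),
               class = "dvhWrongKind")
  expect_error(doseAtVolume(cv, 0), class = "dvhBadArgument")
  expect_error(doseAtVolume(cv, 101), class = "dvhBadArgument")
  # beyond the resolvable range: clamp to curve ends
  cv2 <- dvhCurve(c(5, 20, 40), c(0.9999999, 0.5, 0.2))
  expect_equal(doseAtVolume(cv2, 100), 5)
  expect_equal(doseAtVolume(cv2, 1), 40)
})

test_that("a uniform-dose curve returns the dose at every volume", {
  cv <- uniformDVH(54)
  for (x in c(1, 5, 50, 95, 100))
    expect_equal(doseAtVolume(cv, x), 54, tolerance = 1e-6)
})

test_that("quantiles are nonincreasing in volume on generated curves", {
  cohort <- generateCohort(smallConfig(seed = 13, nPatients = 2))
  xs <- c(1, 5, 25, 50, 75, 95, 99, 100)
  for (plan in cohort[c(1, 5)]) {
    for (cv in curves(plan)) {
      q <- vapply(xs, function(x) doseAtVolume(cv, x), numeric(1))
      expect_true(all(diff(q) <= 1e-12))
    }
  }
})

test_that("dMean is the fraction-weighted midpoint dose", {
  dc <- dvhCurve(c(0, 10, 20), c(0.6, 0.4), kind = "differential")
  expect_equal(dMean(dc), 0.6 * 5 + 0.4 * 15)  # 9 Gy
  expect_equal(dMean(uniformDVH(37.5)), 37.5)
})

test_that("homogeneity index matches its definition and scale invariance", {
  # D5 = 55, D95 = 53 by the tie rule at exactly matching volumes
  cv <- dvhCurve(c(50, 53, 55, 56), c(1, 0.95, 0.05, 0))
  expect_equal(homogeneityIndex(cv, 54), 2 / 54 * 100, tolerance = 1e-9)
  # scaling curve and prescription together leaves HI unchanged
  cv2 <- dvhCurve(2 * c(50, 53, 55, 56), c(1, 0.95, 0.05, 0))
  expect_equal(homogeneityIndex(cv2, 108), homogeneityIndex(cv, 54),
               tolerance = 1e-9)
  expect_equal(homogeneityIndex(uniformDVH(54), 54), 0, tolerance = 1e-6)
  expect_error(homogeneityIndex(cv, 0), class = "dvhBadArgument")
})

test_that("inhomogeneity coefficient matches its definition", {
  # Dmax 56 (last nonzero point), Dmin 52 (still covering 100%), Dmean 54
  cv <- dvhCurve(c(52, 54, 56, 58), c(1, 0.45, 0.05, 0))
  expect_equal(dMax(cv), 56)
  expect_equal(dMin(cv), 52)
  expect_equal(dMean(cv), 0.55 * 53 + 0.4 * 55 + 0.05 * 57)  # 54
  expect_equal(inhomogeneityCoefficient(cv), 4 / 54, tolerance = 1e-9)
  expect_identical(inhomogeneityCoefficient(uniformDVH(54)), 0)
  cohort <- generateCohort(smallConfig(seed = 3, nPatients = 1))
  for (plan in cohort)
    expect_gte(inhomogeneityCoefficient(curves(plan)$ctv), 0)
})

test_that("integral dose is mean dose times absolute volume and additive", {
  cv <- logisticTestCurve(d50 = 10, g = 0.5, absVolume = 50)
  expect_equal(integralDose(cv), dMean(cv) * 50)
  dc <- dvhCurve(c(0, 10, 20), c(0.6, 0.4), kind = "differential",
                 absVolume = 50)
  expect_equal(integralDose(dc), 9 * 50)
  # partition at equal density: ID of the union = sum of part IDs
  part1 <- dvhCurve(c(0, 10, 20), c(0.6, 0.4), kind = "differential",
                    absVolume = 20)
  part2 <- dvhCurve(c(0, 10, 20), c(0.6, 0.4), kind = "differential",
                    absVolume = 30)
  expect_equal(integralDose(part1) + integralDose(part2), integralDose(dc))
  # (numerically) zero dose gives (numerically) zero integral dose
  zero <- dvhCurve(c(0, 1e-9), c(1, 0), absVolume = 100)
  expect_lt(integralDose(zero), 1e-6)
})

test_that("metricBattery covers the table layout and its invariants", {
  plan <- planSet(list(
    uniformDVH(54, structure = "ctv"),
    logisticTestCurve(d50 = 20, g = 0.4, structure = "hippocampus_ipsi",
                      absVolume = 1.3)),
    patientID = "P01", prescriptionDose = 54)
  m <- metricBattery(plan)
  ctv <- m[m$structure == "ctv", ]
  expect_setequal(ctv$metric, c("Dmean", "D1", "D95", "D99", "HI", "IC"))
  oar <- m[m$structure == "hippocampus_ipsi", ]
  expect_setequal(oar$metric, c("Dmean", "D1", "D50", "ID"))
  # uniform target: all D metrics equal, HI and IC zero
  v <- setNames(ctv$value, ctv$metric)
  expect_equal(unname(v["D1"]), unname(v["D95"]), tolerance = 1e-6)
  expect_equal(unname(v["D1"]), unname(v["Dmean"]), tolerance = 1e-6)
  expect_equal(unname(v["HI"]), 0, tolerance = 1e-6)
  expect_equal(unname(v["IC"]), 0, tolerance = 1e-6)
  # ordering invariants on a generated cohort
  cohort <- generateCohort(smallConfig(seed = 5, nPatients = 2))
  for (plan in cohort) {
    mm <- metricBattery(plan)
    for (s in unique(mm$structure)) {
      sub <- setNames(mm$value[mm$structure == s], mm$metric[mm$structure == s])
      if (s == "ctv") {
        expect_true(sub["D1"] >= sub["D95"] && sub["D95"] >= sub["D99"])
      } else {
        expect_true(sub["D1"] >= sub["D50"])
        expect_gte(sub["ID"], 0)
      }
    }
  }
})

test_that("volumeAtDose inverts the curve and clamps outside the grid", {
  cv <- dvhCurve(c(0, 20, 40), c(1, 0.5, 0))
  expect_equal(volumeAtDose(cv, 30), 0.25)
  expect_equal(volumeAtDose(cv, 0), 1)
  expect_equal(volumeAtDose(cv, 100), 0)
})
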