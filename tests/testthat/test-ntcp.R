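test_that("gEUD is the identity on uniform dose and the mean at n = 1", {
  for (n in c(0.1, 0.5, 1))
    expect_equal(geud(uniformDVH(54), n), 54, tolerance = 1e-9)
  half <- dvhCurve(c(15, 25, 35, 45), c(0.5, 0, 0.5), kind = "differential")
  expect_equal(geud(half, 1), 30)
  expect_equal(geud(half, 0.5), sqrt(0.5 * 20^2 + 0.5 * 40^2))  # 31.6228
  expect_error(geud(half, 0), class = "dvhBadArgument")
})

test_that("gEUD at n = 1 equals the mean dose to machine precision", {
  cohort <- generateCohort(smallConfig(seed = 17, nPatients = 2))
  for (plan in cohort[1:3]) {
    for (cv in curves(plan)) {
      expect_equal(geud(cv, 1), dMean(cv), tolerance = 1e-12)
      # power-mean bounds
      cum <- if (dvhKind(cv) == "cumulative") cv else
        differentialToCumulative(cv)
      # upper power-mean bound: highest bin midpoint is dMax + binWidth/2
      g <- geud(cv, 0.4)
      expect_lte(g, dMax(cum) + 0.05 + 1e-9)
      expect_gte(g, 0)
    }
  }
})

test_that("partial-volume tolerance dose follows TD50 v^-n", {
  tin <- lkbParameters("cochlea", "tinnitus", 46.52, 0.35, 1)
  expect_equal(toleranceDosePartial(tin, 1), 46.52)
  expect_equal(toleranceDosePartial(tin, 0.5), 93.04)
  vs <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(toleranceDosePartial(tin, vs)) <= 0))
  expect_error(toleranceDosePartial(tin, 0), class = "dvhBadArgument")
  expect_error(toleranceDosePartial(tin, 1.2), class = "dvhBadArgument")
})

test_that("the probit argument is centred at TD50 and linear in gEUD", {
  tin <- lkbParameters("cochlea", "tinnitus", 46.52, 0.35, 1)
  expect_equal(lkbT(46.52, tin), 0)
  expect_equal(lkbT(54, tin), (54 - 46.52) / (0.35 * 46.52))  # 0.459403
  g <- c(10, 30, 50)
  slopes <- diff(lkbT(g, tin)) / diff(g)
  expect_equal(slopes, rep(1 / (0.35 * 46.52), 2))
})

test_that("ntcpFromT is the standard normal CDF", {
  expect_identical(ntcpFromT(0), 0.5)
  expect_equal(ntcpFromT(-50), 0)
  expect_equal(ntcpFromT(50), 1)
  t0 <- (54 - 46.52) / (0.35 * 46.52)
  expect_equal(ntcpFromT(t0), pnorm(t0))
  expect_equal(ntcpFromT(t0), 0.67703, tolerance = 1e-4)
})

test_that("uniform whole-organ dose at TD50 gives exactly 50% NTCP", {
  for (p in defaultLKBParameters()) {
    rec <- ntcpFromDVH(uniformDVH(p@TD50), p)
    expect_identical(rec$ntcp, 0.5)
    expect_equal(rec$geud, p@TD50, tolerance = 1e-12)
  }
})

test_that("partial-volume and gEUD formulations of the LKB model agree", {
  params <- list(
    lkbParameters("cochlea", "tinnitus", 46.52, 0.35, 1),
    lkbParameters("cochlea", "hearing_loss", 55.57, 0.14, 1),
    lkbParameters("pituitary", "endocrine_dysfunction", 60.6, 0.08, 1),
    lkbParameters("generic", "toy", 40, 0.2, 0.7))
  for (p in params) {
    for (v in c(0.25, 0.5, 1)) {
      for (D in c(20, 40, 54)) {
        rec <- ntcpFromDVH(partialVolumeDVH(D, v), p)
        tdv <- toleranceDosePartial(p, v)
        direct <- pnorm((D - tdv) / (p@m * tdv))
        expect_equal(rec$ntcp, direct, tolerance = 1e-12)
        expect_equal(rec$geud, v^p@n * D, tolerance = 1e-12)
      }
    }
  }
})

test_that("an unirradiated pituitary has essentially zero NTCP", {
  pit <- defaultLKBParameters()[["pituitary.endocrine_dysfunction"]]
  zero <- dvhCurve(c(0, 1e-9), c(1, 0))
  rec <- ntcpFromDVH(zero, pit)
  expect_lt(rec$ntcp, 1e-20)  # Phi(-1/m) = Phi(-12.5)
})

test_that("NTCP increases when any part of the dose distribution increases", {
  tin <- defaultLKBParameters()[["cochlea.tinnitus"]]
  base <- dvhCurve(c(10, 20, 30, 40), c(0.3, 0.4, 0.3), kind = "differential")
  bumped <- dvhCurve(c(10, 20, 32, 42), c(0.3, 0.4, 0.3),
                     kind = "differential")
  expect_gt(ntcpFromDVH(bumped, tin)$ntcp, ntcpFromDVH(base, tin)$ntcp)
  # and strictly monotone in a uniform shift
  shifts <- vapply(c(0, 2, 4), function(s)
    ntcpFromDVH(uniformDVH(30 + s), tin)$ntcp, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("gEUD from the DVH matches a voxel-level brute force", {
  cfg <- smallConfig(seed = 19, nPatients = 1)
  plan <- generateCohort(cfg)[["P01_proton"]]
  ph <- generateVoxelPhantom(cfg, 1, "proton")
  for (s in structureNames(plan)) {
    cv <- curves(plan)[[s]]
    vox <- ph@doses[[s]]
    for (n in c(0.5, 1)) {
      gv <- mean(vox^(1 / n))^n
      expect_equal(geud(cv, n), gv, tolerance = 0.05,
                   ignore_attr = TRUE)
    }
  }
})

test_that("the shipped registry matches the published parameter table", {
  reg <- defaultLKBParameters()
  expect_length(reg, 3L)
  tin <- reg[["cochlea.tinnitus"]]
  expect_equal(c(tin@TD50, tin@m, tin@n), c(46.52, 0.35, 1))
  hl <- reg[["cochlea.hearing_loss"]]
  expect_equal(c(hl@TD50, hl@m, hl@n), c(55.57, 0.14, 1))
  pit <- reg[["pituitary.endocrine_dysfunction"]]
  expect_equal(c(pit@TD50, pit@m, pit@n), c(60.6, 0.08, 1))
  # registry files with missing columns are rejected
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(structure = "x", TD50_Gy = 1), f, row.names = FALSE)
  expect_error(readLKBParameters(f), class = "dvhMalformedHeader")
})

test_that("ntcpBattery maps inner ears to cochlea and pituitary to itself", {
  plan <- generateCohort(smallConfig(seed = 23, nPatients = 1))[["P01_helium"]]
  nt <- ntcpBattery(plan)
  expect_setequal(
    paste(nt$structure, nt$endpoint),
    c("inner_ear_ipsi tinnitus", "inner_ear_ipsi hearing_loss",
      "inner_ear_contra tinnitus", "inner_ear_contra hearing_loss",
      "pituitary endocrine_dysfunction"))
  expect_true(all(nt$ntcp >= 0 & nt$ntcp <= 1))
  # invalid parameter sets are rejected at construction
  expect_error(lkbParameters("x", "y", TD50 = -1, m = 0.1, n = 1))
  expect_error(lkbParameters("x", "y", TD50 = 10, m = 0.1, n = 1.5))
})

test_that("tolerance-dose anchor: gEUD at TD50 also passes through lkbT", {
  tin <- defaultLKBParameters()[["cochlea.tinnitus"]]
  expect_equal(ntcpFromT(lkbT(geud(uniformDVH(46.52), 1), tin)), 0.5,
               tolerance = 1e-12)
})
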