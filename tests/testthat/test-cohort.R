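test_that("a fixed seed reproduces the cohort exactly", {
  c1 <- generateCohort(cohortConfig(seed = 42, nPatients = 3))
  c2 <- generateCohort(cohortConfig(seed = 42, nPatients = 3))
  expect_identical(c1, c2)
  c3 <- generateCohort(cohortConfig(seed = 43, nPatients = 3))
  expect_false(identical(c1, c3))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generateCohort(cohortConfig(seed = 1, nPatients = 1)))
  expect_identical(runif(3), before)
})

test_that("identical modality profiles produce identical curves per patient", {
  coh <- generateCohort(cohortConfig(seed = 5, nPatients = 4,
                                     profiles = nullProfiles()))
  for (i in 1:4) {
    ph <- coh[[sprintf("P%02d_photon", i)]]
    pr <- coh[[sprintf("P%02d_proton", i)]]
    he <- coh[[sprintf("P%02d_helium", i)]]
    for (s in structureNames(ph)) {
      expect_identical(relVolume(curves(pr)[[s]]), relVolume(curves(ph)[[s]]))
      expect_identical(relVolume(curves(he)[[s]]), relVolume(curves(ph)[[s]]))
      expect_identical(absVolume(curves(he)[[s]]), absVolume(curves(ph)[[s]]))
    }
  }
})

test_that("every generated CTV satisfies the coverage constraint", {
  coh <- generateCohort(cohortConfig(seed = 1))
  expect_length(coh, 45L)
  for (plan in coh) {
    cv <- curves(plan)$ctv
    expect_gte(volumeAtDose(cv, 0.95 * prescriptionDose(plan)), 0.95)
  }
})

test_that("plans carry the full fraction schedule and all structures", {
  coh <- generateCohort(cohortConfig(seed = 2, nPatients = 2))
  for (plan in coh) {
    expect_identical(nFractions(plan) * dosePerFraction(plan),
                     prescriptionDose(plan))
    expect_setequal(structureNames(plan),
                    defaultStructureTable()$structure)
    for (cv in curves(plan)) {
      v <- relVolume(cv)
      expect_identical(v[1], 1)
      expect_true(all(diff(v) <= 0))
      expect_gt(absVolume(cv), 0)
    }
  }
})

test_that("a structure added to the table does not perturb other draws", {
  cfg1 <- cohortConfig(seed = 9, nPatients = 2)
  st <- defaultStructureTable()
  extra <- st[st$structure == "brainstem", ]
  extra$structure <- "chiasm"
  extra$d50 <- 30
  profs <- defaultModalityProfiles()
  for (m in names(profs))
    profs[[m]]@oarD50Factor <- c(profs[[m]]@oarD50Factor, chiasm = 1)
  cfg2 <- cohortConfig(seed = 9, nPatients = 2,
                       structureTable = rbind(st, extra), profiles = profs)
  c1 <- generateCohort(cfg1)
  c2 <- generateCohort(cfg2)
  for (nm in names(c1))
    for (s in structureNames(c1[[nm]]))
      expect_identical(relVolume(curves(c2[[nm]])[[s]]),
                       relVolume(curves(c1[[nm]])[[s]]))
})

test_that("a configured helium/proton D50 factor is recovered downstream", {
  # probe a structure configured clear of the prescription-truncation regime
  st <- defaultStructureTable()
  st$sdlog[st$structure == "hippocampus_contra"] <- 0.3
  profs <- defaultModalityProfiles()
  profs$helium@oarD50Factor["hippocampus_contra"] <- 0.75
  diffs <- NULL
  for (s in 1:5) {
    coh <- generateCohort(cohortConfig(seed = s, structureTable = st,
                                       profiles = profs))
    d50 <- vapply(coh, function(p)
      doseAtVolume(curves(p)$hippocampus_contra, 50), numeric(1))
    he <- d50[grepl("helium", names(d50))]
    pr <- d50[grepl("proton", names(d50))]
    diffs <- c(diffs, (he - pr) / pr * 100)
  }
  sem <- sd(diffs) / sqrt(length(diffs))
  expect_lte(abs(mean(diffs) + 25), 2 * sem)
})

test_that("the null-variability config gives an exact constant contrast", {
  st <- defaultStructureTable()
  st$sdlog[st$structure == "hippocampus_contra"] <- 0
  profs <- defaultModalityProfiles()
  profs$helium@oarD50Factor["hippocampus_contra"] <- 0.8
  coh <- generateCohort(cohortConfig(seed = 4, effectSdlog = 0,
                                     structureTable = st, profiles = profs))
  d50 <- vapply(coh, function(p)
    doseAtVolume(curves(p)$hippocampus_contra, 50), numeric(1))
  he <- d50[grepl("helium", names(d50))]
  pr <- d50[grepl("proton", names(d50))]
  diffs <- (he - pr) / pr * 100
  expect_equal(mean(diffs), -20, tolerance = 1e-2)
  expect_lt(sd(diffs) / sqrt(length(diffs)), 1e-2)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nPatients = 0))
  expect_error(cohortConfig(prescriptionDose = 50, nFractions = 30,
                            dosePerFraction = 1.8))
  expect_error(cohortConfig(binWidth = -1))
  profs <- defaultModalityProfiles()
  profs$helium@oarD50Factor <- profs$helium@oarD50Factor[1:3]
  expect_error(cohortConfig(profiles = profs))
})

test_that("voxel phantoms reproduce the generated curves", {
  cfg <- smallConfig(seed = 3, nPatients = 1)
  plan <- generateCohort(cfg)[["P01_helium"]]
  ph <- generateVoxelPhantom(cfg, "P01", "helium")
  expect_s4_class(ph, "VoxelPhantom")
  for (s in structureNames(plan)) {
    cv <- curves(plan)[[s]]
    vox <- ph@doses[[s]]
    # volume bookkeeping: count x voxel volume = structure volume
    expect_equal(length(vox) * ph@voxelVolume[[s]], absVolume(cv))
    # empirical volume-at-or-above matches the curve at every edge
    emp <- vapply(doseEdges(cv), function(d) mean(vox >= d - 1e-9),
                  numeric(1))
    expect_lt(max(abs(emp - relVolume(cv))), 0.01)
    # mean and median agree within half a bin width
    expect_equal(mean(vox), dMean(cv), tolerance = 0.05, ignore_attr = TRUE)
    expect_lt(abs(median(vox) - doseAtVolume(cv, 50)), 0.05)
  }
  # determinism without touching the RNG
  ph2 <- generateVoxelPhantom(cfg, 1, "helium")
  expect_identical(ph, ph2)
  expect_error(generateVoxelPhantom(cfg, 99, "helium"),
               class = "dvhBadArgument")
  expect_error(generateVoxelPhantom(cfg, 1, "neutron"),
               class = "dvhBadArgument")
})
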