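stackedRings <- function(sep = 3.8, tilt = 0) {
  ang <- (0:5) * pi / 3
  l1 <- vapply(1:6, function(k) {
    pdbLine(k, paste0("C", k), "UNL", "A", 1, 1.39 * cos(ang[k]),
            1.39 * sin(ang[k]), 0, "C", het = TRUE)
  }, "")
  rot <- rotationMatrix(c(1, 0, 0), tilt * pi / 180)
  l2 <- vapply(1:6, function(k) {
    p <- rot %*% c(1.39 * cos(ang[k]), 1.39 * sin(ang[k]), 0) + c(0, 0, sep)
    pdbLine(6 + k, paste0("C", k), "UNL", "B", 1, p[1], p[2], p[3], "C",
            het = TRUE)
  }, "")
  pdbText(c(l1, l2))
}

ringsOf <- function(txt) {
  perceiveRings(assignAtomTypes(readStructure(txt)))
}

test_that("pi-pi geometry is labelled by the folded interplanar angle", {
  rr <- ringRingInteractions(ringsOf(stackedRings(3.8, 0)))
  expect_equal(nrow(rr), 1)  # emitted once per unordered pair
  expect_equal(rr$theta, 0, tolerance = 1e-6)
  expect_equal(rr$geometry, "stacked")
  expect_equal(rr$distance, 3.8, tolerance = 1e-3)

  tee <- ringRingInteractions(ringsOf(stackedRings(5.0, 90)))
  expect_equal(tee$theta, 90, tolerance = 1e-6)
  expect_equal(tee$geometry, "t_shaped")

  tilted <- ringRingInteractions(ringsOf(stackedRings(4.5, 45)))
  expect_equal(tilted$geometry, "tilted")

  none <- ringRingInteractions(ringsOf(stackedRings(7, 0)))
  expect_equal(nrow(none), 0)
})

test_that("rotating a stacked ring about the centroid axis keeps theta at zero", {
  for (phi in c(13, 77, 131, 288)) {
    ang <- (0:5) * pi / 3 + phi * pi / 180
    l1 <- vapply(1:6, function(k) {
      pdbLine(k, paste0("C", k), "UNL", "A", 1, 1.39 * cos(ang[k] - phi * pi / 180),
              1.39 * sin(ang[k] - phi * pi / 180), 0, "C", het = TRUE)
    }, "")
    l2 <- vapply(1:6, function(k) {
      pdbLine(6 + k, paste0("C", k), "UNL", "B", 1, 1.39 * cos(ang[k]),
              1.39 * sin(ang[k]), 3.8, "C", het = TRUE)
    }, "")
    rr <- ringRingInteractions(ringsOf(pdbText(c(l1, l2))))
    expect_equal(rr$theta, 0, tolerance = 1e-6, info = phi)
  }
})

test_that("atom-ring subtypes follow flags and the over-the-face gate", {
  s <- assignAtomTypes(readStructure(makeFixture("cation_pi", "ideal")))
  ar <- atomRingInteractions(s, perceiveRings(s))
  expect_equal(nrow(ar), 1)
  expect_true(ar$cation_pi)  # Lys NZ is both cationic and a donor
  expect_true(ar$donor_pi)
  expect_false(ar$halogen_pi)

  # same atom moved into the ring plane: face gate rejects it
  txt <- sub("0\\.000(\\s+)3\\.500", "3.500\\10.000", makeFixture("cation_pi", "ideal"))
  s2 <- assignAtomTypes(readStructure(txt))
  expect_equal(nrow(atomRingInteractions(s2, perceiveRings(s2))), 0)

  # chlorine 10 degrees off-axis over a ring face: halogen-pi
  d <- 3.6
  off <- c(d * sin(10 * pi / 180), 0, d * cos(10 * pi / 180))
  ang <- (0:5) * pi / 3
  lines <- c(
    vapply(1:6, function(k) pdbLine(k, paste0("C", k), "UNL", "A", 1,
                                    1.39 * cos(ang[k]), 1.39 * sin(ang[k]), 0,
                                    "C", het = TRUE), ""),
    pdbLine(7, "CL1", "UNL", "B", 1, off[1], off[2], off[3], "CL", het = TRUE),
    pdbLine(8, "C1", "UNL", "B", 1, off[1], off[2], off[3] + 1.77, "C",
            het = TRUE))
  s3 <- assignAtomTypes(readStructure(pdbText(lines)))
  ar3 <- atomRingInteractions(s3, perceiveRings(s3))
  expect_true(any(ar3$halogen_pi))
  cl_row <- ar3[grepl("CL1", ar3$atom_id), ]
  expect_equal(cl_row$theta, 10, tolerance = 1e-3)  # 3-decimal PDB coords
})

test_that("amide group interactions respect their centroid gates", {
  det <- function(s, v) detectedSubtypes(calculateInteractions(makeFixture(s, v)))
  expect_true(det("amide_amide", "ideal")["amide_amide"])
  expect_true(det("amide_ring", "ideal")["amide_ring"])
  expect_false(det("amide_amide", "boundary_fail")["amide_amide"])
  # 6 A separation: beyond both gates
  s <- assignAtomTypes(readStructure(makeFixture("amide_amide", "ideal")))
  am <- perceiveAmides(s)
  cfg <- defaultGeometryConfig()
  shifted <- am
  shifted$cz[2] <- 6
  expect_equal(nrow(amideGroupInteractions(shifted, ringsOf(stackedRings())[0, ], cfg)), 0)
})

test_that("methionine sulphur-aromatic interactions are Met-specific by default", {
  res <- calculateInteractions(makeFixture("met_aromatic", "ideal"))
  mr <- res@metInteractions
  expect_equal(nrow(mr), 1)
  expect_equal(mr$distance, 5.0, tolerance = 1e-3)
  expect_equal(mr$elevation, 90, tolerance = 1e-6)  # on-axis placement

  # 6.5 A: beyond the gate
  far <- sub("5\\.000$|5\\.000\\s", "6.500 ", makeFixture("met_aromatic", "ideal"))
  txt <- makeFixture("met_aromatic", "ideal")
  txt <- sub("   5.000", "   6.500", txt)
  expect_equal(nrow(calculateInteractions(txt)@metInteractions), 0)

  # Cys SG is excluded by default, included when configured
  cys <- gsub("SD  MET", "SG  CYS", makeFixture("met_aromatic", "ideal"))
  expect_equal(nrow(calculateInteractions(cys)@metInteractions), 0)
  cfg <- defaultGeometryConfig()
  cfg@options$sulphur_aromatic_residues <- c("MET", "CYS")
  expect_equal(nrow(calculateInteractions(cys, config = cfg)@metInteractions), 1)
})

test_that("pure rigid motion changes no interaction", {
  cfg <- defaultGeometryConfig()
  rot <- rotationMatrix(c(1, 2, 3), 1.1)
  for (s in c("pi_pi", "cation_pi", "amide_ring", "hbond", "xbond")) {
    s0 <- readStructure(makeFixture(s, "ideal"))
    s1 <- transformStructure(s0, rot, c(11, -4, 7))
    r0 <- calculateInteractions(s0)
    r1 <- calculateInteractions(s1)
    expect_equal(r1@summary$count, r0@summary$count, info = s)
    expect_equal(contacts(r1)$distance, contacts(r0)$distance,
                 tolerance = 1e-9, info = s)
  }
})
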