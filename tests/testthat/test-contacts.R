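test_that("the 5-Angstrom cutoff is a sharp boundary for pair enumeration", {
  near <- rbind(c(0, 0, 0), c(4.99, 0, 0))
  far <- rbind(c(0, 0, 0), c(5.01, 0, 0))
  expect_equal(nrow(neighborPairs(near)), 1)
  expect_equal(nrow(neighborPairs(far)), 0)
  expect_equal(nrow(neighborPairs(matrix(c(0, 0, 0), 1))), 0)
})

test_that("grid pair enumeration equals the brute-force double loop", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:60, 1)
    xyz <- matrix(runif(3 * n, 0, sample(c(6, 12, 25), 1)), ncol = 3)
    got <- neighborPairs(xyz, cutoff = 5)
    want <- bruteForcePairs(xyz, 5)
    expect_equal(got$i, want$i, info = seed)
    expect_equal(got$j, want$j, info = seed)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("distance classification matches interval arithmetic on the radii tables", {
  cfg <- defaultGeometryConfig()
  rad <- function(el) lookupRadii(el, cfg)
  # C-C at exactly the covalent-radius sum
  expect_equal(classifyDistance(2 * rad("C")$cov, "C", "C"), "covalent")
  # O...O 0.2 A inside the vdW sum
  expect_equal(classifyDistance(2 * rad("O")$vdw - 0.2, "O", "O"), "vdw_clash")
  # beyond vdW + compensation but inside the cutoff
  expect_equal(classifyDistance(4.9, "O", "O"), "proximal")
  # independent interval oracle across a distance sweep and element pairs
  for (pair in list(c("C", "C"), c("N", "O"), c("S", "CL"))) {
    ra <- rad(pair[1]); rb <- rad(pair[2])
    rcov <- ra$cov + rb$cov; rvdw <- ra$vdw + rb$vdw
    tol <- cfg@thresholds[["cov_tol"]]
    d <- seq(0.5, 5, by = 0.01)
    oracle <- ifelse(d < rcov - tol, "clash",
               ifelse(d <= rcov + tol, "covalent",
                ifelse(d < rvdw, "vdw_clash",
                 ifelse(d <= rvdw + 0.1, "vdw", "proximal"))))
    expect_equal(classifyDistance(d, pair[1], pair[2]), oracle)
  }
  expect_error(classifyDistance(2, "XX", "C"), "XX")
})

test_that("hydrogen-bond geometry needs distance and near-linearity", {
  donor <- c(0, 0, 0)
  h <- matrix(c(0.96, 0, 0), 1)
  expect_true(detectHbond(donor, h, c(2.9, 0, 0)))            # linear, 2.9 A
  # H rotated so the D-H...A angle collapses to 60 degrees
  h_bent <- matrix(2.9 / 2 * c(1, tan(pi / 3) / 1, 0), 1)
  h_bent <- matrix(c(1.2, 1.8, 0), 1)
  ang <- pdbSIFt:::.angleDeg(donor - h_bent[1, ], c(2.9, 0, 0) - h_bent[1, ])
  expect_lt(ang, 90)
  expect_false(detectHbond(donor, h_bent, c(2.9, 0, 0)))
  expect_false(detectHbond(donor, h, c(4.5, 0, 0)))           # beyond maximum
  expect_false(detectHbond(donor, NULL, c(2.9, 0, 0)))        # no hydrogens
})

test_that("polar contacts are the angle-free superset of hydrogen bonds", {
  res <- calculateInteractions(makeFixture("polar", "ideal"))
  cc <- contacts(res)
  expect_true(any(cc$polar))
  expect_false(any(cc$hbond))  # no hydrogens modelled
  res2 <- calculateInteractions(makeFixture("hbond", "ideal"))
  cc2 <- contacts(res2)
  hb <- cc2[cc2$hbond, ]
  expect_true(all(hb$polar))   # hbond implies polar at this distance
})

test_that("halogen bonds require sigma-hole directionality", {
  cfg <- defaultGeometryConfig()
  cl <- c(0, 0, 0); c_at <- c(-1.77, 0, 0)
  expect_true(detectXbond(cl, c_at, c(3.2, 0.2, 0), cfg))   # ~175 degrees
  expect_false(detectXbond(cl, c_at, c(0, 3.2, 0), cfg))    # 90 degrees
  expect_false(detectXbond(cl, c_at, c(5, 0, 0), cfg))      # too far
  # fluorine never donates: full-pipeline check
  txt <- pdbText(
    pdbLine(1, "C1", "UNL", "A", 1, 0, 0, 0, "C", het = TRUE),
    pdbLine(2, "F1", "UNL", "A", 1, 1.35, 0, 0, "F", het = TRUE),
    pdbLine(3, "O", "HOH", "B", 1, 1.35 + 2.9, 0, 0, "O", het = TRUE))
  expect_false(any(contacts(calculateInteractions(txt))$xbond))
})

test_that("simple feature detectors respect their distance gates", {
  det <- function(s, v) detectedSubtypes(calculateInteractions(makeFixture(s, v)))
  expect_true(det("ionic", "ideal")["ionic"])
  expect_true(det("metal", "ideal")["metal"])
  expect_true(det("carbonyl", "ideal")["carbonyl"])
  expect_true(det("hydrophobic", "ideal")["hydrophobic"])
  expect_false(det("hydrophobic", "boundary_fail")["hydrophobic"])
  expect_false(det("ionic", "boundary_fail")["ionic"])
})

test_that("contacts are symmetric in atom order and exclude intra-residue pairs", {
  # reversing the file order of the two interacting groups changes nothing
  fwd <- makeFixture("ionic", "ideal")
  lines <- strsplit(fwd, "\n")[[1]]
  atom_lines <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  rev_txt <- paste(c(rev(atom_lines), "END"), collapse = "\n")
  c1 <- contacts(calculateInteractions(fwd))
  c2 <- contacts(calculateInteractions(rev_txt))
  expect_equal(contactSignature(c1), contactSignature(c2))

  # bonded atoms within one residue are never reported
  cc <- contacts(calculateInteractions(glyGlyText()))
  a <- atoms(readStructure(glyGlyText()))
  expect_true(all(a$res_index[cc$i] != a$res_index[cc$j]))
})

test_that("cross-residue 1-2/1-3 bonded pairs carry no feature bits", {
  cc <- contacts(calculateInteractions(glyGlyText()))
  # C(1)-N(2) peptide bond and its 1-3 neighbours appear distance-classified
  bonded <- cc[cc$atom_a == "A/1/C" & cc$atom_b == "A/2/N", ]
  expect_equal(nrow(bonded), 1)
  expect_equal(bonded$distance_class, "covalent")
  expect_false(any(as.logical(bonded[, FEATURE_BITS])))
  one3 <- cc[cc$atom_a == "A/1/O" & cc$atom_b == "A/2/N", ]
  expect_false(any(as.logical(one3[, FEATURE_BITS])))
})

test_that("shrinking a feature-distance maximum never adds a feature bit", {
  cfg <- defaultGeometryConfig()
  shrinkable <- c("hbond_dist_max", "polar_dist_max", "weak_polar_dist_max",
                  "ionic_dist_max", "metal_dist_max", "carbonyl_dist_max",
                  "hydrophobic_dist_max", "aromatic_dist_max")
  for (s in c("hbond", "ionic", "metal", "carbonyl", "hydrophobic",
              "aromatic", "polar", "weak_polar")) {
    base <- contacts(calculateInteractions(makeFixture(s, "ideal")))
    for (th in shrinkable) {
      cfg2 <- cfg
      cfg2@thresholds[[th]] <- max(0.5, cfg@thresholds[[th]] - 1.0)
      cc2 <- contacts(calculateInteractions(makeFixture(s, "ideal", cfg),
                                            config = cfg2))
      for (b in FEATURE_BITS) {
        expect_true(sum(cc2[[b]]) <= sum(base[[b]]),
                    info = paste(s, th, b))
      }
    }
  }
})
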