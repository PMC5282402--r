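typed <- function(txt, ...) assignAtomTypes(readStructure(txt), ...)

flagsOf <- function(s, name, res = NULL) {
  a <- atoms(s)
  keep <- a$name == name
  if (!is.null(res)) keep <- keep & a$res_name == res
  ATOM_FLAGS[typeFlags(s)[which(keep)[1], ]]
}

test_that("hydroxyl, carboxylate and backbone atoms get their dictionary types", {
  ser <- typed(pdbText(pdbLine(1, "CB", "SER", "A", 5, 0, 0, 0, "C"),
                       pdbLine(2, "OG", "SER", "A", 5, 1.42, 0, 0, "O")))
  expect_setequal(intersect(flagsOf(ser, "OG"),
                            c("hbond_donor", "hbond_acceptor")),
                  c("hbond_donor", "hbond_acceptor"))

  asp <- typed(pdbText(pdbLine(1, "CG", "ASP", "A", 1, 0, 0, 0, "C"),
                       pdbLine(2, "OD1", "ASP", "A", 1, 1.25, 0, 0, "O"),
                       pdbLine(3, "OD2", "ASP", "A", 1, -0.6, 1.1, 0, "O")))
  for (nm in c("OD1", "OD2")) {
    fl <- flagsOf(asp, nm)
    # the lenient carboxyl rule: still an acceptor despite the carboxylate
    expect_true(all(c("hbond_acceptor", "neg_ionisable") %in% fl), info = nm)
    expect_false("hbond_donor" %in% fl, info = nm)
  }

  gg <- typed(glyGlyText())
  expect_true("hbond_donor" %in% flagsOf(gg, "N"))
  fl_o1 <- ATOM_FLAGS[typeFlags(gg)[4, ]]  # internal-side carbonyl O
  expect_true(all(c("hbond_acceptor", "carbonyl_oxygen") %in% fl_o1))
  expect_true("carbonyl_carbon" %in% ATOM_FLAGS[typeFlags(gg)[3, ]])
})

test_that("hetero-group typing follows connectivity rules (chlorobenzene)", {
  s <- typed(chlorobenzeneText())
  cl <- flagsOf(s, "CL1")
  expect_true(all(c("halogen", "xbond_donor", "hydrophobe") %in% cl))
  # ring perceived aromatic; ring carbons are weak donors and hydrophobes
  expect_true(all(typeFlags(s)[1:6, "aromatic"]))
  expect_true(all(typeFlags(s)[2:6, "weak_donor"]))
  rings <- perceiveRings(s)
  expect_equal(nrow(rings), 1)
  expect_equal(rings$size, 6)
})

test_that("fluorine is never a halogen-bond donor", {
  txt <- pdbText(pdbLine(1, "C1", "UNL", "A", 1, 0, 0, 0, "C", het = TRUE),
                 pdbLine(2, "F1", "UNL", "A", 1, 1.35, 0, 0, "F", het = TRUE))
  s <- typed(txt)
  fl <- flagsOf(s, "F1")
  expect_true("halogen" %in% fl)
  expect_false("xbond_donor" %in% fl)
})

test_that("terminal correction types a lone C-terminal O as carboxylate, not hydroxyl", {
  gg <- typed(glyGlyText())
  fl_o2 <- ATOM_FLAGS[typeFlags(gg)[8, ]]  # C-terminal O, OXT missing
  expect_true(all(c("hbond_acceptor", "neg_ionisable") %in% fl_o2))
  expect_false("hbond_donor" %in% fl_o2)
  expect_false("carbonyl_oxygen" %in% fl_o2)
  # N-terminal amine is positively ionisable
  expect_true(all(c("hbond_donor", "pos_ionisable") %in%
                  ATOM_FLAGS[typeFlags(gg)[1, ]]))
})

test_that("N-terminal proline N is positive but donates only with an H", {
  noH <- typed(pdbText(pdbLine(1, "N", "PRO", "A", 1, 0, 0, 0, "N"),
                       pdbLine(2, "CA", "PRO", "A", 1, 1.47, 0, 0, "C")))
  expect_true("pos_ionisable" %in% flagsOf(noH, "N"))
  expect_false("hbond_donor" %in% flagsOf(noH, "N"))
  withH <- typed(pdbText(pdbLine(1, "N", "PRO", "A", 1, 0, 0, 0, "N"),
                         pdbLine(2, "CA", "PRO", "A", 1, 1.47, 0, 0, "C"),
                         pdbLine(3, "H", "PRO", "A", 1, -0.5, 0.87, 0, "H")))
  expect_true("hbond_donor" %in% flagsOf(withH, "N"))
})

test_that("terminal correction leaves non-terminal atoms untouched", {
  s0 <- assignAtomTypes(readStructure(glyGlyText()), correctTermini = FALSE)
  s1 <- assignAtomTypes(readStructure(glyGlyText()), correctTermini = TRUE)
  internal <- 2:6  # CA/C/O of residue 1, N/CA of residue 2
  expect_equal(typeFlags(s1)[internal, ], typeFlags(s0)[internal, ])
})

test_that("histidine leniency toggles ring-nitrogen donor/acceptor symmetrically", {
  strict <- typed(hisRingText(withHD1 = FALSE), lenient = FALSE)
  lenient <- typed(hisRingText(withHD1 = FALSE), lenient = TRUE)
  for (nm in c("ND1", "NE2")) {
    expect_false("hbond_donor" %in% flagsOf(strict, nm), info = nm)
    expect_true("hbond_acceptor" %in% flagsOf(strict, nm), info = nm)
    expect_true(all(c("hbond_donor", "hbond_acceptor") %in%
                    flagsOf(lenient, nm)), info = nm)
  }
  # explicit HD1, lenient off: ND1 donor, NE2 acceptor
  prot <- typed(hisRingText(withHD1 = TRUE), lenient = FALSE)
  expect_true("hbond_donor" %in% flagsOf(prot, "ND1"))
  expect_false("hbond_acceptor" %in% flagsOf(prot, "ND1"))
  expect_true("hbond_acceptor" %in% flagsOf(prot, "NE2"))
  # non-His residues unaffected by the switch
  ser <- pdbText(pdbLine(1, "CB", "SER", "A", 1, 0, 0, 0, "C"),
                 pdbLine(2, "OG", "SER", "A", 1, 1.42, 0, 0, "O"))
  expect_equal(typeFlags(typed(ser, lenient = TRUE)),
               typeFlags(typed(ser, lenient = FALSE)))
})

test_that("typing is idempotent", {
  for (txt in list(glyGlyText(), chlorobenzeneText(),
                   makeFixture("ionic", "ideal"))) {
    s1 <- typed(txt)
    s2 <- assignAtomTypes(s1)
    expect_equal(typeFlags(s2), typeFlags(s1))
  }
})

test_that("the dictionary covers every heavy atom of the 20 amino acids", {
  dict <- loadTypingDictionary()
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (res in names(AA_SIDECHAIN_ATOMS)) {
    for (at in c(backbone, AA_SIDECHAIN_ATOMS[[res]])) {
      entry <- pdbSIFt:::.dictLookup(dict, res, at, "peptide")
      expect_false(is.null(entry), info = paste(res, at))
    }
  }
})

test_that("metal flags are exclusive with all other flags", {
  s <- typed(makeFixture("metal", "ideal"))
  a <- atoms(s)
  zn <- which(a$element == "ZN")
  expect_true(typeFlags(s)[zn, "metal"])
  expect_equal(sum(typeFlags(s)[zn, ]), 1)
})
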