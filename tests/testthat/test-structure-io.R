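test_that("a Gly-Gly dipeptide parses into one linked chain with marked termini", {
  s <- readStructure(glyGlyText())
  r <- residues(s)
  expect_equal(nrow(atoms(s)), 8)
  expect_equal(unique(atoms(s)$chain_id), "A")
  expect_equal(r$polymer_class, c("peptide", "peptide"))
  expect_equal(r$terminal, c("n_term", "c_term"))
  # every record maps to exactly one atom, none dropped
  expect_equal(nrow(s@dropped), 0)
})

test_that("alternate locations resolve to highest occupancy, ties alphabetical", {
  txt <- pdbText(
    pdbLine(1, "N", "SER", "A", 1, 0, 0, 0, "N"),
    pdbLine(2, "CA", "SER", "A", 1, 1.45, 0, 0, "C", alt = "A", occ = 0.6),
    pdbLine(3, "CA", "SER", "A", 1, 1.5, 0.1, 0, "C", alt = "B", occ = 0.4))
  s <- readStructure(txt)
  a <- atoms(s)
  expect_equal(nrow(a), 2)
  expect_equal(a$alt_loc[a$name == "CA"], "A")
  expect_equal(s@dropped$reason, "alternate location 'B' not selected")

  tie <- pdbText(
    pdbLine(1, "CA", "SER", "A", 1, 1.45, 0, 0, "C", alt = "B", occ = 0.5),
    pdbLine(2, "CA", "SER", "A", 1, 1.5, 0.1, 0, "C", alt = "A", occ = 0.5))
  expect_equal(atoms(readStructure(tie))$alt_loc, "A")
})

test_that("multi-model files yield the requested model's records only", {
  m1 <- c(pdbLine(1, "O1", "UNL", "A", 1, 0, 0, 0, "O", het = TRUE),
          pdbLine(2, "O1", "UNL", "B", 1, 3, 0, 0, "O", het = TRUE))
  m2 <- c(pdbLine(1, "O1", "UNL", "A", 1, 9, 9, 9, "O", het = TRUE),
          pdbLine(2, "O1", "UNL", "B", 1, 12, 9, 9, "O", het = TRUE),
          pdbLine(3, "O1", "UNL", "C", 1, 15, 9, 9, "O", het = TRUE))
  txt <- paste(c("MODEL        1", m1, "ENDMDL",
                 "MODEL        2", m2, "ENDMDL", "END"), collapse = "\n")
  s1 <- readStructure(txt, model = 1)
  s2 <- readStructure(txt, model = 2)
  # expected counts from a plain text scan of each MODEL block
  expect_equal(nrow(atoms(s1)), sum(grepl("^HETATM", m1)))
  expect_equal(nrow(atoms(s2)), sum(grepl("^HETATM", m2)))
  expect_equal(atoms(s2)$x[1], 9)
  expect_error(readStructure(txt, model = 3), "2 model")
})

test_that("parsing fails cleanly without atoms and on malformed selections", {
  expect_error(readStructure("HEADER    NOTHING\nEND"), "no ATOM or HETATM")
  expect_error(parseSelection("/A/1"), "malformed selection item")
  expect_error(parseSelection("A//"), "malformed selection item")
})

test_that("selection resolution equals brute-force predicate filtering", {
  rnd <- randomStructureText(30, seed = 7)
  txt <- paste(sub("END$", "", rnd$text),
               paste(glyGlyText(), collapse = "\n"), sep = "")
  s <- readStructure(txt)
  a <- atoms(s)
  oracle <- function(chain, res, atom) {
    keep <- rep(TRUE, nrow(a))
    if (nzchar(chain)) keep <- keep & a$chain_id == chain
    if (nzchar(res)) keep <- keep & a$res_seq == as.integer(res)
    if (nzchar(atom)) keep <- keep & a$name == atom
    which(keep)
  }
  cases <- list(c("A", "", ""), c("", "2", ""), c("A", "2", "CA"),
                c("B", "", ""), c("", "", "O1"))
  for (cs in cases) {
    expr <- paste0("/", cs[1], "/", cs[2], "/", cs[3])
    expect_equal(resolveSelection(expr, s), oracle(cs[1], cs[2], cs[3]),
                 info = expr)
  }
  # union of items
  expect_equal(resolveSelection("/A/2/ /B//", s),
               sort(union(oracle("A", "2", ""), oracle("B", "", ""))))
  # absent atom -> empty set, not an error
  expect_length(resolveSelection("/Q/999/XX", s), 0)
})

test_that("entity detection equals hetero connected components plus polymer chains", {
  # protein chain + covalently linked 2-residue hetero group + waters
  lig <- c(pdbLine(9, "C1", "LG1", "B", 1, 10, 0, 0, "C", het = TRUE),
           pdbLine(10, "O1", "LG1", "B", 1, 11.4, 0, 0, "O", het = TRUE),
           pdbLine(11, "C1", "LG2", "B", 2, 12.8, 0, 0, "C", het = TRUE))
  wat <- vapply(1:5, function(k) {
    pdbLine(20 + k, "O", "HOH", "W", k, 30 + 3 * k, 0, 0, "O", het = TRUE)
  }, "")
  txt <- paste(c(strsplit(glyGlyText(), "\n")[[1]][1:8], lig, wat, "END"),
               collapse = "\n")
  ents <- detectEntities(readStructure(txt))
  expect_length(ents, 2)
  expect_setequal(vapply(ents, `[[`, "", "kind"),
                  c("polymer_chain", "hetero_group"))
  het <- ents[[which(vapply(ents, `[[`, "", "kind") == "hetero_group")]]
  expect_length(het$atoms, 3)  # the linked LG1+LG2 component, waters excluded

  # water-only file has no entities
  expect_length(detectEntities(readStructure(pdbText(wat))), 0)

  # random hetero cloud: oracle = connected components of the
  # covalent-distance graph (union-find over radii sums + tolerance)
  rnd <- randomStructureText(40, box = 18, seed = 11)
  s <- readStructure(rnd$text)
  cfg <- defaultGeometryConfig()
  radii <- lookupRadii(atoms(s)$element, cfg)
  n <- nrow(atoms(s))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  xyz <- cbind(atoms(s)$x, atoms(s)$y, atoms(s)$z)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= radii$cov[i] + radii$cov[j] + 0.45 && d > 0.4) {
      parent[find(i)] <- find(j)
    }
  }
  expected_components <- length(unique(vapply(seq_len(n), find, 0L)))
  expect_length(detectEntities(s), expected_components)
})
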