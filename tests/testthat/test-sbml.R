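test_that("SBML write/read round trip preserves ids, bounds, stoichiometry and GPR", {
  m <- makeToyModel(routeLengths = c(2, 3), includeDeadEnd = TRUE,
                    reversibleFraction = 0.4, seed = 3)
  f <- tempfile(fileext = ".xml")
  writeSBML(m, f)
  m2 <- readSBML(f)
  expect_identical(reactionIds(m2), reactionIds(m))
  expect_identical(metaboliteIds(m2), metaboliteIds(m))
  expect_equal(bounds(m2)$lb, bounds(m)$lb, tolerance = 1e-9)
  expect_equal(bounds(m2)$ub, bounds(m)$ub, tolerance = 1e-9)
  expect_equal(max(abs(as.matrix(stoichiometry(m2)) -
                       as.matrix(stoichiometry(m)))), 0, tolerance = 1e-9)
  r1 <- gprRules(m); r2 <- gprRules(m2)
  for (id in reactionIds(m))
    expect_equal(r2[[id]], r1[[id]], info = id)
})

test_that("reactions without GPR come back with an absent rule, not an empty one", {
  m <- makeToyModel(routeLengths = 2)
  f <- tempfile(fileext = ".xml")
  writeSBML(m, f)
  m2 <- readSBML(f)
  expect_null(gprRules(m2)[["UPT"]])
  expect_null(gprRules(m2)[["SEC"]])
  expect_false(is.null(gprRules(m2)[["R1_1"]]))
})

test_that("a nested fbc gene association parses into the expected tree", {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("a_c", "b_c")),
    reactions = data.frame(id = c("IN", "R", "OUT"), lb = 0, ub = 10,
                           gpr = c(NA, "(g1 and g2) or g3", NA)),
    S = matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE))
  f <- tempfile(fileext = ".xml")
  writeSBML(m, f)
  rule <- gprRules(readSBML(f))[["R"]]
  expect_equal(rule, list(op = "or",
                          children = list(list(op = "and",
                                               children = list("g1", "g2")),
                                          "g3")))
})

test_that("level 2 files with notes-encoded GPR and kineticLaw bounds are read", {
  l2 <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="toy">',
    '<listOfSpecies>',
    '<species id="a_c" compartment="c"/>',
    '<species id="b_c" compartment="c"/>',
    '<species id="a_b" compartment="b" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="IN" reversible="true">',
    '<listOfReactants><speciesReference species="a_b"/></listOfReactants>',
    '<listOfProducts><speciesReference species="a_c"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-5"/>',
    '<parameter id="UPPER_BOUND" value="7"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="R1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: g1 or g2</p>',
    '</body></notes>',
    '<listOfReactants><speciesReference species="a_c"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b_c" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  f <- tempfile(fileext = ".xml")
  writeLines(l2, f)
  m <- readSBML(f)
  expect_identical(reactionIds(m), c("IN", "R1"))
  # boundary species dropped
  expect_identical(metaboliteIds(m), c("a_c", "b_c"))
  b <- bounds(m)
  expect_equal(b$lb, c(-5, 0))
  expect_equal(b$ub, c(7, 1000))
  expect_equal(gprRules(m)[["R1"]], list(op = "or",
                                         children = list("g1", "g2")))
  expect_equal(as.numeric(stoichiometry(m)["b_c", "R1"]), 2)
})

test_that("unreadable or degenerate SBML raises a named error", {
  expect_error(readSBML(tempfile()), "cannot read")
  f <- tempfile(fileext = ".xml")
  writeLines("<notxml", f)
  expect_error(readSBML(f), "cannot parse")
  f2 <- tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>',
               '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core">',
               '<model id="x"/></sbml>'), f2)
  expect_error(readSBML(f2), "listOfReactions")
})

test_that("writing the same model twice is byte-identical", {
  m <- makeToyModel(routeLengths = c(2, 2), reversibleFraction = 0.5, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  writeSBML(m, f1); writeSBML(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
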