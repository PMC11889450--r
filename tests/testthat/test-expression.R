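writeExprFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("expression tables parse with optional header, NA skipping and duplicate collapsing", {
  p <- readExpression(writeExprFile(c("gene\tvalue", "g1\t1.5", "g2\t-2",
                                      "g3\t0")), mode = "foldchange")
  expect_equal(p@values, c(g1 = 1.5, g2 = -2, g3 = 0))
  expect_equal(p@mode, "foldchange")

  # no header
  p2 <- readExpression(writeExprFile(c("g1\t1", "g2\t2")), "absolute")
  expect_length(p2@values, 2)

  expect_warning(
    p3 <- readExpression(writeExprFile(c("g1\t2", "g1\t4", "g2\t1")),
                         "foldchange"),
    "duplicate")
  expect_equal(unname(p3@values["g1"]), 3)

  expect_warning(
    p4 <- readExpression(writeExprFile(c("g1\t1", "g2\tNA", "g3\t2")),
                         "foldchange"),
    "NA")
  expect_equal(names(p4@values), c("g1", "g3"))
})

test_that("malformed expression tables raise located errors", {
  expect_error(readExpression(writeExprFile(c("g1\t1", "g2\tabc")),
                              "foldchange"), "line 2.*abc")
  f <- tempfile(); writeLines(character(), f)
  expect_error(readExpression(f, "foldchange"), "empty")
  expect_error(readExpression(writeExprFile("justonefield"), "foldchange"),
               "two tab-separated")
})

test_that("gene-id mapping is applied before duplicate collapsing", {
  mapFile <- tempfile()
  writeLines(c("locus1\tg1", "locus2\tg1"), mapFile)
  expect_warning(
    p <- readExpression(writeExprFile(c("locus1\t2", "locus2\t4",
                                        "other\t1")),
                        "foldchange", mapping = mapFile),
    "duplicate")
  expect_equal(unname(p@values["g1"]), 3)
  expect_true("other" %in% names(p@values))
})

test_that("relative-mode regulation sets apply the +/- theta rule", {
  m <- MetabolicModel(
    metabolites = data.frame(id = c("a_c", "b_c")),
    reactions = data.frame(id = c("r1", "r2", "r3", "r4"),
                           lb = 0, ub = 10,
                           gpr = c("g1", "g2", "g3", NA)),
    S = matrix(c(1, -1, 1, -1, 0, 1, -1, 1), nrow = 2, byrow = TRUE))
  prof <- methods::new("ExpressionProfile", mode = "foldchange",
                       values = c(g1 = 2, g2 = -1.5, g3 = 0.2))
  s <- regulationSets(m, prof)
  expect_equal(s@up, "r1")
  expect_equal(s@down, "r2")
  expect_length(s@universe, 4)          # r4 (no GPR) stays in N as neutral
  expect_equal(sort(setdiff(s@universe, c(s@up, s@down))), c("r3", "r4"))

  # all-zero profile: no calls
  prof0 <- methods::new("ExpressionProfile", mode = "foldchange",
                        values = c(g1 = 0, g2 = 0, g3 = 0))
  s0 <- regulationSets(m, prof0)
  expect_length(s0@up, 0)
  expect_length(s0@down, 0)

  # restricting the universe to valued reactions drops r4
  sv <- regulationSets(m, prof, universe = "valued")
  expect_length(sv@universe, 3)
})

test_that("absolute-mode percentile calls match the quantile oracle", {
  m <- MetabolicModel(
    metabolites = data.frame(id = "a_c"),
    reactions = data.frame(id = paste0("r", 1:8), lb = 0, ub = 10,
                           gpr = paste0("g", 1:8)),
    S = matrix(rep(c(1, -1), 4), nrow = 1))
  vals <- c(10, 40, 20, 80, 60, 30, 70, 50)
  prof <- methods::new("ExpressionProfile", mode = "absolute",
                       values = stats::setNames(vals, paste0("g", 1:8)))
  s <- regulationSets(m, prof)
  qHi <- stats::quantile(vals, 0.75, type = 7, names = FALSE)
  qLo <- stats::quantile(vals, 0.25, type = 7, names = FALSE)
  expect_setequal(s@up, paste0("r", which(vals >= qHi)))
  expect_setequal(s@down, paste0("r", which(vals <= qLo)))
  expect_length(s@up, 2)
  expect_length(s@down, 2)
})

test_that("mode and threshold arguments must agree", {
  m <- makeToyModel(routeLengths = 2)
  rel <- methods::new("ExpressionProfile", mode = "foldchange",
                      values = c(g1_1 = 1))
  abs <- methods::new("ExpressionProfile", mode = "absolute",
                      values = c(g1_1 = 1))
  expect_error(regulationSets(m, rel, highPct = 90), "absolute mode only")
  expect_error(regulationSets(m, abs, upCutoff = 2), "relative mode only")
})

test_that("the partition invariant holds and negation swaps up and down", {
  set.seed(33)
  for (i in 1:10) {
    m <- makeToyModel(routeLengths = sample(1:3, sample(2:3, 1),
                                            replace = TRUE))
    genes <- modelGenes(m)
    vals <- stats::setNames(rnorm(length(genes), 0, 1.5), genes)
    prof <- methods::new("ExpressionProfile", mode = "foldchange",
                         values = vals)
    s <- regulationSets(m, prof)
    expect_length(intersect(s@up, s@down), 0)
    expect_equal(length(s@universe), nrow(m@reactions))
    neg <- methods::new("ExpressionProfile", mode = "foldchange",
                        values = -vals)
    sn <- regulationSets(m, neg)
    expect_setequal(sn@up, s@down)
    expect_setequal(sn@down, s@up)
  }
})
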