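test_that("the MILP has gated coupling and a fixed demand binary", {
  m <- makeToyModel(routeLengths = c(2, 3))
  dt <- makeDemandTask(m, "tgt_c")
  h <- buildMilp(dt$model, dt$task)
  n <- nrow(dt$model@reactions)
  expect_equal(h$n, n)
  expect_equal(length(h$binary), n)
  expect_equal(h$lb[h$n + h$demand], 1)       # demand binary on
  expect_equal(h$lb[h$demand], dt$task@epsilon)
  # y = 0 forces v = 0: fix a route binary off and check its optimal flux
  h2 <- minnet:::.milpAddRow(h, c(R1_1 = 1), -1L, 0)
  mn <- solveMin(h2)
  expect_equal(unname(mn@flux["R1_1"]), 0, tolerance = 1e-9)
  expect_false("R1_1" %in% mn@reactions)
})

test_that("infinite bounds demand a finite big-M cap", {
  m <- makeToyModel(routeLengths = 2)
  m@reactions$ub[2] <- Inf
  dt <- makeDemandTask(m, "tgt_c")
  expect_error(buildMilp(dt$model, dt$task, bigM = Inf), "big-M")
  expect_silent(h <- buildMilp(dt$model, dt$task, bigM = 1000))
  expect_true(all(is.finite(h$ub)) && all(is.finite(h$lb)))
})

test_that("the minimum network of a 2-vs-3-step race is the short route plus helpers", {
  m <- makeToyModel(routeLengths = c(2, 3))
  dt <- makeDemandTask(pruneBlocked(m), "tgt_c")
  mn <- solveMin(buildMilp(dt$model, dt$task))
  expect_true(mn@proven)
  expect_setequal(mn@reactions, c("UPT", "R1_1", "R1_2", "DM_tgt_c"))
  expect_equal(mn@size, 4L)
  # brute-force subset oracle agrees
  ex <- enumerateMinsExhaustive(dt$model, dt$task)
  expect_equal(attr(ex, "sStar"), 4L)
  expect_true(sameSetOfSets(ex, list(mn@reactions)))
})

test_that("a target that is itself taken up yields the two-reaction network", {
  mets <- data.frame(id = "a_c")
  m <- MetabolicModel(metabolites = mets,
                      reactions = data.frame(id = c("UPT_A", "SEC_A"),
                                             lb = 0, ub = 10),
                      S = matrix(c(1, -1), nrow = 1))
  dt <- makeDemandTask(m, "a_c")
  mn <- solveMin(buildMilp(dt$model, dt$task))
  expect_setequal(mn@reactions, c("UPT_A", "DM_a_c"))
  expect_equal(mn@size, 2L)
  ex <- enumerateMinsExhaustive(dt$model, dt$task)
  expect_true(sameSetOfSets(ex, list(mn@reactions)))
})

test_that("an unproducible task raises 'task not producible'", {
  m <- chainModel()                     # C cannot leave: demand on B fails too
  dt <- makeDemandTask(m, "C")
  # demand gives C an exit, so C itself becomes producible; block uptake
  m2 <- dt$model
  m2@reactions$ub[1] <- 0
  expect_error(solveMin(buildMilp(m2, dt$task)), "not producible")
  expect_error(enumerateMins(m2, dt$task), "not producible")
})

test_that("two equal disjoint routes give exactly two alternatives, then stop", {
  m <- makeToyModel(routeLengths = c(2, 2))
  dt <- makeDemandTask(m, "tgt_c")
  mins <- enumerateMins(dt$model, dt$task,
                        enumConfig(maxAlternatives = 5, diverge = 1,
                                   sizeSlack = 0))
  expect_length(mins, 2L)
  expect_false(attr(mins, "truncated"))
  sets <- minReactionSets(mins)
  expect_true(sameSetOfSets(sets, list(
    c("UPT", "R1_1", "R1_2", "DM_tgt_c"),
    c("UPT", "R2_1", "R2_2", "DM_tgt_c"))))
  expect_true(all(vapply(mins, function(x) x@optimal, logical(1))))
})

test_that("a diverge larger than s* stops after one network", {
  m <- makeToyModel(routeLengths = c(2, 2))
  dt <- makeDemandTask(m, "tgt_c")
  mins <- enumerateMins(dt$model, dt$task,
                        enumConfig(maxAlternatives = 5, diverge = 10))
  expect_length(mins, 1L)
})

test_that("size slack zero keeps all alternatives at s*; slack admits longer ones", {
  m <- makeToyModel(routeLengths = c(2, 3))
  dt <- makeDemandTask(m, "tgt_c")
  mins0 <- enumerateMins(dt$model, dt$task,
                         enumConfig(maxAlternatives = 10, sizeSlack = 0))
  expect_length(mins0, 1L)
  expect_true(all(vapply(mins0, function(x) x@size, integer(1)) == 4L))
  mins1 <- enumerateMins(dt$model, dt$task,
                         enumConfig(maxAlternatives = 10, sizeSlack = 1))
  expect_length(mins1, 2L)
  expect_equal(sort(vapply(mins1, function(x) x@size, integer(1))), c(4L, 5L))
  expect_equal(vapply(mins1, function(x) x@optimal, logical(1)),
               c(TRUE, FALSE))
})

test_that("pairwise divergence holds for the one-sided cut", {
  m <- makeToyModel(routeLengths = c(3, 3, 3, 3))
  dt <- makeDemandTask(m, "tgt_c")
  for (D in 1:3) {
    mins <- enumerateMins(dt$model, dt$task,
                          enumConfig(maxAlternatives = 10, diverge = D))
    sets <- minReactionSets(mins)
    if (length(sets) > 1)
      for (k in seq_len(length(sets) - 1))
        for (j in seq(k + 1, length(sets)))
          expect_gte(length(setdiff(sets[[k]], sets[[j]])), D)
  }
})

test_that("the symmetric cut enforces a symmetric difference of at least D", {
  m <- makeToyModel(routeLengths = c(2, 2, 2))
  dt <- makeDemandTask(m, "tgt_c")
  mins <- enumerateMins(dt$model, dt$task,
                        enumConfig(maxAlternatives = 10, diverge = 2,
                                   cutType = "symmetric"))
  sets <- minReactionSets(mins)
  expect_gte(length(sets), 2L)
  for (k in seq_len(length(sets) - 1))
    for (j in seq(k + 1, length(sets))) {
      sd <- length(union(setdiff(sets[[k]], sets[[j]]),
                         setdiff(sets[[j]], sets[[k]])))
      expect_gte(sd, 2)
    }
})

test_that("enumeration equals exhaustive search on small fixtures", {
  for (spec in smallToySpecs()[c(4, 6, 16, 18)]) {
    m <- pruneBlocked(buildToy(spec))
    dt <- makeDemandTask(m, "tgt_c")
    mins <- enumerateMins(dt$model, dt$task,
                          enumConfig(maxAlternatives = 100))
    ex <- enumerateMinsExhaustive(dt$model, dt$task)
    expect_true(sameSetOfSets(minReactionSets(mins), ex),
                info = paste(spec$routeLengths, collapse = ","))
  }
})

test_that("s* never decreases when a bound is tightened toward zero", {
  m <- makeToyModel(routeLengths = c(2, 3))
  dt <- makeDemandTask(m, "tgt_c")
  base <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 1))
  s0 <- attr(base, "sStar")
  # shutting the short route forces the longer one
  m2 <- dt$model
  m2@reactions$ub[m2@reactions$id == "R1_1"] <- 0
  harder <- enumerateMins(m2, dt$task, enumConfig(maxAlternatives = 1))
  expect_gte(attr(harder, "sStar"), s0)
  expect_equal(attr(harder, "sStar"), 5L)
})

test_that("flux witnesses are mass balanced and above the activity tolerance", {
  m <- makeToyModel(routeLengths = c(2, 2), reversibleFraction = 0.5,
                    seed = 5)
  dt <- makeDemandTask(m, "tgt_c")
  mins <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 10))
  S <- as.matrix(stoichiometry(dt$model))
  for (mn in mins) {
    expect_lt(max(abs(S %*% mn@flux)), 1e-6)
    expect_true(all(abs(mn@flux[mn@reactions]) > 1e-6))
    expect_gte(unname(mn@flux["DM_tgt_c"]), dt$task@epsilon - 1e-9)
  }
})

test_that("verifyMinimality accepts optimal networks and rejects padded or empty ones", {
  m <- makeToyModel(routeLengths = c(2, 3))
  dt <- makeDemandTask(m, "tgt_c")
  mn <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 1))[[1]]
  expect_true(verifyMinimality(dt$model, dt$task, mn))
  padded <- methods::new("MinNetwork", task = mn@task,
                         reactions = c(mn@reactions, "SEC"),
                         size = mn@size + 1L, flux = mn@flux,
                         optimal = FALSE, proven = TRUE)
  expect_false(verifyMinimality(dt$model, dt$task, padded))
  empty <- methods::new("MinNetwork", task = mn@task,
                        reactions = character(), size = 0L,
                        flux = mn@flux, optimal = FALSE, proven = TRUE)
  expect_false(verifyMinimality(dt$model, dt$task, empty))
})

test_that("repeated enumeration returns identical results in the same order", {
  m <- makeToyModel(routeLengths = c(2, 2, 2))
  dt <- makeDemandTask(m, "tgt_c")
  a <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 10))
  b <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 10))
  expect_identical(lapply(a, function(x) x@reactions),
                   lapply(b, function(x) x@reactions))
})

test_that("minimal networks serialise to the tab-delimited layout", {
  m <- makeToyModel(routeLengths = c(2, 2))
  dt <- makeDemandTask(m, "tgt_c")
  mins <- enumerateMins(dt$model, dt$task, enumConfig(maxAlternatives = 5))
  f <- tempfile()
  writeMins(mins, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(names(tab),
               c("task_id", "min_index", "size", "optimal", "reactions"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$size, c(4, 4))
  expect_true(all(grepl(";", tab$reactions)))
})
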