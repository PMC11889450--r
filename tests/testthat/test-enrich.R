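test_that("the multivariate hypergeometric pmf matches subset enumeration", {
  # N=10 universe with 3 up, 2 down; draw 4; P(a=3, b=0) = 5/210
  expect_equal(mvhgPmf(10, 3, 2, 4, 3, 0), 5 / 210, tolerance = 1e-12)
  # full enumeration over labelled subsets
  lab <- c(rep("u", 3), rep("d", 2), rep("n", 5))
  cnt <- 0L
  sub <- utils::combn(10, 4)
  for (j in seq_len(ncol(sub))) {
    s <- lab[sub[, j]]
    if (sum(s == "u") == 3 && sum(s == "d") == 0) cnt <- cnt + 1L
  }
  expect_equal(mvhgPmf(10, 3, 2, 4, 3, 0), cnt / ncol(sub))

  # degenerate universe: no regulated reactions
  expect_equal(mvhgPmf(10, 0, 0, 4, 0, 0), 1)
  expect_equal(mvhgPmf(10, 0, 0, 4, 1, 0), 0)

  # outside the support: zero, not an error
  expect_equal(mvhgPmf(10, 3, 2, 4, 5, 0), 0)
  expect_equal(mvhgPmf(10, 3, 2, 4, 0, 3), 0)
})

test_that("the pmf sums to one over its support", {
  set.seed(19)
  for (i in 1:20) {
    N <- sample(4:25, 1)
    Kup <- sample(0:(N - 1), 1)
    Kdown <- sample(0:(N - Kup), 1)
    n <- sample(1:N, 1)
    grid <- expand.grid(a = 0:n, b = 0:n)
    tot <- sum(mvhgPmf(N, Kup, Kdown, n, grid$a, grid$b))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("tail probabilities match the exhaustive subset oracle", {
  # N=4 with 2 up; drawing both up reactions in a size-2 draw: 1/6
  expect_equal(pUp(4, 2, 0, 2, 2, 0), 1 / 6, tolerance = 1e-12)
  expect_equal(pUp(4, 2, 0, 2, 2, 0), enumPUp(4, 2, 0, 2, 2, 0))
  # N=10, 3 up, 2 down, n=4, observed (3, 0): 5/210
  expect_equal(pUp(10, 3, 2, 4, 3, 0), 5 / 210, tolerance = 1e-12)
  expect_equal(pUp(10, 3, 2, 4, 3, 0), enumPUp(10, 3, 2, 4, 3, 0),
               tolerance = 1e-12)
  # mirrored case for the down tail
  expect_equal(pDown(10, 2, 3, 4, 0, 3), 5 / 210, tolerance = 1e-12)
  # whole support: probability one
  expect_equal(pUp(10, 3, 2, 4, 0, 4), 1)
  expect_equal(pDown(10, 3, 2, 4, 4, 0), 1)

  set.seed(23)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    Kup <- sample(1:(N - 2), 1)
    Kdown <- sample(0:(N - Kup - 1), 1)
    n <- sample(2:(N - 1), 1)
    kup <- sample(0:min(Kup, n), 1)
    kdown <- sample(0:min(Kdown, n), 1)
    expect_equal(pUp(N, Kup, Kdown, n, kup, kdown),
                 enumPUp(N, Kup, Kdown, n, kup, kdown), tolerance = 1e-12,
                 info = paste(N, Kup, Kdown, n, kup, kdown))
    # mirror symmetry between the two tails
    expect_equal(pDown(N, Kup, Kdown, n, kup, kdown),
                 pUp(N, Kdown, Kup, n, kdown, kup), tolerance = 1e-15)
  }
})

test_that("with no down-regulated reactions the up tail is classical hypergeometric", {
  for (N in c(20, 100, 1000)) {
    Kup <- round(N / 5); n <- round(N / 4)
    for (kup in c(0, 1, round(Kup / 2), min(Kup, n))) {
      expect_equal(pUp(N, Kup, 0, n, kup, 0),
                   stats::phyper(kup - 1, Kup, N - Kup, n,
                                 lower.tail = FALSE),
                   tolerance = 1e-12, info = paste(N, kup))
    }
  }
})

test_that("the up tail is non-increasing in the observed up count", {
  N <- 40; Kup <- 10; Kdown <- 8; n <- 12; kdown <- 3
  p <- vapply(0:min(Kup, n), function(k) pUp(N, Kup, Kdown, n, k, kdown),
              numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("scoring ranks enriched networks first with deterministic tie-breaks", {
  sets <- methods::new("RegulationSets",
                       universe = paste0("r", 1:10),
                       up = paste0("r", 1:3), down = paste0("r", 4:5),
                       mode = "foldchange", settings = list())
  mkMin <- function(rx) methods::new("MinNetwork", task = "t",
                                     reactions = rx,
                                     size = length(rx),
                                     flux = numeric(), optimal = TRUE,
                                     proven = TRUE)
  mins <- list(mkMin(c("r1", "r2", "r3", "r6")),   # strongly up
               mkMin(c("r4", "r5", "r6", "r7")),   # strongly down
               mkMin(c("r6", "r7", "r8", "r9")))   # neutral
  df <- scoreMins(mins, sets)
  expect_equal(df$rank[1], 1L)
  expect_equal(df$p_up[1], pUp(10, 3, 2, 4, 3, 0))
  expect_gt(df$p_up[3], df$p_up[1])
  # neutral network never beats the enriched one on either tail
  expect_gte(df$p_down[3], df$p_down[2])

  # identical networks tie and are ordered by index
  dfTie <- scoreMins(list(mins[[1]], mins[[1]]), sets)
  expect_equal(dfTie$rank, c(1L, 2L))
  expect_equal(dfTie$p_up[1], dfTie$p_up[2])

  # ranking by the down tail puts the down-regulated network first
  dfDown <- scoreMins(mins, sets, rankBy = "down")
  expect_equal(dfDown$rank[2], 1L)
})

test_that("scoring rejects out-of-universe reactions and handles empty input", {
  sets <- methods::new("RegulationSets", universe = c("r1", "r2"),
                       up = character(), down = character(),
                       mode = "foldchange", settings = list())
  bad <- methods::new("MinNetwork", task = "t", reactions = c("r1", "zz"),
                      size = 2L, flux = numeric(), optimal = TRUE,
                      proven = TRUE)
  expect_error(scoreMins(list(bad), sets), "outside the universe.*zz")
  # excluded helpers are tolerated
  ok <- scoreMins(list(bad), sets, exclude = "zz")
  expect_equal(ok$n, 1)
  expect_equal(nrow(scoreMins(list(), sets)), 0)
})

test_that("percentages and the optional FDR columns are consistent", {
  sets <- methods::new("RegulationSets", universe = paste0("r", 1:8),
                       up = c("r1", "r2"), down = "r3",
                       mode = "foldchange", settings = list())
  mk <- function(rx) methods::new("MinNetwork", task = "t", reactions = rx,
                                  size = length(rx), flux = numeric(),
                                  optimal = TRUE, proven = TRUE)
  df <- scoreMins(list(mk(c("r1", "r2", "r4")), mk(c("r3", "r4"))),
                  sets, fdr = TRUE)
  expect_equal(df$pct_up, 100 * df$k_up / df$n)
  expect_equal(df$pct_down, 100 * df$k_down / df$n)
  expect_equal(df$q_up, stats::p.adjust(df$p_up, "BH"))
  expect_true(all(c("q_up", "q_down") %in% names(df)))
})

test_that("tail probabilities agree with a Monte-Carlo oracle", {
  set.seed(77)
  cases <- list(c(N = 60, Kup = 15, Kdown = 10, n = 12, kup = 5, kdown = 2),
                c(N = 200, Kup = 40, Kdown = 30, n = 20, kup = 7, kdown = 3))
  for (cs in cases) {
    mc <- mcPUp(cs["N"], cs["Kup"], cs["Kdown"], cs["n"], cs["kup"],
                cs["kdown"], draws = 2e4)
    p <- pUp(cs["N"], cs["Kup"], cs["Kdown"], cs["n"], cs["kup"],
             cs["kdown"])
    expect_lt(abs(p - mc$p), 3 * mc$se + 1e-9)
  }
})
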