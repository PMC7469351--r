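test_that("coordinate files parse into region maps preserving file order", {
  ws <- write_fixture(c("A 0 0", "B 1 0", "C 0 1"))
  map <- read_regions(ws)
  expect_s3_class(map, "region_map")
  expect_equal(map$m, 3L)
  expect_equal(map$ids, c("A", "B", "C"))
  expect_equal(map$coords[2, ], c(1, 0))

  csv <- write_fixture(c("id,x,y", "r2,5,5", "r1,0,0"), ".csv")
  map2 <- read_regions(csv, header = TRUE)
  expect_equal(map2$ids, c("r2", "r1"))  # file order is canonical
})

test_that("malformed coordinate inputs fail with informative errors", {
  dup <- write_fixture(c("A 0 0", "A 1 0", "C 0 1"))
  expect_error(read_regions(dup), "duplicate region id: A")
  bad <- write_fixture(c("A 0 0", "B x 0"))
  expect_error(read_regions(bad), "row 2")
  expect_error(region_map("A", cbind(0, 0)), "at least 2")
  expect_error(region_map(c("A", "B"), rbind(c(0, 0), c(NA, 1))),
               "non-finite")
})

test_that("adjacency reads symmetrize either dialect and reject unknown ids", {
  map <- read_regions(write_fixture(c("A 0 0", "B 1 0", "C 0 1")))
  mat <- write_fixture(c("id A B C", "A 1 1 0", "B 0 1 0", "C 0 0 1"))
  m1 <- read_adjacency(mat, map)
  expect_equal(m1$nbrs, list(2L, 1L, integer()))  # diagonal ignored, A-B

  edge <- write_fixture(c("A B"))  # one direction only
  m2 <- read_adjacency(edge, map)
  expect_equal(m2$nbrs[[1]], 2L)
  expect_equal(m2$nbrs[[2]], 1L)

  expect_error(read_adjacency(write_fixture(c("A Z")), map),
               "unknown region")
  notsquare <- write_fixture(c("id A B C", "A 1 0 0", "B 0 1 0"))
  expect_error(read_adjacency(notsquare, map), "not square")
})

test_that("k-nearest-neighbor adjacency follows distance and id tie rules", {
  # three collinear points, k = 1: B is nearest to both A and C
  line <- region_map(c("A", "B", "C"), cbind(c(0, 1, 2), 0))
  adj <- derive_adjacency(line, 1L)
  expect_equal(adj$nbrs, list(2L, c(1L, 3L), 2L))

  # k = m - 1 saturates to the complete graph
  full <- derive_adjacency(line, 2L)
  expect_equal(lengths(full$nbrs), c(2L, 2L, 2L))

  # coincident centroids: deterministic choice by lexicographic id
  co <- region_map(c("A", "B", "C"), rbind(c(0, 0), c(0, 0), c(9, 9)))
  adj2 <- derive_adjacency(co, 1L)
  expect_equal(adj2$nbrs[[3]], 1L)  # C ties A/B at equal distance -> A
})

test_that("knn graphs on random clouds are connected or the disconnection is reported", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    map <- region_map(sprintf("r%02d", 1:n), cbind(runif(n), runif(n)))
    warned <- FALSE
    adj <- withCallingHandlers(
      derive_adjacency(map, 2L),
      warning = function(w) {
        warned <<- grepl("disconnected", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    comp <- igraph::components(multiscan:::map_graph(adj))
    expect_true(comp$no == 1L || warned)
  }
})

test_that("indirect standardization allocates cases proportionally and conserves totals", {
  expect_equal(expected_counts(c(1, 1, 2), 100), c(25, 25, 50))
  # two strata with rates 0.1 and 0.2, each region 10 persons per stratum
  pop <- matrix(10, nrow = 2, ncol = 2)
  expect_equal(expected_counts(pop, cases = c(0.1 * 20, 0.2 * 20)), c(3, 3))
  # degenerate: one region holds everything
  expect_equal(expected_counts(c(5, 0, 0), 42), c(42, 0, 0))
  expect_error(expected_counts(c(0, 0), 10), "zero total population")

  set.seed(1)
  for (rep in 1:20) {
    pop <- matrix(runif(12, 1, 100), nrow = 4)
    cases <- round(runif(3, 5, 50))
    expect_equal(sum(expected_counts(pop, cases)), sum(cases))
  }
})

test_that("zero-expectation regions are dropped with a warning and m reduced", {
  map <- derive_adjacency(
    region_map(c("A", "B", "C", "D"), cbind(1:4, 0)), 1L)
  expect_warning(
    red <- drop_zero_expected(map, c(1, 2, 3, 4), c(1, 0, 2, 2)),
    "zero baseline"
  )
  expect_equal(red$map$m, 3L)
  expect_equal(red$map$ids, c("A", "C", "D"))
  expect_equal(red$data$observed, c(1, 3, 4))
})

test_that("case data validates counts and records the observed total", {
  d <- case_data(c(0, 3, 2), c(1, 2, 2))
  expect_equal(d$total_observed, 5)
  expect_error(case_data(c(-1, 1), c(1, 1)), "non-negative")
  expect_error(case_data(c(1.5, 1), c(1, 1)), "non-negative integers")
  expect_error(case_data(c(1, 1), c(1, 0)), "positive")
})

test_that("case files match regions by id against canonical order", {
  map <- read_regions(write_fixture(c("A 0 0", "B 1 0", "C 0 1")))
  cas <- write_fixture(c("C 7", "A 1", "B 3"))
  expect_equal(read_cases(cas, map), c(A = 1, B = 3, C = 7))
  expect_error(read_cases(write_fixture(c("A 1", "B 2")), map), "missing")
})
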